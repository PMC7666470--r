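// Local De Bruijn assembly of small read clusters.
//
// All reads are expected in a single (reference-forward) orientation, so the
// graph is built on plain k-mers, not canonical ones. Unitigs (maximal
// unbranched paths over k-mers kept at >= min_cov) are emitted as contigs and
// every read is re-placed onto the contigs by exact k-mer seeding plus a
// mismatch-tolerant diagonal check.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <set>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int base2bits(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

// Collect all k-mers of s as 2-bit codes; kmer containing non-ACGT is skipped.
// Emits (position, code) pairs through a callback-like vector fill.
static void for_each_kmer(const std::string& s, int k,
                          std::vector<std::pair<int, uint64_t> >& out) {
    out.clear();
    const int n = (int) s.size();
    if (n < k) return;
    uint64_t code = 0;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int valid = 0;
    for (int i = 0; i < n; ++i) {
        int b = base2bits(s[i]);
        if (b < 0) { valid = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t) b) & mask;
        if (++valid >= k) out.push_back(std::make_pair(i - k + 1, code));
    }
}

// [[Rcpp::export]]
List cpp_assemble(CharacterVector reads, int k, int min_cov,
                  double max_mm_frac, int max_contig_len) {
    if (k < 3 || k > 31) stop("k must be in [3, 31]");
    const int nreads = reads.size();

    std::unordered_map<uint64_t, int> counts;
    std::vector<std::pair<int, uint64_t> > buf;
    std::vector<std::string> rs(nreads);
    for (int r = 0; r < nreads; ++r) {
        rs[r] = as<std::string>(reads[r]);
        for_each_kmer(rs[r], k, buf);
        for (size_t i = 0; i < buf.size(); ++i) counts[buf[i].second]++;
    }

    std::unordered_set<uint64_t> kept;
    kept.reserve(counts.size());
    for (std::unordered_map<uint64_t, int>::iterator it = counts.begin();
         it != counts.end(); ++it)
        if (it->second >= min_cov) kept.insert(it->first);

    const uint64_t mask = (1ULL << (2 * k)) - 1;
    const uint64_t prefmask = (1ULL << (2 * (k - 1))) - 1;

    // successors/predecessors within the kept set
    std::vector<uint64_t> succ_buf(4), pred_buf(4);
    struct Nbr {
        const std::unordered_set<uint64_t>& kept;
        uint64_t mask, prefmask;
        int k;
        Nbr(const std::unordered_set<uint64_t>& s, uint64_t m, uint64_t pm, int kk)
            : kept(s), mask(m), prefmask(pm), k(kk) {}
        int succ(uint64_t x, uint64_t* out) const {
            int n = 0;
            uint64_t base = (x & prefmask) << 2;
            for (uint64_t b = 0; b < 4; ++b) {
                uint64_t y = base | b;
                if (kept.count(y)) out[n++] = y;
            }
            return n;
        }
        int pred(uint64_t x, uint64_t* out) const {
            int n = 0;
            uint64_t suf = x >> 2;
            for (uint64_t b = 0; b < 4; ++b) {
                uint64_t y = (b << (2 * (k - 1))) | suf;
                if (kept.count(y)) out[n++] = y;
            }
            return n;
        }
    } nbr(kept, mask, prefmask, k);

    // ---- unitig extraction (used for tip pruning rounds and final output)
    struct Unitig { std::vector<uint64_t> path; };
    std::vector<Unitig> unitigs;
    uint64_t nb[4], nb2[4];

    // collect maximal unbranched paths over the kept set
    // (a kmer starts a unitig if its in-degree != 1 or its unique
    // predecessor branches out; leftover components are cycles)
    const int maxlen = max_contig_len;
    struct Extract {
        static void run(const std::unordered_set<uint64_t>& kept,
                        const Nbr& nbr, int maxlen,
                        std::vector<Unitig>& out) {
            out.clear();
            std::unordered_set<uint64_t> visited;
            visited.reserve(kept.size());
            uint64_t nb[4], nb2[4];
            for (std::unordered_set<uint64_t>::const_iterator it = kept.begin();
                 it != kept.end(); ++it) {
                uint64_t x = *it;
                if (visited.count(x)) continue;
                int ind = nbr.pred(x, nb);
                bool start = (ind != 1);
                if (!start) start = (nbr.succ(nb[0], nb2) > 1);
                if (!start) continue;
                Unitig u;
                uint64_t cur = x;
                while (true) {
                    u.path.push_back(cur);
                    visited.insert(cur);
                    if ((int) u.path.size() > maxlen) break;
                    if (nbr.succ(cur, nb) != 1) break;
                    uint64_t nxt = nb[0];
                    if (visited.count(nxt)) break;
                    if (nbr.pred(nxt, nb2) != 1) break;
                    cur = nxt;
                }
                out.push_back(u);
            }
            for (std::unordered_set<uint64_t>::const_iterator it = kept.begin();
                 it != kept.end(); ++it) {   // pure cycles, unrolled once
                uint64_t x = *it;
                if (visited.count(x)) continue;
                Unitig u;
                uint64_t cur = x;
                while (!visited.count(cur)) {
                    u.path.push_back(cur);
                    visited.insert(cur);
                    if (nbr.succ(cur, nb) != 1) break;
                    cur = nb[0];
                    if ((int) u.path.size() > maxlen) break;
                }
                out.push_back(u);
            }
        }
    };

    // tip pruning: a unitig that dead-ends on one side, hangs off a branch
    // on the other, and is shorter than 2k is an artifact of sequencing
    // error or a stray read; removing it restores the unbranched main path
    for (int round = 0; round < 3; ++round) {
        Extract::run(kept, nbr, maxlen, unitigs);
        bool removed = false;
        for (size_t ui = 0; ui < unitigs.size(); ++ui) {
            const std::vector<uint64_t>& p = unitigs[ui].path;
            if ((int) (p.size() + k - 1) >= 2 * k) continue;
            int ind = nbr.pred(p.front(), nb);
            int outd = nbr.succ(p.back(), nb2);
            bool deadStart = (ind == 0), deadEnd = (outd == 0);
            if (deadStart == deadEnd) continue;  // isolated or internal
            // the attached side must be a true branch (an alternative exists)
            bool branching = false;
            if (deadStart) {
                // successor node has other predecessors
                for (int j = 0; j < outd; ++j)
                    if (nbr.pred(nb2[j], nb) > 1) branching = true;
            } else {
                for (int j = 0; j < ind; ++j)
                    if (nbr.succ(nb[j], nb2) > 1) branching = true;
            }
            if (!branching) continue;
            for (size_t i = 0; i < p.size(); ++i) kept.erase(p[i]);
            removed = true;
        }
        if (!removed) break;
    }
    Extract::run(kept, nbr, maxlen, unitigs);

    std::vector<std::string> contigs;
    std::vector<double> contig_cov;
    for (size_t ui = 0; ui < unitigs.size(); ++ui) {
        const std::vector<uint64_t>& path = unitigs[ui].path;
        std::string seq;
        seq.reserve(path.size() + k - 1);
        for (int i = k - 1; i >= 0; --i)
            seq.push_back(BITS2BASE[(path[0] >> (2 * i)) & 3]);
        double cov = counts[path[0]];
        for (size_t i = 1; i < path.size(); ++i) {
            seq.push_back(BITS2BASE[path[i] & 3]);
            cov += counts[path[i]];
        }
        contigs.push_back(seq);
        contig_cov.push_back(cov / (double) path.size());
    }

    // read placement: unique k-mer -> (contig, offset) index over all contigs
    std::unordered_map<uint64_t, std::pair<int, int> > index;
    std::unordered_set<uint64_t> dup;
    for (size_t c = 0; c < contigs.size(); ++c) {
        for_each_kmer(contigs[c], k, buf);
        for (size_t i = 0; i < buf.size(); ++i) {
            uint64_t code = buf[i].second;
            if (dup.count(code)) continue;
            if (index.count(code)) { index.erase(code); dup.insert(code); continue; }
            index[code] = std::make_pair((int) c, buf[i].first);
        }
    }

    std::vector<int> p_read, p_contig, p_offset, p_mm, p_ovl;
    std::set<std::pair<int, int> > tried;
    for (int r = 0; r < nreads; ++r) {
        for_each_kmer(rs[r], k, buf);
        int best_c = -1, best_off = 0, best_mm = 0, best_ovl = -1;
        tried.clear();
        // evaluate every distinct (contig, offset) candidate; a read spanning
        // a unitig boundary must be credited to the contig it overlaps most
        for (size_t i = 0; i < buf.size(); ++i) {
            std::unordered_map<uint64_t, std::pair<int, int> >::iterator hit =
                index.find(buf[i].second);
            if (hit == index.end()) continue;
            int c = hit->second.first;
            int off = hit->second.second - buf[i].first;  // read start on contig
            if (!tried.insert(std::make_pair(c, off)).second) continue;
            const std::string& ctg = contigs[c];
            int rl = (int) rs[r].size();
            int from = std::max(0, -off);
            int to = std::min(rl, (int) ctg.size() - off);
            int ovl = to - from, mm = 0;
            if (ovl < k) continue;
            for (int j = from; j < to; ++j)
                if (rs[r][j] != ctg[off + j]) ++mm;
            if (mm <= (int) (max_mm_frac * ovl) &&
                (best_c < 0 || ovl - 5 * mm > best_ovl - 5 * best_mm)) {
                best_c = c; best_off = off; best_mm = mm; best_ovl = ovl;
            }
        }
        if (best_c >= 0) {
            p_read.push_back(r + 1);
            p_contig.push_back(best_c + 1);
            p_offset.push_back(best_off);
            p_mm.push_back(best_mm);
            p_ovl.push_back(best_ovl);
        }
    }

    return List::create(
        _["contigs"] = wrap(contigs),
        _["coverage"] = wrap(contig_cov),
        _["placements"] = DataFrame::create(
            _["read"] = wrap(p_read), _["contig"] = wrap(p_contig),
            _["offset"] = wrap(p_offset), _["mismatches"] = wrap(p_mm),
            _["overlap"] = wrap(p_ovl)));
}
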