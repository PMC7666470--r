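// Alignment primitives used by breakpoint refinement, read-to-allele
// assignment and mechanism detection: a banded affine-gap prefix aligner (for
// the contig split scan), a plain Smith-Waterman, seeded diagonal scoring for
// bulk read assignment, exact k-mer hit enumeration and a tandem-period scan.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int b2b(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static std::string revcomp_str(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) {
        switch (r[i]) {
        case 'A': case 'a': r[i] = 'T'; break;
        case 'C': case 'c': r[i] = 'G'; break;
        case 'G': case 'g': r[i] = 'C'; break;
        case 'T': case 't': r[i] = 'A'; break;
        default: r[i] = 'N';
        }
    }
    return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
    CharacterVector out(x.size());
    for (int i = 0; i < x.size(); ++i)
        out[i] = revcomp_str(as<std::string>(x[i]));
    return out;
}

// Banded affine-gap alignment of prefixes of `q` against `t` anchored so that
// q[0] pairs with t[t0] (0-based). Both alignment ends toward the right are
// free. Returns the prefix length of q (the split point), the matching t end,
// match/mismatch counts on the best path, and its score. Ties in score prefer
// the longer q prefix. Scores: match +1, mismatch -4, gap open -6, ext -1.
// [[Rcpp::export]]
List cpp_prefix_split(std::string q, std::string t, int t0, int band) {
    const int n = (int) q.size();
    const int m = (int) t.size();
    const double NEG = -1e9;
    const double MATCH = 1, MISM = -4, GO = -6, GE = -1;
    const int W = 2 * band + 1;

    // DP over i = 0..n (q prefix length); j offset from diagonal in [-band, band]
    std::vector<double> M(W, NEG), X(W, NEG), Y(W, NEG);
    std::vector<double> Mn(W), Xn(W), Yn(W);
    std::vector<int> Mm(W, 0), Xm(W, 0), Ym(W, 0);        // matches on path
    std::vector<int> Mmm(W, 0), Xmm(W, 0), Ymm(W, 0);     // mismatches on path
    std::vector<int> Mn_m(W), Xn_m(W), Yn_m(W), Mn_mm(W), Xn_mm(W), Yn_mm(W);

    // i = 0 row: only gaps in t (X = gap in q consuming t) allowed from origin
    int center0 = band;
    M[center0] = 0;  // empty alignment at (0, t0)
    for (int d = 1; d <= band; ++d) {
        // consumed d bases of t with a gap
        M[center0 + d] = NEG;
        X[center0 + d] = GO + GE * (d - 1);
    }

    double best = -1; int best_i = 0, best_j = 0, best_ma = 0, best_mm = 0;

    for (int i = 1; i <= n; ++i) {
        std::fill(Mn.begin(), Mn.end(), NEG);
        std::fill(Xn.begin(), Xn.end(), NEG);
        std::fill(Yn.begin(), Yn.end(), NEG);
        for (int w = 0; w < W; ++w) {
            int j = i + (w - band);  // t bases consumed
            if (j < 0 || t0 + j > m) continue;
            // M: q[i-1] vs t[t0 + j - 1]
            if (j >= 1) {
                double diag_best = NEG; int dm = 0, dmm = 0;
                // previous cell (i-1, j-1) has same offset w
                if (M[w] > diag_best) { diag_best = M[w]; dm = Mm[w]; dmm = Mmm[w]; }
                if (X[w] > diag_best) { diag_best = X[w]; dm = Xm[w]; dmm = Xmm[w]; }
                if (Y[w] > diag_best) { diag_best = Y[w]; dm = Ym[w]; dmm = Ymm[w]; }
                if (diag_best > NEG / 2) {
                    bool is_match = (b2b(q[i - 1]) >= 0 &&
                                     b2b(q[i - 1]) == b2b(t[t0 + j - 1]));
                    Mn[w] = diag_best + (is_match ? MATCH : MISM);
                    Mn_m[w] = dm + (is_match ? 1 : 0);
                    Mn_mm[w] = dmm + (is_match ? 0 : 1);
                }
            }
            // X: gap in q (consume t base), from (i, j-1) -> offset w-1 in same row
            if (w >= 1) {
                double o = std::max(Mn[w - 1] + GO, Xn[w - 1] + GE);
                if (o > NEG / 2) {
                    Xn[w] = o;
                    if (Mn[w - 1] + GO >= Xn[w - 1] + GE) {
                        Xn_m[w] = Mn_m[w - 1]; Xn_mm[w] = Mn_mm[w - 1];
                    } else { Xn_m[w] = Xn_m[w - 1]; Xn_mm[w] = Xn_mm[w - 1]; }
                }
            }
            // Y: gap in t (consume q base), from (i-1, j) -> offset w+1 previous row
            if (w + 1 < W) {
                double o = std::max(M[w + 1] + GO, Y[w + 1] + GE);
                if (o > NEG / 2) {
                    Yn[w] = o;
                    if (M[w + 1] + GO >= Y[w + 1] + GE) {
                        Yn_m[w] = Mm[w + 1]; Yn_mm[w] = Mmm[w + 1];
                    } else { Yn_m[w] = Ym[w + 1]; Yn_mm[w] = Ymm[w + 1]; }
                }
            }
            double cell = std::max(Mn[w], std::max(Xn[w], Yn[w]));
            if (cell >= best) {  // >= : prefer longer prefix on ties
                best = cell; best_i = i; best_j = j;
                if (Mn[w] >= Xn[w] && Mn[w] >= Yn[w]) { best_ma = Mn_m[w]; best_mm = Mn_mm[w]; }
                else if (Xn[w] >= Yn[w]) { best_ma = Xn_m[w]; best_mm = Xn_mm[w]; }
                else { best_ma = Yn_m[w]; best_mm = Yn_mm[w]; }
            }
        }
        M.swap(Mn); X.swap(Xn); Y.swap(Yn);
        Mm.swap(Mn_m); Xm.swap(Xn_m); Ym.swap(Yn_m);
        Mmm.swap(Mn_mm); Xmm.swap(Xn_mm); Ymm.swap(Yn_mm);
    }

    return List::create(_["split"] = best_i,          // flank length on q
                        _["t_end"] = t0 + best_j,     // 0-based end-exclusive on t
                        _["score"] = best,
                        _["matches"] = best_ma,
                        _["mismatches"] = best_mm);
}

// Plain affine-gap Smith-Waterman; returns the best score, 1-based end
// coordinates on both sequences and the length/matches of the best segment.
// [[Rcpp::export]]
List cpp_sw_affine(std::string a, std::string b,
                   double match = 1, double mism = -4,
                   double go = -6, double ge = -1) {
    const int n = (int) a.size(), m = (int) b.size();
    std::vector<double> H(m + 1, 0), E(m + 1, 0), Hprev(m + 1, 0);
    std::vector<int> L(m + 1, 0), Lprev(m + 1, 0), ML(m + 1, 0), MLprev(m + 1, 0);
    double best = 0; int bi = 0, bj = 0, blen = 0, bmatch = 0;
    for (int i = 1; i <= n; ++i) {
        std::swap(H, Hprev); std::swap(L, Lprev); std::swap(ML, MLprev);
        double F = 0; int Flen = 0, Fm = 0;
        H[0] = 0; L[0] = 0; ML[0] = 0; E[0] = 0;
        std::vector<double>& Ev = E;
        for (int j = 1; j <= m; ++j) {
            bool ism = (b2b(a[i - 1]) >= 0 && b2b(a[i - 1]) == b2b(b[j - 1]));
            double diag = Hprev[j - 1] + (ism ? match : mism);
            double e = std::max(H[j - 1] + go, Ev[j - 1] + ge);
            double f = std::max(Hprev[j] + go, F + ge);
            Ev[j] = e; F = f;
            double h = std::max(0.0, std::max(diag, std::max(e, f)));
            int len, mt;
            if (h == 0) { len = 0; mt = 0; }
            else if (h == diag) { len = Lprev[j - 1] + 1; mt = MLprev[j - 1] + (ism ? 1 : 0); }
            else if (h == e) { len = L[j - 1] + 1; mt = ML[j - 1]; }
            else { len = Lprev[j] + 1; mt = MLprev[j]; }
            H[j] = h; L[j] = len; ML[j] = mt;
            if (h > best) { best = h; bi = i; bj = j; blen = len; bmatch = mt; }
        }
    }
    return List::create(_["score"] = best, _["a_end"] = bi, _["b_end"] = bj,
                        _["length"] = blen, _["matches"] = bmatch);
}

// Exact k-mer hits of query in target (both plain strings); query k-mers are
// indexed (up to max_per per k-mer), target is scanned once.
// Returns 0-based positions.
// [[Rcpp::export]]
DataFrame cpp_kmer_hits(std::string query, std::string target, int k,
                        int step = 1, int max_per = 8) {
    std::unordered_map<uint64_t, std::vector<int> > idx;
    const uint64_t mask = (1ULL << (2 * k)) - 1;
    uint64_t code = 0; int valid = 0;
    for (int i = 0; i < (int) query.size(); ++i) {
        int b = b2b(query[i]);
        if (b < 0) { valid = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t) b) & mask;
        if (++valid >= k) {
            int pos = i - k + 1;
            if (pos % step == 0) {
                std::vector<int>& v = idx[code];
                if ((int) v.size() < max_per) v.push_back(pos);
            }
        }
    }
    std::vector<int> qpos, tpos;
    code = 0; valid = 0;
    for (int i = 0; i < (int) target.size(); ++i) {
        int b = b2b(target[i]);
        if (b < 0) { valid = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t) b) & mask;
        if (++valid >= k) {
            std::unordered_map<uint64_t, std::vector<int> >::iterator it =
                idx.find(code);
            if (it != idx.end()) {
                for (size_t j = 0; j < it->second.size(); ++j) {
                    qpos.push_back(it->second[j]);
                    tpos.push_back(i - k + 1);
                }
            }
        }
    }
    return DataFrame::create(_["qpos"] = wrap(qpos), _["tpos"] = wrap(tpos));
}

struct DiagHit { double score; int a_start, a_end; };

// Best-scoring ungapped segment on diagonal d (b_pos = a_pos + d), Kadane-style.
static DiagHit diag_best(const std::string& a, const std::string& b, int d,
                         double match, double mism) {
    int from = std::max(0, -d);
    int to = std::min((int) a.size(), (int) b.size() - d);
    DiagHit best; best.score = 0; best.a_start = 0; best.a_end = 0;
    double cur = 0; int cur_start = from;
    for (int i = from; i < to; ++i) {
        bool ism = (b2b(a[i]) >= 0 && b2b(a[i]) == b2b(b[i + d]));
        cur += ism ? match : mism;
        if (cur <= 0) { cur = 0; cur_start = i + 1; }
        else if (cur > best.score) {
            best.score = cur; best.a_start = cur_start; best.a_end = i + 1;
        }
    }
    return best;
}

struct AlleleIndex {
    std::unordered_map<uint64_t, std::vector<int> > idx;
    int k;
    void build(const std::string& s, int kk, int max_per = 16) {
        k = kk;
        const uint64_t mask = (1ULL << (2 * k)) - 1;
        uint64_t code = 0; int valid = 0;
        for (int i = 0; i < (int) s.size(); ++i) {
            int b = b2b(s[i]);
            if (b < 0) { valid = 0; code = 0; continue; }
            code = ((code << 2) | (uint64_t) b) & mask;
            if (++valid >= k) {
                std::vector<int>& v = idx[code];
                if ((int) v.size() < max_per) v.push_back(i - k + 1);
            }
        }
    }
};

// Best local score of `read` against allele `s` using seeded ungapped
// diagonals only; returns score and allele-interval of the best segment.
static void best_local(const std::string& read, const std::string& s,
                       const AlleleIndex& ai, double& score,
                       int& s_start, int& s_end) {
    const int k = ai.k;
    const uint64_t mask = (1ULL << (2 * k)) - 1;
    uint64_t code = 0; int valid = 0;
    std::vector<int> diags;
    for (int i = 0; i < (int) read.size(); ++i) {
        int b = b2b(read[i]);
        if (b < 0) { valid = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t) b) & mask;
        if (++valid >= k) {
            std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
                ai.idx.find(code);
            if (it != ai.idx.end()) {
                int qp = i - k + 1;
                for (size_t j = 0; j < it->second.size(); ++j)
                    diags.push_back(it->second[j] - qp);
            }
        }
    }
    std::sort(diags.begin(), diags.end());
    diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
    score = 0; s_start = 0; s_end = 0;
    for (size_t j = 0; j < diags.size() && j < 24; ++j) {
        DiagHit h = diag_best(read, s, diags[j], 1.0, -4.0);
        if (h.score > score) {
            score = h.score;
            s_start = h.a_start + diags[j];
            s_end = h.a_end + diags[j];
        }
    }
}

// Full Smith-Waterman upgrade of a diagonal result (used only when the
// seeded score could change the assignment decision).
static void sw_upgrade(const std::string& read, const std::string& s,
                       double& score, int& s_start, int& s_end) {
    List sw = cpp_sw_affine(read, s);
    double sc = as<double>(sw["score"]);
    if (sc > score) {
        score = sc;
        s_end = as<int>(sw["b_end"]);
        s_start = s_end - as<int>(sw["length"]);  // approximate (gaps)
    }
}

// Assign each read to the reference or insertion allele. A read supports an
// allele when its best local alignment beats the other allele's by >= margin
// AND the winning alignment spans an allele-distinguishing junction with
// >= min_overlap bases on each side:
//   ref allele:  the breakpoint bp_ref;
//   ins allele:  either phase-change point (ins_start or ins_end).
// Reads lying entirely inside the insertion are not counted, so the
// read-depth ratio does not scale with insertion length.
// Returns 0 = ambiguous, 1 = ref, 2 = alt, plus both scores.
// [[Rcpp::export]]
List cpp_assign_reads(CharacterVector reads, std::string ref_allele,
                      std::string ins_allele, int k, double margin,
                      int min_overlap, int bp_ref, int ins_start, int ins_end) {
    AlleleIndex ri, ii;
    ri.build(ref_allele, k);
    ii.build(ins_allele, k);
    int n = reads.size();
    IntegerVector call(n);
    NumericVector sref(n), salt(n);
    for (int r = 0; r < n; ++r) {
        std::string fwd = as<std::string>(reads[r]);
        std::string rev = revcomp_str(fwd);
        double bs_ref = 0, bs_alt = 0;
        int ref_s = 0, ref_e = 0, alt_s = 0, alt_e = 0;
        for (int o = 0; o < 2; ++o) {
            const std::string& rd = o ? rev : fwd;
            double sc; int s0, s1;
            best_local(rd, ref_allele, ri, sc, s0, s1);
            if (sc > bs_ref) { bs_ref = sc; ref_s = s0; ref_e = s1; }
            best_local(rd, ins_allele, ii, sc, s0, s1);
            if (sc > bs_alt) { bs_alt = sc; alt_s = s0; alt_e = s1; }
        }
        // a full gapped alignment is only needed when the seeded scores
        // leave the decision open: either the read matched neither allele
        // convincingly, or the two scores are close to the margin; a read
        // with one strong seeded hit and a distant runner-up keeps its
        // assignment under any refinement of the weaker score
        double rl = (double) fwd.size();
        if ((bs_ref < 0.6 * rl && bs_alt < 0.6 * rl) ||
            std::fabs(bs_ref - bs_alt) < margin + 10) {
            for (int o = 0; o < 2; ++o) {
                const std::string& rd = o ? rev : fwd;
                sw_upgrade(rd, ref_allele, bs_ref, ref_s, ref_e);
                sw_upgrade(rd, ins_allele, bs_alt, alt_s, alt_e);
            }
        }
        sref[r] = bs_ref; salt[r] = bs_alt;
        int res = 0;
        if (bs_ref - bs_alt >= margin) {
            if (ref_s <= bp_ref - min_overlap && ref_e >= bp_ref + min_overlap)
                res = 1;
        } else if (bs_alt - bs_ref >= margin) {
            bool leftJ = alt_s <= ins_start - min_overlap &&
                         alt_e >= ins_start + min_overlap;
            bool rightJ = alt_s <= ins_end - min_overlap &&
                          alt_e >= ins_end + min_overlap;
            if (leftJ || rightJ) res = 2;
        }
        call[r] = res;
    }
    return List::create(_["call"] = call, _["score_ref"] = sref,
                        _["score_alt"] = salt);
}

// Tandem-period scan: for each period p in 1..pmax, the fraction of the
// sequence consistent with tandemness of period p, i.e.
// (#\{i >= p : s[i] == s[i-p]\} + p) / n.
// [[Rcpp::export]]
NumericVector cpp_tandem_scan(std::string s, int pmax) {
    const int n = (int) s.size();
    pmax = std::min(pmax, n - 1);
    NumericVector out(std::max(pmax, 0));
    for (int p = 1; p <= pmax; ++p) {
        int m = 0;
        for (int i = p; i < n; ++i)
            if (s[i] == s[i - p]) ++m;
        out[p - 1] = (double) (m + p) / (double) n;
    }
    return out;
}

// Count matching bases between a[a0..a0+len) and b[b0..b0+len).
// [[Rcpp::export]]
IntegerVector cpp_diag_matches(std::string a, std::string b, int a0, int b0,
                               int len) {
    int m = 0, valid = 0;
    for (int i = 0; i < len; ++i) {
        if (a0 + i >= (int) a.size() || b0 + i >= (int) b.size()) break;
        ++valid;
        if (a[a0 + i] == b[b0 + i]) ++m;
    }
    return IntegerVector::create(m, valid);
}
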