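// Small helpers for the read simulator: bulk substitution injection (error
// positions and offsets are drawn in R so that everything is governed by the
// R RNG) and a minimal FASTQ writer.

#include <Rcpp.h>
#include <fstream>
#include <string>

using namespace Rcpp;

// Apply substitutions: read i (1-based), position pos (1-based), shift in 1..3
// selecting one of the three alternative bases. Non-ACGT bases are left alone.
// [[Rcpp::export]]
CharacterVector cpp_apply_subs(CharacterVector seqs, IntegerVector read,
                               IntegerVector pos, IntegerVector shift) {
    static const char* BASES = "ACGT";
    std::vector<std::string> v(seqs.size());
    for (int i = 0; i < seqs.size(); ++i) v[i] = as<std::string>(seqs[i]);
    for (int i = 0; i < read.size(); ++i) {
        std::string& s = v[read[i] - 1];
        int p = pos[i] - 1;
        if (p < 0 || p >= (int) s.size()) continue;
        int b;
        switch (s[p]) {
        case 'A': case 'a': b = 0; break;
        case 'C': case 'c': b = 1; break;
        case 'G': case 'g': b = 2; break;
        case 'T': case 't': b = 3; break;
        default: continue;
        }
        s[p] = BASES[(b + shift[i]) & 3];
    }
    return wrap(v);
}

// [[Rcpp::export]]
void cpp_write_fastq(CharacterVector names, CharacterVector seqs,
                     std::string path, char qual = 'I') {
    std::ofstream out(path.c_str());
    if (!out) stop("cannot open '%s' for writing", path.c_str());
    for (int i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        out << '@' << as<std::string>(names[i]) << '\n'
            << s << '\n'
            << "+\n"
            << std::string(s.size(), qual) << '\n';
    }
    out.close();
}
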