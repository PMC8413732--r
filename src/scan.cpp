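#include <Rcpp.h>
using namespace Rcpp;

// Watson-Crick pairing of a piRNA base (read 5'->3') against a target base
// taken from the antiparallel strand. Ambiguous bases never pair.
static inline bool pairs_wc(char a, char b) {
    switch (a) {
    case 'A': return b == 'T';
    case 'C': return b == 'G';
    case 'G': return b == 'C';
    case 'T': return b == 'A';
    default:  return false;
    }
}

// Scan every start position of `target` for an antiparallel duplex with
// `window` (the piRNA 5' window). Window position j (0-based) pairs with
// target position s + w - 1 - j. `anchor` forces a perfect pair at window
// position 0 (the piRNA 5' nucleotide).
// [[Rcpp::export]]
List cpp_find_sites(std::string window, std::string target,
                    int max_mm, bool anchor) {
    const int w = (int) window.size();
    const int L = (int) target.size();
    std::vector<int> starts;
    std::vector<int> mms;
    for (int s = 0; s + w <= L; ++s) {
        if (anchor && !pairs_wc(window[0], target[s + w - 1])) continue;
        int mm = 0;
        bool ok = true;
        for (int j = 0; j < w; ++j) {
            if (!pairs_wc(window[j], target[s + w - 1 - j])) {
                if (++mm > max_mm) { ok = false; break; }
            }
        }
        if (ok) { starts.push_back(s); mms.push_back(mm); }
    }
    return List::create(_["start"] = wrap(starts),
                        _["mismatches"] = wrap(mms));
}

// Best substring match of each read inside a set of references with at most
// `max_mm` Hamming mismatches. References must be supplied sorted by id:
// ties on mismatch count resolve to the earliest reference, and within one
// reference to the smallest offset. Returns an n x 2 matrix of
// (1-based reference index | NA, mismatch count | NA).
// [[Rcpp::export]]
IntegerMatrix cpp_match_class(CharacterVector reads, CharacterVector refs,
                              int max_mm) {
    const int n = reads.size();
    const int m = refs.size();
    std::vector<std::string> ref_s(m);
    for (int k = 0; k < m; ++k) ref_s[k] = as<std::string>(refs[k]);
    IntegerMatrix out(n, 2);
    for (int i = 0; i < n; ++i) {
        std::string rd = as<std::string>(reads[i]);
        const int lr = (int) rd.size();
        int best_ref = -1, best_mm = max_mm + 1;
        for (int k = 0; k < m && best_mm > 0; ++k) {
            const std::string &rf = ref_s[k];
            const int L = (int) rf.size();
            for (int s = 0; s + lr <= L; ++s) {
                int mm = 0;
                bool ok = true;
                for (int j = 0; j < lr; ++j) {
                    if (rd[j] != rf[s + j]) {
                        if (++mm >= best_mm || mm > max_mm) { ok = false; break; }
                    }
                }
                if (ok && mm < best_mm) {
                    best_mm = mm;
                    best_ref = k;
                    if (mm == 0) break;
                }
            }
        }
        if (best_ref < 0) {
            out(i, 0) = NA_INTEGER;
            out(i, 1) = NA_INTEGER;
        } else {
            out(i, 0) = best_ref + 1;
            out(i, 1) = best_mm;
        }
    }
    return out;
}
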