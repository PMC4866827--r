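#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Semi-global, error-tolerant alignment of an adapter against a read,
// in the style of cutadapt: the adapter may occur in full anywhere in the
// read, or (when allow_partial) as a *prefix* of the adapter aligned to the
// read's 3' end. Errors (substitutions + indels) are budgeted as
// floor(error_rate * matched adapter length). 5'-end partial occurrences are
// handled by the R wrapper, which reverses both strings.
//
// Returns c(start, end, n_errors, matched_len) with 1-based read
// coordinates, or NA if there is no admissible occurrence.
// Tie-break: fewest errors, then longest matched adapter portion, then
// preferred start position (largest when prefer_right, smallest otherwise).
// [[Rcpp::export]]
IntegerVector cpp_adapter_align(std::string read, std::string adapter,
                                double error_rate, int min_overlap,
                                bool allow_partial, bool prefer_right) {
    const int n = read.size(), m = adapter.size();
    if (m == 0) stop("adapter must be non-empty");
    if (min_overlap < 1) min_overlap = 1;

    std::vector<int> D(n + 1), Dp(n + 1), S(n + 1), Sp(n + 1);
    for (int j = 0; j <= n; ++j) { Dp[j] = 0; Sp[j] = j; }

    int best_err = -1, best_len = 0, best_start = -1, best_end = -1;
    auto consider = [&](int err, int klen, int start, int end) {
        if (klen < min_overlap) return;
        int budget = (int) std::floor(error_rate * klen);
        if (err > budget) return;
        bool better;
        if (best_err < 0)            better = true;
        else if (err != best_err)    better = err < best_err;
        else if (klen != best_len)   better = klen > best_len;
        else if (start != best_start)
            better = prefer_right ? (start > best_start) : (start < best_start);
        else                         better = false;
        if (better) {
            best_err = err; best_len = klen; best_start = start; best_end = end;
        }
    };

    for (int i = 1; i <= m; ++i) {
        D[0] = i; S[0] = 0;
        const char a = adapter[i - 1];
        for (int j = 1; j <= n; ++j) {
            int v = Dp[j - 1] + (a == read[j - 1] ? 0 : 1);
            int s = Sp[j - 1];
            int del = Dp[j] + 1;       // adapter base consumed, no read base
            if (del < v || (del == v &&
                (prefer_right ? Sp[j] > s : Sp[j] < s))) { v = del; s = Sp[j]; }
            int ins = D[j - 1] + 1;    // read base consumed, no adapter base
            if (ins < v || (ins == v &&
                (prefer_right ? S[j - 1] > s : S[j - 1] < s))) { v = ins; s = S[j - 1]; }
            D[j] = v; S[j] = s;
        }
        if (i == m) {
            for (int j = 1; j <= n; ++j) consider(D[j], m, S[j], j);
        } else if (allow_partial) {
            consider(D[n], i, S[n], n);
        }
        std::swap(D, Dp); std::swap(S, Sp);
    }

    if (best_err < 0)
        return IntegerVector::create(NA_INTEGER, NA_INTEGER, NA_INTEGER, NA_INTEGER);
    return IntegerVector::create(best_start + 1, best_end, best_err, best_len);
}
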