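#include <Rcpp.h>
#include <climits>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

const int NEG = INT_MIN / 4;

// bases are 4-bit masks (A=1, C=2, G=4, T=8); degenerate codes are unions,
// and two codes anneal iff their base sets intersect
inline bool anneal(int a, int b) { return (a & b) != 0; }

} // namespace

// Semi-global binding-site scan with a shared dynamic program per start.
//
// For every template start position s the full query is aligned globally
// against every window T[s, s+w), w in [max(1, m-shift), m+shift].  The
// alignment may not begin or end with an insertion (a template base aligned
// to nothing): a dangling template base belongs to the flank, not to the
// annealed footprint.  Objective: match +1, mismatch -1, gap base -2; among
// equal-score alignments the canonical one has the fewest gap bases.
//
// All window lengths at one start share a single DP matrix (column j of the
// final row is the window of length j), which is what makes the scan cheap
// relative to the per-window reference below.
//
// Returns an integer matrix with columns start0, wlen, score, gaps
// (start0 is 0-based).
// [[Rcpp::export(name = ".scan_windows_cpp")]]
IntegerMatrix scan_windows_cpp(IntegerVector query, IntegerVector tmpl, int shift) {
    const int m = query.size(), L = tmpl.size();
    if (m < 1) stop("empty query");
    if (shift < 0) stop("negative window shift");
    const int wcap = m + shift;
    const int wmin = std::max(1, m - shift);
    const int ncol = wcap + 1;
    std::vector<int> H((m + 1) * ncol), G((m + 1) * ncol);
    std::vector<int> out;

    for (int s = 0; s < L; ++s) {
        const int wmax = std::min(wcap, L - s);
        if (wmax < wmin) continue;

        H[0] = 0; G[0] = 0;
        for (int j = 1; j <= wmax; ++j) { H[j] = NEG; G[j] = 0; } // no leading insertion
        for (int i = 1; i <= m; ++i) {
            H[i * ncol] = -2 * i; // leading deletions: query overhang
            G[i * ncol] = i;
            const int qi = query[i - 1];
            const bool lastRow = (i == m); // insertions after the last query base would trail
            for (int j = 1; j <= wmax; ++j) {
                const int tj = tmpl[s + j - 1];
                int best = NEG, g = 0;
                const int hd = H[(i - 1) * ncol + (j - 1)];
                if (hd > NEG) {
                    best = hd + (anneal(qi, tj) ? 1 : -1);
                    g = G[(i - 1) * ncol + (j - 1)];
                }
                const int hu = H[(i - 1) * ncol + j];
                if (hu > NEG) {
                    const int cand = hu - 2, cg = G[(i - 1) * ncol + j] + 1;
                    if (cand > best || (cand == best && cg < g)) { best = cand; g = cg; }
                }
                if (!lastRow) {
                    const int hl = H[i * ncol + (j - 1)];
                    if (hl > NEG) {
                        const int cand = hl - 2, cg = G[i * ncol + (j - 1)] + 1;
                        if (cand > best || (cand == best && cg < g)) { best = cand; g = cg; }
                    }
                }
                H[i * ncol + j] = best;
                G[i * ncol + j] = g;
            }
        }
        for (int w = wmin; w <= wmax; ++w) {
            const int sc = H[m * ncol + w];
            if (sc <= NEG / 2) continue;
            out.push_back(s); out.push_back(w);
            out.push_back(sc); out.push_back(G[m * ncol + w]);
        }
    }

    const int n = (int)(out.size() / 4);
    IntegerMatrix res(n, 4);
    for (int k = 0; k < n; ++k)
        for (int c = 0; c < 4; ++c) res(k, c) = out[4 * k + c];
    colnames(res) = CharacterVector::create("start0", "wlen", "score", "gaps");
    return res;
}

namespace {

// Reference alignment of the full query against exactly one window: a
// deliberately naive row-major dynamic program over that window alone (no
// sharing across windows), used as the brute-force cross-check of the
// scanning code above.  Same canonical objective and terminal rules.
// Returns false when no alignment satisfies the terminal rules.
bool windowDP(const int* q, int m, const int* win, int w,
              int& score, int& gaps, std::vector<int>& S, std::vector<int>& G) {
    const int nc = w + 1;
    S.assign((m + 1) * nc, NEG);
    G.assign((m + 1) * nc, 0);
    S[0] = 0;
    for (int i = 1; i <= m; ++i) { S[i * nc] = -2 * i; G[i * nc] = i; }
    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= w; ++j) {
            int best = NEG, bg = 0;
            if (S[(i - 1) * nc + j - 1] > NEG) {
                best = S[(i - 1) * nc + j - 1] +
                    (anneal(q[i - 1], win[j - 1]) ? 1 : -1);
                bg = G[(i - 1) * nc + j - 1];
            }
            if (S[(i - 1) * nc + j] > NEG) { // deletion
                const int c = S[(i - 1) * nc + j] - 2;
                const int cg = G[(i - 1) * nc + j] + 1;
                if (c > best || (c == best && cg < bg)) { best = c; bg = cg; }
            }
            if (i < m && S[i * nc + j - 1] > NEG) { // insertion, internal only
                const int c = S[i * nc + j - 1] - 2;
                const int cg = G[i * nc + j - 1] + 1;
                if (c > best || (c == best && cg < bg)) { best = c; bg = cg; }
            }
            S[i * nc + j] = best;
            G[i * nc + j] = bg;
        }
    }
    if (S[m * nc + w] <= NEG / 2) return false;
    score = S[m * nc + w];
    gaps = G[m * nc + w];
    return true;
}

} // namespace

// Single-window reference alignment (see windowDP); returns c(score, gaps)
// or NAs when no alignment satisfies the terminal rules.
// [[Rcpp::export(name = ".window_align_cpp")]]
IntegerVector window_align_cpp(IntegerVector query, IntegerVector window) {
    const int m = query.size(), w = window.size();
    if (m < 1 || w < 1) stop("empty query or window");
    std::vector<int> S, G;
    int score = 0, gaps = 0;
    if (!windowDP(&query[0], m, &window[0], w, score, gaps, S, G))
        return IntegerVector::create(NA_INTEGER, NA_INTEGER);
    return IntegerVector::create(score, gaps);
}

// Exhaustive window enumeration driving the reference alignment: every
// (start, length) window in the shift band is aligned from scratch.
// Same return layout as the scan.
// [[Rcpp::export(name = ".oracle_scan_cpp")]]
IntegerMatrix oracle_scan_cpp(IntegerVector query, IntegerVector tmpl, int shift) {
    const int m = query.size(), L = tmpl.size();
    if (m < 1) stop("empty query");
    if (shift < 0) stop("negative window shift");
    const int wmin = std::max(1, m - shift);
    const int wmax = m + shift;
    std::vector<int> out, S, G;
    for (int s = 0; s < L; ++s) {
        for (int w = wmin; w <= wmax; ++w) {
            if (s + w > L) break;
            int score = 0, gaps = 0;
            if (!windowDP(&query[0], m, &tmpl[0] + s, w, score, gaps, S, G))
                continue;
            out.push_back(s); out.push_back(w);
            out.push_back(score); out.push_back(gaps);
        }
    }
    const int n = (int)(out.size() / 4);
    IntegerMatrix res(n, 4);
    for (int k = 0; k < n; ++k)
        for (int c = 0; c < 4; ++c) res(k, c) = out[4 * k + c];
    colnames(res) = CharacterVector::create("start0", "wlen", "score", "gaps");
    return res;
}
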