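#include <Rcpp.h>
#include <set>
using namespace Rcpp;

// Unit-cost Levenshtein distance, two-row DP.
// [[Rcpp::export]]
int cpp_levenshtein(const std::string& a, const std::string& b) {
    const int n = a.size(), m = b.size();
    if (n == 0) return m;
    if (m == 0) return n;
    std::vector<int> prev(m + 1), cur(m + 1);
    for (int j = 0; j <= m; ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
        cur[0] = i;
        for (int j = 1; j <= m; ++j) {
            int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            int del = prev[j] + 1;
            int ins = cur[j - 1] + 1;
            cur[j] = std::min(sub, std::min(del, ins));
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

static inline double subst_score(char x, char y, double match, double mismatch) {
    // N is ambiguous: never rewarded as a match
    if (x == 'N' || y == 'N') return mismatch;
    return (x == y) ? match : mismatch;
}

// Global affine-gap alignment (Gotoh). A gap of length L costs
// gap_open + L * gap_extend. Deterministic traceback: at score ties the
// diagonal (match/mismatch) state is preferred, then a gap in `b`
// (consuming `a`), then a gap in `a`.
// Returns score, number of matched columns and total alignment columns.
// [[Rcpp::export]]
List cpp_global_align(const std::string& a, const std::string& b,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
    const int n = a.size(), m = b.size();
    const double NEG = -1e18;
    // state 0 = M (diagonal), 1 = X (gap in b, consumes a), 2 = Y (gap in a)
    std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG));
    std::vector<std::vector<double>> X(n + 1, std::vector<double>(m + 1, NEG));
    std::vector<std::vector<double>> Y(n + 1, std::vector<double>(m + 1, NEG));
    // traceback: predecessor state for each cell/state
    std::vector<std::vector<signed char>> tM(n + 1, std::vector<signed char>(m + 1, -1));
    std::vector<std::vector<signed char>> tX(n + 1, std::vector<signed char>(m + 1, -1));
    std::vector<std::vector<signed char>> tY(n + 1, std::vector<signed char>(m + 1, -1));

    M[0][0] = 0.0;
    for (int i = 1; i <= n; ++i) {
        X[i][0] = -(gap_open + i * gap_extend);
        tX[i][0] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
        Y[0][j] = -(gap_open + j * gap_extend);
        tY[0][j] = (j == 1) ? 0 : 2;
    }
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            // M from diagonal, preferring M > X > Y at ties
            double best = M[i - 1][j - 1]; signed char arg = 0;
            if (X[i - 1][j - 1] > best) { best = X[i - 1][j - 1]; arg = 1; }
            if (Y[i - 1][j - 1] > best) { best = Y[i - 1][j - 1]; arg = 2; }
            if (best > NEG / 2) {
                M[i][j] = best + subst_score(a[i - 1], b[j - 1], match, mismatch);
                tM[i][j] = arg;
            }
            // X: consume a[i-1] against a gap
            best = NEG; arg = -1;
            if (M[i - 1][j] > NEG / 2 && M[i - 1][j] - (gap_open + gap_extend) > best) {
                best = M[i - 1][j] - (gap_open + gap_extend); arg = 0;
            }
            if (X[i - 1][j] > NEG / 2 && X[i - 1][j] - gap_extend > best) {
                best = X[i - 1][j] - gap_extend; arg = 1;
            }
            if (Y[i - 1][j] > NEG / 2 && Y[i - 1][j] - (gap_open + gap_extend) > best) {
                best = Y[i - 1][j] - (gap_open + gap_extend); arg = 2;
            }
            if (arg >= 0) { X[i][j] = best; tX[i][j] = arg; }
            // Y: consume b[j-1] against a gap
            best = NEG; arg = -1;
            if (M[i][j - 1] > NEG / 2 && M[i][j - 1] - (gap_open + gap_extend) > best) {
                best = M[i][j - 1] - (gap_open + gap_extend); arg = 0;
            }
            if (X[i][j - 1] > NEG / 2 && X[i][j - 1] - (gap_open + gap_extend) > best) {
                best = X[i][j - 1] - (gap_open + gap_extend); arg = 1;
            }
            if (Y[i][j - 1] > NEG / 2 && Y[i][j - 1] - gap_extend > best) {
                best = Y[i][j - 1] - gap_extend; arg = 2;
            }
            if (arg >= 0) { Y[i][j] = best; tY[i][j] = arg; }
        }
    }
    // final state: prefer M > X > Y at ties
    double score = M[n][m]; int state = 0;
    if (X[n][m] > score) { score = X[n][m]; state = 1; }
    if (Y[n][m] > score) { score = Y[n][m]; state = 2; }

    int i = n, j = m, n_match = 0, aln_len = 0;
    while (i > 0 || j > 0) {
        ++aln_len;
        if (state == 0) {
            if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++n_match;
            state = tM[i][j]; --i; --j;
        } else if (state == 1) {
            state = tX[i][j]; --i;
        } else {
            state = tY[i][j]; --j;
        }
    }
    return List::create(_["score"] = score, _["n_match"] = n_match,
                        _["aln_len"] = aln_len);
}

// Sellers DP: minimum edit distance between `block` and any substring of
// `donor` ending at each position (free start). Returns the global minimum.
static int sellers_min(const std::string& block, const std::string& donor,
                       std::vector<int>& last_row) {
    const int m = block.size(), n = donor.size();
    std::vector<int> prev(n + 1), cur(n + 1);
    for (int j = 0; j <= n; ++j) prev[j] = 0;
    for (int i = 1; i <= m; ++i) {
        cur[0] = i;
        for (int j = 1; j <= n; ++j) {
            int sub = prev[j - 1] + (block[i - 1] == donor[j - 1] ? 0 : 1);
            int del = prev[j] + 1;
            int ins = cur[j - 1] + 1;
            cur[j] = std::min(sub, std::min(del, ins));
        }
        std::swap(prev, cur);
    }
    last_row = prev;
    int d = m;
    for (int j = 0; j <= n; ++j) d = std::min(d, prev[j]);
    return d;
}

static IntegerMatrix hits_to_matrix(const std::set<std::pair<int,int>>& hits,
                                    int dist) {
    IntegerMatrix out(hits.size(), 3);
    int r = 0;
    for (auto& h : hits) {
        out(r, 0) = h.first;   // 0-based offset in donor
        out(r, 1) = h.second;  // segment length
        out(r, 2) = dist;
        ++r;
    }
    colnames(out) = CharacterVector::create("offset", "length", "dist");
    return out;
}

// Exhaustive scan: all donor substrings minimizing the edit distance to
// `block`, provided the minimum is <= max_lev. Substring lengths outside
// [len(block) - max_lev, len(block) + max_lev] cannot reach max_lev and are
// skipped. Returns a 0-row matrix when no substring is within max_lev.
// [[Rcpp::export]]
IntegerMatrix cpp_scan_segments(const std::string& block,
                                const std::string& donor, int max_lev) {
    const int m = block.size(), n = donor.size();
    std::set<std::pair<int,int>> hits;
    if (m == 0 || n == 0) return hits_to_matrix(hits, 0);
    std::vector<int> last_row;
    int dstar = sellers_min(block, donor, last_row);
    if (dstar > max_lev) return hits_to_matrix(hits, 0);
    int lo = std::max(1, m - max_lev), hi = m + max_lev;
    for (int j = 1; j <= n; ++j) {
        if (last_row[j] != dstar) continue;  // only ends achieving the optimum
        for (int len = lo; len <= hi; ++len) {
            int s = j - len;
            if (s < 0) continue;
            if (cpp_levenshtein(block, donor.substr(s, len)) == dstar)
                hits.insert({s, len});
        }
    }
    return hits_to_matrix(hits, dstar);
}

// Seed-and-extend scan (k-mer seeds, pigeonhole over max_lev + 1 pieces):
// any substring within max_lev edits of `block` must contain one piece's
// leading k-mer exactly, shifted by at most max_lev. Candidate substrings
// around each seed hit are verified with the full edit distance, so the
// result equals cpp_scan_segments by construction. Callers must ensure
// len(block) >= k * (max_lev + 1).
// [[Rcpp::export]]
IntegerMatrix cpp_scan_segments_seeded(const std::string& block,
                                       const std::string& donor,
                                       int max_lev, int k) {
    const int m = block.size(), n = donor.size();
    std::set<std::pair<int,int>> cand;
    if (m == 0 || n == 0) return hits_to_matrix(cand, 0);
    const int q = max_lev + 1;
    // q equal-ish pieces; seed = first k nt of each piece
    std::vector<int> seed_pos;
    for (int p = 0; p < q; ++p) {
        int start = (int)((long long)p * m / q);
        if (start + k <= m) seed_pos.push_back(start);
    }
    int lo = std::max(1, m - max_lev), hi = m + max_lev;
    std::set<std::pair<int,int>> checked;
    int best = max_lev + 1;
    std::set<std::pair<int,int>> hits;
    for (int b : seed_pos) {
        const std::string seed = block.substr(b, k);
        for (int p = 0; p + k <= n; ++p) {
            if (donor.compare(p, k, seed) != 0) continue;
            for (int s = p - b - max_lev; s <= p - b + max_lev; ++s) {
                if (s < 0) continue;
                for (int len = lo; len <= hi; ++len) {
                    if (s + len > n) break;
                    auto key = std::make_pair(s, len);
                    if (!checked.insert(key).second) continue;
                    int d = cpp_levenshtein(block, donor.substr(s, len));
                    if (d > max_lev) continue;
                    if (d < best) { best = d; hits.clear(); }
                    if (d == best) hits.insert(key);
                }
            }
        }
    }
    if (best > max_lev) hits.clear();
    return hits_to_matrix(hits, best > max_lev ? 0 : best);
}

static inline bool base_eq(char x, char y) {
    return x == y && x != 'N';
}

static inline char complement(char x) {
    switch (x) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
    }
}

// Repeat scan for direct (mode 0), inverted (mode 1) and mirror (mode 2)
// repeats. Occurrences are maximal agreement runs:
//  - DR: for each arm-start distance d, maximal runs where seq[i] ==
//    seq[i+d]; arm length L = min(run, d), spacer g = d - L; emitted when
//    L >= arm_min and g <= spacer_max.
//  - IR/MR: for each position-sum S, maximal runs of pairs (p, S-p) that
//    agree (reverse-complement for IR, plain for MR); arm = run, spacer
//    determined by the innermost pair.
// Returns (start, end, arm_len, spacer), 0-based half-open.
// [[Rcpp::export]]
IntegerMatrix cpp_scan_repeats(const std::string& seq, int mode,
                               int arm_min, int spacer_max) {
    const int n = seq.size();
    std::vector<std::array<int,4>> occ;
    if (mode == 0) {
        for (int d = arm_min; d <= n - 1; ++d) {
            int run = 0;
            for (int i = n - d - 1; i >= -1; --i) {
                bool agree = (i >= 0) && base_eq(seq[i], seq[i + d]);
                if (agree) { ++run; continue; }
                if (run > 0) {
                    int r0 = i + 1;
                    int L = std::min(run, d);
                    int g = d - L;
                    if (L >= arm_min && g <= spacer_max)
                        occ.push_back({r0, r0 + d + L, L, g});
                }
                run = 0;
            }
        }
    } else {
        for (int S = 1; S <= 2 * n - 3; ++S) {
            int p_lo = std::max(0, S - (n - 1));
            int p_hi_max = (S - 1) / 2;  // strict p < S - p
            if (p_lo > p_hi_max) continue;
            int run = 0;
            for (int p = p_lo; p <= p_hi_max + 1; ++p) {
                bool agree = false;
                if (p <= p_hi_max) {
                    char x = seq[p], y = seq[S - p];
                    agree = (mode == 1) ? base_eq(x, complement(y))
                                        : base_eq(x, y);
                }
                if (agree) { ++run; continue; }
                if (run > 0) {
                    int inner = p - 1;          // innermost agreeing p
                    int L = run;
                    int g = S - 2 * inner - 1;  // gap between the arms
                    if (L >= arm_min && g >= 0 && g <= spacer_max) {
                        int start = inner - L + 1;
                        occ.push_back({start, S - start + 1, L, g});
                    }
                }
                run = 0;
            }
        }
    }
    IntegerMatrix out(occ.size(), 4);
    for (size_t r = 0; r < occ.size(); ++r)
        for (int c = 0; c < 4; ++c) out(r, c) = occ[r][c];
    colnames(out) = CharacterVector::create("start", "end", "arm_len", "spacer");
    return out;
}
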