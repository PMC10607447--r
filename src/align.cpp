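#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Global affine (Gotoh) alignment of two DNA segments with full traceback.
// Returns matches, columns, leading/trailing gap-run lengths (columns at
// the alignment edges where one side is all gaps) and the optimal score.
// Gap of length g costs gapOpen + g * gapExt (Biostrings convention).
// [[Rcpp::export]]
NumericVector cpp_nw_stats(std::string a, std::string b,
                           double match, double mismatch,
                           double gapOpen, double gapExt) {
    const int m = (int)a.size(), n = (int)b.size();
    if (m == 0 && n == 0)
        return NumericVector::create(0, 0, 0, 0, 0);
    if (m == 0 || n == 0) {
        // pure gap: all columns are one terminal run
        int len = m + n;
        return NumericVector::create(0, len, len, 0,
                                     -(gapOpen + gapExt * len));
    }
    const double NEG = -1e18;
    const double go = gapOpen + gapExt; // cost of first gap char
    std::vector<double> M(n + 1), X(n + 1), Y(n + 1);
    std::vector<double> Mp(n + 1), Xp(n + 1), Yp(n + 1);
    // traceback: 2 bits per state per cell; store full byte matrices
    // tb codes: for M: 0 diag-from-M, 1 diag-from-X, 2 diag-from-Y
    //           for X: 0 from M, 1 from X ; for Y likewise
    std::vector<uint8_t> tbM((size_t)(m + 1) * (n + 1));
    std::vector<uint8_t> tbX((size_t)(m + 1) * (n + 1));
    std::vector<uint8_t> tbY((size_t)(m + 1) * (n + 1));
    Mp[0] = 0; Xp[0] = NEG; Yp[0] = NEG;
    for (int j = 1; j <= n; ++j) {
        Mp[j] = NEG; Xp[j] = NEG;
        Yp[j] = -(gapOpen + gapExt * j);
        tbY[j] = (j == 1) ? 0 : 2;
    }
    for (int i = 1; i <= m; ++i) {
        size_t row = (size_t)i * (n + 1);
        M[0] = NEG; Y[0] = NEG;
        X[0] = -(gapOpen + gapExt * i);
        tbX[row] = (i == 1) ? 0 : 1;
        for (int j = 1; j <= n; ++j) {
            double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
            // M: diagonal
            double bm = Mp[j - 1], bx = Xp[j - 1], by = Yp[j - 1];
            uint8_t t = 0; double best = bm;
            if (bx > best) { best = bx; t = 1; }
            if (by > best) { best = by; t = 2; }
            M[j] = best + s; tbM[row + j] = t;
            // X: gap in b (consume a[i])
            double xm = Mp[j] - go, xx = Xp[j] - gapExt, xy = Yp[j] - go;
            if (xm >= xx && xm >= xy) { X[j] = xm; tbX[row + j] = 0; }
            else if (xx >= xy)        { X[j] = xx; tbX[row + j] = 1; }
            else                      { X[j] = xy; tbX[row + j] = 2; }
            // Y: gap in a (consume b[j])
            double ym = M[j - 1] - go, yx = X[j - 1] - go,
                   yy = Y[j - 1] - gapExt;
            if (ym >= yy && ym >= yx) { Y[j] = ym; tbY[row + j] = 0; }
            else if (yy >= yx)        { Y[j] = yy; tbY[row + j] = 2; }
            else                      { Y[j] = yx; tbY[row + j] = 1; }
        }
        std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
    }
    double sM = Mp[n], sX = Xp[n], sY = Yp[n];
    // prefer ending in a gap state on ties: a co-optimal terminal gap then
    // sits at the alignment boundary, where it is classified as overhang
    int state = 0; double score = sM;            // 0=M 1=X 2=Y
    if (sX >= score) { score = sX; state = 1; }
    if (sY >= score) { score = sY; state = 2; }
    // traceback
    int i = m, j = n;
    long matches = 0, columns = 0;
    std::vector<uint8_t> colType; colType.reserve(m + n);
    while (i > 0 || j > 0) {
        size_t row = (size_t)i * (n + 1);
        if (i == 0) {               // remaining prefix of b: gaps in a
            colType.push_back(1); ++columns; --j; continue;
        }
        if (j == 0) {               // remaining prefix of a: gaps in b
            colType.push_back(1); ++columns; --i; continue;
        }
        if (state == 0) {
            uint8_t t = tbM[row + j];
            bool eq = (a[i - 1] == b[j - 1]);
            colType.push_back(0);
            if (eq) ++matches;
            ++columns; --i; --j;
            state = t;
        } else if (state == 1) {
            uint8_t t = tbX[row + j];
            colType.push_back(1);         // gap column (gap in b)
            ++columns; --i;
            state = t;
        } else {
            uint8_t t = tbY[row + j];
            colType.push_back(1);         // gap column (gap in a)
            ++columns; --j;
            state = t;
        }
    }
    // colType is reversed (end -> start); terminal gap runs:
    long lead = 0, trail = 0;
    for (size_t q = colType.size(); q > 0; --q) {  // from alignment start
        if (colType[q - 1] == 1) ++lead; else break;
    }
    for (size_t q = 0; q < colType.size(); ++q) {  // from alignment end
        if (colType[q] == 1) ++trail; else break;
    }
    if (lead + trail > columns) { lead = columns; trail = 0; } // all-gap
    return NumericVector::create((double)matches, (double)columns,
                                 (double)lead, (double)trail, score);
}

static inline int baseCode(char c) {
    switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
    }
}

// Collinear chain of k-mer anchors unique in both sequences, merged into
// maximal same-diagonal blocks. Returns an integer matrix with columns
// (a_start, b_start, length), 1-based. Empty matrix when no anchors chain.
// [[Rcpp::export]]
IntegerMatrix cpp_anchor_blocks(std::string a, std::string b, int k) {
    const int m = (int)a.size(), n = (int)b.size();
    IntegerMatrix empty(0, 3);
    if (m < k || n < k) return empty;
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    // unique k-mer positions of a
    std::unordered_map<uint64_t, int> mapA;
    mapA.reserve((size_t)m * 2);
    {
        uint64_t h = 0; int run = 0;
        for (int i = 0; i < m; ++i) {
            int c = baseCode(a[i]);
            if (c < 0) { run = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t)c) & mask;
            if (++run >= k) {
                auto it = mapA.find(h);
                if (it == mapA.end()) mapA[h] = i - k + 1;
                else it->second = -2;          // duplicate
            }
        }
    }
    // occurrences in b: first position, -2 if duplicated
    std::unordered_map<uint64_t, int> mapB;
    mapB.reserve((size_t)n * 2);
    {
        uint64_t h = 0; int run = 0;
        for (int i = 0; i < n; ++i) {
            int c = baseCode(b[i]);
            if (c < 0) { run = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t)c) & mask;
            if (++run >= k) {
                auto it = mapB.find(h);
                if (it == mapB.end()) mapB[h] = i - k + 1;
                else it->second = -2;
            }
        }
    }
    std::vector<std::pair<int, int>> anchors; // (apos, bpos) 0-based
    for (auto &kv : mapA) {
        if (kv.second < 0) continue;
        auto it = mapB.find(kv.first);
        if (it == mapB.end() || it->second < 0) continue;
        anchors.push_back({kv.second, it->second});
    }
    if (anchors.empty()) return empty;
    std::sort(anchors.begin(), anchors.end());
    // LIS on bpos (strictly increasing), O(N log N)
    const int N = (int)anchors.size();
    std::vector<int> tails;        // indices into anchors
    std::vector<int> prev(N, -1);
    for (int i = 0; i < N; ++i) {
        int bp = anchors[i].second;
        int lo = 0, hi = (int)tails.size();
        while (lo < hi) {
            int mid = (lo + hi) / 2;
            if (anchors[tails[mid]].second < bp) lo = mid + 1; else hi = mid;
        }
        if (lo > 0) prev[i] = tails[lo - 1];
        if (lo == (int)tails.size()) tails.push_back(i);
        else tails[lo] = i;
    }
    std::vector<int> chain;
    for (int i = tails.empty() ? -1 : tails.back(); i >= 0; i = prev[i])
        chain.push_back(i);
    std::reverse(chain.begin(), chain.end());
    // merge into blocks; enforce strictly increasing, non-overlapping runs
    std::vector<std::array<long, 3>> blocks; // astart, bstart, len (0-based)
    long aend = -1, bend = -1; // last used position (inclusive)
    for (int idx : chain) {
        long as = anchors[idx].first, bs = anchors[idx].second, len = k;
        if (!blocks.empty() &&
            as - bs == blocks.back()[0] - blocks.back()[1] &&
            as <= aend + 1) {
            long newEnd = as + len - 1;
            if (newEnd > aend) {
                blocks.back()[2] += newEnd - aend;
                aend = newEnd; bend = bs + len - 1;
            }
            continue;
        }
        long shift = 0;
        if (as <= aend) shift = aend - as + 1;
        if (bs + shift <= bend) shift = bend - bs + 1;
        as += shift; bs += shift; len -= shift;
        if (len <= 0) continue;
        blocks.push_back({as, bs, len});
        aend = as + len - 1; bend = bs + len - 1;
    }
    IntegerMatrix out((int)blocks.size(), 3);
    for (int i = 0; i < (int)blocks.size(); ++i) {
        out(i, 0) = (int)blocks[i][0] + 1;
        out(i, 1) = (int)blocks[i][1] + 1;
        out(i, 2) = (int)blocks[i][2];
    }
    return out;
}
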