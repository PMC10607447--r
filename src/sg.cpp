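#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

// Translated-similarity HSP engine: exact 4-aa (seedLen) word matches
// between frame translations of two genomes, extended ungapped in both
// directions under an X-drop rule with a substitution matrix, reported
// when the HSP score reaches minScore. Seeds falling inside an already
// extended stretch of the same diagonal are skipped.
//
// aprot/bprot: six frame translations (characters; '*' for stops, 'X'
// for ambiguous). alphaIdx: 128-long map char -> row of submat (<0 skips
// seeding on that char). Returns a numeric matrix with one row per HSP:
// (a_frame, b_frame, a_start_aa, a_end_aa, score), 1-based aa positions.
// [[Rcpp::export]]
NumericMatrix cpp_sg_hsps(std::vector<std::string> aprot,
                          std::vector<std::string> bprot,
                          IntegerVector alphaIdx,
                          NumericMatrix submat,
                          int seedLen, double xdrop, double minScore) {
    const int A = (int)submat.nrow();
    const int nfa = (int)aprot.size(), nfb = (int)bprot.size();
    std::vector<std::array<double, 5>> hsps;
    // precompute index codes per frame
    std::vector<std::vector<int>> acode(nfa), bcode(nfb);
    for (int f = 0; f < nfa; ++f) {
        acode[f].resize(aprot[f].size());
        for (size_t i = 0; i < aprot[f].size(); ++i)
            acode[f][i] = alphaIdx[(unsigned char)aprot[f][i] & 127];
    }
    for (int f = 0; f < nfb; ++f) {
        bcode[f].resize(bprot[f].size());
        for (size_t i = 0; i < bprot[f].size(); ++i)
            bcode[f][i] = alphaIdx[(unsigned char)bprot[f][i] & 127];
    }
    long base = 1;
    for (int s = 0; s < seedLen; ++s) base *= A;
    for (int fb = 0; fb < nfb; ++fb) {
        // seed index of this b frame
        std::unordered_map<long, std::vector<int>> index;
        const std::vector<int> &bc = bcode[fb];
        const int nb = (int)bc.size();
        long key = 0, mul = base / A;
        int run = 0;
        for (int j = 0; j < nb; ++j) {
            int c = bc[j];
            if (c < 0 || c >= 20) { run = 0; key = 0; continue; }
            key = (key % mul) * A + c;
            if (++run >= seedLen) index[key].push_back(j - seedLen + 1);
        }
        for (int fa = 0; fa < nfa; ++fa) {
            const std::vector<int> &ac = acode[fa];
            const int na = (int)ac.size();
            // per-diagonal furthest extension end (a coordinate)
            std::unordered_map<long, int> diagEnd;
            long k2 = 0; int run2 = 0;
            for (int i = 0; i < na; ++i) {
                int c = ac[i];
                if (c < 0 || c >= 20) { run2 = 0; k2 = 0; continue; }
                k2 = (k2 % mul) * A + c;
                if (++run2 < seedLen) continue;
                int i0 = i - seedLen + 1;
                auto it = index.find(k2);
                if (it == index.end()) continue;
                for (int j0 : it->second) {
                    long d = (long)i0 - j0;
                    auto de = diagEnd.find(d);
                    if (de != diagEnd.end() && i0 <= de->second) continue;
                    // score the seed
                    double sc = 0;
                    for (int s = 0; s < seedLen; ++s)
                        sc += submat(ac[i0 + s], bc[j0 + s]);
                    // extend right
                    double best = sc, cur = sc;
                    int ar = i0 + seedLen - 1, br = j0 + seedLen - 1;
                    int bestAr = ar;
                    int ii = ar + 1, jj = br + 1;
                    while (ii < na && jj < nb) {
                        int ca = ac[ii], cb2 = bc[jj];
                        if (ca < 0 || cb2 < 0) break;
                        cur += submat(ca, cb2);
                        if (cur > best) { best = cur; bestAr = ii; }
                        if (cur < best - xdrop) break;
                        ++ii; ++jj;
                    }
                    // extend left
                    double cur2 = best, best2 = best;
                    int al = i0, bestAl = i0;
                    ii = i0 - 1; jj = j0 - 1;
                    while (ii >= 0 && jj >= 0) {
                        int ca = ac[ii], cb2 = bc[jj];
                        if (ca < 0 || cb2 < 0) break;
                        cur2 += submat(ca, cb2);
                        if (cur2 > best2) { best2 = cur2; bestAl = ii; }
                        if (cur2 < best2 - xdrop) break;
                        --ii; --jj;
                    }
                    al = bestAl;
                    diagEnd[d] = bestAr;
                    if (best2 >= minScore)
                        hsps.push_back({(double)(fa + 1), (double)(fb + 1),
                                        (double)(al + 1), (double)(bestAr + 1),
                                        best2});
                }
            }
        }
    }
    NumericMatrix out((int)hsps.size(), 5);
    for (int i = 0; i < (int)hsps.size(); ++i)
        for (int j = 0; j < 5; ++j) out(i, j) = hsps[i][j];
    colnames(out) = CharacterVector::create("a_frame", "b_frame",
                                            "a_start", "a_end", "score");
    return out;
}
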