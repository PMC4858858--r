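#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Seed-weighted affine-gap local alignment of a miRNA against a 3'UTR.
//
// The miRNA is hybridized antiparallel to the UTR, so the miRNA is reversed
// (not complemented) and "match" means base-pair complementarity: Watson-Crick
// (A:U, G:C) or G:U wobble. Substitution scores at miRNA positions
// seedStart..seedEnd (5'-based, typically 2..8) are scaled by seedWeight,
// mirroring the seed emphasis of miRanda-class target scanners. The duplex
// free-energy proxy is a sum of per-pair stacking-free energies over paired
// positions only (gaps and mismatches contribute 0), so it is monotone in the
// extent of pairing.

static inline int encode(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
    }
}

// unordered pair class: 0 = WC A:U, 1 = WC G:C, 2 = G:U wobble, -1 = mismatch
static inline int pairClass(int a, int b) {
    if (a < 0 || b < 0) return -1;
    int lo = std::min(a, b), hi = std::max(a, b);
    if (lo == 0 && hi == 3) return 0;  // A with T/U
    if (lo == 1 && hi == 2) return 1;  // C with G
    if (lo == 2 && hi == 3) return 2;  // G with T/U
    return -1;
}

// [[Rcpp::export(name = ".duplex_align_cpp")]]
DataFrame duplex_align_cpp(std::string mirna, std::string utr,
                           double matchScore, double wobbleScore,
                           double mismatchScore,
                           double gapOpen, double gapExt,
                           int seedStart, int seedEnd, double seedWeight,
                           double energyGC, double energyAU, double energyGU,
                           double reportMin, int maxHits) {
    const int m = (int) mirna.size();
    const int n = (int) utr.size();
    std::vector<int> q(m), t(n);
    for (int i = 0; i < m; ++i) q[i] = encode(mirna[m - 1 - i]); // reversed
    for (int j = 0; j < n; ++j) t[j] = encode(utr[j]);

    const double NEG = -1e18;
    std::vector<bool> masked(n, false);

    std::vector<double> score_out, energy_out;
    std::vector<int> us_out, ue_out, ms_out, me_out, np_out;

    // matrices (m+1) x (n+1), row-major
    const int W = n + 1;
    std::vector<double> M((m + 1) * W), Ix((m + 1) * W), Iy((m + 1) * W);
    std::vector<signed char> pM((m + 1) * W), pIx((m + 1) * W), pIy((m + 1) * W);

    while ((int) score_out.size() < maxHits) {
        for (int j = 0; j <= n; ++j) { M[j] = NEG; Ix[j] = NEG; Iy[j] = NEG; }
        double best = 0.0; int bi = -1, bj = -1;
        for (int i = 1; i <= m; ++i) {
            M[i * W] = NEG; Ix[i * W] = NEG; Iy[i * W] = NEG;
            // miRNA position in 5'-based original coordinates
            int pos5 = m - i + 1;
            double w = (pos5 >= seedStart && pos5 <= seedEnd) ? seedWeight : 1.0;
            for (int j = 1; j <= n; ++j) {
                int idx = i * W + j;
                if (masked[j - 1]) { M[idx] = NEG; Ix[idx] = NEG; Iy[idx] = NEG; continue; }
                int pc = pairClass(q[i - 1], t[j - 1]);
                double s = (pc < 0) ? mismatchScore
                                    : (pc == 2 ? wobbleScore : matchScore);
                s *= w;
                // M: align q[i-1] with t[j-1]
                int d = (i - 1) * W + (j - 1);
                double fromM = M[d], fromX = Ix[d], fromY = Iy[d];
                double prev = 0.0; signed char tb = 0;
                if (fromM > prev) { prev = fromM; tb = 1; }
                if (fromX > prev) { prev = fromX; tb = 2; }
                if (fromY > prev) { prev = fromY; tb = 3; }
                M[idx] = prev + s; pM[idx] = tb;
                // Ix: gap in UTR (consumes miRNA base)
                int up = (i - 1) * W + j;
                double xo = M[up] + gapOpen, xe = Ix[up] + gapExt;
                if (xo >= xe) { Ix[idx] = xo; pIx[idx] = 1; }
                else          { Ix[idx] = xe; pIx[idx] = 2; }
                // Iy: gap in miRNA (consumes UTR base)
                int lf = i * W + (j - 1);
                double yo = M[lf] + gapOpen, ye = Iy[lf] + gapExt;
                if (yo >= ye) { Iy[idx] = yo; pIy[idx] = 1; }
                else          { Iy[idx] = ye; pIy[idx] = 3; }
                if (M[idx] > best) { best = M[idx]; bi = i; bj = j; }
            }
        }
        if (bi < 0 || best < reportMin) break;

        // traceback from (bi, bj) in state M
        int i = bi, j = bj, state = 1;
        int iEnd = bi, jEnd = bj, iStart = bi, jStart = bj;
        double energy = 0.0; int nPairs = 0;
        while (true) {
            int idx = i * W + j;
            if (state == 1) {
                int pc = pairClass(q[i - 1], t[j - 1]);
                if (pc == 0) { energy += energyAU; ++nPairs; }
                else if (pc == 1) { energy += energyGC; ++nPairs; }
                else if (pc == 2) { energy += energyGU; ++nPairs; }
                iStart = i; jStart = j;
                signed char tb = pM[idx];
                --i; --j;
                if (tb == 0) break;
                state = tb;
            } else if (state == 2) {
                state = pIx[idx];
                --i;
            } else {
                state = pIy[idx];
                --j;
            }
        }

        score_out.push_back(best);
        energy_out.push_back(energy);
        us_out.push_back(jStart);          // 1-based inclusive on the UTR
        ue_out.push_back(jEnd);
        // convert reversed-query indices back to 5'-based miRNA positions
        ms_out.push_back(m - iEnd + 1);
        me_out.push_back(m - iStart + 1);
        np_out.push_back(nPairs);

        for (int k = jStart - 1; k < jEnd; ++k) masked[k] = true;
    }

    return DataFrame::create(
        Named("score") = score_out,
        Named("utrStart") = us_out,
        Named("utrEnd") = ue_out,
        Named("mirnaStart") = ms_out,
        Named("mirnaEnd") = me_out,
        Named("energy") = energy_out,
        Named("nPairs") = np_out);
}
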