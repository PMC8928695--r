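#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive search for the axis-aligned sub-cuboid maximising the cuboid
// goodness CG = (sum of bone probability inside) / penalty(dims), using a
// 3-D summed-volume table for O(1) box sums. Candidate corner positions
// are supplied per axis, separately for the low and high corner. Ties
// resolve to the smaller volume, then to the lexicographically smallest
// (lo1, lo2, lo3, hi1, hi2, hi3).
//
// penaltyMode 0: (a + b + h)^2   -- total edge length 4(a+b+h), (c/4)^2
// penaltyMode 1: ((a + b) / 2)^2 -- per-slice rectangle perimeter 2(a+b)

static inline double svtAt(const double* S, int n1, int n2,
                           int i, int j, int k) {
  if (i < 1 || j < 1 || k < 1) return 0.0;
  return S[(i - 1) + (size_t)(j - 1) * n1 + (size_t)(k - 1) * n1 * n2];
}

static inline double boxSumC(const double* S, int n1, int n2,
                             int l1, int h1, int l2, int h2,
                             int l3, int h3) {
  return svtAt(S, n1, n2, h1, h2, h3)
       - svtAt(S, n1, n2, l1 - 1, h2, h3)
       - svtAt(S, n1, n2, h1, l2 - 1, h3)
       - svtAt(S, n1, n2, h1, h2, l3 - 1)
       + svtAt(S, n1, n2, l1 - 1, l2 - 1, h3)
       + svtAt(S, n1, n2, l1 - 1, h2, l3 - 1)
       + svtAt(S, n1, n2, h1, l2 - 1, l3 - 1)
       - svtAt(S, n1, n2, l1 - 1, l2 - 1, l3 - 1);
}

// [[Rcpp::export(name = ".bestCuboidCpp")]]
List bestCuboidCpp(NumericVector svt, IntegerVector dims,
                   IntegerVector lo1c, IntegerVector hi1c,
                   IntegerVector lo2c, IntegerVector hi2c,
                   IntegerVector lo3c, IntegerVector hi3c,
                   int minDim, int penaltyMode) {
  const double* S = svt.begin();
  const int n1 = dims[0], n2 = dims[1];
  double bestCG = -1.0;
  long bestVol = 0;
  int b[6] = {0, 0, 0, 0, 0, 0};
  bool found = false;

  for (int a3 = 0; a3 < lo3c.size(); ++a3) {
    int l3 = lo3c[a3];
    for (int b3 = 0; b3 < hi3c.size(); ++b3) {
      int h3 = hi3c[b3];
      int d3 = h3 - l3 + 1;
      if (d3 < minDim) continue;
      for (int a2 = 0; a2 < lo2c.size(); ++a2) {
        int l2 = lo2c[a2];
        for (int b2 = 0; b2 < hi2c.size(); ++b2) {
          int h2 = hi2c[b2];
          int d2 = h2 - l2 + 1;
          if (d2 < minDim) continue;
          for (int a1 = 0; a1 < lo1c.size(); ++a1) {
            int l1 = lo1c[a1];
            for (int b1 = 0; b1 < hi1c.size(); ++b1) {
              int h1 = hi1c[b1];
              int d1 = h1 - l1 + 1;
              if (d1 < minDim) continue;
              double pSum = boxSumC(S, n1, n2, l1, h1, l2, h2, l3, h3);
              double pen;
              if (penaltyMode == 0) {
                double s = d1 + d2 + d3;
                pen = s * s;
              } else {
                double s = (d1 + d2) / 2.0;
                pen = s * s;
              }
              double cg = pSum / pen;
              long vol = (long)d1 * d2 * d3;
              bool better = false;
              if (!found || cg > bestCG) better = true;
              else if (cg == bestCG) {
                if (vol < bestVol) better = true;
                else if (vol == bestVol) {
                  int cur[6] = {l1, l2, l3, h1, h2, h3};
                  for (int t = 0; t < 6; ++t) {
                    if (cur[t] < b[t]) { better = true; break; }
                    if (cur[t] > b[t]) break;
                  }
                }
              }
              if (better) {
                bestCG = cg; bestVol = vol; found = true;
                b[0] = l1; b[1] = l2; b[2] = l3;
                b[3] = h1; b[4] = h2; b[5] = h3;
              }
            }
          }
        }
      }
    }
  }
  if (!found) stop("no candidate cuboid satisfies the minimum dimensions");
  return List::create(_["lo"] = IntegerVector::create(b[0], b[1], b[2]),
                      _["hi"] = IntegerVector::create(b[3], b[4], b[5]),
                      _["cg"] = bestCG);
}
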