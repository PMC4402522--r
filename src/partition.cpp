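#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Partition function and base-pair probabilities for a pair-additive,
// stacking-free RNA secondary-structure model (pseudoknot-free, minimum
// hairpin loop enforced).  Inside recursion over interval partition
// functions Q / Qb, outside recursion for pair probabilities in O(n^3)
// via an auxiliary array T that accumulates enclosing-pair contributions.
//
// All interval quantities are kept per-nucleotide scaled (q = Q / scale^len)
// so that long, strongly pairing sequences do not overflow doubles; pair
// probabilities are scale-invariant and log(Z) is recovered at the end.
//
// Sequence codes: 0=A, 1=C, 2=G, 3=U, 4=N (N never pairs).
// pair_wt is a 5x5 matrix of Boltzmann weights exp(-E/kT); 0 = disallowed.
// unpaired_mask: 1-based positions forced to stay unpaired (for
// constrained-ensemble / substring-PU calculations); may be empty.

// [[Rcpp::export(name = ".partition_cpp")]]
List partition_cpp(IntegerVector codes, NumericMatrix pair_wt,
                   int min_hairpin, double scale,
                   IntegerVector unpaired_mask) {
  const int n = codes.size();
  if (n < 1) stop("empty sequence");
  if (scale <= 0) stop("scale must be positive");

  std::vector<bool> masked(n + 1, false);
  for (int k = 0; k < unpaired_mask.size(); ++k) {
    int p = unpaired_mask[k];
    if (p < 1 || p > n) stop("unpaired_mask position out of range");
    masked[p] = true;
  }

  // q[i][j]: scaled partition function of subsequence i..j (1-based),
  // empty intervals (i > j) have value 1.  Stored as flat (n+2)^2 arrays.
  const int m = n + 2;
  std::vector<double> q((size_t)m * m, 0.0), qb((size_t)m * m, 0.0);
  std::vector<double> pout((size_t)m * m, 0.0), pr((size_t)m * m, 0.0);
  std::vector<double> tarr((size_t)m * m, 0.0);
  auto at = [m](int i, int j) { return (size_t)i * m + j; };
  auto Q = [&](int i, int j) -> double {
    if (i > j) return 1.0;            // empty interval
    return q[at(i, j)];
  };

  auto wt = [&](int i, int j) -> double {
    if (masked[i] || masked[j]) return 0.0;
    return pair_wt(codes[i - 1], codes[j - 1]);
  };

  const double inv_s = 1.0 / scale, inv_s2 = inv_s * inv_s;

  // inside recursion, by increasing span
  for (int i = n; i >= 1; --i) {
    for (int j = i; j <= n; ++j) {
      double w = (j - i - 1 >= min_hairpin) ? wt(i, j) : 0.0;
      if (w > 0.0) qb[at(i, j)] = w * inv_s2 * Q(i + 1, j - 1);
      double acc = Q(i, j - 1) * inv_s;          // j unpaired
      for (int k = i; k <= j - min_hairpin - 1; ++k) {
        double b = qb[at(k, j)];
        if (b > 0.0) acc += Q(i, k - 1) * b;     // j paired with k
      }
      q[at(i, j)] = acc;
    }
  }
  const double qtot = q[at(1, n)];
  const double logZ = std::log(qtot) + n * std::log(scale);

  // outside recursion, by decreasing span.
  // pout[i][j] = scaled outside weight; P[i][j] = qb[i][j] * pout[i][j].
  // tarr[k][j] = sum over finalized pairs (k,l), l > j, of
  //              pout[k][l] * w(k,l) * q(j+1, l-1).
  for (int span = n - 1; span >= min_hairpin + 1; --span) {
    for (int i = 1; i + span <= n; ++i) {
      int j = i + span;
      if (qb[at(i, j)] <= 0.0) continue;
      double ext = Q(1, i - 1) * Q(j + 1, n) / qtot;
      double enc = 0.0;
      for (int k = 1; k < i; ++k) {
        double t = tarr[at(k, j)];
        if (t != 0.0) enc += Q(k + 1, i - 1) * t;
      }
      double po = ext + inv_s2 * enc;
      pout[at(i, j)] = po;
      pr[at(i, j)] = qb[at(i, j)] * po;
      // push contribution of (i,j) as an enclosing pair for all j' < j
      double w = wt(i, j);
      double base = po * w;
      for (int jp = i; jp < j; ++jp)
        tarr[at(i, jp)] += base * Q(jp + 1, j - 1);
    }
  }

  NumericMatrix P(n, n);
  for (int i = 1; i <= n; ++i)
    for (int j = i + 1; j <= n; ++j) {
      double v = pr[at(i, j)];
      if (v < 0) v = 0;
      if (v > 1) v = 1;
      P(i - 1, j - 1) = v;
      P(j - 1, i - 1) = v;
    }

  return List::create(_["p"] = P, _["logZ"] = logZ);
}
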