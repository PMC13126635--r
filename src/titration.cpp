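#include <Rcpp.h>
using namespace Rcpp;

// Microstate energy convention (kcal/mol):
//   E(s, pH) = sum_i s_i * a_i + sum_{i<j} W_ij s_i s_j
// with a_i = 2.303 * R * T * (pH - pKa_int,i) + phi_i.
// The a_i vector is assembled on the R side; here we only need a, W and RT.

static inline double flip_delta(const IntegerVector& s, int k,
                                const NumericVector& a,
                                const NumericMatrix& W) {
  const int n = s.size();
  double de = a[k];
  for (int j = 0; j < n; ++j) {
    if (j != k && s[j]) de += W(k, j);
  }
  return s[k] ? -de : de;
}

// Metropolis single-site flips at fixed pH. One cycle = n_sites attempted
// flips at uniformly chosen sites. Uses R's RNG so results are reproducible
// under set.seed() on the calling side.
// [[Rcpp::export]]
List cpp_sample_states(NumericVector a, NumericMatrix W, double rt,
                       int n_cycles, int burn_in_cycles,
                       IntegerVector init) {
  const int n = a.size();
  IntegerVector s = clone(init);
  NumericVector occ_sum(n);
  long n_rec = 0;

  // batch means for a Monte Carlo standard error of the per-site occupancy
  const int n_batches = 10;
  NumericMatrix batch_sum(n_batches, n);
  IntegerVector batch_n(n_batches);

  const int n_record = n_cycles - burn_in_cycles;
  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    for (int t = 0; t < n; ++t) {
      int k = (int)(unif_rand() * n);
      if (k == n) k = n - 1;
      double de = flip_delta(s, k, a, W);
      if (de <= 0.0 || unif_rand() < std::exp(-de / rt)) s[k] = 1 - s[k];
    }
    if (cyc >= burn_in_cycles) {
      int rec = cyc - burn_in_cycles;
      int b = (int)((double)rec * n_batches / n_record);
      if (b >= n_batches) b = n_batches - 1;
      for (int i = 0; i < n; ++i) {
        occ_sum[i] += s[i];
        batch_sum(b, i) += s[i];
      }
      batch_n[b] += 1;
      ++n_rec;
    }
  }

  NumericVector mean_occ(n), se_occ(n);
  for (int i = 0; i < n; ++i) mean_occ[i] = occ_sum[i] / n_rec;
  int used = 0;
  for (int b = 0; b < n_batches; ++b) if (batch_n[b] > 0) ++used;
  for (int i = 0; i < n; ++i) {
    double m = mean_occ[i], ss = 0.0;
    for (int b = 0; b < n_batches; ++b) {
      if (batch_n[b] > 0) {
        double bm = batch_sum(b, i) / batch_n[b];
        ss += (bm - m) * (bm - m);
      }
    }
    se_occ[i] = used > 1 ? std::sqrt(ss / (used * (used - 1.0))) : NA_REAL;
  }

  return List::create(_["final_state"] = s,
                      _["mean_occupancy"] = mean_occ,
                      _["se_occupancy"] = se_occ,
                      _["n_recorded"] = (double)n_rec);
}

// Exact Boltzmann averages over all 2^N microstates.
// [[Rcpp::export]]
NumericVector cpp_exact_occupancies(NumericVector a, NumericMatrix W,
                                    double rt) {
  const int n = a.size();
  if (n > 20) stop("exact enumeration limited to 20 sites");
  const unsigned long nstates = 1UL << n;
  long double z = 0.0L;
  std::vector<long double> num(n, 0.0L);
  std::vector<int> s(n);
  for (unsigned long code = 0; code < nstates; ++code) {
    double e = 0.0;
    for (int i = 0; i < n; ++i) s[i] = (code >> i) & 1UL;
    for (int i = 0; i < n; ++i) {
      if (!s[i]) continue;
      e += a[i];
      for (int j = i + 1; j < n; ++j) if (s[j]) e += W(i, j);
    }
    long double w = expl(-(long double)e / rt);
    z += w;
    for (int i = 0; i < n; ++i) if (s[i]) num[i] += w;
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (double)(num[i] / z);
  return out;
}
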