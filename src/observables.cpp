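// Pair-distance kernels shared by the structural observables: mean squared
// internal distances, contact probability by genomic separation (optionally
// split by epigenomic state), binned contact maps, and band-pooled contact
// counts for intra/inter-state ratio time courses.
//
// Snapshot layout (as produced by the KMC engine): for snapshot k the
// unwrapped grid coordinates of monomer i are at
//   snaps[k*3N + i], snaps[k*3N + N + i], snaps[k*3N + 2N + i].

#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_pair_stats(IntegerVector snaps, int N, IntegerVector frames,
                    double a, double dc, IntegerVector states) {
  bool has_states = states.size() == N;
  double a2 = a * a;
  double dc2_grid = (dc / a) * (dc / a);
  int nsep = N - 1;
  NumericVector sumR2(nsep), sumR4(nsep), n(nsep), ncontact(nsep);
  NumericVector n_intra(nsep), c_intra(nsep), n_inter(nsep), c_inter(nsep);
  const int *sp = INTEGER(snaps);
  for (int f = 0; f < frames.size(); ++f) {
    const int *x = sp + (int64_t)frames[f] * 3 * N;
    const int *y = x + N, *z = x + 2 * N;
    for (int i = 0; i < N - 1; ++i) {
      for (int j = i + 1; j < N; ++j) {
        double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
        double d2 = dx * dx + dy * dy + dz * dz;   // grid units^2
        int s = j - i - 1;
        double r2 = d2 * a2;
        sumR2[s] += r2; sumR4[s] += r2 * r2; n[s] += 1;
        bool contact = d2 < dc2_grid;
        if (contact) ncontact[s] += 1;
        if (has_states) {
          if (states[i] == states[j]) {
            n_intra[s] += 1; if (contact) c_intra[s] += 1;
          } else {
            n_inter[s] += 1; if (contact) c_inter[s] += 1;
          }
        }
      }
    }
  }
  return List::create(_["n"] = n, _["sumR2"] = sumR2, _["sumR4"] = sumR4,
                      _["ncontact"] = ncontact, _["n_intra"] = n_intra,
                      _["c_intra"] = c_intra, _["n_inter"] = n_inter,
                      _["c_inter"] = c_inter);
}

// [[Rcpp::export]]
NumericMatrix cpp_contact_map(IntegerVector snaps, int N, IntegerVector frames,
                              double a, double dc, int bin) {
  int nbin = (N + bin - 1) / bin;
  NumericMatrix counts(nbin, nbin);
  double dc2_grid = (dc / a) * (dc / a);
  const int *sp = INTEGER(snaps);
  for (int f = 0; f < frames.size(); ++f) {
    const int *x = sp + (int64_t)frames[f] * 3 * N;
    const int *y = x + N, *z = x + 2 * N;
    for (int i = 0; i < N; ++i) {
      int bi = i / bin;
      counts(bi, bi) += 0;  // touch diagonal even if no self pairs
      for (int j = i + 1; j < N; ++j) {
        double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
        if (dx * dx + dy * dy + dz * dz < dc2_grid) {
          int bj = j / bin;
          counts(bi, bj) += 1;
          if (bi != bj) counts(bj, bi) += 1;
        }
      }
    }
  }
  return counts;
}

// [[Rcpp::export]]
List cpp_sep_contacts(IntegerVector snaps, int N, IntegerVector frames,
                      double a, double dc, IntegerVector states,
                      int s_max) {
  // per-frame, per-separation contact counts (all pairs and same-state
  // pairs) up to separation s_max; static per-separation pair counts
  int nf = frames.size();
  bool has_states = states.size() == N;
  if (s_max > N - 1) s_max = N - 1;
  NumericMatrix c_all(nf, s_max), c_intra(nf, s_max);
  NumericVector p_all(s_max), p_intra(s_max);
  for (int s = 1; s <= s_max; ++s) {
    p_all[s - 1] = N - s;
    if (has_states)
      for (int i = 0; i + s < N; ++i)
        if (states[i] == states[i + s]) p_intra[s - 1] += 1;
  }
  double dc2_grid = (dc / a) * (dc / a);
  const int *sp = INTEGER(snaps);
  for (int f = 0; f < nf; ++f) {
    const int *x = sp + (int64_t)frames[f] * 3 * N;
    const int *y = x + N, *z = x + 2 * N;
    for (int i = 0; i < N - 1; ++i) {
      int jmax = i + s_max; if (jmax > N - 1) jmax = N - 1;
      for (int j = i + 1; j <= jmax; ++j) {
        double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
        if (dx * dx + dy * dy + dz * dz < dc2_grid) {
          int s = j - i - 1;
          c_all(f, s) += 1;
          if (has_states && states[i] == states[j]) c_intra(f, s) += 1;
        }
      }
    }
  }
  return List::create(_["contacts_all"] = c_all,
                      _["contacts_intra"] = c_intra,
                      _["pairs_all"] = p_all, _["pairs_intra"] = p_intra);
}
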