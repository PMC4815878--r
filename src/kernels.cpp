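#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Coherent bead-sum intensity |sum_j w_j exp(i q.x_j)|^2 for a set of
// scattering vectors. qvecs: npix x 3, coords: nbead x 3 (same length units
// so q.x is dimensionless). Returns length-npix intensities, NOT normalized.
// [[Rcpp::export(name = ".bead_intensity_cpp")]]
NumericVector bead_intensity_cpp(NumericMatrix qvecs, NumericMatrix coords,
                                 NumericVector weights) {
  const int npix = qvecs.nrow();
  const int nb = coords.nrow();
  NumericVector out(npix);
  for (int p = 0; p < npix; ++p) {
    const double qx = qvecs(p, 0), qy = qvecs(p, 1), qz = qvecs(p, 2);
    double re = 0.0, im = 0.0;
    for (int j = 0; j < nb; ++j) {
      const double ph = qx * coords(j, 0) + qy * coords(j, 1) + qz * coords(j, 2);
      re += weights[j] * std::cos(ph);
      im += weights[j] * std::sin(ph);
    }
    out[p] = re * re + im * im;
  }
  return out;
}

// Debye sum over distinct pairs: for each q, sum_ij w_i w_j sinc(q r_ij)
// excluding the self terms (added by the caller together with the bead
// form factor). dists/pairw: pairwise distances and weight products for
// i < j, each pair once.
// [[Rcpp::export(name = ".debye_pairs_cpp")]]
NumericVector debye_pairs_cpp(NumericVector q, NumericVector dists,
                              NumericVector pairw) {
  const int nq = q.size();
  const R_xlen_t np = dists.size();
  NumericVector out(nq);
  for (int k = 0; k < nq; ++k) {
    const double qk = q[k];
    double s = 0.0;
    if (qk == 0.0) {
      for (R_xlen_t p = 0; p < np; ++p) s += pairw[p];
    } else {
      for (R_xlen_t p = 0; p < np; ++p) {
        const double x = qk * dists[p];
        s += (x < 1e-9) ? pairw[p] : pairw[p] * std::sin(x) / x;
      }
    }
    out[k] = 2.0 * s;  // each unordered pair counted twice in the full sum
  }
  return out;
}

// Pairwise distances (i < j) of an n x 3 coordinate matrix, plus the
// matching weight products. Returns a list(d, w2).
// [[Rcpp::export(name = ".pair_dists_cpp")]]
List pair_dists_cpp(NumericMatrix coords, NumericVector weights) {
  const int n = coords.nrow();
  const R_xlen_t np = (R_xlen_t)n * (n - 1) / 2;
  NumericVector d(np), w2(np);
  R_xlen_t k = 0;
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    const double wi = weights[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - coords(j, 0);
      const double dy = yi - coords(j, 1);
      const double dz = zi - coords(j, 2);
      d[k] = std::sqrt(dx * dx + dy * dy + dz * dz);
      w2[k] = wi * weights[j];
      ++k;
    }
  }
  return List::create(_["d"] = d, _["w2"] = w2);
}

// Distance histogram of all bead pairs (i < j), computed without
// materializing the pair list: bin b covers [b*dmax/nbins, (b+1)*dmax/nbins)
// and accumulates the weight products. Also returns the maximum distance.
// [[Rcpp::export(name = ".debye_hist_cpp")]]
List debye_hist_cpp(NumericMatrix coords, NumericVector weights, int nbins,
                    double dmax) {
  const int n = coords.nrow();
  NumericVector h(nbins);
  const double scale = nbins / dmax;
  double seen_max = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    const double wi = weights[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - coords(j, 0);
      const double dy = yi - coords(j, 1);
      const double dz = zi - coords(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > seen_max) seen_max = d;
      int b = (int)(d * scale);
      if (b >= nbins) b = nbins - 1;
      h[b] += wi * weights[j];
    }
  }
  return List::create(_["h"] = h, _["dmax_seen"] = seen_max);
}

// Spherical average of the bead-sum intensity: for each magnitude q[k],
// mean over unit direction rows of dirs of |sum_j w_j exp(i q u.x_j)|^2.
// [[Rcpp::export(name = ".spherical_average_cpp")]]
NumericVector spherical_average_cpp(NumericVector q, NumericMatrix dirs,
                                    NumericMatrix coords,
                                    NumericVector weights) {
  const int nq = q.size();
  const int nd = dirs.nrow();
  const int nb = coords.nrow();
  NumericVector out(nq);
  for (int k = 0; k < nq; ++k) {
    double acc = 0.0;
    for (int u = 0; u < nd; ++u) {
      const double qx = q[k] * dirs(u, 0);
      const double qy = q[k] * dirs(u, 1);
      const double qz = q[k] * dirs(u, 2);
      double re = 0.0, im = 0.0;
      for (int j = 0; j < nb; ++j) {
        const double ph =
            qx * coords(j, 0) + qy * coords(j, 1) + qz * coords(j, 2);
        re += weights[j] * std::cos(ph);
        im += weights[j] * std::sin(ph);
      }
      acc += re * re + im * im;
    }
    out[k] = acc / nd;
  }
  return out;
}
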