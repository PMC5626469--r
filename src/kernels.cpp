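#include <Rcpp.h>
using namespace Rcpp;

// Per-pixel log survival of an all-zero encounter history:
//   B[g] = sum over operational (j, k) of log(1 - p0[j,k] * exp(-d2[j,g] / (2 sigma^2)))
// Evaluated only at the pixel columns requested (1-based indices).
// [[Rcpp::export]]
NumericVector kernel_logsurv(NumericMatrix dist2, NumericMatrix p0,
                             IntegerMatrix oper, double sigma,
                             IntegerVector pixels) {
  const int J = dist2.nrow(), K = p0.ncol(), nP = pixels.size();
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  // per-trap sums and maxima of p0 over operational occasions: when the
  // kernel is tiny, sum_k log1p(-p0 kern) = -kern * sum_k p0 to below
  // double precision, which skips the transcendental inner loop for the
  // (many) distant trap-pixel pairs
  std::vector<double> p0sum(J, 0.0), p0max(J, 0.0);
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < K; ++k)
      if (oper(j, k) == 1) {
        p0sum[j] += p0(j, k);
        if (p0(j, k) > p0max[j]) p0max[j] = p0(j, k);
      }
  NumericVector out(nP);
  for (int q = 0; q < nP; ++q) {
    const int g = pixels[q] - 1;
    double acc = 0.0;
    for (int j = 0; j < J; ++j) {
      if (p0sum[j] == 0.0) continue;
      const double kern = std::exp(-dist2(j, g) * inv2s2);
      if (kern * p0max[j] < 1e-8) {
        acc -= kern * p0sum[j];        // |error| < K * (1e-8)^2 / 2
        continue;
      }
      for (int k = 0; k < K; ++k) {
        if (oper(j, k) == 0) continue;
        acc += std::log1p(-p0(j, k) * kern);
      }
    }
    out[q] = acc;
  }
  return out;
}

// For a set of detections (trap j, occasion k), the per-pixel adjustment
// converting an all-zero history into the observed one:
//   A[g] = sum over detections of [log p(j,k,g) - log(1 - p(j,k,g))]
// so that individual log likelihood = B[g] + A[g].
// [[Rcpp::export]]
NumericVector kernel_det_adjust(NumericMatrix dist2, NumericMatrix p0,
                                IntegerVector det_j, IntegerVector det_k,
                                double sigma, IntegerVector pixels) {
  const int nD = det_j.size(), nP = pixels.size();
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  // log p = log p0 - d^2/(2 sigma^2): hoist the log p0 terms per detection
  std::vector<double> lp0(nD);
  for (int d = 0; d < nD; ++d) lp0[d] = std::log(p0(det_j[d] - 1, det_k[d] - 1));
  NumericVector out(nP);
  for (int q = 0; q < nP; ++q) {
    const int g = pixels[q] - 1;
    double acc = 0.0;
    for (int d = 0; d < nD; ++d) {
      const int j = det_j[d] - 1, k = det_k[d] - 1;
      const double e = dist2(j, g) * inv2s2;
      acc += lp0[d] - e - std::log1p(-p0(j, k) * std::exp(-e));
    }
    out[q] = acc;
  }
  return out;
}

// Batched version for total-likelihood evaluations: detections of several
// individuals concatenated (offsets CSR-style, 0-based, length n+1), each
// individual evaluated at one pixel (1-based).  Returns one adjustment per
// individual.
// [[Rcpp::export]]
NumericVector kernel_det_adjust_batch(NumericMatrix dist2, NumericMatrix p0,
                                      IntegerVector det_j, IntegerVector det_k,
                                      IntegerVector offsets, double sigma,
                                      IntegerVector pixel) {
  const int n = offsets.size() - 1;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const int g = pixel[i] - 1;
    double acc = 0.0;
    for (int d = offsets[i]; d < offsets[i + 1]; ++d) {
      const int j = det_j[d] - 1, k = det_k[d] - 1;
      const double p = p0(j, k) * std::exp(-dist2(j, g) * inv2s2);
      acc += std::log(p) - std::log1p(-p);
    }
    out[i] = acc;
  }
  return out;
}

// Half-normal kernel matrix exp(-d2 / (2 sigma^2)): computed once per
// sigma and shared by the updates that leave sigma unchanged.
// [[Rcpp::export]]
NumericMatrix halfnorm_kernel(NumericMatrix dist2, double sigma) {
  const int J = dist2.nrow(), G = dist2.ncol();
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  NumericMatrix out(J, G);
  for (int g = 0; g < G; ++g)
    for (int j = 0; j < J; ++j)
      out(j, g) = std::exp(-dist2(j, g) * inv2s2);
  return out;
}

// kernel_logsurv with a precomputed kernel matrix.  For trap-pixel pairs
// with small encounter probability the occasion loop is replaced by the
// quadratic expansion sum_k log1p(-p0 k) = -k sum p0 - k^2 sum p0^2 / 2,
// whose error (< K x^3 / 3 at x < 1e-4) is far below MCMC resolution.
// [[Rcpp::export]]
NumericVector kernel_logsurv_k(NumericMatrix kern, NumericMatrix p0,
                               IntegerMatrix oper, IntegerVector pixels) {
  const int J = kern.nrow(), K = p0.ncol(), nP = pixels.size();
  std::vector<double> p0sum(J, 0.0), p0sq(J, 0.0), p0max(J, 0.0);
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < K; ++k)
      if (oper(j, k) == 1) {
        p0sum[j] += p0(j, k);
        p0sq[j] += p0(j, k) * p0(j, k);
        if (p0(j, k) > p0max[j]) p0max[j] = p0(j, k);
      }
  NumericVector out(nP);
  for (int q = 0; q < nP; ++q) {
    const int g = pixels[q] - 1;
    double acc = 0.0;
    for (int j = 0; j < J; ++j) {
      if (p0sum[j] == 0.0) continue;
      const double kk = kern(j, g);
      if (kk * p0max[j] < 1e-4) {
        acc -= kk * p0sum[j] + 0.5 * kk * kk * p0sq[j];
        continue;
      }
      for (int k = 0; k < K; ++k) {
        if (oper(j, k) == 0) continue;
        acc += std::log1p(-p0(j, k) * kk);
      }
    }
    out[q] = acc;
  }
  return out;
}

// draw one index from the categorical distribution with unnormalised log
// weights (1-based return); uses R's RNG for reproducibility
// [[Rcpp::export]]
int sample_categorical_log(NumericVector logw) {
  const int n = logw.size();
  double m = logw[0];
  for (int i = 1; i < n; ++i) if (logw[i] > m) m = logw[i];
  double tot = 0.0;
  std::vector<double> w(n);
  for (int i = 0; i < n; ++i) { w[i] = std::exp(logw[i] - m); tot += w[i]; }
  const double u = R::unif_rand() * tot;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    acc += w[i];
    if (u <= acc) return i + 1;
  }
  return n;
}

// kernel_det_adjust with a precomputed kernel matrix (dist2 supplies the
// log of the kernel without a transcendental call)
// [[Rcpp::export]]
NumericVector kernel_det_adjust_k(NumericMatrix dist2, NumericMatrix kern,
                                  NumericMatrix p0, IntegerVector det_j,
                                  IntegerVector det_k, double sigma,
                                  IntegerVector pixels) {
  const int nD = det_j.size(), nP = pixels.size();
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<double> lp0(nD);
  for (int d = 0; d < nD; ++d) lp0[d] = std::log(p0(det_j[d] - 1, det_k[d] - 1));
  NumericVector out(nP);
  for (int q = 0; q < nP; ++q) {
    const int g = pixels[q] - 1;
    double acc = 0.0;
    for (int d = 0; d < nD; ++d) {
      const int j = det_j[d] - 1, k = det_k[d] - 1;
      acc += lp0[d] - dist2(j, g) * inv2s2 -
             std::log1p(-p0(j, k) * kern(j, g));
    }
    out[q] = acc;
  }
  return out;
}

// batched total-likelihood adjustments with a precomputed kernel
// [[Rcpp::export]]
NumericVector kernel_det_adjust_batch_k(NumericMatrix dist2,
                                        NumericMatrix kern, NumericMatrix p0,
                                        IntegerVector det_j,
                                        IntegerVector det_k,
                                        IntegerVector offsets, double sigma,
                                        IntegerVector pixel) {
  const int n = offsets.size() - 1;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const int g = pixel[i] - 1;
    double acc = 0.0;
    for (int d = offsets[i]; d < offsets[i + 1]; ++d) {
      const int j = det_j[d] - 1, k = det_k[d] - 1;
      const double p = p0(j, k) * kern(j, g);
      acc += std::log(p) - std::log1p(-p);
    }
    out[i] = acc;
  }
  return out;
}
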