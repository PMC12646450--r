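#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Kaspar-Schuster production complexity c(S): the number of phrases in the
// exhaustive-history parse of an integer symbol sequence. Works for any
// finite alphabet.
// [[Rcpp::export]]
int lzc_ks_cpp(IntegerVector s) {
  const int n = s.size();
  if (n == 0) stop("empty sequence");
  int c = 1, u = 1, v = 1, vmax = 1, i = 0;
  while (u + v <= n) {
    if (s[i + v - 1] == s[u + v - 1]) {
      ++v;
    } else {
      if (v > vmax) vmax = v;
      ++i;
      if (i == u) {          // every start position tried: new phrase
        ++c;
        u += vmax;
        i = 0;
        v = 1;
        vmax = 1;
      } else {
        v = 1;
      }
    }
  }
  if (v != 1) ++c;           // unfinished trailing phrase counts
  return c;
}

static arma::vec iir_filter(const arma::vec& b, const arma::vec& a,
                            const arma::vec& x) {
  const int nb = b.n_elem, na = a.n_elem, n = x.n_elem;
  const int nz = std::max(nb, na) - 1;
  arma::vec z(nz, arma::fill::zeros), y(n);
  arma::vec bb(nz + 1, arma::fill::zeros), aa(nz + 1, arma::fill::zeros);
  bb.head(nb) = b; aa.head(na) = a;
  for (int t = 0; t < n; ++t) {
    double yt = bb[0] * x[t] + (nz ? z[0] : 0.0);
    for (int i = 0; i < nz - 1; ++i)
      z[i] = bb[i + 1] * x[t] + z[i + 1] - aa[i + 1] * yt;
    if (nz) z[nz - 1] = bb[nz] * x[t] - aa[nz] * yt;
    y[t] = yt;
  }
  return y;
}

// Zero-phase IIR filtering: odd-reflection padding at both ends, then
// forward and reverse passes of the direct-form-II-transposed filter.
// [[Rcpp::export]]
arma::vec filtfilt_cpp(const arma::vec& b, const arma::vec& a,
                       const arma::vec& x, int pad) {
  const int n = x.n_elem;
  if (n < 2) stop("signal too short to filter");
  const int L = std::min(pad, n - 1);
  arma::vec ext(n + 2 * L);
  for (int i = 0; i < L; ++i) ext[i] = 2.0 * x[0] - x[L - i];
  ext.subvec(L, L + n - 1) = x;
  for (int i = 0; i < L; ++i)
    ext[L + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  arma::vec y = iir_filter(b, a, ext);
  y = arma::reverse(y);
  y = iir_filter(b, a, y);
  y = arma::reverse(y);
  return y.subvec(L, L + n - 1);
}

// Surrogate phase-lag-index ensemble for one narrowband-filtered
// multichannel segment set. For each of `ns` surrogates, every channel of
// every epoch keeps its amplitude spectrum but receives independent
// uniform random phases (destroying all cross-channel phase structure);
// the analytic signal is synthesized directly from the positive-frequency
// half-spectrum, and PLI = |mean sign(Im(z_a conj(z_b)))| is computed per
// channel pair after trimming a fraction `trim` of samples at each end.
// One surrogate's PLI is the average over the supplied epochs, mirroring
// the real-data estimator. Uses R's RNG: deterministic under set.seed().
//
// `epochs`: list of samples x channels real matrices (one frequency band).
// Returns an ns x npairs matrix of surrogate PLI values; pairs are in
// column-major upper-triangle order (1-2, 1-3, 2-3, 1-4, ...).
// [[Rcpp::export]]
NumericMatrix surrogate_pli_ensemble_cpp(List epochs, int ns, double trim) {
  const int n_ep = epochs.size();
  if (n_ep == 0) stop("no epochs supplied");
  if (ns < 1) stop("ns must be >= 1");
  NumericMatrix first = epochs[0];
  const int nch = first.ncol();
  const int npair = nch * (nch - 1) / 2;

  // precompute per-epoch, per-channel amplitude spectra (one forward FFT
  // each). Bins below 1e-10 of the channel maximum are zeroed: they carry
  // no phase information for a narrowband input and subnormal magnitudes
  // would dominate the runtime.
  std::vector<int> nlen(n_ep);
  std::vector<std::vector<arma::vec>> amp(n_ep);
  std::vector<std::vector<arma::cx_double>> dc(n_ep), nyq(n_ep);
  for (int e = 0; e < n_ep; ++e) {
    NumericMatrix em = epochs[e];
    const int n = em.nrow();
    if (em.ncol() != nch) stop("epochs disagree in channel count");
    const int half = n / 2;
    if (n - 2 * (int)std::floor(n * trim) < 2)
      stop("epoch too short after edge trimming");
    nlen[e] = n;
    amp[e].resize(nch); dc[e].resize(nch); nyq[e].resize(nch);
    for (int ch = 0; ch < nch; ++ch) {
      arma::vec x(n);
      for (int t = 0; t < n; ++t) x[t] = em(t, ch);
      arma::cx_vec F = arma::fft(x);
      amp[e][ch] = arma::abs(F.subvec(1, half - 1));
      double thresh = 1e-10 * amp[e][ch].max();
      amp[e][ch].elem(arma::find(amp[e][ch] < thresh)).zeros();
      dc[e][ch] = F[0];
      nyq[e][ch] = (n % 2 == 0) ? F[half] : arma::cx_double(0.0, 0.0);
    }
  }

  NumericMatrix out(ns, npair);
  for (int s = 0; s < ns; ++s) {
    std::vector<double> acc(npair, 0.0);
    for (int e = 0; e < n_ep; ++e) {
      const int n = nlen[e];
      const int half = n / 2;
      const int t0 = (int)std::floor(n * trim);
      const int t1 = n - t0;
      arma::cx_mat z(n, nch);
      arma::cx_vec spec(n);
      for (int ch = 0; ch < nch; ++ch) {
        spec.zeros();
        spec[0] = dc[e][ch];
        for (int k = 1; k < half; ++k) {
          double a = amp[e][ch][k - 1];
          if (a == 0.0) continue;
          double phi = unif_rand() * 2.0 * M_PI;
          // analytic-signal convention: double the positive frequencies
          spec[k] = arma::cx_double(2.0 * a * std::cos(phi),
                                    2.0 * a * std::sin(phi));
        }
        if (n % 2 == 0) spec[half] = nyq[e][ch];
        z.col(ch) = arma::ifft(spec);
      }
      int p = 0;
      for (int b = 1; b < nch; ++b) {
        for (int a = 0; a < b; ++a) {
          double sum = 0.0;
          for (int t = t0; t < t1; ++t) {
            double im = std::imag(z(t, a) * std::conj(z(t, b)));
            sum += (im > 0) - (im < 0);
          }
          acc[p++] += std::fabs(sum / (t1 - t0));
        }
      }
    }
    for (int p = 0; p < npair; ++p) out(s, p) = acc[p] / n_ep;
  }
  return out;
}
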