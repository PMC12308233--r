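// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Noise with a prescribed one-sided PSD, synthesized by frequency-domain
// overlap-add of sqrt-Hann windowed blocks (hop = B/2). Each block gets
// the exact target magnitude spectrum with phases drawn uniformly through
// the R RNG (so set.seed() controls output); the sum over ~32k independent
// phased bins makes the time samples Gaussian to any practical degree.
// `amp` holds per-bin spectral magnitudes for bins 0..B/2 of a block of
// size B: amp[k] = sqrt(B * fs * S_two(f_k)).
// [[Rcpp::export]]
arma::vec cpp_shaped_noise(int n, const arma::vec& amp) {
  const int B = 2 * ((int)amp.n_elem - 1);
  const int H = B / 2;
  const int nb = (n + H) / H + 1; // blocks starting at -H, 0, H, ...
  arma::vec out(n, arma::fill::zeros);
  arma::vec w(B);
  for (int t = 0; t < B; ++t)
    w[t] = std::sqrt(0.5 * (1.0 - std::cos(2.0 * M_PI * t / B)));
  arma::cx_vec X(B);
  for (int b = 0; b < nb; ++b) {
    const int s = -H + b * H;
    NumericVector ph = runif(H - 1, 0.0, 2.0 * M_PI);
    X[0] = arma::cx_double(0.0, 0.0);
    for (int k = 1; k < H; ++k)
      X[k] = std::polar(amp[k], ph[k - 1]);
    X[H] = arma::cx_double((unif_rand() < 0.5 ? -1.0 : 1.0) * amp[H], 0.0);
    for (int k = H + 1; k < B; ++k) X[k] = std::conj(X[B - k]);
    arma::vec xb = arma::real(arma::ifft(X));
    const int t0 = std::max(0, -s);
    const int t1 = std::min(B, n - s);
    for (int t = t0; t < t1; ++t) out[s + t] += w[t] * xb[t];
  }
  return out;
}

// Polyphase rational resampler (upfirdn): upsample by p, FIR filter h
// (designed at rate p*fs, already scaled by p), downsample by q.
// Output sample m corresponds to upsampled index m*q; the filter group
// delay (len(h)-1)/2 is compensated so input/output timestamps align.
// [[Rcpp::export]]
arma::vec cpp_upfirdn(const arma::vec& x, const arma::vec& h, int p, int q) {
  const long long n = x.n_elem, nh = h.n_elem;
  const long long delay = (nh - 1) / 2;
  const long long nout = (long long)std::llround((double)n * p / q);
  arma::vec y(nout, arma::fill::zeros);
  // contiguous polyphase branches: hp[r] holds h[r], h[r+p], ...
  const long long blen = (nh + p - 1) / p;
  std::vector<std::vector<double>> hp(p, std::vector<double>(blen, 0.0));
  for (long long j = 0; j < nh; ++j) hp[j % p][j / p] = h[j];
  for (long long m = 0; m < nout; ++m) {
    const long long i0 = m * (long long)q + delay;
    const int r = (int)(i0 % p);
    const long long xtop = i0 / p; // x index paired with hp[r][0]
    const std::vector<double>& hr = hp[r];
    const long long jmax = std::min<long long>((long long)hr.size(), xtop + 1);
    const long long jmin = std::max<long long>(0, xtop - (n - 1));
    double acc = 0.0;
    const double* xp = x.memptr() + xtop;
    for (long long j = jmin; j < jmax; ++j) acc += hr[j] * xp[-j];
    y[m] = acc;
  }
  return y;
}

// Windowed short-time power spectra: |FFT(w * frame)|^2 for bins
// 0..nfft/2, frames of length(w) samples advanced by `hop`. The trailing
// partial frame is dropped. Scaling to PSD units happens in R.
// [[Rcpp::export]]
arma::mat cpp_frame_power(const arma::vec& x, const arma::vec& w, int hop) {
  const int nfft = w.n_elem;
  const int nb = nfft / 2 + 1;
  if ((int)x.n_elem < nfft) Rcpp::stop("segment shorter than one frame");
  const int nf = (int)((x.n_elem - nfft) / hop) + 1;
  arma::mat out(nb, nf);
  arma::vec buf(nfft);
  for (int j = 0; j < nf; ++j) {
    const long long s = (long long)j * hop;
    for (int t = 0; t < nfft; ++t) buf[t] = x[s + t] * w[t];
    arma::cx_vec F = arma::fft(buf);
    for (int k = 0; k < nb; ++k) out(k, j) = std::norm(F[k]);
  }
  return out;
}

// Fused framing + PSD + per-bin median for one segment: avoids
// materializing the bins x frames matrix on the R side. `scale` is the
// per-bin PSD scale (one-sided factors included).
// [[Rcpp::export]]
arma::vec cpp_frame_psd_median(const arma::vec& x, const arma::vec& w,
                               int hop, const arma::vec& scale) {
  const int nfft = w.n_elem;
  const int nb = nfft / 2 + 1;
  if ((int)x.n_elem < nfft) Rcpp::stop("segment shorter than one frame");
  const int nf = (int)((x.n_elem - nfft) / hop) + 1;
  arma::mat P(nb, nf);
  arma::vec buf(nfft);
  for (int j = 0; j < nf; ++j) {
    const long long s = (long long)j * hop;
    for (int t = 0; t < nfft; ++t) buf[t] = x[s + t] * w[t];
    arma::cx_vec F = arma::fft(buf);
    for (int k = 0; k < nb; ++k) P(k, j) = std::norm(F[k]) * scale[k];
  }
  arma::vec out(nb);
  std::vector<double> v(nf);
  for (int k = 0; k < nb; ++k) {
    for (int j = 0; j < nf; ++j) v[j] = P(k, j);
    const int mid = nf / 2;
    std::nth_element(v.begin(), v.begin() + mid, v.end());
    if (nf % 2 == 1) out[k] = v[mid];
    else out[k] = 0.5 * (v[mid] + *std::max_element(v.begin(), v.begin() + mid));
  }
  return out;
}

// Per-row median with midpoint convention for even counts.
// [[Rcpp::export]]
arma::vec cpp_row_medians(const arma::mat& m) {
  const int nr = m.n_rows, nc = m.n_cols;
  arma::vec out(nr);
  std::vector<double> v(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) v[j] = m(i, j);
    const int mid = nc / 2;
    std::nth_element(v.begin(), v.begin() + mid, v.end());
    if (nc % 2 == 1) {
      out[i] = v[mid];
    } else {
      double hi = v[mid];
      double lo = *std::max_element(v.begin(), v.begin() + mid);
      out[i] = 0.5 * (lo + hi);
    }
  }
  return out;
}

// Add damped-sinusoid snap transients in place: one kernel per snap,
// onset sample pos[i] (1-based), centre frequency fc[i], peak amplitude
// amp[i], shared decay tau at rate fs. Kernel sampled until its envelope
// falls below 1% of peak, matching make_snap_kernel().
// [[Rcpp::export]]
arma::vec cpp_add_snaps(const arma::vec& x, const arma::vec& pos,
                        const arma::vec& fc, const arma::vec& amp,
                        double tau, double fs) {
  arma::vec out = x;
  const long long n = out.n_elem;
  const int klen = (int)std::ceil(tau * std::log(100.0) * fs);
  std::vector<double> kern(klen);
  for (arma::uword i = 0; i < pos.n_elem; ++i) {
    double peak = 0.0;
    for (int t = 0; t < klen; ++t) {
      double tt = t / fs;
      kern[t] = std::exp(-tt / tau) * std::sin(2.0 * M_PI * fc[i] * tt);
      peak = std::max(peak, std::abs(kern[t]));
    }
    const double s = amp[i] / peak;
    const long long j0 = (long long)pos[i] - 1;
    const long long j1 = std::min(n, j0 + klen);
    for (long long j = j0; j < j1; ++j) out[j] += s * kern[j - j0];
  }
  return out;
}
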