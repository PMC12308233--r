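#' Band analysis configurations
#'
#' A band configuration fixes the short-time FFT analysis of one frequency
#' band: the analysis sample rate, FFT length, frame overlap, Kaiser window
#' shape and the frequency limits inside which the spectral peak is searched.
#' The two standard configurations mirror common reef-PAM practice: the
#' low-frequency (LF) fish band is analysed at 4 kHz with 256-point FFTs and
#' 75% overlap (bin width 15.625 Hz), the high-frequency (HF) snapping-shrimp
#' band at 44.1 kHz with 64-point FFTs and 50% overlap (bin width
#' 689.0625 Hz).
#'
#' The LF peak search excludes the DC bin (and by default everything below
#' the first non-DC bin) because low-frequency mooring noise otherwise
#' dominates; the lower search bound is configurable via `f_lo`.
#'
#' @param name band label, `"LF"` or `"HF"` (free-form for custom bands).
#' @param analysis_rate analysis sample rate in Hz.
#' @param fft_len FFT length in samples.
#' @param overlap_frac frame overlap as a fraction in `[0, 1)`.
#' @param kaiser_beta Kaiser window shape parameter (default 5, sidelobes
#'   around -37 dB).
#' @param f_lo,f_hi peak-search band edges in Hz. The search uses
#'   `f_lo < f <= f_hi` when `lo_open = TRUE` (LF convention, excludes DC)
#'   and `f_lo <= f <= f_hi` otherwise (HF convention).
#' @param lo_open logical; is the lower edge open?
#'
#' @return A `reefpam_band` object (a named list) with an additional
#'   `bin_width` field (`analysis_rate / fft_len`).
#' @examples
#' lf_band()$bin_width # 15.625 Hz
#' hf_band()$bin_width # 689.0625 Hz
#' @export
band_config <- function(name, analysis_rate, fft_len, overlap_frac,
                        kaiser_beta = 5, f_lo, f_hi, lo_open = FALSE) {
  stopifnot(analysis_rate > 0, fft_len >= 4, fft_len %% 2 == 0)
  if (overlap_frac < 0 || overlap_frac >= 1) {
    abort("`overlap_frac` must be in [0, 1)")
  }
  if (f_hi > analysis_rate / 2) {
    abort("`f_hi` exceeds the analysis Nyquist frequency")
  }
  hop <- as.integer(round(fft_len * (1 - overlap_frac)))
  stopifnot(hop >= 1)
  structure(
    list(
      name = name, analysis_rate = analysis_rate, fft_len = as.integer(fft_len),
      overlap_frac = overlap_frac, hop = hop, kaiser_beta = kaiser_beta,
      f_lo = f_lo, f_hi = f_hi, lo_open = lo_open,
      bin_width = analysis_rate / fft_len
    ),
    class = "reefpam_band"
  )
}

#' @rdname band_config
#' @export
lf_band <- function(kaiser_beta = 5) {
  band_config("LF", analysis_rate = 4000, fft_len = 256, overlap_frac = 0.75,
              kaiser_beta = kaiser_beta, f_lo = 0, f_hi = 2000, lo_open = TRUE)
}

#' @rdname band_config
#' @export
hf_band <- function(kaiser_beta = 5) {
  band_config("HF", analysis_rate = 44100, fft_len = 64, overlap_frac = 0.50,
              kaiser_beta = kaiser_beta, f_lo = 2000, f_hi = 22000,
              lo_open = FALSE)
}

#' @export
print.reefpam_band <- function(x, ...) {
  cat(sprintf(
    "<reefpam_band %s> rate %g Hz, nfft %d, overlap %g%%, Kaiser beta %g, search (%g, %g] Hz, bin %g Hz\n",
    x$name, x$analysis_rate, x$fft_len, 100 * x$overlap_frac, x$kaiser_beta,
    x$f_lo, x$f_hi, x$bin_width
  ))
  invisible(x)
}

# frequency axis of the one-sided spectrum for a band
band_freqs <- function(band) {
  (0:(band$fft_len / 2)) * band$bin_width
}

# logical mask of bins searched for the peak
band_mask <- function(band, freqs = band_freqs(band)) {
  if (band$lo_open) freqs > band$f_lo & freqs <= band$f_hi
  else freqs >= band$f_lo & freqs <= band$f_hi
}
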