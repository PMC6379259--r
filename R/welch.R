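#' Welch power spectral density estimate
#'
#' Overlapped-segment averaging estimator: the signal is split into
#' `window_s`-second segments overlapping by `overlap`, each segment is
#' Hann-tapered, and the one-sided modified periodograms are averaged.
#' Density is scaled so that the discrete Parseval relation holds for the
#' tapered segments: `sum(density) * df` equals the mean tapered segment
#' power (up to the one-sided folding of DC/Nyquist bins).
#'
#' @param x Numeric signal (one channel).
#' @param sample_rate Sampling rate, Hz.
#' @param window_s Segment length in seconds (default 2, giving a frequency
#'   resolution of 0.5 Hz at any rate).
#' @param overlap Fractional overlap between consecutive segments in
#'   `[0, 1)`, default 0.5.
#' @param demean Subtract the signal mean first (default TRUE; EEG
#'   amplifiers leave arbitrary DC offsets).
#' @return List with `freq` (Hz) and `density` (signal units^2 / Hz).
#' @export
welch_psd <- function(x, sample_rate, window_s = 2, overlap = 0.5,
                      demean = TRUE) {
  if (any(!is.finite(x))) stopf("signal contains non-finite values")
  L <- as.integer(round(window_s * sample_rate))
  if (L < 8L) stopf("window too short: %d samples", L)
  if (length(x) < L)
    stopf("signal too short: %d samples, need >= %d", length(x), L)
  if (overlap < 0 || overlap >= 1) stopf("overlap must be in [0, 1)")
  if (demean) x <- x - mean(x)
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq.int(1L, length(x) - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / L))   # periodic Hann
  U <- sum(w^2)
  nh <- L %/% 2L
  segs <- matrix(x[outer(0:(L - 1L), starts, "+")], nrow = L)
  F <- stats::mvfft(segs * w)
  P <- rowMeans(Mod(F[1:(nh + 1L), , drop = FALSE])^2)
  dens <- P / (sample_rate * U)
  # fold the negative-frequency half onto interior bins
  dens[2:(nh + if (L %% 2L == 0L) 0L else 1L)] <-
    2 * dens[2:(nh + if (L %% 2L == 0L) 0L else 1L)]
  list(freq = (0:nh) * sample_rate / L, density = dens)
}

#' EEG frequency bands
#'
#' The four analysis bands: theta 4-8 Hz, alpha 8-13 Hz, beta 13-24 Hz,
#' gamma 30-50 Hz. Edges follow the computational definition used for the
#' clustered band-power features (gamma capped at 50 Hz, below the 64 Hz
#' Nyquist of the 128 Hz recordings).
#'
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
eeg_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 24), gamma = c(30, 50))
}

#' Band power from a PSD
#'
#' Aggregates density over the bins with `low <= f < high`. The default is
#' the mean density (units^2/Hz), so bands of different widths stay
#' comparable in units; `mode = "integral"` returns the integrated power
#' (mean density times band width in Hz).
#'
#' @param freq,density A PSD as returned by [welch_psd()].
#' @param band Numeric `c(low, high)` in Hz.
#' @param mode `"mean"` or `"integral"`.
#' @return Scalar band power.
#' @export
band_power <- function(freq, density, band, mode = c("mean", "integral")) {
  mode <- match.arg(mode)
  if (length(band) != 2L || band[1] >= band[2]) stopf("band must be c(low, high)")
  sel <- freq >= band[1] & freq < band[2]
  if (!any(sel)) stopf("no frequency bins in band [%g, %g)", band[1], band[2])
  m <- mean(density[sel])
  if (mode == "mean") m else m * (band[2] - band[1])
}
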