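#' Construct a trial audio object
#'
#' One bowing trial's mono waveform together with its identity in the
#' session (subject, experimental group, trial index 1-20). Groups: `EG`
#' (experts), `BF` (beginners with sound-quality visual feedback), `BNF`
#' (beginners without it).
#'
#' @param subject_id Subject identifier.
#' @param group One of `"EG"`, `"BF"`, `"BNF"`.
#' @param trial_index Integer in 1-20.
#' @param samples Numeric waveform, nominally in `[-1, 1]`, all finite.
#' @param sample_rate Sampling rate in Hz (44100 expected).
#' @return An object of class `trial_audio`.
#' @export
trial_audio <- function(subject_id, group, trial_index, samples,
                        sample_rate = 44100) {
  group <- match.arg(group, c("EG", "BF", "BNF"))
  trial_index <- as.integer(trial_index)
  if (is.na(trial_index) || trial_index < 1L || trial_index > 20L)
    stopf("trial_index must be in 1..20, got %s", trial_index)
  if (!is.numeric(samples) || length(samples) < 2L)
    stopf("samples must be a numeric vector")
  if (any(!is.finite(samples))) stopf("samples contain non-finite values")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stopf("sample_rate must be positive")
  structure(list(subject_id = as.character(subject_id), group = group,
                 trial_index = trial_index, samples = as.numeric(samples),
                 sample_rate = sample_rate),
            class = "trial_audio")
}

#' @export
print.trial_audio <- function(x, ...) {
  cat(sprintf("<trial_audio> subject %s (%s), trial %d: %.2f s @ %g Hz\n",
              x$subject_id, x$group, x$trial_index,
              length(x$samples) / x$sample_rate, x$sample_rate))
  invisible(x)
}

#' Convert frequency to cents relative to a reference
#'
#' `1200 * log2(frequency / reference)`; 1200 cents is one octave and the
#' default reference is A4 = 440 Hz (the open A string of the exercise).
#'
#' @param frequency Frequency in Hz (> 0). Vectorised.
#' @param reference Reference frequency in Hz (> 0).
#' @return Pitch offset in cents.
#' @examples
#' hz_to_cents(880)            # +1200
#' hz_to_cents(466.1638)       # ~ +100, one equal-tempered semitone
#' @export
hz_to_cents <- function(frequency, reference = 440) {
  if (any(!is.finite(frequency)) || any(frequency <= 0))
    stopf("frequency must be positive and finite")
  if (!is.finite(reference) || reference <= 0)
    stopf("reference must be positive and finite")
  1200 * log2(frequency / reference)
}

#' Per-frame Yin metrics of a bowing trial
#'
#' Runs the Yin fundamental-frequency procedure over sliding analysis
#' windows: squared difference function, cumulative-mean-normalised
#' difference (CMNDF), absolute-threshold dip selection, and parabolic
#' interpolation of the selected lag. Each frame yields
#' \describe{
#'   \item{f0_cents}{fundamental frequency in cents re 440 Hz (`NA` when the
#'     frame is unvoiced, i.e. no CMNDF dip falls below `yin_threshold`)}
#'   \item{power}{mean squared amplitude over the window (linear,
#'     dimensionless)}
#'   \item{aperiodicity}{aperiodic power divided by total power at the best
#'     lag, in `[0, 1]`; near 0 for a clean tone, near 1 for noise}
#' }
#'
#' The difference function is computed exactly via FFT cross-correlation
#' plus running energy sums, so results match the direct O(W * tau)
#' evaluation to rounding error while frames are processed in batches.
#'
#' @param audio A [trial_audio()] (or any list with `samples` and
#'   `sample_rate`).
#' @param window_s Analysis window in seconds (default 0.033 = 33 ms).
#' @param hop_s Hop between window starts in seconds (default 0.0007).
#' @param yin_threshold Absolute threshold on the CMNDF (default 0.15).
#' @param f0_min,f0_max Search limits for the fundamental, Hz.
#' @return A `frame_series` data frame with columns `time`, `f0_cents`,
#'   `power`, `aperiodicity`, `voiced`.
#' @export
yin_frame_metrics <- function(audio, window_s = 0.033, hop_s = 0.0007,
                              yin_threshold = 0.15, f0_min = 100,
                              f0_max = 2000) {
  x <- audio$samples
  sr <- audio$sample_rate
  if (is.null(x) || is.null(sr)) stopf("audio must carry samples and sample_rate")
  if (any(!is.finite(x))) stopf("samples contain non-finite values")
  if (hop_s <= 0) stopf("hop_s must be positive")
  W <- as.integer(round(window_s * sr))
  if (W < 2L) stopf("window too short: %d samples", W)
  hop <- max(1L, as.integer(round(hop_s * sr)))
  tau_min <- max(2L, as.integer(floor(sr / f0_max)))
  tau_max <- as.integer(ceiling(sr / f0_min))
  if (tau_max <= tau_min + 2L) stopf("f0 search range too narrow")
  L <- W + tau_max
  n <- length(x)
  if (n < L)
    stopf("audio too short for analysis: %d samples, need >= %d", n, L)

  starts <- seq.int(1L, n - L + 1L, by = hop)
  nf <- length(starts)
  nfft <- 2L^ceiling(log2(L))
  taus <- seq_len(tau_max)

  f0_cents <- rep(NA_real_, nf)
  power <- numeric(nf)
  aper <- numeric(nf)
  voiced <- logical(nf)

  chunk <- 512L
  for (c0 in seq.int(1L, nf, by = chunk)) {
    cols <- c0:min(nf, c0 + chunk - 1L)
    m <- length(cols)
    idx <- outer(0:(L - 1L), starts[cols], "+")
    S <- matrix(x[idx], nrow = L, ncol = m)
    CS <- apply(S * S, 2L, cumsum)
    if (m == 1L) CS <- matrix(CS, ncol = 1L)
    P0 <- CS[W, ]
    PT <- CS[W + taus, , drop = FALSE] - CS[taus, , drop = FALSE]

    Az <- matrix(0, nfft, m); Az[seq_len(W), ] <- S[seq_len(W), ]
    Sz <- matrix(0, nfft, m); Sz[seq_len(L), ] <- S
    RC <- Re(stats::mvfft(Conj(stats::mvfft(Az)) * stats::mvfft(Sz),
                          inverse = TRUE)) / nfft
    D <- pmax(sweep(PT, 2L, P0, "+") - 2 * RC[1L + taus, , drop = FALSE], 0)
    cum <- apply(D, 2L, cumsum)
    if (m == 1L) cum <- matrix(cum, ncol = 1L)
    Dp <- D * (taus / cum)
    Dp[!is.finite(Dp)] <- 1

    for (j in seq_len(m)) {
      dpj <- Dp[, j]
      k <- cols[j]
      power[k] <- P0[j] / W
      lo <- tau_min
      below <- which(dpj[lo:tau_max] < yin_threshold)
      if (length(below)) {
        t <- lo + below[1L] - 1L
        while (t < tau_max && dpj[t + 1L] < dpj[t]) t <- t + 1L
        voiced[k] <- TRUE
      } else {
        t <- lo - 1L + which.min(dpj[lo:tau_max])
      }
      tp <- P0[j] + PT[t, j]
      aper[k] <- if (tp > 0) min(1, max(0, D[t, j] / tp)) else 1
      if (voiced[k]) {
        tt <- t
        if (t > 1L && t < tau_max) {
          den <- dpj[t - 1L] - 2 * dpj[t] + dpj[t + 1L]
          if (is.finite(den) && den > 0)
            tt <- t + 0.5 * (dpj[t - 1L] - dpj[t + 1L]) / den
        }
        f0_cents[k] <- hz_to_cents(sr / tt)
      }
    }
  }

  structure(
    data.frame(time = (starts - 1L) / sr, f0_cents = f0_cents,
               power = power, aperiodicity = aper, voiced = voiced),
    class = c("frame_series", "data.frame"),
    sample_rate = sr, window_s = window_s, hop_s = hop_s,
    yin_threshold = yin_threshold)
}
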