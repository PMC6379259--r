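# Independent oracles used to cross-check the implementation. These
# deliberately avoid the package's own code paths.

# Brute-force autocorrelation-peak f0 estimate on the same framing the Yin
# analysis uses: r(tau) = sum_{i=1}^{W} x_i * x_{i+tau}, peak picked over
# the lag range, refined by parabolic interpolation.
acf_f0_oracle <- function(samples, sample_rate, window_s = 0.033,
                          hop_s = 0.007, f0_min = 100, f0_max = 2000) {
  W <- round(window_s * sample_rate)
  hop <- max(1, round(hop_s * sample_rate))
  tau_min <- max(2, floor(sample_rate / f0_max))
  tau_max <- ceiling(sample_rate / f0_min)
  L <- W + tau_max
  starts <- seq(1, length(samples) - L + 1, by = hop)
  taus <- tau_min:tau_max
  vapply(starts, function(s) {
    seg <- samples[s:(s + L - 1)]
    # energy-normalised autocorrelation (McLeod's NSDF) so the peak is
    # symmetric and interpolation is unbiased
    r <- vapply(taus, function(tau) {
      a <- seg[1:W]; b <- seg[(1 + tau):(W + tau)]
      2 * sum(a * b) / (sum(a * a) + sum(b * b))
    }, numeric(1))
    # fundamental period = smallest lag whose correlation is essentially
    # maximal (the global max recurs at lag multiples for periodic input);
    # climb to the nearest local maximum before interpolating
    i <- which(r >= 0.995 * max(r))[1]
    while (i < length(r) && r[i + 1] > r[i]) i <- i + 1
    while (i > 1 && r[i - 1] > r[i]) i <- i - 1
    t <- taus[i]
    if (i > 1 && i < length(taus)) {
      den <- r[i - 1] - 2 * r[i] + r[i + 1]
      if (is.finite(den) && den < 0)
        t <- t + 0.5 * (r[i - 1] - r[i + 1]) / den
    }
    sample_rate / t
  }, numeric(1))
}

# Exhaustive-permutation two-sided p-value for the Wilcoxon rank-sum /
# Mann-Whitney test (no ties). Matches the exact-distribution convention:
# p = min(1, 2 * min(P(U <= u), P(U >= u))).
exact_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Plain entropy-based information gain for a given set of cut points.
ig_oracle <- function(x, labels, cuts) {
  ent <- function(l) {
    p <- table(l) / length(l)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  bin <- findInterval(x, sort(cuts))
  ent(labels) - sum(vapply(split(labels, bin), function(l)
    length(l) / length(labels) * ent(l), numeric(1)))
}

# Spreadsheet-style center/scale/average composite oracle.
composite_oracle <- function(dyn, pit, ap = NULL, zscore = TRUE) {
  std <- function(v) {
    v <- v - mean(v)
    if (zscore) v <- v / sqrt(mean(v^2))
    v
  }
  comps <- list(std(dyn), std(pit))
  if (!is.null(ap)) comps <- c(comps, list(std(ap)))
  Reduce(`+`, comps) / length(comps)
}

# Shared tiny synthetic cohort for pipeline-level tests (built once per
# test run; ~1 min of work).
tiny_cohort_manifest <- local({
  path <- NULL
  function() {
    if (!is.null(path) && file.exists(path)) return(path)
    dir <- file.path(tempdir(), "bowlearn-tiny-cohort")
    spec <- synth_cohort_spec(group_sizes = c(EG = 2L, BF = 2L, BNF = 2L),
                              audio = list(duration_s = 1),
                              eeg = list(duration_s = 8))
    path <<- synth_cohort(spec, dir, seed = 42L)
    path
  }
})

tiny_report <- local({
  rep <- NULL
  function() {
    if (is.null(rep))
      rep <<- run_analysis(tiny_cohort_manifest(), hop_s = 0.007,
                           verbose = FALSE)
    rep
  }
})
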