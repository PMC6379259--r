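#' Bonferroni-adjusted per-test alpha
#'
#' @param family_alpha Family-wise error rate, default 0.05.
#' @param m Number of tests in the family (>= 1).
#' @return `family_alpha / m`.
#' @examples
#' bonferroni_alpha(0.05, 156)   # 0.000320513, the 156-test threshold
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m) {
  if (!is.numeric(m) || m < 1) stopf("m must be >= 1")
  if (family_alpha <= 0 || family_alpha >= 1)
    stopf("family_alpha must be in (0, 1)")
  family_alpha / m
}

stat_result <- function(test_name, comparison, statistic, p_value,
                        adjusted_alpha, effect = NA_character_) {
  data.frame(test_name = test_name, comparison = comparison,
             statistic = statistic, p_value = p_value,
             adjusted_alpha = adjusted_alpha,
             significant = p_value < adjusted_alpha,
             effect = effect, stringsAsFactors = FALSE)
}

#' Normality gate for the test battery
#'
#' Runs a Shapiro-Wilk test per group and reports whether any group rejects
#' normality at `alpha`, steering downstream comparisons to nonparametric
#' tests. A constant (zero-spread) group cannot be tested and is treated as
#' failing the gate.
#'
#' @param samples Named list of numeric vectors, one per group (each
#'   n >= 3).
#' @param alpha Significance level, default 0.05.
#' @return List with `nonparametric` (flag), `p_values` (named, `NA` for
#'   degenerate groups) and `alpha`.
#' @export
normality_gate <- function(samples, alpha = 0.05) {
  if (!is.list(samples) || is.null(names(samples)))
    stopf("samples must be a named list of group vectors")
  p <- vapply(names(samples), function(g) {
    x <- samples[[g]]
    if (length(x) < 3L) stopf("group %s has n = %d < 3", g, length(x))
    if (stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  list(nonparametric = any(is.na(p) | p < alpha), p_values = p, alpha = alpha)
}

#' Two-sample and related-sample tests of the analysis battery
#'
#' A thin, uniform wrapper around the standard tests the pipeline uses:
#' \describe{
#'   \item{`rank_sum` / `mann_whitney`}{Wilcoxon rank-sum (Mann-Whitney U)
#'     between two independent samples `x`, `y`.}
#'   \item{`signed_rank`}{Wilcoxon signed-rank on paired `x`, `y` (or on
#'     `x` against 0 when `y` is `NULL`); zero differences are dropped, as
#'     is standard, with a note in the result.}
#'   \item{`friedman`}{Friedman test on a subjects x conditions matrix
#'     `x` (k >= 3 related conditions).}
#'   \item{`paired_t`}{Paired-sample t-test on `x`, `y`.}
#' }
#' All tests are two-sided. Exact rank-test p-values are used where
#' `stats::wilcox.test` provides them (small samples, no ties); otherwise
#' the mid-rank normal approximation applies.
#'
#' @param kind Test kind, see above.
#' @param x,y Samples (matrix for `friedman`).
#' @param comparison Label describing what is compared.
#' @param adjusted_alpha Per-test alpha after any family correction.
#' @return A one-row `StatResult` data frame: `test_name`, `comparison`,
#'   `statistic`, `p_value`, `adjusted_alpha`, `significant`, `effect`.
#' @export
nonparametric_test <- function(kind = c("rank_sum", "mann_whitney",
                                        "signed_rank", "friedman",
                                        "paired_t"),
                               x, y = NULL, comparison = "",
                               adjusted_alpha = 0.05) {
  kind <- match.arg(kind)
  if (kind %in% c("rank_sum", "mann_whitney")) {
    if (is.null(y)) stopf("%s needs two samples", kind)
    ht <- suppressWarnings(stats::wilcox.test(x, y))
    eff <- sprintf("median x %.4g vs y %.4g", stats::median(x),
                   stats::median(y))
  } else if (kind == "signed_rank") {
    d <- if (is.null(y)) x else {
      if (length(x) != length(y)) stopf("paired samples differ in length")
      x - y
    }
    nz <- d != 0
    note <- if (any(!nz)) sprintf(" (%d zero differences dropped)",
                                  sum(!nz)) else ""
    if (!any(nz)) {
      return(stat_result("signed_rank", comparison, 0, 1, adjusted_alpha,
                         paste0("all differences zero", note)))
    }
    ht <- suppressWarnings(stats::wilcox.test(d[nz]))
    eff <- sprintf("median difference %.4g%s", stats::median(d), note)
  } else if (kind == "friedman") {
    if (!is.matrix(x) || ncol(x) < 3L)
      stopf("friedman needs a subjects x conditions matrix with k >= 3")
    if (all(apply(x, 1L, stats::sd) == 0))
      return(stat_result("friedman", comparison, 0, 1, adjusted_alpha,
                         "identical conditions (no signal)"))
    ht <- stats::friedman.test(x)
    eff <- sprintf("condition means %s",
                   paste(signif(colMeans(x), 4), collapse = ", "))
  } else {
    if (is.null(y) || length(x) != length(y))
      stopf("paired_t needs equal-length samples")
    if (length(x) < 2L) stopf("paired_t needs at least 2 pairs")
    if (stats::sd(x - y) == 0) {
      d1 <- mean(x - y)
      return(if (d1 == 0)
        stat_result("paired_t", comparison, 0, 1, adjusted_alpha,
                    "all differences zero (no signal)")
        else
          stat_result("paired_t", comparison, sign(d1) * Inf, 0,
                      adjusted_alpha, "constant nonzero difference"))
    }
    ht <- stats::t.test(x, y, paired = TRUE)
    eff <- sprintf("mean difference %.4g", mean(x - y))
  }
  stat_result(kind, comparison, unname(ht$statistic), ht$p.value,
              adjusted_alpha, eff)
}

#' Per-band correlation between frontal band power and sound quality
#'
#' Pearson-correlates, per frequency band, the trial-averaged frontal band
#' power with the trial-averaged Sound-instability score across the
#' session's trials, reporting R-squared, the correlation sign, and
#' Bonferroni-adjusted significance over the number of bands tested.
#'
#' @param band_by_trial Data frame with columns `trial_index`, `band`,
#'   `power` (already averaged over the subjects of interest).
#' @param score_by_trial Data frame with columns `trial_index`, `score`.
#' @param family_alpha Family-wise alpha, default 0.05.
#' @return Data frame with one row per band: `band`, `r`, `r_squared`,
#'   `p_value`, `adjusted_alpha`, `significant`, `n_trials`.
#' @export
trialwise_correlation <- function(band_by_trial, score_by_trial,
                                  family_alpha = 0.05) {
  bands <- unique(band_by_trial$band)
  alpha <- bonferroni_alpha(family_alpha, length(bands))
  rows <- lapply(bands, function(b) {
    bp <- band_by_trial[band_by_trial$band == b, ]
    m <- merge(bp, score_by_trial, by = "trial_index")
    if (nrow(m) < 3L) stopf("band %s: fewer than 3 paired trials", b)
    if (stats::sd(m$power) == 0 || stats::sd(m$score) == 0)
      stopf("band %s: zero variance; correlation undefined", b)
    ht <- stats::cor.test(m$power, m$score, method = "pearson")
    r <- unname(ht$estimate)
    data.frame(band = b, r = r, r_squared = r^2, p_value = ht$p.value,
               adjusted_alpha = alpha, significant = ht$p.value < alpha,
               n_trials = nrow(m))
  })
  do.call(rbind, rows)
}

#' Learning-material request comparisons
#'
#' Compares how often each beginner group requested each learning material:
#' a Mann-Whitney U test per material type between the feedback (BF) and
#' no-feedback (BNF) beginners, Bonferroni-corrected over the number of
#' material types tested, plus a paired t-test within the BF group between
#' reference-video requests and score (automatic evaluation) requests when
#' both are recorded.
#'
#' @param behavior Data frame with columns `subject_id`, `group`,
#'   `material_type`, `request_count` (non-negative integers).
#' @param family_alpha Family-wise alpha for the between-group family.
#' @return Data frame of `StatResult` rows.
#' @export
behavioral_comparison <- function(behavior, family_alpha = 0.05) {
  need <- c("subject_id", "group", "material_type", "request_count")
  miss <- setdiff(need, names(behavior))
  if (length(miss)) stopf("behavior lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(behavior$request_count < 0)) stopf("negative request counts")
  bf <- behavior[behavior$group == "BF", ]
  bnf <- behavior[behavior$group == "BNF", ]
  shared <- intersect(unique(bf$material_type), unique(bnf$material_type))
  if (!length(shared)) stopf("no material type present in both BF and BNF")
  alpha <- bonferroni_alpha(family_alpha, length(shared))
  res <- do.call(rbind, lapply(shared, function(mt) {
    xb <- bf$request_count[bf$material_type == mt]
    xn <- bnf$request_count[bnf$material_type == mt]
    if (!length(xb) || !length(xn)) stopf("empty group for material %s", mt)
    nonparametric_test("mann_whitney", xb, xn,
                       comparison = sprintf("BF vs BNF: %s requests", mt),
                       adjusted_alpha = alpha)
  }))
  # within-BF: reference video vs score evaluation requests (paired)
  bf_types <- unique(bf$material_type)
  if (all(c("reference_video", "score") %in% bf_types) &&
      length(unique(bf$subject_id)) >= 2L) {
    wide <- merge(bf[bf$material_type == "reference_video",
                     c("subject_id", "request_count")],
                  bf[bf$material_type == "score",
                     c("subject_id", "request_count")],
                  by = "subject_id", suffixes = c("_ref", "_score"))
    res <- rbind(res, nonparametric_test(
      "paired_t", wide$request_count_ref, wide$request_count_score,
      comparison = "BF: reference video vs score requests",
      adjusted_alpha = family_alpha))
  }
  res
}
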