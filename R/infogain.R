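#' Shannon entropy of a label vector, in bits
#'
#' @param labels Factor or character vector of class labels.
#' @return Entropy in bits.
#' @export
entropy_bits <- function(labels) {
  p <- table(labels)
  p <- p[p > 0] / length(labels)
  -sum(p * log2(p))
}

# Fayyad-Irani MDL supervised discretization: recursively pick the binary
# entropy-minimising cut and keep it only if the information gain beats the
# MDL coding cost. Returns sorted cut points (possibly empty).
mdl_cut_points <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- as.character(y)[o]
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 4L) return(numeric(0))
    xs <- x[lo:hi]; ys <- y[lo:hi]
    ent_s <- entropy_bits(ys)
    if (ent_s == 0) return(numeric(0))
    # candidate cuts between distinct adjacent values
    distinct <- which(diff(xs) > 0)
    if (!length(distinct)) return(numeric(0))
    best_gain <- -Inf; best_i <- NA_integer_
    for (i in distinct) {
      e1 <- entropy_bits(ys[1:i]); e2 <- entropy_bits(ys[(i + 1L):n])
      gain <- ent_s - (i * e1 + (n - i) * e2) / n
      if (gain > best_gain) { best_gain <- gain; best_i <- i }
    }
    i <- best_i
    k0 <- length(unique(ys))
    k1 <- length(unique(ys[1:i])); k2 <- length(unique(ys[(i + 1L):n]))
    e1 <- entropy_bits(ys[1:i]); e2 <- entropy_bits(ys[(i + 1L):n])
    delta <- log2(3^k0 - 2) - (k0 * ent_s - k1 * e1 - k2 * e2)
    if (best_gain <= (log2(n - 1) + delta) / n) return(numeric(0))
    cut <- (xs[i] + xs[i + 1L]) / 2
    c(recurse(lo, lo + i - 1L), cut, recurse(lo + i, hi))
  }
  sort(recurse(1L, length(x)))
}

#' Information gain of a numeric feature for a class label
#'
#' `IG = H(labels) - sum_bins P(bin) * H(labels | bin)` in bits, after
#' discretizing the feature. The default discretizer is supervised
#' Fayyad-Irani MDL binary splitting (the behaviour of the standard
#' gain-attribute evaluators); `"equal_width"` bins the feature range into
#' `k` equal-width intervals and serves as a simple, oracle-friendly
#' fallback. A constant feature has zero gain by construction.
#'
#' @param feature Numeric vector.
#' @param labels Class labels, at least 2 distinct classes.
#' @param discretizer `"mdl"` or `"equal_width"`.
#' @param k Number of bins for the equal-width discretizer.
#' @return Information gain in bits, with attribute `cuts` (the cut points
#'   used; empty means a single bin, hence IG = 0).
#' @export
information_gain <- function(feature, labels,
                             discretizer = c("mdl", "equal_width"),
                             k = 10L) {
  discretizer <- match.arg(discretizer)
  if (length(feature) != length(labels)) stopf("length mismatch")
  if (anyNA(feature)) {        # rows lost to e.g. outlier masking
    keep <- !is.na(feature)
    feature <- feature[keep]
    labels <- labels[keep]
  }
  if (any(!is.finite(feature))) stopf("non-finite feature values")
  if (length(unique(labels)) < 2L) stopf("need at least 2 classes")
  cuts <- if (length(unique(feature)) < 2L) {
    numeric(0)
  } else if (discretizer == "mdl") {
    mdl_cut_points(feature, labels)
  } else {
    br <- seq(min(feature), max(feature), length.out = k + 1L)
    br[-c(1L, length(br))]
  }
  h0 <- entropy_bits(labels)
  if (!length(cuts)) {
    ig <- 0
  } else {
    bin <- findInterval(feature, cuts)
    cond <- vapply(split(labels, bin),
                   function(l) length(l) * entropy_bits(l), numeric(1))
    ig <- h0 - sum(cond) / length(labels)
  }
  structure(ig, cuts = cuts)
}

#' Rank features by information gain
#'
#' @param table Data frame of numeric feature columns.
#' @param labels Class labels, one per row of `table`.
#' @param discretizer,k Passed to [information_gain()].
#' @return Data frame `feature`, `information_gain_bits`, `rank`, ordered
#'   by descending gain; ties broken by feature name so the ranking is
#'   deterministic. Missing feature values (e.g. trials lost to outlier
#'   masking) are dropped per feature.
#' @export
rank_features <- function(table, labels, discretizer = "mdl", k = 10L) {
  feats <- names(table)[vapply(table, is.numeric, logical(1))]
  if (!length(feats)) stopf("no numeric feature columns")
  ig <- vapply(feats, function(f)
    as.numeric(information_gain(table[[f]], labels, discretizer, k)),
    numeric(1))
  o <- order(-ig, feats)
  data.frame(feature = feats[o], information_gain_bits = unname(ig[o]),
             rank = seq_along(feats))
}
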