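#' Per-trial sound-quality descriptors
#'
#' Reduces a trial's frame series to the three tone-quality descriptors:
#' \describe{
#'   \item{dynamic_instability}{population standard deviation of frame power
#'     (power units). High values mean an uneven, wobbly dynamic level.}
#'   \item{pitch_instability}{population standard deviation of frame pitch
#'     in cents, over voiced frames only (unvoiced frames carry no f0).}
#'   \item{aperiodicity}{mean frame aperiodicity over all frames, including
#'     unvoiced ones -- scratchy, non-periodic frames are precisely the
#'     bad-sound signal.}
#' }
#' Both instabilities are the direct population SD (1/N inside the root),
#' i.e. the inverse orientation of "stability": larger = worse sound.
#'
#' @param frames A `frame_series` from [yin_frame_metrics()].
#' @param voiced_only If `TRUE` (default) the pitch SD uses voiced frames
#'   only; power SD and aperiodicity always use all frames.
#' @return A one-row data frame of class `trial_sound_descriptors`.
#' @export
trial_descriptors <- function(frames, voiced_only = TRUE) {
  if (nrow(frames) < 2L) stopf("need at least 2 frames, got %d", nrow(frames))
  f0 <- frames$f0_cents
  use <- if (voiced_only) frames$voiced else rep(TRUE, nrow(frames))
  if (voiced_only && !any(use))
    stopf(paste0("degenerate trial: all %d frames unvoiced ",
                 "(median aperiodicity %.2f); no pitch track available"),
          nrow(frames), stats::median(frames$aperiodicity))
  f0 <- f0[use]
  f0 <- f0[is.finite(f0)]
  if (length(f0) < 2L) stopf("fewer than 2 usable voiced frames")
  structure(
    data.frame(dynamic_instability = pop_sd(frames$power),
               pitch_instability = pop_sd(f0),
               aperiodicity = mean(frames$aperiodicity)),
    class = c("trial_sound_descriptors", "data.frame"))
}

#' Sound-instability composite over a cohort of trials
#'
#' Standardises dynamic instability, pitch instability and (optionally)
#' aperiodicity across the cohort and averages the standardised components
#' per trial. The composite is defined only relative to a cohort: its cohort
#' mean is 0 by construction. With `scale = "zscore"` (default) each
#' component is centred and divided by its population SD, so components in
#' different physical units (power^2, cents, ratio) contribute comparably;
#' `scale = "center"` subtracts the mean only.
#'
#' @param cohort Data frame with columns `dynamic_instability`,
#'   `pitch_instability`, `aperiodicity`, one row per trial (any extra
#'   identity columns are carried through).
#' @param include_aperiodicity Include aperiodicity as a third component?
#' @param scale `"zscore"` or `"center"`.
#' @return `cohort` with a `sound_instability` column added, plus attribute
#'   `components` naming the standardised components used.
#' @export
sound_instability <- function(cohort, include_aperiodicity = TRUE,
                              scale = c("zscore", "center")) {
  scale <- match.arg(scale)
  comps <- c("dynamic_instability", "pitch_instability",
             if (include_aperiodicity) "aperiodicity")
  missing_cols <- setdiff(comps, names(cohort))
  if (length(missing_cols))
    stopf("cohort lacks component column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (nrow(cohort) < 2L) stopf("cohort must have >= 2 trials")
  z <- sapply(comps, function(cn) {
    v <- cohort[[cn]]
    if (any(!is.finite(v))) stopf("non-finite values in %s", cn)
    v <- v - mean(v)
    if (scale == "zscore") {
      s <- pop_sd(v)
      if (s == 0) stopf("zero variance in component %s under zscore scaling", cn)
      v <- v / s
    }
    v
  })
  cohort$sound_instability <- rowMeans(matrix(z, nrow = nrow(cohort)))
  attr(cohort, "components") <- comps
  attr(cohort, "scale") <- scale
  cohort
}

#' Percent change of a score per block relative to the baseline block
#'
#' For each non-baseline block `b`:
#' `100 * (mean(baseline) - mean(b)) / |mean(baseline)|`,
#' so a positive value means the score decreased relative to baseline.
#' For instability scores, positive = improvement; the convention is
#' recorded in the result's `direction` attribute so no consumer has to
#' guess the sign.
#'
#' @param scores Numeric vector of per-trial scores named by trial index, or
#'   a data frame with columns `trial_index` and `score`.
#' @param design A [block_design()].
#' @return Data frame with `block` and `percent_change`, attribute
#'   `direction = "positive = score decreased vs baseline (improvement)"`.
#' @export
block_percent_change <- function(scores, design = block_design()) {
  if (is.data.frame(scores)) {
    v <- scores$score
    names(v) <- scores$trial_index
    scores <- v
  }
  trials <- as.integer(names(scores))
  if (anyNA(trials)) stopf("scores must be named by trial index")
  base_idx <- trials %in% design$baseline
  if (!any(base_idx)) stopf("no baseline trials present")
  base_mean <- mean(scores[base_idx])
  if (base_mean == 0) stopf("baseline mean is 0; percent change undefined")
  blocks <- setdiff(names(design), "baseline")
  out <- do.call(rbind, lapply(blocks, function(b) {
    sel <- trials %in% design[[b]]
    if (!any(sel)) return(NULL)
    data.frame(block = b,
               percent_change = 100 * (base_mean - mean(scores[sel])) /
                 abs(base_mean))
  }))
  if (is.null(out) || nrow(out) == 0L)
    stopf("no non-baseline blocks populated")
  attr(out, "direction") <-
    "positive = score decreased vs baseline (improvement)"
  out
}

#' Offline feedback payload for a learner after a trial
#'
#' Assembles the content of the sound-quality visual feedback screen shown
#' to a learner right after finishing a trial: their own per-trial dynamic
#' instability, pitch instability and aperiodicity up to and including the
#' current trial, next to the expert reference series over all 20 trials.
#'
#' @param learner_scores Data frame with columns `trial_index`,
#'   `dynamic_instability`, `pitch_instability`, `aperiodicity` for the
#'   learner (must cover trials `1..current_trial` without gaps).
#' @param expert_scores Same columns for the expert reference, covering all
#'   20 trials.
#' @param current_trial Trial just performed (1-20).
#' @return An object of class `feedback_payload`.
#' @export
feedback_payload <- function(learner_scores, expert_scores, current_trial) {
  current_trial <- as.integer(current_trial)
  if (current_trial < 1L || current_trial > 20L)
    stopf("current_trial must be in 1..20")
  need <- c("trial_index", "dynamic_instability", "pitch_instability",
            "aperiodicity")
  for (df_name in c("learner_scores", "expert_scores")) {
    df <- get(df_name)
    miss <- setdiff(need, names(df))
    if (length(miss)) stopf("%s lacks column(s): %s", df_name,
                            paste(miss, collapse = ", "))
  }
  gaps <- setdiff(seq_len(current_trial), learner_scores$trial_index)
  if (length(gaps))
    stopf("learner scores missing for trial(s): %s",
          paste(gaps, collapse = ", "))
  gaps_e <- setdiff(1:20, expert_scores$trial_index)
  if (length(gaps_e))
    stopf("expert reference missing for trial(s): %s",
          paste(gaps_e, collapse = ", "))
  descr <- c("dynamic_instability", "pitch_instability", "aperiodicity")
  take <- function(df, trials) {
    df <- df[match(trials, df$trial_index), , drop = FALSE]
    lapply(stats::setNames(descr, descr), function(d) as.numeric(df[[d]]))
  }
  structure(list(current_trial = current_trial,
                 descriptors = take(learner_scores, seq_len(current_trial)),
                 expert = take(expert_scores, 1:20)),
            class = "feedback_payload")
}

#' @export
print.feedback_payload <- function(x, ...) {
  cat(sprintf("<feedback_payload> after trial %d (%d learner points/descriptor)\n",
              x$current_trial, x$current_trial))
  invisible(x)
}

#' Serialise / deserialise a feedback payload as JSON
#'
#' The JSON interface is
#' `{current_trial, descriptors: {name: [values...]}, expert: {name: [values...]}}`.
#'
#' @param payload A [feedback_payload()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `payload_to_json`: JSON string or `path`; `payload_from_json`:
#'   a `feedback_payload`.
#' @export
payload_to_json <- function(payload, path = NULL) {
  stopifnot(inherits(payload, "feedback_payload"))
  js <- jsonlite::toJSON(unclass(payload), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname payload_to_json
#' @param json JSON string or path to a JSON file.
#' @export
payload_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  structure(list(current_trial = as.integer(obj$current_trial),
                 descriptors = lapply(obj$descriptors, as.numeric),
                 expert = lapply(obj$expert, as.numeric)),
            class = "feedback_payload")
}

#' Write the per-trial descriptor table as TSV
#'
#' Columns: subject_id, group, trial_index, dynamic_instability,
#' pitch_instability, aperiodicity, sound_instability. UTF-8, '.' decimal.
#'
#' @param descriptors Data frame with those columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(descriptors, path) {
  cols <- c("subject_id", "group", "trial_index", "dynamic_instability",
            "pitch_instability", "aperiodicity", "sound_instability")
  miss <- setdiff(cols, names(descriptors))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  write_tsv(descriptors[, cols], path)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
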