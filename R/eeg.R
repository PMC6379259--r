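#' The 14-channel consumer-EEG montage
#'
#' Electrode names of the 10-20 subset recorded by the 14-channel headset
#' used for the sessions (saline electrodes, 128 Hz per channel).
#'
#' @return Character vector of 14 electrode names.
#' @export
eeg_montage <- function() {
  c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1", "O2",
    "P8", "T8", "FC6", "F4", "F8", "AF4")
}

#' Electrode clusters
#'
#' The 13 named scalp clusters over which per-electrode band powers are
#' averaged, from whole-region groupings (frontal, posterior) down to
#' single electrodes (left/right parietal).
#'
#' @return Named list mapping cluster name to member electrodes.
#' @export
electrode_clusters <- function() {
  list(
    frontal         = c("AF3", "F7", "F3", "FC5", "FC6", "F4", "F8", "AF4"),
    midfrontal      = c("F3", "F4"),
    left_frontal    = c("AF3", "F7", "F3", "FC5"),
    right_frontal   = c("FC6", "F4", "F8", "AF4"),
    posterior       = c("P7", "O1", "O2", "P8"),
    left_posterior  = c("P7", "O1"),
    right_posterior = c("O2", "P8"),
    occipital       = c("O1", "O2"),
    left_parietal   = "P7",
    right_parietal  = "P8",
    temporal        = c("T7", "T8"),
    left_temporal   = "T7",
    right_temporal  = "T8")
}

#' Construct an EEG recording object
#'
#' @param subject_id Subject identifier.
#' @param group One of `"EG"`, `"BF"`, `"BNF"`.
#' @param trial_index Trial number 1-20.
#' @param data Numeric matrix, channels x time, in microvolts.
#' @param channel_names Row names of `data`; must be unique members of
#'   [eeg_montage()].
#' @param sample_rate Hz (128 for the headset used).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(subject_id, group, trial_index, data,
                          channel_names = rownames(data),
                          sample_rate = 128) {
  group <- match.arg(group, c("EG", "BF", "BNF"))
  data <- as.matrix(data)
  if (is.null(channel_names)) stopf("channel names are required")
  if (length(channel_names) != nrow(data))
    stopf("%d channel names for %d data rows", length(channel_names),
          nrow(data))
  bad <- setdiff(channel_names, eeg_montage())
  if (length(bad)) stopf("unknown electrode(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(channel_names)) stopf("duplicated channel names")
  if (any(!is.finite(data))) stopf("EEG data contains non-finite values")
  rownames(data) <- channel_names
  structure(list(subject_id = as.character(subject_id), group = group,
                 trial_index = as.integer(trial_index), data = data,
                 sample_rate = sample_rate),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s (%s), trial %d: %d ch x %.1f s @ %g Hz\n",
              x$subject_id, x$group, x$trial_index, nrow(x$data),
              ncol(x$data) / x$sample_rate, x$sample_rate))
  invisible(x)
}

#' Read a per-trial EEG CSV
#'
#' Expected layout: first column `time_s`, then one column per channel
#' named exactly as in the montage; header row required, '.' decimal.
#'
#' @param path CSV path.
#' @param subject_id,group,trial_index Identity attached to the recording.
#' @param sample_rate If `NULL`, inferred from the median `time_s` step.
#' @return An [eeg_recording()].
#' @export
read_eeg_csv <- function(path, subject_id, group, trial_index,
                         sample_rate = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df)[1], "time_s"))
    stopf("%s: first column must be time_s", path)
  if (is.null(sample_rate)) {
    dt <- stats::median(diff(df$time_s))
    if (!is.finite(dt) || dt <= 0) stopf("%s: cannot infer sample rate", path)
    sample_rate <- round(1 / dt)
  }
  eeg_recording(subject_id, group, trial_index,
                t(as.matrix(df[, -1, drop = FALSE])),
                channel_names = names(df)[-1], sample_rate = sample_rate)
}

#' Clustered band-power table
#'
#' For every recording, computes each electrode's Welch PSD, extracts mean
#' density per band, and averages electrodes within each cluster. One row
#' per (subject, trial, cluster, band).
#'
#' @param recordings List of [eeg_recording()] objects.
#' @param clusters Named list, see [electrode_clusters()].
#' @param bands Named list, see [eeg_bands()].
#' @param window_s,overlap Welch parameters, see [welch_psd()].
#' @param mode Band aggregation, see [band_power()].
#' @return Data frame with columns `subject_id`, `group`, `trial_index`,
#'   `cluster`, `band`, `power` (and `outlier_flag = FALSE`, to be set by
#'   [mask_outlier_trials()]).
#' @export
cluster_band_table <- function(recordings, clusters = electrode_clusters(),
                               bands = eeg_bands(), window_s = 2,
                               overlap = 0.5, mode = "mean") {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  rows <- lapply(recordings, function(rec) {
    needed <- unique(unlist(clusters))
    miss <- setdiff(needed, rownames(rec$data))
    if (length(miss))
      stopf("subject %s trial %d: missing electrode(s): %s", rec$subject_id,
            rec$trial_index, paste(miss, collapse = ", "))
    bp <- sapply(needed, function(ch) {
      psd <- welch_psd(rec$data[ch, ], rec$sample_rate, window_s, overlap)
      vapply(bands, function(b) band_power(psd$freq, psd$density, b, mode),
             numeric(1))
    })  # bands x electrodes
    do.call(rbind, lapply(names(clusters), function(cl) {
      vals <- rowMeans(bp[, clusters[[cl]], drop = FALSE])
      data.frame(subject_id = rec$subject_id, group = rec$group,
                 trial_index = rec$trial_index, cluster = cl,
                 band = names(bands), power = unname(vals))
    }))
  })
  out <- do.call(rbind, rows)
  out$outlier_flag <- FALSE
  rownames(out) <- NULL
  out
}

#' Modified Z-score outlier flags
#'
#' `M_i = 0.6745 * (x_i - median(x)) / MAD(x)` with MAD the raw median
#' absolute deviation; values with `|M_i| > threshold` (default 3.5) are
#' flagged as outliers. With zero MAD the spread is degenerate: nothing is
#' flagged and a warning is emitted.
#'
#' @param values Numeric vector (length >= 3).
#' @param threshold Cutoff on `|M|`, default 3.5.
#' @return Logical vector of flags.
#' @export
modified_zscore_mask <- function(values, threshold = 3.5) {
  if (length(values) < 3L) stopf("need at least 3 values")
  if (any(!is.finite(values))) stopf("non-finite values")
  med <- stats::median(values)
  mad_raw <- stats::median(abs(values - med))
  if (mad_raw == 0) {
    warning("degenerate spread (MAD = 0); no outliers flagged", call. = FALSE)
    return(rep(FALSE, length(values)))
  }
  abs(0.6745 * (values - med) / mad_raw) > threshold
}

#' Flag outlier trials in a band-power table
#'
#' Applies [modified_zscore_mask()] so aberrant trials (movement
#' artifacts, electrode pops) are excluded from block averages without
#' mixing subjects. With the default `scope = "block"` the mask is
#' computed within each (subject, cluster, band, block) cell across that
#' block's trials, so a genuine block-level power shift -- the very
#' learning effect ERD quantifies, which can reach tens of percent -- is
#' never mistaken for outliers. `scope = "subject"` pools the subject's
#' whole session (all 20 trials) per cluster and band; it is kept as an
#' option but will flag entire blocks when the block effect is large
#' relative to trial-to-trial spread.
#'
#' @param band_table Output of [cluster_band_table()].
#' @param threshold Cutoff on the modified Z-score.
#' @param scope `"block"` (default) or `"subject"`.
#' @param design A [block_design()], used for `scope = "block"`.
#' @return `band_table` with `outlier_flag` set.
#' @export
mask_outlier_trials <- function(band_table, threshold = 3.5,
                                scope = c("block", "subject"),
                                design = block_design()) {
  scope <- match.arg(scope)
  key <- if (scope == "block") {
    interaction(band_table$subject_id, band_table$cluster, band_table$band,
                block_of_trial(band_table$trial_index, design), drop = TRUE)
  } else {
    interaction(band_table$subject_id, band_table$cluster,
                band_table$band, drop = TRUE)
  }
  for (k in levels(key)) {
    sel <- which(key == k)
    if (length(sel) >= 3L)
      band_table$outlier_flag[sel] <- suppressWarnings(
        modified_zscore_mask(band_table$power[sel], threshold))
  }
  band_table
}

#' ERD/ERS percentage
#'
#' `100 * (baseline - test) / test`: positive values are event-related
#' desynchronization (band power fell below baseline), negative values are
#' synchronization. The denominator is the test-interval power by
#' definition here; `denominator = "baseline"` gives the classic
#' baseline-normalised variant and is deliberately non-default.
#'
#' @param baseline_power,test_power Positive band powers. Vectorised.
#' @param denominator `"test"` (the definition used throughout) or
#'   `"baseline"`.
#' @return Signed percentage.
#' @export
erd_ers <- function(baseline_power, test_power,
                    denominator = c("test", "baseline")) {
  denominator <- match.arg(denominator)
  if (any(baseline_power <= 0) || any(test_power <= 0))
    stopf("band powers must be positive")
  den <- if (denominator == "test") test_power else baseline_power
  100 * (baseline_power - test_power) / den
}

#' Block-wise ERD/ERS table
#'
#' Per (subject, cluster, band): baseline power is the mean over unmasked
#' trials of the baseline block; each learning block's power is the mean
#' over its unmasked trials; ERD/ERS is computed by [erd_ers()]. Cells
#' where a block lost all trials to masking are omitted with a message.
#'
#' @param band_table Output of [cluster_band_table()], ideally after
#'   [mask_outlier_trials()].
#' @param design A [block_design()].
#' @param denominator Passed to [erd_ers()].
#' @return Data frame with `subject_id`, `group`, `block`, `cluster`,
#'   `band`, `erd_percent`.
#' @export
block_erd_table <- function(band_table, design = block_design(),
                            denominator = "test") {
  keep <- !band_table$outlier_flag
  bt <- band_table[keep, , drop = FALSE]
  bt$block <- block_of_trial(bt$trial_index, design)
  blocks <- setdiff(names(design), "baseline")
  split_key <- interaction(bt$subject_id, bt$cluster, bt$band, drop = TRUE)
  rows <- lapply(split(bt, split_key), function(cell) {
    base <- cell$power[cell$block == "baseline"]
    if (!length(base)) {
      message(sprintf("omitting %s/%s/%s: baseline fully masked",
                      cell$subject_id[1], cell$cluster[1], cell$band[1]))
      return(NULL)
    }
    do.call(rbind, lapply(blocks, function(b) {
      p <- cell$power[cell$block == b]
      if (!length(p)) {
        message(sprintf("omitting %s/%s/%s block %s: all trials masked",
                        cell$subject_id[1], cell$cluster[1], cell$band[1], b))
        return(NULL)
      }
      data.frame(subject_id = cell$subject_id[1], group = cell$group[1],
                 block = b, cluster = cell$cluster[1], band = cell$band[1],
                 erd_percent = erd_ers(mean(base), mean(p), denominator))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
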