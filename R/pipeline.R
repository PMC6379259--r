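#' Validate a session manifest
#'
#' Checks that the manifest has the required columns, group labels in
#' {EG, BF, BNF}, exactly trials 1..20 once each per subject, and that all
#' referenced audio/EEG files exist (paths resolved relative to the
#' manifest). All problems are reported together.
#'
#' @param path Manifest CSV with columns `subject_id`, `group`,
#'   `trial_index`, `audio_path`, `eeg_path`.
#' @param trials Expected trials per subject (default 20).
#' @return The validated session index (data frame with absolute paths),
#'   class `session_manifest`.
#' @export
validate_manifest <- function(path, trials = 20L) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  problems <- character(0)
  need <- c("subject_id", "group", "trial_index", "audio_path", "eeg_path")
  miss <- setdiff(need, names(mf))
  if (length(miss))
    stopf("manifest lacks column(s): %s", paste(miss, collapse = ", "))
  bad_grp <- setdiff(unique(mf$group), c("EG", "BF", "BNF"))
  if (length(bad_grp))
    problems <- c(problems, sprintf("unknown group label(s): %s",
                                    paste(bad_grp, collapse = ", ")))
  for (sid in unique(mf$subject_id)) {
    tr <- sort(mf$trial_index[mf$subject_id == sid])
    missing_tr <- setdiff(seq_len(trials), tr)
    if (length(missing_tr))
      problems <- c(problems, sprintf("subject %s missing trial(s): %s", sid,
                                      paste(missing_tr, collapse = ", ")))
    if (anyDuplicated(tr))
      problems <- c(problems, sprintf("subject %s has duplicated trials", sid))
  }
  root <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(root, p))
  mf$audio_path <- resolve(mf$audio_path)
  mf$eeg_path <- resolve(mf$eeg_path)
  for (col in c("audio_path", "eeg_path")) {
    gone <- !file.exists(mf[[col]])
    if (any(gone))
      problems <- c(problems, sprintf("missing file: %s", mf[[col]][gone]))
  }
  if (length(problems))
    stopf("manifest validation failed:\n  %s",
          paste(problems, collapse = "\n  "))
  structure(mf, class = c("session_manifest", "data.frame"), root = root)
}

#' Run the full analysis pipeline on a session manifest
#'
#' Orchestrates, in order: audio descriptor extraction (Yin frame metrics
#' per trial, Sound-instability composite over the whole cohort, block
#' percent changes per group), EEG clustered band power with modified
#' Z-score outlier masking and block ERD/ERS, and the statistics battery
#' (information-gain rankings on the baseline block, group and block
#' tests with Bonferroni control, frontal band-power vs sound-quality
#' correlations, behavioural request-count comparisons). Trials 1-5 are
#' the baseline for both audio percent change and ERD; information-gain
#' rankings use only those baseline trials (before any feedback).
#'
#' @param manifest Path to a manifest CSV, or a validated
#'   `session_manifest`.
#' @param include_aperiodicity Include aperiodicity in the composite.
#' @param scale Composite standardisation, see [sound_instability()].
#' @param window_s,hop_s,yin_threshold Audio analysis parameters, see
#'   [yin_frame_metrics()].
#' @param welch_window_s,welch_overlap Welch parameters, see [welch_psd()].
#' @param mask_threshold Modified Z-score cutoff, see
#'   [mask_outlier_trials()].
#' @param mask_scope Outlier-mask scope (`"block"` or `"subject"`), see
#'   [mask_outlier_trials()].
#' @param erd_denominator `"test"` (definitional) or `"baseline"`.
#' @param family_alpha Family-wise alpha for all corrected families.
#' @param discretizer Information-gain discretizer.
#' @param correlation_groups Groups pooled for the trialwise correlation
#'   (default the two beginner groups).
#' @param design A [block_design()].
#' @param verbose Log one line per stage per subject to stderr.
#' @return An object of class `bowlearn_report`; see [write_report()].
#' @export
run_analysis <- function(manifest, include_aperiodicity = TRUE,
                         scale = "zscore", window_s = 0.033,
                         hop_s = 0.0007, yin_threshold = 0.15,
                         welch_window_s = 2, welch_overlap = 0.5,
                         mask_threshold = 3.5, mask_scope = "block",
                         erd_denominator = "test",
                         family_alpha = 0.05, discretizer = "mdl",
                         correlation_groups = c("BF", "BNF"),
                         design = block_design(), verbose = TRUE) {
  if (!inherits(manifest, "session_manifest"))
    manifest <- validate_manifest(manifest)
  say <- function(...) if (verbose) message(sprintf(...))

  ## ---- audio stage ----
  desc <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    wav <- read_wav(row$audio_path)
    au <- trial_audio(row$subject_id, row$group, row$trial_index,
                      wav$samples, wav$sample_rate)
    fr <- yin_frame_metrics(au, window_s, hop_s, yin_threshold)
    cbind(data.frame(subject_id = row$subject_id, group = row$group,
                     trial_index = row$trial_index),
          as.data.frame(trial_descriptors(fr)))
  }))
  say("audio: %d trials, %d subjects", nrow(desc),
      length(unique(desc$subject_id)))
  desc <- sound_instability(desc, include_aperiodicity, scale)
  noap <- sound_instability(desc[, c("dynamic_instability",
                                     "pitch_instability", "aperiodicity")],
                            include_aperiodicity = FALSE, scale = scale)
  desc$sound_instability_noap <- noap$sound_instability
  desc$block <- block_of_trial(desc$trial_index, design)

  pct <- do.call(rbind, lapply(split(desc, desc$group), function(d) {
    per_trial <- tapply(d$sound_instability, d$trial_index, mean)
    cbind(group = d$group[1], block_percent_change(per_trial, design))
  }))
  rownames(pct) <- NULL

  ## ---- audio stats ----
  first <- desc[desc$block == "baseline", ]
  lab <- ifelse(first$group == "EG", "expert", "beginner")
  audio_feats <- c("dynamic_instability", "pitch_instability",
                   "aperiodicity", "sound_instability",
                   "sound_instability_noap")
  stats_rows <- list()
  ig_audio <- NULL
  if (length(unique(lab)) == 2L) {
    ig_audio <- rank_features(first[, audio_feats], lab, discretizer)
    for (f in audio_feats)
      stats_rows[[length(stats_rows) + 1L]] <- nonparametric_test(
        "rank_sum", first[[f]][lab == "beginner"],
        first[[f]][lab == "expert"],
        comparison = sprintf("beginners vs experts: %s (baseline block)", f),
        adjusted_alpha = family_alpha)
  } else say("single-class cohort: skipping beginner-vs-expert contrasts")

  # per-group block tests on the composite
  a3 <- bonferroni_alpha(family_alpha, length(unique(desc$group)))
  subj_block <- stats::aggregate(
    sound_instability ~ subject_id + group + block, desc, mean)
  for (g in unique(desc$group)) {
    sb <- subj_block[subj_block$group == g, ]
    wide <- stats::reshape(sb[, c("subject_id", "block", "sound_instability")],
                           idvar = "subject_id", timevar = "block",
                           direction = "wide")
    base <- wide$sound_instability.baseline
    rest <- rowMeans(wide[, paste0("sound_instability.",
                                   setdiff(names(design), "baseline")),
                          drop = FALSE])
    stats_rows[[length(stats_rows) + 1L]] <- nonparametric_test(
      "signed_rank", base, rest,
      comparison = sprintf("%s: baseline vs learning blocks (composite)", g),
      adjusted_alpha = a3)
    if (nrow(wide) >= 2L)
      stats_rows[[length(stats_rows) + 1L]] <- nonparametric_test(
        "friedman",
        as.matrix(wide[, paste0("sound_instability.",
                                setdiff(names(design), "baseline"))]),
        comparison = sprintf("%s: composite across learning blocks", g),
        adjusted_alpha = a3)
  }

  ## ---- EEG stage ----
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    read_eeg_csv(row$eeg_path, row$subject_id, row$group, row$trial_index)
  })
  bp <- cluster_band_table(recs, window_s = welch_window_s,
                           overlap = welch_overlap)
  bp <- mask_outlier_trials(bp, mask_threshold, mask_scope, design)
  say("eeg: %d band-power records, %d flagged as outliers", nrow(bp),
      sum(bp$outlier_flag))
  erd <- block_erd_table(bp, design, erd_denominator)

  ## ---- EEG stats ----
  ig_eeg <- NULL
  bp$feature <- paste(bp$cluster, bp$band, sep = "_")
  first_bp <- bp[bp$trial_index %in% design$baseline & !bp$outlier_flag, ]
  wide_bp <- stats::reshape(
    first_bp[, c("subject_id", "group", "trial_index", "feature", "power")],
    idvar = c("subject_id", "group", "trial_index"), timevar = "feature",
    direction = "wide")
  names(wide_bp) <- sub("^power\\.", "", names(wide_bp))
  lab_bp <- ifelse(wide_bp$group == "EG", "expert", "beginner")
  if (length(unique(lab_bp)) == 2L) {
    feat_cols <- setdiff(names(wide_bp),
                         c("subject_id", "group", "trial_index"))
    ig_eeg <- rank_features(wide_bp[, feat_cols], lab_bp, discretizer)
    top8 <- utils::head(ig_eeg$feature, 8L)
    a8 <- bonferroni_alpha(family_alpha, length(top8))
    for (f in top8) {
      v <- wide_bp[[f]]
      ok <- is.finite(v)
      stats_rows[[length(stats_rows) + 1L]] <- nonparametric_test(
        "rank_sum", v[ok & lab_bp == "beginner"], v[ok & lab_bp == "expert"],
        comparison = sprintf("beginners vs experts: %s (baseline block)", f),
        adjusted_alpha = a8)
    }
  }

  # ERD-vs-zero tests per group x cluster x band x block; the family is
  # the cluster x band x block grid (13 * 4 * 3 = 156 for the default
  # cluster and band sets)
  n_family <- length(unique(erd$cluster)) * length(unique(erd$band)) *
    length(unique(erd$block))
  a_erd <- bonferroni_alpha(family_alpha, n_family)
  erd_tests <- do.call(rbind, lapply(
    split(erd, list(erd$group, erd$cluster, erd$band, erd$block),
          drop = TRUE),
    function(cell) {
      if (nrow(cell) < 2L) return(NULL)
      r <- nonparametric_test(
        "signed_rank", cell$erd_percent,
        comparison = sprintf("%s: %s %s ERD vs 0, %s block", cell$group[1],
                             cell$cluster[1], cell$band[1], cell$block[1]),
        adjusted_alpha = a_erd)
      cbind(group = cell$group[1], cluster = cell$cluster[1],
            band = cell$band[1], block = cell$block[1],
            median_erd = stats::median(cell$erd_percent), r)
    }))
  rownames(erd_tests) <- NULL

  ## ---- correlation stage ----
  corr <- NULL
  sel_bp <- bp[bp$group %in% correlation_groups & bp$cluster == "frontal" &
                 !bp$outlier_flag, ]
  sel_sc <- desc[desc$group %in% correlation_groups, ]
  if (nrow(sel_bp) && nrow(sel_sc)) {
    band_by_trial <- stats::aggregate(power ~ trial_index + band, sel_bp,
                                      mean)
    score_by_trial <- stats::aggregate(
      cbind(score = sound_instability) ~ trial_index, sel_sc, mean)
    corr <- trialwise_correlation(band_by_trial, score_by_trial,
                                  family_alpha)
  }

  ## ---- behavioural stage ----
  behavior <- NULL; behav_tests <- NULL
  root <- attr(manifest, "root")
  if (is.null(root)) root <- dirname(dirname(manifest$audio_path[1]))
  behav_path <- file.path(root, "behavior.csv")
  if (file.exists(behav_path)) {
    behavior <- utils::read.csv(behav_path, stringsAsFactors = FALSE)
    if (all(c("BF", "BNF") %in% behavior$group))
      behav_tests <- behavioral_comparison(behavior, family_alpha)
  }

  stats_tbl <- do.call(rbind, stats_rows)
  rownames(stats_tbl) <- NULL

  cfg <- list(include_aperiodicity = include_aperiodicity, scale = scale,
              window_s = window_s, hop_s = hop_s,
              yin_threshold = yin_threshold,
              welch_window_s = welch_window_s,
              welch_overlap = welch_overlap,
              mask_threshold = mask_threshold, mask_scope = mask_scope,
              erd_denominator = erd_denominator,
              family_alpha = family_alpha, discretizer = discretizer,
              correlation_groups = correlation_groups,
              erd_family_size = n_family)
  structure(list(
    descriptors = desc, percent_change = pct, band_power = bp,
    erd = erd, ig_audio = ig_audio, ig_eeg = ig_eeg,
    stats = stats_tbl, erd_tests = erd_tests, correlation = corr,
    behavior = behavior, behavior_tests = behav_tests,
    provenance = list(config = cfg, config_hash = config_hash(cfg),
                      package_version =
                        as.character(utils::packageVersion("bowlearn")),
                      n_subjects = length(unique(manifest$subject_id)),
                      n_trials = nrow(manifest))),
    class = "bowlearn_report")
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' @export
print.bowlearn_report <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<bowlearn_report> %d subjects, %d trials (config %s)\n",
              p$n_subjects, p$n_trials, substr(p$config_hash, 1, 8)))
  cat(sprintf("  descriptors: %d rows; band power: %d rows; ERD: %d rows\n",
              nrow(x$descriptors), nrow(x$band_power), nrow(x$erd)))
  if (!is.null(x$ig_audio))
    cat(sprintf("  top audio feature by IG: %s (%.3f bits)\n",
                x$ig_audio$feature[1], x$ig_audio$information_gain_bits[1]))
  if (!is.null(x$ig_eeg))
    cat(sprintf("  top EEG feature by IG:   %s (%.3f bits)\n",
                x$ig_eeg$feature[1], x$ig_eeg$information_gain_bits[1]))
  cat(sprintf("  statistical tests: %d (+%d ERD cells)\n",
              nrow(x$stats), if (is.null(x$erd_tests)) 0L
              else nrow(x$erd_tests)))
  invisible(x)
}

#' @export
summary.bowlearn_report <- function(object, ...) {
  print(object)
  cat("\nPercent change of Sound instability vs baseline",
      "(positive = improvement):\n")
  print(object$percent_change, row.names = FALSE)
  if (!is.null(object$correlation)) {
    cat("\nFrontal band power vs Sound instability (per trial):\n")
    print(object$correlation, row.names = FALSE)
  }
  sig <- object$stats[object$stats$significant, , drop = FALSE]
  cat(sprintf("\nSignificant tests (%d of %d):\n", nrow(sig),
              nrow(object$stats)))
  if (nrow(sig)) print(sig[, c("test_name", "comparison", "p_value")],
                       row.names = FALSE)
  invisible(object)
}

#' Write a report's tables to disk
#'
#' Writes the TSV set (`descriptors.tsv`, `percent_change.tsv`,
#' `band_power.tsv`, `erd.tsv`, `ig_ranking.tsv`, `stats_report.tsv`,
#' `correlation.tsv`, `behavior.tsv`) plus `report.json` with the
#' provenance block, under `out_dir`. Numeric columns use 6 significant
#' digits.
#'
#' @param report A `bowlearn_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "bowlearn_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) if (!is.null(df))
    write_tsv(df, file.path(out_dir, name))
  w(report$descriptors, "descriptors.tsv")
  w(report$percent_change, "percent_change.tsv")
  w(report$band_power[, setdiff(names(report$band_power), "feature")],
    "band_power.tsv")
  w(report$erd, "erd.tsv")
  ig <- rbind(
    if (!is.null(report$ig_audio)) cbind(set = "audio", report$ig_audio),
    if (!is.null(report$ig_eeg)) cbind(set = "eeg", report$ig_eeg))
  w(ig, "ig_ranking.tsv")
  w(rbind(report$stats,
          if (!is.null(report$erd_tests))
            report$erd_tests[, names(report$stats)],
          if (!is.null(report$behavior_tests)) report$behavior_tests),
    "stats_report.tsv")
  w(report$correlation, "correlation.tsv")
  w(report$behavior, "behavior.tsv")
  writeLines(jsonlite::toJSON(report$provenance, auto_unbox = TRUE,
                              digits = NA, pretty = TRUE),
             file.path(out_dir, "report.json"))
  invisible(out_dir)
}
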