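# Synthetic cohort generation: audio and EEG with programmed group/block
# structure, so every analysis stage can be exercised without the recorded
# dataset.

# AR(1) path with stationary SD `sd` and lag-1 correlation `rho`; used for
# slow pitch/amplitude drift so analysis windows see locally coherent
# values rather than frame-to-frame i.i.d. jitter.
ar1_path <- function(n, sd, rho) {
  if (sd == 0) return(numeric(n))
  e <- stats::rnorm(n, sd = sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive",
                           init = stats::rnorm(1, sd = sd)))
}

#' Synthesise one bowed open-string trial
#'
#' Harmonic tone (1/k amplitude rolloff) at a nominal fundamental, with a
#' smooth bowing envelope (`strokes` gentle dips emulating bow direction
#' changes), slow mean-reverting pitch drift with stationary SD
#' `pitch_jitter_sd` cents, a slow log-amplitude drift giving relative
#' power SD about `power_jitter_sd`, and additive white noise at
#' `noise_snr` dB. The drift processes are generated at a 100 Hz control
#' rate and interpolated, so 33 ms analysis windows see locally coherent
#' pitch -- i.i.d. per-frame jitter would register as aperiodicity, not
#' pitch instability.
#'
#' @param f0 Nominal fundamental, Hz (440 = open A string).
#' @param duration_s Trial length in seconds (>= 1).
#' @param pitch_jitter_sd Stationary SD of the pitch drift, cents.
#' @param power_jitter_sd Relative SD of the slow power drift.
#' @param noise_snr Signal-to-noise ratio in dB (`Inf` = no noise).
#' @param strokes Number of bow strokes across the trial.
#' @param n_harmonics Number of harmonics.
#' @param stroke_depth Fractional amplitude dip at stroke turns, in `[0, 1)`.
#' @param sample_rate Hz.
#' @param subject_id,group,trial_index Identity of the generated trial.
#' @param seed Optional RNG seed for a reproducible trial.
#' @return A [trial_audio()].
#' @export
synth_violin_trial <- function(f0 = 440, duration_s = 2,
                               pitch_jitter_sd = 0, power_jitter_sd = 0,
                               noise_snr = Inf, strokes = 8,
                               n_harmonics = 6, stroke_depth = 0.3,
                               sample_rate = 44100,
                               subject_id = "synthetic", group = "EG",
                               trial_index = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.na(duration_s) || duration_s < 1) stopf("duration_s must be >= 1 s")
  if (pitch_jitter_sd < 0 || power_jitter_sd < 0) stopf("jitter SDs must be >= 0")
  if (is.na(noise_snr)) stopf("noise_snr must be a number or Inf")
  n <- as.integer(round(duration_s * sample_rate))
  t <- (seq_len(n) - 1L) / sample_rate

  ctrl_rate <- 100
  nc <- as.integer(ceiling(duration_s * ctrl_rate)) + 2L
  tc <- (seq_len(nc) - 1L) / ctrl_rate
  rho <- exp(-1 / (ctrl_rate * 0.15))   # ~150 ms correlation time
  cents <- stats::approx(tc, ar1_path(nc, pitch_jitter_sd, rho), xout = t,
                         rule = 2)$y
  logamp <- stats::approx(tc, ar1_path(nc, power_jitter_sd, rho), xout = t,
                          rule = 2)$y

  f_inst <- f0 * 2^(cents / 1200)
  phase <- 2 * pi * cumsum(f_inst) / sample_rate
  wave <- numeric(n)
  for (k in seq_len(n_harmonics)) wave <- wave + sin(k * phase) / k
  env <- 1 - stroke_depth * sin(pi * strokes * t / duration_s)^2
  wave <- wave * env * exp(logamp / 2)   # power multiplier exp(logamp)
  wave <- 0.5 * wave / max(abs(wave))
  if (is.finite(noise_snr)) {
    rms <- sqrt(mean(wave^2))
    wave <- wave + stats::rnorm(n, sd = rms * 10^(-noise_snr / 20))
    peak <- max(abs(wave))
    if (peak > 1) wave <- wave / peak
  }
  trial_audio(subject_id, group, trial_index, wave, sample_rate)
}

# Disjoint generator regions covering the montage; every analysis cluster
# is a subset of exactly one region, so region-level density targets fix
# every cluster's expected value.
eeg_regions <- function() {
  list(frontal = c("AF3", "F7", "F3", "FC5", "FC6", "F4", "F8", "AF4"),
       posterior = c("P7", "O1", "O2", "P8"),
       temporal = c("T7", "T8"))
}

#' Expand per-region band density targets to per-channel targets
#'
#' @param frontal,posterior,temporal Named numeric vectors
#'   `c(theta=, alpha=, beta=, gamma=)` of one-sided densities in uV^2/Hz.
#' @return List `band -> named per-channel density vector` for
#'   [synth_eeg_trial()].
#' @export
region_band_targets <- function(frontal, posterior, temporal) {
  regions <- eeg_regions()
  vals <- list(frontal = frontal, posterior = posterior,
               temporal = temporal)
  bands <- names(eeg_bands())
  lapply(stats::setNames(bands, bands), function(b) {
    out <- numeric(0)
    for (r in names(regions)) {
      if (!b %in% names(vals[[r]]))
        stopf("region %s lacks a %s target", r, b)
      out <- c(out, stats::setNames(rep(vals[[r]][[b]],
                                        length(regions[[r]])),
                                    regions[[r]]))
    }
    out
  })
}

#' Synthesise one EEG trial with programmed band densities
#'
#' Each channel is the sum over bands of band-limited Gaussian noise built
#' by brick-wall filtering white noise in the frequency domain (a zero-phase
#' filter with exact unit passband gain) and rescaling each realisation so
#' its variance equals `density * bandwidth` exactly. The measured Welch
#' mean density inside each band then matches the target up to taper
#' leakage at the band edges.
#'
#' @param band_density_targets List `band -> density`, where density is a
#'   scalar (all channels) or a named per-channel vector in uV^2/Hz; see
#'   [region_band_targets()]. Band names must exist in [eeg_bands()].
#' @param duration_s Trial length in seconds (> 0).
#' @param sample_rate Hz (default 128).
#' @param channel_names Channels to generate, default the full montage.
#' @param subject_id,group,trial_index Identity of the generated trial.
#' @param seed Optional RNG seed.
#' @return An [eeg_recording()].
#' @export
synth_eeg_trial <- function(band_density_targets, duration_s = 30,
                            sample_rate = 128,
                            channel_names = eeg_montage(),
                            subject_id = "synthetic", group = "EG",
                            trial_index = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.na(duration_s) || duration_s <= 0) stopf("duration_s must be > 0")
  bands <- eeg_bands()
  bad <- setdiff(names(band_density_targets), names(bands))
  if (length(bad)) stopf("unknown band(s): %s", paste(bad, collapse = ", "))
  n <- as.integer(round(duration_s * sample_rate))
  if (n < 2L * sample_rate) stopf("duration too short for 2 s Welch windows")
  freq <- (0:(n - 1)) * sample_rate / n
  data <- matrix(0, length(channel_names), n,
                 dimnames = list(channel_names, NULL))
  for (b in names(band_density_targets)) {
    rng <- bands[[b]]
    if (rng[2] > sample_rate / 2)
      stopf("band %s [%g, %g) exceeds Nyquist %g Hz", b, rng[1], rng[2],
            sample_rate / 2)
    tgt <- band_density_targets[[b]]
    if (length(tgt) == 1L && is.null(names(tgt)))
      tgt <- stats::setNames(rep(tgt, length(channel_names)), channel_names)
    if (any(tgt <= 0)) stopf("band %s: densities must be positive", b)
    pos <- which(freq > 0 & freq < sample_rate / 2 &
                   freq >= rng[1] & freq < rng[2])
    mask <- logical(n)
    mask[pos] <- TRUE
    mask[n + 2L - pos] <- TRUE
    for (ch in channel_names) {
      if (!ch %in% names(tgt)) stopf("band %s: no target for channel %s", b, ch)
      F <- stats::fft(stats::rnorm(n))
      F[!mask] <- 0
      y <- Re(stats::fft(F, inverse = TRUE)) / n
      v <- mean(y^2)
      if (v > 0) y <- y * sqrt(tgt[[ch]] * (rng[2] - rng[1]) / v)
      data[ch, ] <- data[ch, ] + y
    }
  }
  eeg_recording(subject_id, group, trial_index, data,
                sample_rate = sample_rate)
}

#' Specification of a synthetic cohort
#'
#' Bundles the programmed study conditions: group sizes (7 experts, 9 + 9
#' beginners), 20 trials of 4 blocks, per-group audio jitter/noise levels
#' with per-block improvement multipliers, per-region EEG band densities
#' with per-group scaling and per-block multipliers, and Poisson rates for
#' learning-material requests. Defaults programme the qualitative study
#' structure: experts stable throughout; beginners start unstable and
#' improve block by block (feedback group slightly faster); beginners carry
#' elevated frontal beta/gamma power in the baseline block; frontal gamma
#' density drops to 0.7 of baseline after the baseline block in both
#' beginner groups (posterior and temporal gamma drop mildly in all
#' groups); experts show a temporal beta rise.
#'
#' @param group_sizes Named integer vector `c(EG=, BF=, BNF=)`.
#' @param trials Trials per subject (20).
#' @param audio,eeg,behavior Optional lists overriding individual defaults
#'   (see the function body for the field names).
#' @return An object of class `synth_cohort_spec`.
#' @export
synth_cohort_spec <- function(group_sizes = c(EG = 7L, BF = 9L, BNF = 9L),
                              trials = 20L, audio = list(), eeg = list(),
                              behavior = list()) {
  if (any(group_sizes < 1L)) stopf("group sizes must be >= 1")
  audio_def <- list(
    f0 = 440, duration_s = 2, sample_rate = 44100,
    pitch_jitter_sd = c(EG = 3, BF = 15, BNF = 15),
    power_jitter_sd = c(EG = 0.05, BF = 0.25, BNF = 0.25),
    noise_snr = c(EG = 35, BF = 18, BNF = 18),
    block_multipliers = list(
      EG = c(baseline = 1, early = 1, middle = 1, late = 1),
      BF = c(baseline = 1, early = 0.75, middle = 0.6, late = 0.5),
      BNF = c(baseline = 1, early = 0.85, middle = 0.75, late = 0.65)))
  eeg_def <- list(
    duration_s = 30, sample_rate = 128,
    base_density = c(theta = 8, alpha = 10, beta = 5, gamma = 2),
    group_region_scale = list(      # region x band multipliers per group
      EG = list(),
      BF = list(frontal = c(beta = 2.9, gamma = 1.16)),
      BNF = list(frontal = c(beta = 2.9, gamma = 1.16))),
    block_multipliers = rbind(      # applied in early/middle/late blocks
      data.frame(group = c("BF", "BNF"), region = "frontal", band = "gamma",
                 multiplier = 0.7),
      data.frame(group = c("EG", "BF", "BNF"), region = "posterior",
                 band = "gamma", multiplier = 0.8),
      data.frame(group = c("EG", "BF", "BNF"), region = "temporal",
                 band = "gamma", multiplier = 0.8),
      data.frame(group = "EG", region = "temporal", band = "beta",
                 multiplier = 1.3)))
  behavior_def <- list(
    lambda = list(BF = c(instructional = 5, reference_video = 12.6,
                         score = 11),
                  BNF = c(instructional = 5, reference_video = 10)))
  spec <- list(group_sizes = group_sizes, trials = as.integer(trials),
               audio = utils::modifyList(audio_def, audio),
               eeg = utils::modifyList(eeg_def, eeg),
               behavior = utils::modifyList(behavior_def, behavior))
  if (any(unlist(spec$audio$block_multipliers) <= 0))
    stopf("block multipliers must be > 0")
  structure(spec, class = "synth_cohort_spec")
}

eeg_trial_targets <- function(spec, group, block) {
  regions <- names(eeg_regions())
  dens <- lapply(stats::setNames(regions, regions), function(r) {
    d <- spec$eeg$base_density
    gs <- spec$eeg$group_region_scale[[group]][[r]]
    if (!is.null(gs)) d[names(gs)] <- d[names(gs)] * gs
    if (block != "baseline") {
      bm <- spec$eeg$block_multipliers
      sel <- bm$group == group & bm$region == r
      if (any(sel)) {
        bm <- bm[sel, ]
        d[bm$band] <- d[bm$band] * bm$multiplier
      }
    }
    d
  })
  region_band_targets(dens$frontal, dens$posterior, dens$temporal)
}

#' Generate and write a full synthetic cohort
#'
#' Writes, under `out_dir`: per-trial mono WAV audio, per-trial EEG CSVs
#' (`time_s` plus one column per montage channel), an events CSV, a
#' behaviour CSV of learning-material request counts, and a session
#' manifest (`subject_id, group, trial_index, audio_path, eeg_path`,
#' paths relative to the manifest). Fully reproducible: the same spec and
#' seed give byte-identical outputs.
#'
#' @param spec A [synth_cohort_spec()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed fixing all randomness end-to-end.
#' @return Path to the manifest CSV, invisibly.
#' @export
synth_cohort <- function(spec = synth_cohort_spec(), out_dir, seed = 1L) {
  stopifnot(inherits(spec, "synth_cohort_spec"))
  dir.create(file.path(out_dir, "audio"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "eeg"), showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s", out_dir)
  set.seed(as.integer(seed))
  design <- block_design()
  manifest <- list(); events <- list(); behavior <- list()
  for (g in names(spec$group_sizes)) {
    for (s in seq_len(spec$group_sizes[[g]])) {
      sid <- sprintf("%s%02d", g, s)
      for (tr in seq_len(spec$trials)) {
        blk <- block_of_trial(tr, design)
        mult <- spec$audio$block_multipliers[[g]][[blk]]
        au <- synth_violin_trial(
          f0 = spec$audio$f0, duration_s = spec$audio$duration_s,
          pitch_jitter_sd = spec$audio$pitch_jitter_sd[[g]] * mult,
          power_jitter_sd = spec$audio$power_jitter_sd[[g]] * mult,
          noise_snr = spec$audio$noise_snr[[g]],
          sample_rate = spec$audio$sample_rate,
          subject_id = sid, group = g, trial_index = tr)
        wav_rel <- file.path("audio", sprintf("%s_t%02d.wav", sid, tr))
        write_wav(au$samples, file.path(out_dir, wav_rel),
                  spec$audio$sample_rate)
        rec <- synth_eeg_trial(
          eeg_trial_targets(spec, g, blk),
          duration_s = spec$eeg$duration_s,
          sample_rate = spec$eeg$sample_rate,
          subject_id = sid, group = g, trial_index = tr)
        eeg_rel <- file.path("eeg", sprintf("%s_t%02d.csv", sid, tr))
        df <- data.frame(time_s = (seq_len(ncol(rec$data)) - 1L) /
                           rec$sample_rate,
                         round(t(rec$data), 4), check.names = FALSE)
        utils::write.csv(df, file.path(out_dir, eeg_rel), row.names = FALSE)
        manifest[[length(manifest) + 1L]] <-
          data.frame(subject_id = sid, group = g, trial_index = tr,
                     audio_path = wav_rel, eeg_path = eeg_rel)
        events[[length(events) + 1L]] <-
          data.frame(subject_id = sid, trial_index = tr, start_s = 0,
                     end_s = spec$eeg$duration_s)
      }
      lam <- spec$behavior$lambda[[g]]
      if (!is.null(lam))
        behavior[[length(behavior) + 1L]] <-
          data.frame(subject_id = sid, group = g,
                     material_type = names(lam),
                     request_count = stats::rpois(length(lam), lam))
    }
  }
  utils::write.csv(do.call(rbind, manifest),
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, events), file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  if (length(behavior))
    utils::write.csv(do.call(rbind, behavior),
                     file.path(out_dir, "behavior.csv"), row.names = FALSE)
  invisible(file.path(out_dir, "manifest.csv"))
}
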