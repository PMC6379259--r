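test_that("the clean-tone limit has negligible instability and aperiodicity", {
  au <- synth_violin_trial(pitch_jitter_sd = 0, power_jitter_sd = 0,
                           noise_snr = Inf, seed = 101)
  d <- trial_descriptors(yin_frame_metrics(au, hop_s = 0.007))
  expect_lt(d$pitch_instability, 1)
  expect_lt(d$aperiodicity, 0.02)
})

test_that("noisier bowing reads as higher aperiodicity", {
  ap <- sapply(c(40, 10), function(snr) {
    au <- synth_violin_trial(noise_snr = snr, seed = 102)
    mean(yin_frame_metrics(au, hop_s = 0.007)$aperiodicity)
  })
  expect_gt(ap[2], ap[1])
})

test_that("programmed pitch jitter is recovered within the stationary band", {
  set.seed(103)
  meas <- sapply(1:6, function(i) {
    au <- synth_violin_trial(pitch_jitter_sd = 20, noise_snr = 30)
    trial_descriptors(yin_frame_metrics(au, hop_s = 0.007))$pitch_instability
  })
  expect_gt(mean(meas), 14)
  expect_lt(mean(meas), 26)
})

test_that("measured pitch instability increases strictly with programmed jitter", {
  set.seed(104)
  lvls <- c(2, 5, 10, 20, 40)
  means <- sapply(lvls, function(sd) {
    mean(sapply(1:3, function(i) {
      au <- synth_violin_trial(pitch_jitter_sd = sd, noise_snr = 30)
      trial_descriptors(yin_frame_metrics(au, hop_s = 0.007))$pitch_instability
    }))
  })
  expect_equal(cor(means, lvls, method = "spearman"), 1)
})

test_that("synthetic EEG hits its programmed band densities", {
  rec <- synth_eeg_trial(list(theta = 4, alpha = 6, beta = 3, gamma = 2),
                         duration_s = 60, seed = 105)
  psd <- welch_psd(rec$data["F3", ], rec$sample_rate)
  tol <- 0.1
  expect_equal(band_power(psd$freq, psd$density, eeg_bands()$alpha), 6,
               tolerance = tol)
  expect_equal(band_power(psd$freq, psd$density, eeg_bands()$beta), 3,
               tolerance = tol)
  expect_equal(band_power(psd$freq, psd$density, eeg_bands()$gamma), 2,
               tolerance = tol)

  # per-channel targets: frontal gamma halved relative to posterior
  tg <- region_band_targets(frontal = c(theta = 4, alpha = 6, beta = 3,
                                        gamma = 1),
                            posterior = c(theta = 4, alpha = 6, beta = 3,
                                          gamma = 2),
                            temporal = c(theta = 4, alpha = 6, beta = 3,
                                         gamma = 2))
  rec2 <- synth_eeg_trial(tg, duration_s = 60, seed = 106)
  g <- function(ch) {
    p <- welch_psd(rec2$data[ch, ], 128)
    band_power(p$freq, p$density, eeg_bands()$gamma)
  }
  expect_equal(g("AF3") / g("P7"), 0.5, tolerance = 0.15)

  expect_error(synth_eeg_trial(list(gamma = 1), duration_s = 0), "> 0")
  expect_error(synth_eeg_trial(list(gamma = 1), duration_s = 30,
                               sample_rate = 64), "Nyquist")
  expect_error(synth_eeg_trial(list(delta = 1)), "unknown band")
})

test_that("cohort generation is byte-identical under a fixed seed", {
  spec <- synth_cohort_spec(group_sizes = c(EG = 1L, BF = 1L, BNF = 1L),
                            trials = 2L,
                            audio = list(duration_s = 1),
                            eeg = list(duration_s = 4))
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  m1 <- synth_cohort(spec, d1, seed = 7)
  m2 <- synth_cohort(spec, d2, seed = 7)
  files <- c("manifest.csv", "behavior.csv", "audio/EG01_t01.wav",
             "eeg/BF01_t02.csv")
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # a different seed changes the data
  d3 <- file.path(tempdir(), "det3")
  synth_cohort(spec, d3, seed = 8)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "audio/EG01_t01.wav"))),
    unname(tools::md5sum(file.path(d3, "audio/EG01_t01.wav")))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("generator inputs are validated", {
  expect_error(synth_violin_trial(duration_s = 0.5), ">= 1")
  expect_error(synth_violin_trial(pitch_jitter_sd = -1), ">= 0")
  expect_error(synth_violin_trial(noise_snr = NA), "noise_snr")
  expect_error(synth_cohort_spec(group_sizes = c(EG = 0L)), ">= 1")
})
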