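frame_df <- function(power, f0, ap = rep(0, length(power)),
                     voiced = rep(TRUE, length(power))) {
  structure(data.frame(time = seq_along(power), f0_cents = f0,
                       power = power, aperiodicity = ap, voiced = voiced),
            class = c("frame_series", "data.frame"))
}

test_that("instabilities are population SDs of frame metrics", {
  d <- trial_descriptors(frame_df(c(2, 2, 2, 2), c(0, 0, 0, 0)))
  expect_equal(d$dynamic_instability, 0)
  expect_equal(d$pitch_instability, 0)

  d2 <- trial_descriptors(frame_df(c(0, 2, 0, 2), c(0, 0, 0, 0)))
  expect_equal(d2$dynamic_instability, 1.0)

  d3 <- trial_descriptors(frame_df(rep(1, 4), c(-3, -1, 1, 3)))
  expect_equal(d3$pitch_instability, sqrt(5))

  # unvoiced frames are excluded from the pitch SD but not the power SD
  d4 <- trial_descriptors(frame_df(c(0, 2, 0, 2), c(0, 0, 9, 9),
                                   voiced = c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(d4$pitch_instability, 0)
  expect_equal(d4$dynamic_instability, 1.0)

  expect_error(trial_descriptors(
    frame_df(1:4, rep(NA_real_, 4), ap = rep(0.9, 4),
             voiced = rep(FALSE, 4))), "unvoiced")
})

test_that("composite equals the center/scale/average oracle", {
  set.seed(7)
  toy <- data.frame(dynamic_instability = c(0.1, 0.4, 0.2, 0.9, 0.3),
                    pitch_instability = c(12, 30, 18, 55, 21),
                    aperiodicity = c(0.02, 0.2, 0.05, 0.4, 0.08))
  for (zs in c(TRUE, FALSE)) {
    got <- sound_instability(toy, include_aperiodicity = TRUE,
                             scale = if (zs) "zscore" else "center")
    want <- composite_oracle(toy$dynamic_instability, toy$pitch_instability,
                             toy$aperiodicity, zscore = zs)
    expect_equal(got$sound_instability, want, tolerance = 1e-12)
  }
  got2 <- sound_instability(toy, include_aperiodicity = FALSE)
  want2 <- composite_oracle(toy$dynamic_instability, toy$pitch_instability)
  expect_equal(got2$sound_instability, want2, tolerance = 1e-12)
})

test_that("composite is centered, monotone, and guards degenerate cohorts", {
  # identical trials: centering annihilates everything (center scale)
  same <- data.frame(dynamic_instability = rep(1, 4),
                     pitch_instability = rep(2, 4),
                     aperiodicity = rep(0.1, 4))
  expect_equal(sound_instability(same, scale = "center")$sound_instability,
               rep(0, 4))
  expect_error(sound_instability(same, scale = "zscore"),
               "dynamic_instability")

  two <- data.frame(dynamic_instability = c(2, 1),
                    pitch_instability = c(20, 10),
                    aperiodicity = c(0.3, 0.1))
  si <- sound_instability(two)$sound_instability
  expect_gt(si[1], si[2])

  set.seed(21)
  for (i in 1:20) {
    coh <- data.frame(dynamic_instability = rexp(8),
                      pitch_instability = rexp(8) * 10,
                      aperiodicity = runif(8))
    expect_lt(abs(mean(sound_instability(coh)$sound_instability)), 1e-9)
  }
  expect_error(sound_instability(same[1, , drop = FALSE]), ">= 2")
})

test_that("block percent change follows the baseline-minus-block formula", {
  sc <- setNames(c(rep(2, 5), rep(2, 5), rep(1, 5), rep(4, 5)), 1:20)
  pc <- block_percent_change(sc)
  expect_equal(pc$percent_change[pc$block == "early"], 0)
  expect_equal(pc$percent_change[pc$block == "middle"], 50)
  expect_equal(pc$percent_change[pc$block == "late"], -100)
  expect_match(attr(pc, "direction"), "improvement")

  expect_error(block_percent_change(setNames(rep(0, 20), 1:20)),
               "baseline mean")
  # negative baseline mean: |baseline| in the denominator keeps direction
  sc2 <- setNames(c(rep(-2, 5), rep(-1, 15)), 1:20)
  expect_equal(block_percent_change(sc2)$percent_change, rep(-50, 3))
})

test_that("feedback payload truncates at the current trial and round-trips", {
  mk <- function(n) data.frame(trial_index = 1:n,
                               dynamic_instability = runif(n),
                               pitch_instability = runif(n) * 30,
                               aperiodicity = runif(n))
  set.seed(5)
  expert <- mk(20)
  learner <- mk(9)
  pl <- feedback_payload(learner, expert, current_trial = 9)
  expect_length(pl$descriptors$pitch_instability, 9)
  expect_length(pl$expert$pitch_instability, 20)

  pl1 <- feedback_payload(mk(1), expert, current_trial = 1)
  expect_length(pl1$descriptors$aperiodicity, 1)

  rt <- payload_from_json(payload_to_json(pl))
  expect_equal(rt, pl)

  expect_error(feedback_payload(learner[-3, ], expert, 9), "3")
})

test_that("WAV files round-trip at 16-bit precision", {
  set.seed(3)
  x <- runif(2000, -0.9, 0.9)
  f <- tempfile(fileext = ".wav")
  write_wav(x, f, 44100)
  got <- read_wav(f)
  expect_equal(got$sample_rate, 44100)
  expect_equal(got$samples, x, tolerance = 1 / 32768 * 2)
  unlink(f)
})
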