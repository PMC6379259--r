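mk_rec <- function(data, sid = "s1", group = "EG", trial = 1)
  eeg_recording(sid, group, trial, data, sample_rate = 128)

test_that("recordings validate their montage", {
  d <- matrix(rnorm(14 * 256), 14, dimnames = list(eeg_montage(), NULL))
  expect_s3_class(mk_rec(d), "eeg_recording")
  rownames(d)[1] <- "CZ"
  expect_error(mk_rec(d), "CZ")
  rownames(d)[1] <- "F7"
  expect_error(mk_rec(d), "duplicated")
  d2 <- matrix(rnorm(14 * 256), 14, dimnames = list(eeg_montage(), NULL))
  d2[3, 5] <- NA
  expect_error(mk_rec(d2), "non-finite")
})

test_that("cluster means equal the brute-force per-electrode mean", {
  set.seed(10)
  n <- 128 * 8
  base <- rnorm(n)
  # identical channels: every cluster equals the single-channel value
  d <- matrix(rep(base, each = 14), 14,
              dimnames = list(eeg_montage(), NULL))
  tbl <- cluster_band_table(mk_rec(d))
  ref <- welch_psd(base, 128)
  for (b in names(eeg_bands())) {
    v <- tbl$power[tbl$band == b]
    expect_equal(v, rep(band_power(ref$freq, ref$density, eeg_bands()[[b]]),
                        length(v)))
  }

  # independent channels: frontal = mean of its 8 electrodes, computed
  # independently; singleton cluster equals its electrode exactly
  d2 <- matrix(rnorm(14 * n), 14, dimnames = list(eeg_montage(), NULL))
  tbl2 <- cluster_band_table(mk_rec(d2))
  members <- electrode_clusters()$frontal
  for (b in names(eeg_bands())) {
    per_el <- vapply(members, function(ch) {
      psd <- welch_psd(d2[ch, ], 128)
      band_power(psd$freq, psd$density, eeg_bands()[[b]])
    }, numeric(1))
    expect_equal(tbl2$power[tbl2$cluster == "frontal" & tbl2$band == b],
                 mean(per_el), tolerance = 1e-12)
    p7 <- welch_psd(d2["P7", ], 128)
    expect_equal(tbl2$power[tbl2$cluster == "left_parietal" & tbl2$band == b],
                 band_power(p7$freq, p7$density, eeg_bands()[[b]]))
  }

  # permutation invariance in electrode order
  perm <- sample(14)
  tbl3 <- cluster_band_table(mk_rec(d2[perm, ]))
  expect_equal(tbl2$power, tbl3$power)

  expect_error(cluster_band_table(mk_rec(d2[1:10, ])), "missing electrode")
})

test_that("modified Z-score flags the hand-computed outlier and only it", {
  x <- c(1, 2, 3, 4, 100)
  flags <- modified_zscore_mask(x)
  expect_equal(flags, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # median 3, MAD 1 -> M(100) = 0.6745 * 97
  expect_equal(0.6745 * (100 - 3) / 1, 65.4265)
  # the median itself can never be flagged
  expect_false(modified_zscore_mask(c(5, 1, 9, 5, 200, -90))[1])
  expect_warning(out <- modified_zscore_mask(rep(2, 5)), "degenerate")
  expect_false(any(out))
  expect_error(modified_zscore_mask(c(1, 2)), "at least 3")
})

test_that("clean Gaussian data is almost never flagged", {
  set.seed(12)
  rate <- mean(replicate(300, mean(modified_zscore_mask(rnorm(100)))))
  expect_lt(rate, 0.01)
})

test_that("ERD/ERS follows its defining formula and sign law", {
  expect_equal(erd_ers(100, 100), 0)
  expect_equal(erd_ers(200, 100), 100)
  expect_equal(erd_ers(100, 200), -50)
  expect_error(erd_ers(-1, 5), "positive")
  expect_error(erd_ers(5, 0), "positive")
  # classic baseline-denominator variant
  expect_equal(erd_ers(200, 100, denominator = "baseline"), 50)
  set.seed(13)
  b <- rexp(200) + 0.01
  t <- rexp(200) + 0.01
  e <- erd_ers(b, t)
  expect_true(all(e[t < b] > 0))
  expect_true(all(e[t > b] < 0))
})

test_that("block ERD table recovers programmed multipliers exactly", {
  grid <- expand.grid(trial_index = 1:20, cluster = c("frontal", "temporal"),
                      band = c("beta", "gamma"), stringsAsFactors = FALSE)
  grid$subject_id <- "s1"; grid$group <- "BF"
  grid$power <- 10
  grid$outlier_flag <- FALSE

  # constant power everywhere: all ERD 0
  erd0 <- block_erd_table(grid)
  expect_true(all(erd0$erd_percent == 0))

  # gamma x 0.7 in all non-baseline trials -> ERD = (0.3/0.7)*100
  g1 <- grid
  sel <- g1$band == "gamma" & g1$trial_index > 5
  g1$power[sel] <- 7
  erd1 <- block_erd_table(g1)
  expect_equal(erd1$erd_percent[erd1$band == "gamma"],
               rep(100 * 0.3 / 0.7, 6), tolerance = 1e-12)
  expect_equal(erd1$erd_percent[erd1$band == "beta"], rep(0, 6))

  # beta doubled in the late block only
  g2 <- grid
  g2$power[g2$band == "beta" & g2$trial_index >= 16] <- 20
  erd2 <- block_erd_table(g2)
  beta <- erd2[erd2$band == "beta" & erd2$cluster == "frontal", ]
  expect_equal(beta$erd_percent[beta$block == "late"], -50)
  expect_equal(beta$erd_percent[beta$block != "late"], c(0, 0))

  # masked baseline block is omitted, others survive
  g3 <- grid
  g3$outlier_flag[g3$band == "gamma" & g3$cluster == "frontal" &
                    g3$trial_index <= 5] <- TRUE
  expect_message(erd3 <- block_erd_table(g3), "baseline fully masked")
  expect_false(any(erd3$cluster == "frontal" & erd3$band == "gamma"))
})

test_that("the block-scoped outlier mask spares programmed block effects", {
  set.seed(14)
  tbl <- data.frame(subject_id = "s1", group = "BF", trial_index = 1:20,
                    cluster = "frontal", band = "gamma",
                    power = c(rnorm(5, 2, 0.05), rnorm(15, 1.4, 0.05)),
                    outlier_flag = FALSE)
  masked <- mask_outlier_trials(tbl)
  expect_false(any(masked$outlier_flag[1:5]))
  # the subject-level scope (20-trial window) would flag the baseline
  masked_subj <- mask_outlier_trials(tbl, scope = "subject")
  expect_true(any(masked_subj$outlier_flag[1:5]))
})

test_that("EEG CSVs round-trip through the reader", {
  d <- matrix(round(rnorm(14 * 256), 4), 14,
              dimnames = list(eeg_montage(), NULL))
  f <- tempfile(fileext = ".csv")
  df <- data.frame(time_s = (0:255) / 128, t(d), check.names = FALSE)
  write.csv(df, f, row.names = FALSE)
  rec <- read_eeg_csv(f, "s2", "BNF", 3)
  expect_equal(rec$sample_rate, 128)
  expect_equal(unname(rec$data), unname(d), tolerance = 1e-8)
  expect_equal(rec$trial_index, 3L)
  unlink(f)
})
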