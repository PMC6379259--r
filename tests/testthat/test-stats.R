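test_that("Bonferroni adjustment divides the family alpha", {
  expect_equal(bonferroni_alpha(0.05, 156), 0.05 / 156)
  expect_equal(signif(bonferroni_alpha(0.05, 156), 2), 0.00032)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 4), 0.0125)
  expect_error(bonferroni_alpha(0.05, 0), ">= 1")
})

test_that("normality gate calibrates on Gaussian data and catches heavy tails", {
  set.seed(41)
  rej <- mean(replicate(400, {
    normality_gate(list(g = rnorm(50)))$p_values[["g"]] < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)

  rej_ln <- mean(replicate(200, {
    normality_gate(list(g = rlnorm(50)))$p_values[["g"]] < 0.05
  }))
  expect_gt(rej_ln, 0.5)

  deg <- normality_gate(list(g = rep(3, 10), h = rnorm(10)))
  expect_true(deg$nonparametric)
  expect_true(is.na(deg$p_values[["g"]]))
  expect_error(normality_gate(list(g = c(1, 2))), "n = 2")
})

test_that("rank-sum p-values agree with exhaustive permutation enumeration", {
  expect_equal(nonparametric_test("rank_sum", c(1, 2, 3),
                                  c(101, 102, 103))$p_value,
               exact_ranksum_p(c(1, 2, 3), c(101, 102, 103)))
  set.seed(42)
  for (i in 1:15) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -2, 2))
    got <- nonparametric_test("mann_whitney", x, y)$p_value
    expect_equal(got, exact_ranksum_p(x, y), tolerance = 1e-12)
  }
})

test_that("related-sample tests behave on degenerate and simple inputs", {
  r <- nonparametric_test("signed_rank", c(4, 5, 6), c(4, 5, 6))
  expect_equal(r$p_value, 1)
  expect_false(r$significant)

  fr <- nonparametric_test("friedman", matrix(rep(1:4, 3), 4, 3))
  expect_equal(fr$statistic, 0)
  expect_equal(fr$p_value, 1)

  pt <- nonparametric_test("paired_t", c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_lt(pt$p_value, 0.01)

  expect_error(nonparametric_test("paired_t", 1:3, 1:4), "equal-length")
  expect_error(nonparametric_test("friedman", matrix(1:4, 2)), "k >= 3")
  expect_error(nonparametric_test("rank_sum", 1:3), "two samples")
})

test_that("every significance flag equals p < adjusted alpha", {
  set.seed(43)
  for (i in 1:20) {
    a <- runif(1, 1e-4, 0.2)
    r <- nonparametric_test("rank_sum", rnorm(6), rnorm(6, 2),
                            adjusted_alpha = a)
    expect_identical(r$significant, r$p_value < a)
  }
})

test_that("trialwise correlation reports R2 with its sign and family control", {
  x <- seq_len(20)
  bt <- rbind(data.frame(trial_index = x, band = "gamma", power = 2 * x + 1),
              data.frame(trial_index = x, band = "beta", power = -x),
              data.frame(trial_index = x, band = "alpha",
                         power = sin(x) + 10))
  sc <- data.frame(trial_index = x, score = x)
  ct <- trialwise_correlation(bt, sc)
  expect_equal(ct$adjusted_alpha, rep(0.05 / 3, 3))
  g <- ct[ct$band == "gamma", ]
  expect_equal(g$r_squared, 1)
  expect_gt(g$r, 0)
  b <- ct[ct$band == "beta", ]
  expect_equal(b$r_squared, 1)
  expect_lt(b$r, 0)

  # null expectation of R^2 for independent series is 1/(n-1)
  set.seed(44)
  r2 <- replicate(400, {
    bt1 <- data.frame(trial_index = x, band = "g", power = rnorm(20))
    sc1 <- data.frame(trial_index = x, score = rnorm(20))
    trialwise_correlation(bt1, sc1)$r_squared
  })
  expect_equal(mean(r2), 1 / 19, tolerance = 0.25)

  expect_error(trialwise_correlation(
    data.frame(trial_index = x, band = "g", power = rep(1, 20)), sc),
    "zero variance")
})

test_that("behavioural comparisons pair the right groups and materials", {
  mk <- function(group, n, mats) do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(subject_id = sprintf("%s%02d", group, i), group = group,
               material_type = names(mats), request_count = unname(mats))))
  b <- rbind(mk("BF", 9, c(instructional = 10, reference_video = 10,
                           score = 10)),
             mk("BNF", 9, c(instructional = 2, reference_video = 2)))
  res <- behavioral_comparison(b)
  mw <- res[res$test_name == "mann_whitney", ]
  expect_equal(nrow(mw), 2)             # two shared material types
  expect_equal(mw$adjusted_alpha, rep(0.025, 2))
  # all BF > all BNF: U is maximal (81 at n = 9, 9)
  expect_true(all(mw$statistic == 81))
  # identical within-BF counts: paired test carries no signal
  pt <- res[res$test_name == "paired_t", ]
  expect_equal(nrow(pt), 1)
  expect_false(isTRUE(pt$significant))

  single <- b[b$material_type == "instructional", ]
  res1 <- behavioral_comparison(single)
  expect_equal(res1$adjusted_alpha[res1$test_name == "mann_whitney"], 0.05)
  expect_error(behavioral_comparison(transform(b, request_count = -1)),
               "negative")
})
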