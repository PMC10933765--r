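test_that("the 2x2 chi-square matches its closed form and printed reproductions", {
  closed_form <- function(m) {
    N <- sum(m)
    N * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
      prod(rowSums(m)) / prod(colSums(m))
  }
  set.seed(55)
  for (i in 1:50) {
    m <- matrix(sample(1:60, 4, replace = TRUE), 2)
    expect_equal(chi_square_2x2(m)$statistic, closed_form(m), tolerance = 1e-10)
  }
  # gainer frequencies 32/50 vs 25/49 and multi-gainers 11/32 vs 9/25
  expect_equal(chi_square_2x2(matrix(c(32, 25, 18, 24), 2))$statistic,
               1.707, tolerance = 2e-4)
  expect_lt(abs(chi_square_2x2(matrix(c(11, 9, 21, 16), 2))$statistic - 0.016),
            5e-4)
  expect_equal(chi_square_2x2(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("the 2x2 chi-square is invariant to row/column swaps and transposition", {
  set.seed(56)
  for (i in 1:20) {
    m <- matrix(sample(1:40, 4, replace = TRUE), 2)
    s <- chi_square_2x2(m)$statistic
    expect_equal(chi_square_2x2(m[2:1, ])$statistic, s)
    expect_equal(chi_square_2x2(m[, 2:1])$statistic, s)
    expect_equal(chi_square_2x2(t(m))$statistic, s)
  }
})

test_that("the pooled t works from summaries, raw data, and degenerate input", {
  # magnitude comparison from the printed arm summaries
  r <- two_sample_t(mean_x = 23.0, sd_x = 9.0, n_x = 44,
                    mean_y = 20.8, sd_y = 7.3, n_y = 33)
  expect_equal(r$t, 1.149, tolerance = 1e-3)
  expect_equal(r$df, 75)
  # raw-data route agrees with stats::t.test var.equal
  set.seed(57)
  x <- rnorm(20, 10, 3); y <- rnorm(15, 12, 3)
  ref <- t.test(x, y, var.equal = TRUE)
  r2 <- two_sample_t(x = x, y = y)
  expect_equal(r2$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r2$p, ref$p.value, tolerance = 1e-10)
  expect_equal(two_sample_t(x = x, y = x)$t, 0)
  r3 <- two_sample_t(x = c(5, 5), y = c(7, 7))
  expect_true(r3$infinite)
})

test_that("the pooled t keeps its nominal type-I error under the null", {
  set.seed(58)
  rej <- 0L
  for (i in 1:1000) {
    x <- rnorm(20); y <- rnorm(20)
    if (two_sample_t(x = x, y = y)$p < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / 1000 - 0.05), 0.02)
})

test_that("baseline equivalence tests run per arm and flag degenerate arms", {
  set.seed(59)
  ass <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:50), condition = "ct",
    baseline = rnorm(50, 85, 18))
  st <- tibble::tibble(participant_id = ass$participant_id, condition = "ct",
                       gainer = rep(c(TRUE, FALSE), 25))
  r <- baseline_equivalence_test(ass, st)
  expect_equal(r$df, 48)
  expect_lt(abs(r$t), 3)
  ass3 <- tibble::tibble(participant_id = c("A", "B"), condition = "ct",
                         baseline = c(80, 90))
  st3 <- tibble::tibble(participant_id = c("A", "B"), condition = "ct",
                        gainer = c(TRUE, FALSE))
  expect_false(baseline_equivalence_test(ass3, st3)$estimable)
})

test_that("a noiseless cohort returns the configured outcome differences exactly", {
  cfg <- simulation_config(n_per_arm = c(40, 40), outcome_re_sd = 0,
                           outcome_resid_sd = 0)
  co <- generate_cohort(cfg, seed = 61)
  fit <- fit_outcome_model(co$assessments, co$gain_status)
  expect_equal(fit$comparisons$adjusted_difference,
               c(16.40, 14.70, 10.20), tolerance = 1e-6)
  expect_equal(fit$comparisons$timepoint,
               c("posttreatment", "followup_3m", "followup_12m"))
  expect_equal(fit$comparisons$clinically_meaningful, c(TRUE, TRUE, FALSE))
})

test_that("configured outcome differences are recovered at simulation scale", {
  cfg <- simulation_config(n_per_arm = c(1000, 1000))
  co <- generate_cohort(cfg, seed = 62)
  fit <- fit_outcome_model(co$assessments, co$gain_status)
  # Monte-Carlo error: SE of a group difference at n = 2000 with total SD
  # ~12.8 is about 0.6; allow ~3 SEs
  expect_true(all(abs(fit$comparisons$adjusted_difference -
                        c(16.40, 14.70, 10.20)) < 1.8))
  expect_true(all(fit$comparisons$p < 0.001))
  expect_true(all(fit$comparisons$d > 0.5))
  expect_equal(fit$meta$estimation, "ML")
})

test_that("shuffled gain labels give near-zero adjusted differences", {
  cfg <- simulation_config(n_per_arm = c(500, 500))
  co <- generate_cohort(cfg, seed = 63)
  st <- co$gain_status
  set.seed(64)
  st$gainer <- sample(st$gainer)
  fit <- fit_outcome_model(co$assessments, st)
  expect_true(all(abs(fit$comparisons$adjusted_difference) < 2.5))
  expect_true(all(abs(fit$comparisons$d) < 0.2))
})

test_that("missing follow-ups are retained via the likelihood, not dropped cases", {
  cfg <- simulation_config(n_per_arm = c(200, 200))
  co <- generate_cohort(cfg, seed = 65)
  ass <- co$assessments
  set.seed(66)
  ass$followup_12m[sample(nrow(ass), 80)] <- NA
  ass$followup_3m[sample(nrow(ass), 40)] <- NA
  fit <- fit_outcome_model(ass, co$gain_status)
  expect_equal(nrow(fit$comparisons), 3)
  expect_true(all(is.finite(fit$comparisons$adjusted_difference)))
  expect_error(fit_outcome_model(ass, dplyr::mutate(co$gain_status,
                                                    gainer = TRUE)),
               "both gain-status levels")
})
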