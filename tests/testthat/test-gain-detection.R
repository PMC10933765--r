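toy <- c(80, 78, 76, 75, 50, 49, 51, 48, 48, 48, 48, 48, 48, 48)

test_that("the reliable change cutoff follows the Jacobson-Truax closed form", {
  r <- compute_rci_cutoff(18.0, 0.95)
  expect_equal(r$raw, 1.96 * 18 * sqrt(2 * 0.05))
  expect_equal(r$cutoff, 12)
  expect_equal(compute_rci_cutoff(0, 0.95)$cutoff, 0)
  r2 <- compute_rci_cutoff(5.0, 0.5)
  expect_equal(r2$raw, 9.8)
  expect_equal(r2$cutoff, 10)
  expect_equal(compute_rci_cutoff(5.0, 0.5, rounding = "raw")$cutoff, 9.8)
  expect_error(compute_rci_cutoff(18, 1.2), "alpha")
})

test_that("pooled_sd matches the df-weighted definition and its edge cases", {
  expect_equal(pooled_sd(c(78, 76, 75), c(50, 49, 51)),
               sqrt((2 * 7 / 3 + 2 * 1) / 4), tolerance = 1e-12)
  x <- c(3, 5, 9, 1)
  expect_equal(pooled_sd(x, x + 10), sd(x))           # identical spreads
  expect_equal(pooled_sd(c(10, 10), c(20, 20)), 0)    # zero variance
  expect_error(pooled_sd(1, c(2, 3)), "2 values")
  # simple-average variant differs with unbalanced sides
  expect_equal(pooled_sd(c(0, 4), c(1, 2, 3), method = "simple_average"),
               sqrt((8 + 1) / 2))
})

test_that("evaluate_interval applies all three criteria on the worked series", {
  ev <- evaluate_interval(toy, 4)
  expect_true(ev$evaluable)
  expect_equal(ev$magnitude, 25)
  expect_true(ev$crit1$pass)                       # 25 >= 12
  expect_true(ev$crit2$pass)                       # 25/75 = 33% >= 25%
  expect_equal(ev$crit3$mean_diff, mean(c(78, 76, 75)) - mean(c(50, 49, 51)))
  expect_equal(ev$crit3$pooled_sd, 1.290994, tolerance = 1e-6)
  expect_equal(ev$crit3$multiplier, 2.78)
  expect_true(ev$crit3$pass)
  expect_true(ev$pass_all)
})

test_that("boundary, missing-endpoint and thin-window intervals are not evaluable", {
  expect_false(evaluate_interval(toy, 1)$evaluable)     # first session
  expect_false(evaluate_interval(toy, 13)$evaluable)    # penultimate session
  expect_error(evaluate_interval(toy, 14), "out of range")
  s <- toy; s[5] <- NA
  expect_equal(evaluate_interval(s, 4)$reason, "missing endpoint")
  # two missing window values leave only 4 points
  s2 <- toy; s2[c(2, 3)] <- NA
  expect_equal(evaluate_interval(s2, 4)$reason, "too few window points")
  # one missing interior value switches to the five-point multiplier
  s3 <- toy; s3[2] <- NA
  expect_equal(evaluate_interval(s3, 4)$crit3$multiplier, 3.18)
  # series boundary at n = 2 also uses the five-point multiplier
  s4 <- c(80, 79, 50, 49, 51, 48, 48, 48)
  expect_equal(evaluate_interval(s4, 2)$crit3$multiplier, 3.18)
})

test_that("flat or sub-threshold series yield no gains but full denominators", {
  flat <- detect_gains(rep(60, 14))
  expect_equal(nrow(flat$gains), 0)
  expect_equal(flat$n_evaluable, 11)
  # an 11-point drop fails criterion one at cutoff 12
  s <- c(40, 40, 40, 40, 29, 29, 29, 29, 29, 29, 29, 29, 29, 29)
  expect_equal(nrow(detect_gains(s)$gains), 0)
  # the same drop passes at cutoff 11
  expect_equal(detect_gains(s, gain_criteria(rci_cutoff = 11))$gains$n, 4)
})

test_that("detect_gains agrees with the brute-force oracle on random series", {
  set.seed(202)
  for (i in 1:400) {
    s <- random_series()
    got <- detect_gains(s)
    want <- oracle_detect(s)
    expect_equal(got$gains$n, want$hits,
                 info = paste("series", i, paste(round(s, 2), collapse = ",")))
    expect_equal(got$n_evaluable, want$n_evaluable)
  }
})

test_that("detections are monotone in the thresholds and respect their bounds", {
  set.seed(303)
  for (i in 1:100) {
    s <- random_series(miss = 0)
    n_lo <- nrow(detect_gains(s, gain_criteria(rci_cutoff = 8))$gains)
    n_mid <- nrow(detect_gains(s, gain_criteria(rci_cutoff = 12))$gains)
    n_hi <- nrow(detect_gains(s, gain_criteria(rci_cutoff = 20))$gains)
    expect_true(n_lo >= n_mid && n_mid >= n_hi)
    n_rel <- nrow(detect_gains(s, gain_criteria(relative_drop = 0.4))$gains)
    expect_true(n_mid >= n_rel)
    g <- detect_gains(s)$gains
    if (nrow(g) > 0) {
      expect_true(all(g$magnitude >= 12))
      expect_true(all(g$magnitude >= 0.25 * g$pregain))
    }
  }
})

test_that("criteria two and three are scale-invariant; criterion one is not", {
  set.seed(404)
  crit <- gain_criteria()
  for (i in 1:50) {
    s <- random_series(miss = 0)
    k <- runif(1, 0.5, 3)
    for (n in 2:(length(s) - 2)) {
      a <- evaluate_interval(s, n, crit)
      b <- evaluate_interval(s * k, n, crit)
      if (!a$evaluable) { expect_false(b$evaluable); next }
      expect_equal(a$crit2$pass, b$crit2$pass)
      expect_equal(a$crit3$pass, b$crit3$pass)
    }
  }
  # criterion one is deliberately absolute: shrink the scale and it flips
  s <- toy
  expect_true(evaluate_interval(s, 4, crit)$crit1$pass)
  expect_false(evaluate_interval(s * 0.1, 4, crit)$crit1$pass)
})

test_that("primary-gain selection follows the largest and tape-study rules", {
  g <- tibble::tibble(n = c(5L, 9L), magnitude = c(20, 25))
  expect_equal(select_primary_gain(g, "largest")$n, 9L)
  # consecutive pair: later member dropped under the tape rule
  g2 <- tibble::tibble(n = c(6L, 7L), magnitude = c(10, 30))
  expect_equal(select_primary_gain(g2, "tape_study")$n, 6L)
  expect_equal(select_primary_gain(g2, "largest")$n, 7L)
  # ties broken by the earliest pregain index
  g3 <- tibble::tibble(n = c(10L, 4L), magnitude = c(15, 15))
  expect_equal(select_primary_gain(g3, "largest")$n, 4L)
  expect_null(select_primary_gain(g3[0, ], "largest"))
  # a chain of three consecutive gains keeps only the first
  g4 <- tibble::tibble(n = c(5L, 6L, 7L), magnitude = c(10, 20, 30))
  expect_equal(select_primary_gain(g4, "tape_study")$n, 5L)
})

test_that("improvement fractions handle zero and missing denominators", {
  expect_equal(gain_fraction_of_improvement(20, 90, 50)$fraction, 0.5)
  r <- gain_fraction_of_improvement(20, 50, 50)
  expect_false(r$defined)
  expect_false(gain_fraction_of_improvement(20, 90, NA)$defined)
})

test_that("timing distributions report all tied modes per arm", {
  g <- tibble::tibble(condition = "ct", n = c(4L, 4L, 7L))
  expect_equal(gain_timing_distribution(g)$modes$ct, 4L)
  empty <- gain_timing_distribution(g[0, ])
  expect_equal(nrow(empty$counts), 0)
  g2 <- tibble::tibble(condition = "ct", n = c(5L, 5L, 12L, 12L, 8L))
  expect_equal(gain_timing_distribution(g2)$modes$ct, c(5L, 12L))
})
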