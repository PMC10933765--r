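# Build a gains table for tape-design scenarios: `consecutive` participants
# get a second gain one session after their first.
make_gain_table <- function(n_gainers, consecutive = 0, sessions = NULL) {
  set.seed(1234)
  if (is.null(sessions)) sessions <- sample(3:11, n_gainers, replace = TRUE)
  g <- tibble::tibble(participant_id = sprintf("G%02d", seq_len(n_gainers)),
                      n = as.integer(sessions),
                      magnitude = runif(n_gainers, 15, 35))
  if (consecutive > 0) {
    extra <- g[seq_len(consecutive), ]
    extra$n <- extra$n + 1L
    extra$magnitude <- extra$magnitude + 5   # later gain is larger
    g <- dplyr::bind_rows(g, extra)
  }
  g
}

test_that("the full pair-selection rule chain reproduces the expected design size", {
  gains <- make_gain_table(32, consecutive = 5)
  # 7 participants lose their pregain tape; 5 others lose the n-1 control
  # but have n-2 available as a fallback
  avail <- dplyr::bind_rows(
    tibble::tibble(participant_id = sprintf("G%02d", 1:7),
                   session = gains$n[1:7], available = FALSE),
    tibble::tibble(participant_id = sprintf("G%02d", 8:12),
                   session = gains$n[8:12] - 1L, available = FALSE))
  design <- select_tape_pairs(gains, avail, foil_pool = sprintf("N%02d", 1:30),
                              ratio = 2, seed = 7)
  expect_equal(design$n_gain_pairs, 25)
  expect_equal(design$n_foil_pairs, 13)
  expect_equal(sum(design$excluded$reason == "pregain tape unavailable"), 7)
  # fallback participants got n-2 as control
  fb <- design$pairs[design$pairs$participant_id %in% sprintf("G%02d", 8:12), ]
  expect_equal(fb$control_session, fb$pregain_session - 2L)
  # consecutive-gain participants keep their earlier (first) gain
  cg <- design$pairs[design$pairs$participant_id %in% sprintf("G%02d", 1:5), ]
  expect_true(all(cg$pregain_session == gains$n[1:5]))
})

test_that("tape designs are deterministic under a seed and order hides pair kind", {
  gains <- make_gain_table(20)
  d1 <- select_tape_pairs(gains, NULL, sprintf("N%02d", 1:20), seed = 11)
  d2 <- select_tape_pairs(gains, NULL, sprintf("N%02d", 1:20), seed = 11)
  d3 <- select_tape_pairs(gains, NULL, sprintf("N%02d", 1:20), seed = 12)
  expect_identical(d1$pairs, d2$pairs)
  expect_false(identical(d1$pairs$pair_id, d3$pairs$pair_id) &&
                 identical(d1$pairs$participant_id, d3$pairs$participant_id))
  # counterbalancing: half the pairs show the pregain/first member first
  expect_equal(sum(d1$pairs$pregain_first), nrow(d1$pairs) %/% 2)
  # pair kinds are interleaved by the randomised ordering, not blocked
  kinds <- d1$pairs$pair_kind
  expect_true(any(kinds[seq_len(d1$n_gain_pairs)] == "foil"))
})

test_that("zero gainers give an empty design and an empty pool errors", {
  empty <- make_gain_table(5)[0, ]
  d <- select_tape_pairs(empty, NULL, sprintf("N%02d", 1:5), seed = 3)
  expect_equal(d$n_gain_pairs, 0)
  expect_equal(d$n_foil_pairs, 0)
  gains <- make_gain_table(4)
  expect_error(select_tape_pairs(gains, NULL, character(0), seed = 3),
               "foil pool")
})

test_that("foil session numbers track the gain-pair session distribution", {
  gains <- make_gain_table(200, sessions = sample(c(4, 5, 9), 200,
                                                  replace = TRUE,
                                                  prob = c(0.5, 0.3, 0.2)))
  d <- select_tape_pairs(gains, NULL, sprintf("N%03d", 1:150), ratio = 2,
                         seed = 21)
  gain_tab <- table(factor(d$pairs$pregain_session[d$pairs$pair_kind == "gain"],
                           levels = c(4, 5, 9)))
  foil_tab <- table(factor(d$pairs$pregain_session[d$pairs$pair_kind == "foil"],
                           levels = c(4, 5, 9)))
  gof <- suppressWarnings(chisq.test(foil_tab, p = gain_tab / sum(gain_tab)))
  expect_gt(gof$p.value, 0.01)
})

test_that("ICC(2,1) matches the ANOVA mean-squares oracle and its invariances", {
  m <- matrix(c(9, 2, 6, 1, 8, 4, 7, 1, 10, 5, 6, 2), ncol = 2, byrow = TRUE)
  r <- icc_2_1(m)
  # frozen value from an independent two-way random-effects ANOVA computation
  expect_equal(r$icc, 0.12565445026178, tolerance = 1e-10)
  # cross-check the mean squares against aov()
  d <- data.frame(y = as.vector(m),
                  target = factor(rep(1:6, 2)), rater = factor(rep(1:2, each = 6)))
  ms <- summary(aov(y ~ target + rater, data = d))[[1]][, "Mean Sq"]
  expect_equal(c(r$msr, r$msc, r$mse), unname(ms), tolerance = 1e-10)
  # perfect agreement
  x <- cbind(1:6, 1:6)
  expect_equal(icc_2_1(x)$icc, 1)
  # absolute agreement penalises a constant rater offset
  expect_lt(icc_2_1(cbind(1:4, 3:6))$icc, 1)
  # invariant to a global constant, degraded by a single-rater shift
  base <- cbind(c(1, 5, 3, 8), c(2, 4, 3, 7))
  expect_equal(icc_2_1(base + 10)$icc, icc_2_1(base)$icc)
  shifted <- base; shifted[, 2] <- shifted[, 2] + 5
  expect_lt(icc_2_1(shifted)$icc, icc_2_1(base)$icc)
  # constant matrix is degenerate, not zero
  expect_true(icc_2_1(matrix(3, 4, 2))$degenerate)
})

test_that("rating validation enforces the 0-2 and 0-6 scale ranges", {
  ok <- tibble::tibble(therapist_generalised = c(0, 2),
                       client_generalised = c(0, 6))
  expect_silent(validate_ratings(ok))
  bad <- tibble::tibble(therapist_generalised = c(0, 3))
  expect_error(validate_ratings(bad), "0-2")
  bad2 <- tibble::tibble(client_specific = c(7, 1))
  expect_error(validate_ratings(bad2), "0-6")
})

test_that("paired pregain-control comparisons handle effects and degeneracies", {
  pre <- tibble::tibble(client_generalised = c(4, 5, 3, 6, 4))
  ctl <- tibble::tibble(client_generalised = c(3, 4, 3, 4, 3))
  r <- compare_pregain_vs_control(pre, ctl)
  diffs <- pre$client_generalised - ctl$client_generalised
  expect_equal(r$t, mean(diffs) / (sd(diffs) / sqrt(5)))
  expect_equal(r$df, 4L)
  expect_equal(r$d, mean(diffs) / sd(diffs))
  # identical sessions
  r0 <- compare_pregain_vs_control(pre, pre)
  expect_equal(r0$t, 0); expect_equal(r0$d, 0)
  # constant nonzero difference has no spread: flagged infinite
  rc <- compare_pregain_vs_control(pre, dplyr::mutate(
    pre, client_generalised = client_generalised - 1))
  expect_true(rc$infinite)
  # a single pair is inestimable
  r1 <- compare_pregain_vs_control(pre[1, ], ctl[1, ])
  expect_false(r1$estimable)
})

test_that("paired d estimates centre on the configured standardised effect", {
  set.seed(91)
  dvals <- replicate(300, {
    diffs <- rnorm(25, 1, 2)
    pre <- tibble::tibble(client_generalised = rnorm(25, 3, 1.5) + diffs)
    ctl <- tibble::tibble(client_generalised = pre$client_generalised - diffs)
    compare_pregain_vs_control(pre, ctl)$d
  })
  expect_lt(abs(mean(dvals) - 0.5), 0.05)
})

test_that("between-group comparisons use the pooled df and detect group gaps", {
  set.seed(92)
  g <- tibble::tibble(client_generalised = rnorm(25, 4, 1.6))
  n <- tibble::tibble(client_generalised = rnorm(26, 3, 1.6))
  r <- compare_gainers_vs_nongainers(g, n)
  expect_equal(r$df, 49L)
  ref <- t.test(g$client_generalised, n$client_generalised, var.equal = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-10)
  expect_false(compare_gainers_vs_nongainers(g[1, ], n)$estimable)
})

test_that("simulated ratings elevate client scales only in pregain sessions", {
  gains <- make_gain_table(150)
  design <- select_tape_pairs(gains, NULL, sprintf("N%03d", 1:100), ratio = 2,
                              seed = 41)
  ratings <- simulate_tape_ratings(design, client_pregain_effect = 1.5,
                                   seed = 42)
  expect_identical(ratings,
                   simulate_tape_ratings(design, client_pregain_effect = 1.5,
                                         seed = 42))
  pre <- ratings[ratings$role == "pregain", ]
  ctl <- ratings[ratings$role == "control", ]
  expect_gt(mean(pre$client_generalised) - mean(ctl$client_generalised), 0.8)
  expect_lt(abs(mean(pre$therapist_generalised) -
                  mean(ctl$therapist_generalised)), 0.25)
})
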