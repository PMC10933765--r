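#' Assemble the blinded videotape-pair design
#'
#' Builds the set of session-tape pairs an independent assistant would hand
#' to a blinded rater. For each gaining participant the rules are applied
#' in order: (1) the later member of any pair of gains at consecutive
#' pregain indices is discarded (it has no usable control session); (2) the
#' largest remaining gain is selected; (3) if the pregain session tape is
#' unavailable the participant is excluded; (4) the control session is the
#' previous session `n - 1`, falling back to `n - 2` when that tape is
#' unavailable, and the participant is excluded when neither exists. Foil
#' pairs — two consecutive sessions from participants who never gained —
#' are added at the configured pair ratio, with foil session numbers drawn
#' to match the empirical frequency of the gain-pair session numbers.
#' Viewing order within pairs is counterbalanced 50/50 (an odd leftover
#' pair ordered at random) and the order of pairs is randomised, so pair
#' kind is not derivable from position. Deterministic under a fixed seed.
#'
#' @param gains Tibble of all detected gains (`participant_id`, `n`,
#'   `magnitude`).
#' @param availability Optional tibble (`participant_id`, `session`,
#'   `available`); sessions absent from the table count as available.
#'   `NULL` means every tape exists.
#' @param foil_pool Character vector of non-gaining participant ids whose
#'   tapes may serve as foils.
#' @param ratio Gain-pairs-to-foil-pairs ratio (default 2, i.e. one foil
#'   per two gain pairs, rounded up).
#' @param seed Integer seed driving order randomisation and foil sampling.
#' @return List of class `tape_design`: `pairs` (tibble: `pair_id`,
#'   `pair_kind`, `participant_id`, `pregain_session`, `control_session`,
#'   `first_session`, `second_session`, `pregain_first`), `excluded`
#'   (tibble of exclusions with reasons), `n_gain_pairs`, `n_foil_pairs`.
#' @export
select_tape_pairs <- function(gains, availability = NULL, foil_pool,
                              ratio = 2, seed = 1L) {
  restore <- .set_local_seed(seed)
  on.exit(restore(), add = TRUE)
  is_avail <- function(pid, session) {
    if (session < 1) return(FALSE)
    if (is.null(availability)) return(TRUE)
    hit <- availability$participant_id == pid &
      availability$session == session
    if (!any(hit)) return(TRUE)
    all(availability$available[hit])
  }

  pair_rows <- list(); excl_rows <- list()
  exclude <- function(pid, reason) {
    excl_rows[[length(excl_rows) + 1L]] <<- tibble::tibble(
      participant_id = pid, reason = reason)
  }
  for (pid in unique(gains$participant_id)) {
    sel <- select_primary_gain(gains[gains$participant_id == pid, ],
                               rule = "tape_study")
    if (is.null(sel)) { exclude(pid, "no gain with usable control"); next }
    n <- sel$n
    if (!is_avail(pid, n)) { exclude(pid, "pregain tape unavailable"); next }
    control <- if (is_avail(pid, n - 1L)) n - 1L else
      if (is_avail(pid, n - 2L)) n - 2L else NA_integer_
    if (is.na(control)) { exclude(pid, "no available control tape"); next }
    pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
      pair_kind = "gain", participant_id = pid, pregain_session = n,
      control_session = control)
  }
  gain_pairs <- if (length(pair_rows) > 0) dplyr::bind_rows(pair_rows) else
    tibble::tibble(pair_kind = character(), participant_id = character(),
                   pregain_session = integer(), control_session = integer())

  n_gain <- nrow(gain_pairs)
  n_foil <- if (ratio > 0) ceiling(n_gain / ratio) else 0L
  foil_pairs <- tibble::tibble(pair_kind = character(),
                               participant_id = character(),
                               pregain_session = integer(),
                               control_session = integer())
  if (n_foil > 0) {
    if (length(foil_pool) < n_foil) {
      stop("foil pool too small for requested ratio")
    }
    # session numbers of foil pairs mirror the gain-pair frequencies
    foil_sessions <- sample(gain_pairs$pregain_session, n_foil,
                            replace = TRUE)
    foil_ids <- sample(foil_pool, n_foil, replace = FALSE)
    foil_pairs <- tibble::tibble(
      pair_kind = "foil", participant_id = foil_ids,
      pregain_session = as.integer(foil_sessions),
      control_session = as.integer(foil_sessions) - 1L)
  }

  pairs <- dplyr::bind_rows(gain_pairs, foil_pairs)
  if (nrow(pairs) > 0) {
    # counterbalance viewing order 50/50, odd leftover at random
    k <- nrow(pairs)
    first_flags <- rep(c(TRUE, FALSE), length.out = 2 * (k %/% 2))
    if (k %% 2 == 1) first_flags <- c(first_flags, runif(1) < 0.5)
    pairs$pregain_first <- sample(first_flags, k)
    pairs$first_session <- ifelse(pairs$pregain_first, pairs$pregain_session,
                                  pairs$control_session)
    pairs$second_session <- ifelse(pairs$pregain_first, pairs$control_session,
                                   pairs$pregain_session)
    pairs <- pairs[sample.int(k), , drop = FALSE]
    pairs$pair_id <- seq_len(k)
    pairs <- pairs[, c("pair_id", "pair_kind", "participant_id",
                       "pregain_session", "control_session", "first_session",
                       "second_session", "pregain_first")]
  }
  structure(list(
    pairs = pairs,
    excluded = if (length(excl_rows) > 0) dplyr::bind_rows(excl_rows) else
      tibble::tibble(participant_id = character(), reason = character()),
    n_gain_pairs = n_gain, n_foil_pairs = nrow(foil_pairs)),
    class = "tape_design")
}

#' @export
print.tape_design <- function(x, ...) {
  cat(sprintf("<tape_design> %d gain pairs, %d foil pairs, %d exclusions\n",
              x$n_gain_pairs, x$n_foil_pairs, nrow(x$excluded)))
  invisible(x)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater intraclass
#' correlation from the Shrout-Fleiss mean squares:
#' `(MSR - MSE) / (MSR + (k - 1) MSE + (k / n)(MSC - MSE))`, where `MSR`,
#' `MSC` and `MSE` are the target, rater and error mean squares of the
#' two-way ANOVA over an `n x k` complete targets-by-raters matrix.
#' Degenerate matrices (no between-target variance, or a non-positive
#' denominator) return an explicit flag rather than a number.
#'
#' @param ratings Numeric matrix, targets in rows, raters in columns,
#'   complete.
#' @return List with `icc`, `degenerate`, and the three mean squares.
#' @export
icc_2_1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 targets and 2 raters")
  if (anyNA(ratings)) stop("ratings matrix must be complete")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (sst == 0 || denom <= 0) {
    return(list(icc = NA_real_, degenerate = TRUE,
                msr = msr, msc = msc, mse = mse))
  }
  list(icc = (msr - mse) / denom, degenerate = FALSE,
       msr = msr, msc = msc, mse = mse)
}

# scale ranges of the four rating scales
.rating_scales <- c(therapist_generalised = 2, therapist_specific = 2,
                    client_generalised = 6, client_specific = 6)

#' Validate a table of session ratings
#'
#' Checks that each of the four rating scales stays within its declared
#' range: therapist question scales 0-2, client statement scales 0-6.
#'
#' @param ratings Tibble with the four scale columns.
#' @return Invisibly, `ratings`; errors on out-of-range scores.
#' @export
validate_ratings <- function(ratings) {
  for (sc in names(.rating_scales)) {
    if (!sc %in% names(ratings)) next
    v <- ratings[[sc]][!is.na(ratings[[sc]])]
    if (any(v < 0 | v > .rating_scales[[sc]])) {
      stop(sprintf("%s scores must lie in 0-%d", sc, .rating_scales[[sc]]))
    }
  }
  invisible(ratings)
}

#' Paired comparison of pregain and control sessions
#'
#' Paired t tests per rating scale across the gain pairs, with
#' `df = pairs - 1` and the paired Cohen's d (mean difference over the SD
#' of the differences). Differences are pregain minus control, so more of
#' a behaviour in pregain sessions is positive. Constant differences with
#' zero spread are flagged infinite; fewer than two pairs is inestimable.
#'
#' @param pregain,control Tibbles of per-pair scale scores with identical
#'   row order, columns among the four scale names.
#' @return Tibble: `scale`, `t`, `df`, `p`, `d`, `estimable`, `infinite`.
#' @export
compare_pregain_vs_control <- function(pregain, control) {
  scales <- intersect(names(.rating_scales), names(pregain))
  out <- lapply(scales, function(sc) {
    diffs <- pregain[[sc]] - control[[sc]]
    diffs <- diffs[!is.na(diffs)]
    n <- length(diffs)
    if (n < 2) {
      return(tibble::tibble(scale = sc, t = NA_real_, df = NA_integer_,
                            p = NA_real_, d = NA_real_, estimable = FALSE,
                            infinite = FALSE))
    }
    sdd <- sd(diffs); md <- mean(diffs)
    if (sdd == 0) {
      if (md == 0) {
        return(tibble::tibble(scale = sc, t = 0, df = n - 1L, p = 1, d = 0,
                              estimable = TRUE, infinite = FALSE))
      }
      return(tibble::tibble(scale = sc, t = sign(md) * Inf, df = n - 1L,
                            p = 0, d = sign(md) * Inf, estimable = TRUE,
                            infinite = TRUE))
    }
    t <- md / (sdd / sqrt(n))
    tibble::tibble(scale = sc, t = t, df = n - 1L,
                   p = 2 * pt(-abs(t), n - 1), d = md / sdd,
                   estimable = TRUE, infinite = FALSE)
  })
  dplyr::bind_rows(out)
}

#' Between-group comparison of gainers' pregain and non-gainers' foil sessions
#'
#' Independent pooled-variance t tests per rating scale,
#' `df = n1 + n2 - 2`. Groups of fewer than two sessions are inestimable.
#'
#' @param gainer,nongainer Tibbles of per-session scale scores.
#' @return Tibble: `scale`, `t`, `df`, `p`, `estimable`.
#' @export
compare_gainers_vs_nongainers <- function(gainer, nongainer) {
  scales <- intersect(names(.rating_scales), names(gainer))
  out <- lapply(scales, function(sc) {
    x <- gainer[[sc]][!is.na(gainer[[sc]])]
    y <- nongainer[[sc]][!is.na(nongainer[[sc]])]
    if (length(x) < 2 || length(y) < 2) {
      return(tibble::tibble(scale = sc, t = NA_real_, df = NA_integer_,
                            p = NA_real_, estimable = FALSE))
    }
    r <- two_sample_t(x = x, y = y)
    tibble::tibble(scale = sc, t = r$t, df = r$df, p = r$p, estimable = TRUE)
  })
  dplyr::bind_rows(out)
}

#' Simulate blinded session ratings for a tape design
#'
#' Generates the four scale scores for every session of a design, with a
#' configurable mean elevation of the client scales in true pregain
#' sessions (therapist scales are generated with no pregain effect).
#' Scores are rounded and clamped to each scale's range. Intended for
#' power/design studies and for exercising the rating comparisons.
#'
#' @param design A `tape_design`.
#' @param client_pregain_effect Mean elevation of client scales in pregain
#'   sessions (default 1 scale point).
#' @param client_mean,client_sd Base client-scale distribution (defaults
#'   2.8 and 1.6).
#' @param therapist_mean,therapist_sd Base therapist-scale distribution
#'   (defaults 1 and 0.6).
#' @param seed Integer seed.
#' @return Tibble of rating records, one row per (pair, session role).
#' @export
simulate_tape_ratings <- function(design, client_pregain_effect = 1,
                                  client_mean = 2.8, client_sd = 1.6,
                                  therapist_mean = 1, therapist_sd = 0.6,
                                  seed = 1L) {
  restore <- .set_local_seed(seed)
  on.exit(restore(), add = TRUE)
  pairs <- design$pairs
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- pairs[i, ]
    roles <- if (pr$pair_kind == "gain") c("pregain", "control") else
      c("foil_a", "foil_b")
    sess <- c(pr$pregain_session, pr$control_session)
    bump <- ifelse(roles == "pregain", client_pregain_effect, 0)
    tibble::tibble(
      pair_id = pr$pair_id, participant_id = pr$participant_id,
      session = sess, role = roles,
      therapist_generalised = pmin(pmax(round(
        rnorm(2, therapist_mean, therapist_sd)), 0), 2),
      therapist_specific = pmin(pmax(round(
        rnorm(2, therapist_mean, therapist_sd)), 0), 2),
      client_generalised = pmin(pmax(round(
        rnorm(2, client_mean + bump, client_sd)), 0), 6),
      client_specific = pmin(pmax(round(
        rnorm(2, client_mean + 0.5 * bump, client_sd)), 0), 6))
  })
  validate_ratings(dplyr::bind_rows(rows))
}
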