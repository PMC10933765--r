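#' Configure the three sudden-gain criteria
#'
#' Holds every threshold of the three-criterion rule as an explicit,
#' testable parameter. Criterion one requires the between-session drop to
#' reach an absolute cutoff (the reliable change index, in score units);
#' criterion two requires the drop to be at least `relative_drop` of the
#' pregain score; criterion three requires the mean of up to three pregain
#' scores to exceed the mean of up to three postgain scores by more than a
#' critical multiple of their pooled standard deviation. The multiplier is
#' 2.78 when all six window points are available and 3.18 when only five
#' are (at series boundaries or with one interior point missing); these are
#' the 97.5th percentiles of the t distribution at 4 and 3 degrees of
#' freedom, rounded to two decimals.
#'
#' @param rci_cutoff Criterion-one cutoff in score units (default 12, the
#'   rounded-up reliable change index for an LSAS-like scale with baseline
#'   SD 18 and reliability 0.95; see [compute_rci_cutoff()]).
#' @param relative_drop Criterion-two proportion of the pregain score
#'   (default 0.25).
#' @param crit3_multiplier_full Criterion-three multiplier with six window
#'   points (default 2.78).
#' @param crit3_multiplier_five Adjusted multiplier with five window points
#'   (default 3.18).
#' @param min_points_per_side Minimum non-missing values required on each
#'   side of the window (default 2).
#' @param pooled_sd_method `"df_weighted"` (default) pools variances with
#'   degree-of-freedom weights; `"simple_average"` averages the two
#'   variances, available for sensitivity analysis.
#' @return An object of class `gain_criteria`.
#' @export
gain_criteria <- function(rci_cutoff = 12, relative_drop = 0.25,
                          crit3_multiplier_full = 2.78,
                          crit3_multiplier_five = 3.18,
                          min_points_per_side = 2,
                          pooled_sd_method = c("df_weighted", "simple_average")) {
  stopifnot(rci_cutoff > 0, relative_drop > 0, relative_drop < 1,
            crit3_multiplier_full > 0, crit3_multiplier_five > 0,
            min_points_per_side >= 1)
  structure(list(rci_cutoff = rci_cutoff, relative_drop = relative_drop,
                 crit3_multiplier_full = crit3_multiplier_full,
                 crit3_multiplier_five = crit3_multiplier_five,
                 min_points_per_side = min_points_per_side,
                 pooled_sd_method = match.arg(pooled_sd_method)),
            class = "gain_criteria")
}

#' Reliable change index cutoff (Jacobson-Truax)
#'
#' Computes the smallest score change unlikely to be measurement error,
#' `1.96 * sqrt(2 * (SD * sqrt(1 - alpha))^2)`, from the baseline standard
#' deviation of the scale and its internal consistency, and rounds it up to
#' the nearest whole score point (the conventional criterion-one cutoff).
#'
#' @param baseline_sd Standard deviation of baseline scores (score units).
#' @param alpha Scale reliability (Cronbach's alpha), in \[0, 1\].
#' @param rounding `"ceiling"` (default) rounds up to an integer cutoff;
#'   `"raw"` leaves the cutoff unrounded.
#' @return List with `raw` (the unrounded index) and `cutoff`.
#' @examples
#' compute_rci_cutoff(18.0, 0.95)  # raw 11.157, cutoff 12
#' @export
compute_rci_cutoff <- function(baseline_sd, alpha,
                               rounding = c("ceiling", "raw")) {
  rounding <- match.arg(rounding)
  if (baseline_sd < 0) stop("baseline_sd must be >= 0")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  raw <- 1.96 * sqrt(2 * (baseline_sd * sqrt(1 - alpha))^2)
  cutoff <- if (rounding == "ceiling") ceiling(raw) else raw
  list(raw = raw, cutoff = cutoff, baseline_sd = baseline_sd, alpha = alpha)
}

#' Pooled standard deviation of the pre- and postgain windows
#'
#' @param pre_values,post_values Window values (missing entries removed by
#'   the caller); at least two per side.
#' @param method `"df_weighted"` (default): `sqrt(((n1-1) s1^2 + (n2-1)
#'   s2^2) / (n1 + n2 - 2))`; `"simple_average"`: `sqrt((s1^2 + s2^2) / 2)`.
#' @return The pooled standard deviation in score units.
#' @export
pooled_sd <- function(pre_values, post_values,
                      method = c("df_weighted", "simple_average")) {
  method <- match.arg(method)
  n1 <- length(pre_values); n2 <- length(post_values)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per side")
  v1 <- var(pre_values); v2 <- var(post_values)
  if (method == "df_weighted") {
    sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  } else {
    sqrt((v1 + v2) / 2)
  }
}

#' Evaluate the three criteria at one between-session interval
#'
#' Assesses the interval between sessions `n` (pregain) and `n + 1`
#' (postgain). Intervals at the series boundaries (`n = 1` or `n = T - 1`),
#' intervals with a missing endpoint, and intervals whose criterion-three
#' window retains fewer than five points (or fewer than
#' `min_points_per_side` on either side) are reported as not evaluable —
#' a state kept distinct from criterion failure.
#'
#' @param values Numeric vector of weekly totals, `NA` for missing weeks.
#' @param n Pregain session index, `1 <= n <= length(values) - 1`.
#' @param criteria A [gain_criteria()] object.
#' @return A list: `evaluable` plus either `reason` (when not evaluable) or
#'   `pregain`, `postgain`, `magnitude`, per-criterion diagnostics
#'   (`crit1`, `crit2`, `crit3`) and `pass_all`.
#' @export
evaluate_interval <- function(values, n, criteria = gain_criteria()) {
  T_ <- length(values)
  if (n < 1 || n > T_ - 1) stop("pregain index out of range")
  not_ev <- function(reason) list(evaluable = FALSE, reason = reason)
  if (n == 1 || n == T_ - 1) return(not_ev("boundary"))
  x_n <- values[n]; x_n1 <- values[n + 1]
  if (is.na(x_n) || is.na(x_n1)) return(not_ev("missing endpoint"))

  magnitude <- x_n - x_n1
  crit1 <- list(value = magnitude, threshold = criteria$rci_cutoff,
                pass = magnitude >= criteria$rci_cutoff)
  crit2 <- list(value = magnitude, threshold = criteria$relative_drop * x_n,
                pass = magnitude >= criteria$relative_drop * x_n)

  pre_idx <- (n - 2):n
  post_idx <- (n + 1):(n + 3)
  pre <- values[pre_idx[pre_idx >= 1]]
  post <- values[post_idx[post_idx <= T_]]
  pre <- pre[!is.na(pre)]; post <- post[!is.na(post)]
  n_pts <- length(pre) + length(post)
  if (n_pts < 5 || length(pre) < criteria$min_points_per_side ||
      length(post) < criteria$min_points_per_side) {
    return(not_ev("too few window points"))
  }
  mult <- if (n_pts == 6) criteria$crit3_multiplier_full else
    criteria$crit3_multiplier_five
  psd <- pooled_sd(pre, post, method = criteria$pooled_sd_method)
  mean_diff <- mean(pre) - mean(post)
  crit3 <- list(pre_window = pre, post_window = post, n_points = n_pts,
                mean_diff = mean_diff, pooled_sd = psd, multiplier = mult,
                threshold = mult * psd, pass = mean_diff > mult * psd)

  list(evaluable = TRUE, n = n, pregain = x_n, postgain = x_n1,
       magnitude = magnitude, crit1 = crit1, crit2 = crit2, crit3 = crit3,
       pass_all = crit1$pass && crit2$pass && crit3$pass)
}

#' Detect sudden gains on one trajectory
#'
#' Scans every evaluable pregain index in ascending order and returns the
#' intervals passing all three criteria, together with the count of
#' evaluable intervals (the denominator for interval-level rates).
#'
#' @param values Numeric vector of weekly totals (`NA` for missing weeks),
#'   length at least 6.
#' @param criteria A [gain_criteria()] object.
#' @return List with `gains` (tibble: `n`, `pregain`, `postgain`,
#'   `magnitude`, criterion diagnostics) and `n_evaluable`.
#' @export
detect_gains <- function(values, criteria = gain_criteria()) {
  T_ <- length(values)
  if (T_ < 6) stop("series must have at least 6 timepoints")
  rows <- list(); n_ev <- 0L
  for (n in seq_len(T_ - 1)) {
    ev <- evaluate_interval(values, n, criteria)
    if (!ev$evaluable) next
    n_ev <- n_ev + 1L
    if (ev$pass_all) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n = n, pregain = ev$pregain, postgain = ev$postgain,
        magnitude = ev$magnitude,
        crit1_pass = ev$crit1$pass, crit2_pass = ev$crit2$pass,
        crit3_pass = ev$crit3$pass,
        crit3_mean_diff = ev$crit3$mean_diff,
        crit3_pooled_sd = ev$crit3$pooled_sd,
        crit3_multiplier = ev$crit3$multiplier,
        crit3_n_points = ev$crit3$n_points)
    }
  }
  gains <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble::tibble(
    n = integer(), pregain = numeric(), postgain = numeric(),
    magnitude = numeric(), crit1_pass = logical(), crit2_pass = logical(),
    crit3_pass = logical(), crit3_mean_diff = numeric(),
    crit3_pooled_sd = numeric(), crit3_multiplier = numeric(),
    crit3_n_points = integer())
  list(gains = gains, n_evaluable = n_ev)
}

#' Detect sudden gains across a cohort
#'
#' Applies [detect_gains()] to every participant's trajectory on one
#' measure.
#'
#' @param cohort A `gain_cohort`.
#' @param measure Measure to scan (default `"lsas"`).
#' @param criteria A [gain_criteria()] object.
#' @return List with `gains` (tibble with `participant_id`, `condition` and
#'   the per-gain columns of [detect_gains()]) and `intervals` (tibble:
#'   `participant_id`, `condition`, `n_evaluable`).
#' @export
detect_cohort_gains <- function(cohort, measure = "lsas",
                                criteria = gain_criteria()) {
  tr <- cohort$trajectories
  idx <- unique(tr[tr$measure == measure, c("participant_id", "condition")])
  vals <- series_matrix(cohort, measure)
  g_rows <- list(); n_eval <- integer(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    pid <- idx$participant_id[i]
    res <- detect_gains(vals[pid, ], criteria)
    n_eval[i] <- res$n_evaluable
    if (nrow(res$gains) > 0) {
      g_rows[[length(g_rows) + 1L]] <- tibble::tibble(
        participant_id = pid, condition = idx$condition[i], res$gains)
    }
  }
  gains <- if (length(g_rows) > 0) dplyr::bind_rows(g_rows) else
    tibble::tibble(participant_id = character(), condition = character(),
                   n = integer(), pregain = numeric(), postgain = numeric(),
                   magnitude = numeric(), crit1_pass = logical(),
                   crit2_pass = logical(), crit3_pass = logical(),
                   crit3_mean_diff = numeric(), crit3_pooled_sd = numeric(),
                   crit3_multiplier = numeric(), crit3_n_points = integer())
  intervals <- tibble::tibble(participant_id = idx$participant_id,
                              condition = idx$condition,
                              n_evaluable = n_eval)
  list(gains = gains, intervals = intervals)
}

#' Select one primary gain per participant
#'
#' Two selection rules are provided. `"largest"` takes the gain of maximum
#' magnitude, ties broken by the earliest pregain index (used for the
#' around-gain analyses). `"tape_study"` first discards the later member of
#' any pair of gains at consecutive pregain indices (that gain has no
#' usable control session) and then takes the largest of the remainder
#' (used when assembling videotape pairs).
#'
#' @param gains Tibble of one participant's gains with columns `n` and
#'   `magnitude`.
#' @param rule `"largest"` or `"tape_study"`.
#' @return A one-row tibble, or `NULL` when no gain survives.
#' @export
select_primary_gain <- function(gains, rule = c("largest", "tape_study")) {
  rule <- match.arg(rule)
  if (is.null(gains) || nrow(gains) == 0) return(NULL)
  g <- gains
  if (rule == "tape_study") {
    g <- g[!(g$n - 1L) %in% gains$n, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
  }
  g <- g[order(-g$magnitude, g$n), , drop = FALSE]
  g[1, , drop = FALSE]
}

#' Primary gains for every gaining participant in a cohort
#'
#' @param gains Tibble of all detected gains (with `participant_id`).
#' @param rule Passed to [select_primary_gain()].
#' @return Tibble with one row per participant that retains a gain.
#' @export
primary_gains <- function(gains, rule = c("largest", "tape_study")) {
  rule <- match.arg(rule)
  if (nrow(gains) == 0) return(gains)
  picked <- lapply(split(gains, gains$participant_id),
                   select_primary_gain, rule = rule)
  dplyr::bind_rows(picked[!vapply(picked, is.null, logical(1))])
}

#' Fraction of overall improvement carried by a gain
#'
#' Divides the gain magnitude by the participant's baseline-to-posttreatment
#' improvement. Undefined (returned as `NA` with the reason recorded) when
#' the posttreatment score is missing or the improvement is not positive.
#'
#' @param magnitude Gain magnitude (score units).
#' @param baseline,posttreatment Assessment scores.
#' @return List with `fraction` (`NA_real_` when undefined) and `defined`.
#' @export
gain_fraction_of_improvement <- function(magnitude, baseline, posttreatment) {
  if (is.na(posttreatment)) {
    return(list(fraction = NA_real_, defined = FALSE, reason = "missing posttreatment"))
  }
  improvement <- baseline - posttreatment
  if (improvement <= 0) {
    return(list(fraction = NA_real_, defined = FALSE, reason = "no improvement"))
  }
  list(fraction = magnitude / improvement, defined = TRUE, reason = NULL)
}

#' Distribution of pregain session indices
#'
#' @param gains Tibble of gains with columns `n` and optionally `condition`.
#' @return List with `counts` (tibble: `condition` if present, `n`,
#'   `count`) and `modes` (per condition, all tied modal indices).
#' @export
gain_timing_distribution <- function(gains) {
  if (nrow(gains) == 0) {
    return(list(counts = tibble::tibble(condition = character(), n = integer(),
                                        count = integer()),
                modes = list()))
  }
  if (!"condition" %in% names(gains)) gains$condition <- "all"
  counts <- dplyr::count(gains, .data$condition, .data$n, name = "count")
  modes <- lapply(split(counts, counts$condition), function(d) {
    sort(d$n[d$count == max(d$count)])
  })
  list(counts = counts, modes = modes)
}
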