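#' Configure the synthetic two-arm trajectory cohort
#'
#' The generator emulates a two-arm weekly-measurement therapy trial: 14
#' scheduled assessments of a 0-144 primary symptom scale, a subset of
#' participants receiving one or two abrupt persistent between-week drops
#' (the injected sudden gains), linked process measures whose decline
#' partly precedes the gain (negative cognitions, self-focused attention)
#' or is purely concurrent with it (depressed mood), and end-of-treatment /
#' follow-up outcomes that differ by gain status after baseline adjustment.
#'
#' @param n_per_arm Participants per arm (default `c(50, 49)`).
#' @param n_weeks Scheduled weekly timepoints T (default 14).
#' @param baseline_mean,baseline_sd Primary-measure baseline distribution
#'   (defaults 85 and 18 score points).
#' @param gradual_weekly_change Mean per-week drift of the primary measure
#'   outside gains (default -2 points/week, so gradual change plus a
#'   typical injected gain reproduce a realistic overall improvement).
#' @param noise_sd Week-to-week measurement noise SD (default 2 points).
#' @param ar1_rho AR(1) autocorrelation of the weekly noise (default 0,
#'   i.i.d. noise; nonzero values support false-positive studies).
#' @param gain_probability Per-arm probability that a participant receives
#'   at least one injected gain (defaults `c(0.64, 0.51)`).
#' @param gain_magnitude_mean,gain_magnitude_sd Per-arm normal magnitude
#'   distribution of injected gains (defaults 23.0/9.0 and 20.8/7.3 points),
#'   floored at zero.
#' @param multi_gain_probability Per-arm probability that a gainer receives
#'   a second gain (defaults `11/32` and `9/25`).
#' @param gain_positions Allowed pregain indices (default `2:(n_weeks - 2)`).
#' @param score_range Primary-measure score range (default `c(0, 144)`).
#' @param ensure_detectable When `TRUE`, injected magnitudes are floored at
#'   the detection threshold `max(rci_cutoff, relative_drop * pregain
#'   level)` so that ground truth is recoverable by design (used for
#'   parameter-recovery studies); default `FALSE`, which preserves the
#'   configured magnitude distribution.
#' @param rci_cutoff,relative_drop Detection thresholds consumed only by
#'   `ensure_detectable`.
#' @param process Named list of process-measure settings, each a list with
#'   `baseline_mean`, `baseline_sd`, `weekly_change`, `noise_sd`,
#'   `pre_gain_drop` (applied over the interval n-1 to n, i.e. before the
#'   primary gain), `concurrent_drop` (applied over n to n+1) and `range`.
#'   Defaults cover SCQ frequency/belief, general and difficult-situation
#'   self-focused attention, and a nine-item depression measure whose
#'   pre-gain drop is zero.
#' @param outcome_intercepts Non-gainer mean outcome at posttreatment,
#'   3-month and 12-month follow-up (default `c(52, 50, 49)`).
#' @param outcome_gain_effects Adjusted gain-status differences (non-gainer
#'   minus gainer) at the three timepoints (defaults `c(16.40, 14.70,
#'   10.20)` points).
#' @param outcome_baseline_slope Linear effect of (centred) baseline on
#'   outcomes (default 0.5).
#' @param outcome_re_sd,outcome_resid_sd Participant random-effect and
#'   residual SDs of the outcome model (defaults 10 and 8).
#' @param missing_rate Probability that a weekly total (week 2 onward) is
#'   missing (default 0).
#' @param conditions Arm labels (default `c("ct", "ict")`).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_arm = c(50, 49), n_weeks = 14,
                              baseline_mean = 85, baseline_sd = 18,
                              gradual_weekly_change = -2, noise_sd = 2,
                              ar1_rho = 0,
                              gain_probability = c(0.64, 0.51),
                              gain_magnitude_mean = c(23.0, 20.8),
                              gain_magnitude_sd = c(9.0, 7.3),
                              multi_gain_probability = c(11 / 32, 9 / 25),
                              gain_positions = NULL,
                              score_range = c(0, 144),
                              ensure_detectable = FALSE,
                              rci_cutoff = 12, relative_drop = 0.25,
                              process = default_process_config(),
                              outcome_intercepts = c(52, 50, 49),
                              outcome_gain_effects = c(16.40, 14.70, 10.20),
                              outcome_baseline_slope = 0.5,
                              outcome_re_sd = 10, outcome_resid_sd = 8,
                              missing_rate = 0,
                              conditions = c("ct", "ict")) {
  if (is.null(gain_positions)) gain_positions <- 2:(n_weeks - 2)
  stopifnot(n_weeks >= 6, length(n_per_arm) == 2,
            all(gain_probability >= 0 & gain_probability <= 1),
            all(multi_gain_probability >= 0 & multi_gain_probability <= 1),
            all(gain_magnitude_sd >= 0), noise_sd >= 0, baseline_sd >= 0,
            ar1_rho >= 0, ar1_rho < 1,
            all(gain_positions >= 2 & gain_positions <= n_weeks - 2),
            missing_rate >= 0, missing_rate < 1,
            length(conditions) == 2)
  structure(as.list(environment()), class = "simulation_config")
}

#' Default process-measure simulation settings
#'
#' Baselines, drifts and drop sizes for five weekly process measures. The
#' drop sizes follow the qualitative lead/lag structure the generator is
#' meant to emulate: cognition and attention measures decline both in the
#' interval before the primary gain and concurrently with it, while the
#' depression measure declines only concurrently. A consecutive-timepoint
#' contrast therefore expects `weekly_change + drop` over an interval
#' carrying a gain-locked drop and `weekly_change` elsewhere; the
#' depression measure's background drift is zero so that its pre-gain
#' interval shows no change at any sample size.
#'
#' @return Named list of per-measure parameter lists.
#' @export
default_process_config <- function() {
  list(
    scq_freq = list(baseline_mean = 45, baseline_sd = 8, weekly_change = -0.8,
                    noise_sd = 4, pre_gain_drop = 3.65, concurrent_drop = 6.79,
                    range = c(0, 88)),
    scq_belief = list(baseline_mean = 1100, baseline_sd = 250,
                      weekly_change = -20, noise_sd = 110,
                      pre_gain_drop = 136.5, concurrent_drop = 116.7,
                      range = c(0, 2200)),
    sfa_gen = list(baseline_mean = 5, baseline_sd = 1.2, weekly_change = -0.1,
                   noise_sd = 0.8, pre_gain_drop = 0.5, concurrent_drop = 0.48,
                   range = c(0, 8)),
    sfa_diff = list(baseline_mean = 5.5, baseline_sd = 1.2,
                    weekly_change = -0.1, noise_sd = 0.9,
                    pre_gain_drop = 0.42, concurrent_drop = 0.51,
                    range = c(0, 8)),
    phq9 = list(baseline_mean = 12, baseline_sd = 4, weekly_change = 0,
                noise_sd = 1.5, pre_gain_drop = 0, concurrent_drop = 1.39,
                range = c(0, 27)))
}

#' Inject a persistent step drop into a weekly series
#'
#' Values after the pregain index `n` are reduced by `magnitude` and
#' truncated at the scale floor; values up to and including `n` are left
#' unchanged.
#'
#' @param values Numeric weekly series.
#' @param n Pregain index, `1 <= n < length(values)`.
#' @param magnitude Drop size, `>= 0`.
#' @param floor_value Scale floor (default 0).
#' @return The modified series.
#' @export
inject_gain <- function(values, n, magnitude, floor_value = 0) {
  if (n < 1 || n >= length(values)) stop("position out of range")
  if (magnitude < 0) stop("magnitude must be >= 0")
  post <- (n + 1):length(values)
  values[post] <- pmax(values[post] - magnitude, floor_value)
  values
}

# Draw one participant's noise vector (i.i.d. or AR(1), stationary variance
# noise_sd^2).
draw_noise <- function(n, noise_sd, rho) {
  if (noise_sd == 0) return(rep(0, n))
  if (rho == 0) return(rnorm(n, 0, noise_sd))
  e <- numeric(n)
  e[1] <- rnorm(1, 0, noise_sd)
  innov_sd <- noise_sd * sqrt(1 - rho^2)
  for (i in 2:n) e[i] <- rho * e[i - 1] + rnorm(1, 0, innov_sd)
  e
}

#' Generate a synthetic cohort
#'
#' Builds every participant's primary-measure trajectory as baseline plus
#' cumulative gradual drift plus injected step drops plus weekly noise,
#' truncated to the score range; generates the linked process-measure
#' trajectories and the baseline/posttreatment/follow-up assessments; and
#' records the injected gains as ground truth. Fully reproducible under a
#' fixed seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed for all randomness.
#' @return A `gain_cohort` with extra elements `ground_truth` (tibble:
#'   `participant_id`, `condition`, `position`, `magnitude`) and
#'   `gain_status` (tibble: `participant_id`, `condition`, `gainer`).
#' @export
generate_cohort <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  withr_seed <- .set_local_seed(seed)
  on.exit(withr_seed(), add = TRUE)

  T_ <- config$n_weeks
  n_total <- sum(config$n_per_arm)
  measures <- c("lsas", names(config$process))
  # trajectory values land in preallocated participant-by-week matrices;
  # tibbles are assembled once at the end (building one per participant is
  # far too slow at simulation-study sizes)
  value_mat <- lapply(setNames(measures, measures),
                      function(m) matrix(NA_real_, n_total, T_))
  pids <- character(n_total); conds <- character(n_total)
  gainer_v <- logical(n_total)
  base_v <- numeric(n_total)
  out_mat <- matrix(NA_real_, n_total, 3)
  gt_pid <- list(); gt_cond <- list(); gt_pos <- list(); gt_mag <- list()
  row_i <- 0L

  for (arm in 1:2) {
    cond <- config$conditions[arm]
    for (i in seq_len(config$n_per_arm[arm])) {
      row_i <- row_i + 1L
      pid <- sprintf("%s_%03d", cond, i)
      pids[row_i] <- pid; conds[row_i] <- cond
      base <- min(max(rnorm(1, config$baseline_mean, config$baseline_sd),
                      config$score_range[1]), config$score_range[2])

      # ground-truth injections
      positions <- integer(0); magnitudes <- numeric(0)
      if (runif(1) < config$gain_probability[arm]) {
        k <- 1L + (runif(1) < config$multi_gain_probability[arm])
        p1 <- sample(config$gain_positions, 1)
        positions <- p1
        if (k == 2L) {
          cand <- config$gain_positions[config$gain_positions != p1]
          # in detectable mode, keep the criterion-three windows of the two
          # gains disjoint so each remains recoverable in isolation
          if (config$ensure_detectable) {
            cand <- cand[abs(cand - p1) >= 4]
          }
          if (length(cand) > 0) {
            positions <- sort(c(p1, if (length(cand) == 1) cand else
              sample(cand, 1)))
          }
        }
        magnitudes <- pmax(rnorm(length(positions),
                                 config$gain_magnitude_mean[arm],
                                 config$gain_magnitude_sd[arm]), 0)
      }

      # primary trajectory: baseline at week 1, drift from week 2 onward
      clean <- base + config$gradual_weekly_change * (0:(T_ - 1))
      if (length(positions) > 0) {
        keep <- rep(TRUE, length(positions))
        for (j in seq_along(positions)) {
          if (config$ensure_detectable) {
            # floor the magnitude at the detection threshold, and skip the
            # injection entirely when the trajectory has no headroom above
            # the scale floor (a truncated step is not recoverable)
            pregain_level <- clean[positions[j]]
            floor_m <- max(config$rci_cutoff,
                           config$relative_drop * pregain_level)
            headroom <- pregain_level - config$score_range[1] -
              3 * abs(config$gradual_weekly_change)
            if (floor_m > headroom) {
              keep[j] <- FALSE
              next
            }
            magnitudes[j] <- min(max(magnitudes[j], floor_m), headroom)
          }
          clean <- inject_gain(clean, positions[j], magnitudes[j],
                               floor_value = config$score_range[1])
        }
        positions <- positions[keep]
        magnitudes <- magnitudes[keep]
      }
      noise <- draw_noise(T_, config$noise_sd, config$ar1_rho)
      noise[1] <- 0   # week 1 is the baseline assessment itself
      value_mat$lsas[row_i, ] <- pmin(pmax(clean + noise,
                                           config$score_range[1]),
                                      config$score_range[2])

      # process measures aligned to the primary (largest-magnitude) gain
      prim <- if (length(positions) > 0) positions[which.max(magnitudes)] else NA
      for (m in names(config$process)) {
        pc <- config$process[[m]]
        pbase <- rnorm(1, pc$baseline_mean, pc$baseline_sd)
        pclean <- pbase + pc$weekly_change * (0:(T_ - 1))
        if (!is.na(prim)) {
          # pre-gain drop lands on week n (change over n-1 -> n), the
          # concurrent drop on week n+1 (change over n -> n+1)
          if (pc$pre_gain_drop != 0 && prim >= 2) {
            pclean <- inject_gain(pclean, prim - 1L, pc$pre_gain_drop,
                                  floor_value = pc$range[1])
          }
          pclean <- inject_gain(pclean, prim, pc$concurrent_drop,
                                floor_value = pc$range[1])
        }
        pnoise <- draw_noise(T_, pc$noise_sd, config$ar1_rho)
        value_mat[[m]][row_i, ] <- pmin(pmax(pclean + pnoise, pc$range[1]),
                                        pc$range[2])
      }

      gainer <- length(positions) > 0
      gainer_v[row_i] <- gainer
      base_v[row_i] <- base
      if (gainer) {
        j <- length(gt_pid) + 1L
        gt_pid[[j]] <- rep(pid, length(positions))
        gt_cond[[j]] <- rep(cond, length(positions))
        gt_pos[[j]] <- positions
        gt_mag[[j]] <- magnitudes
      }

      # outcome assessments
      u <- rnorm(1, 0, config$outcome_re_sd)
      eff <- if (gainer) config$outcome_gain_effects else c(0, 0, 0)
      out <- config$outcome_intercepts - eff +
        config$outcome_baseline_slope * (base - config$baseline_mean) +
        u + rnorm(3, 0, config$outcome_resid_sd)
      out_mat[row_i, ] <- pmin(pmax(out, config$score_range[1]),
                               config$score_range[2])
    }
  }

  trajectories <- dplyr::bind_rows(lapply(measures, function(m) {
    tibble::tibble(
      participant_id = rep(pids, each = T_),
      condition = rep(conds, each = T_),
      measure = m,
      week = rep(seq_len(T_), n_total),
      value = as.vector(t(value_mat[[m]])))
  }))
  ranges <- c(list(lsas = config$score_range),
              lapply(config$process, `[[`, "range"))
  assessments <- tibble::tibble(
    participant_id = pids, condition = conds, measure = "lsas",
    baseline = base_v, posttreatment = out_mat[, 1],
    followup_3m = out_mat[, 2], followup_12m = out_mat[, 3])
  cohort <- gain_cohort(trajectories, assessments = assessments,
                        n_weeks = T_, score_ranges = ranges)
  cohort$ground_truth <- tibble::tibble(
    participant_id = unlist(gt_pid) %||% character(),
    condition = unlist(gt_cond) %||% character(),
    position = as.integer(unlist(gt_pos) %||% integer()),
    magnitude = as.numeric(unlist(gt_mag) %||% numeric()))
  cohort$gain_status <- tibble::tibble(participant_id = pids,
                                       condition = conds, gainer = gainer_v)
  if (config$missing_rate > 0) {
    cohort <- apply_missingness(cohort, config$missing_rate,
                                seed = seed + 1L)
  }
  cohort
}

#' Mark weekly totals missing at random
#'
#' Each weekly total from week 2 onward is set missing independently with
#' the given rate; the week-1 baseline is never removed.
#'
#' @param cohort A `gain_cohort`.
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The cohort with `NA`s inserted.
#' @export
apply_missingness <- function(cohort, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(cohort)
  restore <- .set_local_seed(seed)
  on.exit(restore(), add = TRUE)
  tr <- cohort$trajectories
  eligible <- tr$week > 1L
  drop <- eligible & (runif(nrow(tr)) < rate)
  tr$value[drop] <- NA_real_
  cohort$trajectories <- tr
  cohort
}

# Set the RNG seed locally; returns a restore function.
.set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
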