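#' Run the full sudden-gains analysis pipeline
#'
#' Simulates (or accepts) a cohort, detects sudden gains on the primary
#' measure, aligns the process measures around each participant's largest
#' gain and fits the consecutive contrasts, fits the outcome-by-gain-status
#' model, computes the arm-level frequency statistics, and assembles the
#' blinded tape design. All artifacts are returned as one bundle and,
#' when `out_dir` is given, written as CSV/JSON files that embed the seed
#' and a hash of the configuration, so a rerun with the same configuration
#' reproduces the bundle exactly.
#'
#' @param config A [simulation_config()] (ignored when `cohort` is given).
#' @param criteria A [gain_criteria()].
#' @param seed Integer seed for simulation and design randomisation.
#' @param cohort Optional pre-built `gain_cohort` to analyse instead of
#'   simulating.
#' @param process_measures Process measures for the around-gain contrasts.
#' @param tape_ratio Gain-to-foil pair ratio for the tape design.
#' @param out_dir Optional output directory.
#' @return List of class `gain_report` with elements `cohort`, `gains`,
#'   `intervals`, `primary`, `contrasts`, `outcome_model`,
#'   `frequency`, `tape_design`, `summary`, `seed`, `config_hash`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         criteria = gain_criteria(), seed = 1L,
                         cohort = NULL,
                         process_measures = c("scq_freq", "scq_belief",
                                              "sfa_gen", "sfa_diff", "phq9"),
                         tape_ratio = 2, out_dir = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(config, seed = seed)
  det <- detect_cohort_gains(cohort, measure = "lsas", criteria = criteria)
  gains <- det$gains
  intervals <- det$intervals
  prim <- primary_gains(gains, rule = "largest")

  gainers <- unique(gains$participant_id)
  status <- unique(cohort$trajectories[, c("participant_id", "condition")])
  status$gainer <- status$participant_id %in% gainers

  contrasts <- list()
  if (nrow(prim) >= 2) {
    for (m in intersect(process_measures,
                        unique(cohort$trajectories$measure))) {
      w <- extract_windows(cohort, prim, m)
      contrasts[[m]] <- fit_consecutive_contrasts(w)
    }
  }

  outcome <- NULL
  freq <- frequency_summary(status, gains, intervals)
  if (!is.null(cohort$assessments) && length(unique(status$gainer)) == 2) {
    outcome <- fit_outcome_model(cohort$assessments, status,
                                 rci_cutoff = criteria$rci_cutoff)
  }

  design <- NULL
  if (nrow(prim) > 0) {
    pool <- status$participant_id[!status$gainer]
    if (length(pool) > 0) {
      design <- select_tape_pairs(gains, availability = NULL,
                                  foil_pool = pool, ratio = tape_ratio,
                                  seed = seed + 7L)
    }
  }

  bundle <- structure(list(
    cohort = cohort, gains = gains, intervals = intervals, primary = prim,
    contrasts = contrasts, outcome_model = outcome, frequency = freq,
    tape_design = design, seed = seed,
    config_hash = rlang::hash(config)), class = "gain_report")
  bundle$summary <- summarize_pipeline(bundle)

  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' Arm-level gain frequency statistics
#'
#' Counts gainers, gains and evaluable intervals per arm and runs the
#' three Pearson chi-square comparisons: gainer proportion by arm,
#' gain-interval proportion by arm, and multi-gainer proportion among
#' gainers by arm.
#'
#' @param status Tibble (`participant_id`, `condition`, `gainer`).
#' @param gains Tibble of all detected gains.
#' @param intervals Tibble (`participant_id`, `condition`, `n_evaluable`).
#' @return List with `by_arm` (tibble of counts) and `tests` (list of
#'   chi-square results, `NULL` where a marginal is zero).
#' @export
frequency_summary <- function(status, gains, intervals) {
  conds <- sort(unique(status$condition))
  by_arm <- dplyr::bind_rows(lapply(conds, function(cd) {
    ids <- status$participant_id[status$condition == cd]
    g <- gains[gains$condition == cd, , drop = FALSE]
    per <- table(factor(g$participant_id, levels = ids))
    tibble::tibble(
      condition = cd, n = length(ids), n_gainers = sum(per > 0),
      n_multi_gainers = sum(per > 1), n_gains = nrow(g),
      n_intervals = sum(intervals$n_evaluable[intervals$condition == cd]),
      mean_magnitude = if (nrow(g) > 0) mean(g$magnitude) else NA_real_,
      sd_magnitude = if (nrow(g) > 1) sd(g$magnitude) else NA_real_)
  }))
  safe_chi <- function(m) tryCatch(chi_square_2x2(m), error = function(e) NULL)
  tests <- list()
  if (nrow(by_arm) == 2) {
    tests$gainers <- safe_chi(cbind(by_arm$n_gainers,
                                    by_arm$n - by_arm$n_gainers))
    tests$intervals <- safe_chi(cbind(by_arm$n_gains,
                                      by_arm$n_intervals - by_arm$n_gains))
    tests$multi_gainers <- safe_chi(cbind(
      by_arm$n_multi_gainers, by_arm$n_gainers - by_arm$n_multi_gainers))
    if (all(by_arm$n_gains > 1)) {
      g1 <- gains$magnitude[gains$condition == conds[1]]
      g2 <- gains$magnitude[gains$condition == conds[2]]
      tests$magnitude_t <- two_sample_t(x = g1, y = g2)
    }
  }
  list(by_arm = by_arm, tests = tests)
}

#' Render the headline summary of a report bundle
#'
#' @param bundle A `gain_report`.
#' @return Character vector of summary lines (also printed by
#'   `print.gain_report`).
#' @export
summarize_pipeline <- function(bundle) {
  ba <- bundle$frequency$by_arm
  lines <- character(0)
  if (nrow(ba) == 0 || sum(ba$n) == 0) {
    return("0 participants")
  }
  tot_gains <- sum(ba$n_gains); tot_int <- sum(ba$n_intervals)
  lines <- c(lines, sprintf(
    "%d participants; %d of %d intervals were sudden gains (%.1f%%)",
    sum(ba$n), tot_gains, tot_int,
    if (tot_int > 0) 100 * tot_gains / tot_int else 0))
  for (i in seq_len(nrow(ba))) {
    lines <- c(lines, sprintf(
      "  %s: %d/%d gainers (%.0f%%), %d gains, magnitude M = %.1f (SD %.1f)",
      ba$condition[i], ba$n_gainers[i], ba$n[i],
      100 * ba$n_gainers[i] / ba$n[i], ba$n_gains[i],
      ba$mean_magnitude[i], ba$sd_magnitude[i]))
  }
  tst <- bundle$frequency$tests
  if (!is.null(tst$gainers)) {
    lines <- c(lines, sprintf(
      "  gainer proportion by arm: chi2(1) = %.3f, p = %.3f",
      tst$gainers$statistic, tst$gainers$p))
  }
  if (!is.null(tst$magnitude_t)) {
    lines <- c(lines, sprintf(
      "  magnitude by arm: t(%d) = %.3f, p = %.3f",
      tst$magnitude_t$df, tst$magnitude_t$t, tst$magnitude_t$p))
  }
  lines
}

#' @export
print.gain_report <- function(x, ...) {
  cat(paste(x$summary, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes `gains.csv`, `intervals.csv`, `contrasts.csv`,
#' `outcome_model.json`, `frequency_tables.json`, `design.csv` and
#' `summary.json` into `out_dir`. Every JSON artifact embeds the seed and
#' configuration hash.
#'
#' @param bundle A `gain_report`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, `out_dir`.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(seed = bundle$seed, config_hash = bundle$config_hash)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(out_dir, f), auto_unbox = TRUE, digits = 10, pretty = TRUE)
  write.csv(bundle$gains, file.path(out_dir, "gains.csv"), row.names = FALSE)
  write.csv(bundle$intervals, file.path(out_dir, "intervals.csv"),
            row.names = FALSE)
  if (length(bundle$contrasts) > 0) {
    ctr <- dplyr::bind_rows(lapply(names(bundle$contrasts), function(m) {
      tibble::tibble(measure = m, bundle$contrasts[[m]])
    }))
    write.csv(ctr, file.path(out_dir, "contrasts.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$outcome_model)) {
    wj(c(stamp, list(comparisons = bundle$outcome_model$comparisons,
                     variance_components = bundle$outcome_model$variance_components,
                     meta = bundle$outcome_model$meta)),
       "outcome_model.json")
  }
  wj(c(stamp, list(by_arm = bundle$frequency$by_arm,
                   tests = bundle$frequency$tests)),
     "frequency_tables.json")
  if (!is.null(bundle$tape_design)) {
    write.csv(bundle$tape_design$pairs, file.path(out_dir, "design.csv"),
              row.names = FALSE)
  }
  wj(c(stamp, list(summary = bundle$summary)), "summary.json")
  invisible(out_dir)
}
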