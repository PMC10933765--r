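#' Pearson chi-square test for a 2x2 frequency table
#'
#' Plain Pearson chi-square without continuity correction, as used for
#' comparing gain frequencies between arms; equivalent to the closed form
#' `N (ad - bc)^2 / (r1 r2 c1 c2)` with 1 degree of freedom.
#'
#' @param table 2x2 integer matrix (rows: arm; columns: outcome present /
#'   absent).
#' @return List with `statistic`, `df` (1) and `p`.
#' @examples
#' # gainers vs non-gainers in two arms of 50 and 49
#' chi_square_2x2(matrix(c(32, 25, 18, 24), nrow = 2))
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0)) stop("cells must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal")
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = 1L, p = unname(ct$p.value))
}

#' Pooled-variance two-sample t test
#'
#' Works from raw values or from printed summary statistics (means, SDs,
#' group sizes), with `df = n1 + n2 - 2`. Degenerate zero-pooled-variance
#' comparisons with unequal means are flagged as infinite rather than
#' failing.
#'
#' @param x,y Raw score vectors (used when both are supplied).
#' @param mean_x,sd_x,n_x,mean_y,sd_y,n_y Summary statistics (used when raw
#'   vectors are absent).
#' @return List with `t`, `df`, `p` and `infinite`.
#' @export
two_sample_t <- function(x = NULL, y = NULL, mean_x = NULL, sd_x = NULL,
                         n_x = NULL, mean_y = NULL, sd_y = NULL, n_y = NULL) {
  if (!is.null(x) && !is.null(y)) {
    mean_x <- mean(x); sd_x <- sd(x); n_x <- length(x)
    mean_y <- mean(y); sd_y <- sd(y); n_y <- length(y)
  }
  if (n_x < 2 || n_y < 2) stop("need at least 2 observations per group")
  df <- n_x + n_y - 2
  sp2 <- ((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / df
  se <- sqrt(sp2 * (1 / n_x + 1 / n_y))
  if (se == 0) {
    if (mean_x == mean_y) {
      return(list(t = 0, df = df, p = 1, infinite = FALSE))
    }
    return(list(t = sign(mean_x - mean_y) * Inf, df = df, p = 0,
                infinite = TRUE))
  }
  t <- (mean_x - mean_y) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df), infinite = FALSE)
}

#' Baseline equivalence of gainers and non-gainers, per arm
#'
#' Independent pooled-variance t test on baseline scores by gain status
#' within each treatment arm (`df = n_arm - 2`). Arms where one gain-status
#' level is absent, or with fewer than two participants per level, are
#' flagged inestimable.
#'
#' @param assessments Tibble with `participant_id`, `condition`, `baseline`.
#' @param gain_status Tibble with `participant_id`, `gainer` (logical).
#' @return Tibble with one row per condition: `condition`, `t`, `df`, `p`,
#'   `estimable`.
#' @export
baseline_equivalence_test <- function(assessments, gain_status) {
  d <- dplyr::inner_join(assessments, gain_status,
                         by = c("participant_id", "condition"))
  out <- lapply(split(d, d$condition), function(a) {
    g <- a$baseline[a$gainer]; ng <- a$baseline[!a$gainer]
    if (length(g) < 2 || length(ng) < 2) {
      return(tibble::tibble(condition = a$condition[1], t = NA_real_,
                            df = NA_integer_, p = NA_real_, estimable = FALSE))
    }
    r <- two_sample_t(x = g, y = ng)
    tibble::tibble(condition = a$condition[1], t = r$t, df = r$df, p = r$p,
                   estimable = TRUE)
  })
  dplyr::bind_rows(out)
}

#' Outcome-by-gain-status mixed model
#'
#' Models the repeated outcome assessments (posttreatment, 3-month and
#' 12-month follow-up) with categorical fixed factors of timepoint,
#' treatment condition and gain status (including the timepoint-by-status
#' interaction so the status difference is estimated at each timepoint), a
#' random participant intercept, the baseline score as covariate, maximum
#' likelihood estimation and, when it converges, an unstructured
#' residual covariance over the repeated timepoints; otherwise the model
#' falls back to the random-intercept-only covariance and records the
#' fallback. Missing outcome rows are retained via the likelihood.
#'
#' Pairwise gain-status comparisons at each timepoint are computed from the
#' model's estimated marginal means; the adjusted difference is non-gainer
#' minus gainer, so a benefit of having had a gain is positive. The effect
#' size `d` divides the adjusted difference by the total model SD,
#' `sqrt(random-intercept variance + residual variance)` — a documented
#' convention, since standardisation choices differ across reports. A
#' comparison is flagged clinically meaningful when the adjusted difference
#' reaches the reliable-change cutoff.
#'
#' @param assessments Tibble with `participant_id`, `condition`,
#'   `baseline`, `posttreatment`, `followup_3m`, `followup_12m` (the last
#'   three possibly `NA`).
#' @param gain_status Tibble with `participant_id`, `condition`, `gainer`.
#' @param rci_cutoff Reliable-change cutoff for the clinical-meaning flag
#'   (default 12).
#' @param adjust Multiplicity adjustment across the three timepoints:
#'   `"none"` (default, plain pairwise comparisons) or `"holm"`.
#' @return List with `comparisons` (tibble: `timepoint`,
#'   `adjusted_difference`, `se`, `df`, `p`, `d`, `clinically_meaningful`),
#'   `variance_components`, and `meta` (estimation, covariance structure
#'   actually used, convergence notes).
#' @export
fit_outcome_model <- function(assessments, gain_status, rci_cutoff = 12,
                              adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  d <- dplyr::inner_join(assessments, gain_status,
                         by = c("participant_id", "condition"))
  if (length(unique(d$gainer)) < 2) {
    stop("both gain-status levels must be present")
  }
  if (anyNA(d$baseline)) stop("baseline must be present for all participants")
  long <- tidyr::pivot_longer(
    d, cols = c("posttreatment", "followup_3m", "followup_12m"),
    names_to = "timepoint", values_to = "score")
  long$timepoint <- factor(long$timepoint,
                           levels = c("posttreatment", "followup_3m",
                                      "followup_12m"))
  long$tp_num <- as.integer(long$timepoint)
  long$gain <- factor(ifelse(long$gainer, "gain", "no_gain"),
                      levels = c("no_gain", "gain"))
  long <- long[!is.na(long$score), , drop = FALSE]

  notes <- character(0)
  structure_used <- "unstructured"
  fit <- tryCatch(
    nlme::lme(score ~ timepoint * gain + condition + baseline,
              random = ~ 1 | participant_id,
              correlation = nlme::corSymm(form = ~ tp_num | participant_id),
              weights = nlme::varIdent(form = ~ 1 | timepoint),
              data = long, method = "ML", na.action = na.omit),
    error = function(e) {
      notes <<- c(notes, paste("unstructured covariance failed:",
                               conditionMessage(e)))
      NULL
    })
  if (is.null(fit)) {
    structure_used <- "random_intercept"
    fit <- tryCatch(
      suppressWarnings(
        nlme::lme(score ~ timepoint * gain + condition + baseline,
                  random = ~ 1 | participant_id,
                  data = long, method = "ML", na.action = na.omit,
                  control = nlme::lmeControl(returnObject = TRUE))),
      error = function(e) {
        notes <<- c(notes, paste("random intercept failed:",
                                 conditionMessage(e)))
        NULL
      })
  }
  if (is.null(fit)) {
    structure_used <- "ols"
    fit <- lm(score ~ timepoint * gain + condition + baseline, data = long)
  }

  emm <- emmeans::emmeans(fit, ~ gain | timepoint, data = long)
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  # contrast is "no_gain - gain": positive when gainers score lower
  if (adjust == "holm") prs$p.value <- p.adjust(prs$p.value, method = "holm")

  if (inherits(fit, "lme")) {
    vc <- as.numeric(nlme::VarCorr(fit)[, "Variance"])
    var_int <- vc[1]; var_res <- vc[2]
  } else {
    var_int <- 0; var_res <- summary(fit)$sigma^2
    notes <- c(notes, "OLS fallback: no random-intercept variance")
  }
  total_sd <- sqrt(var_int + var_res)

  comparisons <- tibble::tibble(
    timepoint = as.character(prs$timepoint),
    adjusted_difference = prs$estimate,
    se = prs$SE,
    df = prs$df,
    p = prs$p.value,
    d = if (total_sd > 0) prs$estimate / total_sd else
      ifelse(prs$estimate == 0, 0, Inf * sign(prs$estimate)),
    clinically_meaningful = prs$estimate >= rci_cutoff)

  list(comparisons = comparisons,
       variance_components = list(random_intercept = var_int,
                                  residual = var_res, total_sd = total_sd),
       meta = list(estimation = "ML", covariance = structure_used,
                   covariate = "baseline", adjust = adjust, notes = notes))
}
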