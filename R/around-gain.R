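#' Align a process measure around each participant's primary gain
#'
#' For every participant with a selected (largest) gain at pregain index
#' `n`, extracts the measure's values at offsets -2..+3, i.e. sessions
#' n-2 .. n+3. Offsets falling outside 1..T are marked missing.
#'
#' @param cohort A `gain_cohort`.
#' @param gains Tibble of primary gains (one row per participant, columns
#'   `participant_id`, `n`), as returned by [primary_gains()] with rule
#'   `"largest"`.
#' @param measure Measure to align.
#' @return Long tibble (`participant_id`, `offset`, `week`, `value`) with
#'   attribute `n_without_gain`, the count of cohort participants excluded
#'   for lacking a gain.
#' @export
extract_windows <- function(cohort, gains, measure) {
  all_ids <- unique(cohort$trajectories$participant_id)
  T_ <- cohort$n_weeks
  if (nrow(gains) > 0) {
    vals <- series_matrix(cohort, measure)
    offs <- rep(-2:3, nrow(gains))
    pid <- rep(gains$participant_id, each = 6)
    weeks <- rep(gains$n, each = 6) + offs
    in_range <- weeks >= 1 & weeks <= T_
    value <- rep(NA_real_, length(weeks))
    value[in_range] <- vals[cbind(match(pid[in_range], rownames(vals)),
                                  weeks[in_range])]
    out <- tibble::tibble(participant_id = pid, offset = offs, week = weeks,
                          value = value)
  } else {
    out <- tibble::tibble(participant_id = character(), offset = integer(),
                          week = integer(), value = numeric())
  }
  attr(out, "n_without_gain") <- length(setdiff(all_ids, gains$participant_id))
  out
}

# Offset labels in the field's n-relative notation.
offset_label <- function(o) {
  ifelse(o < 0, paste0("n-", -o), ifelse(o == 0, "n", paste0("n+", o)))
}

#' Consecutive-timepoint contrasts around the gain
#'
#' Fits a linear mixed-effects model with timepoint (offset -2..+3 relative
#' to the gain) as a categorical fixed factor and a random participant
#' intercept, by maximum likelihood, omitting missing offsets via the
#' likelihood. Returns the five planned contrasts between consecutive
#' timepoints as unstandardised mean differences (later minus earlier, so
#' a symptom decline is negative) with standard errors and two-sided
#' p-values from the large-sample normal approximation. Treatment condition
#' is deliberately not a factor. When the mixed model is degenerate (e.g.
#' zero residual variance), the fixed effects are estimated by a
#' within-participant fixed-effects regression instead and the fallback is
#' recorded.
#'
#' @param windows Long tibble from [extract_windows()].
#' @return Tibble with columns `contrast`, `estimate`, `se`, `p`,
#'   `estimable`, plus attribute `method` (`"lme"` or `"fixed_effects"`).
#' @export
fit_consecutive_contrasts <- function(windows) {
  d <- windows[!is.na(windows$value), , drop = FALSE]
  if (nrow(d) == 0 || length(unique(d$participant_id)) < 2) {
    stop("need at least 2 participants with observed window values")
  }
  d$timepoint <- factor(offset_label(d$offset),
                        levels = offset_label(-2:3))
  present <- levels(d$timepoint)[table(d$timepoint) > 0]
  d$timepoint <- factor(as.character(d$timepoint), levels = present)

  method <- "lme"
  fit <- tryCatch(
    suppressWarnings(
      nlme::lme(value ~ timepoint, random = ~ 1 | participant_id,
                data = d, method = "ML", na.action = na.omit,
                control = nlme::lmeControl(returnObject = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    beta <- nlme::fixef(fit)
    V <- vcov(fit)
  } else {
    method <- "fixed_effects"
    ols <- lm(value ~ timepoint + participant_id, data = d)
    keep <- grep("^\\(Intercept\\)$|^timepoint", names(coef(ols)))
    beta <- coef(ols)[keep]
    V <- vcov(ols)[keep, keep, drop = FALSE]
    V[is.na(V)] <- 0
    beta[is.na(beta)] <- 0
  }

  # cell mean at each present level: intercept + level coefficient
  level_coef <- function(lv) {
    nm <- paste0("timepoint", lv)
    if (lv == present[1]) 0 else unname(beta[nm])
  }
  level_var_vec <- function(lv) {
    k <- numeric(length(beta)); names(k) <- names(beta)
    nm <- paste0("timepoint", lv)
    if (lv != present[1]) k[nm] <- 1
    k
  }

  labels <- offset_label(-2:3)
  out <- lapply(seq_len(5), function(i) {
    a <- labels[i]; b <- labels[i + 1]
    cn <- paste(a, "to", b)
    if (!(a %in% present) || !(b %in% present)) {
      return(tibble::tibble(contrast = cn, estimate = NA_real_, se = NA_real_,
                            p = NA_real_, estimable = FALSE))
    }
    est <- level_coef(b) - level_coef(a)
    L <- level_var_vec(b) - level_var_vec(a)
    se <- sqrt(drop(t(L) %*% V %*% L))
    # a numerically zero SE marks an exact (noiseless) fit: the contrast is
    # either exactly its estimate (p -> 0) or exactly null (p -> 1)
    p <- if (se < 1e-8) as.numeric(abs(est) < 1e-8) else
      2 * pnorm(-abs(est / se))
    tibble::tibble(contrast = cn, estimate = unname(est), se = se, p = p,
                   estimable = TRUE)
  })
  res <- dplyr::bind_rows(out)
  attr(res, "method") <- method
  res
}
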