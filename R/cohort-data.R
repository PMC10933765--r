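#' @importFrom rlang .data %||%
#' @importFrom stats aggregate anova aov as.formula coef complete.cases lm
#'   na.omit p.adjust pchisq pnorm pt qnorm rbinom rnorm runif sd setNames
#'   t.test var vcov chisq.test
#' @importFrom utils head read.csv write.csv
NULL

#' Assemble a longitudinal questionnaire cohort
#'
#' A cohort bundles the weekly trajectory table, the end-of-treatment and
#' follow-up assessments, and per-measure score ranges into one object that
#' all downstream analysis steps consume. Weeks are indexed 1..T and missing
#' weekly totals are kept as explicit `NA`s, never dropped.
#'
#' @param trajectories Tibble/data frame with columns `participant_id`,
#'   `condition`, `measure`, `week` (integer 1..T) and `value` (numeric,
#'   `NA` for a missed questionnaire).
#' @param assessments Optional tibble with columns `participant_id`,
#'   `condition`, `measure`, `baseline`, `posttreatment`, `followup_3m`,
#'   `followup_12m`. `baseline` must be present for every participant.
#' @param n_weeks Number of scheduled weekly timepoints T. Defaults to the
#'   maximum week present.
#' @param score_ranges Named list mapping measure name to `c(lo, hi)`;
#'   present values outside the declared range are a validation error.
#' @return An object of class `gain_cohort`.
#' @export
gain_cohort <- function(trajectories, assessments = NULL, n_weeks = NULL,
                        score_ranges = list()) {
  trajectories <- tibble::as_tibble(trajectories)
  needed <- c("participant_id", "condition", "measure", "week", "value")
  missing_cols <- setdiff(needed, names(trajectories))
  if (length(missing_cols) > 0) {
    stop("trajectories is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.logical(trajectories$value) && all(is.na(trajectories$value))) {
    trajectories$value <- as.numeric(trajectories$value)  # empty/all-NA column
  }
  if (!is.numeric(trajectories$value)) {
    stop("trajectory values must be numeric")
  }
  trajectories$week <- as.integer(trajectories$week)
  if (any(trajectories$week < 1L, na.rm = TRUE)) stop("weeks must be >= 1")
  dup <- duplicated(trajectories[, c("participant_id", "week", "measure")])
  if (any(dup)) {
    bad <- trajectories[dup, , drop = FALSE][1, ]
    stop(sprintf("duplicate rows for participant %s, week %d, measure %s",
                 bad$participant_id, bad$week, bad$measure))
  }
  if (is.null(n_weeks)) n_weeks <- max(trajectories$week, 1L)
  n_weeks <- as.integer(n_weeks)
  if (any(trajectories$week > n_weeks)) stop("week index exceeds n_weeks")

  for (m in names(score_ranges)) {
    rng <- score_ranges[[m]]
    v <- trajectories$value[trajectories$measure == m]
    v <- v[!is.na(v)]
    if (length(v) > 0 && (min(v) < rng[1] || max(v) > rng[2])) {
      stop(sprintf("values for measure %s outside declared range [%g, %g]",
                   m, rng[1], rng[2]))
    }
  }

  if (!is.null(assessments)) {
    assessments <- tibble::as_tibble(assessments)
    if (!"baseline" %in% names(assessments) ||
        anyNA(assessments$baseline)) {
      stop("assessments must carry a non-missing baseline for every participant")
    }
  }

  cond <- unique(trajectories$condition)
  structure(
    list(trajectories = trajectories, assessments = assessments,
         n_weeks = n_weeks, conditions = cond, score_ranges = score_ranges),
    class = "gain_cohort")
}

#' @export
print.gain_cohort <- function(x, ...) {
  ids <- unique(x$trajectories$participant_id)
  cat(sprintf("<gain_cohort> %d participants, %d weeks, measures: %s\n",
              length(ids), x$n_weeks,
              paste(unique(x$trajectories$measure), collapse = ", ")))
  invisible(x)
}

#' Extract one participant's weekly series as a length-T vector
#'
#' @param cohort A `gain_cohort`.
#' @param participant_id Participant identifier.
#' @param measure Measure name.
#' @return Numeric vector of length `n_weeks` with `NA` at unobserved weeks.
#' @export
series_values <- function(cohort, participant_id, measure) {
  tr <- cohort$trajectories
  rows <- tr[tr$participant_id == participant_id & tr$measure == measure, ]
  out <- rep(NA_real_, cohort$n_weeks)
  out[rows$week] <- rows$value
  out
}

# One pass over the trajectory table: participants-by-week value matrix for
# one measure (rows named by participant id). Avoids per-participant scans.
series_matrix <- function(cohort, measure) {
  tr <- cohort$trajectories
  tr <- tr[tr$measure == measure, , drop = FALSE]
  ids <- unique(tr$participant_id)
  m <- matrix(NA_real_, length(ids), cohort$n_weeks,
              dimnames = list(ids, NULL))
  m[cbind(match(tr$participant_id, ids), tr$week)] <- tr$value
  m
}

#' Prorate a questionnaire total from item responses
#'
#' When some items are missing, the total is estimated as the mean of the
#' completed items scaled up to the full item count. If no items were
#' completed, or the completed fraction falls below
#' `min_complete_fraction`, the total is not estimated and `NA` is returned.
#'
#' @param items Numeric vector of item scores, `NA` for missing items.
#' @param n_items Total number of items on the scale; defaults to
#'   `length(items)`.
#' @param min_complete_fraction Minimum fraction of items that must be
#'   completed for prorating (default 0.5, the conventional half-scale rule).
#' @param item_range Optional `c(lo, hi)` per-item score range; present
#'   scores outside it are a validation error.
#' @return The (possibly prorated) total score, or `NA_real_`.
#' @examples
#' prorate_total(rep(2, 24))            # plain sum: 48
#' prorate_total(c(2, 2, NA, 2))        # prorated: 8
#' prorate_total(c(1, 3, NA, NA, NA))   # below half-scale: NA
#' @export
prorate_total <- function(items, n_items = length(items),
                          min_complete_fraction = 0.5, item_range = NULL) {
  if (n_items < 1) stop("n_items must be >= 1")
  if (length(items) != n_items) stop("items must have length n_items")
  done <- items[!is.na(items)]
  if (!is.null(item_range)) {
    if (any(done < item_range[1] | done > item_range[2])) {
      stop("item scores outside declared item range")
    }
  } else if (any(done < 0)) {
    stop("negative item scores are invalid")
  }
  frac <- length(done) / n_items
  if (length(done) == 0 || frac < min_complete_fraction) return(NA_real_)
  if (length(done) == n_items) return(sum(done))
  mean(done) * n_items
}

#' Read a cohort from CSV
#'
#' Supports a long layout (`participant_id, condition, week, measure, value`)
#' and a wide layout (`participant_id, condition, measure, w1..wT`). Empty
#' cells and the configured missing token map to `NA`.
#'
#' @param path Path to the trajectory CSV.
#' @param layout `"long"` or `"wide"`.
#' @param assessments_path Optional path to an assessments CSV
#'   (`participant_id, condition, measure, baseline, posttreatment,
#'   followup_3m, followup_12m`).
#' @param missing_token String encoding a missing cell (default `"NA"`);
#'   empty cells are always treated as missing.
#' @param conditions Optional character vector of the allowed condition
#'   labels; labels outside it are an error.
#' @param n_weeks,score_ranges Passed to [gain_cohort()].
#' @return A `gain_cohort`.
#' @export
read_cohort <- function(path, layout = c("long", "wide"),
                        assessments_path = NULL, missing_token = "NA",
                        conditions = NULL, n_weeks = NULL,
                        score_ranges = list()) {
  layout <- match.arg(layout)
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("", missing_token), check.names = FALSE)
  if (layout == "long") {
    tr <- tibble::as_tibble(raw)
    if (nrow(tr) > 0 && !is.numeric(tr$value)) stop("non-numeric score cells")
  } else {
    wk_cols <- grep("^w[0-9]+$", names(raw), value = TRUE)
    if (nrow(raw) == 0) {
      tr <- tibble::tibble(participant_id = character(), condition = character(),
                           measure = character(), week = integer(),
                           value = numeric())
    } else {
      tr <- tidyr::pivot_longer(tibble::as_tibble(raw), dplyr::all_of(wk_cols),
                                names_to = "week", values_to = "value")
      tr$week <- as.integer(sub("^w", "", tr$week))
      if (!is.numeric(tr$value)) stop("non-numeric score cells")
    }
  }
  if (!is.null(conditions) && nrow(tr) > 0) {
    unknown <- setdiff(unique(tr$condition), conditions)
    if (length(unknown) > 0) {
      stop("unknown condition labels: ", paste(unknown, collapse = ", "))
    }
  }
  assess <- NULL
  if (!is.null(assessments_path)) {
    assess <- tibble::as_tibble(
      read.csv(assessments_path, stringsAsFactors = FALSE,
               na.strings = c("", missing_token)))
  }
  gain_cohort(tr, assessments = assess, n_weeks = n_weeks,
              score_ranges = score_ranges)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: stable column order, missing weekly totals
#' written as the missing token. Round-trips bit-exactly for non-missing
#' cells.
#'
#' @param cohort A `gain_cohort`.
#' @param path Output path for the trajectory CSV.
#' @param layout `"long"` or `"wide"`.
#' @param assessments_path Optional output path for the assessments table.
#' @param missing_token Token written for missing cells (default `"NA"`).
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, layout = c("long", "wide"),
                         assessments_path = NULL, missing_token = "NA") {
  layout <- match.arg(layout)
  tr <- cohort$trajectories[, c("participant_id", "condition", "measure",
                                "week", "value")]
  if (layout == "wide") {
    if (nrow(tr) == 0) {
      tr <- tibble::tibble(participant_id = character(), condition = character(),
                           measure = character())
    } else {
      tr <- tidyr::pivot_wider(tr, names_from = "week", values_from = "value",
                               names_prefix = "w",
                               names_sort = TRUE)
    }
  } else {
    tr <- tr[order(tr$participant_id, tr$measure, tr$week), ]
  }
  write.csv(tr, path, row.names = FALSE, na = missing_token)
  if (!is.null(assessments_path) && !is.null(cohort$assessments)) {
    write.csv(cohort$assessments, assessments_path, row.names = FALSE,
              na = missing_token)
  }
  invisible(path)
}
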