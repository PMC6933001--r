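#' Score a single praxis-task item
#'
#' Item-level scoring rules of the three praxis screening tasks:
#' \describe{
#'   \item{gesture_production}{6 items; 2 = correct and accurate, 1 =
#'     recognizable but inaccurate, 0 = no response within 15 s,
#'     unrecognizable, or perseveration. Task maximum 12.}
#'   \item{gesture_recognition}{6 items; 1 per correct multiple-choice
#'     response, 0 otherwise. Task maximum 6.}
#'   \item{gesture_imitation}{4 items; 3 = correct and precise after the 1st
#'     presentation, 2 = correct after the 2nd presentation, 1 = one error
#'     after the 2nd presentation, 0 = more than one error, no response or
#'     perseveration. Task maximum 12.}
#' }
#'
#' @param task one of `"gesture_production"`, `"gesture_recognition"`,
#'   `"gesture_imitation"`.
#' @param outcome the item's coded outcome (see Details).
#' @return integer item score.
#' @export
score_item <- function(task = c("gesture_production", "gesture_recognition",
                                "gesture_imitation"),
                       outcome) {
  task <- match.arg(task)
  rules <- list(
    gesture_production = c(correct = 2L, recognizable_inaccurate = 1L, none = 0L),
    gesture_recognition = c(correct = 1L, incorrect = 0L),
    gesture_imitation = c(correct_1st = 3L, correct_2nd = 2L,
                          one_error_2nd = 1L, fail = 0L))
  r <- rules[[task]]
  if (!outcome %in% names(r))
    stop("unknown outcome '", outcome, "' for ", task,
         "; expected one of: ", paste(names(r), collapse = ", "))
  unname(r[[outcome]])
}

#' Age-banded praxis cut-off tables
#'
#' Normative cut-offs per task and age band (years `<= 64`, `65-74`,
#' `>= 75`). Two published forms are shipped: `"integer"` (the age-adjusted
#' 5th-percentile table; a patient is impaired when the score is at or below
#' the cut-off) and `"fractional"` (two SDs below the age-matched control
#' mean: 11.5 / 5.8 / 11.5, identical across bands; impaired when strictly
#' below). On the integer score grid the two conventions flag the same
#' patients only for the fractional thresholds' own table; the integer table
#' is the default used for classification.
#'
#' Both tables are also shipped as plain CSV under
#' `system.file("extdata", package = "praxismap")` for use outside R.
#'
#' @param version `"integer"` or `"fractional"`.
#' @return data.frame with columns `task`, `band_le64`, `band_65_74`,
#'   `band_ge75` and attribute `rule` (`"le"` or `"lt"`).
#' @export
bcos_cutoffs <- function(version = c("integer", "fractional")) {
  version <- match.arg(version)
  tab <- if (version == "integer") {
    structure(data.frame(
      task = c("gesture_production", "gesture_recognition", "gesture_imitation"),
      band_le64 = c(10, 5, 9),
      band_65_74 = c(9, 5, 9),
      band_ge75 = c(9, 4, 9),
      stringsAsFactors = FALSE), rule = "le")
  } else {
    structure(data.frame(
      task = c("gesture_production", "gesture_recognition", "gesture_imitation"),
      band_le64 = c(11.5, 5.8, 11.5),
      band_65_74 = c(11.5, 5.8, 11.5),
      band_ge75 = c(11.5, 5.8, 11.5),
      stringsAsFactors = FALSE), rule = "lt")
  }
  maxima <- task_maxima()[tab$task]
  stopifnot(all(tab$band_le64 <= maxima), all(tab$band_65_74 <= maxima),
            all(tab$band_ge75 <= maxima))
  tab
}

age_band_column <- function(age) {
  if (age < 0) stop("age must be non-negative")
  if (age <= 64) "band_le64" else if (age <= 74) "band_65_74" else "band_ge75"
}

#' Classify praxis impairment against age-banded cut-offs
#'
#' Flags each praxis task as impaired when the score falls below the
#' patient's age-band cut-off (at or below for the integer table, strictly
#' below for the fractional one), and flags apraxia when at least one task
#' is impaired.
#'
#' @param record one-row data.frame (or list) with `age_years`,
#'   `gesture_production`, `gesture_recognition`, `gesture_imitation`.
#' @param cutoffs a [bcos_cutoffs()] table.
#' @return list with logical `gesture_production`, `gesture_recognition`,
#'   `gesture_imitation` and `apraxic`.
#' @export
classify_impairment <- function(record, cutoffs = bcos_cutoffs("integer")) {
  band <- age_band_column(record$age_years)
  rule <- attr(cutoffs, "rule")
  flag1 <- function(task) {
    cut <- cutoffs[cutoffs$task == task, band]
    score <- record[[task]]
    if (is.null(score) || is.na(score)) stop("missing score for ", task)
    if (rule == "le") score <= cut else score < cut
  }
  flags <- list(gesture_production = flag1("gesture_production"),
                gesture_recognition = flag1("gesture_recognition"),
                gesture_imitation = flag1("gesture_imitation"))
  flags$apraxic <- any(unlist(flags))
  flags
}

#' Composite apraxia score
#'
#' Sum of the three praxis scores, each rescaled to `[0, 1]` by its task
#' maximum; range `[0, 3]`, strictly increasing in each task score.
#'
#' @param record one-row data.frame (or list) with the three praxis scores.
#' @return numeric composite in `[0, 3]`.
#' @export
composite_apraxia_score <- function(record) {
  m <- task_maxima()
  tasks <- c("gesture_production", "gesture_recognition", "gesture_imitation")
  vals <- vapply(tasks, function(t) {
    s <- record[[t]]
    if (is.null(s) || is.na(s)) stop("missing score for ", t)
    s / m[[t]]
  }, numeric(1))
  sum(vals)
}

#' Pearson correlation with a two-sided p value
#'
#' @param x,y numeric vectors of equal length `>= 3` with non-zero variance.
#' @return list with `r`, `p` (two-sided, t approximation with `n - 2` df)
#'   and `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cohort summary of praxis performance
#'
#' Per-task mean, SD, min and max plus counts of patients impaired on each
#' task and overall (apraxic on at least one task). With a single patient the
#' SD is reported as `NA` (undefined), with a message.
#'
#' @param records data.frame of patient records (see [classify_impairment()]
#'   for required columns).
#' @param cutoffs a [bcos_cutoffs()] table.
#' @return list with `scores` (data.frame: task, mean, sd, min, max,
#'   n_impaired) and `n_apraxic`.
#' @export
cohort_summary <- function(records, cutoffs = bcos_cutoffs("integer")) {
  if (nrow(records) == 0) stop("empty cohort")
  tasks <- c("gesture_production", "gesture_recognition", "gesture_imitation")
  single <- nrow(records) == 1
  if (single) message("single patient: SD is undefined and reported as NA")
  flags <- lapply(seq_len(nrow(records)),
                  function(i) classify_impairment(records[i, ], cutoffs))
  tab <- do.call(rbind, lapply(tasks, function(t) {
    s <- records[[t]]
    data.frame(task = t,
               mean = mean(s),
               sd = if (single) NA_real_ else stats::sd(s),
               min = min(s), max = max(s),
               n_impaired = sum(vapply(flags, `[[`, logical(1), t)),
               stringsAsFactors = FALSE)
  }))
  list(scores = tab,
       n_apraxic = sum(vapply(flags, `[[`, logical(1), "apraxic")))
}
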