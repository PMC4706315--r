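#' Discretize effector functions by cohort-wide median split
#'
#' For each of the seven functions, the threshold is the cohort-wide median
#' of non-missing values (all groups pooled); a subject is "high" when its
#' value strictly exceeds the threshold and "low" at or below it (ties low).
#' Missing values give missing flags.
#'
#' @param cohort A cohort tibble.
#' @return A long tibble with `subject_id`, `group`, `fn`, `value`,
#'   `threshold` and `high` (logical, `NA` when the value is missing).
#' @export
discretize_functions <- function(cohort) {
  purrr::map_dfr(function_names(), function(fn) {
    v <- cohort[[fn]]
    if (all(is.na(v))) stop("function ", fn, " is entirely missing", call. = FALSE)
    thr <- median(v, na.rm = TRUE)
    tibble::tibble(
      subject_id = cohort$subject_id, group = cohort$group,
      fn = fn, value = v, threshold = thr, high = v > thr
    )
  })
}

#' Assign polyfunctional class from high/low flags
#'
#' Counts the functions in which each subject is high and classifies subjects
#' high in two or more functions as polyfunctional, those high in one or none
#' as non-polyfunctional. Subjects with any missing flag are excluded
#' (complete-case labeling).
#'
#' @param flags Long tibble from [discretize_functions()].
#' @param quiet Suppress the message counting excluded subjects.
#' @return A tibble with `subject_id`, `group`, `n_high` (0-7) and
#'   `polyfunctional` (logical).
#' @export
assign_polyfunction_class <- function(flags, quiet = FALSE) {
  per_subject <- dplyr::group_by(flags, .data$subject_id, .data$group) |>
    dplyr::summarise(
      n_missing = sum(is.na(.data$high)),
      n_high = sum(.data$high, na.rm = TRUE),
      .groups = "drop"
    )
  excluded <- per_subject$n_missing > 0
  if (!quiet && any(excluded)) {
    message(sum(excluded), " subject(s) with missing function values excluded",
            " from polyfunctionality labeling")
  }
  out <- per_subject[!excluded, c("subject_id", "group", "n_high")]
  out$polyfunctional <- out$n_high >= 2
  # preserve input subject order
  out[order(match(out$subject_id, unique(flags$subject_id))), ]
}

#' Polyfunctionality labels for a cohort
#'
#' Convenience wrapper: [discretize_functions()] then
#' [assign_polyfunction_class()].
#'
#' @inheritParams discretize_functions
#' @inheritParams assign_polyfunction_class
#' @return See [assign_polyfunction_class()].
#' @export
polyfunction_labels <- function(cohort, quiet = FALSE) {
  assign_polyfunction_class(discretize_functions(cohort), quiet = quiet)
}

#' Classifier feature matrix from subclass titers
#'
#' Builds the subject x feature matrix the classifier trains on: the five
#' gp120-specific measurements (total IgG and IgG1-IgG4), by default on the
#' `log1p(MFI)` scale (monotone; tames the lognormal tails). Subjects missing
#' any feature are dropped (complete-case modeling).
#'
#' @param cohort A cohort tibble.
#' @param log_transform Use `log1p(MFI)` instead of raw MFI.
#' @param features Which titer columns to use.
#' @return A numeric matrix with `subject_id` row names and an attribute
#'   `dropped` counting excluded subjects.
#' @export
subclass_features <- function(cohort, log_transform = TRUE,
                              features = subclass_names()) {
  m <- as.matrix(cohort[, features, drop = FALSE])
  rownames(m) <- cohort$subject_id
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  if (log_transform) m <- log1p(m)
  attr(m, "dropped") <- sum(!keep)
  m
}
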