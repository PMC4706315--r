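# shared Spearman-grid kernel: correlate every row-variable against every
# column-variable of a data frame, pairwise-complete, flagging undefined cells
spearman_grid <- function(df, row_vars, col_vars, extra = list()) {
  purrr::map_dfr(row_vars, function(rv) {
    purrr::map_dfr(col_vars, function(cv) {
      res <- tryCatch(spearman_rho(df[[rv]], df[[cv]]), error = function(e) NULL)
      base <- if (is.null(res)) {
        tibble::tibble(rho = NA_real_, p_value = NA_real_,
                       n = sum(stats::complete.cases(df[[rv]], df[[cv]])),
                       ok = FALSE)
      } else {
        tibble::tibble(rho = res$rho, p_value = res$p_value, n = res$n, ok = TRUE)
      }
      row <- dplyr::bind_cols(tibble::tibble(var_a = rv, var_b = cv), base)
      if (length(extra) > 0) {
        row <- dplyr::bind_cols(tibble::tibble(!!!extra), row)
      }
      row
    })
  })
}

#' Threshold from negative-control replicates
#'
#' The mean-plus-3-SD rule on negative-control MFI replicates (sample SD),
#' the usual background-based positivity criterion for bead-array data.
#'
#' @param controls Numeric vector of control MFI replicates (length >= 2).
#' @return The positivity threshold (MFI).
#' @examples
#' positivity_threshold_from_controls(c(50, 60, 70)) # 60 + 3 * 10 = 90
#' @export
positivity_threshold_from_controls <- function(controls) {
  controls <- controls[!is.na(controls)]
  if (length(controls) < 2) stop("need at least 2 control replicates", call. = FALSE)
  mean(controls) + 3 * sd(controls)
}

#' Call per-subject subclass positivity
#'
#' A subject is positive for a subclass when its MFI strictly exceeds the
#' subclass threshold; a value exactly at the threshold is negative. Missing
#' MFIs give missing calls. Thresholds may be fixed per subclass or derived
#' from negative-control replicates via
#' [positivity_threshold_from_controls()].
#'
#' @param cohort A cohort tibble.
#' @param thresholds Named numeric vector of MFI thresholds (>= 0). Names are
#'   subclasses (`IgG1`..`IgG4`, optionally `IgG_total`); a single unnamed
#'   value is recycled to the four subclasses.
#' @return A tibble with `subject_id`, `group`, `subclass`, `mfi`,
#'   `threshold_used` and `positive` (logical, `NA` when MFI is missing).
#' @export
call_positivity <- function(cohort, thresholds = 100) {
  if (is.null(names(thresholds))) {
    if (length(thresholds) != 1) {
      stop("unnamed thresholds must be a single value", call. = FALSE)
    }
    thresholds <- setNames(rep(thresholds, 4), paste0("IgG", 1:4))
  }
  if (any(thresholds < 0)) stop("thresholds must be >= 0", call. = FALSE)
  bad <- setdiff(names(thresholds), subclass_names())
  if (length(bad) > 0) stop("unknown subclass: ", paste(bad, collapse = ", "),
                            call. = FALSE)
  purrr::map_dfr(names(thresholds), function(sc) {
    tibble::tibble(
      subject_id = cohort$subject_id,
      group = cohort$group,
      subclass = sc,
      mfi = cohort[[sc]],
      threshold_used = thresholds[[sc]],
      positive = cohort[[sc]] > thresholds[[sc]]
    )
  })
}

#' Positivity prevalence by group and subclass
#'
#' @param calls Output of [call_positivity()].
#' @return A tibble with `group`, `subclass`, `n_positive`, `n` (non-missing
#'   calls) and `prevalence = n_positive / n`.
#' @export
prevalence_by_group <- function(calls) {
  dplyr::group_by(calls, .data$group, .data$subclass) |>
    dplyr::summarise(
      n_positive = sum(.data$positive, na.rm = TRUE),
      n = sum(!is.na(.data$positive)),
      prevalence = .data$n_positive / .data$n,
      .groups = "drop"
    )
}

#' Subclass-subclass Spearman correlation matrix
#'
#' Spearman correlations between the five titer measurements across all
#' subjects (pooled), revealing co-induction structure — IgG1 with IgG3 and
#' IgG2 with IgG4 travel together, while opposing-activity subclasses do not.
#' Zero-variance columns (e.g. an all-zero IgG4) yield flagged undefined
#' entries rather than fabricated coefficients.
#'
#' @param cohort A cohort tibble.
#' @return A long-form tibble with `var_a`, `var_b`, `rho`, `p_value`, `n`,
#'   `ok`, covering all ordered pairs of the five measurements (diagonal
#'   rho = 1).
#' @export
subclass_correlation_matrix <- function(cohort) {
  scs <- subclass_names()
  out <- spearman_grid(cohort, scs, scs)
  out$rho[out$var_a == out$var_b & out$ok] <- 1
  out
}

#' Compare subclass levels across groups
#'
#' Kruskal-Wallis test plus Dunn's post-hoc comparisons for each titer
#' measurement (total IgG and the four subclasses) across subject groups.
#' Zero MFIs (non-responders) are retained and tie at the bottom of the
#' ranks, so level comparisons reflect the full group, not just responders.
#'
#' @param cohort A cohort tibble.
#' @return A list with `tests` (tibble: `subclass`, `statistic`, `df`,
#'   `p_value`) and `posthoc` (tibble: `subclass`, `group_a`, `group_b`,
#'   `statistic`, `p_value`, `adjusted_p`).
#' @export
compare_subclass_levels <- function(cohort) {
  grs <- levels(droplevels(factor(cohort$group)))
  res <- purrr::map(subclass_names(), function(sc) {
    vals <- purrr::map(setNames(grs, grs), function(g) {
      v <- cohort[[sc]][cohort$group == g]
      v[!is.na(v)]
    })
    if (any(lengths(vals) < 2)) {
      stop("group with fewer than 2 non-missing values for ", sc, call. = FALSE)
    }
    kw <- kruskal_wallis(vals)
    dn <- dunn_posthoc(vals, design = "independent")
    list(test = dplyr::bind_cols(tibble::tibble(subclass = sc), kw),
         posthoc = dplyr::bind_cols(tibble::tibble(subclass = sc), dn))
  })
  list(
    tests = purrr::map_dfr(res, "test"),
    posthoc = purrr::map_dfr(res, "posthoc")
  )
}
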