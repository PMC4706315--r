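#' Relative subclass levels
#'
#' Adds the four relative-level columns `IgG1_rel`..`IgG4_rel`, each defined
#' as subclass MFI divided by total IgG MFI. Ratios are undefined (`NA`) when
#' total IgG is 0 or missing; subjects whose subclass MFI exceeds total IgG
#' (an assay artifact MFIs permit, since they are not strictly compositional)
#' are retained with ratio > 1.
#'
#' @param cohort A cohort tibble.
#' @param quiet Suppress the message counting excluded/over-unity subjects.
#' @return The cohort with four `_rel` columns appended.
#' @export
relative_levels <- function(cohort, quiet = FALSE) {
  tot <- cohort$IgG_total
  bad <- !is.na(tot) & tot == 0
  out <- cohort
  for (sc in paste0("IgG", 1:4)) {
    rel <- cohort[[sc]] / tot
    rel[bad] <- NA_real_
    out[[paste0(sc, "_rel")]] <- rel
  }
  if (!quiet) {
    n_over <- sum(as.matrix(out[, paste0("IgG", 1:4, "_rel")]) > 1, na.rm = TRUE)
    if (sum(bad) > 0 || n_over > 0) {
      message(sum(bad), " subject(s) with zero total IgG excluded from ratios; ",
              n_over, " ratio(s) > 1 retained")
    }
  }
  out
}

#' Titer-function correlation matrix per group
#'
#' Within each subject group, the Spearman correlation (unadjusted two-tailed
#' p) between each of the five titer measurements and each of the seven
#' effector functions — a 5 x 7 grid per group linking antibody level to
#' activity. Zero-variance titers in a group yield flagged undefined cells.
#'
#' @param cohort A cohort tibble.
#' @param groups Groups to analyse; defaults to all present.
#' @return A tibble with `group`, `var_a` (titer), `var_b` (function), `rho`,
#'   `p_value`, `n`, `ok`; 35 rows per group.
#' @export
titer_function_matrix <- function(cohort, groups = NULL) {
  if (is.null(groups)) groups <- levels(droplevels(factor(cohort$group)))
  purrr::map_dfr(groups, function(g) {
    sub <- cohort[cohort$group == g, , drop = FALSE]
    spearman_grid(sub, subclass_names(), function_names(),
                  extra = list(group = g))
  })
}

#' Relative-level vs function correlation matrix across all subjects
#'
#' Spearman correlations (unadjusted p) between the four relative subclass
#' levels (subclass MFI / total IgG MFI) and the seven effector functions,
#' pooled over all subjects — the view in which skewing towards IgG2/IgG4 is
#' negatively associated with functionality independent of overall titer.
#'
#' @param cohort A cohort tibble.
#' @param by_group Compute per group instead of pooled.
#' @return A tibble with (`group` when `by_group`), `var_a` (relative level),
#'   `var_b` (function), `rho`, `p_value`, `n`, `ok`; 28 rows per stratum.
#' @export
relative_level_matrix <- function(cohort, by_group = FALSE) {
  df <- relative_levels(cohort, quiet = TRUE)
  rels <- paste0("IgG", 1:4, "_rel")
  if (by_group) {
    purrr::map_dfr(levels(droplevels(factor(df$group))), function(g) {
      spearman_grid(df[df$group == g, , drop = FALSE], rels, function_names(),
                    extra = list(group = g))
    })
  } else {
    spearman_grid(df, rels, function_names())
  }
}
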