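#' Pairwise function-function Spearman correlations per group
#'
#' The coordination statistic's raw material: within each subject group, the
#' Spearman correlation (with unadjusted two-tailed p) of every unordered pair
#' of the seven effector functions — 21 pairs per group — computed on
#' pairwise-complete observations. Pairs with fewer than 3 complete
#' observations or zero variance are flagged (`ok = FALSE`, `rho = NA`) rather
#' than silently dropped.
#'
#' @param cohort A cohort tibble.
#' @param groups Groups to analyse; defaults to all groups present.
#' @return A tibble with columns `group`, `function_a`, `function_b`, `rho`,
#'   `p_value`, `n` and `ok`, 21 rows per group, pairs ordered by
#'   [function_names()].
#' @export
pairwise_function_correlations <- function(cohort, groups = NULL) {
  if (is.null(groups)) groups <- levels(droplevels(factor(cohort$group)))
  fns <- function_names()
  pairs <- utils::combn(fns, 2)
  purrr::map_dfr(groups, function(g) {
    sub <- cohort[cohort$group == g, , drop = FALSE]
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      fa <- pairs[1, j]; fb <- pairs[2, j]
      res <- tryCatch(spearman_rho(sub[[fa]], sub[[fb]]), error = function(e) NULL)
      if (is.null(res)) {
        n_ok <- sum(stats::complete.cases(sub[[fa]], sub[[fb]]))
        tibble::tibble(group = g, function_a = fa, function_b = fb,
                       rho = NA_real_, p_value = NA_real_, n = n_ok, ok = FALSE)
      } else {
        tibble::tibble(group = g, function_a = fa, function_b = fb,
                       rho = res$rho, p_value = res$p_value, n = res$n, ok = TRUE)
      }
    })
  })
}

#' Compare functional coordination across groups
#'
#' Tests whether the distribution of the 21 pairwise function-function
#' Spearman coefficients differs between subject groups: a Friedman rank test
#' on the pairs x groups matrix of correlation coefficients (blocks = function
#' pairs, treatments = groups), followed by Dunn's post-hoc pairwise
#' comparisons on the block ranks. Blocks with a missing coefficient in any
#' group are excluded listwise (the Friedman test requires complete blocks).
#'
#' @param corrsets Output of [pairwise_function_correlations()] covering at
#'   least two groups with identical pair sets.
#' @return An object of class `polyfc_coordination` with elements `test`
#'   (Friedman, one-row tibble), `posthoc` (Dunn comparisons tibble),
#'   `mean_rank` (per-group mean block rank, higher = more coordinated) and
#'   `blocks` (the matrix used).
#' @export
compare_group_coordination <- function(corrsets) {
  wide <- tidyr::pivot_wider(
    corrsets[, c("group", "function_a", "function_b", "rho")],
    names_from = "group", values_from = "rho"
  )
  grp_cols <- setdiff(names(wide), c("function_a", "function_b"))
  if (length(grp_cols) < 2) stop("need at least 2 groups to compare", call. = FALSE)
  # canonical group order so results do not depend on row order of the input
  grp_cols <- grp_cols[order(match(grp_cols, group_levels()), grp_cols)]
  mat <- as.matrix(wide[, grp_cols])
  rownames(mat) <- paste(wide$function_a, wide$function_b, sep = ":")
  n_pairs <- length(unique(rownames(mat)))
  if (n_pairs != nrow(mat)) stop("mismatched pair sets across groups", call. = FALSE)
  complete <- stats::complete.cases(mat)
  if (sum(complete) < 2) stop("fewer than 2 complete blocks", call. = FALSE)
  mat <- mat[complete, , drop = FALSE]
  test <- friedman_test(mat)
  posthoc <- dunn_posthoc(mat, design = "blocked")
  ranks <- t(apply(mat, 1, rank))
  structure(
    list(test = test, posthoc = posthoc,
         mean_rank = sort(colMeans(ranks), decreasing = TRUE),
         blocks = mat),
    class = "polyfc_coordination"
  )
}

#' @export
print.polyfc_coordination <- function(x, ...) {
  cat("Coordination comparison (Friedman / Dunn on", nrow(x$blocks),
      "function-pair blocks)\n")
  cat(sprintf("  chi-squared = %.3f, df = %d, p = %.3g\n",
              x$test$statistic, x$test$df, x$test$p_value))
  cat("  mean block rank (higher = more coordinated):\n")
  print(round(x$mean_rank, 2))
  cat("  pairwise (Dunn, Bonferroni-adjusted):\n")
  print(as.data.frame(x$posthoc), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Bin pairwise correlations by strength
#'
#' Assigns each pair's correlation coefficient to exactly one half-open bin
#' `[lo, hi)` (the last bin is closed) and reports counts and proportions per
#' group — the "prevalence of functional correlations by strength" view.
#'
#' @param corrset Output of [pairwise_function_correlations()].
#' @param bin_edges Strictly increasing edges covering all observed
#'   coefficients. The defaults split the positive range into 0.2-wide bands.
#' @return A tibble with `group`, `bin` (label), `bin_lo`, `bin_hi`, `count`
#'   and `proportion` (summing to 1 within group over non-missing pairs).
#' @export
strength_histogram <- function(corrset,
                               bin_edges = c(-1, 0, 0.2, 0.4, 0.6, 0.8, 1)) {
  if (any(diff(bin_edges) <= 0)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  rho <- corrset$rho[corrset$ok]
  if (any(rho < bin_edges[1] | rho > bin_edges[length(bin_edges)])) {
    stop("bin edges do not cover all observed coefficients", call. = FALSE)
  }
  nb <- length(bin_edges) - 1
  labels <- sprintf("[%g,%g%s", bin_edges[-length(bin_edges)], bin_edges[-1],
                    c(rep(")", nb - 1), "]"))
  dplyr::group_by(corrset[corrset$ok, ], .data$group) |>
    dplyr::reframe({
      idx <- findInterval(.data$rho, bin_edges, rightmost.closed = TRUE)
      cnt <- tabulate(idx, nbins = nb)
      tibble::tibble(bin = labels, bin_lo = bin_edges[-length(bin_edges)],
                     bin_hi = bin_edges[-1], count = cnt,
                     proportion = cnt / sum(cnt))
    })
}

#' Per-group correlation matrix report
#'
#' Expands the 21 unordered pairs to a full symmetric 7x7 matrix per group
#' (diagonal 1) in long form, with unadjusted p-values — the serializable
#' analogue of a correlation heat map.
#'
#' @param corrsets Output of [pairwise_function_correlations()].
#' @return A long-form tibble with `group`, `function_a`, `function_b`, `rho`
#'   and `p_value`, 49 rows per group.
#' @export
correlation_matrix_report <- function(corrsets) {
  fns <- function_names()
  purrr::map_dfr(unique(corrsets$group), function(g) {
    sub <- corrsets[corrsets$group == g, ]
    full <- tidyr::expand_grid(function_a = fns, function_b = fns)
    full$group <- g
    key <- paste(sub$function_a, sub$function_b)
    idx <- match(paste(full$function_a, full$function_b), key)
    idx2 <- match(paste(full$function_b, full$function_a), key)
    idx[is.na(idx)] <- idx2[is.na(idx)]
    full$rho <- ifelse(full$function_a == full$function_b, 1, sub$rho[idx])
    full$p_value <- ifelse(full$function_a == full$function_b, NA_real_,
                           sub$p_value[idx])
    full[, c("group", "function_a", "function_b", "rho", "p_value")]
  })
}

#' Rebuild a numeric correlation matrix for one group
#'
#' @param report Output of [correlation_matrix_report()] (or a compatible
#'   long-form table).
#' @param group Group label to extract.
#' @return A named symmetric 7x7 matrix of correlation coefficients.
#' @export
corr_matrix <- function(report, group) {
  sub <- report[report$group == group, ]
  if (nrow(sub) == 0) stop("group not present in report", call. = FALSE)
  fns <- function_names()
  m <- matrix(NA_real_, 7, 7, dimnames = list(fns, fns))
  m[cbind(sub$function_a, sub$function_b)] <- sub$rho
  m
}
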