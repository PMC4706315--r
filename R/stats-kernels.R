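#' Spearman rank correlation with t-approximation p-value
#'
#' Computes Spearman's rho from average ranks (midranks on ties) on
#' pairwise-complete observations, with a two-tailed p-value from the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom. At `rho = +/-1` the p-value is 0.
#'
#' @param x,y Numeric vectors of equal length; pairs with any `NA` are dropped.
#' @return A one-row tibble with `rho`, `p_value`, `n` (pairs used) and
#'   `method`.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 pairwise-complete observations", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance: Spearman correlation undefined", call. = FALSE)
  }
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  tibble::tibble(rho = rho, p_value = p, n = n, method = "spearman_t_approx")
}

#' Friedman rank test for complete blocks
#'
#' Tie-corrected Friedman chi-squared statistic for an `n_blocks x k` matrix
#' of values (blocks in rows, treatments in columns), ranked within blocks
#' with midranks, compared to a chi-squared distribution on `k - 1` degrees of
#' freedom. Used here to compare coordination (pairwise-correlation blocks)
#' across subject groups.
#'
#' @param block_matrix Numeric matrix, blocks x treatments, no missing cells.
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `n_blocks`,
#'   `method`.
#' @export
friedman_test <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (anyNA(m)) stop("blocks must be complete (no missing cells)", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 blocks and 2 treatments", call. = FALSE)
  r <- t(apply(m, 1, rank))
  ties <- apply(r, 1, function(u) {
    tab <- table(u)
    sum(tab^3 - tab)
  })
  denom <- n * k * (k + 1) - sum(ties) / (k - 1)
  stat <- if (denom <= 0) 0 else {
    12 * sum((colSums(r) - n * (k + 1) / 2)^2) / denom
  }
  tibble::tibble(
    statistic = stat, df = k - 1,
    p_value = pchisq(stat, df = k - 1, lower.tail = FALSE),
    n_blocks = n, method = "friedman"
  )
}

#' Kruskal-Wallis rank test across independent groups
#'
#' Tie-corrected H statistic with a chi-squared reference on `k - 1` degrees
#' of freedom (delegates to [stats::kruskal.test()]).
#'
#' @param groups A list of numeric vectors, one per group; `NA`s dropped.
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `method`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  all_v <- unlist(groups)
  if (length(all_v) < 3) stop("need total n >= 3", call. = FALSE)
  if (length(unique(all_v)) == 1) {
    stop("all values identical: Kruskal-Wallis statistic undefined", call. = FALSE)
  }
  kt <- kruskal.test(groups)
  tibble::tibble(
    statistic = unname(kt$statistic), df = unname(kt$parameter),
    p_value = kt$p.value, method = "kruskal_wallis"
  )
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z-statistics on rank sums with a Bonferroni-style adjustment
#' (`adjusted_p = min(1, p * m)` over the `m` pairwise tests), as the
#' classical follow-up to a Kruskal-Wallis test (`design = "independent"`,
#' joint midranks with tie-corrected variance) or a Friedman test
#' (`design = "blocked"`, within-block ranks, variance `n k (k + 1) / 6`).
#'
#' @param groups_or_ranks For `"independent"`, a named list of numeric
#'   vectors; for `"blocked"`, a complete blocks-by-treatments matrix with
#'   column names.
#' @param design `"independent"` or `"blocked"`.
#' @return A tibble with one row per unordered pair: `group_a`, `group_b`,
#'   `statistic` (z), `p_value`, `adjusted_p`.
#' @export
dunn_posthoc <- function(groups_or_ranks, design = c("independent", "blocked")) {
  design <- match.arg(design)
  if (design == "independent") {
    groups <- lapply(groups_or_ranks, function(g) g[!is.na(g)])
    k <- length(groups)
    if (k < 2) stop("need at least 2 groups", call. = FALSE)
    sizes <- lengths(groups)
    if (any(sizes < 2)) stop("every group needs at least 2 observations", call. = FALSE)
    if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
    all_v <- unlist(groups)
    N <- length(all_v)
    rk <- rank(all_v)
    idx <- rep(seq_len(k), sizes)
    mean_rank <- tapply(rk, idx, mean)
    tab <- table(rk)
    tie_corr <- sum(tab^3 - tab) / (12 * (N - 1))
    base_var <- N * (N + 1) / 12 - tie_corr
    pairs <- utils::combn(k, 2)
    m <- ncol(pairs)
    purrr::map_dfr(seq_len(m), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      se <- sqrt(base_var * (1 / sizes[[i1]] + 1 / sizes[[i2]]))
      z <- if (se == 0) 0 else unname((mean_rank[[i1]] - mean_rank[[i2]]) / se)
      p <- 2 * pnorm(abs(z), lower.tail = FALSE)
      tibble::tibble(
        group_a = names(groups)[i1], group_b = names(groups)[i2],
        statistic = z, p_value = p, adjusted_p = min(1, p * m)
      )
    })
  } else {
    mat <- as.matrix(groups_or_ranks)
    if (anyNA(mat)) stop("blocked design requires complete blocks", call. = FALSE)
    n <- nrow(mat); k <- ncol(mat)
    if (k < 2) stop("need at least 2 treatments", call. = FALSE)
    if (is.null(colnames(mat))) colnames(mat) <- paste0("g", seq_len(k))
    r <- t(apply(mat, 1, rank))
    rank_sum <- colSums(r)
    se <- sqrt(n * k * (k + 1) / 6)
    pairs <- utils::combn(k, 2)
    m <- ncol(pairs)
    purrr::map_dfr(seq_len(m), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      z <- (rank_sum[[i1]] - rank_sum[[i2]]) / se
      p <- 2 * pnorm(abs(z), lower.tail = FALSE)
      tibble::tibble(
        group_a = colnames(mat)[i1], group_b = colnames(mat)[i2],
        statistic = z, p_value = p, adjusted_p = min(1, p * m)
      )
    })
  }
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Ordinary one-way ANOVA F test across groups followed by Tukey's honestly
#' significant difference pairwise comparisons (studentized-range adjusted
#' p-values), via [stats::aov()] and [stats::TukeyHSD()].
#'
#' @param groups A named list of numeric vectors, each with at least 2
#'   non-missing observations.
#' @return A list with `test` (one-row tibble: `statistic`, `df1`, `df2`,
#'   `p_value`, `method`) and `posthoc` (tibble: `group_a`, `group_b`,
#'   `diff`, `adjusted_p`).
#' @export
group_anova_tukey <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (all(vapply(groups, function(g) var(g) == 0, logical(1)))) {
    stop("zero within-group variance everywhere: ANOVA undefined", call. = FALSE)
  }
  df <- tibble::tibble(
    value = unlist(groups),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  hsd <- TukeyHSD(fit)$group
  pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  posthoc <- tibble::tibble(
    group_a = vapply(pairs, `[[`, "", 2),
    group_b = vapply(pairs, `[[`, "", 1),
    diff = -unname(hsd[, "diff"]),
    adjusted_p = unname(hsd[, "p adj"])
  )
  list(
    test = tibble::tibble(
      statistic = an[["F value"]][1], df1 = an[["Df"]][1], df2 = an[["Df"]][2],
      p_value = an[["Pr(>F)"]][1], method = "anova"
    ),
    posthoc = posthoc
  )
}

#' Balanced accuracy of a binary prediction
#'
#' `(sensitivity + specificity) / 2`, robust to class imbalance. The positive
#' class is `TRUE`/1.
#'
#' @param truth,predicted Logical or 0/1 vectors of equal length; `truth` must
#'   contain both classes.
#' @return A number in \[0, 1\].
#' @export
balanced_accuracy <- function(truth, predicted) {
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  if (anyNA(truth) || anyNA(predicted)) stop("NA in truth or predicted", call. = FALSE)
  if (length(unique(truth)) < 2) {
    stop("balanced accuracy undefined: truth contains a single class", call. = FALSE)
  }
  sens <- mean(predicted[truth])
  spec <- mean(!predicted[!truth])
  (sens + spec) / 2
}
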