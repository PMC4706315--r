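test_that("spearman_rho matches the rank formula and handles perfect monotone cases", {
  expect_equal(spearman_rho(c(1, 2, 3), c(10, 20, 30))$rho, 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(10, 20, 30))$p_value, 0)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  # hand computation: d = (-1, 1, -1, 1), rho = 1 - 6*4/(4*15) = 0.6
  res <- spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$rho, 0.6)
  # t-approximation: t = 0.6 * sqrt(2 / (1 - 0.36))
  tt <- 0.6 * sqrt((4 - 2) / (1 - 0.36))
  expect_equal(res$p_value, 2 * pt(tt, df = 2, lower.tail = FALSE))
})

test_that("spearman_rho is symmetric, monotone-invariant, and drops incomplete pairs", {
  set.seed(1)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(spearman_rho(x, y)$rho, spearman_rho(y, x)$rho)
  expect_equal(spearman_rho(exp(x), y)$rho, spearman_rho(x, y)$rho)
  expect_equal(spearman_rho(x, y^3)$rho, spearman_rho(x, y)$rho)
  x_na <- x; x_na[1:3] <- NA
  expect_equal(spearman_rho(x_na, y)$n, 27)
  expect_equal(spearman_rho(x_na, y)$rho, spearman_rho(x[-(1:3)], y[-(1:3)])$rho)
})

test_that("spearman_rho rejects degenerate input", {
  expect_error(spearman_rho(c(1, 2), c(1, 2)), "at least 3")
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("friedman_test matches hand computation and algebraic extremes", {
  # identical ordering in every block: statistic = n * (k - 1)
  m <- matrix(rep(c(1, 2, 3, 4), 21), 21, 4, byrow = TRUE)
  expect_equal(friedman_test(m)$statistic, 21 * 3)
  # all cells equal: complete ties, statistic 0
  expect_equal(friedman_test(matrix(5, 6, 3))$statistic, 0)
  # hand computation: rank sums (4, 6, 8), chi2 = (12/36)*116 - 36 = 8/3
  m3 <- rbind(c(1, 2, 3), c(2, 1, 3), c(1, 3, 2))
  expect_equal(friedman_test(m3)$statistic, 12 / 36 * (16 + 36 + 64) - 36)
  expect_equal(friedman_test(m3)$df, 2)
})

test_that("friedman_test agrees with the reference implementation and is shift-invariant", {
  set.seed(7)
  m <- matrix(rnorm(40), 10, 4)
  ref <- stats::friedman.test(m)
  res <- friedman_test(m)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  shifted <- m + rnorm(10)  # add a per-block constant
  expect_equal(friedman_test(shifted)$statistic, res$statistic)
  # statistic bounded by n(k-1)
  expect_lte(res$statistic, 10 * 3)
  expect_error(friedman_test(rbind(c(1, NA), c(2, 3))), "complete")
})

test_that("kruskal_wallis matches hand computation and enumeration extremes", {
  # interleaved ranks: rank sums 9 and 12, H = (12/42)*(27+48) - 21
  res <- kruskal_wallis(list(c(1, 3, 5), c(2, 4, 6)))
  expect_equal(res$statistic, 12 / 42 * (81 / 3 + 144 / 3) - 21)
  # maximal separation is the largest H over all rank arrangements of n=4, k=2
  res_max <- kruskal_wallis(list(c(1, 2), c(100, 200)))
  h_all <- apply(utils::combn(4, 2), 2, function(idx) {
    r1 <- sum(idx); r2 <- sum(setdiff(1:4, idx))
    12 / (4 * 5) * (r1^2 / 2 + r2^2 / 2) - 3 * 5
  })
  expect_equal(res_max$statistic, max(h_all))
  # identical groups: perfectly overlapping ranks, H = 0, p = 1
  res_id <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res_id$statistic, 0)
  expect_equal(res_id$p_value, 1)
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
})

test_that("dunn_posthoc independent design matches hand-computed rank sums", {
  g <- list(a = c(1, 4, 7), b = c(2, 5, 8, 10), c = c(3, 6, 9))
  res <- dunn_posthoc(g, design = "independent")
  # values are the ranks themselves (1..10, no ties)
  mr <- c(a = mean(c(1, 4, 7)), b = mean(c(2, 5, 8, 10)), c = mean(c(3, 6, 9)))
  vr <- 10 * 11 / 12
  z_ab <- (mr["a"] - mr["b"]) / sqrt(vr * (1 / 3 + 1 / 4))
  z_ac <- (mr["a"] - mr["c"]) / sqrt(vr * (1 / 3 + 1 / 3))
  expect_equal(res$statistic[res$group_a == "a" & res$group_b == "b"],
               unname(z_ab))
  expect_equal(res$statistic[res$group_a == "a" & res$group_b == "c"],
               unname(z_ac))
  expect_equal(res$adjusted_p, pmin(1, res$p_value * 3))
  expect_true(all(res$adjusted_p >= res$p_value))
})

test_that("dunn_posthoc degenerate and symmetric cases", {
  res <- dunn_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)), design = "independent")
  expect_equal(res$statistic, 0)
  expect_equal(res$adjusted_p, 1)
  # equally spaced groups: all pairwise |z| equal for adjacent pairs by rank symmetry
  res3 <- dunn_posthoc(list(a = c(1, 2, 3), b = c(101, 102, 103),
                            c = c(201, 202, 203)), design = "independent")
  adj <- res3$statistic[c(1, 3)]  # a-b and b-c
  expect_equal(abs(adj[1]), abs(adj[2]))
  expect_error(dunn_posthoc(list(a = 1, b = c(1, 2)), design = "independent"),
               "at least 2")
})

test_that("dunn_posthoc blocked design uses within-block rank sums", {
  m <- rbind(c(1, 2, 3), c(1.5, 2.5, 3.5), c(0, 5, 9), c(2, 4, 6))
  colnames(m) <- c("x", "y", "z")
  res <- dunn_posthoc(m, design = "blocked")
  # every block ranks x < y < z: rank sums 4, 8, 12; se = sqrt(4*3*4/6)
  se <- sqrt(4 * 3 * 4 / 6)
  expect_equal(res$statistic[res$group_a == "x" & res$group_b == "z"],
               (4 - 12) / se)
  expect_error(dunn_posthoc(rbind(c(1, NA), c(1, 2)), design = "blocked"),
               "complete")
})

test_that("kruskal and dunn chi-squared p-values track exhaustive permutation at tiny n", {
  # total n = 7: enumerate all assignments of ranks to groups of sizes 3, 4
  g1 <- c(1.2, 3.4, 5.1); g2 <- c(2.2, 4.9, 6.3, 7.8)
  obs <- kruskal_wallis(list(g1, g2))
  pooled <- c(g1, g2)
  combos <- utils::combn(7, 3)
  stats <- apply(combos, 2, function(idx) {
    kruskal_wallis(list(pooled[idx], pooled[-idx]))$statistic
  })
  p_exact <- mean(stats >= obs$statistic - 1e-12)
  # the chi-squared reference deviates from the exact permutation p by its
  # approximation error, which is ~0.1 at n = 7; the statistic itself must be
  # reproduced exactly by the enumeration at the identity assignment
  expect_lt(abs(obs$p_value - p_exact), 0.15)
  expect_equal(stats[1], obs$statistic)
  # both references order evidence identically: p decreases as H increases
  ord <- order(stats)
  p_chi <- pchisq(stats, df = 1, lower.tail = FALSE)
  expect_true(all(diff(p_chi[ord]) <= 1e-12))
})

test_that("group_anova_tukey reduces to t-test for two groups and matches SS decomposition", {
  set.seed(3)
  a <- rnorm(12); b <- rnorm(12, 1)
  res <- group_anova_tukey(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$test$statistic, unname(tt$statistic)^2)
  expect_equal(res$test$p_value, tt$p.value)
  # three-group fixture against direct sums of squares
  g <- list(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(5, 5, 6, 7))
  res3 <- group_anova_tukey(g)
  gm <- mean(unlist(g))
  ss_b <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, numeric(1)))
  ss_w <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  f_direct <- (ss_b / 2) / (ss_w / 9)
  expect_equal(res3$test$statistic, f_direct)
  expect_equal(nrow(res3$posthoc), 3)
  expect_error(group_anova_tukey(list(a = c(1, 1), b = c(2, 2))),
               "zero within-group variance")
})

test_that("balanced_accuracy follows its definition and relabeling invariance", {
  expect_equal(balanced_accuracy(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE)), 1)
  truth <- rep(c(TRUE, FALSE), c(6, 4))
  expect_equal(balanced_accuracy(truth, rep(TRUE, 10)), 0.5)
  # TP = 5, FN = 5, TN = 10, FP = 0
  truth2 <- rep(c(TRUE, FALSE), c(10, 10))
  pred2 <- c(rep(TRUE, 5), rep(FALSE, 5), rep(FALSE, 10))
  expect_equal(balanced_accuracy(truth2, pred2), 0.75)
  # class relabeling applied to both arguments
  expect_equal(balanced_accuracy(!truth2, !pred2),
               balanced_accuracy(truth2, pred2))
  expect_error(balanced_accuracy(rep(TRUE, 4), rep(TRUE, 4)), "single class")
})
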