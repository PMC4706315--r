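test_that("median split flags strictly-above-median values high, ties low", {
  ch <- tiny_cohort(2)
  ch$ADCC <- c(1, 2, 3, 4, 5, 1, 2, 3)  # median 2.5 -> high: 3, 4, 5, 3
  flags <- discretize_functions(ch)
  adcc <- flags[flags$fn == "ADCC", ]
  expect_equal(adcc$high, ch$ADCC > 2.5)
  # a constant function marks nobody high
  ch$ADCP <- rep(7, 8)
  flags2 <- discretize_functions(ch)
  expect_false(any(flags2$high[flags2$fn == "ADCP"]))
  # an exact-median value is low
  ch$ADCD <- c(1, 2, 3, 4, 5, 6, 7, 8)
  flags3 <- discretize_functions(ch)
  expect_false(flags3$high[flags3$fn == "ADCD"][4])  # 4 <= median 4.5 is low
  expect_true(flags3$high[flags3$fn == "ADCD"][5])
})

test_that("polyfunctional class requires high activity in two or more functions", {
  ch <- tiny_cohort(2)
  for (fn in function_names()) ch[[fn]] <- rep(5, 8)
  # constant columns -> nobody high -> nobody polyfunctional
  lab0 <- polyfunction_labels(ch, quiet = TRUE)
  expect_equal(lab0$n_high, rep(0L, 8))
  expect_false(any(lab0$polyfunctional))
  # craft counts 0, 1, 2, 3 high (medians 3.5; ties-low)
  ch2 <- tiny_cohort(1)
  for (fn in function_names()) ch2[[fn]] <- c(1, 1, 1, 1)
  ch2$ADCC <- c(1, 2, 5, 5)
  ch2$ADCP <- c(1, 5, 2, 5)
  ch2$ADCD <- c(1, 2, 5, 5)
  lab <- polyfunction_labels(ch2, quiet = TRUE)
  expect_equal(lab$n_high, c(0L, 1L, 2L, 3L))
  expect_equal(lab$polyfunctional, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("subjects with missing function values are excluded from labeling", {
  ch <- tiny_cohort(2)
  ch$NK_IFNg[3] <- NA
  expect_message(lab <- polyfunction_labels(ch), "1 subject")
  expect_equal(nrow(lab), 7)
  expect_false(ch$subject_id[3] %in% lab$subject_id)
})

test_that("ridge fit matches a brute-force minimizer of the penalized deviance", {
  fx <- classifier_fixture(n = 20, p = 3)
  for (lam in c(1, 0.1, 0.01)) {
    fit <- fit_ridge_classifier(fx$X, fx$y, lambda = lam)
    oracle <- ridge_objective_oracle(fx$X, fx$y, lam)
    expect_equal(unname(fit$coefficients), oracle$beta, tolerance = 1e-6)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-6)
  }
})

test_that("ridge fit agrees with an independent coordinate-descent implementation", {
  skip_if_not_installed("glmnet")
  fx <- classifier_fixture(n = 40, p = 4, seed = 11)
  Z <- scale(fx$X)
  lam <- 0.05
  gn <- glmnet::glmnet(Z, fx$y, family = "binomial", alpha = 0,
                       lambda = c(5, 1, 0.2, lam), standardize = FALSE,
                       thresh = 1e-14)
  fit <- fit_ridge_classifier(fx$X, fx$y, lambda = lam)
  expect_equal(unname(fit$coefficients),
               as.numeric(glmnet::coef.glmnet(gn, s = lam))[-1],
               tolerance = 1e-4)
})

test_that("penalty limits behave as the objective dictates", {
  fx <- classifier_fixture(n = 30, p = 2)
  # lambda -> infinity: coefficients -> 0, intercept -> log-odds of prevalence
  fit_big <- fit_ridge_classifier(fx$X, fx$y, lambda = 1e6)
  expect_lt(max(abs(fit_big$coefficients)), 1e-4)
  expect_equal(fit_big$intercept, qlogis(mean(fx$y)), tolerance = 1e-3)
  # separable single feature at small lambda: coefficient sign follows separation
  x1 <- matrix(c(-(5:1), 1:5), ncol = 1, dimnames = list(NULL, "f"))
  y1 <- rep(c(0, 1), each = 5)
  fit_sep <- fit_ridge_classifier(x1, y1, lambda = 0.01)
  expect_gt(fit_sep$coefficients[["f"]], 0)
  # coefficient norm is non-increasing in lambda
  norms <- vapply(c(0.01, 0.1, 1, 10), function(l) {
    sum(fit_ridge_classifier(fx$X, fx$y, lambda = l)$coefficients^2)
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("ridge fit validates its inputs", {
  fx <- classifier_fixture()
  expect_error(fit_ridge_classifier(fx$X, rep(1, nrow(fx$X)), lambda = 1),
               "single class")
  Xbad <- fx$X; Xbad[1, 1] <- Inf
  expect_error(fit_ridge_classifier(Xbad, fx$y, lambda = 1), "non-finite")
})

test_that("repeated CV recovers the no-signal and perfect-signal extremes", {
  set.seed(20)
  n <- 150
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y_noise <- rep(c(0, 1), n / 2)
  arm0 <- repeated_cv(X, y_noise, iterations = 30, seed = 1)
  expect_lt(abs(arm0$mean_accuracy - 0.5), 0.05)
  y_perfect <- as.numeric(X[, 1] > median(X[, 1]))
  arm1 <- repeated_cv(X, y_perfect, iterations = 10, seed = 2)
  expect_gt(arm1$mean_accuracy, 0.95)
})

test_that("cross-validation arms are deterministic given a seed", {
  fx <- classifier_fixture(n = 30, p = 3, seed = 5)
  a1 <- repeated_cv(fx$X, fx$y, iterations = 8, seed = 7)
  a2 <- repeated_cv(fx$X, fx$y, iterations = 8, seed = 7)
  expect_identical(a1$accuracy, a2$accuracy)
  expect_identical(a1$coef, a2$coef)
  p1 <- permutation_null(fx$X, fx$y, iterations = 8, seed = 9)
  p2 <- permutation_null(fx$X, fx$y, iterations = 8, seed = 9)
  expect_identical(p1$accuracy, p2$accuracy)
  expect_false(identical(a1$accuracy,
                         repeated_cv(fx$X, fx$y, iterations = 8, seed = 8)$accuracy))
})

test_that("permuted-label accuracy centers at one half regardless of signal", {
  set.seed(33)
  n <- 80
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- as.numeric(X[, 1] > 0)  # strong signal in the true labels
  perm <- permutation_null(X, y, iterations = 60, seed = 3)
  expect_lt(abs(perm$mean_accuracy - 0.5), 0.05)
  expect_true(all(perm$accuracy >= 0 & perm$accuracy <= 1))
})

test_that("stratification guards against too-rare classes", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(rep(1, 3), rep(0, 17))  # only 3 positives < k = 5
  expect_error(repeated_cv(X, y, k = 5, iterations = 2, seed = 1),
               "at least 5")
})

test_that("compare_arms matches the reference test statistics", {
  a <- structure(list(accuracy = c(0.6, 0.65, 0.62, 0.7)), class = "polyfc_cv_arm")
  b <- structure(list(accuracy = c(0.5, 0.48, 0.52, 0.49)), class = "polyfc_cv_arm")
  res <- compare_arms(a, b)
  ref <- t.test(a$accuracy, b$accuracy)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  res_w <- compare_arms(a, b, method = "wilcoxon")
  expect_equal(res_w$p_value,
               wilcox.test(a$accuracy, b$accuracy, exact = FALSE)$p.value)
  # identical arms: p = 1 under the rank test
  expect_equal(compare_arms(a, a, method = "wilcoxon")$p_value, 1)
  b_short <- structure(list(accuracy = c(0.5, 0.5)), class = "polyfc_cv_arm")
  expect_error(compare_arms(a, b_short), "unequal arm lengths")
})

test_that("coefficient_report summarizes signs and stability", {
  arm <- structure(
    list(coef = cbind(up = c(1, 2, 1.5, 0.5), down = c(-1, -2, -0.5, 0.1)),
         arm = "true"),
    class = "polyfc_cv_arm"
  )
  rep <- coefficient_report(arm)
  expect_equal(rep$feature, c("up", "down"))
  expect_equal(rep$sign, c(1, -1))
  expect_equal(rep$stability, c(1, 0.75))
})

test_that("the full model run is reproducible end to end from cohort and seed", {
  ch <- simulate_cohort(cohort_config(group_sizes = c(EC = 20, VC = 20, CT = 20, CU = 20),
                                      seed = 4))
  r1 <- polyfunction_model(ch, iterations = 4, seed = 11)
  r2 <- polyfunction_model(ch, iterations = 4, seed = 11)
  expect_identical(r1$true$accuracy, r2$true$accuracy)
  expect_identical(r1$permuted$accuracy, r2$permuted$accuracy)
  expect_identical(r1$coefficients, r2$coefficients)
  expect_s3_class(glance(r1), "tbl_df")
  expect_equal(nrow(tidy(r1)), 5)
})

test_that("shuffling features across subjects is indistinguishable from the permuted arm", {
  ch <- simulate_cohort(cohort_config(seed = 21))
  lab <- polyfunction_labels(ch, quiet = TRUE)
  X <- subclass_features(ch)
  set.seed(17)
  X_shuf <- X[sample(nrow(X)), , drop = FALSE]
  arm_shuf <- repeated_cv(X_shuf, lab$polyfunctional, iterations = 30, seed = 2)
  expect_lt(abs(arm_shuf$mean_accuracy - 0.5), 0.05)
})
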