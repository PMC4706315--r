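# one arm of repeated stratified k-fold cross-validation; permute = TRUE
# reshuffles the labels once per iteration before fold assignment
cv_arm <- function(features, labels, k, iterations, lambda, lambdas, seed,
                   permute, arm_name) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as.numeric(as.logical(labels))
  n <- length(y)
  if (nrow(X) != n) stop("features and labels length mismatch", call. = FALSE)
  if (n < 2 * k) stop("need at least 2 * k subjects", call. = FALSE)
  min_class <- min(table(y))
  if (min_class < k) {
    stop("class too rare for stratified ", k, "-fold CV: need at least ", k,
         " subjects per class, have ", min_class, call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  use_cv <- identical(lambda, "cv")
  acc <- numeric(iterations)
  coef_mat <- matrix(NA_real_, iterations, ncol(X),
                     dimnames = list(NULL, colnames(X)))
  for (it in seq_len(iterations)) {
    y_it <- if (permute) sample(y) else y
    foldid <- stratified_folds(y_it, k)
    pred <- numeric(n)
    fold_coefs <- matrix(NA_real_, k, ncol(X))
    for (f in seq_len(k)) {
      test <- foldid == f
      Xtr <- X[!test, , drop = FALSE]
      ytr <- y_it[!test]
      lam <- if (use_cv) {
        inner <- stratified_folds(ytr, 5)
        dev <- .ridge_cv_deviance_cpp(Xtr, ytr, as.integer(inner),
                                      as.numeric(lambdas))
        lambdas[which.min(dev)]
      } else lambda
      fit <- .ridge_irls_cpp(Xtr, ytr, lam)
      fold_coefs[f, ] <- as.numeric(fit$beta)
      Zte <- sweep(sweep(X[test, , drop = FALSE], 2,
                         as.numeric(fit$center), `-`),
                   2, as.numeric(fit$scale), `/`)
      pred[test] <- plogis(drop(fit$intercept + Zte %*% fit$beta))
    }
    acc[it] <- balanced_accuracy(y_it == 1, pred > 0.5)
    coef_mat[it, ] <- colMeans(fold_coefs)
  }
  structure(
    list(accuracy = acc, coef = coef_mat,
         mean_accuracy = mean(acc), sd_accuracy = sd(acc),
         arm = arm_name, k = k, iterations = iterations,
         lambda_rule = if (use_cv) "cv" else lambda, seed = seed, n = n),
    class = "polyfc_cv_arm"
  )
}

#' Repeated stratified cross-validation of the ridge classifier
#'
#' Runs `iterations` independent rounds of stratified k-fold cross-validation:
#' each round draws a fresh fold partition, fits the ridge classifier on each
#' training fold (with the penalty chosen by inner 5-fold cross-validation
#' per training set when `lambda = "cv"`), pools the out-of-fold predicted
#' classes, and records one balanced accuracy per round plus the
#' fold-averaged standardized coefficients.
#'
#' @param features Numeric matrix, subjects x features.
#' @param labels Logical or 0/1 class vector; each class needs at least `k`
#'   subjects.
#' @param k Number of folds.
#' @param iterations Number of repeated rounds.
#' @param lambda `"cv"` or a fixed positive penalty.
#' @param lambdas Penalty grid for inner selection.
#' @param seed Integer seed making the run reproducible.
#' @return An object of class `polyfc_cv_arm`: per-iteration `accuracy`,
#'   iterations x features coefficient matrix `coef`, `mean_accuracy`,
#'   `sd_accuracy` and run metadata.
#' @export
repeated_cv <- function(features, labels, k = 5, iterations = 250,
                        lambda = "cv", lambdas = lambda_grid(), seed = NULL) {
  cv_arm(features, labels, k, iterations, lambda, lambdas, seed,
         permute = FALSE, arm_name = "true")
}

#' Permuted-label null arm of repeated cross-validation
#'
#' Identical to [repeated_cv()] except that the class labels are randomly
#' permuted once per iteration before fold assignment, giving the null
#' distribution of balanced accuracy under no feature-label association.
#'
#' @inheritParams repeated_cv
#' @return An object of class `polyfc_cv_arm` with `arm = "permuted"`.
#' @export
permutation_null <- function(features, labels, k = 5, iterations = 250,
                             lambda = "cv", lambdas = lambda_grid(),
                             seed = NULL) {
  cv_arm(features, labels, k, iterations, lambda, lambdas, seed,
         permute = TRUE, arm_name = "permuted")
}

#' @export
print.polyfc_cv_arm <- function(x, ...) {
  cat(sprintf("%s arm: %d x %d-fold CV, balanced accuracy %.3f +/- %.3f\n",
              x$arm, x$iterations, x$k, x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

#' Compare the true and permuted cross-validation arms
#'
#' Two-sample comparison of the per-iteration balanced accuracies of the true
#' and permuted arms: Welch's t-test by default, Mann-Whitney as an option.
#'
#' @param true_arm A `polyfc_cv_arm` (or a `polyfc_run`, in which case
#'   `permuted_arm` is taken from it).
#' @param permuted_arm The permuted `polyfc_cv_arm`.
#' @param method `"welch"` or `"wilcoxon"`.
#' @return A one-row tibble with `mean_true`, `mean_permuted`, `difference`,
#'   `statistic`, `p_value` and `method`.
#' @export
compare_arms <- function(true_arm, permuted_arm = NULL,
                         method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  if (inherits(true_arm, "polyfc_run")) {
    permuted_arm <- true_arm$permuted
    true_arm <- true_arm$true
  }
  a <- true_arm$accuracy
  b <- permuted_arm$accuracy
  if (length(a) != length(b)) stop("unequal arm lengths", call. = FALSE)
  ht <- if (method == "welch") t.test(a, b) else wilcox.test(a, b, exact = FALSE)
  tibble::tibble(
    mean_true = mean(a), mean_permuted = mean(b),
    difference = mean(a) - mean(b),
    statistic = unname(ht$statistic), p_value = ht$p.value,
    method = if (method == "welch") "welch_t" else "mann_whitney"
  )
}

#' Coefficient report for a cross-validation arm
#'
#' Per-feature mean standardized coefficient across iterations, its sign, and
#' the stability of that sign (fraction of iterations whose fold-averaged
#' coefficient shares the sign of the mean).
#'
#' @param arm A `polyfc_cv_arm` (or a `polyfc_run`, whose true arm is used).
#' @return A tibble with `feature`, `mean_weight`, `sign` and `stability`.
#' @export
coefficient_report <- function(arm) {
  if (inherits(arm, "polyfc_run")) arm <- arm$true
  mw <- colMeans(arm$coef)
  tibble::tibble(
    feature = colnames(arm$coef),
    mean_weight = unname(mw),
    sign = sign(unname(mw)),
    stability = vapply(seq_along(mw), function(j) {
      mean(sign(arm$coef[, j]) == sign(mw[j]))
    }, numeric(1))
  )
}

#' Fit and validate the polyfunctionality classifier on a cohort
#'
#' The full modeling stage: derive polyfunctionality labels (cohort-wide
#' median split, two-or-more-high rule), build the subclass feature matrix,
#' run the true and permuted-label arms of repeated stratified k-fold
#' cross-validation, and compare them. The permuted arm's seed is derived
#' deterministically from `seed` (seed + 1), so the whole run is reproducible
#' from (cohort, parameters, seed).
#'
#' @param cohort A cohort tibble.
#' @param k,iterations,lambda,lambdas Passed to the arms.
#' @param seed Master seed of the run.
#' @param log_transform Use `log1p(MFI)` features (see [subclass_features()]).
#' @param features Titer columns used as features.
#' @return An object of class `polyfc_run`: `labels`, `true`, `permuted`,
#'   `comparison` (tibble), `coefficients` (tibble), `assumptions` (character
#'   notes on conventions the published analysis left unstated), `seed`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 7))
#' run <- polyfunction_model(cohort, iterations = 5, seed = 7)
#' glance(run)
#' tidy(run)
#' @export
polyfunction_model <- function(cohort, k = 5, iterations = 250, lambda = "cv",
                               lambdas = lambda_grid(), seed = 1,
                               log_transform = TRUE,
                               features = subclass_names()) {
  labels <- polyfunction_labels(cohort, quiet = TRUE)
  X <- subclass_features(cohort, log_transform = log_transform,
                         features = features)
  common <- intersect(labels$subject_id, rownames(X))
  labels <- labels[match(common, labels$subject_id), ]
  X <- X[common, , drop = FALSE]
  y <- labels$polyfunctional
  true_arm <- repeated_cv(X, y, k = k, iterations = iterations,
                          lambda = lambda, lambdas = lambdas, seed = seed)
  perm_arm <- permutation_null(X, y, k = k, iterations = iterations,
                               lambda = lambda, lambdas = lambdas,
                               seed = as.integer(seed) + 1L)
  structure(
    list(labels = labels, true = true_arm, permuted = perm_arm,
         comparison = compare_arms(true_arm, perm_arm),
         coefficients = coefficient_report(true_arm),
         assumptions = c(
           "features standardized per training fold",
           "penalty chosen by inner 5-fold CV on a 50-point log grid",
           "folds stratified by class",
           "total IgG included as a feature alongside the four subclasses",
           "features on the log1p(MFI) scale"
         ),
         seed = seed),
    class = "polyfc_run"
  )
}

#' @export
print.polyfc_run <- function(x, ...) {
  cat(sprintf("Polyfunctionality classification (%d subjects, %d polyfunctional)\n",
              nrow(x$labels), sum(x$labels$polyfunctional)))
  cat(sprintf("  true:     balanced accuracy %.3f +/- %.3f\n",
              x$true$mean_accuracy, x$true$sd_accuracy))
  cat(sprintf("  permuted: balanced accuracy %.3f +/- %.3f\n",
              x$permuted$mean_accuracy, x$permuted$sd_accuracy))
  cat(sprintf("  difference %.3f, %s p = %.3g\n", x$comparison$difference,
              x$comparison$method, x$comparison$p_value))
  invisible(x)
}

#' @export
tidy.polyfc_run <- function(x, ...) x$coefficients

#' @export
glance.polyfc_run <- function(x, ...) {
  tibble::tibble(
    n = x$true$n,
    n_polyfunctional = sum(x$labels$polyfunctional),
    iterations = x$true$iterations,
    k = x$true$k,
    mean_accuracy = x$true$mean_accuracy,
    sd_accuracy = x$true$sd_accuracy,
    mean_permuted = x$permuted$mean_accuracy,
    sd_permuted = x$permuted$sd_accuracy,
    p_value = x$comparison$p_value
  )
}

#' @export
tidy.polyfc_cv_arm <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$accuracy), arm = x$arm,
                 balanced_accuracy = x$accuracy)
}
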