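#' Default penalty grid for ridge cross-validation
#'
#' A 50-point logarithmic grid, descending from strong to weak penalty, on
#' the mean-deviance scale of the ridge objective.
#'
#' @param from,to Log10 endpoints of the grid.
#' @param length Number of grid points.
#' @return A numeric vector of penalties, decreasing.
#' @export
lambda_grid <- function(from = 2, to = -4, length = 50) {
  10^seq(from, to, length.out = length)
}

# stratified fold assignment: shuffles within each class, deals folds round
# robin, then shuffles the deal so fold sizes differ by at most 1 per class
stratified_folds <- function(labels, k) {
  foldid <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    foldid[sample(idx)] <- rep_len(sample(k), length(idx))
  }
  foldid
}

#' Fit an L2-penalized (ridge) logistic classifier
#'
#' Minimizes the penalized binomial deviance
#' `mean(-loglik) + lambda * sum(beta^2) / 2` with an unpenalized intercept,
#' by Newton iterations with step halving. Features are standardized
#' internally (centering and scaling recorded, coefficients reported on the
#' standardized scale). Deterministic given data and `lambda`; when
#' `lambda = "cv"`, the penalty is chosen by stratified k-fold inner
#' cross-validation as the deviance-minimizing point of `lambdas` (this draws
#' fold assignments from the current RNG state).
#'
#' @param features Numeric matrix or data frame, subjects x features.
#' @param labels Logical or 0/1 vector; both classes must be present.
#' @param lambda A positive penalty, or `"cv"` for inner-CV selection.
#' @param lambdas Penalty grid used when `lambda = "cv"`.
#' @param inner_k Folds of the inner cross-validation.
#' @return An object of class `polyfc_ridge`: `intercept`, `coefficients`
#'   (named, standardized scale), `center`, `scale`, `lambda`, `mean_nll`.
#' @export
fit_ridge_classifier <- function(features, labels, lambda = "cv",
                                 lambdas = lambda_grid(), inner_k = 5) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as.numeric(as.logical(labels))
  if (nrow(X) != length(y)) stop("features and labels length mismatch", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  if (anyNA(y)) stop("missing labels", call. = FALSE)
  if (length(unique(y)) < 2) stop("labels contain a single class", call. = FALSE)
  if (identical(lambda, "cv")) {
    foldid <- stratified_folds(y, inner_k)
    dev <- .ridge_cv_deviance_cpp(X, y, as.integer(foldid), as.numeric(lambdas))
    lambda <- lambdas[which.min(dev)]
  }
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda > 0)
  fit <- .ridge_irls_cpp(X, y, lambda)
  coefs <- as.numeric(fit$beta)
  names(coefs) <- colnames(X)
  structure(
    list(intercept = fit$intercept, coefficients = coefs,
         center = as.numeric(fit$center), scale = as.numeric(fit$scale),
         lambda = lambda, mean_nll = fit$mean_nll, n = nrow(X)),
    class = "polyfc_ridge"
  )
}

#' @export
predict.polyfc_ridge <- function(object, newdata,
                                 type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  Z <- sweep(sweep(X, 2, object$center, `-`), 2, object$scale, `/`)
  eta <- drop(object$intercept + Z %*% object$coefficients)
  switch(type,
         link = eta,
         response = plogis(eta),
         class = plogis(eta) > 0.5)
}

#' @export
print.polyfc_ridge <- function(x, ...) {
  cat(sprintf("Ridge logistic classifier (lambda = %.4g, n = %d)\n",
              x$lambda, x$n))
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 4))
  invisible(x)
}
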