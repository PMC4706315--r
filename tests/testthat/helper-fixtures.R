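# small cohort built in code: 4 subjects per group, deterministic values
tiny_cohort <- function(n_per_group = 4) {
  set.seed(99)
  groups <- rep(group_levels(), each = n_per_group)
  n <- length(groups)
  df <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    group = groups
  )
  for (fn in c("ADCC", "ADCD", "NK_CD107a", "NK_IFNg", "NK_MIP1b")) {
    df[[fn]] <- round(runif(n, 0, 100), 3)
  }
  for (fn in c("ADCP", "ADNP")) df[[fn]] <- round(runif(n, 0, 30), 3)
  for (sc in subclass_names()) df[[sc]] <- round(runif(n, 0, 5000), 2)
  validate_cohort(df)
}

# cohort where a chosen set of columns share one common vector
constant_function_cohort <- function(n = 10) {
  base <- seq_len(n) + 0.5
  df <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    group = rep("EC", n)
  )
  for (fn in function_names()) df[[fn]] <- base
  for (sc in subclass_names()) df[[sc]] <- base * 100
  validate_cohort(df)
}

# brute-force minimizer of the ridge objective on the standardized design,
# independent of the IRLS path (Nelder-Mead/BFGS via optim)
ridge_objective_oracle <- function(X, y, lambda) {
  Z <- scale(X)
  obj <- function(par) {
    eta <- par[1] + drop(Z %*% par[-1])
    mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      lambda / 2 * sum(par[-1]^2)
  }
  fit <- optim(rep(0, ncol(X) + 1), obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  list(intercept = fit$par[1], beta = fit$par[-1], value = fit$value)
}

# deterministic 20-subject two-class fixture for classifier tests
classifier_fixture <- function(n = 20, p = 3, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- as.numeric(X[, 1] + 0.5 * rnorm(n) > 0)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(X = X, y = y)
}
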