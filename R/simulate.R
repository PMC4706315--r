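#' Latent-normal correlation inducing a target Spearman correlation
#'
#' For a bivariate Gaussian copula, a latent Pearson correlation of
#' `2 * sin(pi * rho_s / 6)` induces Spearman correlation `rho_s` on the
#' observed (monotone-transformed) scale. Used to calibrate the generator's
#' correlation targets.
#'
#' @param rho_s Target Spearman correlation, strictly inside (-1, 1).
#' @return The latent Pearson correlation.
#' @export
spearman_to_pearson_latent <- function(rho_s) {
  if (any(!is.finite(rho_s)) || any(abs(rho_s) >= 1)) {
    stop("rho_s must lie strictly inside (-1, 1)", call. = FALSE)
  }
  2 * sin(pi * rho_s / 6)
}

#' Nearest positive semi-definite correlation matrix
#'
#' Eigenvalue clipping: eigenvalues below `eps` are floored at `eps`, the
#' matrix is reconstructed and rescaled to unit diagonal. A matrix that is
#' already PSD is returned unchanged.
#'
#' @param m Symmetric matrix with unit diagonal.
#' @param eps Eigenvalue floor (small positive).
#' @return A PSD correlation matrix.
#' @export
nearest_psd_correlation <- function(m, eps = 1e-8) {
  m <- as.matrix(m)
  if (!isSymmetric(m, tol = 1e-10)) stop("matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(m) - 1) > 1e-8)) stop("matrix must have unit diagonal", call. = FALSE)
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -1e-12) return(m)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- 1 / sqrt(diag(out))
  out <- out * tcrossprod(d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  out
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates the generator parameters. Defaults encode the
#' statistical structure the analysis assumes: the study's group sizes
#' (50/64/45/38), strong functional coordination in elite controllers and
#' weak coordination in untreated viremics, co-induction of IgG1 with IgG3
#' and IgG2 with IgG4, group-dependent subclass levels and positivity
#' (viremic groups higher-titer, IgG4 nearly absent in controllers), and
#' subclass-driven function with IgG1/IgG3 positive and relative IgG2/IgG4
#' negative effects.
#'
#' @param group_sizes Named integer vector of subjects per group (each >= 2).
#' @param coordination_loading Named vector in \[0, 1): loading of the shared
#'   subject-level quality factor on every function, per group. Squared
#'   loading over (squared loading + `noise_sd^2`) is the induced latent
#'   pairwise correlation.
#' @param function_corr_target Optional named list of 7x7 target Spearman
#'   correlation matrices per group; when supplied for a group, function
#'   latents are drawn from a Gaussian copula calibrated with
#'   [spearman_to_pearson_latent()] instead of the shared-factor model.
#' @param subclass_means_log Group x subclass (IgG1..IgG4) matrix of log-MFI
#'   means.
#' @param subclass_sd_log Log-scale SD of subclass MFIs.
#' @param subclass_positivity Group x subclass matrix of responder
#'   probabilities; non-responders get MFI exactly 0.
#' @param coinduction_rho Latent correlation within the \{IgG1, IgG3\} and
#'   \{IgG2, IgG4\} blocks (across-block correlation 0).
#' @param effect_weights Named vector of planted subclass effects on every
#'   function. Names `IgG1`..`IgG4` act through standardized `log1p(MFI)`;
#'   names `IgG1_rel`..`IgG4_rel` act through the standardized ratio
#'   MFI / total-IgG MFI.
#' @param effect_strength In \[0, 1\]: the share of the subject quality factor
#'   carried by the (unit-variance) planted effect index. The factor becomes
#'   `sqrt(1 - effect_strength^2) * q + effect_strength * E`, so group
#'   coordination is governed by the loading alone while subclass-function
#'   coupling scales with that same loading — strong where functions are
#'   coordinated, weak where they are not.
#' @param effect_magnitude Additional additive scale of the effect index on
#'   every function, common to all groups: the magnitude component of the
#'   planted effect (drives the pooled relative-level associations), as
#'   opposed to the coordination component carried by `effect_strength`.
#' @param noise_sd Per-function latent noise SD (> 0).
#' @param total_residual_meanlog,total_residual_sdlog Lognormal residual added
#'   to the subclass sum to form total IgG MFI.
#' @param assay_floor Named per-function detection floor; readouts below it
#'   are set to 0 (background subtraction).
#' @param seed Default seed used by [simulate_cohort()].
#' @return A validated list of class `polyfc_config`.
#' @export
cohort_config <- function(group_sizes = c(EC = 50, VC = 64, CT = 45, CU = 38),
                          coordination_loading = c(EC = 0.8, VC = 0.4, CT = 0.6, CU = 0.3),
                          function_corr_target = NULL,
                          subclass_means_log = default_subclass_means(),
                          subclass_sd_log = 1.0,
                          subclass_positivity = default_subclass_positivity(),
                          coinduction_rho = 0.7,
                          effect_weights = c(IgG1 = 0.6, IgG3 = 0.8,
                                             IgG2_rel = -0.5, IgG4_rel = -0.7),
                          effect_strength = 0.9,
                          effect_magnitude = 0.2,
                          noise_sd = 0.45,
                          total_residual_meanlog = 6.5,
                          total_residual_sdlog = 0.5,
                          assay_floor = setNames(rep(0, 7), function_names()),
                          seed = 1L) {
  stopifnot(length(group_sizes) >= 1, !is.null(names(group_sizes)))
  if (!all(names(group_sizes) %in% group_levels())) {
    stop("group_sizes names must be among ", paste(group_levels(), collapse = ", "),
         call. = FALSE)
  }
  if (any(group_sizes < 2)) stop("each group needs at least 2 subjects", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (coinduction_rho < 0 || coinduction_rho >= 1) {
    stop("coinduction_rho must lie in [0, 1)", call. = FALSE)
  }
  if (effect_strength < 0 || effect_strength > 1) {
    stop("effect_strength must lie in [0, 1]", call. = FALSE)
  }
  loadings <- coordination_loading[names(group_sizes)]
  if (anyNA(loadings) || any(loadings < 0) || any(loadings >= 1)) {
    stop("coordination_loading must cover all groups with values in [0, 1)",
         call. = FALSE)
  }
  ok_feats <- c(paste0("IgG", 1:4), paste0("IgG", 1:4, "_rel"))
  if (length(effect_weights) > 0 && !all(names(effect_weights) %in% ok_feats)) {
    stop("effect_weights names must be among ", paste(ok_feats, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(group_sizes = group_sizes,
         coordination_loading = coordination_loading,
         function_corr_target = function_corr_target,
         subclass_means_log = subclass_means_log,
         subclass_sd_log = subclass_sd_log,
         subclass_positivity = subclass_positivity,
         coinduction_rho = coinduction_rho,
         effect_weights = effect_weights,
         effect_strength = effect_strength,
         effect_magnitude = effect_magnitude,
         noise_sd = noise_sd,
         total_residual_meanlog = total_residual_meanlog,
         total_residual_sdlog = total_residual_sdlog,
         assay_floor = assay_floor,
         seed = as.integer(seed)),
    class = "polyfc_config"
  )
}

#' @rdname cohort_config
#' @export
default_subclass_means <- function() {
  m <- rbind(
    EC = c(8.0, 5.5, 6.5, 4.5),
    VC = c(8.6, 6.5, 7.0, 5.0),
    CT = c(8.2, 6.5, 6.5, 5.5),
    CU = c(8.6, 7.0, 7.0, 6.0)
  )
  colnames(m) <- paste0("IgG", 1:4)
  m
}

#' @rdname cohort_config
#' @export
default_subclass_positivity <- function() {
  m <- rbind(
    EC = c(0.98, 0.35, 0.60, 0.05),
    VC = c(0.98, 0.70, 0.80, 0.10),
    CT = c(0.98, 0.80, 0.70, 0.50),
    CU = c(0.98, 0.85, 0.80, 0.60)
  )
  colnames(m) <- paste0("IgG", 1:4)
  m
}

# offsets/slopes mapping the unit-scale function latent to assay scales;
# strictly monotone, so all rank statistics are unchanged by this map
assay_transforms <- function() {
  list(
    percent_slope = 0.9,
    percent_shift = c(ADCC = 0.2, ADCD = -0.3, NK_CD107a = -1.0,
                      NK_IFNg = -1.8, NK_MIP1b = -1.2),
    score_slope = 0.45,
    score_shift = c(ADCP = 2.2, ADNP = 2.5)
  )
}

#' Generate a synthetic cohort
#'
#' Draws a cohort with the statistical structure the downstream analyses
#' assume. Per subject: (1) subclass log-MFIs from a two-block latent-normal
#' model (\{IgG1, IgG3\} and \{IgG2, IgG4\} blocks with within-block
#' correlation `coinduction_rho`), exponentiated to lognormal MFIs with
#' group-specific means and zeroed for non-responders; total IgG is the
#' subclass sum plus a lognormal residual; (2) a unit-variance subject quality
#' factor — a blend of an idiosyncratic `q ~ N(0, 1)` and the planted subclass
#' effect index, mixed by `effect_strength` — shared by all seven functions
#' with group-specific loading (or, when a correlation target matrix is
#' supplied, a Gaussian-copula draw calibrated to the target Spearman matrix),
#' plus per-function noise; (3) strictly monotone maps to assay scales
#' (logistic to \[0, 100\] for percent readouts, exponential for phagocytic
#' scores) and detection-floor censoring. Deterministic given `config` and
#' `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A cohort tibble (see [read_cohort()] for columns) carrying a
#'   generation report (achieved per-group Spearman matrices, achieved
#'   positivity, seed, config) retrievable with [generation_report()].
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 42))
#' group_sizes(cohort)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "polyfc_config"))
  set.seed(as.integer(seed))
  groups <- names(config$group_sizes)
  sc_names <- paste0("IgG", 1:4)

  # latent correlation for the two co-induction blocks (IgG1/IgG3, IgG2/IgG4)
  r <- config$coinduction_rho
  R4 <- diag(4)
  dimnames(R4) <- list(sc_names, sc_names)
  R4["IgG1", "IgG3"] <- R4["IgG3", "IgG1"] <- r
  R4["IgG2", "IgG4"] <- R4["IgG4", "IgG2"] <- r
  L4 <- chol(R4)

  subj <- list(); sub_mfi <- list(); totals <- list()
  q_all <- list(); eps_all <- list(); base_all <- list()
  for (g in groups) {
    n <- config$group_sizes[[g]]
    z <- matrix(rnorm(n * 4), n, 4) %*% L4
    mu <- config$subclass_means_log[g, sc_names]
    mfi <- exp(sweep(z * config$subclass_sd_log, 2, mu, `+`))
    resp <- matrix(0, n, 4)
    for (j in seq_len(4)) {
      resp[, j] <- rbinom(n, 1, config$subclass_positivity[g, sc_names[j]])
    }
    mfi <- mfi * resp
    colnames(mfi) <- sc_names
    tot <- rowSums(mfi) + rlnorm(n, config$total_residual_meanlog,
                                 config$total_residual_sdlog)

    # function latent randomness; in copula mode the same draws are rotated
    # to the calibrated latent correlation
    q <- rnorm(n)
    eps <- matrix(rnorm(n * 7), n, 7)
    target <- config$function_corr_target[[g]]
    base <- NULL
    if (!is.null(target)) {
      target <- as.matrix(target)
      if (!isSymmetric(target, tol = 1e-8)) {
        stop("function_corr_target for group ", g, " is not symmetric", call. = FALSE)
      }
      latent_corr <- nearest_psd_correlation(spearman_to_pearson_latent_mat(target))
      base <- eps %*% chol(latent_corr)
    }

    subj[[g]] <- sprintf("%s%03d", g, seq_len(n))
    sub_mfi[[g]] <- mfi
    totals[[g]] <- tot
    q_all[[g]] <- q
    eps_all[[g]] <- eps
    base_all[[g]] <- base
  }

  mfi <- do.call(rbind, sub_mfi)
  total <- unlist(totals, use.names = FALSE)
  group <- rep(groups, config$group_sizes[groups])

  # planted effect index: weighted sum of per-feature standardized subclass
  # features, standardized cohort-wide to unit variance
  eff <- rep(0, nrow(mfi))
  if (length(config$effect_weights) > 0) {
    for (nm in names(config$effect_weights)) {
      x <- if (grepl("_rel$", nm)) {
        mfi[, sub("_rel$", "", nm)] / total
      } else {
        log1p(mfi[, nm])
      }
      sx <- sd(x)
      if (sx > 0) eff <- eff + config$effect_weights[[nm]] * (x - mean(x)) / sx
    }
    se <- sd(eff)
    if (se > 0) eff <- eff / se
  }

  # the subclass effect enters through the group-loaded quality factor:
  # u = sqrt(1 - tau^2) q + tau E_g (E_g re-standardized within group) keeps
  # the within-group var(u) at 1, so group coordination is governed by the
  # loading alone while subclass-function coupling scales with that same
  # loading (strong in coordinated groups, weak otherwise)
  tau <- if (sd(eff) > 0) config$effect_strength else 0
  f_rows <- vector("list", length(groups))
  offset <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n <- config$group_sizes[[g]]
    idx <- offset + seq_len(n)
    offset <- offset + n
    if (!is.null(config$function_corr_target[[g]])) {
      # copula mode: the target matrix specifies the complete dependence
      f_rows[[gi]] <- base_all[[g]]
    } else {
      a <- config$coordination_loading[[g]]
      eg <- eff[idx]
      if (sd(eg) > 0) eg <- (eg - mean(eg)) / sd(eg)
      u <- sqrt(1 - tau^2) * q_all[[g]] + tau * eg
      f_rows[[gi]] <- a * u + config$effect_magnitude * eff[idx] +
        config$noise_sd * eps_all[[g]]
    }
  }
  f <- do.call(rbind, f_rows)
  colnames(f) <- function_names()

  tr <- assay_transforms()
  out <- matrix(NA_real_, nrow(f), 7, dimnames = list(NULL, function_names()))
  for (fn in percent_functions()) {
    out[, fn] <- 100 * plogis(tr$percent_slope * f[, fn] + tr$percent_shift[[fn]])
  }
  for (fn in c("ADCP", "ADNP")) {
    out[, fn] <- exp(tr$score_slope * f[, fn] + tr$score_shift[[fn]])
  }
  for (fn in function_names()) {
    fl <- config$assay_floor[[fn]]
    if (!is.null(fl) && fl > 0) out[out[, fn] < fl, fn] <- 0
  }

  cohort <- tibble::tibble(
    subject_id = unlist(subj, use.names = FALSE),
    group = factor(group, levels = group_levels())
  )
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(out))
  cohort$IgG_total <- total
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(mfi))
  cohort <- cohort[, c("subject_id", "group", function_names(), subclass_names())]
  cohort <- validate_cohort(cohort)

  achieved_spearman <- lapply(setNames(groups, groups), function(g) {
    cor(as.matrix(cohort[cohort$group == g, function_names()]), method = "spearman")
  })
  achieved_pos <- t(vapply(setNames(groups, groups), function(g) {
    colMeans(mfi[group == g, , drop = FALSE] > 0)
  }, numeric(4)))
  attr(cohort, "generation_report") <- list(
    achieved_spearman = achieved_spearman,
    achieved_positivity = achieved_pos,
    seed = as.integer(seed),
    config = config
  )
  cohort
}

# elementwise copula calibration, keeping the unit diagonal exact
spearman_to_pearson_latent_mat <- function(m) {
  out <- m
  off <- row(m) != col(m)
  out[off] <- spearman_to_pearson_latent(m[off])
  diag(out) <- 1
  out
}

#' Retrieve the generation report of a simulated cohort
#'
#' @param cohort A cohort produced by [simulate_cohort()].
#' @return A list with achieved per-group Spearman matrices of the seven
#'   functions, achieved subclass positivity, the seed and the config echo.
#' @export
generation_report <- function(cohort) {
  rep <- attr(cohort, "generation_report")
  if (is.null(rep)) stop("cohort carries no generation report", call. = FALSE)
  rep
}
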