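#' Pipeline configuration
#'
#' One object from which every stage's parameters are derived. Either a
#' cohort file (`cohort_path`) or a synthetic-generator configuration
#' (`synthetic`) must be supplied. Stage seeds are derived deterministically
#' from the master seed (generator: `seed`; classifier: `seed + 100`), so
#' stages can be rerun in isolation.
#'
#' @param cohort_path Optional path to a cohort CSV/TSV.
#' @param synthetic Optional [cohort_config()] used when no cohort file is
#'   given.
#' @param bin_edges Strength-histogram bin edges.
#' @param positivity_thresholds Per-subclass MFI positivity thresholds.
#' @param iterations,k,lambda Classifier cross-validation parameters.
#' @param seed Master seed.
#' @return A list of class `polyfc_pipeline_config`.
#' @export
pipeline_config <- function(cohort_path = NULL, synthetic = cohort_config(),
                            bin_edges = c(-1, 0, 0.2, 0.4, 0.6, 0.8, 1),
                            positivity_thresholds = 100,
                            iterations = 250, k = 5, lambda = "cv",
                            seed = 1L) {
  structure(
    list(cohort_path = cohort_path, synthetic = synthetic,
         bin_edges = bin_edges, positivity_thresholds = positivity_thresholds,
         iterations = iterations, k = k, lambda = lambda,
         seed = as.integer(seed)),
    class = "polyfc_pipeline_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Chains every stage on one cohort with one configuration and seed:
#' simulate (or load) the cohort, per-function group comparisons
#' (ANOVA/Tukey), coordination analysis (pairwise Spearman, Friedman/Dunn,
#' strength histogram, correlation matrices), subclass landscape (positivity
#' prevalence, co-induction matrix, Kruskal-Wallis/Dunn level tests),
#' titer-function and relative-level correlation matrices, and the
#' permutation-validated ridge classifier. All tables are written as TSV with
#' a JSON manifest; `report.md` is assembled by reading the stage outputs
#' back (never recomputing). A stage failure aborts with the stage name;
#' outputs of completed stages are preserved.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the output directory.
#' @export
run_all <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "polyfc_pipeline_config"))
  if (is.null(config$cohort_path) && is.null(config$synthetic)) {
    stop("config needs either a cohort_path or a synthetic generator config",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- run_stage("cohort", {
    if (!is.null(config$cohort_path)) {
      read_cohort(config$cohort_path)
    } else {
      ch <- simulate_cohort(config$synthetic, seed = config$seed)
      readr::write_csv(ch, file.path(out_dir, "cohort.csv"), progress = FALSE)
      rep <- generation_report(ch)
      jsonlite::write_json(
        list(seed = rep$seed,
             achieved_positivity = as.data.frame(rep$achieved_positivity),
             achieved_spearman = lapply(rep$achieved_spearman, function(m) {
               as.data.frame(round(m, 4))
             })),
        file.path(out_dir, "generation_report.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
      ch
    }
  })

  fn_tests <- run_stage("function_tests", {
    purrr::map_dfr(function_names(), function(fn) {
      grs <- levels(droplevels(factor(cohort$group)))
      vals <- purrr::map(setNames(grs, grs),
                         function(g) cohort[[fn]][cohort$group == g])
      res <- group_anova_tukey(vals)
      dplyr::bind_cols(tibble::tibble(fn = fn), res$test)
    })
  })

  coord <- run_stage("coordination", {
    cs <- pairwise_function_correlations(cohort)
    list(correlations = cs,
         test = compare_group_coordination(cs),
         histogram = strength_histogram(cs, config$bin_edges),
         matrices = correlation_matrix_report(cs))
  })

  subc <- run_stage("subclass", {
    calls <- call_positivity(cohort, config$positivity_thresholds)
    list(prevalence = prevalence_by_group(calls),
         corr = subclass_correlation_matrix(cohort),
         levels = compare_subclass_levels(cohort))
  })

  landscape <- run_stage("landscape", {
    list(titer_function = titer_function_matrix(cohort),
         relative = relative_level_matrix(cohort))
  })

  run <- run_stage("polyfx", {
    polyfunction_model(cohort, k = config$k, iterations = config$iterations,
                       lambda = config$lambda, seed = config$seed + 100L)
  })

  run_stage("write", {
    write_results(
      list(function_tests = fn_tests,
           correlations = coord$correlations,
           strength_histogram = coord$histogram,
           correlation_matrices = coord$matrices,
           coordination_posthoc = coord$test$posthoc,
           prevalence = subc$prevalence,
           subclass_corr = subc$corr,
           level_tests = subc$levels$tests,
           level_posthoc = subc$levels$posthoc,
           titer_function_by_group = landscape$titer_function,
           relative_matrix = landscape$relative,
           labels = run$labels,
           coefficients = run$coefficients),
      out_dir,
      config = list(bin_edges = config$bin_edges,
                    positivity_thresholds = config$positivity_thresholds,
                    iterations = config$iterations, k = config$k,
                    lambda = config$lambda),
      seed = config$seed
    )
    jsonlite::write_json(
      c(as.list(glance(run)),
        list(coordination_test = as.list(coord$test$test),
             comparison_method = run$comparison$method,
             assumptions = run$assumptions)),
      file.path(out_dir, "run_summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  run_stage("report", write_report(out_dir))
  invisible(out_dir)
}

# assembles report.md strictly from files already written to out_dir
write_report <- function(out_dir) {
  rd <- function(f) readr::read_tsv(file.path(out_dir, f), show_col_types = FALSE,
                                    progress = FALSE)
  summ <- jsonlite::read_json(file.path(out_dir, "run_summary.json"))
  fn_tests <- rd("function_tests.tsv")
  posthoc <- rd("coordination_posthoc.tsv")
  prev <- rd("prevalence.tsv")
  lev <- rd("level_tests.tsv")
  coefs <- rd("coefficients.tsv")
  lines <- c(
    "# Polyfunctionality analysis report", "",
    "## Per-function group comparisons (ANOVA)", "",
    sprintf("- %s: F = %.2f, p = %.3g", fn_tests$fn, fn_tests$statistic,
            fn_tests$p_value), "",
    "## Coordination (Friedman on 21 function-pair blocks)", "",
    sprintf("- chi-squared = %.2f, df = %d, p = %.3g",
            summ$coordination_test$statistic, summ$coordination_test$df,
            summ$coordination_test$p_value),
    sprintf("- Dunn %s vs %s: adjusted p = %.3g", posthoc$group_a,
            posthoc$group_b, posthoc$adjusted_p), "",
    "## Subclass landscape", "",
    sprintf("- prevalence %s / %s: %.0f%%", prev$group, prev$subclass,
            100 * prev$prevalence),
    sprintf("- level test %s: H = %.2f, p = %.3g", lev$subclass,
            lev$statistic, lev$p_value), "",
    "## Polyfunctionality classifier", "",
    sprintf("- true balanced accuracy %.3f +/- %.3f over %d x %d-fold CV",
            summ$mean_accuracy, summ$sd_accuracy, summ$iterations, summ$k),
    sprintf("- permuted balanced accuracy %.3f +/- %.3f", summ$mean_permuted,
            summ$sd_permuted),
    sprintf("- arm comparison (%s) p = %.3g", summ$comparison_method,
            summ$p_value),
    sprintf("- coefficient %s: mean weight %.3f (stability %.2f)",
            coefs$feature, coefs$mean_weight, coefs$stability)
  )
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(file.path(out_dir, "report.md"))
}
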