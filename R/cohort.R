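#' Read and validate a cohort table
#'
#' Reads a delimited text file of per-subject assay readouts and gp120-specific
#' IgG titers into a validated cohort tibble. The expected columns are
#' `subject_id`, `group` (one of `EC`, `VC`, `CT`, `CU`), the seven effector
#' functions ([function_names()]) and the five titer measurements
#' ([subclass_names()]); differently named columns can be remapped via
#' `schema`. Empty cells become `NA` (recorded as missing, never zero) and row
#' order is preserved.
#'
#' The four groups are HIV-infected subject strata: elite controllers (EC,
#' <50 RNA copies/ml untreated), viremic controllers (VC, 50-2000 copies/ml),
#' chronic treated (CT, suppressed on ART) and chronic untreated (CU).
#'
#' @param path Path to a `.csv` (comma) or `.tsv`/`.txt` (tab) file with a
#'   header row. The delimiter is chosen from the extension.
#' @param schema Optional named character vector mapping required roles to the
#'   file's column names, e.g. `c(subject_id = "id", ADCC = "adcc_pct")`.
#'   Roles not listed are assumed to match the canonical names.
#' @return A validated cohort tibble with `group` as a factor with levels
#'   `EC, VC, CT, CU`.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' cohort <- simulate_cohort(cohort_config(group_sizes = c(EC = 3, VC = 3, CT = 3, CU = 3),
#'                                         seed = 1))
#' readr::write_csv(cohort, path)
#' read_cohort(path)
#' @export
read_cohort <- function(path, schema = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  roles <- c("subject_id", "group", function_names(), subclass_names())
  colmap <- setNames(roles, roles)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), roles)
    if (length(bad) > 0) {
      stop("unknown schema roles: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    colmap[names(schema)] <- schema
  }
  missing_cols <- colmap[!colmap %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- raw[, unname(colmap)]
  names(df) <- names(colmap)
  df <- dplyr::mutate(
    df,
    subject_id = as.character(.data$subject_id),
    dplyr::across(dplyr::all_of(c(function_names(), subclass_names())), as.numeric)
  )
  validate_cohort(df)
}

#' Validate a cohort tibble
#'
#' Checks the cohort invariants: unique subject ids, known group codes, all
#' present MFI values nonnegative, and percent-type readouts (ADCC, ADCD and
#' the three NK readouts) within \[0, 100\]. ADCP/ADNP phagocytic scores are
#' unbounded nonnegative. Missing values are allowed everywhere and left as
#' `NA`.
#'
#' @param cohort A data frame with the cohort columns.
#' @return The cohort as a tibble with `group` converted to a factor, invisibly
#'   checked; errors name the offending rows.
#' @export
validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  bad_group <- which(!is.na(cohort$group) & !cohort$group %in% group_levels())
  if (length(bad_group) > 0) {
    stop("unknown group code ", paste0("'", cohort$group[bad_group[1]], "'"),
         " in row(s) ", paste(bad_group, collapse = ", "), call. = FALSE)
  }
  if (anyNA(cohort$group)) {
    stop("missing group code in row(s) ",
         paste(which(is.na(cohort$group)), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(cohort$subject_id)
  if (any(dup)) {
    stop("duplicate subject_id: ",
         paste(unique(cohort$subject_id[dup]), collapse = ", "), call. = FALSE)
  }
  for (sc in subclass_names()) {
    bad <- which(!is.na(cohort[[sc]]) & cohort[[sc]] < 0)
    if (length(bad) > 0) {
      stop("negative MFI for ", sc, " in row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  for (fn in percent_functions()) {
    v <- cohort[[fn]]
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad) > 0) {
      stop(fn, " outside [0, 100] in row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  for (fn in c("ADCP", "ADNP")) {
    bad <- which(!is.na(cohort[[fn]]) & cohort[[fn]] < 0)
    if (length(bad) > 0) {
      stop(fn, " negative in row(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  cohort$group <- factor(as.character(cohort$group), levels = group_levels())
  cohort
}

#' Group sizes of a cohort
#'
#' @param cohort A cohort tibble.
#' @return A named integer vector of subjects per group (represented groups
#'   only).
#' @export
group_sizes <- function(cohort) {
  tab <- table(factor(cohort$group, levels = group_levels()))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[out > 0]
}

#' Write result tables with a manifest
#'
#' Writes each named table as a TSV under `path` and a `manifest.json` listing
#' file names, row counts and the configuration/seed used, so a result
#' directory is self-describing.
#'
#' @param tables A non-empty named list of data frames.
#' @param path Output directory (created if needed).
#' @param config Optional list echoed verbatim into the manifest.
#' @param seed Optional seed recorded in the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(tables, path, config = NULL, seed = NULL) {
  if (length(tables) == 0 || is.null(names(tables)) || any(names(tables) == "")) {
    stop("'tables' must be a non-empty named list of data frames", call. = FALSE)
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path, call. = FALSE)
  files <- purrr::imap(tables, function(tbl, nm) {
    f <- file.path(path, paste0(nm, ".tsv"))
    readr::write_tsv(tibble::as_tibble(tbl), f, progress = FALSE)
    list(file = paste0(nm, ".tsv"), rows = nrow(tbl), cols = ncol(tbl))
  })
  manifest <- list(tables = files, config = config, seed = seed,
                   written = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
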