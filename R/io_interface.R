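#' The methylene-blue biosorption L25 run sheet
#'
#' The packaged designed-experiment table of the dye-biosorption study:
#' 25 runs of the five-factor, five-level orthogonal array with the
#' physical factor settings, the observed removal percentage (mean of
#' three biological replicates, with standard deviation), the additive
#' model prediction and the reported larger-is-better S/N ratio.
#'
#' @return A tibble with columns `run_id`, `pH`, `incubation_time_h`,
#'   `initial_mb_mgL`, `glucose_pct`, `peptone_pct`, `removal_actual`,
#'   `removal_sd`, `removal_predicted`, `snr`.
#' @examples
#' mb_taguchi_runs()
#' @export
mb_taguchi_runs <- function() {
  path <- system.file("extdata", "mb_taguchi_l25.csv", package = "biosorb",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Read a designed-experiment run sheet
#'
#' Reads a CSV laid out as `run_id`, one column of physical factor values
#' per factor, a `response` column and an optional `sd` column, maps the
#' physical values back to level indices against the declared factor
#' specifications, and verifies design orthogonality (warning, not error,
#' on failure — non-orthogonal sheets are still analyzable).
#'
#' @param path CSV file path.
#' @param specs list of [factor_spec()] declaring the factors and levels.
#' @param response name of the response column (default `"response"`).
#' @param tol level-matching tolerance, see [levels_to_indices()].
#' @return List with `design` (an `oa_design` with the specs bound) and
#'   `runs` (tibble `run_id`, `Y`, `sd`).
#' @export
read_run_sheet <- function(path, specs, response = "response", tol = 1e-8) {
  df <- utils::read.csv(path, check.names = FALSE)
  fnames <- vapply(specs, function(s) s$name, character(1))
  missing_cols <- setdiff(c(fnames, response), names(df))
  if (length(missing_cols))
    stop("run sheet is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyNA(df[[response]]))
    stop("missing response value(s) in the run sheet", call. = FALSE)
  idx <- levels_to_indices(df, specs, tol = tol)
  p <- length(specs[[1]]$levels)
  design <- structure(list(p = as.integer(p), runs = idx, factors = specs),
                      class = "oa_design")
  chk <- verify_orthogonality(design)
  if (!chk$balanced || !chk$orthogonal)
    warning("run sheet is not a balanced orthogonal array; analyses assuming ",
            "balance may be invalid", call. = FALSE)
  runs <- tibble::tibble(
    run_id = if ("run_id" %in% names(df)) as.character(df$run_id)
             else paste0("L", seq_len(nrow(df))),
    Y = as.numeric(df[[response]]),
    sd = if ("sd" %in% names(df)) as.numeric(df$sd) else NA_real_
  )
  list(design = design, runs = runs)
}

#' Write a designed-experiment run sheet
#'
#' Inverse of [read_run_sheet()]: writes `run_id`, the physical factor
#' values and the response (plus `sd` when present) as CSV.
#'
#' @param design an `oa_design` with factor specs bound.
#' @param runs tibble with `Y` (and optionally `run_id`, `sd`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_run_sheet <- function(design, runs, path) {
  sheet <- assign_levels(design)
  sheet$response <- runs$Y
  if (!is.null(runs$sd) && !all(is.na(runs$sd))) sheet$sd <- runs$sd
  if (!is.null(runs$run_id)) sheet$run_id <- runs$run_id
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read equilibrium batch data
#'
#' Reads a CSV of batch isotherm measurements with columns `C0` and
#' either `Ce` or `removal` (percent; converted via [ce_from_removal()]),
#' plus optional per-row `V` and `M` overriding the arguments.
#'
#' @param path CSV file path.
#' @param V,M defaults for batch volume (L) and sorbent mass (g) when the
#'   file carries no such columns.
#' @return An [isotherm_data()] tibble.
#' @export
read_batch_data <- function(path, V = 0.1, M = 0.05) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"C0" %in% names(df))
    stop("batch data needs a C0 column", call. = FALSE)
  V <- if ("V" %in% names(df)) df$V else V
  M <- if ("M" %in% names(df)) df$M else M
  Ce <- if ("Ce" %in% names(df)) df$Ce
        else if ("removal" %in% names(df)) ce_from_removal(df$C0, df$removal)
        else stop("batch data needs a Ce or removal column", call. = FALSE)
  isotherm_data(Ce = Ce, C0 = df$C0, V = V, M = M)
}

#' Read an uptake time course
#'
#' Reads a CSV with columns `time` (minutes) and either `qt` (mg/g) or a
#' residual-concentration column `Ct` (mg/L, converted through the mass
#' balance using `C0`, `V`, `M`).
#'
#' @param path CSV file path.
#' @param C0 initial concentration, mg/L (needed only for `Ct` input).
#' @param V,M batch volume (L) and sorbent mass (g).
#' @param qe_exp optional equilibrium capacity; defaults to the last `qt`.
#' @return A [kinetic_data()] tibble.
#' @export
read_kinetic_data <- function(path, C0 = NULL, V = 0.1, M = 0.05,
                              qe_exp = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df))
    stop("kinetic data needs a time column", call. = FALSE)
  qt <- if ("qt" %in% names(df)) df$qt
        else if ("Ct" %in% names(df)) {
          if (is.null(C0)) stop("C0 is required to convert Ct to qt",
                                call. = FALSE)
          capacity_qe(C0, df$Ct, V, M)
        } else stop("kinetic data needs a qt or Ct column", call. = FALSE)
  kinetic_data(df$time, qt, qe_exp = qe_exp)
}

#' Serialize an analysis result bundle
#'
#' Writes a named list of tables and scalars as JSON (full precision),
#' with package-version metadata, and reads it back. Requires the
#' `jsonlite` package.
#'
#' @param bundle named list of results (data frames, vectors, scalars).
#' @param path output `.json` path.
#' @param seed optional seed recorded in the metadata.
#' @return `path`, invisibly.
#' @export
write_result_bundle <- function(bundle, path, seed = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for JSON serialization", call. = FALSE)
  out <- list(
    metadata = list(
      package = "biosorb",
      version = as.character(utils::packageVersion("biosorb")),
      seed = seed
    ),
    results = bundle
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_result_bundle
#' @export
read_result_bundle <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for JSON serialization", call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
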