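#' Factor specification for a designed experiment
#'
#' Binds a factor name and unit to its ordered physical levels. An
#' `L_p^2(p^k)` array needs exactly `p` levels per factor.
#'
#' @param name factor label, e.g. `"pH"`.
#' @param unit measurement unit label (may be `""`).
#' @param levels ordered numeric vector of distinct physical level values.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("pH", "", c(5.5, 6.5, 7.5, 8.5, 9.5))
#' @export
factor_spec <- function(name, unit, levels) {
  levels <- as.numeric(levels)
  if (anyDuplicated(levels))
    stop("factor levels must be distinct", call. = FALSE)
  structure(list(name = name, unit = unit, levels = levels),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s%s: %s\n", x$name,
              if (nzchar(x$unit)) paste0(" (", x$unit, ")") else "",
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Factor specifications of the methylene-blue biosorption study
#'
#' The five culture factors varied in the dye-biosorption optimization:
#' pH, incubation time (h), initial methylene-blue concentration (mg/L),
#' glucose (%) and peptone (%), each at five levels.
#'
#' @return A list of five [factor_spec()] objects.
#' @export
mb_factor_specs <- function() {
  list(
    factor_spec("pH", "", c(5.5, 6.5, 7.5, 8.5, 9.5)),
    factor_spec("incubation_time_h", "h", c(24, 36, 48, 60, 72)),
    factor_spec("initial_mb_mgL", "mg/L", c(10, 15, 20, 25, 30)),
    factor_spec("glucose_pct", "%", c(0.5, 1.0, 1.5, 2.0, 2.5)),
    factor_spec("peptone_pct", "%", c(1.0, 1.5, 2.0, 2.5, 3.0))
  )
}

is_prime <- function(p) {
  p <- as.integer(p)
  if (p < 2L) return(FALSE)
  if (p <= 3L) return(TRUE)
  !any(p %% 2:floor(sqrt(p)) == 0L)
}

#' Construct a p-level orthogonal array L_{p^2}(p^k)
#'
#' Builds the `p^2`-run orthogonal array for up to `p + 1` factors at `p`
#' levels (prime `p`) by the Latin-square construction: writing run
#' `r - 1 = p*i + j` with `i, j` in `0..p-1`, column 1 carries `i`,
#' column 2 carries `j`, and column `2 + m` carries `(m*i + j) mod p`
#' (all reported 1-based). For `p = 5`, `k = 5` this is the classical
#' `L25(5^5)` array. Every column is balanced and every ordered pair of
#' levels occurs exactly once in every pair of columns.
#'
#' @param p prime number of levels (default 5).
#' @param n_factors number of factor columns, `2 <= n_factors <= p + 1`.
#' @param factors optional list of [factor_spec()] (one per column) bound
#'   to the design.
#' @return An object of class `oa_design`: a list with elements `p`,
#'   `runs` (a `p^2 x n_factors` integer matrix of 1-based level indices)
#'   and `factors`.
#' @examples
#' d <- build_orthogonal_array(5, 5)
#' d$runs[19, ] # 4 4 2 5 3
#' @export
build_orthogonal_array <- function(p = 5, n_factors = 5, factors = NULL) {
  if (!is_prime(p))
    stop("unsupported design: p must be prime for the Latin-square construction",
         call. = FALSE)
  if (n_factors < 2 || n_factors > p + 1)
    stop(sprintf("array capacity: n_factors must lie in [2, %d] for p = %d",
                 p + 1, p), call. = FALSE)
  r <- 0:(p^2 - 1)
  i <- r %/% p
  j <- r %% p
  cols <- list(i, j)
  if (n_factors > 2) {
    for (m in seq_len(n_factors - 2)) cols[[2 + m]] <- (m * i + j) %% p
  }
  runs <- do.call(cbind, cols) + 1L
  storage.mode(runs) <- "integer"
  colnames(runs) <- if (!is.null(factors)) {
    vapply(factors, function(f) f$name, character(1))
  } else paste0("F", seq_len(n_factors))
  if (!is.null(factors) && length(factors) != n_factors)
    stop("one factor_spec per design column is required", call. = FALSE)
  structure(list(p = as.integer(p), runs = runs, factors = factors),
            class = "oa_design")
}

#' @export
print.oa_design <- function(x, ...) {
  cat(sprintf("<oa_design> L%d(%d^%d): %d runs x %d factors\n",
              nrow(x$runs), x$p, ncol(x$runs), nrow(x$runs), ncol(x$runs)))
  invisible(x)
}

#' Bind physical factor levels to an orthogonal design
#'
#' Maps the 1-based level indices of an `oa_design` to the physical values
#' declared in the factor specifications, producing the run sheet a
#' laboratory would execute.
#'
#' @param design an [build_orthogonal_array()] result.
#' @param specs list of [factor_spec()], one per design column, each with
#'   `p` levels.
#' @return A tibble with `run_id` and one column of physical values per
#'   factor.
#' @export
assign_levels <- function(design, specs = design$factors) {
  stopifnot(inherits(design, "oa_design"))
  if (is.null(specs))
    stop("no factor specifications supplied or bound to the design",
         call. = FALSE)
  if (length(specs) != ncol(design$runs))
    stop("configuration error: one factor_spec per design column required",
         call. = FALSE)
  bad <- vapply(specs, function(s) length(s$levels) != design$p, logical(1))
  if (any(bad))
    stop(sprintf("configuration error: factor(s) %s do not have %d levels",
                 paste(vapply(specs[bad], `[[`, "", "name"), collapse = ", "),
                 design$p), call. = FALSE)
  vals <- vapply(seq_along(specs), function(k) {
    specs[[k]]$levels[design$runs[, k]]
  }, numeric(nrow(design$runs)))
  colnames(vals) <- vapply(specs, function(s) s$name, character(1))
  tibble::as_tibble(cbind(
    tibble::tibble(run_id = paste0("L", seq_len(nrow(design$runs)))),
    tibble::as_tibble(vals)
  ))
}

#' Verify balance and orthogonality of a design
#'
#' Checks that every column contains each level index equally often
#' (balance) and that every ordered pair of levels occurs equally often in
#' every pair of columns (orthogonality), by exhaustive pair counting.
#'
#' @param design an `oa_design`, or a plain integer matrix of level indices.
#' @return A list with logical elements `balanced` and `orthogonal`, plus
#'   `unbalanced_columns` and `offending_pairs` (character vector of
#'   `"colA:colB"` labels for column pairs failing the pair-count test).
#' @export
verify_orthogonality <- function(design) {
  runs <- if (inherits(design, "oa_design")) design$runs else as.matrix(design)
  p <- max(runs)
  n <- nrow(runs)
  k <- ncol(runs)
  reps <- n / p
  balanced_col <- vapply(seq_len(k), function(c) {
    tab <- tabulate(runs[, c], nbins = p)
    all(tab == reps)
  }, logical(1))
  offending <- character(0)
  if (k >= 2) {
    pair_reps <- n / p^2
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        counts <- table(factor(runs[, a], levels = 1:p),
                        factor(runs[, b], levels = 1:p))
        if (!all(counts == pair_reps))
          offending <- c(offending, paste0(colnames(runs)[a], ":",
                                           colnames(runs)[b]))
      }
    }
  }
  list(
    balanced = all(balanced_col),
    orthogonal = length(offending) == 0,
    unbalanced_columns = colnames(runs)[!balanced_col],
    offending_pairs = offending
  )
}

#' Recover level indices from a run sheet of physical values
#'
#' Inverse of [assign_levels()]: matches each physical value back to its
#' declared level index (nearest match within `tol`).
#'
#' @param sheet data frame with one column per factor of physical values.
#' @param specs list of [factor_spec()] in column order.
#' @param tol absolute tolerance for matching a value to a declared level.
#' @return Integer matrix of 1-based level indices.
#' @export
levels_to_indices <- function(sheet, specs, tol = 1e-8) {
  idx <- vapply(seq_along(specs), function(k) {
    s <- specs[[k]]
    x <- as.numeric(sheet[[s$name]])
    out <- integer(length(x))
    for (r in seq_along(x)) {
      d <- abs(s$levels - x[r])
      m <- which.min(d)
      if (d[m] > tol)
        stop(sprintf("value %g in row %d, column '%s' matches no declared level",
                     x[r], r, s$name), call. = FALSE)
      out[r] <- m
    }
    out
  }, integer(nrow(sheet)))
  colnames(idx) <- vapply(specs, function(s) s$name, character(1))
  idx
}
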