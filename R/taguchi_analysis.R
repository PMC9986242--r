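#' Taguchi signal-to-noise ratios
#'
#' Robustness statistics used to pick factor levels that maximize a
#' response while minimizing its sensitivity to noise. For a
#' larger-is-better response with observations `Y_1..Y_n`,
#' `S/N = -10 * log10( mean(1 / Y^2) )` in decibels; with a single
#' observation this reduces to `20 * log10(Y)`. Smaller-is-better and
#' nominal-is-best variants are provided for completeness.
#'
#' @param values positive numeric vector of replicate observations of one
#'   experimental run.
#' @return S/N ratio in dB (scalar).
#' @examples
#' snr_larger_better(87.14) # 38.80 dB
#' @export
snr_larger_better <- function(values) {
  if (length(values) == 0 || any(!is.finite(values)) || any(values <= 0))
    stop("larger-is-better S/N requires strictly positive responses",
         call. = FALSE)
  -10 * log10(mean(1 / values^2))
}

#' @rdname snr_larger_better
#' @export
snr_smaller_better <- function(values) {
  if (length(values) == 0 || any(!is.finite(values)))
    stop("responses must be finite", call. = FALSE)
  -10 * log10(mean(values^2))
}

#' @rdname snr_larger_better
#' @details `snr_nominal_best()` uses the mean/variance form
#'   `10 * log10(ybar^2 / s^2)` and needs at least two replicates.
#' @export
snr_nominal_best <- function(values) {
  if (length(values) < 2)
    stop("nominal-is-best S/N needs at least 2 replicates", call. = FALSE)
  10 * log10(mean(values)^2 / stats::var(values))
}

#' @rdname snr_larger_better
#' @param Y numeric vector of per-run responses (one observation per run),
#'   or a list of replicate vectors.
#' @details `snr_table()` applies the larger-is-better statistic
#'   run-by-run, preserving length.
#' @export
snr_table <- function(Y) {
  if (is.list(Y)) return(vapply(Y, snr_larger_better, numeric(1)))
  vapply(Y, snr_larger_better, numeric(1))
}

check_runs <- function(design, Y) {
  stopifnot(inherits(design, "oa_design"))
  if (length(Y) != nrow(design$runs))
    stop("one response per design run is required", call. = FALSE)
  chk <- verify_orthogonality(design)
  if (!chk$balanced)
    stop("analysis requires a balanced design (equal replication of every level)",
         call. = FALSE)
  invisible(TRUE)
}

#' Level-mean response table with delta and rank
#'
#' For every factor, the mean response at each of its `p` levels, the
#' range of those level means (`delta = max - min`) and the factor ranking
#' by descending delta (rank 1 = most influential; ties broken by column
#' order). The table can be computed on the raw response scale or on the
#' larger-is-better S/N scale.
#'
#' @param design an `oa_design` (balanced).
#' @param Y numeric vector of per-run responses (raw scale).
#' @param scale `"raw"` (default) or `"snr"`.
#' @return An object of class `response_table`: list with `means`
#'   (`p x n_factors` matrix, rows = levels), `delta`, `rank` (named
#'   vectors) and `scale`.
#' @examples
#' d <- build_orthogonal_array(5, 5, mb_factor_specs())
#' y <- mb_taguchi_runs()$removal_actual
#' response_table(d, y)
#' @export
response_table <- function(design, Y, scale = c("raw", "snr")) {
  scale <- match.arg(scale)
  check_runs(design, Y)
  resp <- if (scale == "snr") snr_table(Y) else as.numeric(Y)
  p <- design$p
  k <- ncol(design$runs)
  means <- vapply(seq_len(k), function(c) {
    vapply(seq_len(p), function(l) mean(resp[design$runs[, c] == l]),
           numeric(1))
  }, numeric(p))
  colnames(means) <- colnames(design$runs)
  rownames(means) <- seq_len(p)
  delta <- apply(means, 2, function(x) max(x) - min(x))
  rk <- rank(-delta, ties.method = "first")
  structure(list(means = means, delta = delta, rank = rk, scale = scale),
            class = "response_table")
}

#' @export
print.response_table <- function(x, digits = 2, ...) {
  cat(sprintf("Level-mean response table (%s scale)\n", x$scale))
  out <- rbind(round(x$means, digits),
               Delta = round(x$delta, digits),
               Rank = x$rank)
  print(out)
  invisible(x)
}

#' @rdname response_table
#' @param x a `response_table`.
#' @details `as_response_df()` flattens the table into the conventional
#'   level-by-factor layout with `Delta` and `Rank` rows appended, for CSV
#'   export.
#' @export
as_response_df <- function(x) {
  stopifnot(inherits(x, "response_table"))
  df <- as.data.frame(rbind(x$means, Delta = x$delta, Rank = x$rank))
  tibble::as_tibble(cbind(level = c(rownames(x$means), "Delta", "Rank"), df))
}

#' Optimum level combination from an S/N response table
#'
#' Selects, per factor, the level index whose S/N (or raw) level mean is
#' largest; ties go to the lower index.
#'
#' @param table a [response_table()].
#' @return Named integer vector of optimal level indices, with the
#'   corresponding physical values as attribute `"values"` when the table's
#'   design factors are known.
#' @export
select_optimum <- function(table) {
  stopifnot(inherits(table, "response_table"))
  idx <- apply(table$means, 2, which.max)
  names(idx) <- colnames(table$means)
  idx
}

#' Additive main-effects prediction
#'
#' The Taguchi confirmation estimate for a level combination: the grand
#' mean plus the sum over factors of that factor's level-mean deviation
#' from the grand mean, all on the raw response scale. With `combo = NULL`
#' every run's own combination is predicted, reproducing the fitted values
#' of the additive main-effects model.
#'
#' @param design an `oa_design` (balanced).
#' @param Y per-run responses (raw scale).
#' @param combo integer vector of level indices (one per factor), or
#'   `NULL` for per-run fitted values.
#' @return Predicted response (scalar, or vector of length `nrow(runs)`).
#' @examples
#' d <- build_orthogonal_array(5, 5, mb_factor_specs())
#' y <- mb_taguchi_runs()$removal_actual
#' predict_additive(d, y, combo = d$runs[19, ]) # 87.27
#' @export
predict_additive <- function(design, Y, combo = NULL) {
  check_runs(design, Y)
  g <- mean(Y)
  rt <- response_table(design, Y, scale = "raw")
  one <- function(cmb) {
    if (length(cmb) != ncol(design$runs))
      stop("combo needs one level index per factor", call. = FALSE)
    if (any(cmb < 1 | cmb > design$p))
      stop("invalid level index in combo", call. = FALSE)
    g + sum(rt$means[cbind(cmb, seq_along(cmb))] - g)
  }
  if (is.null(combo)) {
    apply(design$runs, 1, one)
  } else {
    one(as.integer(combo))
  }
}

#' Main-effects ANOVA for a balanced orthogonal design
#'
#' Partitions the total sum of squares of the response into per-factor
#' main-effect sums of squares plus residual. For a balanced `p`-level
#' design, `SS_factor = p_reps * sum((level mean - grand mean)^2)` with
#' `p - 1` degrees of freedom per factor (here each level is seen
#' `n / p` times); the residual picks up what the additive model leaves.
#' F statistics and upper-tail p values are reported against the residual
#' mean square. In a saturated design (residual df = 0) sums of squares
#' are still reported and F/p are `NA` with a flag.
#'
#' @inheritParams response_table
#' @return An object of class `taguchi_anova`: a tibble with columns
#'   `source`, `df`, `sum_sq`, `mean_sq`, `statistic`, `p_value`, with
#'   attributes `r_squared`, `adj_r_squared` and `saturated`.
#' @export
main_effects_anova <- function(design, Y) {
  check_runs(design, Y)
  Y <- as.numeric(Y)
  n <- length(Y)
  p <- design$p
  k <- ncol(design$runs)
  g <- mean(Y)
  reps <- n / p
  ss_fac <- vapply(seq_len(k), function(c) {
    m <- vapply(seq_len(p), function(l) mean(Y[design$runs[, c] == l]),
                numeric(1))
    reps * sum((m - g)^2)
  }, numeric(1))
  ss_tot <- sum((Y - g)^2)
  df_fac <- rep(p - 1, k)
  df_res <- (n - 1) - sum(df_fac)
  ss_res <- ss_tot - sum(ss_fac)
  saturated <- df_res <= 0
  ms_fac <- ss_fac / df_fac
  ms_res <- if (saturated) NA_real_ else ss_res / df_res
  Fval <- if (saturated) rep(NA_real_, k) else ms_fac / ms_res
  pval <- if (saturated) rep(NA_real_, k) else
    stats::pf(Fval, df_fac, df_res, lower.tail = FALSE)
  tab <- tibble::tibble(
    source = c(colnames(design$runs), "Residual", "Total"),
    df = c(df_fac, df_res, n - 1),
    sum_sq = c(ss_fac, ss_res, ss_tot),
    mean_sq = c(ms_fac, rep(ms_res, 1), NA_real_),
    statistic = c(Fval, NA_real_, NA_real_),
    p_value = c(pval, NA_real_, NA_real_)
  )
  attr(tab, "r_squared") <- 1 - ss_res / ss_tot
  attr(tab, "adj_r_squared") <-
    if (saturated) NA_real_ else 1 - (ss_res / df_res) / (ss_tot / (n - 1))
  attr(tab, "saturated") <- saturated
  class(tab) <- c("taguchi_anova", class(tab))
  tab
}

#' @export
print.taguchi_anova <- function(x, ...) {
  NextMethod()
  cat(sprintf("R-squared: %.4f  adjusted R-squared: %.4f%s\n",
              attr(x, "r_squared"), attr(x, "adj_r_squared"),
              if (attr(x, "saturated")) "  [saturated: F/p unavailable]" else ""))
  invisible(x)
}

#' Residual diagnostics for an additive-model fit
#'
#' Residuals (observed minus predicted), their standardization, a
#' Shapiro-Wilk normality test, and a count of sign runs in run order as a
#' crude randomness check.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return List with `residuals`, `standardized`, `mean`,
#'   `shapiro_statistic`, `shapiro_p`, `sign_runs`.
#' @export
residual_diagnostics <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  res <- observed - predicted
  s <- stats::sd(res)
  std <- if (s > 0) res / s else res * 0
  sh <- stats::shapiro.test(res)
  signs <- sign(res[res != 0])
  sign_runs <- if (length(signs)) 1 + sum(diff(signs) != 0) else 0L
  list(
    residuals = res,
    standardized = std,
    mean = mean(res),
    shapiro_statistic = unname(sh$statistic),
    shapiro_p = sh$p.value,
    sign_runs = sign_runs
  )
}
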