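#' Equilibrium isotherm dataset
#'
#' Assembles equilibrium batch data for isotherm fitting. `qe` is computed
#' from the mass balance when not supplied.
#'
#' @param Ce equilibrium concentrations, mg/L.
#' @param qe sorbed capacities, mg/g; computed via [capacity_qe()] from
#'   `C0` when missing.
#' @param C0 optional initial concentrations, mg/L.
#' @param V,M batch volume (L) and sorbent mass (g) used when deriving `qe`.
#' @return A tibble with columns `Ce`, `qe` (and `C0` when known), with
#'   `V`, `M` kept as attributes.
#' @export
isotherm_data <- function(Ce, qe = NULL, C0 = NULL, V = 0.1, M = 0.05) {
  if (is.null(qe)) {
    if (is.null(C0)) stop("either qe or C0 must be supplied", call. = FALSE)
    qe <- capacity_qe(C0, Ce, V, M)
  }
  if (any(Ce < 0) || any(qe < 0))
    stop("Ce and qe must be non-negative", call. = FALSE)
  out <- tibble::tibble(Ce = as.numeric(Ce), qe = as.numeric(qe))
  if (!is.null(C0)) out$C0 <- as.numeric(C0)
  attr(out, "V") <- V
  attr(out, "M") <- M
  out
}

new_isotherm_fit <- function(model, parameters, slope, intercept, r_squared,
                             method, admissible = TRUE, flags = character(0),
                             data = NULL) {
  structure(list(model = model, parameters = parameters, slope = slope,
                 intercept = intercept, r_squared = r_squared,
                 method = method, admissible = admissible, flags = flags,
                 data = data),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("<isotherm_fit> %s (%s): %s; R2 = %.4f%s\n",
              x$model, x$method,
              paste(sprintf("%s = %.4g", names(x$parameters),
                            unlist(x$parameters)), collapse = ", "),
              x$r_squared,
              if (!x$admissible) paste0(" [", paste(x$flags, collapse = "; "), "]")
              else ""))
  invisible(x)
}

check_iso_data <- function(data, need_log_Ce = FALSE, need_pos_qe = FALSE) {
  if (nrow(data) < 3)
    stop("at least 3 equilibrium points are needed for isotherm fitting",
         call. = FALSE)
  if (need_log_Ce && any(data$Ce <= 0))
    stop("log-domain error: Ce must be strictly positive for this model",
         call. = FALSE)
  if (need_pos_qe && any(data$qe <= 0))
    stop("log-domain error: qe must be strictly positive for this model",
         call. = FALSE)
  invisible(TRUE)
}

lin_r2 <- function(fit) r2_of_lm(fit)

#' Fit the Langmuir isotherm
#'
#' Monolayer adsorption on energetically identical sites:
#' `qe = q_m * K_L * Ce / (1 + K_L * Ce)`. The default linear method
#' regresses `Ce/qe` on `Ce` (slope `1/q_m`, intercept `1/(q_m K_L)`), the
#' form whose plot conventionally accompanies reported parameters; the
#' nonlinear method refines by least squares on the untransformed curve,
#' initialized from the linear fit.
#'
#' @param data an [isotherm_data()] tibble (or any data frame with `Ce`,
#'   `qe`).
#' @param method `"linear"` (default) or `"nonlinear"`.
#' @return An `isotherm_fit` with parameters `q_m` (mg/g) and `K_L`
#'   (L/mg), the linear slope/intercept, and the coefficient of
#'   determination of the fitted (transformed, for linear) regression.
#'   Non-positive slope or intercept flags the fit inadmissible rather
#'   than erroring.
#' @export
fit_langmuir <- function(data, method = c("linear", "nonlinear")) {
  method <- match.arg(method)
  check_iso_data(data, need_pos_qe = TRUE)
  if (any(data$Ce <= 0))
    stop("Langmuir linearization Ce/qe vs Ce degenerates at Ce = 0; drop such points",
         call. = FALSE)
  lf <- stats::lm(I(Ce / qe) ~ Ce, data = data)
  slope <- unname(stats::coef(lf)[2])
  intercept <- unname(stats::coef(lf)[1])
  flags <- character(0)
  if (slope <= 0) flags <- c(flags, "non-positive slope: q_m inadmissible")
  if (intercept <= 0) flags <- c(flags, "non-positive intercept: K_L inadmissible")
  q_m <- 1 / slope
  K_L <- slope / intercept
  r2 <- lin_r2(lf)
  fit <- new_isotherm_fit("langmuir", list(q_m = q_m, K_L = K_L),
                          slope, intercept, r2, method,
                          admissible = length(flags) == 0, flags = flags,
                          data = data)
  if (method == "nonlinear") {
    start <- list(q_m = if (q_m > 0) q_m else max(data$qe),
                  K_L = if (K_L > 0) K_L else 0.1)
    nl <- minpack.lm::nlsLM(qe ~ q_m * K_L * Ce / (1 + K_L * Ce),
                            data = data, start = start)
    cf <- stats::coef(nl)
    pred <- stats::predict(nl)
    r2n <- 1 - sum((data$qe - pred)^2) / sum((data$qe - mean(data$qe))^2)
    fit$parameters <- list(q_m = unname(cf["q_m"]), K_L = unname(cf["K_L"]))
    fit$r_squared <- r2n
    fit$admissible <- all(unlist(fit$parameters) > 0)
  }
  fit
}

#' Fit the Freundlich isotherm
#'
#' Empirical multilayer/heterogeneous-surface law `qe = K_F * Ce^(1/n_f)`,
#' fitted by regressing `ln qe` on `ln Ce`: `K_F = exp(intercept)`,
#' `n_f = 1/slope`.
#'
#' @inheritParams fit_langmuir
#' @return An `isotherm_fit` with parameters `K_F` and `n_f`.
#' @export
fit_freundlich <- function(data, method = c("linear", "nonlinear")) {
  method <- match.arg(method)
  check_iso_data(data, need_log_Ce = TRUE, need_pos_qe = TRUE)
  lf <- stats::lm(log(qe) ~ log(Ce), data = data)
  slope <- unname(stats::coef(lf)[2])
  intercept <- unname(stats::coef(lf)[1])
  flags <- character(0)
  if (abs(slope) < 1e-10) {
    flags <- c(flags, "zero slope: n_f unbounded (constant qe)")
    n_f <- Inf
  } else n_f <- 1 / slope
  K_F <- exp(intercept)
  fit <- new_isotherm_fit("freundlich", list(K_F = K_F, n_f = n_f),
                          slope, intercept, lin_r2(lf), method,
                          admissible = length(flags) == 0, flags = flags,
                          data = data)
  if (method == "nonlinear") {
    start <- list(K_F = if (is.finite(K_F)) K_F else 1,
                  inv_n = if (is.finite(n_f) && n_f != 0) 1 / n_f else 0.5)
    nl <- minpack.lm::nlsLM(qe ~ K_F * Ce^inv_n, data = data, start = start)
    cf <- stats::coef(nl)
    pred <- stats::predict(nl)
    fit$parameters <- list(K_F = unname(cf["K_F"]), n_f = 1 / unname(cf["inv_n"]))
    fit$r_squared <- 1 - sum((data$qe - pred)^2) /
      sum((data$qe - mean(data$qe))^2)
  }
  fit
}

#' Fit the Temkin isotherm
#'
#' Adsorption with linearly falling heat of adsorption:
#' `qe = B * ln(K_T * Ce)`, fitted by regressing `qe` on `ln Ce`:
#' `B = slope`, `K_T = exp(intercept / B)`.
#'
#' @inheritParams fit_langmuir
#' @return An `isotherm_fit` with parameters `B` and `K_T`.
#' @export
fit_temkin <- function(data, method = c("linear", "nonlinear")) {
  method <- match.arg(method)
  check_iso_data(data, need_log_Ce = TRUE)
  lf <- stats::lm(qe ~ log(Ce), data = data)
  slope <- unname(stats::coef(lf)[2])
  intercept <- unname(stats::coef(lf)[1])
  if (abs(slope) < 1e-10)
    stop("degenerate Temkin fit: B ~ 0, K_T undefined", call. = FALSE)
  flags <- character(0)
  if (slope <= 0) flags <- c(flags, "non-positive B: inadmissible heat term")
  B <- slope
  K_T <- exp(intercept / B)
  fit <- new_isotherm_fit("temkin", list(B = B, K_T = K_T),
                          slope, intercept, lin_r2(lf), method,
                          admissible = length(flags) == 0, flags = flags,
                          data = data)
  if (method == "nonlinear") {
    nl <- minpack.lm::nlsLM(qe ~ B * log(K_T * Ce), data = data,
                            start = list(B = B, K_T = max(K_T, 1e-6)))
    cf <- stats::coef(nl)
    pred <- stats::predict(nl)
    fit$parameters <- list(B = unname(cf["B"]), K_T = unname(cf["K_T"]))
    fit$r_squared <- 1 - sum((data$qe - pred)^2) /
      sum((data$qe - mean(data$qe))^2)
  }
  fit
}

#' Fit and rank all three isotherm models
#'
#' Fits Langmuir, Freundlich and Temkin to the same equilibrium data and
#' orders the fits by descending coefficient of determination (ties broken
#' by that model order). Models whose preconditions fail are excluded with
#' the error recorded.
#'
#' @inheritParams fit_langmuir
#' @return List with `fits` (ranked list of `isotherm_fit`) and `excluded`
#'   (named character vector of failure reasons).
#' @export
compare_isotherms <- function(data, method = c("linear", "nonlinear")) {
  method <- match.arg(method)
  fitters <- list(langmuir = fit_langmuir, freundlich = fit_freundlich,
                  temkin = fit_temkin)
  fits <- list()
  excluded <- character(0)
  for (m in names(fitters)) {
    res <- tryCatch(fitters[[m]](data, method),
                    error = function(e) conditionMessage(e))
    if (inherits(res, "isotherm_fit")) fits[[m]] <- res
    else excluded[m] <- res
  }
  ord <- order(-vapply(fits, `[[`, numeric(1), "r_squared"),
               match(names(fits), names(fitters)))
  list(fits = fits[ord], excluded = excluded)
}

#' Evaluate an isotherm law
#'
#' Predicted `qe` at concentrations `Ce` for a named model and parameter
#' list (as in an `isotherm_fit`).
#'
#' @param model `"langmuir"`, `"freundlich"` or `"temkin"`.
#' @param params named list/vector of model parameters.
#' @param Ce concentrations, mg/L.
#' @return Numeric vector of capacities, mg/g.
#' @export
isotherm_qe <- function(model, params, Ce) {
  p <- as.list(params)
  switch(model,
    langmuir = p$q_m * p$K_L * Ce / (1 + p$K_L * Ce),
    freundlich = p$K_F * Ce^(1 / p$n_f),
    temkin = p$B * log(p$K_T * Ce),
    stop("unknown isotherm model: ", model, call. = FALSE)
  )
}

#' Isotherm parameter report
#'
#' Flattens a set of isotherm fits into a long table of model, parameter,
#' value rows (including each model's R-squared), the conventional layout
#' of published isotherm parameter tables.
#'
#' @param fits list of `isotherm_fit` objects (e.g. `compare_isotherms()$fits`).
#' @return A tibble with columns `model`, `parameter`, `value`.
#' @export
isotherm_report <- function(fits) {
  rows <- lapply(fits, function(f) {
    tibble::tibble(
      model = f$model,
      parameter = c(names(f$parameters), "R2"),
      value = c(unlist(f$parameters), f$r_squared)
    )
  })
  do.call(rbind, rows)
}
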