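#' Uptake time-course dataset
#'
#' Sorbed amount `qt` (mg/g) sampled at strictly increasing contact times
#' (minutes). `qe_exp`, the experimental equilibrium capacity, defaults to
#' the final-time `qt` (the observed plateau) and feeds the
#' pseudo-first-order log transform.
#'
#' @param times contact times in minutes, strictly increasing, positive.
#' @param qt sorbed amounts, mg/g, non-negative.
#' @param qe_exp experimental equilibrium capacity, mg/g; defaults to
#'   `qt` at the last time point.
#' @param tol slack allowed for `qe_exp` below `max(qt)` before erroring.
#' @return A tibble with columns `time` and `qt`; `qe_exp` is kept as an
#'   attribute.
#' @export
kinetic_data <- function(times, qt, qe_exp = NULL, tol = 1e-8) {
  times <- as.numeric(times)
  qt <- as.numeric(qt)
  if (length(times) != length(qt))
    stop("times and qt must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(times <= 0))
    stop("times must be positive (log-based models need t > 0)", call. = FALSE)
  if (any(qt < 0)) stop("qt must be non-negative", call. = FALSE)
  if (is.null(qe_exp)) qe_exp <- qt[length(qt)]
  if (qe_exp < max(qt) - tol)
    stop("qe_exp below the observed maximum uptake", call. = FALSE)
  out <- tibble::tibble(time = times, qt = qt)
  attr(out, "qe_exp") <- qe_exp
  out
}

qe_exp_of <- function(data) {
  qe <- attr(data, "qe_exp")
  if (is.null(qe)) qe <- max(data$qt)
  qe
}

new_kinetic_fit <- function(model, parameters, slope, intercept, r_squared,
                            admissible = TRUE, flags = character(0),
                            extra = list()) {
  structure(c(list(model = model, parameters = parameters, slope = slope,
                   intercept = intercept, r_squared = r_squared,
                   admissible = admissible, flags = flags), extra),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  pars <- if (is.data.frame(x$parameters)) {
    paste0(nrow(x$parameters), " segments")
  } else {
    paste(sprintf("%s = %.4g", names(x$parameters), unlist(x$parameters)),
          collapse = ", ")
  }
  cat(sprintf("<kinetic_fit> %s: %s; R2 = %s%s\n", x$model, pars,
              paste(round(x$r_squared, 4), collapse = ", "),
              if (!x$admissible) paste0(" [", paste(x$flags, collapse = "; "), "]")
              else ""))
  invisible(x)
}

#' Pseudo-first-order (Lagergren) kinetic fit
#'
#' Linearized form `ln(qe - qt) = ln(qe_cal) - k1 * t`, regressed over the
#' points with `qt < qe_exp` (others are excluded from the log transform
#' and reported). `k1 = -slope` (1/min), `qe_cal = exp(intercept)` (mg/g).
#' A negative `k1` estimate (positive slope) is flagged, not hidden.
#'
#' @param data a [kinetic_data()] tibble.
#' @param qe_exp equilibrium capacity used in the transform; defaults to
#'   the dataset attribute.
#' @return A `kinetic_fit` with parameters `qe_cal`, `k1`, the excluded
#'   time points (`excluded`), and the relative gap `qe_gap` between
#'   `qe_cal` and `qe_exp`.
#' @export
fit_pfo <- function(data, qe_exp = NULL) {
  if (is.null(qe_exp)) qe_exp <- qe_exp_of(data)
  use <- data$qt < qe_exp
  excluded <- data$time[!use]
  if (sum(use) < 3)
    stop("fewer than 3 usable points (qt < qe_exp) for the PFO log transform",
         call. = FALSE)
  d <- data[use, ]
  y <- log(qe_exp - d$qt)
  lf <- stats::lm(y ~ d$time)
  slope <- unname(stats::coef(lf)[2])
  intercept <- unname(stats::coef(lf)[1])
  flags <- character(0)
  if (abs(slope) < 1e-12) flags <- c(flags, "zero slope: k1 = 0 (no kinetics)")
  if (slope > 0) flags <- c(flags, "positive slope: negative k1 estimate")
  new_kinetic_fit("pfo",
                  list(qe_cal = exp(intercept), k1 = -slope),
                  slope, intercept, r2_of_lm(lf),
                  admissible = length(flags) == 0, flags = flags,
                  extra = list(qe_exp = qe_exp, excluded = excluded,
                               qe_gap = abs(exp(intercept) - qe_exp) / qe_exp))
}

#' Pseudo-second-order kinetic fit
#'
#' Linearized form `t/qt = 1/(k2 * qe^2) + t/qe`, regressed as `t/qt` on
#' `t`: `qe_cal = 1/slope` (mg/g), `k2 = slope^2 / intercept` (g/mg/min).
#' Consistency of the second-order law with uptake data is conventionally
#' read as chemisorption control.
#'
#' @inheritParams fit_pfo
#' @return A `kinetic_fit` with parameters `qe_cal`, `k2` and the relative
#'   gap `qe_gap` to `qe_exp`.
#' @export
fit_pso <- function(data, qe_exp = NULL) {
  if (is.null(qe_exp)) qe_exp <- qe_exp_of(data)
  if (any(data$qt <= 0))
    stop("PSO linearization t/qt needs strictly positive qt", call. = FALSE)
  if (nrow(data) < 3) stop("at least 3 points required", call. = FALSE)
  lf <- stats::lm(I(time / qt) ~ time, data = data)
  slope <- unname(stats::coef(lf)[2])
  intercept <- unname(stats::coef(lf)[1])
  flags <- character(0)
  if (slope <= 0) flags <- c(flags, "non-positive slope: qe_cal inadmissible")
  if (intercept <= 0) flags <- c(flags, "non-positive intercept: k2 inadmissible")
  qe_cal <- 1 / slope
  new_kinetic_fit("pso",
                  list(qe_cal = qe_cal, k2 = slope^2 / intercept),
                  slope, intercept, r2_of_lm(lf),
                  admissible = length(flags) == 0, flags = flags,
                  extra = list(qe_exp = qe_exp,
                               qe_gap = abs(qe_cal - qe_exp) / qe_exp))
}

#' Elovich kinetic fit
#'
#' Logarithmic chemisorption law. The default `"literal"` parameterization
#' is the linear reading `qt = alpha + beta * ln t`, reporting the
#' regression intercept as `alpha` (mg/g/min) and slope as `beta` (g/mg) —
#' the form under which published parameter pairs for this system are
#' mutually consistent. The `"standard"` parameterization maps the same
#' regression onto the classical `qt = (1/b) ln(a*b) + (1/b) ln t`, with
#' `b = 1/slope` and `a = slope * exp(intercept/slope)`.
#'
#' @inheritParams fit_pfo
#' @param parameterization `"literal"` (default) or `"standard"`.
#' @return A `kinetic_fit` with parameters `alpha`, `beta` (literal) or
#'   `a`, `b` (standard).
#' @export
fit_elovich <- function(data, parameterization = c("literal", "standard")) {
  parameterization <- match.arg(parameterization)
  if (nrow(data) < 3) stop("at least 3 points required", call. = FALSE)
  lf <- stats::lm(qt ~ log(time), data = data)
  slope <- unname(stats::coef(lf)[2])
  intercept <- unname(stats::coef(lf)[1])
  flags <- character(0)
  if (abs(slope) < 1e-12) flags <- c(flags, "zero slope: degenerate (constant qt)")
  else if (slope < 0) flags <- c(flags, "negative slope: inadmissible desorption trend")
  params <- if (parameterization == "literal") {
    list(alpha = intercept, beta = slope)
  } else {
    if (length(flags)) list(a = NA_real_, b = NA_real_)
    else list(a = slope * exp(intercept / slope), b = 1 / slope)
  }
  new_kinetic_fit("elovich", params, slope, intercept,
                  r2_of_lm(lf),
                  admissible = length(flags) == 0, flags = flags,
                  extra = list(parameterization = parameterization))
}

ipd_segment_fit <- function(time, qt, origin_tol) {
  x <- sqrt(time)
  lf <- stats::lm(qt ~ x)
  slope <- unname(stats::coef(lf)[2])
  intercept <- unname(stats::coef(lf)[1])
  r2 <- if (length(qt) > 2) r2_of_lm(lf) else 1
  c(k_id = slope, c = intercept, r_squared = r2,
    through_origin = as.numeric(abs(intercept) <= origin_tol))
}

#' Weber-Morris intraparticle-diffusion fit
#'
#' Regresses `qt` on the square root of time, per segment:
#' `qt = k_id * sqrt(t) + c`. A line through the origin (`c ~ 0`) signals
#' pure intraparticle control; multi-linearity signals successive
#' film-diffusion, pore-diffusion and equilibrium stages. Segments can be
#' given explicitly (as the last time of each leading segment) or found
#' automatically by exhaustive search over the observed time grid
#' minimizing total residual sum of squares.
#'
#' @inheritParams fit_pfo
#' @param breakpoints `"auto"` or a numeric vector of segment-boundary
#'   times (the last time point included in each segment but the final
#'   one).
#' @param n_segments number of segments searched in `"auto"` mode.
#' @param min_points minimum points per segment (default 3).
#' @param origin_tol absolute tolerance on the intercept for the
#'   through-origin flag.
#' @return A `kinetic_fit` whose `parameters` is a tibble with one row per
#'   segment (`k_id`, `c`, `r_squared`, `through_origin`, `from`, `to`);
#'   `r_squared` on the fit object is the per-segment vector.
#' @export
fit_ipd <- function(data, breakpoints = "auto", n_segments = 1,
                    min_points = 3, origin_tol = 1e-6) {
  n <- nrow(data)
  if (identical(breakpoints, "auto")) {
    if (n_segments < 1) stop("n_segments must be >= 1", call. = FALSE)
    if (n_segments * min_points > n)
      stop("infeasible segmentation: not enough points for the requested segments",
           call. = FALSE)
    cuts <- best_ipd_cuts(data$time, data$qt, n_segments, min_points)
  } else {
    bp <- as.numeric(breakpoints)
    cuts <- vapply(bp, function(b) {
      w <- which(data$time <= b)
      if (!length(w)) stop("breakpoint before first time point", call. = FALSE)
      max(w)
    }, integer(1))
    if (any(diff(c(0, cuts, n)) < 2))
      stop("infeasible segmentation: each segment needs at least 2 points",
           call. = FALSE)
  }
  bounds <- cbind(c(1, cuts + 1), c(cuts, n))
  segs <- lapply(seq_len(nrow(bounds)), function(s) {
    idx <- bounds[s, 1]:bounds[s, 2]
    est <- ipd_segment_fit(data$time[idx], data$qt[idx], origin_tol)
    tibble::tibble(segment = s, from = data$time[bounds[s, 1]],
                   to = data$time[bounds[s, 2]],
                   k_id = est["k_id"], c = est["c"],
                   r_squared = est["r_squared"],
                   through_origin = est["through_origin"] > 0)
  })
  segs <- do.call(rbind, segs)
  new_kinetic_fit("ipd", segs, segs$k_id, segs$c, segs$r_squared,
                  extra = list(cuts = cuts))
}

# exhaustive search over interior cut positions (short series make this cheap)
best_ipd_cuts <- function(time, qt, n_segments, min_points) {
  n <- length(time)
  if (n_segments == 1) return(integer(0))
  x <- sqrt(time)
  seg_rss <- function(idx) {
    lf <- stats::lm(qt[idx] ~ x[idx])
    sum(stats::resid(lf)^2)
  }
  candidates <- utils::combn(seq_len(n - 1), n_segments - 1, simplify = FALSE)
  best <- NULL
  best_rss <- Inf
  for (cand in candidates) {
    sizes <- diff(c(0, cand, n))
    if (any(sizes < min_points)) next
    bounds <- cbind(c(1, cand + 1), c(cand, n))
    rss <- sum(vapply(seq_len(nrow(bounds)), function(s)
      seg_rss(bounds[s, 1]:bounds[s, 2]), numeric(1)))
    if (rss < best_rss) {
      best_rss <- rss
      best <- cand
    }
  }
  if (is.null(best))
    stop("infeasible segmentation: min_points too large for series length",
         call. = FALSE)
  best
}

#' Fit and rank the four kinetic models
#'
#' Fits pseudo-first-order, pseudo-second-order, Elovich and (single
#' segment) intraparticle diffusion to the same time course and ranks by
#' descending coefficient of determination (ties by that model order).
#' The PFO/PSO calculated-vs-experimental equilibrium-capacity gaps are
#' reported alongside, since a high R2 with a wildly wrong `qe_cal` is the
#' classical sign of a misapplied first-order fit.
#'
#' @inheritParams fit_pfo
#' @return List with `fits` (ranked), `excluded` (failure reasons) and
#'   `qe_gaps` (named numeric, PFO/PSO relative gaps).
#' @export
compare_kinetics <- function(data, qe_exp = NULL) {
  if (is.null(qe_exp)) qe_exp <- qe_exp_of(data)
  fitters <- list(
    pfo = function(d) fit_pfo(d, qe_exp),
    pso = function(d) fit_pso(d, qe_exp),
    elovich = function(d) fit_elovich(d),
    ipd = function(d) fit_ipd(d, n_segments = 1)
  )
  fits <- list()
  excluded <- character(0)
  for (m in names(fitters)) {
    res <- tryCatch(fitters[[m]](data), error = function(e) conditionMessage(e))
    if (inherits(res, "kinetic_fit")) fits[[m]] <- res
    else excluded[m] <- res
  }
  r2 <- vapply(fits, function(f) f$r_squared[1], numeric(1))
  ord <- order(-r2, match(names(fits), names(fitters)))
  gaps <- vapply(fits[intersect(names(fits), c("pfo", "pso"))],
                 function(f) f$qe_gap, numeric(1))
  list(fits = fits[ord], excluded = excluded, qe_gaps = gaps)
}

#' Evaluate a kinetic rate law
#'
#' Predicted uptake `qt` at times `t` for a named model and parameter
#' list. PFO: `qe(1 - exp(-k1 t))`; PSO: `qe^2 k2 t / (1 + qe k2 t)`;
#' Elovich (literal): `alpha + beta ln t`; IPD: `k_id sqrt(t) + c`
#' (single segment).
#'
#' @param model `"pfo"`, `"pso"`, `"elovich"` or `"ipd"`.
#' @param params named list of parameters (`qe`, `k1` / `qe`, `k2` /
#'   `alpha`, `beta` / `k_id`, `c`).
#' @param t times in minutes.
#' @return Numeric vector of uptakes, mg/g.
#' @export
kinetic_qt <- function(model, params, t) {
  p <- as.list(params)
  switch(model,
    pfo = p$qe * (1 - exp(-p$k1 * t)),
    pso = p$qe^2 * p$k2 * t / (1 + p$qe * p$k2 * t),
    elovich = p$alpha + p$beta * log(t),
    ipd = p$k_id * sqrt(t) + p$c,
    stop("unknown kinetic model: ", model, call. = FALSE)
  )
}

#' Kinetic parameter report
#'
#' Long table of model, parameter, value rows for a set of kinetic fits,
#' the conventional layout of published kinetic parameter tables.
#' Regression-derived equilibrium capacities are always labelled
#' `qe_cal`; the data-derived one `qe_exp`.
#'
#' @param fits list of `kinetic_fit` objects (e.g. `compare_kinetics()$fits`).
#' @return A tibble with columns `model`, `parameter`, `value`.
#' @export
kinetic_report <- function(fits) {
  rows <- lapply(fits, function(f) {
    if (is.data.frame(f$parameters)) {
      seg <- f$parameters
      tibble::tibble(
        model = f$model,
        parameter = c(outer(paste0(c("k_id", "c", "R2"), "_seg"),
                            seg$segment, paste0)),
        value = c(t(cbind(seg$k_id, seg$c, seg$r_squared)))
      )
    } else {
      pars <- c(unlist(f$parameters),
                if (!is.null(f$qe_exp)) c(qe_exp = f$qe_exp),
                R2 = f$r_squared)
      tibble::tibble(model = f$model, parameter = names(pars),
                     value = unname(pars))
    }
  })
  do.call(rbind, rows)
}
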