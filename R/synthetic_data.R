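#' Seeded RNG scope
#'
#' Runs `expr` under `set.seed(seed)` (Mersenne-Twister) without touching
#' the caller's RNG state; with `seed = NULL` the expression runs on the
#' current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

#' Simulate responses of an additive main-effects designed experiment
#'
#' Generates one response per design run as
#' `Y = grand_mean + sum_f effect[f, level] + N(0, sd)`. Per-factor effect
#' vectors are centred to sum to zero so `grand_mean` stays the expected
#' overall mean. Non-positive responses (which would break a
#' larger-is-better log transform) are flagged via the `clipped` column.
#'
#' @param design an `oa_design`.
#' @param grand_mean expected overall response.
#' @param effects list (one numeric vector of length `p` per factor) of
#'   level deviations; recycled names from the design columns.
#' @param sd additive Gaussian noise standard deviation (response units).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A tibble with `run_id`, `Y`, `clipped`; the noiseless truth is
#'   kept in attributes `truth` (per-run expected response) and `effects`
#'   (the centred effect list).
#' @export
gen_taguchi_responses <- function(design, grand_mean, effects, sd = 0,
                                  seed = NULL) {
  stopifnot(inherits(design, "oa_design"))
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  k <- ncol(design$runs)
  if (length(effects) != k)
    stop("one effect vector per factor is required", call. = FALSE)
  effects <- lapply(effects, function(e) {
    if (length(e) != design$p)
      stop("each effect vector needs one entry per level", call. = FALSE)
    e - mean(e)
  })
  names(effects) <- colnames(design$runs)
  truth <- grand_mean + Reduce(`+`, lapply(seq_len(k), function(c)
    effects[[c]][design$runs[, c]]))
  Y <- with_seed(seed, truth + stats::rnorm(length(truth), 0, sd))
  out <- tibble::tibble(
    run_id = paste0("L", seq_along(Y)),
    Y = Y,
    clipped = Y <= 0
  )
  attr(out, "truth") <- truth
  attr(out, "effects") <- effects
  attr(out, "grand_mean") <- grand_mean
  out
}

#' Simulate an equilibrium isotherm batch series
#'
#' For each initial concentration, solves the batch mass balance
#' `(C0 - Ce) * V / M = isotherm(Ce)` for the equilibrium concentration
#' `Ce` by bracketed root-finding on `[0, C0]`, then perturbs the capacity
#' multiplicatively: `qe_obs = qe * (1 + N(0, noise))`. At `noise = 0` the
#' triple `(C0, Ce, qe)` is mass-balance consistent to the root-finder
#' tolerance.
#'
#' @param model `"langmuir"`, `"freundlich"` or `"temkin"`.
#' @param params named parameters for [isotherm_qe()].
#' @param C0 vector of initial concentrations, mg/L.
#' @param V,M batch volume (L) and sorbent mass (g).
#' @param noise multiplicative noise fraction on `qe` (e.g. `0.02`).
#' @param seed integer seed.
#' @param tol absolute root-finding tolerance on `Ce`.
#' @return An [isotherm_data()] tibble with columns `Ce`, `qe`, `C0`, and
#'   attribute `truth` (model, params, noiseless `qe`).
#' @export
gen_isotherm_dataset <- function(model, params, C0, V = 0.1, M = 0.05,
                                 noise = 0, seed = NULL, tol = 1e-12) {
  if (noise < 0) stop("noise must be non-negative", call. = FALSE)
  if (any(C0 <= 0)) stop("C0 must be positive", call. = FALSE)
  Ce <- vapply(C0, function(c0) {
    f <- function(ce) (c0 - ce) * V / M - isotherm_qe(model, params, ce)
    lo <- c0 * 1e-12 # keep log-based laws finite at the bracket edge
    if (f(lo) < 0)
      stop("generation error: no mass-balance root in (0, C0] for these parameters",
           call. = FALSE)
    stats::uniroot(f, lower = lo, upper = c0, tol = tol)$root
  }, numeric(1))
  qe_true <- (C0 - Ce) * V / M
  qe <- with_seed(seed,
                  qe_true * (1 + stats::rnorm(length(qe_true), 0, noise)))
  out <- isotherm_data(Ce = Ce, qe = qe, C0 = C0, V = V, M = M)
  attr(out, "truth") <- list(model = model, params = params, qe = qe_true)
  out
}

#' Simulate an uptake time course
#'
#' Evaluates the chosen rate law at the sampling times and adds Gaussian
#' noise. Negative values (possible at high noise) are clipped to zero and
#' flagged.
#'
#' @param model `"pfo"`, `"pso"`, `"elovich"` or `"ipd"` (see
#'   [kinetic_qt()] for parameter names).
#' @param params named parameter list.
#' @param times sampling times, minutes, strictly increasing.
#' @param noise additive Gaussian noise standard deviation, mg/g.
#' @param seed integer seed.
#' @param qe_exp equilibrium capacity stored on the dataset; defaults to
#'   the model's own asymptote (PFO/PSO `qe`) or the final noiseless value.
#' @return A [kinetic_data()] tibble with attribute `truth` and a
#'   `clipped` column.
#' @export
gen_kinetic_series <- function(model, params, times = seq(5, 120, by = 5),
                               noise = 0, seed = NULL, qe_exp = NULL) {
  if (noise < 0) stop("noise must be non-negative", call. = FALSE)
  qt_true <- kinetic_qt(model, params, times)
  if (any(!is.finite(qt_true)))
    stop("generation error: rate law non-finite at the requested times",
         call. = FALSE)
  qt <- with_seed(seed, qt_true + stats::rnorm(length(times), 0, noise))
  clipped <- qt < 0
  qt[clipped] <- 0
  if (is.null(qe_exp)) {
    p <- as.list(params)
    qe_exp <- if (model %in% c("pfo", "pso")) p$qe
              else max(qt_true[length(qt_true)], max(qt))
  }
  out <- kinetic_data(times, qt, qe_exp = max(qe_exp, max(qt)))
  out$clipped <- clipped
  attr(out, "truth") <- list(model = model, params = params, qt = qt_true)
  out
}

#' Main-effect deviations observed in the methylene-blue study
#'
#' Per-factor level-mean deviations from the grand mean, computed from the
#' packaged run sheet. These are the natural "true effects" for
#' study-like simulations with [gen_taguchi_responses()].
#'
#' @return Named list of five length-5 centred effect vectors.
#' @export
mb_taguchi_effects <- function() {
  d <- build_orthogonal_array(5, 5, mb_factor_specs())
  Y <- mb_taguchi_runs()$removal_actual
  rt <- response_table(d, Y)
  g <- mean(Y)
  effs <- lapply(seq_len(ncol(rt$means)), function(c) rt$means[, c] - g)
  names(effs) <- colnames(rt$means)
  effs
}

#' Study conditions of the methylene-blue biosorption experiments
#'
#' The packaged preset mirroring the experimental setup analysed
#' throughout: the five-factor L25 design with its physical levels, the
#' batch geometry (0.1 L, 0.05 g), the observed overall removal mean, the
#' Langmuir parameters of the equilibrium series, the pseudo-second-order
#' parameters of the 10 mg/L time course, and the sampling grids.
#'
#' @return Named list of condition values.
#' @export
mb_study_conditions <- function() {
  list(
    specs = mb_factor_specs(),
    V = 0.1, M = 0.05,
    grand_mean = 75.19,
    taguchi_sd = 0.5,
    isotherm_C0 = c(5, 10, 25, 50, 100, 150, 200),
    langmuir = list(q_m = 68.827, K_L = 0.100),
    freundlich = list(K_F = 376.150, n_f = 2.940),
    temkin = list(B = 9.962, K_T = 3.775),
    kinetic_times = seq(5, 120, by = 5),
    pso = list(qe = 16.215, k2 = 0.008),
    pfo = list(qe = 14.102, k1 = 0.02),
    elovich = list(alpha = 1.392, beta = 3.29),
    ipd = list(k_id = 1.53, c = 3.745)
  )
}
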