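#' Batch mass-balance quantities for sorption experiments
#'
#' A batch sorption point is described by the initial sorbate concentration
#' `C0` (mg/L), the residual (equilibrium) concentration `Ce` (mg/L), the
#' solution volume `V` (L) and the dry sorbent mass `M` (g). Removal
#' percentage and sorbed capacity follow from the mass balance over the
#' liquid phase. Defaults `V = 0.1` L and `M = 0.05` g are the batch setup
#' used throughout: 100 mL of dye solution contacted with 50 mg of dried
#' biomass.
#'
#' @param C0 initial sorbate concentration, mg/L (non-negative).
#' @param Ce equilibrium sorbate concentration, mg/L; must satisfy
#'   `0 <= Ce <= C0`.
#' @param V solution volume in litres (positive).
#' @param M sorbent dry mass in grams (positive).
#' @return [batch_point()] returns a tibble with columns `C0`, `Ce`, `V`,
#'   `M`, `removal` (percent) and `qe` (mg/g).
#' @examples
#' batch_point(C0 = 10, Ce = 2.9491)
#' removal_percent(10, 2.9491) # 70.509
#' capacity_qe(10, 2.9491)    # 14.1018 mg/g
#' @export
batch_point <- function(C0, Ce, V = 0.1, M = 0.05) {
  n <- max(length(C0), length(Ce))
  pts <- tibble::tibble(
    C0 = rep_len(as.numeric(C0), n),
    Ce = rep_len(as.numeric(Ce), n),
    V = rep_len(as.numeric(V), n),
    M = rep_len(as.numeric(M), n)
  )
  validate_batch(pts$C0, pts$Ce, pts$V, pts$M)
  pts$removal <- removal_percent(pts$C0, pts$Ce)
  pts$qe <- capacity_qe(pts$C0, pts$Ce, pts$V, pts$M)
  pts
}

validate_batch <- function(C0, Ce, V = 0.1, M = 0.05) {
  if (any(!is.finite(C0)) || any(C0 < 0))
    stop("C0 must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(Ce)) || any(Ce < 0))
    stop("Ce must be finite and non-negative", call. = FALSE)
  if (any(Ce > C0))
    stop("Ce exceeds C0: equilibrium concentration cannot exceed the initial one",
         call. = FALSE)
  if (any(V <= 0) || any(M <= 0))
    stop("V and M must be positive", call. = FALSE)
  invisible(TRUE)
}

#' @rdname batch_point
#' @details `removal_percent()` computes `100 * (C0 - Ce) / C0`, the
#'   percentage of sorbate removed from solution; it requires `C0 > 0`.
#' @export
removal_percent <- function(C0, Ce) {
  validate_batch(C0, Ce)
  if (any(C0 == 0))
    stop("removal percentage is undefined at C0 = 0", call. = FALSE)
  100 * (C0 - Ce) / C0
}

#' @rdname batch_point
#' @param R removal percentage, in `[0, 100]`.
#' @details `ce_from_removal()` inverts the removal equation:
#'   `Ce = C0 * (1 - R/100)`. Useful when a study reports removal
#'   percentages rather than residual concentrations.
#' @export
ce_from_removal <- function(C0, R) {
  if (any(!is.finite(R)) || any(R < 0) || any(R > 100))
    stop("R must lie in [0, 100]", call. = FALSE)
  if (any(C0 < 0)) stop("C0 must be non-negative", call. = FALSE)
  C0 * (1 - R / 100)
}

#' @rdname batch_point
#' @details `capacity_qe()` computes the sorbed amount per unit sorbent mass,
#'   `qe = (C0 - Ce) * V / M` in mg of sorbate per g of sorbent.
#' @export
capacity_qe <- function(C0, Ce, V = 0.1, M = 0.05) {
  validate_batch(C0, Ce, V, M)
  (C0 - Ce) * V / M
}

#' Langmuir separation factor
#'
#' The dimensionless separation factor `RL = 1 / (1 + b * C0)` classifies a
#' Langmuir-type sorption process at initial concentration `C0`:
#' `0 < RL < 1` favorable, `RL > 1` unfavorable (impossible for
#' non-negative `b`, kept for completeness), `RL = 0` irreversible and
#' `RL = 1` linear.
#'
#' @param b Langmuir affinity constant, L/mg (non-negative).
#' @param C0 initial sorbate concentration, mg/L (non-negative).
#' @param tol absolute tolerance used when deciding the boundary categories
#'   `RL = 0` (irreversible) and `RL = 1` (linear).
#' @return A tibble with columns `RL` and `category`.
#' @examples
#' separation_factor(b = 0.100, C0 = 10) # RL = 0.500, favorable
#' @export
separation_factor <- function(b, C0, tol = 1e-12) {
  if (any(b < 0) || any(C0 < 0))
    stop("b and C0 must be non-negative", call. = FALSE)
  n <- max(length(b), length(C0))
  b <- rep_len(as.numeric(b), n)
  C0 <- rep_len(as.numeric(C0), n)
  RL <- 1 / (1 + b * C0)
  category <- ifelse(RL <= tol, "irreversible",
              ifelse(abs(RL - 1) <= tol, "linear",
              ifelse(RL > 1, "unfavorable", "favorable")))
  tibble::tibble(RL = RL, category = category)
}
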