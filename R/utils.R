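# Coefficient of determination of a fitted lm, computed directly so that
# exact (zero-residual) fits report R^2 = 1 without the summary.lm
# near-perfect-fit warning. Returns NA for a response with zero variance.
r2_of_lm <- function(fit) {
  r <- stats::resid(fit)
  y <- stats::fitted(fit) + r
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) return(NA_real_)
  1 - sum(r^2) / tss
}
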