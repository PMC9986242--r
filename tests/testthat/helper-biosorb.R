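# Shared fixtures: the study's L25 design with its factor levels bound,
# and the packaged run sheet.
mb_design <- function() build_orthogonal_array(5, 5, mb_factor_specs())

mb_runs <- function() mb_taguchi_runs()

# brute-force additive prediction, independent of predict_additive():
# fit the cell-means deviations by explicit averaging over data subsets
oracle_additive <- function(sheet, fac_cols, y_col, row) {
  Y <- sheet[[y_col]]
  g <- mean(Y)
  g + sum(vapply(fac_cols, function(f) {
    mean(Y[sheet[[f]] == sheet[[f]][row]]) - g
  }, numeric(1)))
}
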