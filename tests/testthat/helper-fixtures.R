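# Shared fixtures: small generators used across test files.

# Noiseless Page-model moisture-ratio series on a 30-min grid.
page_mr <- function(k, n, total_min = 210, temperature_C = NA_real_) {
  tt <- seq(0, total_min, by = 30)
  mr_series(tt, evaluate_model("page", c(k = k, n = n), tt / 60),
            temperature_C = temperature_C)
}

# Table-style Page constants per temperature (literature scale, h^-n).
study_page_constants <- data.frame(
  temperature_C = c(50, 60, 70, 80, 90),
  k = c(0.3344, 0.5325, 0.6635, 0.7454, 0.9282),
  n = c(1.0569, 1.0838, 1.0826, 1.1818, 1.1896)
)

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_lt(abs(object - expected) / abs(expected), rel_tol)
}
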