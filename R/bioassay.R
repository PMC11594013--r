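#' Percent inhibition from control and sample absorbances
#'
#' Radical-scavenging assays (DPPH, ABTS) report the drop in absorbance of
#' the radical solution caused by the sample. Two conventions are
#' provided:
#'
#' * `"standard"` (default): 100 (A_c - A_s) / A_c — the usual
#'   scavenging definition, increasing as the sample quenches the radical.
#' * `"as_printed"`: 100 (1 - (A_c - A_s) / A_c) = 100 A_s / A_c — the
#'   algebraic complement, which some sources print; it increases with
#'   residual absorbance. The two conventions sum to 100.
#'
#' @param A_c Control absorbance (> 0).
#' @param A_s Sample absorbance (vectorized).
#' @param convention `"standard"` or `"as_printed"`.
#' @return Percent inhibition.
#' @export
#' @examples
#' percent_inhibition(1.0, 0.25)                   # 75
#' percent_inhibition(1.0, 0.25, "as_printed")     # 25
percent_inhibition <- function(A_c, A_s,
                               convention = c("standard", "as_printed")) {
  convention <- match.arg(convention)
  if (any(A_c <= 0)) stop_input("control absorbance `A_c` must be > 0")
  std <- 100 * (A_c - A_s) / A_c
  if (convention == "standard") std else 100 - std
}

#' Construct a dose-response series
#'
#' Concentration vs percent-inhibition pairs from a serial-dilution
#' antioxidant assay. Raw absorbances may be supplied instead of
#' inhibitions, in which case [percent_inhibition()] is applied.
#'
#' @param concentrations Concentrations in mg mL^-1, strictly increasing
#'   and positive.
#' @param inhibition_pct Percent inhibition per concentration; must lie in
#'   `[-5, 105]` (measurement slack around the 0-100 range).
#' @param A_c,A_s Alternative input: control absorbance and per-dilution
#'   sample absorbances.
#' @param assay Label, e.g. `"DPPH"` or `"ABTS"`.
#' @return An object of class `dose_response`: data frame with columns
#'   `concentration` and `inhibition` plus an `assay` attribute.
#' @export
dose_response <- function(concentrations, inhibition_pct = NULL,
                          A_c = NULL, A_s = NULL, assay = "") {
  concentrations <- as.numeric(concentrations)
  if (any(concentrations <= 0))
    stop_input("concentrations must be strictly positive")
  if (any(diff(concentrations) <= 0))
    stop_input("concentrations must be strictly increasing")
  if (is.null(inhibition_pct)) {
    if (is.null(A_c) || is.null(A_s))
      stop_input("supply `inhibition_pct` or both `A_c` and `A_s`")
    inhibition_pct <- percent_inhibition(A_c, A_s)
  }
  inhibition_pct <- as.numeric(inhibition_pct)
  if (length(inhibition_pct) != length(concentrations))
    stop_input("concentration and inhibition lengths differ")
  if (any(inhibition_pct < -5 | inhibition_pct > 105))
    stop_input("inhibition outside [-5, 105]")
  structure(
    data.frame(concentration = concentrations, inhibition = inhibition_pct),
    assay = assay, class = c("dose_response", "data.frame")
  )
}

# Four-parameter logistic in the inhibition parameterization.
logistic4 <- function(conc, ic50, hill, lower = 0, upper = 100) {
  lower + (upper - lower) / (1 + (ic50 / conc)^hill)
}

#' Fit an IC50 by four-parameter logistic regression
#'
#' Fits inhibition(c) = lower + (upper - lower) / (1 + (IC50 / c)^hill)
#' by least squares. By default the asymptotes are fixed at 0 and 100
#' (percent scale) and only IC50 and the Hill slope are estimated; set
#' `fix_asymptotes = FALSE` to free them. IC50 and hill are optimized on
#' the log scale for conditioning (serial dilutions are geometric) and
#' reported on the linear scale.
#'
#' If the observed inhibition never crosses 50 % the estimate is an
#' extrapolation: a warning is raised and the result is flagged. A series
#' that decreases with concentration beyond noise is rejected.
#'
#' @param series A [dose_response()] object or data frame with columns
#'   `concentration` and `inhibition`.
#' @param fix_asymptotes Keep lower = 0, upper = 100 fixed (default TRUE).
#' @param n_starts Multi-start count over the concentration range.
#' @param seed Seed for the multi-start draw.
#' @return An object of class `ic50_fit`: list with `ic50` (mg mL^-1),
#'   `hill_slope`, `lower`, `upper`, `r_squared`, `extrapolated` and the
#'   data used.
#' @export
#' @examples
#' conc <- 0.13 / 2^(7:0)
#' dr <- dose_response(conc, logistic4(conc, 0.016, 1))
#' fit_ic50(dr)$ic50
fit_ic50 <- function(series, fix_asymptotes = TRUE, n_starts = 5L,
                     seed = 1L) {
  if (!is.data.frame(series) ||
      !all(c("concentration", "inhibition") %in% names(series)))
    stop_input("`series` must have columns `concentration` and `inhibition`")
  conc <- series$concentration
  y <- series$inhibition
  if (length(conc) < 4)
    stop_input("need at least 4 concentrations to fit an IC50")
  # reject strongly non-monotone responses (decreasing with dose)
  if (cor(conc, y, method = "spearman") < -0.5)
    stop(errorCondition("inhibition decreases with concentration",
                        class = c("drypom_fit_failure", "error")))
  extrapolated <- max(y) < 50 || min(y) > 50
  if (extrapolated)
    warning("response does not cross 50 %; IC50 is an extrapolation")

  resid_fn <- function(p) {
    lw <- if (fix_asymptotes) 0 else p[["lower"]]
    up <- if (fix_asymptotes) 100 else p[["upper"]]
    logistic4(conc, exp(p[["log_ic50"]]), exp(p[["log_hill"]]), lw, up) - y
  }
  lg_range <- log(range(conc))
  starts <- with_seed(seed, {
    s <- cbind(log_ic50 = runif(n_starts, lg_range[1], lg_range[2]),
               log_hill = runif(n_starts, log(0.3), log(3)))
    rbind(c(log_ic50 = mean(lg_range), log_hill = 0), s)
  })
  lower_b <- c(log_ic50 = lg_range[1] - log(1e4), log_hill = log(0.05))
  upper_b <- c(log_ic50 = lg_range[2] + log(1e4), log_hill = log(20))
  if (!fix_asymptotes) {
    starts <- cbind(starts, lower = 0, upper = 100)
    lower_b <- c(lower_b, lower = -20, upper = 50)
    upper_b <- c(upper_b, lower = 50, upper = 120)
  }
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-12,
                                     maxiter = 500)
  best <- NULL; best_sse <- Inf
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower_b,
                         upper = upper_b, fn = resid_fn, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    sse <- sum(res$fvec^2)
    if (sse < best_sse) { best_sse <- sse; best <- res }
  }
  if (is.null(best))
    stop(errorCondition("IC50 fit failed from every start",
                        class = c("drypom_fit_failure", "error")))
  p <- best$par
  lw <- if (fix_asymptotes) 0 else unname(p[["lower"]])
  up <- if (fix_asymptotes) 100 else unname(p[["upper"]])
  sst <- sum((y - mean(y))^2)
  structure(list(
    ic50 = exp(unname(p[["log_ic50"]])),
    hill_slope = exp(unname(p[["log_hill"]])),
    lower = lw, upper = up,
    r_squared = if (sst > 0) 1 - best_sse / sst else NA_real_,
    extrapolated = extrapolated,
    data = data.frame(concentration = conc, inhibition = y)
  ), class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("IC50 = %.4g mg/mL (hill = %.3g, R^2 = %.4f)%s\n",
              x$ic50, x$hill_slope, x$r_squared,
              if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

#' Interpolate concentrations on a linear standard curve
#'
#' Trivial helper for gallic-acid / ascorbic-acid style standard curves:
#' given standard concentrations and absorbances, fits absorbance =
#' a + b * concentration and inverts it for the sample absorbances.
#'
#' @param std_conc,std_abs Standard-curve concentrations and absorbances.
#' @param sample_abs Sample absorbances to interpolate.
#' @return Interpolated concentrations (same unit as `std_conc`).
#' @export
standard_curve_interpolate <- function(std_conc, std_abs, sample_abs) {
  if (length(std_conc) < 2) stop_input("need >= 2 standard points")
  fit <- lm(std_abs ~ std_conc)
  b <- coef(fit)
  if (b[2] == 0) stop_input("flat standard curve")
  unname((sample_abs - b[1]) / b[2])
}

#' Read a dose-response series from a delimited text file
#'
#' Accepts either `concentration_mg_ml, inhibition_pct` or
#' `concentration_mg_ml, a_control, a_sample` columns.
#'
#' @param path Path to a comma-separated file with a header.
#' @param assay Assay label.
#' @return A [dose_response()] object.
#' @export
read_dose_response <- function(path, assay = "") {
  if (!file.exists(path)) stop_input("file not found: ", path)
  d <- read.csv(path, check.names = FALSE)
  if (!("concentration_mg_ml" %in% names(d)))
    stop_input("missing `concentration_mg_ml` column in ", path)
  if ("inhibition_pct" %in% names(d)) {
    dose_response(d$concentration_mg_ml, d$inhibition_pct, assay = assay)
  } else if (all(c("a_control", "a_sample") %in% names(d))) {
    dose_response(d$concentration_mg_ml,
                  A_c = d$a_control, A_s = d$a_sample, assay = assay)
  } else {
    stop_input("expected `inhibition_pct` or `a_control, a_sample` in ", path)
  }
}
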