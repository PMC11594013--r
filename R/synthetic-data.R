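#' Simulate a convective-drying experiment
#'
#' Generates a weighing series with the structure of a tray-drying run:
#' the moisture ratio follows a chosen generator (a thin-layer model or
#' the Fick slab solution) on a 30-min grid, is clipped at an
#' equilibrium-plateau floor, converted to dry-basis moisture, and
#' perturbed with additive Gaussian balance noise (optionally quantized at
#' the balance resolution). The generating truth is attached so recovery
#' tests never re-enter it by hand.
#'
#' Thin-layer generators are evaluated with time in hours (the scale the
#' rate constants are reported on); the Fick generator takes a
#' diffusivity in m^2 s^-1 and converts internally.
#'
#' The default equilibrium floor interpolates linearly from 3.5e-3 at
#' 50 C to 1.54e-2 at 90 C, the equilibrium moisture-ratio range typical
#' of berry pomace over this temperature window (higher drying
#' temperatures harden the surface and trap residual moisture).
#'
#' @param model Generator: a thin-layer model name (see
#'   [thin_layer_models()]) or `"fick_slab"`.
#' @param params Named true parameters: model constants for a thin-layer
#'   generator, or `c(D_cal = ..., L = ...)` for `"fick_slab"`.
#' @param temperature_C Nominal drying temperature.
#' @param times Sampling grid in minutes (default 0-810 by 30).
#' @param noise_sd Additive Gaussian noise s.d. on the moisture ratio.
#'   Default 0.005.
#' @param M_0 Initial dry-basis moisture (default 4.0 kg/kg db).
#' @param M_e Equilibrium dry-basis moisture (default 0.05 kg/kg db).
#' @param mr_floor Equilibrium moisture-ratio floor; default interpolated
#'   from temperature as described above.
#' @param quantize Quantize the moisture column at `resolution`.
#' @param resolution Balance resolution in the units of the moisture
#'   column. Default 0.001.
#' @param seed Seed fixing the noise draw.
#'
#' @return A [moisture_series()] with a `truth` attribute (list of the
#'   generator, parameters, floor, M_0, M_e, noise_sd and seed).
#' @export
#' @examples
#' s <- simulate_drying_experiment(params = c(k = 0.6635, n = 1.0826),
#'                                 temperature_C = 70, seed = 7)
#' attr(s, "truth")$params
simulate_drying_experiment <- function(model = "page",
                                       params = c(k = 0.6635, n = 1.0826),
                                       temperature_C = 70,
                                       times = seq(0, 810, by = 30),
                                       noise_sd = 0.005,
                                       M_0 = 4.0, M_e = 0.05,
                                       mr_floor = NULL,
                                       quantize = FALSE,
                                       resolution = 0.001,
                                       seed = NULL) {
  if (noise_sd < 0) stop_input("`noise_sd` must be >= 0")
  if (is.null(mr_floor)) {
    f <- (temperature_C - 50) / 40
    f <- min(max(f, 0), 1)
    mr_floor <- 3.5e-3 + f * (1.54e-2 - 3.5e-3)
  }
  mr_true <- if (identical(model, "fick_slab")) {
    simulate_fick_mr(params[["D_cal"]], params[["L"]], times)
  } else {
    evaluate_model(model, params, times / 60)
  }
  mr_true <- pmax(mr_true, mr_floor)
  mr_noisy <- with_seed(seed, mr_true + rnorm(length(mr_true), 0, noise_sd))
  if (any(mr_noisy < -0.1))
    stop_input("noise level drives the moisture ratio below -0.1; ",
               "reduce `noise_sd`")
  moisture <- pmax(mr_noisy * (M_0 - M_e) + M_e, 0)
  if (quantize) moisture <- round(moisture / resolution) * resolution
  out <- moisture_series(times, moisture, temperature_C = temperature_C,
                         label = sprintf("synthetic_%gC", temperature_C))
  attr(out, "truth") <- list(model = model, params = params,
                             mr_floor = mr_floor, M_0 = M_0, M_e = M_e,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate an Arrhenius diffusivity set
#'
#' D_eff(T) = D_0 exp(-E_a / (R (T + 273.15))) with optional lognormal
#' noise (additive Gaussian on log D_eff).
#'
#' @param D_0 Pre-exponential factor, m^2 s^-1 (> 0).
#' @param E_a Activation energy in kJ mol^-1.
#' @param temperatures Temperatures in degrees Celsius (default the study
#'   grid 50-90 C).
#' @param noise_sd_logD Gaussian s.d. on ln(D_eff). Default 0.
#' @param seed Seed fixing the noise draw.
#' @return Data frame `(temperature_C, deff_m2s)` with a `truth`
#'   attribute.
#' @export
simulate_arrhenius_set <- function(D_0, E_a,
                                   temperatures = c(50, 60, 70, 80, 90),
                                   noise_sd_logD = 0, seed = NULL) {
  if (D_0 <= 0) stop_input("`D_0` must be > 0")
  if (noise_sd_logD < 0) stop_input("`noise_sd_logD` must be >= 0")
  R_gas <- 8.314
  ln_d <- log(D_0) - E_a * 1000 / (R_gas * (temperatures + 273.15))
  ln_d <- with_seed(seed, ln_d + rnorm(length(ln_d), 0, noise_sd_logD))
  out <- data.frame(temperature_C = temperatures, deff_m2s = exp(ln_d))
  attr(out, "truth") <- list(D_0 = D_0, E_a = E_a,
                             noise_sd_logD = noise_sd_logD, seed = seed)
  out
}

#' Simulate a serial-dilution dose-response series
#'
#' Four-parameter logistic inhibition with asymptotes 0/100 plus additive
#' Gaussian noise, clipped to the assay's measurable range `[-5, 105]`.
#' The default grid is an 8-point two-fold dilution series from
#' 0.13 mg mL^-1 (the upper end of the ascorbic-acid standard window).
#'
#' @param ic50 True midpoint, mg mL^-1 (> 0).
#' @param hill True Hill slope.
#' @param concentrations Concentration grid, mg mL^-1.
#' @param noise_sd_pct Gaussian noise s.d. in percent-inhibition units.
#' @param seed Seed fixing the noise draw.
#' @param assay Assay label.
#' @return A [dose_response()] object with a `truth` attribute.
#' @export
simulate_dose_response <- function(ic50, hill = 1,
                                   concentrations = 0.13 / 2^(7:0),
                                   noise_sd_pct = 0, seed = NULL,
                                   assay = "DPPH") {
  if (ic50 <= 0) stop_input("`ic50` must be > 0")
  if (noise_sd_pct < 0) stop_input("`noise_sd_pct` must be >= 0")
  concentrations <- sort(as.numeric(concentrations))
  y <- logistic4(concentrations, ic50, hill)
  y <- with_seed(seed, y + rnorm(length(y), 0, noise_sd_pct))
  y <- pmin(pmax(y, -5), 105)
  out <- dose_response(concentrations, y, assay = assay)
  attr(out, "truth") <- list(ic50 = ic50, hill = hill,
                             noise_sd_pct = noise_sd_pct, seed = seed)
  out
}

#' Simulate a replicated treatment-property table
#'
#' Normal replicates around stated treatment means, emulating a
#' "mean +/- SD of triplicate experiments" table.
#'
#' @param means Named numeric vector of treatment means (names are the
#'   treatment labels).
#' @param sds Per-treatment standard deviations, recycled if scalar; all
#'   >= 0.
#' @param n_replicates Replicates per treatment (>= 2). Default 3.
#' @param seed Seed fixing the draw.
#' @param property,unit Labels for the resulting [group_table()].
#' @return A [group_table()] with a `truth` attribute.
#' @export
simulate_property_table <- function(means, sds, n_replicates = 3,
                                    seed = NULL, property = "", unit = "") {
  if (is.null(names(means)))
    stop_input("`means` must be named by treatment")
  sds <- rep_len(as.numeric(sds), length(means))
  if (any(sds < 0)) stop_input("standard deviations must be >= 0")
  if (n_replicates < 2) stop_input("`n_replicates` must be >= 2")
  vals <- with_seed(seed, {
    unlist(lapply(seq_along(means), function(i)
      rnorm(n_replicates, means[i], sds[i])))
  })
  out <- group_table(rep(names(means), each = n_replicates), vals,
                     property = property, unit = unit)
  attr(out, "truth") <- list(means = means, sds = sds,
                             n_replicates = n_replicates, seed = seed)
  out
}

#' Write a moisture series and its truth sidecar
#'
#' Writes the delimited format [read_moisture_series()] consumes
#' (`time_min, moisture_db`) and, when the series carries a `truth`
#' attribute, a key-value sidecar `<path>.truth.txt`.
#'
#' @param series A [moisture_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_moisture_series <- function(series, path) {
  stopifnot(inherits(series, "moisture_series"))
  write.csv(data.frame(time_min = series$time_min,
                       moisture_db = series$moisture_db),
            path, row.names = FALSE)
  truth <- attr(series, "truth")
  if (!is.null(truth)) {
    flat <- unlist(truth)
    writeLines(paste0(names(flat), ": ", vapply(flat, format, character(1))),
               paste0(path, ".truth.txt"))
  }
  invisible(path)
}
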