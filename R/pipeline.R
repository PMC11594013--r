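#' Read a run configuration file
#'
#' Flat key-value (YAML-compatible) configuration. Recognized keys:
#' `thickness_m` (default 0.01), `R_g` (13.1), `alpha` (0.05), `models`
#' (default all five), `seed` (1), `out_dir`, and `inputs` (a map of
#' temperature to file path). Unknown keys are kept and passed through.
#'
#' @param path Path to the YAML/key-value file.
#' @return A named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(thickness_m = 0.01, R_g = 13.1, alpha = 0.05,
                   models = names(thin_layer_models()), seed = 1L,
                   out_dir = ".")
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (!is.null(cfg$inputs) && anyDuplicated(names(cfg$inputs)))
    stop_input("duplicate temperatures in `inputs`")
  cfg
}

report_header <- function(seed, extra = character()) {
  c(sprintf("# drypom %s",
            as.character(utils::packageVersion("drypom"))),
    sprintf("# seed: %s", format(seed)),
    paste0("# ", extra))
}

write_report <- function(df, path, seed, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(report_header(seed, extra), con)
  write.csv(format(df, digits = 4, scientific = NA, trim = TRUE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Resolve a per-temperature input set into a named list of moisture_series.
resolve_series <- function(inputs, thickness_m = 0.01) {
  if (inherits(inputs, "moisture_series")) inputs <- list(inputs)
  lapply(seq_along(inputs), function(i) {
    x <- inputs[[i]]
    if (inherits(x, "moisture_series")) return(x)
    temp <- suppressWarnings(as.numeric(names(inputs)[i]))
    read_moisture_series(x, temperature_C = temp, thickness_m = thickness_m)
  })
}

#' Simulate a full drying study to disk
#'
#' Writes one synthetic weighing series per temperature (plus truth
#' sidecars) in the delimited format [run_fit()] and [run_diffusivity()]
#' consume. The defaults emulate the study protocol: Page-model kinetics
#' with per-temperature constants on the literature scale, 30-min
#' sampling, drying times shrinking from 810 min at 50 C to 210 min at
#' 90 C, and 0.005 moisture-ratio balance noise.
#'
#' @param out_dir Output directory (created if missing).
#' @param temperatures Temperatures in degrees Celsius.
#' @param page_constants Data frame `(temperature_C, k, n)` of generating
#'   Page constants per temperature.
#' @param total_time_min Total drying time per temperature (minutes);
#'   recycled.
#' @param noise_sd Moisture-ratio noise s.d.
#' @param seed Master seed; per-temperature draws use `seed + index`.
#' @return Named character vector of the written series files.
#' @export
run_simulate <- function(out_dir,
                         temperatures = c(50, 60, 70, 80, 90),
                         page_constants = data.frame(
                           temperature_C = c(50, 60, 70, 80, 90),
                           k = c(0.3344, 0.5325, 0.6635, 0.7454, 0.9282),
                           n = c(1.0569, 1.0838, 1.0826, 1.1818, 1.1896)),
                         total_time_min = c(810, 660, 510, 360, 210),
                         noise_sd = 0.005,
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  total_time_min <- rep_len(total_time_min, length(temperatures))
  paths <- character(0)
  for (i in seq_along(temperatures)) {
    tc <- temperatures[i]
    row <- page_constants[page_constants$temperature_C == tc, , drop = FALSE]
    if (!nrow(row))
      stop_input("no generating constants for ", tc, " C")
    s <- simulate_drying_experiment(
      model = "page", params = c(k = row$k[1], n = row$n[1]),
      temperature_C = tc, times = seq(0, total_time_min[i], by = 30),
      noise_sd = noise_sd, seed = seed + i)
    p <- file.path(out_dir, sprintf("drying_%dC.csv", as.integer(tc)))
    write_moisture_series(s, p)
    paths[as.character(tc)] <- p
  }
  paths
}

#' Fit the model bank across temperatures
#'
#' Fits every requested thin-layer model to every input series and writes
#' a report in the conventional layout (model, temperature, constants,
#' seven fit statistics) with a per-temperature ranking.
#'
#' @param inputs Named list/vector: per-temperature file paths (names are
#'   temperatures in C) or `moisture_series` objects.
#' @param models Model names to fit; default all five.
#' @param out_file Optional report path; when `NULL` nothing is written.
#' @param seed Seed for the multi-start draws (embedded in the report).
#' @param thickness_m Bed thickness passed to the reader.
#' @return Invisibly, a list with `report` (data frame), `fits` (nested
#'   list by temperature) and `best` (best model name per temperature).
#' @export
run_fit <- function(inputs, models = names(thin_layer_models()),
                    out_file = NULL, seed = 1L, thickness_m = 0.01) {
  series <- resolve_series(inputs, thickness_m)
  ctrl <- fit_control(seed = seed)
  fits <- list()
  best <- character(0)
  for (s in series) {
    mr <- moisture_ratio(s)
    temp <- attr(s, "temperature_C")
    fs <- lapply(models, function(m) fit_drying_model(mr, m, control = ctrl))
    ranked <- rank_models(fs)
    key <- as.character(temp)
    fits[[key]] <- ranked
    best[key] <- ranked[[1]]$model
  }
  report <- fit_report(unlist(fits, recursive = FALSE))
  names(report)[names(report) == "k"] <- "k_per_h_pow_n"
  names(report)[names(report) == "b"] <- "b_per_h"
  if (!is.null(out_file))
    write_report(report, out_file, seed,
                 extra = sprintf("models: %s", paste(models, collapse = ", ")))
  invisible(list(report = report, fits = fits, best = best))
}

#' Diffusivity and Arrhenius analysis across temperatures
#'
#' Chains [estimate_dcal()] and [correct_geometry()] per temperature and,
#' with two or more temperatures, [fit_arrhenius()] over the resulting
#' effective diffusivities.
#'
#' @param inputs As in [run_fit()]; or a named vector of `time_min, mr`
#'   file paths read with [read_mr_series()] when `input_type = "mr"`.
#' @param thickness_m Bed thickness in metres; the slab half-thickness
#'   used is `L = thickness_m / 2` unless `L` is given.
#' @param L Slab half-thickness override in metres.
#' @param R_g Geometric factor. Default 13.1.
#' @param input_type `"moisture"` (default) or `"mr"`.
#' @param out_file Optional report path.
#' @param seed Seed recorded in the report (the analysis itself is
#'   deterministic).
#' @return Invisibly, a list with `table` (per-temperature slope, D_cal,
#'   D_eff), `arrhenius` (an `arrhenius_result` or `NULL`) and
#'   `estimates`.
#' @export
run_diffusivity <- function(inputs, thickness_m = 0.01, L = NULL,
                            R_g = 13.1, input_type = c("moisture", "mr"),
                            out_file = NULL, seed = 1L) {
  input_type <- match.arg(input_type)
  if (is.null(L)) L <- thickness_m / 2
  mrs <- if (input_type == "mr") {
    lapply(seq_along(inputs), function(i) {
      x <- inputs[[i]]
      if (inherits(x, "mr_series")) x
      else read_mr_series(x, temperature_C = as.numeric(names(inputs)[i]))
    })
  } else {
    lapply(resolve_series(inputs, thickness_m), moisture_ratio)
  }
  ests <- lapply(mrs, function(m) correct_geometry(estimate_dcal(m, L), R_g))
  tab <- do.call(rbind, lapply(ests, function(e) data.frame(
    temperature_C = e$temperature_C, slope_per_s = e$slope,
    r_squared_line = e$r_squared_line, D_cal_m2s = e$D_cal,
    R_g = e$R_g, D_eff_m2s = e$D_eff, L_m = e$L,
    n_points_used = e$n_points_used)))
  arr <- NULL
  if (nrow(tab) >= 2) {
    arr <- fit_arrhenius(data.frame(temperature_C = tab$temperature_C,
                                    deff_m2s = tab$D_eff_m2s))
  } else {
    warning("single temperature: Arrhenius fit skipped")
  }
  if (!is.null(out_file)) {
    extra <- if (is.null(arr)) "arrhenius: skipped (single temperature)"
             else sprintf("arrhenius: E_a_kJ_mol = %.6g, D_0_m2s = %.6g, r_squared = %.6g",
                          arr$E_a, arr$D_0, arr$r_squared)
    write_report(tab, out_file, seed, extra = extra)
  }
  invisible(list(table = tab, arrhenius = arr, estimates = ests))
}

#' IC50 analysis of a dose-response input
#'
#' @param input A [dose_response()] object or a delimited file for
#'   [read_dose_response()].
#' @param out_file Optional report path.
#' @param seed Seed for the fit's multi-start draw.
#' @param ... Passed to [fit_ic50()].
#' @return Invisibly, the `ic50_fit`.
#' @export
run_ic50 <- function(input, out_file = NULL, seed = 1L, ...) {
  dr <- if (is.character(input)) read_dose_response(input) else input
  fit <- fit_ic50(dr, seed = seed, ...)
  if (!is.null(out_file)) {
    write_report(data.frame(ic50_mg_ml = fit$ic50,
                            hill_slope = fit$hill_slope,
                            lower_pct = fit$lower, upper_pct = fit$upper,
                            r_squared = fit$r_squared,
                            extrapolated = fit$extrapolated),
                 out_file, seed)
  }
  invisible(fit)
}

#' Treatment comparison with mean +/- SD and Tukey letters
#'
#' @param input A long-format file for [read_group_tables()], a single
#'   [group_table()], or a named list of them.
#' @param alpha Significance level. Default 0.05.
#' @param out_file Optional report path.
#' @param seed Seed recorded in the report (the test is deterministic).
#' @return Invisibly, a list per property with `summary` (treatment,
#'   mean, sd, n, letters), the `tukey_outcome` and advisory screens.
#' @export
run_compare <- function(input, alpha = 0.05, out_file = NULL, seed = 1L) {
  gts <- if (is.character(input)) read_group_tables(input)
         else if (inherits(input, "group_table")) list(input)
         else input
  out <- lapply(gts, function(gt) {
    tk <- tukey_letters(gt, alpha = alpha)
    m <- tapply(gt$value, gt$treatment, mean)
    s <- tapply(gt$value, gt$treatment, sd)
    n <- tapply(gt$value, gt$treatment, length)
    list(summary = data.frame(
           property = attr(gt, "property"),
           treatment = names(m), mean = as.numeric(m), sd = as.numeric(s),
           n = as.numeric(n),
           letters = unname(tk$letters[names(m)])),
         tukey = tk, screens = advisory_screens(gt, alpha))
  })
  if (!is.null(out_file)) {
    write_report(do.call(rbind, lapply(out, `[[`, "summary")),
                 out_file, seed, extra = sprintf("alpha: %g", alpha))
  }
  invisible(out)
}
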