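#' Moisture ratio under the one-term Fick slab solution
#'
#' First-term series solution of Fick's second law for a slab drying from
#' both faces: MR(t) = (8 / pi^2) exp(-pi^2 D_cal t / (4 L^2)), with time
#' converted from minutes to seconds internally so diffusivities are in
#' m^2 s^-1.
#'
#' @param D_cal Calculated moisture diffusivity, m^2 s^-1 (> 0).
#' @param L Slab half-thickness, m (> 0).
#' @param times Times in minutes.
#' @return Moisture ratio at each time.
#' @export
#' @examples
#' simulate_fick_mr(2.0043e-9, L = 0.005, times = c(0, 30, 60))
simulate_fick_mr <- function(D_cal, L, times) {
  if (!is.numeric(D_cal) || D_cal <= 0) stop_input("`D_cal` must be > 0")
  if (!is.numeric(L) || L <= 0) stop_input("`L` must be > 0")
  t_sec <- as.numeric(times) * 60
  (8 / pi^2) * exp(-pi^2 * D_cal * t_sec / (4 * L^2))
}

#' Slope-method estimate of the calculated moisture diffusivity
#'
#' Ordinary least squares of ln(MR) on time (in seconds) over the points
#' with MR above `mr_floor`; under the one-term Fick slab solution the
#' slope equals -pi^2 D_cal / (4 L^2), so D_cal = -slope * 4 L^2 / pi^2.
#' The t = 0 point is kept (it lies on the line under the slab solution);
#' points at or below the floor — the equilibrium plateau, where the
#' normalized ratio collapses into noise — are excluded and counted.
#'
#' @param mr An [mr_series()] or data frame with columns `time_min`, `mr`.
#' @param L Slab half-thickness in metres (> 0). For a bed dried on a tray
#'   this is half the bed thickness.
#' @param mr_floor Points with MR <= this floor are excluded. Default 1e-4.
#'
#' @return An object of class `diffusivity_estimate`: list with
#'   `temperature_C`, `slope` (s^-1), `intercept`, `r_squared_line`,
#'   `D_cal` (m^2 s^-1), `L`, `n_points_used`, `n_points_excluded`, and
#'   placeholders `R_g`/`D_eff` filled by [correct_geometry()]. A positive
#'   slope (non-drying series) yields a warning and a negative `D_cal`.
#' @export
estimate_dcal <- function(mr, L, mr_floor = 1e-4) {
  if (!is.data.frame(mr) || !all(c("time_min", "mr") %in% names(mr)))
    stop_input("`mr` must have columns `time_min` and `mr`")
  if (!is.numeric(L) || L <= 0) stop_input("`L` must be > 0")
  use <- mr$mr > mr_floor
  n_excl <- sum(!use)
  t_sec <- mr$time_min[use] * 60
  y <- log(mr$mr[use])
  if (length(y) < 3)
    stop_input("fewer than 3 usable points (MR > ", mr_floor, ")")
  fit <- lm(y ~ t_sec)
  slope <- unname(coef(fit)[2])
  if (slope > 0)
    warning("positive ln(MR) slope: series is not drying; D_cal is negative")
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else NA_real_
  structure(list(
    temperature_C = if (!is.null(attr(mr, "temperature_C")))
      attr(mr, "temperature_C") else NA_real_,
    slope = slope,
    intercept = unname(coef(fit)[1]),
    r_squared_line = r2,
    D_cal = -slope * 4 * L^2 / pi^2,
    R_g = NA_real_, D_eff = NA_real_, L = L,
    n_points_used = length(y), n_points_excluded = n_excl
  ), class = "diffusivity_estimate")
}

#' Apply the geometric correction to a slope-method diffusivity
#'
#' D_eff = D_cal / R_g, where R_g is a dimensionless geometric factor
#' (13.1 for the flat tray-bed geometry used here; configurable since its
#' value is empirical and geometry-specific).
#'
#' @param D_cal A `diffusivity_estimate` from [estimate_dcal()], or a bare
#'   numeric diffusivity in m^2 s^-1.
#' @param R_g Geometric factor (> 0). Default 13.1.
#' @return For a `diffusivity_estimate` input, the object with `R_g` and
#'   `D_eff` filled in; for a numeric input, the numeric D_eff.
#' @export
#' @examples
#' correct_geometry(2.0043e-9)           # -> 1.53e-10
correct_geometry <- function(D_cal, R_g = 13.1) {
  if (!is.numeric(R_g) || R_g <= 0) stop_input("`R_g` must be > 0")
  if (inherits(D_cal, "diffusivity_estimate")) {
    D_cal$R_g <- R_g
    D_cal$D_eff <- D_cal$D_cal / R_g
    return(D_cal)
  }
  D_cal / R_g
}

#' Arrhenius fit of effective diffusivity against temperature
#'
#' Least squares of ln(D_eff) on inverse absolute temperature
#' 1 / (T + 273.15); the activation energy is E_a = -slope * R (reported
#' in kJ mol^-1, gas constant R = 8.314 J mol^-1 K^-1) and the
#' pre-exponential factor is D_0 = exp(intercept).
#'
#' @param temperature_C Temperatures in degrees Celsius (>= 2 values), or
#'   a two-column data frame `(temperature_C, deff_m2s)`.
#' @param D_eff Effective diffusivities in m^2 s^-1, all > 0 (ignored when
#'   the first argument is a data frame).
#'
#' @return An object of class `arrhenius_result`: list with `D_0`
#'   (m^2 s^-1), `E_a` (kJ mol^-1), `R_gas` (8.314 J mol^-1 K^-1),
#'   `r_squared` and the `points` used.
#' @export
#' @examples
#' d <- simulate_arrhenius_set(1e-5, 34.90, noise_sd_logD = 0)
#' fit_arrhenius(d)$E_a
fit_arrhenius <- function(temperature_C, D_eff = NULL) {
  if (is.data.frame(temperature_C)) {
    df <- temperature_C
    nm <- names(df)
    if (!("temperature_C" %in% nm))
      stop_input("data frame input needs a `temperature_C` column")
    dcol <- intersect(c("deff_m2s", "D_eff"), nm)
    if (!length(dcol)) stop_input("data frame input needs a `deff_m2s` column")
    temperature_C <- df$temperature_C
    D_eff <- df[[dcol[1]]]
  }
  if (length(temperature_C) < 2 || length(D_eff) != length(temperature_C))
    stop_input("need >= 2 matching (temperature, D_eff) points")
  if (any(D_eff <= 0)) stop_input("all D_eff must be > 0")
  R_gas <- 8.314  # J mol^-1 K^-1
  inv_T <- 1 / (temperature_C + 273.15)
  ln_d <- log(D_eff)
  if (length(unique(signif(ln_d, 12))) == 1L) {
    # temperature-independent diffusivity: flat line, E_a = 0
    slope <- 0
    intercept <- ln_d[1]
    r2 <- 1
  } else {
    fit <- lm(ln_d ~ inv_T)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    sst <- sum((ln_d - mean(ln_d))^2)
    r2 <- 1 - sum(fit$residuals^2) / sst
  }
  structure(list(
    D_0 = exp(intercept),
    E_a = -slope * R_gas / 1000,
    R_gas = R_gas,
    r_squared = r2,
    points = data.frame(temperature_C = temperature_C, D_eff = D_eff)
  ), class = "arrhenius_result")
}

#' @export
print.arrhenius_result <- function(x, ...) {
  cat(sprintf("Arrhenius fit over %d temperatures:\n", nrow(x$points)))
  cat(sprintf("  E_a = %.4g kJ/mol, D_0 = %.4g m^2/s, R^2 = %.4f\n",
              x$E_a, x$D_0, x$r_squared))
  invisible(x)
}
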