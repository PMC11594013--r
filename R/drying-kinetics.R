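#' Construct a moisture series
#'
#' A moisture series is the primary record of one drying run: dry-basis
#' moisture content measured at successive times at a single drying-air
#' temperature. Times are minutes since the start of drying; moisture is
#' kg water per kg bone-dry solid.
#'
#' @param times Numeric vector of sampling times in minutes, strictly
#'   increasing, first element 0.
#' @param moisture Numeric vector of dry-basis moisture contents
#'   (kg H2O per kg db), same length as `times`, all non-negative.
#' @param temperature_C Drying-air temperature in degrees Celsius.
#' @param thickness_m Slab (bed) thickness in metres; must be positive.
#' @param label Optional free-text treatment identifier.
#'
#' @return An object of class `moisture_series`: a data frame with columns
#'   `time_min` and `moisture_db` and attributes `temperature_C`,
#'   `thickness_m` and `label`.
#' @export
#' @examples
#' ms <- moisture_series(c(0, 30, 60), c(4, 2.5, 1.2), temperature_C = 70)
moisture_series <- function(times, moisture, temperature_C = NA_real_,
                            thickness_m = 0.01, label = "") {
  times <- as.numeric(times)
  moisture <- as.numeric(moisture)
  if (length(times) != length(moisture))
    stop_input("`times` and `moisture` must have the same length")
  if (length(times) < 3L)
    stop_input("a moisture series needs at least 3 points")
  if (any(!is.finite(times)) || any(!is.finite(moisture)))
    stop_input("times and moisture must be finite")
  if (any(diff(times) <= 0))
    stop_input("`times` must be strictly increasing")
  if (times[1] != 0)
    stop_input("the first time must be 0 (start of drying)")
  if (any(moisture < 0))
    stop_input("moisture values must be >= 0")
  if (!is.na(thickness_m) && thickness_m <= 0)
    stop_input("`thickness_m` must be > 0")
  structure(
    data.frame(time_min = times, moisture_db = moisture),
    temperature_C = as.numeric(temperature_C),
    thickness_m = as.numeric(thickness_m),
    label = as.character(label),
    class = c("moisture_series", "data.frame")
  )
}

#' Construct a moisture-ratio series
#'
#' Dimensionless moisture ratio MR(t) = (M_t - M_e) / (M_0 - M_e) per
#' sampling time; decays from 1 toward 0 during drying.
#'
#' @param times Sampling times in minutes.
#' @param mr Moisture ratio per time; `mr[1]` must equal 1 within
#'   floating-point tolerance and all values must be >= 0, up to a small
#'   negative excursion (-0.05) tolerated because balance noise around the
#'   equilibrium plateau pushes the normalized ratio slightly below zero.
#' @param temperature_C Drying-air temperature in degrees Celsius.
#'
#' @return An object of class `mr_series`: a data frame with columns
#'   `time_min` and `mr` plus a `temperature_C` attribute.
#' @export
mr_series <- function(times, mr, temperature_C = NA_real_) {
  times <- as.numeric(times)
  mr <- as.numeric(mr)
  if (length(times) != length(mr))
    stop_input("`times` and `mr` must have the same length")
  if (any(diff(times) <= 0))
    stop_input("`times` must be strictly increasing")
  if (abs(mr[1] - 1) > 1e-8)
    stop_input("mr[1] must equal 1 (normalized series)")
  if (any(mr < -0.05))
    stop_input("mr values must be >= 0 (tolerance -0.05 for plateau noise)")
  structure(
    data.frame(time_min = times, mr = mr),
    temperature_C = as.numeric(temperature_C),
    class = c("mr_series", "data.frame")
  )
}

#' Detect the equilibrium endpoint of a drying run
#'
#' Applies the stopping rule used when logging drying experiments: the run
#' has reached equilibrium at the first measurement where the relative
#' change between consecutive readings has stayed below `rel_threshold`
#' over three consecutive measurements (i.e. the two most recent
#' inter-reading changes are both below the threshold). The default
#' threshold 1e-4 corresponds to a 0.01 % weight change. Because the
#' criterion is relative it gives the same answer whether it is applied to
#' raw mass or to dry-basis moisture (the two are proportional up to the
#' bone-dry offset), so it is applied to whichever column the series holds.
#'
#' @param series A [moisture_series()], or a bare numeric vector of
#'   monotone readings (mass or moisture).
#' @param rel_threshold Relative-change threshold (fraction); default
#'   `1e-4` = 0.01 %.
#'
#' @return A list with `index` (1-based index of the equilibrium
#'   measurement), `M_e` (the reading at that index), and `converged`
#'   (`FALSE` when the rule is never satisfied, in which case `index` is
#'   the last index).
#' @export
#' @examples
#' detect_equilibrium(c(4, 2, 1, 0.9999, 0.99985, 0.99981))
detect_equilibrium <- function(series, rel_threshold = 1e-4) {
  x <- if (inherits(series, "moisture_series")) series$moisture_db
       else as.numeric(series)
  if (length(x) < 3L)
    stop_input("equilibrium detection needs at least 3 measurements")
  if (!is.numeric(rel_threshold) || rel_threshold <= 0)
    stop_input("`rel_threshold` must be > 0")
  rel <- abs(diff(x)) / abs(x[-length(x)])
  rel[!is.finite(rel)] <- Inf
  # strict "less than": a change equal to the threshold (within floating
  # tolerance) does not satisfy the criterion
  thr <- rel_threshold * (1 - 1e-9)
  for (i in 3:length(x)) {
    if (rel[i - 1] < thr && rel[i - 2] < thr) {
      return(list(index = i, M_e = x[i], converged = TRUE))
    }
  }
  list(index = length(x), M_e = x[length(x)], converged = FALSE)
}

#' Compute the moisture ratio of a drying run
#'
#' MR_i = (M_i - M_e) / (M_0 - M_e), where M_0 is the initial moisture and
#' M_e the equilibrium moisture. The first value is exactly 1.
#'
#' @param series A [moisture_series()].
#' @param M_e Equilibrium moisture content (kg H2O per kg db). Defaults to
#'   the value found by [detect_equilibrium()].
#'
#' @return An [mr_series()] covering the same time grid.
#' @export
#' @examples
#' ms <- moisture_series(c(0, 30, 60), c(4, 2.025, 0.05))
#' moisture_ratio(ms, M_e = 0.05)
moisture_ratio <- function(series, M_e = NULL) {
  stopifnot(inherits(series, "moisture_series"))
  if (is.null(M_e)) M_e <- detect_equilibrium(series)$M_e
  M0 <- series$moisture_db[1]
  if (M0 == M_e)
    stop_input("degenerate series: initial moisture equals equilibrium moisture")
  mr <- (series$moisture_db - M_e) / (M0 - M_e)
  mr[1] <- 1
  mr_series(series$time_min, mr,
            temperature_C = attr(series, "temperature_C"))
}

#' Compute per-interval drying rates
#'
#' For each consecutive pair of measurements the drying rate is the
#' moisture lost per unit time, DR = (M_t1 - M_t2) / (t2 - t1), in
#' kg H2O per kg db per minute. The positive-magnitude convention is used:
#' a decreasing (drying) series yields positive rates. Intervals where the
#' moisture increases (rewetting, condensation or balance error) keep their
#' negative sign and are flagged.
#'
#' @param series A [moisture_series()].
#'
#' @return A data frame with one row per interval: `t_mid` (interval
#'   midpoint, minutes), `dr` (kg H2O kg^-1 db min^-1) and `rewetting`
#'   (logical flag for negative rates).
#' @export
drying_rate <- function(series) {
  stopifnot(inherits(series, "moisture_series"))
  t <- series$time_min
  m <- series$moisture_db
  if (length(t) < 2L) stop_input("drying rate needs at least 2 points")
  dt <- diff(t)
  if (any(dt == 0)) stop_input("duplicate time stamps")
  dr <- -diff(m) / dt  # (M_t1 - M_t2) / (t2 - t1)
  data.frame(
    t_mid = (t[-1] + t[-length(t)]) / 2,
    dr = dr,
    rewetting = dr < 0
  )
}

#' Invert a moisture-ratio series back to moisture content
#'
#' M_i = MR_i * (M_0 - M_e) + M_e. Companion of [moisture_ratio()].
#'
#' @param mr An [mr_series()].
#' @param M_0,M_e Initial and equilibrium moisture contents.
#' @param thickness_m,label Passed to [moisture_series()].
#' @return A [moisture_series()].
#' @export
moisture_from_ratio <- function(mr, M_0, M_e, thickness_m = 0.01, label = "") {
  stopifnot(inherits(mr, "mr_series"))
  moisture_series(mr$time_min, mr$mr * (M_0 - M_e) + M_e,
                  temperature_C = attr(mr, "temperature_C"),
                  thickness_m = thickness_m, label = label)
}

#' Convert wet-basis moisture to dry basis
#'
#' Dry-basis moisture M_db = w / (1 - w) for wet-basis fraction w.
#'
#' @param wet_basis Wet-basis moisture fraction(s), in `[0, 1)`.
#' @return Dry-basis moisture, kg H2O per kg dry solid.
#' @export
wet_to_dry_basis <- function(wet_basis) {
  if (any(wet_basis < 0 | wet_basis >= 1))
    stop_input("wet-basis moisture must lie in [0, 1)")
  wet_basis / (1 - wet_basis)
}

#' Read a moisture series from a delimited text file
#'
#' Expects a header and either columns `time_min, moisture_db`, or columns
#' `time_min, mass_g` together with a bone-dry mass (`dry_mass_g`) used to
#' convert mass to dry-basis moisture: M = (mass - dry_mass) / dry_mass.
#'
#' @param path Path to a comma-separated file with a header row.
#' @param temperature_C,thickness_m,label Metadata attached to the series.
#' @param dry_mass_g Bone-dry mass in grams, required when the file has a
#'   `mass_g` column.
#' @return A [moisture_series()].
#' @export
read_moisture_series <- function(path, temperature_C = NA_real_,
                                 thickness_m = 0.01, label = "",
                                 dry_mass_g = NULL) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  d <- read.csv(path, check.names = FALSE)
  if (!("time_min" %in% names(d)))
    stop_input("missing `time_min` column in ", path)
  if ("moisture_db" %in% names(d)) {
    m <- d$moisture_db
  } else if ("mass_g" %in% names(d)) {
    if (is.null(dry_mass_g))
      stop_input("`dry_mass_g` is required for a mass_g series")
    m <- (d$mass_g - dry_mass_g) / dry_mass_g
  } else {
    stop_input("expected a `moisture_db` or `mass_g` column in ", path)
  }
  moisture_series(d$time_min, m, temperature_C = temperature_C,
                  thickness_m = thickness_m, label = label)
}

#' Read a moisture-ratio series from a delimited text file
#'
#' Expects a header with columns `time_min, mr`.
#'
#' @param path Path to a comma-separated file.
#' @param temperature_C Temperature metadata.
#' @return An [mr_series()].
#' @export
read_mr_series <- function(path, temperature_C = NA_real_) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  d <- read.csv(path, check.names = FALSE)
  if (!all(c("time_min", "mr") %in% names(d)))
    stop_input("expected columns `time_min, mr` in ", path)
  mr_series(d$time_min, d$mr, temperature_C = temperature_C)
}
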