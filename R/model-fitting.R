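#' Control options for thin-layer model fitting
#'
#' @param n_starts Number of multi-start points (Latin hypercube over the
#'   parameter bounds, plus one heuristic start). Default 5.
#' @param seed Seed fixing the Latin hypercube draw, so fits are
#'   reproducible. Default 1.
#' @param sse_tol Convergence tolerance on the sum of squared errors
#'   passed to the Levenberg-Marquardt optimizer. Default 1e-10.
#' @param max_iter Maximum optimizer iterations per start.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(n_starts = 5L, seed = 1L, sse_tol = 1e-10,
                        max_iter = 500L) {
  stopifnot(n_starts >= 1, sse_tol > 0)
  structure(list(n_starts = as.integer(n_starts), seed = seed,
                 sse_tol = sse_tol, max_iter = as.integer(max_iter)),
            class = "fit_control")
}

# Latin-hypercube starts over the bounds; k is sampled log-uniformly
# because its bounds span many decades.
lh_starts <- function(model, n, seed) {
  K <- length(model$param_names)
  u <- with_seed(seed, lhs::randomLHS(n, K))
  starts <- matrix(NA_real_, n, K, dimnames = list(NULL, model$param_names))
  for (j in seq_len(K)) {
    p <- model$param_names[j]
    lo <- model$lower[j]; hi <- model$upper[j]
    if (p == "k") {
      starts[, j] <- exp(log(lo) + u[, j] * (log(hi) - log(lo)))
    } else {
      starts[, j] <- lo + u[, j] * (hi - lo)
    }
  }
  starts
}

# Moment-style heuristic start: k from the early log-linear decay, neutral
# shape parameters elsewhere.
heuristic_start <- function(model, times, y) {
  pos <- which(y > 0.05 & times > 0)
  k0 <- if (length(pos) >= 1) {
    max(1e-4, -log(y[pos[1]]) / times[pos[1]])
  } else 1
  full <- c(k = min(k0, 49), n = 1, a = 1, b = 0, c = 0)
  pmin(pmax(full[model$param_names], model$lower + 1e-9),
       model$upper - 1e-9)
}

#' Fit a thin-layer drying model by bounded nonlinear least squares
#'
#' Estimates the model constants minimizing the sum of squared errors
#' between observed and predicted moisture ratios, using
#' Levenberg-Marquardt least squares ([minpack.lm::nls.lm()]) from a
#' seeded Latin-hypercube multi-start over the parameter bounds plus one
#' heuristic start. The best of all starts is returned together with the
#' full goodness-of-fit battery from [goodness_of_fit()].
#'
#' Fitting is performed on the hour scale by default (`time_unit = "h"`,
#' i.e. the minute grid of an [mr_series()] is divided by 60), which
#' places the rate constant `k` on the customary literature scale for
#' thin-bed pomace drying (k of order 0.1-1 h^-n). Use
#' `time_unit = "min"` to fit on the raw minute grid.
#'
#' @param mr An [mr_series()], or any data frame with columns `time_min`
#'   and `mr`.
#' @param model A `tl_model` or model name (see [thin_layer_models()]).
#' @param control A [fit_control()] list.
#' @param time_unit `"h"` (default) or `"min"`: unit the time grid is
#'   converted to before fitting; the unit `k` is reported in.
#'
#' @return An object of class `drying_fit`: list with `model`, `params`
#'   (named estimates), `N`, `K`, `stats` (R2, chi_sq, MSE, SSE, RMSE,
#'   AIC, AICc), `converged`, `n_starts_used`, `time_unit`,
#'   `temperature_C`, and the fitted data (`times`, `mr_exp`, `mr_pre`).
#' @export
#' @examples
#' tt <- seq(0, 210, 30)
#' y <- evaluate_model("page", c(k = 0.6635, n = 1.0826), tt / 60)
#' fit <- fit_drying_model(mr_series(tt, y), "page")
#' fit$params
fit_drying_model <- function(mr, model, control = fit_control(),
                             time_unit = c("h", "min")) {
  time_unit <- match.arg(time_unit)
  if (is.character(model)) model <- tl_model(model)
  stopifnot(inherits(model, "tl_model"))
  if (!is.data.frame(mr) || !all(c("time_min", "mr") %in% names(mr)))
    stop_input("`mr` must have columns `time_min` and `mr`")
  times <- mr$time_min / if (time_unit == "h") 60 else 1
  y <- mr$mr
  if (any(!is.finite(y))) stop_input("mr values must be finite")
  K <- length(model$param_names)
  N <- length(y)
  if (N < K + 2)
    stop_input("need at least K + 2 = ", K + 2, " observations to fit ",
               model$name)

  resid_fn <- function(p) {
    model$fun(as.list(setNames(p, model$param_names)), times) - y
  }
  starts <- rbind(heuristic_start(model, times, y),
                  lh_starts(model, control$n_starts, control$seed))
  ctrl <- minpack.lm::nls.lm.control(
    ftol = control$sse_tol * 1e-3, ptol = 1e-12,
    maxiter = control$max_iter)

  best <- NULL
  best_sse <- Inf
  n_ok <- 0L
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = model$lower,
                         upper = model$upper, fn = resid_fn,
                         control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    n_ok <- n_ok + 1L
    sse <- sum(res$fvec^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- res
    }
  }
  if (is.null(best))
    stop(errorCondition(
      paste0("no start converged for model ", model$name),
      class = c("drypom_fit_failure", "error")))

  params <- setNames(as.numeric(best$par), model$param_names)
  pred <- model$fun(as.list(params), times)
  stats <- goodness_of_fit(y, pred, K)
  structure(list(
    model = model$name,
    params = params,
    N = N, K = K,
    stats = stats,
    converged = best$info %in% 1:4,
    n_starts_used = n_ok,
    time_unit = time_unit,
    temperature_C = if (!is.null(attr(mr, "temperature_C")))
      attr(mr, "temperature_C") else NA_real_,
    times = times, mr_exp = y, mr_pre = pred
  ), class = "drying_fit")
}

#' @export
print.drying_fit <- function(x, ...) {
  cat("Thin-layer fit:", x$model,
      sprintf("(N = %d, K = %d, k in %s^-n scale)\n", x$N, x$K, x$time_unit))
  print(signif(x$params, 4))
  cat(sprintf("R2 = %.4f  RMSE = %.4g  AICc = %.4f\n",
              x$stats$R2, x$stats$RMSE, x$stats$AICc))
  invisible(x)
}

#' Goodness-of-fit battery for a fitted drying model
#'
#' Computes the seven statistics used to compare thin-layer drying models:
#'
#' * R2 = 1 - SSE / sum((mean(MR_exp) - MR_exp_i)^2)
#' * chi_sq = sum((MR_exp - MR_pre)^2 / MR_pre), excluding points with
#'   predicted MR below `chi_guard` (division guard; the number excluded
#'   is reported and a warning raised)
#' * MSE = SSE / N, RMSE = sqrt(MSE)
#' * AIC = N log(SSE / N) + 2 K
#' * AICc = AIC + 2 K (K + 1) / (N - K - 1)
#'
#' A perfect fit (SSE = 0) reports AIC and AICc as `-Inf` with
#' `perfect_fit = TRUE` rather than erroring; this occurs routinely on
#' noiseless synthetic data. When N <= K + 1 the small-sample correction
#' is undefined and AICc is `NaN` with a warning.
#'
#' @param mr_exp Observed moisture ratios.
#' @param mr_pre Predicted moisture ratios, same length.
#' @param K Number of fitted model parameters.
#' @param chi_guard Predicted values at or below this floor are excluded
#'   from the chi-square sum. Default 1e-6.
#'
#' @return Named list: `R2`, `chi_sq`, `MSE`, `SSE`, `RMSE`, `AIC`,
#'   `AICc`, plus `N`, `K`, `chi_sq_n_excluded` and `perfect_fit`.
#' @export
#' @examples
#' goodness_of_fit(c(1, 0.6, 0.3), c(0.9, 0.65, 0.35), K = 2)
goodness_of_fit <- function(mr_exp, mr_pre, K, chi_guard = 1e-6) {
  if (length(mr_exp) != length(mr_pre))
    stop_input("observed and predicted series must have equal length")
  N <- length(mr_exp)
  if (N < 2) stop_input("need at least 2 observations")
  sse <- sum((mr_exp - mr_pre)^2)
  sst <- sum((mean(mr_exp) - mr_exp)^2)
  if (sst == 0)
    stop_input("R2 undefined: observed series is constant")
  use <- mr_pre > chi_guard
  n_excl <- sum(!use)
  if (n_excl > 0)
    warning(n_excl, " point(s) with predicted MR <= ", chi_guard,
            " excluded from the chi-square sum")
  chi_sq <- sum((mr_exp[use] - mr_pre[use])^2 / mr_pre[use])
  mse <- sse / N
  perfect <- sse == 0
  aic <- if (perfect) -Inf else N * log(sse / N) + 2 * K
  aicc <- if (N > K + 1) {
    aic + 2 * K * (K + 1) / (N - K - 1)
  } else {
    warning("AICc undefined for N <= K + 1; returning NaN")
    NaN
  }
  list(R2 = 1 - sse / sst, chi_sq = chi_sq, MSE = mse, SSE = sse,
       RMSE = sqrt(mse), AIC = aic, AICc = aicc,
       N = N, K = K, chi_sq_n_excluded = n_excl, perfect_fit = perfect)
}

#' Rank competing model fits
#'
#' Orders fits of the same data by ascending AICc (the small-sample
#' criterion), breaking ties by RMSE and then by fewer parameters.
#' Perfect fits (AICc = -Inf) sort first.
#'
#' @param fits A list of `drying_fit` objects computed on the same data.
#' @return The list reordered best-first, with a `ranking` attribute: a
#'   data frame of model, K, SSE, RMSE, AICc.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "drying_fit")))
  Ns <- vapply(fits, function(f) f$N, numeric(1))
  if (length(unique(Ns)) != 1)
    stop(errorCondition("fits computed on different numbers of observations",
                        class = c("drypom_invalid_comparison", "error")))
  aicc <- vapply(fits, function(f) f$stats$AICc, numeric(1))
  rmse <- vapply(fits, function(f) f$stats$RMSE, numeric(1))
  K <- vapply(fits, function(f) f$K, numeric(1))
  ord <- order(aicc, rmse, K)
  out <- fits[ord]
  attr(out, "ranking") <- data.frame(
    model = vapply(out, function(f) f$model, character(1)),
    K = K[ord], SSE = vapply(out, function(f) f$stats$SSE, numeric(1)),
    RMSE = rmse[ord], AICc = aicc[ord])
  out
}

#' Tabulate fits in the conventional report layout
#'
#' One row per fit: model, temperature, the five possible constants (NA
#' where a model lacks one) and the seven fit statistics.
#'
#' @param fits A list of `drying_fit` objects (possibly across
#'   temperatures).
#' @return A data frame.
#' @export
fit_report <- function(fits) {
  stopifnot(all(vapply(fits, inherits, TRUE, "drying_fit")))
  rows <- lapply(fits, function(f) {
    p <- setNames(rep(NA_real_, 5), c("a", "b", "c", "k", "n"))
    p[names(f$params)] <- f$params
    data.frame(model = f$model, temperature_C = f$temperature_C,
               t(p), R2 = f$stats$R2, chi_sq = f$stats$chi_sq,
               MSE = f$stats$MSE, SSE = f$stats$SSE, RMSE = f$stats$RMSE,
               AIC = f$stats$AIC, AICc = f$stats$AICc,
               converged = f$converged)
  })
  do.call(rbind, rows)
}
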