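#' The thin-layer drying model bank
#'
#' Five classical semi-empirical thin-layer drying models for the moisture
#' ratio MR(t):
#'
#' | name              | equation                     | parameters |
#' |-------------------|------------------------------|------------|
#' | `page`            | exp(-k t^n)                  | k, n       |
#' | `modified_page`   | \[exp(-k t)\]^n              | k, n       |
#' | `henderson_pabis` | a exp(-k t)                  | a, k       |
#' | `logarithmic`     | a exp(-k t) + c              | a, k, c    |
#' | `midilli`         | a exp(-k t^n) + b t          | a, k, n, b |
#'
#' Rate constants `k` carry units of (time unit)^-n, so the numeric value
#' depends on the time unit of the grid the model is evaluated on; the
#' fitting pipeline works on the hour scale by default, where literature
#' values for berry pomace fall in roughly 0.2-1 h^-n.
#'
#' Default parameter bounds used by the fitting routine:
#' k in (1e-6, 50), n in (0.1, 5), a in (0.5, 1.5), b in (-0.01, 0.01),
#' c in (-0.5, 0.5). Fitted constants on sensible drying data lie well
#' inside these; they exist to keep multi-start optimization in a sane box.
#'
#' @param name Model name; one of the five above.
#'
#' @return `thin_layer_models()` returns a named list of all five model
#'   specifications; `tl_model()` returns a single specification: a list
#'   with `name`, `param_names`, `lower`, `upper` and `fun(params, t)`.
#' @export
#' @examples
#' names(thin_layer_models())
#' tl_model("page")$param_names
thin_layer_models <- function() {
  lapply(setNames(nm = c("page", "modified_page", "henderson_pabis",
                         "logarithmic", "midilli")), tl_model)
}

.tl_bounds <- list(
  k = c(1e-6, 50), n = c(0.1, 5), a = c(0.5, 1.5),
  b = c(-0.01, 0.01), c = c(-0.5, 0.5)
)

.tl_funs <- list(
  page            = function(p, t) exp(-p[["k"]] * t^p[["n"]]),
  modified_page   = function(p, t) exp(-p[["k"]] * t)^p[["n"]],
  henderson_pabis = function(p, t) p[["a"]] * exp(-p[["k"]] * t),
  logarithmic     = function(p, t) p[["a"]] * exp(-p[["k"]] * t) + p[["c"]],
  midilli         = function(p, t)
    p[["a"]] * exp(-p[["k"]] * t^p[["n"]]) + p[["b"]] * t
)

.tl_params <- list(
  page = c("k", "n"), modified_page = c("k", "n"),
  henderson_pabis = c("a", "k"), logarithmic = c("a", "k", "c"),
  midilli = c("a", "k", "n", "b")
)

#' @rdname thin_layer_models
#' @export
tl_model <- function(name) {
  name <- match.arg(name, names(.tl_funs))
  pn <- .tl_params[[name]]
  structure(list(
    name = name,
    param_names = pn,
    lower = vapply(pn, function(p) .tl_bounds[[p]][1], numeric(1)),
    upper = vapply(pn, function(p) .tl_bounds[[p]][2], numeric(1)),
    fun = .tl_funs[[name]]
  ), class = "tl_model")
}

#' Evaluate a thin-layer drying model
#'
#' Predicted moisture ratio at the given times for a complete parameter
#' set. The time unit is whatever unit `times` is expressed in; `k` is
#' then per that unit (raised to `n` where applicable).
#'
#' @param model A `tl_model` object or a model name.
#' @param params Named numeric vector or list covering the model's
#'   `param_names`.
#' @param times Non-negative numeric vector of times.
#'
#' @return Numeric vector of predicted MR values.
#' @export
#' @examples
#' evaluate_model("page", c(k = 0.3344, n = 1.0569), times = 1)
evaluate_model <- function(model, params, times) {
  if (is.character(model)) model <- tl_model(model)
  stopifnot(inherits(model, "tl_model"))
  params <- unlist(params)
  missing <- setdiff(model$param_names, names(params))
  if (length(missing))
    stop_input("missing parameter(s) for ", model$name, ": ",
               paste(missing, collapse = ", "))
  times <- as.numeric(times)
  if (any(times < 0)) stop_input("times must be >= 0")
  as.numeric(model$fun(as.list(params), times))
}
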