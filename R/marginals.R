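#' Default transform kind per parameter
#'
#' Durations and millisecond-scale HRV metrics use a log-normal transform;
#' the two parameters with hard two-sided physiological ranges of modest
#' width (LF/HF, PNN50) use a bounded logit transform. Overridable via the
#' `transforms` entry of a run configuration.
#'
#' @return Named character vector, values `"lognormal"` or `"logit"`.
#' @export
default_transforms <- function() {
  c(total_sleep_h = "lognormal", deep_sleep_h = "lognormal",
    light_sleep_h = "lognormal", sdnn_ms = "lognormal",
    rmssd_ms = "lognormal", lf_hf = "logit", pnn50_pct = "logit")
}

# epsilon shrinkage (as a fraction of interval width) applied before log/logit
# so exact-boundary values map to finite latents
.marg_eps <- 1e-6

marg_prepare <- function(x, kind, bounds) {
  w <- bounds[2] - bounds[1]
  lo <- bounds[1] + .marg_eps * w
  hi <- bounds[2] - .marg_eps * w
  clipped <- sum(x < lo | x > hi)
  x <- pmin(pmax(x, lo), hi)
  y <- switch(kind,
    lognormal = log(x),
    logit = stats::qlogis((x - bounds[1]) / w),
    rlang::abort(paste0("unknown transform kind: ", kind))
  )
  list(y = y, clipped = clipped)
}

#' Fit a constraint-preserving marginal transform
#'
#' Maps one physiological parameter to a latent standard-normal scale:
#' `z = (log x - mu) / sigma` for log-normal parameters, or the logit of the
#' min-max rescaled value, standardized, for bounded parameters. Values at or
#' beyond the box bounds are shrunk inward by 1e-6 of the interval width so
#' latents stay finite; the clip count is recorded.
#'
#' @param values Numeric vector, n >= 10.
#' @param parameter Canonical parameter name.
#' @param bounds Length-2 numeric bounds (defaults to the constraint box).
#' @param kind `"lognormal"` or `"logit"`; defaults per [default_transforms()].
#' @return A `marginal_model`: list with `parameter`, `kind`, `location`,
#'   `scale`, `bounds`, `n`, `clipped`.
#' @export
fit_marginal <- function(values, parameter,
                         bounds = default_constraints()$box_bounds[[parameter]],
                         kind = default_transforms()[[parameter]]) {
  if (length(values) < 10) rlang::abort("need at least 10 values to fit a marginal")
  if (any(!is.finite(values))) rlang::abort("`values` must be finite")
  pr <- marg_prepare(values, kind, bounds)
  s <- stats::sd(pr$y)
  if (!is.finite(s) || s < 1e-12) {
    rlang::abort(paste0("degenerate column: `", parameter, "` has zero variance"))
  }
  structure(list(parameter = parameter, kind = kind,
                 location = mean(pr$y), scale = s,
                 bounds = as.numeric(bounds),
                 n = length(values), clipped = pr$clipped),
            class = "marginal_model")
}

#' @export
print.marginal_model <- function(x, ...) {
  cat(sprintf("<marginal_model> %s (%s): location %.4f, scale %.4f on [%g, %g]\n",
              x$parameter, x$kind, x$location, x$scale, x$bounds[1], x$bounds[2]))
  invisible(x)
}

#' Fit marginal transforms for all seven parameters
#'
#' @param records Data frame with the canonical columns.
#' @param cs Constraint set providing the bounds.
#' @param transforms Named character vector of transform kinds.
#' @return Named list of `marginal_model` objects in canonical column order.
#' @export
fit_marginals <- function(records, cs = default_constraints(),
                          transforms = default_transforms()) {
  assert_records(records)
  models <- purrr::map(sleep_parameters(), function(p) {
    fit_marginal(records[[p]], p, bounds = cs$box_bounds[[p]], kind = transforms[[p]])
  })
  rlang::set_names(models, sleep_parameters())
}

marg_forward <- function(x, m) {
  pr <- marg_prepare(x, m$kind, m$bounds)
  (pr$y - m$location) / m$scale
}

marg_backward <- function(z, m) {
  y <- z * m$scale + m$location
  switch(m$kind,
    lognormal = pmin(pmax(exp(y), m$bounds[1]), m$bounds[2]),
    logit = m$bounds[1] + (m$bounds[2] - m$bounds[1]) * stats::plogis(y)
  )
}

#' Map records to the latent standard-normal scale and back
#'
#' `to_latent()` applies each fitted transform column-wise; `from_latent()`
#' inverts it. The round trip is the identity (to floating-point precision)
#' for in-bounds values, and `from_latent()` output always lies inside the
#' parameter bounds.
#'
#' @param records Data frame with the canonical columns (for `to_latent`).
#' @param latent Data frame/matrix of latent columns (for `from_latent`).
#' @param models Named list from [fit_marginals()].
#' @return A tibble with the canonical columns.
#' @export
to_latent <- function(records, models) {
  assert_records(records)
  check_model_set(models)
  tibble::as_tibble(purrr::map(rlang::set_names(sleep_parameters()), function(p) {
    marg_forward(records[[p]], models[[p]])
  }))
}

#' @rdname to_latent
#' @export
from_latent <- function(latent, models) {
  check_model_set(models)
  latent <- tibble::as_tibble(as.data.frame(latent))
  if (!all(sleep_parameters() %in% names(latent))) {
    if (ncol(latent) == 7L) {
      names(latent) <- sleep_parameters()
    } else {
      rlang::abort("`latent` must have the seven canonical columns")
    }
  }
  tibble::as_tibble(purrr::map(rlang::set_names(sleep_parameters()), function(p) {
    marg_backward(latent[[p]], models[[p]])
  }))
}

check_model_set <- function(models) {
  if (!identical(sort(names(models)), sort(sleep_parameters()))) {
    rlang::abort("`models` must contain one marginal_model per canonical parameter")
  }
  invisible(models)
}

#' Standard-normal CDF and quantile used by the latent-uniform bridge
#'
#' Thin wrappers with domain checking: the sampler draws correlated uniforms
#' from the copula, maps them to latent normals with `std_normal_quantile()`
#' and back with `std_normal_cdf()`.
#'
#' @param x,u Numeric vectors; `u` must lie strictly inside (0, 1).
#' @return Numeric vector.
#' @export
std_normal_cdf <- function(x) stats::pnorm(x)

#' @rdname std_normal_cdf
#' @export
std_normal_quantile <- function(u) {
  if (any(u <= 0 | u >= 1)) rlang::abort("`u` must lie strictly in (0, 1)")
  stats::qnorm(u)
}

marginal_to_list <- function(m) unclass(m)

marginal_from_list <- function(x) {
  x$bounds <- as.numeric(x$bounds)
  structure(x, class = "marginal_model")
}
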