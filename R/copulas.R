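#' Default two-subsystem partition of the seven parameters
#'
#' Sleep-architecture subsystem (total, deep, light sleep duration) and
#' autonomic-regulation subsystem (SDNN, RMSSD, LF/HF, PNN50).
#'
#' @return Named list of character vectors of canonical parameter names.
#' @export
default_partition <- function() {
  list(
    sleep_architecture = c("total_sleep_h", "deep_sleep_h", "light_sleep_h"),
    autonomic = c("sdnn_ms", "rmssd_ms", "lf_hf", "pnn50_pct")
  )
}

#' Pseudo-observations by average ranks
#'
#' Ranks scaled by (n + 1) so values lie strictly inside (0, 1); ties take
#' average ranks.
#'
#' @param x Numeric vector or data frame/matrix (column-wise).
#' @return Object of the same shape with entries in (0, 1).
#' @export
pseudo_obs <- function(x) {
  if (is.data.frame(x)) return(tibble::as_tibble(purrr::map(x, pseudo_obs)))
  if (is.matrix(x)) return(apply(x, 2, pseudo_obs))
  rank(x, ties.method = "average") / (length(x) + 1)
}

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected Kendall correlation (tau-b). Constant input carries no
#' dependence information and yields `NA` with a warning.
#'
#' @param u,v Equal-length numeric vectors, n >= 2.
#' @return Scalar in \[-1, 1\], or `NA` for constant input.
#' @export
kendall_tau <- function(u, v) {
  if (length(u) != length(v)) rlang::abort("`u` and `v` must have equal length")
  if (length(u) < 2) rlang::abort("need at least 2 observations")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    rlang::warn("constant input: no dependence information")
    return(NA_real_)
  }
  stats::cor(u, v, method = "kendall")
}

mean_pairwise_tau <- function(u) {
  u <- as.matrix(u)
  d <- ncol(u)
  taus <- c()
  for (i in seq_len(d - 1)) for (j in (i + 1):d) {
    taus <- c(taus, kendall_tau(u[, i], u[, j]))
  }
  mean(taus, na.rm = TRUE)
}

#' Empirical tail-dependence coefficients
#'
#' Estimates the lower and upper tail-dependence coefficients of a bivariate
#' copula sample at quantile level `q`:
#' `lambda_L = P(v < q | u < q)` and `lambda_U = P(v > 1-q | u > 1-q)`.
#'
#' @param u,v Pseudo-observations in (0, 1), n >= 50.
#' @param q Tail quantile level in (0, 0.5\].
#' @return List with `lambda_lower`, `lambda_upper`, `n_lower`, `n_upper`
#'   (tail point counts) and `wide` (TRUE when either tail has < 10 points,
#'   flagging an unstable estimate).
#' @export
tail_dependence <- function(u, v, q = 0.05) {
  if (q <= 0 || q > 0.5) rlang::abort("`q` must lie in (0, 0.5]")
  if (length(u) < 50) rlang::abort("need n >= 50 for tail estimation")
  n_lo <- sum(u < q)
  n_up <- sum(u > 1 - q)
  lam_lo <- if (n_lo > 0) sum(u < q & v < q) / n_lo else NA_real_
  lam_up <- if (n_up > 0) sum(u > 1 - q & v > 1 - q) / n_up else NA_real_
  list(lambda_lower = lam_lo, lambda_upper = lam_up,
       n_lower = n_lo, n_upper = n_up,
       wide = (n_lo < 10 || n_up < 10))
}

#' Select a copula family from tail behaviour
#'
#' Compares mean pairwise empirical upper and lower tail dependence: a clear
#' upper-tail excess selects Gumbel, a clear lower-tail excess selects
#' Clayton, otherwise the Gaussian family is the fallback.
#'
#' @param u Matrix/data frame of pseudo-observations, n >= 100.
#' @param q Tail quantile level.
#' @param delta Decision margin on the tail-coefficient difference.
#' @return One of `"gumbel"`, `"clayton"`, `"gaussian"`.
#' @export
select_family <- function(u, q = 0.05, delta = 0.1) {
  u <- as.matrix(u)
  if (nrow(u) < 100) rlang::abort("need n >= 100 for family selection")
  d <- ncol(u)
  lo <- up <- c()
  for (i in seq_len(d - 1)) for (j in (i + 1):d) {
    td <- tail_dependence(u[, i], u[, j], q)
    lo <- c(lo, td$lambda_lower); up <- c(up, td$lambda_upper)
  }
  dlo <- mean(lo, na.rm = TRUE); dup <- mean(up, na.rm = TRUE)
  if (dup - dlo > delta) "gumbel"
  else if (dlo - dup > delta) "clayton"
  else "gaussian"
}

new_copula_model <- function(family, dim, theta = NULL, sigma = NULL) {
  if (family == "gumbel" && (is.null(theta) || theta < 1)) {
    rlang::abort("gumbel theta must be >= 1")
  }
  if (family == "clayton" && (is.null(theta) || theta <= 0)) {
    rlang::abort("clayton theta must be > 0")
  }
  structure(list(family = family, dim = dim, theta = theta, sigma = sigma),
            class = "copula_model")
}

#' @export
print.copula_model <- function(x, ...) {
  if (x$family %in% c("gumbel", "clayton")) {
    cat(sprintf("<copula_model> %s, d = %d, theta = %.4f (tau = %.4f)\n",
                x$family, x$dim, x$theta, implied_tau(x)))
  } else {
    cat(sprintf("<copula_model> %s, d = %d\n", x$family, x$dim))
  }
  invisible(x)
}

#' Model-implied Kendall tau of a fitted copula
#'
#' Closed forms: Gumbel `tau = 1 - 1/theta`, Clayton `tau = theta/(theta+2)`,
#' Gaussian `tau = (2/pi) asin(rho)` averaged over off-diagonal pairs,
#' independence 0.
#'
#' @param model A `copula_model`.
#' @return Scalar Kendall tau.
#' @export
implied_tau <- function(model) {
  switch(model$family,
    gumbel = 1 - 1 / model$theta,
    clayton = model$theta / (model$theta + 2),
    gaussian = {
      s <- model$sigma
      mean((2 / pi) * asin(s[upper.tri(s)]))
    },
    independence = 0
  )
}

#' Fit a copula by Kendall-tau inversion
#'
#' Archimedean parameters come from the mean pairwise tau-b through the
#' closed forms `theta = 1/(1 - tau)` (Gumbel) and `theta = 2 tau/(1 - tau)`
#' (Clayton). The Gaussian family uses the rank-based normal-scores
#' correlation matrix, repaired to the nearest positive-definite correlation
#' matrix when needed. Non-positive tau makes an Archimedean family collapse
#' to independence (Gumbel: theta = 1; Clayton: independence fallback with a
#' warning).
#'
#' @param u Matrix/data frame of pseudo-observations in (0, 1), n >= 30.
#' @param family `"gumbel"`, `"clayton"`, `"gaussian"` or `"independence"`.
#' @return A `copula_model`.
#' @export
fit_copula <- function(u, family) {
  u <- as.matrix(u)
  if (nrow(u) < 30) rlang::abort("need n >= 30 to fit a copula")
  if (any(u <= 0 | u >= 1)) rlang::abort("pseudo-observations must lie in (0, 1)")
  d <- ncol(u)
  if (family == "independence") return(new_copula_model("independence", d))
  if (family == "gaussian") {
    z <- stats::qnorm(u)
    s <- stats::cor(z)
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8) {
      s <- as.matrix(Matrix::nearPD(s, corr = TRUE)$mat)
    }
    return(new_copula_model("gaussian", d, sigma = s))
  }
  tau <- mean_pairwise_tau(u)
  if (family == "gumbel") {
    if (is.na(tau) || tau <= 0) return(new_copula_model("gumbel", d, theta = 1))
    return(new_copula_model("gumbel", d, theta = 1 / (1 - tau)))
  }
  if (family == "clayton") {
    if (is.na(tau) || tau <= 0) {
      rlang::warn("non-positive tau: falling back to the independence copula")
      return(new_copula_model("independence", d))
    }
    return(new_copula_model("clayton", d, theta = 2 * tau / (1 - tau)))
  }
  rlang::abort(paste0("unknown family: ", family))
}

# Positive-stable(alpha) draws with Laplace transform exp(-t^alpha),
# Chambers-Mallows-Stuck construction; the Gumbel frailty.
rpostable <- function(n, alpha) {
  v <- stats::runif(n, 0, pi)
  w <- stats::rexp(n)
  (sin(alpha * v) / sin(v)^(1 / alpha)) *
    (sin((1 - alpha) * v) / w)^((1 - alpha) / alpha)
}

#' Sample from a fitted copula
#'
#' Exact samplers: Gumbel via the positive-stable frailty construction,
#' Clayton via the gamma frailty, Gaussian via the Cholesky factor of the
#' correlation matrix, independence via i.i.d. uniforms. Margins are uniform
#' on (0, 1) by construction.
#'
#' @param model A `copula_model`.
#' @param n Number of rows.
#' @return An n x d matrix of uniforms in (0, 1).
#' @export
sample_copula <- function(model, n) {
  if (n < 1) rlang::abort("`n` must be >= 1")
  d <- model$dim
  switch(model$family,
    independence = matrix(stats::runif(n * d), n, d),
    gumbel = {
      if (model$theta == 1) return(matrix(stats::runif(n * d), n, d))
      s <- rpostable(n, 1 / model$theta)
      e <- matrix(stats::rexp(n * d), n, d)
      exp(-(e / s)^(1 / model$theta))
    },
    clayton = {
      g <- stats::rgamma(n, shape = 1 / model$theta, rate = 1)
      e <- matrix(stats::rexp(n * d), n, d)
      (1 + e / g)^(-1 / model$theta)
    },
    gaussian = {
      ch <- chol(model$sigma)
      z <- matrix(stats::rnorm(n * d), n, d) %*% ch
      stats::pnorm(z)
    }
  )
}

#' Build the two-level vine structure linking the subsystems
#'
#' Fits the cross-subsystem dependence through one conditional pair:
#' the deep-sleep ratio (deep/total) and RMSSD, coupled by a bivariate
#' Gaussian linking copula fitted on normal scores of ranks. The ratio's
#' latent score is additionally regressed on the three sleep-architecture
#' latents so that it can be reconstructed during sampling.
#'
#' @param u Data frame of pseudo-observations for the seven parameters.
#' @param partition Subsystem partition, see [default_partition()].
#' @param models Named list of fitted per-subsystem `copula_model`s.
#' @param ratio Numeric vector of deep/total ratios from the training
#'   records (same row order as `u`); `NULL` drops the link.
#' @return A `vine_structure`: partition, subsystem models and the link
#'   (`NULL` when dropped).
#' @export
build_vine <- function(u, partition = default_partition(), models, ratio = NULL) {
  stopifnot(identical(names(models), names(partition)))
  link <- NULL
  if (!is.null(ratio)) {
    if (stats::sd(ratio) < 1e-12) {
      rlang::warn("degenerate deep-sleep ratio: cross-subsystem link dropped")
    } else {
      z <- stats::qnorm(as.matrix(pseudo_obs(tibble::as_tibble(u))))
      colnames(z) <- names(u)
      zr <- stats::qnorm(pseudo_obs(ratio))
      sub1 <- partition[[1]]
      fit <- stats::lm.fit(x = cbind(1, z[, sub1, drop = FALSE]), y = zr)
      rho <- stats::cor(zr, z[, "rmssd_ms"])
      link <- list(
        source = "deep_sleep_ratio", target = "rmssd_ms",
        rho = rho,
        coef = stats::setNames(fit$coefficients, c("(Intercept)", sub1)),
        resid_sd = stats::sd(fit$residuals)
      )
    }
  }
  structure(list(partition = partition, models = models, link = link),
            class = "vine_structure")
}

#' @export
print.vine_structure <- function(x, ...) {
  cat("<vine_structure>\n")
  for (nm in names(x$models)) {
    cat("  ", nm, ": ", sep = "")
    print(x$models[[nm]])
  }
  if (is.null(x$link)) cat("  link: none\n")
  else cat(sprintf("  link: %s -> %s, Gaussian rho = %.4f\n",
                   x$link$source, x$link$target, x$link$rho))
  invisible(x)
}

#' Sample correlated uniforms from the vine structure
#'
#' Samples the sleep-architecture subsystem, reconstructs the deep-sleep
#' ratio's latent score from the regression stored in the link, then samples
#' the autonomic subsystem and shifts its linked coordinate (RMSSD) through
#' the conditional of the bivariate Gaussian linking copula. The shift
#' preserves uniform margins and attenuates within-subsystem dependence of
#' the linked coordinate only by the factor sqrt(1 - rho^2).
#'
#' @param vine A `vine_structure`.
#' @param n Number of rows.
#' @return An n x 7 matrix of uniforms, columns in canonical order.
#' @export
sample_vine <- function(vine, n) {
  part <- vine$partition
  u1 <- sample_copula(vine$models[[1]], n)
  colnames(u1) <- part[[1]]
  u2 <- sample_copula(vine$models[[2]], n)
  colnames(u2) <- part[[2]]
  if (!is.null(vine$link)) {
    z1 <- stats::qnorm(u1)
    co <- vine$link$coef
    zr <- co[1] + z1 %*% co[-1] + vine$link$resid_sd * stats::rnorm(n)
    zr <- as.numeric(zr)
    # reconstructed ratio score is ~N(0,1) by construction of the regression
    j <- vine$link$target
    rho <- vine$link$rho
    z_t <- rho * zr + sqrt(1 - rho^2) * stats::qnorm(u2[, j])
    u2[, j] <- stats::pnorm(z_t)
  }
  u <- cbind(u1, u2)[, sleep_parameters(), drop = FALSE]
  # guard exact 0/1 from floating point
  pmin(pmax(u, 1e-12), 1 - 1e-12)
}

copula_to_list <- function(m) {
  out <- list(family = m$family, dim = m$dim)
  if (!is.null(m$theta)) out$theta <- m$theta
  if (!is.null(m$sigma)) out$sigma <- as.data.frame(m$sigma)
  out
}

copula_from_list <- function(x) {
  sigma <- if (!is.null(x$sigma)) as.matrix(x$sigma) else NULL
  if (!is.null(sigma)) dimnames(sigma) <- NULL
  new_copula_model(x$family, as.integer(x$dim), theta = x$theta, sigma = sigma)
}

vine_to_list <- function(v) {
  list(partition = v$partition,
       models = purrr::map(v$models, copula_to_list),
       link = v$link)
}

vine_from_list <- function(x) {
  link <- x$link
  if (!is.null(link)) {
    link$coef <- unlist(link$coef)
    link$rho <- as.numeric(link$rho)
    link$resid_sd <- as.numeric(link$resid_sd)
  }
  structure(list(partition = lapply(x$partition, as.character),
                 models = purrr::map(x$models, copula_from_list),
                 link = link),
            class = "vine_structure")
}
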