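#' Histogram KL divergence between two samples
#'
#' Estimates KL(real || synth) on shared equal-width bins spanning the
#' pooled range. Both histograms receive an additive epsilon and are
#' renormalized, so empty synthetic bins stay finite.
#'
#' @param real,synth Numeric samples, each n >= 50.
#' @param bins Number of equal-width bins.
#' @param epsilon Additive smoothing constant.
#' @return Nonnegative scalar.
#' @export
kl_divergence <- function(real, synth, bins = 50, epsilon = 1e-8) {
  if (length(real) < 50 || length(synth) < 50) {
    rlang::abort("both samples must have n >= 50")
  }
  rng <- range(c(real, synth))
  if (diff(rng) <= 0) rlang::abort("degenerate pooled range")
  brk <- seq(rng[1], rng[2], length.out = bins + 1)
  p <- tabulate(findInterval(real, brk, rightmost.closed = TRUE, all.inside = TRUE),
                nbins = bins) / length(real)
  q <- tabulate(findInterval(synth, brk, rightmost.closed = TRUE, all.inside = TRUE),
                nbins = bins) / length(synth)
  p <- (p + epsilon) / sum(p + epsilon)
  q <- (q + epsilon) / sum(q + epsilon)
  sum(p * log(p / q))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Wrapper over the classical two-sample KS test comparing empirical CDFs;
#' tie warnings (common for projected synthetic values at constraint bounds)
#' are suppressed.
#'
#' @param real,synth Numeric samples, each n >= 10.
#' @return List with `statistic` and `p_value`.
#' @export
ks_two_sample <- function(real, synth) {
  if (length(real) < 10 || length(synth) < 10) rlang::abort("need n >= 10 per sample")
  kt <- suppressWarnings(stats::ks.test(real, synth))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

median_bandwidth <- function(x) {
  d <- as.matrix(stats::dist(x))
  m <- stats::median(d[upper.tri(d)])
  if (!is.finite(m) || m <= 0) 1 else m
}

gauss_gram <- function(x, bw) {
  d2 <- as.matrix(stats::dist(x))^2
  exp(-d2 / (2 * bw^2))
}

#' Hilbert-Schmidt Independence Criterion
#'
#' Gaussian-kernel biased V-statistic `HSIC = trace(K H L H) / n^2` with the
#' centering operator `H = I - 11'/n`; bandwidths by the median heuristic per
#' block. The p-value permutes the rows of `y` relative to `x`.
#'
#' @param x,y Numeric matrices/data frames with the same number of rows
#'   (n >= 20).
#' @param n_perm Number of permutations for the p-value (>= 200 recommended;
#'   0 skips the test).
#' @param bandwidth Optional fixed bandwidths `c(bx, by)`.
#' @return List with `hsic`, `p_value` (NA when `n_perm = 0`), `bandwidth`.
#' @export
hsic <- function(x, y, n_perm = 200, bandwidth = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (n != nrow(y)) rlang::abort("`x` and `y` must have equal n")
  if (n < 20) rlang::abort("need n >= 20")
  if (any(apply(x, 2, stats::sd) == 0) || any(apply(y, 2, stats::sd) == 0)) {
    rlang::abort("zero-variance input column")
  }
  bx <- if (is.null(bandwidth)) median_bandwidth(x) else bandwidth[1]
  by <- if (is.null(bandwidth)) median_bandwidth(y) else bandwidth[2]
  K <- gauss_gram(x, bx)
  L <- gauss_gram(y, by)
  H <- diag(n) - matrix(1 / n, n, n)
  Kc <- H %*% K %*% H
  stat <- sum(Kc * L) / n^2   # = trace(K H L H)/n^2
  p <- NA_real_
  if (n_perm > 0) {
    null <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      sum(Kc * L[idx, idx]) / n^2
    }, numeric(1))
    p <- (1 + sum(null >= stat)) / (n_perm + 1)
  }
  list(hsic = stat, p_value = p, bandwidth = c(x = bx, y = by))
}

#' Fidelity report comparing a synthetic cohort with its reference
#'
#' Computes, per canonical variable, the histogram KL divergence
#' (KL(real || synth), with the similarity transform exp(-KL) reported
#' alongside) and the two-sample KS statistic and p-value, plus a
#' dataset-level HSIC between the rank-standardized real and synthetic
#' tables. Two HSIC modes are available because "diversity" can be read
#' either as cross-dataset dependence (`"dataset"`) or as mean within-
#' dataset pairwise coupling of the synthetic table (`"within"`).
#'
#' @param real,synth Data frames with the canonical columns.
#' @param bins,epsilon KL estimator settings.
#' @param hsic_mode `"dataset"` or `"within"`.
#' @param n_perm Permutations for the HSIC p-value.
#' @param max_n Row cap for the HSIC computation (kernel matrices are
#'   O(n^2)); larger inputs are subsampled deterministically.
#' @return A `fidelity_report`: list with `per_variable` tibble, `ks_median_p`,
#'   `ks_min_p`, `hsic`, `hsic_p`, `hsic_mode`, `n_real`, `n_synth`, settings.
#' @export
evaluate_fidelity <- function(real, synth, bins = 50, epsilon = 1e-8,
                              hsic_mode = c("dataset", "within"),
                              n_perm = 200, max_n = 500) {
  assert_records(real); assert_records(synth)
  hsic_mode <- match.arg(hsic_mode)
  pv <- purrr::map_dfr(sleep_parameters(), function(p) {
    ks <- ks_two_sample(real[[p]], synth[[p]])
    kl <- kl_divergence(real[[p]], synth[[p]], bins, epsilon)
    tibble::tibble(parameter = p, kl = kl, kl_similarity = exp(-kl),
                   ks_statistic = ks$statistic, ks_p = ks$p_value)
  })
  ru <- apply(stats::qnorm(as.matrix(pseudo_obs(tibble::as_tibble(real)[sleep_parameters()]))), 2, identity)
  su <- apply(stats::qnorm(as.matrix(pseudo_obs(tibble::as_tibble(synth)[sleep_parameters()]))), 2, identity)
  sub_r <- if (nrow(ru) > max_n) ru[seq(1, nrow(ru), length.out = max_n), ] else ru
  sub_s <- if (nrow(su) > max_n) su[seq(1, nrow(su), length.out = max_n), ] else su
  if (hsic_mode == "dataset") {
    m <- min(nrow(sub_r), nrow(sub_s))
    hh <- hsic(sub_r[seq_len(m), ], sub_s[seq_len(m), ], n_perm = n_perm)
  } else {
    # mean pairwise HSIC across the 21 synthetic column pairs
    cols <- sleep_parameters()
    vals <- c()
    for (i in seq_along(cols)[-length(cols)]) for (j in (i + 1):length(cols)) {
      vals <- c(vals, hsic(sub_s[, i, drop = FALSE], sub_s[, j, drop = FALSE],
                           n_perm = 0)$hsic)
    }
    hh <- list(hsic = mean(vals), p_value = NA_real_)
  }
  structure(list(per_variable = pv,
                 ks_median_p = stats::median(pv$ks_p),
                 ks_min_p = min(pv$ks_p),
                 hsic = hh$hsic, hsic_p = hh$p_value, hsic_mode = hsic_mode,
                 n_real = nrow(real), n_synth = nrow(synth),
                 settings = list(bins = bins, epsilon = epsilon,
                                 n_perm = n_perm, max_n = max_n)),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat(sprintf("<fidelity_report> n_real = %d, n_synth = %d\n", x$n_real, x$n_synth))
  print(x$per_variable)
  cat(sprintf("KS p: median %.4f, min %.4f; HSIC (%s) %.5f (p = %s)\n",
              x$ks_median_p, x$ks_min_p, x$hsic_mode, x$hsic,
              format(x$hsic_p)))
  invisible(x)
}

clopper_pearson <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(stats::binom.test(x, n, conf.level = conf)$conf.int)
}

#' Sensitivity and specificity of predicted clinical endpoints
#'
#' Compares predicted against reference event labels for the two endpoints
#' (autonomic dysfunction, sympathetic dominance): 2x2 confusion counts,
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), with exact
#' Clopper-Pearson 95% confidence intervals. An endpoint with no positive
#' (or no negative) references gets an `NA` estimate and is flagged.
#'
#' @param predictions,references Data frames with logical columns
#'   `autonomic_dysfunction` and `sympathetic_dominance`, equal row count.
#' @return A tibble with one row per endpoint: counts, estimates and CIs.
#' @export
endpoint_performance <- function(predictions, references) {
  eps <- c("autonomic_dysfunction", "sympathetic_dominance")
  stopifnot(nrow(predictions) == nrow(references),
            all(eps %in% names(predictions)), all(eps %in% names(references)))
  purrr::map_dfr(eps, function(e) {
    p <- predictions[[e]]; r <- references[[e]]
    tp <- sum(p & r); fn <- sum(!p & r); tn <- sum(!p & !r); fp <- sum(p & !r)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    ci_se <- clopper_pearson(tp, tp + fn)
    ci_sp <- clopper_pearson(tn, tn + fp)
    tibble::tibble(endpoint = e, tp = tp, fn = fn, tn = tn, fp = fp,
                   sensitivity = sens, sens_ci_lo = ci_se[1], sens_ci_hi = ci_se[2],
                   specificity = spec, spec_ci_lo = ci_sp[1], spec_ci_hi = ci_sp[2],
                   undefined = is.na(sens) || is.na(spec))
  })
}
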