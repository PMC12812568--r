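#' Read / write sleep-record CSV files
#'
#' The canonical schema has exactly the seven parameter columns (extra
#' columns are preserved and passed through untouched). Reading validates
#' presence and numeric type of every canonical column and reports the
#' offending column; writing keeps full double precision so a write/read
#' round trip is lossless.
#'
#' @param path CSV path.
#' @return `read_records()` returns a tibble; `write_records()` returns
#'   `path` invisibly.
#' @export
read_records <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(sleep_parameters(), names(df))
  if (length(missing)) {
    rlang::abort(paste0("file is missing required columns: ",
                        paste(missing, collapse = ", ")))
  }
  for (p in sleep_parameters()) {
    if (!is.numeric(df[[p]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[p]]))) & !is.na(df[[p]]))
      rlang::abort(sprintf("column `%s` is not numeric (e.g. row %s)",
                           p, if (length(bad)) bad[1] else "?"))
    }
    if (any(is.na(df[[p]]))) {
      rlang::abort(sprintf("column `%s` has missing values (row %d)",
                           p, which(is.na(df[[p]]))[1]))
    }
  }
  df
}

#' @rdname read_records
#' @param records Data frame with the canonical columns.
#' @export
write_records <- function(records, path) {
  assert_records(records)
  readr::write_csv(tibble::as_tibble(records), path)
  invisible(path)
}

#' Specification of the offline reference-cohort generator
#'
#' Defines the ground truth the fixture generator draws from: per-parameter
#' marginal location/scale on the transformed axis, the within-subsystem
#' copula families and parameters (Gumbel for sleep architecture, Clayton
#' for the autonomic subsystem), and the cross-subsystem Gaussian linking
#' correlation. Defaults emulate a healthy adult cohort: ~7.2 h total sleep
#' with ~21% deep-sleep ratio, SDNN around 50 ms, RMSSD around 35 ms, LF/HF
#' around 2 and PNN50 around 20%, with strong positive rank dependence
#' within each subsystem. Under these settings the implied records satisfy
#' the constraint system with probability > 0.99 before enforcement.
#'
#' @param n Default cohort size.
#' @param sub1_family,sub1_theta Sleep-architecture copula.
#' @param sub2_family,sub2_theta Autonomic copula.
#' @param link_rho Gaussian linking correlation (deep-sleep ratio vs RMSSD).
#' @param archetype_mixture Optional length-3 mixture weights over the three
#'   HRV archetypes; when set, the autonomic latents receive archetype-
#'   specific mean shifts so the cohort contains profile blobs.
#' @param blob_shift Latent-scale shift magnitude for the archetype blobs.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n = 1000,
                         sub1_family = "gumbel", sub1_theta = 2,
                         sub2_family = "clayton", sub2_theta = 1.5,
                         link_rho = 0.3,
                         archetype_mixture = NULL, blob_shift = 3.5) {
  marginals <- list(
    total_sleep_h = list(kind = "lognormal", location = log(7.2), scale = 0.12),
    deep_sleep_h  = list(kind = "lognormal", location = log(1.5), scale = 0.18),
    light_sleep_h = list(kind = "lognormal", location = log(4.0), scale = 0.13),
    sdnn_ms       = list(kind = "lognormal", location = log(50), scale = 0.35),
    rmssd_ms      = list(kind = "lognormal", location = log(35), scale = 0.35),
    lf_hf         = list(kind = "logit", location = stats::qlogis((2 - 0.1) / 6.9), scale = 0.8),
    pnn50_pct     = list(kind = "logit", location = stats::qlogis(20 / 70), scale = 0.8)
  )
  if (!is.null(archetype_mixture)) {
    stopifnot(length(archetype_mixture) == 3, all(archetype_mixture >= 0))
    archetype_mixture <- archetype_mixture / sum(archetype_mixture)
  }
  structure(list(n = n, marginals = marginals,
                 sub1_family = sub1_family, sub1_theta = sub1_theta,
                 sub2_family = sub2_family, sub2_theta = sub2_theta,
                 link_rho = link_rho,
                 archetype_mixture = archetype_mixture,
                 blob_shift = blob_shift),
            class = "fixture_spec")
}

# assemble a synthesis_model directly from known generating parameters
fixture_model <- function(spec = fixture_spec(), cs = default_constraints()) {
  marginals <- purrr::imap(spec$marginals, function(m, p) {
    structure(list(parameter = p, kind = m$kind, location = m$location,
                   scale = m$scale, bounds = cs$box_bounds[[p]],
                   n = NA_integer_, clipped = 0L),
              class = "marginal_model")
  })
  part <- default_partition()
  mk <- function(fam, theta, d) {
    if (fam == "independence") new_copula_model("independence", d)
    else new_copula_model(fam, d, theta = theta)
  }
  models <- list(sleep_architecture = mk(spec$sub1_family, spec$sub1_theta, 3),
                 autonomic = mk(spec$sub2_family, spec$sub2_theta, 4))
  # latent score of the deep-sleep ratio: log(deep) - log(total) standardized,
  # expressed in the sleep-architecture latents
  s_t <- spec$marginals$total_sleep_h$scale
  s_d <- spec$marginals$deep_sleep_h$scale
  tau1 <- implied_tau(models$sleep_architecture)
  r_td <- sin(pi * tau1 / 2)    # normal-scale correlation implied by tau
  v <- s_d^2 + s_t^2 - 2 * r_td * s_d * s_t
  coef <- c("(Intercept)" = 0, total_sleep_h = -s_t / sqrt(v),
            deep_sleep_h = s_d / sqrt(v), light_sleep_h = 0)
  link <- if (abs(spec$link_rho) > 0) {
    list(source = "deep_sleep_ratio", target = "rmssd_ms",
         rho = spec$link_rho, coef = coef, resid_sd = 0.05)
  } else NULL
  vine <- structure(list(partition = part, models = models, link = link),
                    class = "vine_structure")
  structure(list(version = "1.0", marginals = marginals, partition = part,
                 vine = vine, constraints = cs,
                 strategy = sampling_strategy(),
                 families = c(sleep_architecture = spec$sub1_family,
                              autonomic = spec$sub2_family),
                 n_reference = NA_integer_, n_dropped = 0L),
            class = "synthesis_model")
}

#' Generate an offline reference cohort with known ground truth
#'
#' Draws records from the specified marginals and copulas (standing in for
#' external reference cohorts, which this package deliberately does not
#' require), enforces the constraint system by rejection with projection as
#' last resort, and attaches a manifest recording every generating
#' parameter so fitted models can be scored against the truth. With an
#' archetype mixture set, each record's autonomic latents are shifted by
#' its archetype before back-transformation, producing three profile blobs.
#'
#' @param spec A `fixture_spec`.
#' @param seed Integer seed; identical (spec, seed) gives identical output.
#' @return Tibble of `spec$n` records, all passing [check_records()];
#'   attributes `manifest` (generating parameters, enforcement counts,
#'   archetype assignments when mixed) and `ground_truth` (the generating
#'   `synthesis_model`).
#' @export
generate_fixture <- function(spec = fixture_spec(), seed = 1L) {
  model <- fixture_model(spec)
  set.seed(as.integer(seed))
  n <- spec$n
  want <- n
  out <- list()
  arch <- list()
  drawn <- 0L; projected <- 0L
  hrv <- default_partition()$autonomic
  shifts <- rbind(
    high_variability_low_stress = c(sdnn_ms = 0.6, rmssd_ms = 1, lf_hf = -1, pnn50_pct = 1),
    low_variability_high_stress = c(sdnn_ms = -1, rmssd_ms = -0.6, lf_hf = 1, pnn50_pct = -1),
    moderate = c(sdnn_ms = 0, rmssd_ms = 0, lf_hf = 0.2, pnn50_pct = 0)
  )[, hrv]
  n_valid <- 0L
  while (want > 0 && drawn < 50 * n) {
    m <- max(ceiling(1.1 * want), 64L)
    u <- sample_vine(model$vine, m)
    z <- stats::qnorm(u)
    a <- NULL
    if (!is.null(spec$archetype_mixture)) {
      a <- sample(archetypes(), m, replace = TRUE, prob = spec$archetype_mixture)
      z[, hrv] <- z[, hrv] + spec$blob_shift * shifts[a, ]
    }
    cand <- from_latent(z, model$marginals)
    drawn <- drawn + m
    bad <- unique(check_records(cand, model$constraints)$row)
    keep_rows <- if (length(bad)) setdiff(seq_len(m), bad) else seq_len(m)
    n_valid <- n_valid + length(keep_rows)
    keep_rows <- utils::head(keep_rows, want)
    if (length(keep_rows)) {
      out[[length(out) + 1L]] <- cand[keep_rows, , drop = FALSE]
      if (!is.null(a)) arch[[length(arch) + 1L]] <- a[keep_rows]
      want <- want - length(keep_rows)
    }
  }
  if (want > 0) {
    u <- sample_vine(model$vine, want)
    z <- stats::qnorm(u)
    a <- NULL
    if (!is.null(spec$archetype_mixture)) {
      a <- sample(archetypes(), want, replace = TRUE, prob = spec$archetype_mixture)
      z[, hrv] <- z[, hrv] + spec$blob_shift * shifts[a, ]
    }
    cand <- project_to_constraints(from_latent(z, model$marginals),
                                   model$constraints)
    projected <- want
    out[[length(out) + 1L]] <- cand
    if (!is.null(a)) arch[[length(arch) + 1L]] <- a
    want <- 0L
  }
  records <- utils::head(dplyr::bind_rows(out), n)
  manifest <- list(seed = as.integer(seed), n = n,
                   spec = unclass(spec), n_drawn = drawn,
                   n_projected = projected,
                   rejection_rate = 1 - n_valid / drawn)
  if (length(arch)) manifest$archetype <- utils::head(unlist(arch), n)
  attr(records, "manifest") <- manifest
  attr(records, "ground_truth") <- model
  records
}

#' Default run configuration
#'
#' Central defaults for every stage, serializable to JSON: synthesis size
#' and enforcement, copula family choice and selection margin, evaluation
#' estimator settings, clustering and routing hyperparameters.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    synthesis = list(n = 5000, enforcement = "reject", pool_factor = 4,
                     max_attempts = 50, region_weight = 2),
    copulas = list(families = "auto", delta = 0.1, tail_q = 0.05),
    evaluation = list(bins = 50, epsilon = 1e-8, hsic_mode = "dataset",
                      n_perm = 200),
    clustering = list(k = 3, nstart = 10, noise_sd = 0.1, n_boot = 100),
    routing = list(n_experts = 6, k = 3, tau = 0.5, d_in = 768,
                   d_profile_enc = 128,
                   lambda_a = 0.1, lambda_f = 0.15, lambda_p = 0.05)
  )
}

#' Validate a run configuration against the expected schema
#'
#' @param config A list, e.g. from `jsonlite::fromJSON()`.
#' @return The merged configuration (defaults filled in); errors name the
#'   offending entry.
#' @export
validate_config <- function(config) {
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    rlang::abort(paste0("unknown config section(s): ", paste(unknown, collapse = ", ")))
  }
  merged <- utils::modifyList(def, config)
  chk_num <- function(x, nm, lo = -Inf) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo) {
      rlang::abort(paste0("config entry `", nm, "` must be a finite number >= ", lo))
    }
  }
  chk_num(merged$seed, "seed")
  chk_num(merged$synthesis$n, "synthesis.n", 1)
  chk_num(merged$copulas$delta, "copulas.delta", 0)
  chk_num(merged$evaluation$bins, "evaluation.bins", 2)
  chk_num(merged$clustering$k, "clustering.k", 2)
  chk_num(merged$routing$tau, "routing.tau", 1e-12)
  if (merged$routing$k > merged$routing$n_experts) {
    rlang::abort("config entry `routing.k` must be <= routing.n_experts")
  }
  if (!merged$synthesis$enforcement %in% c("reject", "project")) {
    rlang::abort("config entry `synthesis.enforcement` must be 'reject' or 'project'")
  }
  merged
}

#' Write a run manifest
#'
#' Records seed, configuration hash and package version next to every
#' artifact a run writes, for provenance.
#'
#' @param path Output JSON path.
#' @param seed Integer seed used.
#' @param config Configuration list.
#' @param extra Named list of run-specific counters.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, seed, config = default_config(), extra = list()) {
  manifest <- c(list(
    seed = as.integer(seed),
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("sleepsynth")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
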