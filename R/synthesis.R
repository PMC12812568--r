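#' Define a physiologically guided sampling strategy
#'
#' Clinically significant regions are predicates over the seven parameters
#' with importance weights >= 1; synthesis oversamples records falling in a
#' region in proportion to its weight. Region predicates are R expressions
#' over the canonical column names, kept as strings so strategies serialize
#' to JSON.
#'
#' @param regions A data frame (or tibble) with columns `name`, `expr`
#'   (string predicate) and `weight`, or `NULL` for plain sampling.
#' @param pool_factor Candidate pool size as a multiple of the requested n.
#' @param max_attempts Rejection budget per accepted record before switching
#'   to projection.
#' @param enforcement `"reject"` (rejection first, projection as last
#'   resort) or `"project"` (repair every violating candidate directly).
#' @return A `sampling_strategy` object.
#' @export
sampling_strategy <- function(regions = NULL, pool_factor = 4,
                              max_attempts = 50,
                              enforcement = c("reject", "project")) {
  enforcement <- match.arg(enforcement)
  if (!is.null(regions)) {
    regions <- tibble::as_tibble(regions)
    stopifnot(all(c("name", "expr", "weight") %in% names(regions)))
    if (any(!is.finite(regions$weight)) || any(regions$weight < 1)) {
      rlang::abort("region weights must be finite and >= 1")
    }
  }
  structure(list(regions = regions, pool_factor = pool_factor,
                 max_attempts = max_attempts, enforcement = enforcement),
            class = "sampling_strategy")
}

#' The four standard clinical regions as a preset strategy
#'
#' Short sleep, low SDNN, high deep-sleep ratio and elevated LF/HF, each at
#' weight 2 (the emphasis regions of the sampling strategy; numeric weights
#' are a package default).
#'
#' @param weight Importance weight shared by the four regions.
#' @inheritParams sampling_strategy
#' @return A `sampling_strategy`.
#' @export
clinical_regions_strategy <- function(weight = 2, pool_factor = 4,
                                      max_attempts = 50,
                                      enforcement = "reject") {
  regions <- tibble::tibble(
    name = c("short_sleep", "low_sdnn", "high_deep_ratio", "elevated_lf_hf"),
    expr = c("total_sleep_h < 6", "sdnn_ms < 50",
             "deep_sleep_h / total_sleep_h > 0.30", "lf_hf > 3"),
    weight = weight
  )
  sampling_strategy(regions, pool_factor, max_attempts, enforcement)
}

region_matches <- function(records, strategy) {
  if (is.null(strategy$regions) || nrow(strategy$regions) == 0) {
    return(matrix(FALSE, nrow(records), 0))
  }
  m <- vapply(strategy$regions$expr, function(e) {
    as.logical(eval(parse(text = e), envir = records))
  }, logical(nrow(records)))
  matrix(m, nrow = nrow(records),
         dimnames = list(NULL, strategy$regions$name))
}

#' Fit the full synthesis model on a reference cohort
#'
#' Algorithm: validate the cohort against the constraint knowledge base
#' (violating rows are dropped with a logged count), fit the marginal
#' transforms, form pseudo-observations, select (or accept) a copula family
#' per subsystem, fit each subsystem copula by tau inversion, and fit the
#' cross-subsystem Gaussian link on the deep-sleep ratio and RMSSD.
#' Fitting is deterministic given the input row order.
#'
#' @param records Reference cohort, >= 100 constraint-satisfying rows.
#' @param cs Constraint set.
#' @param families Either `"auto"` (tail-dependence based selection) or a
#'   character vector naming a family per subsystem.
#' @param strategy A `sampling_strategy` stored with the model.
#' @param transforms Transform kinds per parameter.
#' @param delta Family-selection margin passed to [select_family()].
#' @return A `synthesis_model`.
#' @export
synth_fit <- function(records, cs = default_constraints(),
                      families = "auto",
                      strategy = sampling_strategy(),
                      transforms = default_transforms(),
                      delta = 0.1) {
  assert_records(records)
  viol <- check_records(records, cs)
  drop_rows <- unique(viol$row)
  if (length(drop_rows)) records <- records[-drop_rows, , drop = FALSE]
  if (nrow(records) < 100) {
    rlang::abort(sprintf("only %d valid reference records (need >= 100)", nrow(records)))
  }
  marginals <- fit_marginals(records, cs, transforms)
  part <- default_partition()
  u <- pseudo_obs(tibble::as_tibble(records)[sleep_parameters()])
  fams <- if (identical(families, "auto")) {
    purrr::map_chr(part, function(p) select_family(u[p], delta = delta))
  } else {
    rlang::set_names(rep_len(families, length(part)), names(part))
  }
  models <- purrr::imap(part, function(p, nm) fit_copula(u[p], fams[[nm]]))
  ratio <- records$deep_sleep_h / records$total_sleep_h
  vine <- build_vine(u, part, models, ratio = ratio)
  structure(list(version = "1.0", marginals = marginals, partition = part,
                 vine = vine, constraints = cs, strategy = strategy,
                 families = fams, n_reference = nrow(records),
                 n_dropped = length(drop_rows)),
            class = "synthesis_model")
}

#' @export
print.synthesis_model <- function(x, ...) {
  cat(sprintf("<synthesis_model> fitted on %d records (%d dropped)\n",
              x$n_reference, x$n_dropped))
  print(x$vine)
  invisible(x)
}

#' Repair a record to satisfy every constraint
#'
#' Deterministic projection: box violations are clipped to the bounds; a
#' stage-sum violation rescales deep and light sleep proportionally to fit
#' the total; a deep-ratio violation moves deep sleep to the nearest ratio
#' bound and transfers the difference to light sleep. Idempotent; an
#' already-valid record is returned unchanged.
#'
#' @param records Data frame of records (any number of rows).
#' @param cs Constraint set.
#' @return Tibble of repaired records passing [check_records()].
#' @export
project_to_constraints <- function(records, cs = default_constraints()) {
  assert_records(records)
  out <- tibble::as_tibble(records)
  for (p in sleep_parameters()) {
    b <- cs$box_bounds[[p]]
    out[[p]] <- pmin(pmax(out[[p]], b[1]), b[2])
  }
  total <- out$total_sleep_h; deep <- out$deep_sleep_h; light <- out$light_sleep_h
  s <- deep + light
  bad <- s > total
  scale <- ifelse(bad, total / s, 1)
  deep <- deep * scale; light <- light * scale
  rb <- cs$ratio_bound
  r <- deep / total
  hi <- r > rb[2]
  lo <- r < rb[1]
  new_deep <- ifelse(hi, rb[2] * total, ifelse(lo, rb[1] * total, deep))
  # nudge strictly into the interval when rounding lands a hair outside
  r2 <- new_deep / total
  fix_lo <- (hi | lo) & r2 < rb[1]
  fix_hi <- (hi | lo) & r2 > rb[2]
  new_deep[fix_lo] <- rb[1] * total[fix_lo] * (1 + 1e-12)
  new_deep[fix_hi] <- rb[2] * total[fix_hi] * (1 - 1e-12)
  light <- pmax(light + (deep - new_deep), 0)
  # guard one-ulp overshoot of the sum rule from the rescaling arithmetic
  light <- pmin(light, total - new_deep)
  over <- new_deep + light > total
  if (any(over)) light[over] <- light[over] * (1 - 1e-12)
  out$deep_sleep_h <- new_deep
  out$light_sleep_h <- light
  resid <- check_records(out, cs)
  if (nrow(resid)) {
    rlang::abort(c("projection failed to satisfy the constraint system",
                   i = paste0(utils::head(resid$message, 5), collapse = "; ")))
  }
  out
}

draw_candidates <- function(model, n) {
  u <- sample_vine(model$vine, n)
  z <- stats::qnorm(u)
  from_latent(z, model$marginals)
}

#' Generate a synthetic cohort from a fitted model
#'
#' Samples correlated uniforms from the vine, maps them through the inverse
#' normal CDF to the latent scale and back through the inverse marginal
#' transforms, then enforces the constraint system: candidates violating a
#' constraint are rejected up to the strategy's attempt budget, after which
#' remaining candidates are repaired by [project_to_constraints()]. When the
#' strategy defines weighted clinical regions, a 'pool_factor'-times
#' oversized pool of valid candidates is reduced to n by weight-proportional
#' stratified resampling, so a region's achieved share is
#' `w p / (w p + (1 - p))` for unweighted share p and weight w.
#'
#' @param model A `synthesis_model`.
#' @param n Number of records to generate.
#' @param seed Integer seed; identical (model, n, seed) gives identical output.
#' @return A tibble of n records, all passing [check_records()]. The
#'   attribute `"manifest"` records seed, draw/projection counts and the
#'   projected fraction.
#' @export
synthesize <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "synthesis_model"), n >= 1)
  set.seed(as.integer(seed))
  strat <- model$strategy
  weighted <- !is.null(strat$regions) && nrow(strat$regions) > 0
  pool_n <- if (weighted) ceiling(strat$pool_factor * n) else n
  budget <- strat$max_attempts * pool_n
  drawn <- 0L
  projected <- 0L
  keep <- list()
  kept <- 0L
  while (kept < pool_n && drawn < budget) {
    m <- min(max(pool_n - kept, 256L), budget - drawn)
    cand <- draw_candidates(model, m)
    drawn <- drawn + m
    if (strat$enforcement == "project") {
      viol_rows <- unique(check_records(cand, model$constraints)$row)
      if (length(viol_rows)) {
        cand[viol_rows, ] <- project_to_constraints(cand[viol_rows, ], model$constraints)
        projected <- projected + length(viol_rows)
      }
      ok <- cand
    } else {
      viol_rows <- unique(check_records(cand, model$constraints)$row)
      ok <- if (length(viol_rows)) cand[-viol_rows, , drop = FALSE] else cand
    }
    if (nrow(ok)) {
      keep[[length(keep) + 1L]] <- ok
      kept <- kept + nrow(ok)
    }
  }
  pool <- dplyr::bind_rows(keep)
  if (nrow(pool) < pool_n) {
    # rejection budget exhausted: repair fresh candidates to fill the pool
    short <- pool_n - nrow(pool)
    cand <- project_to_constraints(draw_candidates(model, short), model$constraints)
    projected <- projected + short
    drawn <- drawn + short
    pool <- dplyr::bind_rows(pool, cand)
  }
  pool <- utils::head(pool, pool_n)
  if (weighted) {
    mm <- region_matches(pool, strat)
    w <- rep(1, nrow(pool))
    for (j in seq_len(ncol(mm))) {
      w <- pmax(w, ifelse(mm[, j], strat$regions$weight[j], 1))
    }
    out <- stratified_resample(pool, w, n)
  } else {
    out <- pool
  }
  manifest <- list(seed = as.integer(seed), n = n, n_drawn = drawn,
                   n_pool = nrow(pool), n_projected = projected,
                   fraction_projected = projected / max(drawn, 1L),
                   enforcement = strat$enforcement)
  attr(out, "manifest") <- manifest
  out
}

# weight-proportional stratified resampling: strata are the distinct weights;
# stratum s with pool share p_s gets round(n * w_s p_s / sum(w p)) rows,
# allocated by largest remainder, sampled without replacement within stratum
stratified_resample <- function(pool, w, n) {
  ws <- sort(unique(w))
  p <- vapply(ws, function(x) mean(w == x), numeric(1))
  targ <- n * ws * p / sum(ws * p)
  base <- floor(targ)
  rem <- targ - base
  short <- n - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1L
  }
  # cap at stratum availability, spill deficit into the largest stratum
  avail <- vapply(ws, function(x) sum(w == x), numeric(1))
  over <- pmax(base - avail, 0)
  base <- pmin(base, avail)
  if (sum(over) > 0) {
    spill <- order(avail - base, decreasing = TRUE)
    need <- sum(over)
    for (i in spill) {
      take <- min(need, avail[i] - base[i])
      base[i] <- base[i] + take
      need <- need - take
      if (need <= 0) break
    }
  }
  idx <- unlist(purrr::map2(ws, base, function(x, k) {
    cand <- which(w == x)
    if (k >= length(cand)) cand else sample(cand, k)
  }))
  pool[sample(idx), , drop = FALSE]
}

#' Serialize / restore a fitted synthesis model as JSON
#'
#' The bundle holds marginal transforms, subsystem partition, copulas, the
#' vine link, the constraint set and the sampling strategy under a version
#' field, so a fitted model round-trips losslessly.
#'
#' @param model A `synthesis_model`.
#' @param path Optional output path.
#' @return JSON string, or (for `synthesis_model_from_json`) the model.
#' @export
synthesis_model_to_json <- function(model, path = NULL) {
  x <- list(
    version = model$version,
    marginals = purrr::map(model$marginals, marginal_to_list),
    partition = model$partition,
    vine = vine_to_list(model$vine),
    constraints = {
      cs <- unclass(model$constraints)
      cs$clinical_thresholds <- as.data.frame(cs$clinical_thresholds)
      cs
    },
    strategy = {
      s <- unclass(model$strategy)
      if (!is.null(s$regions)) s$regions <- as.data.frame(s$regions)
      s
    },
    families = as.list(model$families),
    n_reference = model$n_reference,
    n_dropped = model$n_dropped
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname synthesis_model_to_json
#' @param json JSON string or path.
#' @export
synthesis_model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  cs <- x$constraints
  cs$box_bounds <- lapply(cs$box_bounds, as.numeric)
  cs$ratio_bound <- as.numeric(cs$ratio_bound)
  cs$clinical_thresholds <- tibble::as_tibble(cs$clinical_thresholds)
  cs <- structure(cs, class = "constraint_set")
  st <- x$strategy
  strategy <- sampling_strategy(st$regions, st$pool_factor, st$max_attempts, st$enforcement)
  structure(list(version = x$version,
                 marginals = purrr::map(x$marginals, marginal_from_list),
                 partition = lapply(x$partition, as.character),
                 vine = vine_from_list(x$vine),
                 constraints = cs, strategy = strategy,
                 families = unlist(x$families),
                 n_reference = x$n_reference, n_dropped = x$n_dropped),
            class = "synthesis_model")
}
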