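#' HRV profile columns in canonical order
#' @return Character vector `s_sdnn, s_rmssd, s_pnn50, s_lf_hf`.
#' @export
profile_columns <- function() c("s_sdnn", "s_rmssd", "s_pnn50", "s_lf_hf")

#' Extract the 4-dimensional HRV profile from sleep records
#'
#' The profile vector is the ordered quadruple (SDNN, RMSSD, PNN50, LF/HF) —
#' the autonomic summary used for archetype clustering and chain selection.
#'
#' @param records Data frame with the canonical columns.
#' @return Tibble with columns `s_sdnn`, `s_rmssd`, `s_pnn50`, `s_lf_hf`.
#' @export
make_profile <- function(records) {
  assert_records(records)
  tibble::tibble(s_sdnn = records$sdnn_ms, s_rmssd = records$rmssd_ms,
                 s_pnn50 = records$pnn50_pct, s_lf_hf = records$lf_hf)
}

#' Archetype labels
#' @return Character vector of the three archetype identifiers.
#' @export
archetypes <- function() {
  c("high_variability_low_stress", "low_variability_high_stress", "moderate")
}

assert_profiles <- function(profiles) {
  missing <- setdiff(profile_columns(), names(profiles))
  if (length(missing)) {
    rlang::abort(paste0("missing profile columns: ", paste(missing, collapse = ", ")))
  }
  invisible(profiles)
}

map_archetypes <- function(centers) {
  # centers: k x 4 standardized centroids; rules on centroid sums
  k <- nrow(centers)
  lab <- rep(NA_character_, k)
  hv <- which.max(centers[, "s_rmssd"] + centers[, "s_pnn50"])
  lab[hv] <- "high_variability_low_stress"
  rest <- setdiff(seq_len(k), hv)
  lv <- rest[which.min(centers[rest, "s_sdnn"] + centers[rest, "s_pnn50"])]
  lab[lv] <- "low_variability_high_stress"
  lab[is.na(lab)] <- "moderate"
  lab
}

#' Cluster HRV profiles into archetypes
#'
#' Z-scores each profile column, runs k-means (k-means++-style multi-start
#' via `nstart` restarts) and maps each cluster to one of three descriptive
#' archetypes by its standardized centroid: the highest `s_rmssd + s_pnn50`
#' centroid is "high variability / low stress", the lowest
#' `s_sdnn + s_pnn50` among the rest is "low variability / high stress",
#' and any remaining cluster is "moderate". The mapping is invariant to
#' k-means label permutations.
#'
#' @param profiles Data frame with the four profile columns, n >= 3k.
#' @param k Number of clusters (3 by default; archetype names assume 3).
#' @param nstart Random restarts.
#' @param seed Integer seed for reproducible restarts.
#' @return A `cluster_model`: standardization parameters, standardized
#'   centroids, archetype per cluster, preamble text per archetype, and the
#'   training assignments.
#' @export
cluster_profiles <- function(profiles, k = 3, nstart = 10, seed = 1L) {
  assert_profiles(profiles)
  x <- as.matrix(tibble::as_tibble(profiles)[profile_columns()])
  if (nrow(x) < 3 * k) rlang::abort("need at least 3k profiles")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  z <- scale(x, center = mu, scale = sdv)
  set.seed(as.integer(seed))
  km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100)
  centers <- km$centers
  colnames(centers) <- profile_columns()
  arch <- if (k == 3) map_archetypes(centers) else rep("moderate", k)
  structure(list(k = k, center = mu, scale = sdv, centroids = centers,
                 archetype = arch, preambles = archetype_preambles(),
                 cluster = km$cluster, seed = as.integer(seed)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d\n", x$k))
  for (i in seq_len(x$k)) {
    cat(sprintf("  cluster %d (%s): centroid [%s]\n", i, x$archetype[i],
                paste(sprintf("%.2f", x$centroids[i, ]), collapse = ", ")))
  }
  invisible(x)
}

#' Assign profiles to the nearest cluster
#'
#' Nearest-centroid assignment in the standardized profile space; exact ties
#' go to the lowest cluster id.
#'
#' @param profiles Data frame with the four profile columns.
#' @param model A `cluster_model`.
#' @return Tibble with `cluster`, `archetype`, `preamble` per row.
#' @export
assign_cluster <- function(profiles, model) {
  assert_profiles(profiles)
  x <- as.matrix(tibble::as_tibble(profiles)[profile_columns()])
  z <- scale(x, center = model$center, scale = model$scale)
  d2 <- outer(rowSums(z^2), rep(1, model$k)) -
    2 * z %*% t(model$centroids) +
    outer(rep(1, nrow(z)), rowSums(model$centroids^2))
  cl <- apply(d2, 1, which.min)   # which.min takes the lowest index on ties
  arch <- model$archetype[cl]
  tibble::tibble(cluster = as.integer(cl), archetype = arch,
                 preamble = unname(model$preambles[arch]))
}

silhouette_mean <- function(z, cl) {
  mean(cluster::silhouette(cl, stats::dist(z))[, "sil_width"])
}

calinski_harabasz <- function(z, cl) {
  n <- nrow(z); k <- length(unique(cl))
  gm <- colMeans(z)
  bss <- sum(vapply(unique(cl), function(g) {
    m <- colMeans(z[cl == g, , drop = FALSE])
    sum(cl == g) * sum((m - gm)^2)
  }, numeric(1)))
  wss <- sum(vapply(unique(cl), function(g) {
    m <- colMeans(z[cl == g, , drop = FALSE])
    sum(sweep(z[cl == g, , drop = FALSE], 2, m)^2)
  }, numeric(1)))
  (bss / (k - 1)) / (wss / (n - k))
}

jaccard_matched <- function(cl_a, cl_b, idx) {
  # greedy best-overlap matching of cluster labels on the shared index set
  a <- cl_a[idx]; b <- cl_b
  ga <- sort(unique(a)); gb <- sort(unique(b))
  scores <- c()
  used <- c()
  for (i in ga) {
    best <- -1; bestj <- NA
    for (j in setdiff(gb, used)) {
      jac <- sum(a == i & b == j) / sum(a == i | b == j)
      if (jac > best) { best <- jac; bestj <- j }
    }
    used <- c(used, bestj)
    scores <- c(scores, best)
  }
  mean(scores)
}

#' Validate a profile clustering
#'
#' Computes the silhouette score and Calinski-Harabasz index of the fitted
#' partition, the mean bootstrap Jaccard stability (resampling 80% subsets,
#' refitting, greedy best-overlap label matching), and the fraction of
#' points reassigned after perturbing each profile column with Gaussian
#' noise of relative standard deviation `noise_sd`.
#'
#' @param profiles The profiles the model was fitted on.
#' @param model A `cluster_model`.
#' @param noise_sd Noise level as a fraction of each column's sd.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return List with `silhouette`, `calinski_harabasz`, `jaccard`,
#'   `reassignment_fraction`, `n`, `noise_sd`, `n_boot`.
#' @export
validate_clustering <- function(profiles, model, noise_sd = 0.1,
                                n_boot = 100, seed = 1L) {
  assert_profiles(profiles)
  x <- as.matrix(tibble::as_tibble(profiles)[profile_columns()])
  z <- scale(x, center = model$center, scale = model$scale)
  cl <- assign_cluster(profiles, model)$cluster
  sil <- silhouette_mean(z, cl)
  ch <- calinski_harabasz(z, cl)
  set.seed(as.integer(seed))
  n <- nrow(x)
  jac <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, size = floor(0.8 * n))
    sub <- tibble::as_tibble(as.data.frame(x[idx, , drop = FALSE]))
    names(sub) <- profile_columns()
    m_b <- cluster_profiles(sub, k = model$k, seed = model$seed + b)
    jaccard_matched(cl, m_b$cluster, idx)
  }, numeric(1))
  noisy <- x + matrix(stats::rnorm(length(x)), nrow(x)) %*%
    diag(noise_sd * apply(x, 2, stats::sd))
  noisy <- tibble::as_tibble(as.data.frame(pmax(noisy, 0)))
  names(noisy) <- profile_columns()
  cl_noisy <- assign_cluster(noisy, model)$cluster
  list(silhouette = sil, calinski_harabasz = ch, jaccard = mean(jac),
       reassignment_fraction = mean(cl_noisy != cl),
       n = n, noise_sd = noise_sd, n_boot = n_boot)
}
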