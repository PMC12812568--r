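test_that("profiles are the ordered HRV quadruple", {
  p <- make_profile(valid_record(sdnn = 50, rmssd = 40, pnn50 = 20, lf_hf = 2))
  expect_identical(names(p), c("s_sdnn", "s_rmssd", "s_pnn50", "s_lf_hf"))
  expect_identical(as.numeric(p[1, ]), c(50, 40, 20, 2))
  # profiles of synthesized records inherit the HRV box bounds
  recs <- fixture_cohort()
  pr <- make_profile(recs)
  expect_true(all(pr$s_sdnn >= 15 & pr$s_sdnn <= 220))
  expect_true(all(pr$s_lf_hf >= 0.1 & pr$s_lf_hf <= 7))
})

test_that("archetype blobs are separated and mapped to the right labels", {
  bp <- blob_profiles()
  m <- cluster_profiles(bp$profiles, seed = 7)
  val <- validate_clustering(bp$profiles, m, n_boot = 20, seed = 7)
  expect_gt(val$silhouette, 0.5)
  # each generating archetype lands in a cluster carrying its own label
  asg <- assign_cluster(bp$profiles, m)
  agree <- mean(asg$archetype == bp$archetype)
  expect_gt(agree, 0.9)
})

test_that("clustering is deterministic and invariant to duplication", {
  bp <- blob_profiles()
  m1 <- cluster_profiles(bp$profiles, seed = 3)
  m2 <- cluster_profiles(bp$profiles, seed = 3)
  expect_identical(m1$cluster, m2$cluster)
  expect_equal(m1$centroids, m2$centroids)
  dup <- dplyr::bind_rows(bp$profiles, bp$profiles)
  md <- cluster_profiles(dup, seed = 3)
  # same partition up to label permutation (k-means restarts differ, so
  # centroids agree to optimization precision, not exactly)
  key <- function(m) m$centroids[order(m$archetype), ]
  expect_equal(key(md), key(m1), tolerance = 0.05)
  expect_identical(sort(md$archetype), sort(m1$archetype))
})

test_that("assignment is nearest-centroid with lowest-id tie-break", {
  bp <- blob_profiles()
  m <- cluster_profiles(bp$profiles, seed = 5)
  # a centroid maps to its own cluster
  for (i in 1:3) {
    raw <- m$centroids[i, ] * m$scale + m$center
    p <- tibble::as_tibble(as.list(raw))
    expect_identical(assign_cluster(p, m)$cluster, i)
  }
  # elevated rmssd + pnn50 profile lands in the high-variability archetype
  hv <- tibble::tibble(s_sdnn = stats::quantile(bp$profiles$s_sdnn, 0.7),
                       s_rmssd = max(bp$profiles$s_rmssd),
                       s_pnn50 = max(bp$profiles$s_pnn50),
                       s_lf_hf = min(bp$profiles$s_lf_hf))
  expect_identical(assign_cluster(hv, m)$archetype, "high_variability_low_stress")
  # exact equidistance resolves to the lowest cluster id
  mt <- m
  mt$centroids <- rbind(c(1, 0, 0, 0), c(-1, 0, 0, 0), c(3, 3, 3, 3))
  colnames(mt$centroids) <- profile_columns()
  mid <- tibble::as_tibble(as.list(rlang::set_names(m$center, profile_columns())))
  expect_identical(assign_cluster(mid, mt)$cluster, 1L)
})

test_that("silhouette and Calinski-Harabasz match definitional brute force", {
  set.seed(9)
  z <- rbind(matrix(rnorm(80, 0), ncol = 2), matrix(rnorm(80, 4), ncol = 2))
  cl <- rep(1:2, each = 40)
  # brute-force silhouette
  sil_brute <- mean(sapply(seq_len(nrow(z)), function(i) {
    d <- sqrt(colSums((t(z) - z[i, ])^2))
    a <- mean(d[cl == cl[i]][-which(which(cl == cl[i]) == i)])
    b <- min(sapply(setdiff(unique(cl), cl[i]), function(g) mean(d[cl == g])))
    (b - a) / max(a, b)
  }))
  expect_equal(sleepsynth:::silhouette_mean(z, cl), sil_brute, tolerance = 1e-10)
  # brute-force CH
  n <- nrow(z); k <- 2; gm <- colMeans(z)
  bss <- sum(sapply(1:2, function(g) sum(cl == g) * sum((colMeans(z[cl == g, ]) - gm)^2)))
  wss <- sum(sapply(1:2, function(g) sum(sweep(z[cl == g, ], 2, colMeans(z[cl == g, ]))^2)))
  expect_equal(sleepsynth:::calinski_harabasz(z, cl),
               (bss / (k - 1)) / (wss / (n - k)), tolerance = 1e-10)
})

test_that("archetype mapping is invariant to cluster relabeling", {
  bp <- blob_profiles()
  m <- cluster_profiles(bp$profiles, seed = 2)
  perm <- c(3, 1, 2)
  mp <- m
  mp$centroids <- m$centroids[perm, ]
  mp$archetype <- sleepsynth:::map_archetypes(mp$centroids)
  expect_identical(mp$archetype, m$archetype[perm])
})

test_that("validation metrics behave under structure, noise and no structure", {
  bp <- blob_profiles()
  m <- cluster_profiles(bp$profiles, seed = 1)
  v <- validate_clustering(bp$profiles, m, noise_sd = 0, n_boot = 25, seed = 1)
  expect_gt(v$jaccard, 0.9)
  expect_identical(v$reassignment_fraction, 0)

  # one isotropic blob forced into k = 3: silhouette near zero
  set.seed(33)
  iso <- tibble::as_tibble(rlang::set_names(
    purrr::map(1:4, ~ rnorm(120, 50, 5)), profile_columns()))
  mi <- cluster_profiles(iso, seed = 4)
  vi <- validate_clustering(iso, mi, n_boot = 10, seed = 4)
  expect_lt(vi$silhouette, 0.25)
  expect_lt(vi$jaccard, v$jaccard)

  # reassignment fraction is nondecreasing in noise (averaged over seeds)
  frac <- sapply(c(0.05, 0.2, 0.8), function(ns) {
    mean(sapply(1:8, function(s) {
      validate_clustering(bp$profiles, m, noise_sd = ns, n_boot = 0, seed = s
      )$reassignment_fraction
    }))
  })
  expect_lte(frac[1], frac[2] + 0.02)
  expect_lte(frac[2], frac[3] + 0.02)
})
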