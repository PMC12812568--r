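# brute-force tau-b over all pairs, the definitional oracle
tau_b_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    if (dx == 0) { tx <- tx + 1; next }
    if (dy == 0) { ty <- ty + 1; next }
    if (dx * dy > 0) conc <- conc + 1 else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  # pairs tied in both count in neither correction term
  nx <- sum(sapply(table(x)[table(x) > 1], function(t) t * (t - 1) / 2))
  ny <- sum(sapply(table(y)[table(y) > 1], function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - nx) * (n0 - ny))
}

test_that("kendall_tau matches the brute-force pair count, with ties", {
  expect_identical(kendall_tau(1:3, 1:3), 1)
  expect_identical(kendall_tau(1:3, 3:1), -1)
  set.seed(5)
  for (i in 1:5) {
    x <- sample(1:8, 20, replace = TRUE)  # replace = TRUE forces ties
    y <- sample(1:8, 20, replace = TRUE)
    expect_equal(kendall_tau(x, y), tau_b_brute(x, y), tolerance = 1e-12)
  }
  expect_warning(t0 <- kendall_tau(rep(1, 10), 1:10), "constant")
  expect_true(is.na(t0))
})

test_that("tail dependence estimates match their sampling oracles", {
  set.seed(11)
  u <- runif(5000); v <- runif(5000)
  td <- tail_dependence(u, v, q = 0.05)
  # independence: conditional tail probability equals q
  expect_lt(abs(td$lambda_lower - 0.05), 0.03)
  expect_lt(abs(td$lambda_upper - 0.05), 0.03)
  expect_false(td$wide)

  u <- runif(2000)
  td <- tail_dependence(u, u, q = 0.05)
  expect_identical(td$lambda_lower, 1)
  expect_identical(td$lambda_upper, 1)

  # Clayton has lower- but not upper-tail dependence (lambda_L = 2^(-1/theta))
  cl <- sleepsynth:::new_copula_model("clayton", 2, theta = 2)
  uc <- sample_copula(cl, 5000)
  td <- tail_dependence(uc[, 1], uc[, 2], q = 0.05)
  expect_gt(td$lambda_lower, td$lambda_upper + 0.2)
  expect_equal(td$lambda_lower, 2^(-1 / 2), tolerance = 0.2)
})

test_that("family selection identifies the generating family", {
  set.seed(21)
  gu <- sample_copula(sleepsynth:::new_copula_model("gumbel", 3, theta = 3), 2000)
  expect_identical(select_family(gu), "gumbel")
  cl <- sample_copula(sleepsynth:::new_copula_model("clayton", 3, theta = 3), 2000)
  expect_identical(select_family(cl), "clayton")
  ind <- matrix(runif(2000 * 3), ncol = 3)
  expect_identical(select_family(ind), "gaussian")
})

test_that("tau inversion uses the closed forms and guards degenerate cases", {
  # tau = 0.5 <=> gumbel theta 2 and clayton theta 2; verify on simulated data
  set.seed(31)
  u <- sample_copula(sleepsynth:::new_copula_model("gumbel", 2, theta = 2), 8000)
  fit_g <- fit_copula(u, "gumbel")
  expect_equal(fit_g$theta, 2, tolerance = 0.1)
  u <- sample_copula(sleepsynth:::new_copula_model("clayton", 2, theta = 2), 8000)
  fit_c <- fit_copula(u, "clayton")
  expect_equal(fit_c$theta, 2, tolerance = 0.1)

  # independence data: gumbel collapses to theta 1, clayton falls back
  ind <- pseudo_obs(matrix(rnorm(600), ncol = 2))
  g0 <- fit_copula(ind, "gumbel")
  expect_equal(g0$theta, 1, tolerance = 0.15)
  neg <- pseudo_obs(cbind(1:100, 100:1))
  expect_warning(c0 <- fit_copula(neg, "clayton"), "independence")
  expect_identical(c0$family, "independence")

  # gaussian: rank-based correlation matrix is a valid correlation matrix
  z <- matrix(rnorm(3000), ncol = 3) %*% chol(matrix(c(1, .6, .3, .6, 1, .5, .3, .5, 1), 3))
  fg <- fit_copula(pseudo_obs(z), "gaussian")
  expect_identical(fg$family, "gaussian")
  expect_equal(diag(fg$sigma), rep(1, 3))
  expect_true(all(eigen(fg$sigma, only.values = TRUE)$values > 0))
  expect_equal(fg$sigma[1, 2], 0.6, tolerance = 0.07)
})

test_that("copula samplers reproduce the model-implied dependence and margins", {
  set.seed(41)
  # gumbel theta 1 is independence
  u <- sample_copula(sleepsynth:::new_copula_model("gumbel", 2, theta = 1), 2000)
  expect_lt(abs(kendall_tau(u[, 1], u[, 2])), 0.05)
  # clayton theta 2 has tau 0.5
  u <- sample_copula(sleepsynth:::new_copula_model("clayton", 2, theta = 2), 5000)
  expect_lt(abs(kendall_tau(u[, 1], u[, 2]) - 0.5), 0.05)
  # gumbel theta 2 has tau 0.5 and uniform margins
  u <- sample_copula(sleepsynth:::new_copula_model("gumbel", 3, theta = 2), 5000)
  expect_lt(abs(kendall_tau(u[, 1], u[, 3]) - 0.5), 0.05)
  for (j in 1:3) {
    expect_gt(suppressWarnings(stats::ks.test(u[, j], "punif"))$p.value, 0.01)
  }
  # gaussian sampler: tau = (2/pi) asin(rho)
  s <- matrix(c(1, 0.7, 0.7, 1), 2)
  u <- sample_copula(sleepsynth:::new_copula_model("gaussian", 2, sigma = s), 5000)
  expect_lt(abs(kendall_tau(u[, 1], u[, 2]) - (2 / pi) * asin(0.7)), 0.05)
})

test_that("exchangeable subsystems have equal pairwise taus", {
  set.seed(51)
  u <- sample_copula(sleepsynth:::new_copula_model("clayton", 4, theta = 1.5), 4000)
  taus <- c()
  for (i in 1:3) for (j in (i + 1):4) taus <- c(taus, kendall_tau(u[, i], u[, j]))
  expect_lt(max(taus) - min(taus), 0.06)
})

test_that("the vine link is recovered in sign and magnitude, and dropped when degenerate", {
  recs <- fixture_cohort()
  u <- pseudo_obs(recs[sleep_parameters()])
  part <- default_partition()
  models <- list(
    sleep_architecture = fit_copula(u[part$sleep_architecture], "gumbel"),
    autonomic = fit_copula(u[part$autonomic], "clayton"))
  ratio <- recs$deep_sleep_h / recs$total_sleep_h
  vine <- build_vine(u, part, models, ratio = ratio)
  expect_gt(vine$link$rho, 0.1)   # fixture generates positive cross-dependence

  expect_warning(v0 <- build_vine(u, part, models, ratio = rep(0.2, nrow(recs))),
                 "degenerate")
  expect_null(v0$link)

  # independent subsystems: linking correlation near zero
  set.seed(61)
  fake <- random_inbox_records(3000, seed = 61)
  uf <- pseudo_obs(fake[sleep_parameters()])
  mi <- list(sleep_architecture = fit_copula(uf[part$sleep_architecture], "gaussian"),
             autonomic = fit_copula(uf[part$autonomic], "gaussian"))
  vi <- build_vine(uf, part, mi, ratio = fake$deep_sleep_h / fake$total_sleep_h)
  us <- sample_vine(vi, 5000)
  zr <- qnorm(pseudo_obs(us[, "deep_sleep_h"]))  # proxy check: taus below
  for (i in 1:3) for (j in 4:7) {
    expect_lt(abs(kendall_tau(us[, i], us[, j])), 0.06)
  }
})

test_that("vine sampling reproduces fitted within-subsystem and link dependence", {
  recs <- fixture_cohort()
  model <- synth_fit(recs)
  set.seed(71)
  u <- sample_vine(model$vine, 5000)
  part <- default_partition()
  for (nm in names(part)) {
    cols <- part[[nm]]
    taus <- c()
    for (i in seq_along(cols)[-length(cols)]) for (j in (i + 1):length(cols)) {
      taus <- c(taus, kendall_tau(u[, cols[i]], u[, cols[j]]))
    }
    expect_lt(abs(mean(taus) - implied_tau(model$vine$models[[nm]])), 0.05)
  }
  # margins are uniform
  for (j in 1:7) {
    expect_gt(suppressWarnings(stats::ks.test(u[, j], "punif"))$p.value, 0.01)
  }
  # the link's normal-scale correlation is reproduced
  co <- model$vine$link$coef
  z <- qnorm(u)
  zr_hat <- co[1] + z[, part$sleep_architecture] %*% co[-1]
  r <- cor(as.numeric(zr_hat), z[, "rmssd_ms"])
  expect_lt(abs(r - model$vine$link$rho), 0.06)
})

test_that("vine structures round-trip through their list/JSON form", {
  recs <- fixture_cohort()
  model <- synth_fit(recs)
  js <- jsonlite::toJSON(sleepsynth:::vine_to_list(model$vine),
                         auto_unbox = TRUE, digits = NA)
  v2 <- sleepsynth:::vine_from_list(jsonlite::fromJSON(js))
  expect_equal(v2$models[[1]]$theta, model$vine$models[[1]]$theta)
  expect_equal(v2$link$rho, model$vine$link$rho)
  expect_equal(unname(v2$link$coef), unname(model$vine$link$coef))
  expect_equal(v2$partition, model$vine$partition)
})
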