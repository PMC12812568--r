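# a router whose parameters are all zero produces fully symmetric logits
zero_router <- function(n_experts = 6, k = 3, tau = 1, d_in = 4) {
  st <- router_state(n_experts, k, tau, d_in, d_profile_enc = 4, seed = 1)
  st$w_gate[] <- 0; st$w_profile[] <- 0; st$b_gate[] <- 0
  st$w_enc[] <- 0; st$b_enc[] <- 0
  st
}

test_that("routing follows the gate equations and the tie-break contract", {
  st <- zero_router()
  r <- route(rep(1, 4), c(50, 40, 20, 2), st)
  expect_equal(r$prob, rep(1 / 6, 6))
  expect_identical(r$selected, 1:3)        # ties resolve to lowest indices
  expect_equal(r$weights, c(1, 1, 1, 0, 0, 0) / 6)
  expect_equal(sum(r$prob), 1)

  # one unit logit at expert 1, tau = 1: p1 = e/(e + 5)
  st1 <- zero_router(tau = 1)
  st1$b_gate <- c(1, 0, 0, 0, 0, 0)
  r <- route(rep(0, 4), rep(0, 4), st1)
  expect_equal(r$prob[1], exp(1) / (exp(1) + 5), tolerance = 1e-12)
  expect_lt(abs(r$prob[1] - 0.3521), 1e-4)

  # small temperature concentrates on the argmax
  stc <- zero_router(tau = 0.01)
  stc$b_gate <- c(0.2, 0.1, 0, -0.1, -0.2, -0.3)
  r <- route(rep(0, 4), rep(0, 4), stc)
  expect_gt(r$prob[1], 0.99)

  # renormalized weights sum to one
  rn <- route(rep(0, 4), rep(0, 4), st1, renormalize = TRUE)
  expect_equal(sum(rn$weights), 1)
})

test_that("routing invariants hold for random states and inputs", {
  set.seed(8)
  for (i in 1:20) {
    N <- sample(3:8, 1)
    k <- sample(seq_len(N), 1)
    st <- router_state(N, k, tau = runif(1, 0.1, 2), d_in = 5,
                       d_profile_enc = 3, seed = i)
    r <- route(rnorm(5), rnorm(4), st)
    expect_equal(sum(r$prob), 1, tolerance = 1e-12)
    expect_equal(sum(r$mask), as.numeric(k))
    expect_identical(sum(r$weights > 0), k)
    expect_equal(r$weights, r$prob * r$mask)
    expect_equal(r$weights[r$mask == 1], r$prob[r$mask == 1])
  }
})

test_that("loss components evaluate to their closed-form values", {
  expect_identical(profile_loss(c(1, 0, 0), 1), 0)
  expect_equal(profile_loss(c(0.7, 0.2, 0.1), 1), 0.35667, tolerance = 1e-4)
  expect_equal(profile_loss(c(0, 0.5, 0.5), 1), -log(1e-12))
  expect_error(profile_loss(c(0.5, 0.5), 3), "cot_index")

  expect_identical(aux_loss(rep(1 / 6, 6), rep(1 / 6, 6)), 0)
  one_hot <- c(1, 0, 0, 0, 0, 0)
  expect_equal(aux_loss(one_hot, one_hot), 5 / 3, tolerance = 1e-12)
  perm <- c(0, 0, 1, 0, 0, 0)
  expect_equal(aux_loss(perm, perm), aux_loss(one_hot, one_hot))
  expect_error(aux_loss(c(0.5, 0.2), c(0.5, 0.5)), "summing to 1")

  expect_identical(freq_loss(c(5, 5), 10, k = 1), 0)
  expect_identical(freq_loss(c(10, 0), 10, k = 1), 50)
  expect_identical(freq_loss(c(10, 0), 10, k = 1, normalize = TRUE), 0.5)
  expect_error(freq_loss(c(9, 0), 10, k = 1), "mismatch")

  lb <- total_loss(1, 1, 1, 1)
  expect_equal(lb$total, 1.3)        # 1 + 0.1 + 0.15 + 0.05
  expect_identical(total_loss(0, 0, 0, 0)$total, 0)
  expect_identical(total_loss(2.5, 9, 9, 9, 0, 0, 0)$total, 2.5)
  expect_error(total_loss(1, lambda_a = -0.1), "nonnegative")
})

test_that("utilization reports CV and activation entropy", {
  uniform <- diag(6)[rep(1:6, 10), ]
  u <- utilization(uniform)
  expect_equal(u$cv, 0)
  expect_equal(u$entropy, log(6), tolerance = 1e-12)
  single <- matrix(rep(c(1, 0, 0, 0, 0, 0), 10), ncol = 6, byrow = TRUE)
  expect_identical(utilization(single)$entropy, 0)
  set.seed(4)
  for (i in 1:10) {
    m <- matrix(rbinom(60, 1, 0.5), ncol = 6)
    m[rowSums(m) == 0, 1] <- 1
    uu <- utilization(m)
    expect_lte(uu$entropy, log(6) + 1e-12)
    expect_gte(uu$cv, 0)
  }
})

test_that("analytic regularizer gradients match numerical differentiation", {
  set.seed(5)
  for (i in 1:5) {
    g <- rnorm(6); tau <- runif(1, 0.2, 1.5); ci <- sample(1:6, 1)
    f <- rep(1 / 6, 6)
    num <- sapply(1:6, function(j) {
      e <- rep(0, 6); e[j] <- 1e-6
      (profile_loss(sleepsynth:::softmax(g + e, tau), ci) -
         profile_loss(sleepsynth:::softmax(g - e, tau), ci)) / 2e-6
    })
    expect_equal(sleepsynth:::grad_profile_loss_logits(g, tau, ci), num,
                 tolerance = 1e-5)
    num_aux <- sapply(1:6, function(j) {
      e <- rep(0, 6); e[j] <- 1e-6
      (aux_loss(f, sleepsynth:::softmax(g + e, tau)) -
         aux_loss(f, sleepsynth:::softmax(g - e, tau))) / 2e-6
    })
    expect_equal(sleepsynth:::grad_aux_loss_logits(g, tau, f), num_aux,
                 tolerance = 1e-5)
  }
})

test_that("the toy trainer produces a finite, broadly decreasing loss trace", {
  d <- make_routing_data(200, d_in = 10, seed = 1)
  res <- toy_train(d, d_profile_enc = 8, epochs = 60, seed = 1)
  tr <- res$trace
  expect_true(all(is.finite(tr$total)))
  # smoothed total loss decreases from start to finish
  expect_lt(mean(tail(tr$total, 10)), mean(head(tr$total, 10)))
  expect_identical(nrow(tr), 60L)
  expect_true(all(tr$entropy <= log(6) + 1e-9))
})
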