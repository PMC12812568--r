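#' Initialize a profile-aided router
#'
#' Holds the gate projection, profile projection, gate bias, a temperature
#' tau for the softmax, and a seeded affine profile encoder mapping the
#' 4-dimensional HRV profile to the encoded profile space. Defaults mirror
#' a six-expert, top-3 configuration with temperature 0.5 and encoded
#' profile dimension 128; `d_in` is configurable so desk-scale experiments
#' can shrink the hidden state.
#'
#' @param n_experts Number of experts N.
#' @param k Sparsity (top-k), 1 <= k <= N.
#' @param tau Softmax temperature, > 0.
#' @param d_in Hidden-state dimension.
#' @param d_profile_enc Encoded profile dimension.
#' @param init_sd Standard deviation of the random initialization.
#' @param seed Integer seed for the initialization.
#' @return A `router_state`.
#' @export
router_state <- function(n_experts = 6, k = 3, tau = 0.5, d_in = 768,
                         d_profile_enc = 128, init_sd = 0.05, seed = 1L) {
  if (k < 1 || k > n_experts) rlang::abort("need 1 <= k <= n_experts")
  if (tau <= 0) rlang::abort("`tau` must be > 0")
  set.seed(as.integer(seed))
  structure(list(
    n_experts = as.integer(n_experts), k = as.integer(k), tau = tau,
    d_in = as.integer(d_in), d_profile_enc = as.integer(d_profile_enc),
    w_gate = matrix(stats::rnorm(d_in * n_experts, sd = init_sd), d_in, n_experts),
    w_profile = matrix(stats::rnorm(d_profile_enc * n_experts, sd = init_sd),
                       d_profile_enc, n_experts),
    b_gate = rep(0, n_experts),
    w_enc = matrix(stats::rnorm(d_profile_enc * 4, sd = init_sd), d_profile_enc, 4),
    b_enc = rep(0, d_profile_enc)
  ), class = "router_state")
}

#' Encode a profile through the router's affine encoder
#' @param profile Numeric length-4 vector or n x 4 matrix.
#' @param state A `router_state`.
#' @return Encoded profile (length `d_profile_enc` vector or n x d matrix).
#' @export
encode_profile <- function(profile, state) {
  if (is.matrix(profile)) {
    sweep(profile %*% t(state$w_enc), 2, state$b_enc, "+")
  } else {
    as.numeric(state$w_enc %*% profile + state$b_enc)
  }
}

softmax <- function(g, tau = 1) {
  e <- exp((g - max(g)) / tau)
  e / sum(e)
}

topk_mask <- function(prob, k) {
  # order() is stable, so exact ties resolve to the lowest index
  sel <- order(prob, decreasing = TRUE)[seq_len(k)]
  m <- rep(0, length(prob))
  m[sel] <- 1
  list(selected = sort(sel), mask = m)
}

#' Route one hidden state through the profile-aided gate
#'
#' Gate logits are `t(W_gate) h + t(W_profile) enc(p) + b`; probabilities
#' come from a temperature-scaled softmax; the top-k experts are selected
#' (ties to the lowest index) and the sparse weights are the probabilities
#' masked to the selection, deliberately not renormalized (a
#' `renormalize = TRUE` flag is available for comparison).
#'
#' @param h Hidden-state vector of length `d_in`.
#' @param profile Length-4 profile vector.
#' @param state A `router_state`.
#' @param renormalize Renormalize the masked weights to sum to one.
#' @return A `routing_result`: `logits`, `prob`, `selected`, `mask`,
#'   `weights`.
#' @export
route <- function(h, profile, state, renormalize = FALSE) {
  penc <- encode_profile(as.numeric(profile), state)
  g <- as.numeric(t(state$w_gate) %*% h + t(state$w_profile) %*% penc + state$b_gate)
  if (any(!is.finite(g))) rlang::abort("non-finite gate logits")
  prob <- softmax(g, state$tau)
  tk <- topk_mask(prob, state$k)
  w <- prob * tk$mask
  if (renormalize) w <- w / sum(w)
  structure(list(logits = g, prob = prob, selected = tk$selected,
                 mask = tk$mask, weights = w),
            class = "routing_result")
}

#' Profile-alignment loss
#'
#' Negative log activation probability of the expert designated by the
#' user's chain-of-thought path, with the probability clamped at 1e-12.
#'
#' @param prob Probability vector over experts (sums to 1).
#' @param cot_index Designated expert index (1-based), 1 <= index <= N.
#' @return Nonnegative scalar.
#' @export
profile_loss <- function(prob, cot_index) {
  if (cot_index < 1 || cot_index > length(prob)) rlang::abort("invalid `cot_index`")
  -log(max(prob[cot_index], 1e-12))
}

check_distribution <- function(x, name) {
  if (any(x < 0) || abs(sum(x) - 1) > 1e-8) {
    rlang::abort(paste0("`", name, "` must be a nonnegative vector summing to 1"))
  }
}

#' Load-balancing auxiliary loss
#'
#' Squared deviation of both the token-share fractions F and the
#' probability-share fractions P from the uniform allocation 1/N:
#' `sum_i (F_i - 1/N)^2 + (P_i - 1/N)^2`. Zero exactly at the uniform
#' allocation.
#'
#' @param f Token-share fractions (nonnegative, sums to 1).
#' @param p Probability-share fractions (nonnegative, sums to 1).
#' @return Nonnegative scalar.
#' @export
aux_loss <- function(f, p) {
  if (length(f) != length(p)) rlang::abort("`f` and `p` must have equal length")
  check_distribution(f, "f"); check_distribution(p, "p")
  n <- length(f)
  sum((f - 1 / n)^2) + sum((p - 1 / n)^2)
}

#' Activation-frequency regularization loss
#'
#' Literal squared deviation of per-expert selection counts from T/N over T
#' routing decisions: `sum_i (A_i - T/N)^2`. Because top-k selection makes
#' `sum A_i = k T`, the literal form has a nonzero floor for k > 1; the
#' normalized mode divides by T^2 to put the value on a fraction scale.
#'
#' @param a Integer selection counts per expert.
#' @param t_count Number of routing decisions T.
#' @param k Top-k used when counting (validates `sum(a) == k * t_count`).
#' @param normalize Divide by T^2.
#' @return Nonnegative scalar.
#' @export
freq_loss <- function(a, t_count, k = 1, normalize = FALSE) {
  if (any(a < 0)) rlang::abort("counts must be nonnegative")
  if (sum(a) != k * t_count) {
    rlang::abort(sprintf("count mismatch: sum(a) = %g but k * T = %g",
                         sum(a), k * t_count))
  }
  v <- sum((a - t_count / length(a))^2)
  if (normalize) v / t_count^2 else v
}

#' Combine the four loss terms
#'
#' `L_total = L_ce + lambda_a L_aux + lambda_f L_freq + lambda_p L_profile`,
#' with the default coefficients lambda_a = 0.1, lambda_f = 0.15,
#' lambda_p = 0.05.
#'
#' @param l_ce,l_aux,l_freq,l_profile Component losses (nonnegative).
#' @param lambda_a,lambda_f,lambda_p Coefficients (nonnegative).
#' @return A `loss_bundle` list with the components, coefficients and `total`.
#' @export
total_loss <- function(l_ce, l_aux = 0, l_freq = 0, l_profile = 0,
                       lambda_a = 0.1, lambda_f = 0.15, lambda_p = 0.05) {
  if (lambda_a < 0 || lambda_f < 0 || lambda_p < 0) {
    rlang::abort("loss coefficients must be nonnegative")
  }
  structure(list(l_ce = l_ce, l_aux = l_aux, l_freq = l_freq,
                 l_profile = l_profile,
                 lambda_a = lambda_a, lambda_f = lambda_f, lambda_p = lambda_p,
                 total = l_ce + lambda_a * l_aux + lambda_f * l_freq +
                   lambda_p * l_profile),
            class = "loss_bundle")
}

#' Expert-utilization metrics from a routing history
#'
#' Token share of expert i is its selection count over all top-k selections;
#' the coefficient of variation is sd/mean of the shares and the activation
#' entropy is `-sum share log share` (natural log, at most log N).
#'
#' @param history List of `routing_result`s, or an n x N binary selection
#'   matrix.
#' @return List with `cv`, `entropy`, `shares`, `counts`, `t_count`.
#' @export
utilization <- function(history) {
  m <- if (is.matrix(history)) history else do.call(rbind, purrr::map(history, "mask"))
  if (is.null(dim(m)) || nrow(m) == 0) rlang::abort("empty routing history")
  counts <- colSums(m)
  shares <- counts / sum(counts)
  nz <- shares[shares > 0]
  list(cv = stats::sd(shares) / mean(shares),
       entropy = -sum(nz * log(nz)),
       shares = shares, counts = counts, t_count = nrow(m))
}

# analytic gradients wrt gate logits for the differentiable regularizers;
# used by the trainer and checked against numerical differentiation
grad_profile_loss_logits <- function(g, tau, cot_index) {
  p <- softmax(g, tau)
  d <- p
  d[cot_index] <- d[cot_index] - 1
  d / tau
}

grad_aux_loss_logits <- function(g, tau, f) {
  p <- softmax(g, tau)
  n <- length(p)
  a <- 2 * (p - 1 / n)            # dL/dp (P-term; F is held fixed)
  (p * (a - sum(a * p))) / tau    # softmax Jacobian, temperature-scaled
}

#' Synthetic routed-task data for the toy training harness
#'
#' Each sample carries a 4-dimensional profile drawn from one of three
#' archetype blobs, a designated chain-of-thought expert via `path_map`, a
#' hidden state, and a regression target produced by a cluster-specific
#' linear map — a desk-scale surrogate for routed language-model training.
#'
#' @param n Number of samples.
#' @param d_in Hidden-state dimension.
#' @param path_map Integer vector mapping the 3 chain paths to expert
#'   indices.
#' @param blob_sep Separation of the profile blobs in standardized units.
#' @param noise_sd Target noise standard deviation.
#' @param seed Integer seed.
#' @return List with `h` (n x d_in), `profile` (n x 4), `cluster`,
#'   `cot_index`, `y`, `path_map`.
#' @export
make_routing_data <- function(n, d_in = 16, path_map = c(1, 3, 5),
                              blob_sep = 3, noise_sd = 0.1, seed = 1L) {
  set.seed(as.integer(seed))
  cl <- sample.int(3, n, replace = TRUE)
  centers <- blob_sep * rbind(c(1, 1, 1, -1), c(-1, -1, -1, 1), c(0, 0, 0, 0)) / 2
  profile <- centers[cl, ] + matrix(stats::rnorm(4 * n, sd = 0.5), n, 4)
  h <- matrix(stats::rnorm(n * d_in), n, d_in)
  # unit-norm cluster maps keep the regression target at unit scale, so the
  # task loss sits on the O(1) scale the loss coefficients assume
  maps <- matrix(stats::rnorm(3 * d_in), 3, d_in)
  maps <- maps / sqrt(rowSums(maps^2))
  y <- rowSums(maps[cl, , drop = FALSE] * h) + stats::rnorm(n, sd = noise_sd)
  list(h = h, profile = profile, cluster = cl,
       cot_index = path_map[cl], y = y, path_map = path_map)
}

batch_forward <- function(data, state, experts) {
  penc <- encode_profile(data$profile, state)
  g <- sweep(data$h %*% state$w_gate + penc %*% state$w_profile, 2,
             state$b_gate, "+")
  gs <- g / state$tau
  gs <- gs - apply(gs, 1, max)
  e <- exp(gs)
  prob <- e / rowSums(e)
  n <- nrow(prob); N <- ncol(prob)
  mask <- matrix(0, n, N)
  for (i in seq_len(n)) {
    mask[i, order(prob[i, ], decreasing = TRUE)[seq_len(state$k)]] <- 1
  }
  wts <- prob * mask
  eo <- data$h %*% t(experts)      # n x N expert outputs
  yhat <- rowSums(wts * eo)
  list(penc = penc, g = g, prob = prob, mask = mask, wts = wts,
       eo = eo, yhat = yhat)
}

#' Train the toy router and experts end to end
#'
#' Full-batch gradient descent on the router (gate, profile projection,
#' encoder) and N linear experts over the surrogate routed-regression task.
#' The task loss is the mean squared error of the sparsely mixed expert
#' outputs; the profile-alignment and the differentiable (probability-share)
#' part of the load-balancing loss are backpropagated through the softmax
#' (top-k mask treated as constant, the usual straight-through convention);
#' the activation-frequency loss is computed from integer counts and
#' therefore monitored rather than differentiated.
#'
#' @param data Output of [make_routing_data()].
#' @param n_experts,k,tau,d_profile_enc Router configuration.
#' @param lambda_a,lambda_f,lambda_p Loss coefficients.
#' @param epochs,lr Optimization settings.
#' @param seed Integer seed (initialization).
#' @return List with `trace` (per-epoch tibble: losses, cv, entropy, mean
#'   designated-expert probability), `state`, `experts`, `final`.
#' @export
toy_train <- function(data, n_experts = 6, k = 3, tau = 0.5,
                      d_profile_enc = 16,
                      lambda_a = 0.1, lambda_f = 0.15, lambda_p = 0.05,
                      epochs = 150, lr = 0.1, seed = 1L) {
  n <- nrow(data$h); d_in <- ncol(data$h)
  state <- router_state(n_experts, k, tau, d_in, d_profile_enc,
                        init_sd = 0.05, seed = seed)
  set.seed(as.integer(seed) + 1L)
  experts <- matrix(stats::rnorm(n_experts * d_in, sd = 0.1), n_experts, d_in)
  trace <- vector("list", epochs)
  N <- n_experts
  for (ep in seq_len(epochs)) {
    fw <- batch_forward(data, state, experts)
    resid <- fw$yhat - data$y
    l_task <- mean(resid^2)
    ip <- cbind(seq_len(n), data$cot_index)
    l_prof <- mean(-log(pmax(fw$prob[ip], 1e-12)))
    f_share <- colSums(fw$mask) / sum(fw$mask)
    p_share <- colMeans(fw$prob)
    l_aux <- sum((f_share - 1 / N)^2) + sum((p_share - 1 / N)^2)
    l_freq <- freq_loss(colSums(fw$mask), n, k = k, normalize = TRUE)
    lb <- total_loss(l_task, l_aux, l_freq, l_prof, lambda_a, lambda_f, lambda_p)
    if (!is.finite(lb$total)) {
      rlang::abort("training diverged: non-finite loss",
                   body = c(i = sprintf("epoch %d", ep)))
    }
    ut <- utilization(fw$mask)
    trace[[ep]] <- tibble::tibble(
      epoch = ep, l_task = l_task, l_profile = l_prof, l_aux = l_aux,
      l_freq = l_freq, total = lb$total, cv = ut$cv, entropy = ut$entropy,
      designated_prob = mean(fw$prob[ip]))
    # gradients
    dyhat <- 2 * resid / n
    d_experts <- t(fw$wts * dyhat) %*% data$h            # N x d_in
    dprob <- (dyhat * fw$eo) * fw$mask                   # task, straight-through
    if (lambda_p > 0) {
      dp <- matrix(0, n, N)
      dp[ip] <- -1 / (n * pmax(fw$prob[ip], 1e-12))
      dprob <- dprob + lambda_p * dp
    }
    if (lambda_a > 0) {
      dprob <- dprob + lambda_a *
        matrix(2 * (p_share - 1 / N) / n, n, N, byrow = TRUE)
    }
    # softmax Jacobian rows
    dg <- (fw$prob * (dprob - rowSums(dprob * fw$prob))) / state$tau
    dW_gate <- t(data$h) %*% dg
    dW_profile <- t(fw$penc) %*% dg
    db <- colSums(dg)
    dpenc <- dg %*% t(state$w_profile)
    dW_enc <- t(dpenc) %*% data$profile
    db_enc <- colSums(dpenc)
    experts <- experts - lr * d_experts
    state$w_gate <- state$w_gate - lr * dW_gate
    state$w_profile <- state$w_profile - lr * dW_profile
    state$b_gate <- state$b_gate - lr * db
    state$w_enc <- state$w_enc - lr * dW_enc
    state$b_enc <- state$b_enc - lr * db_enc
  }
  trace <- dplyr::bind_rows(trace)
  list(trace = trace, state = state, experts = experts,
       final = trace[nrow(trace), ])
}
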