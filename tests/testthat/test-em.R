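test_that("responsibilities match a brute-force Bayes computation", {
  set.seed(61)
  n <- 6; q <- 2; K <- 2
  W <- matrix(rnorm(n * q), n, q)
  X <- list(matrix(rnorm(n * 3), n, 3), matrix(rnorm(n * 2), n, 2))
  y <- c(1, 0, 1, 1, 0, 0)
  gamma <- rbind(rnorm(K), matrix(rnorm(q * K), q, K)); gamma[, K] <- 0
  betas <- list(matrix(rnorm(4 * K), 4, K), matrix(rnorm(3 * K), 3, K))
  d <- nutrimoe_data(W, X, y)
  params <- nutrimoe_params(gamma, betas)

  r <- e_step(d, params)                 # pooled
  rl <- e_step(d, params, pool = FALSE)  # per level

  for (i in seq_len(n)) {
    e <- exp(c(sum(c(1, W[i, ]) * gamma[, 1]), sum(c(1, W[i, ]) * gamma[, 2])))
    pi_i <- e / sum(e)
    bern <- function(l, k) {
      s <- plogis(sum(c(1, X[[l]][i, ]) * betas[[l]][, k]))
      if (y[i] == 1) s else 1 - s
    }
    joint <- pi_i * c(bern(1, 1) * bern(2, 1), bern(1, 2) * bern(2, 2))
    expect_equal(r[i, ], joint / sum(joint), tolerance = 1e-12,
                 ignore_attr = TRUE)
    lev1 <- pi_i * c(bern(1, 1), bern(1, 2))
    expect_equal(rl[[1]][i, ], lev1 / sum(lev1), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_rows_sum_to_one(r, tol = 1e-10)
})

test_that("E-step limiting cases: single class and identical experts", {
  set.seed(62)
  n <- 5; q <- 2
  W <- matrix(rnorm(n * q), n, q)
  X <- matrix(rnorm(n * 3), n, 3)
  y <- c(1, 0, 1, 0, 1)
  d <- nutrimoe_data(W, X, y)
  p1 <- nutrimoe_params(matrix(0, q + 1, 1), matrix(rnorm(4), 4, 1))
  expect_equal(unname(e_step(d, p1)), matrix(1, n, 1), ignore_attr = TRUE)
  # identical experts cancel: responsibilities reduce to the gating
  b <- matrix(rnorm(4), 4, 1)
  gamma <- rbind(c(0.4, 0), c(-1, 0), c(2, 0))
  p2 <- nutrimoe_params(gamma, cbind(b, b))
  expect_equal(unname(e_step(d, p2)), unname(gating_probs(W, gamma)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the objective trace is non-decreasing for varied configurations", {
  set.seed(63)
  cases <- list(
    list(seed = 1, K = 2, alpha1 = 1),
    list(seed = 2, K = 2, alpha1 = 0.5),
    list(seed = 3, K = 3, alpha1 = 1)
  )
  for (cs in cases) {
    sim <- small_sim(seed = cs$seed)
    tr <- split_half(sim)$train
    fit <- suppressWarnings(
      nutrimoe(tr$data$W, tr$data$X, tr$data$y, K = cs$K,
               lambda1 = 0.02, alpha1 = cs$alpha1, lambda2 = 0.02,
               penalty_scale = "per_obs", n_restarts = 2,
               max_em_iter = 25, seed = 100 + cs$seed)
    )
    expect_true(all(diff(fit$rll_trace) >= -1e-8))
    expect_rows_sum_to_one(fit$responsibilities, tol = 1e-10)
  }
})

test_that("the final objective equals the exported regularized log-likelihood", {
  sim <- small_sim(seed = 4)
  tr <- split_half(sim)$train
  fit <- suppressWarnings(
    nutrimoe(tr$data$W, tr$data$X, tr$data$y, K = 2, lambda1 = 0.02,
             lambda2 = 0.02, penalty_scale = "per_obs", n_restarts = 1,
             max_em_iter = 20, seed = 9)
  )
  d <- nutrimoe_data(tr$data$W, tr$data$X, tr$data$y)
  expect_equal(fit$rll_trace[length(fit$rll_trace)],
               regularized_loglik(d, fit$params, fit$penalty),
               tolerance = 1e-8)
})

test_that("a K = 1 fit is exactly one weighted elastic-net logistic per level", {
  sim <- small_sim(seed = 5)
  tr <- split_half(sim)$train
  X1 <- tr$data$X[[2]]
  fit <- nutrimoe(tr$data$W, X1, tr$data$y, K = 1, lambda1 = 0.03,
                  lambda2 = 0.01, penalty_scale = "per_obs",
                  n_restarts = 1, seed = 2)
  direct <- enet_logistic(X1, tr$data$y, lambda = 0.03 * length(tr$data$y),
                          alpha = 1)
  expect_equal(unname(fit$params$betas[[1]][, 1]), unname(direct$beta),
               tolerance = 1e-8)
  expect_equal(unname(fit$params$gamma), matrix(0, ncol(tr$data$W) + 1, 1))
  expect_equal(unname(fit$responsibilities), matrix(1, nrow(X1), 1),
               ignore_attr = TRUE)
})

test_that("huge expert penalties force all non-intercept coefficients to zero", {
  sim <- small_sim(seed = 6)
  tr <- split_half(sim)$train
  fit <- suppressWarnings(
    nutrimoe(tr$data$W, tr$data$X, tr$data$y, K = 2, lambda1 = 1e5,
             lambda2 = 1e5, n_restarts = 1, max_em_iter = 10, seed = 3)
  )
  for (b in fit$params$betas) expect_true(all(b[-1, ] == 0))
  expect_true(all(fit$params$gamma[-1, ] == 0))
})

test_that("classes come back ordered by size and predictions are label-free", {
  sim <- small_sim(seed = 7)
  tr <- split_half(sim)$train
  fit <- suppressWarnings(
    nutrimoe(tr$data$W, tr$data$X, tr$data$y, K = 2, lambda1 = 0.02,
             lambda2 = 0.02, penalty_scale = "per_obs", n_restarts = 2,
             max_em_iter = 20, seed = 4)
  )
  sizes <- colSums(fit$responsibilities)
  expect_true(diff(sizes) <= 0)
  expect_equal(unname(fit$params$gamma[, fit$params$K]),
               rep(0, ncol(tr$data$W) + 1))
  # manual label swap leaves the objective and predictions unchanged
  K <- 2
  gswap <- fit$params$gamma[, c(2, 1)]
  gswap <- gswap - gswap[, K]
  pswap <- nutrimoe_params(gswap, lapply(fit$params$betas, function(b) b[, c(2, 1)]))
  d <- nutrimoe_data(tr$data$W, tr$data$X, tr$data$y)
  expect_equal(regularized_loglik(d, fit$params, fit$penalty),
               regularized_loglik(d, pswap, fit$penalty), tolerance = 1e-10)
  expect_equal(mixture_prob(fit$params, tr$data$W, tr$data$X[[2]], 2),
               mixture_prob(pswap, tr$data$W, tr$data$X[[2]], 2),
               tolerance = 1e-12)
})

test_that("prediction equals the mixture probability and its degenerate limits", {
  sim <- small_sim(seed = 8)
  sp <- split_half(sim)
  tr <- sp$train; te <- sp$test
  fit <- suppressWarnings(
    nutrimoe(tr$data$W, tr$data$X, tr$data$y, K = 2, lambda1 = 0.02,
             lambda2 = 0.02, penalty_scale = "per_obs", n_restarts = 1,
             max_em_iter = 15, seed = 6)
  )
  # per-level prediction consistency on training data
  expect_equal(predict(fit, tr$data$W, tr$data$X, level = 2),
               mixture_prob(fit$params, tr$data$W, tr$data$X[[2]], 2))
  # aggregate = equal-weight mean across levels
  agg <- (mixture_prob(fit$params, te$data$W, te$data$X[[1]], 1) +
          mixture_prob(fit$params, te$data$W, te$data$X[[2]], 2)) / 2
  expect_equal(predict(fit, te$data$W, te$data$X), agg)
  # all-zero experts predict one half everywhere
  p0 <- nutrimoe_params(fit$params$gamma,
                        lapply(fit$params$betas, function(b) b * 0))
  f0 <- fit; f0$params <- p0
  expect_equal(unname(predict(f0, te$data$W, te$data$X)),
               rep(0.5, nrow(te$data$W)))
})

test_that("the spectral initialization recovers planted structure end to end", {
  sim <- simulate_ecotypes(sim_config(n = 250, p = 24, q = 8, eta = 0.3,
                                      levels = c(8, 24), n_signal_gating = 3,
                                      n_signal_expert = 10, seed = 12))
  tr <- split_half(sim)$train
  fit <- suppressWarnings(
    nutrimoe(tr$data$W, tr$data$X, tr$data$y, K = 2, n_restarts = 1,
             max_em_iter = 50, seed = 21)
  )
  expect_gt(adjusted_rand_index(fit$cluster, tr$z), 0.6)
})

test_that("leave-one-out AUC of a sparse logistic model behaves sanely", {
  set.seed(64)
  n <- 24
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rbinom(n, 1, plogis(3 * X[, 1])); y[1:2] <- 0:1
  W <- matrix(rnorm(n * 2), n, 2)
  d <- nutrimoe_data(W, X, y)
  r <- loocv_auc(d, method = "sparse_logistic", lambda = 1, seed = 1)
  expect_gt(r$auc, 0.7)
  expect_length(r$scores, n)
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
})

test_that("LOOCV with a single latent class equals plain sparse logistic LOOCV", {
  set.seed(65)
  n <- 14
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(2 * X[, 1])); y[1:2] <- 0:1
  W <- matrix(rnorm(n * 2), n, 2)
  d <- nutrimoe_data(W, X, y)
  a <- loocv_auc(d, method = "nutrimoe", K = 1, lambda1 = 1.5, lambda2 = 1,
                 n_restarts = 1, seed = 3)
  b <- loocv_auc(d, method = "sparse_logistic", lambda = 1.5, seed = 3)
  expect_equal(a$scores, b$scores, tolerance = 1e-7)
  expect_equal(a$auc, b$auc, tolerance = 1e-7)
})
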