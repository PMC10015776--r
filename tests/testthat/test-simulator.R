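test_that("simulation is a deterministic function of its configuration", {
  s1 <- simulate_ecotypes(sim_config(n = 30, p = 10, q = 4, levels = c(4, 10),
                                     n_signal_expert = 4, n_signal_gating = 2,
                                     seed = 5))
  s2 <- simulate_ecotypes(sim_config(n = 30, p = 10, q = 4, levels = c(4, 10),
                                     n_signal_expert = 4, n_signal_gating = 2,
                                     seed = 5))
  expect_identical(s1$data$W, s2$data$W)
  expect_identical(s1$data$X, s2$data$X)
  expect_identical(s1$data$y, s2$data$y)
  expect_identical(s1$truth$z, s2$truth$z)
  s3 <- simulate_ecotypes(sim_config(n = 30, p = 10, q = 4, levels = c(4, 10),
                                     n_signal_expert = 4, n_signal_gating = 2,
                                     seed = 6))
  expect_false(identical(s1$data$W, s3$data$W))
  # simulation must not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123)
  invisible(simulate_ecotypes(sim_config(n = 20, p = 6, q = 4, levels = 6,
                                         n_signal_expert = 3,
                                         n_signal_gating = 2, seed = 1)))
  expect_identical(rnorm(1), before)
})

test_that("simulated dimensions and truth records match the configuration", {
  cf <- sim_config(n = 40, p = 12, q = 6, levels = c(3, 7, 12),
                   n_signal_gating = 3, n_signal_expert = 5, seed = 2)
  sim <- simulate_ecotypes(cf)
  expect_equal(nrow(sim$data$W), 80)  # 2n samples
  expect_equal(ncol(sim$data$W), 6)
  expect_equal(vapply(sim$data$X, ncol, 0L), c(3L, 7L, 12L), ignore_attr = TRUE)
  expect_equal(length(sim$truth$z), 80)
  expect_true(all(sim$truth$z %in% 1:2))
  expect_equal(sum(sim$truth$beta[-1, 1] != 0), 5)
  # class 2 mirrors class 1 at the finest level
  expect_equal(sim$truth$beta[, 2], -sim$truth$beta[, 1])
  # reference class of the true gating is zero
  expect_equal(sim$truth$gamma[, 2], rep(0, 7))
  # levels are standardized
  expect_lt(max(abs(colMeans(sim$data$X[[2]]))), 1e-10)
})

test_that("the multi-level acceptance configuration is reproduced exactly", {
  cf <- sim_config(seed = 1)
  expect_equal(cf$n, 500); expect_equal(cf$p, 100); expect_equal(cf$q, 30)
  expect_equal(cf$eta, 0.1); expect_equal(cf$c_e, 2); expect_equal(cf$c_g, 2)
  expect_equal(cf$K, 2); expect_equal(cf$rho, 0)
  expect_equal(cf$levels, c(30, 50, 80, 100))
  sim <- simulate_ecotypes(cf)
  sp <- split_half(sim)
  expect_equal(nrow(sp$train$data$W), 500)
  expect_equal(nrow(sp$test$data$W), 500)
})

test_that("level aggregation conserves totals and respects nesting", {
  set.seed(41)
  X <- matrix(runif(6 * 8), 6, 8)
  X <- X / rowSums(X)  # proportion scale
  maps <- list(c(1, 1, 2, 2), c(1, 1, 2, 2, 3, 3, 4, 4))
  out <- aggregate_levels(X, maps, fun = "sum")
  expect_length(out, 3)
  # column sums conserved at every level on the proportion scale
  expect_equal(rowSums(out[[1]]), rowSums(X))
  expect_equal(rowSums(out[[2]]), rowSums(X))
  # two children summing: parent of columns 1:2
  expect_equal(out[[2]][, 1], X[, 1] + X[, 2], ignore_attr = TRUE)
  # identity map returns the input
  ident <- aggregate_levels(X, list(seq_len(8)), fun = "sum")
  expect_equal(unname(ident[[1]]), unname(X))
  # mean-scale aggregation averages children
  outm <- aggregate_levels(X, list(c(1, 1, 2, 2, 3, 3, 4, 4)), fun = "mean")
  expect_equal(outm[[1]][, 1], (X[, 1] + X[, 2]) / 2, ignore_attr = TRUE)
})

test_that("edge-table taxonomies are accepted and non-nested maps rejected", {
  X <- matrix(runif(4 * 4), 4, 4,
              dimnames = list(NULL, paste0("t", 1:4)))
  edges <- data.frame(child = paste0("t", 1:4),
                      parent = c("p1", "p1", "p2", "p2"))
  out <- aggregate_levels(X, list(edges), fun = "sum")
  expect_equal(colnames(out[[1]]), c("p1", "p2"))
  expect_equal(out[[1]][, "p1"], X[, 1] + X[, 2], ignore_attr = TRUE)
  bad <- rbind(edges, data.frame(child = "t1", parent = "p2"))
  expect_error(aggregate_levels(X, list(bad)), "non-nested")
})

test_that("the train/test split is the deterministic first/second half", {
  sim <- simulate_ecotypes(sim_config(n = 25, p = 8, q = 4, levels = 8,
                                      n_signal_expert = 4, n_signal_gating = 2,
                                      seed = 3))
  sp <- split_half(sim)
  expect_equal(sp$train$data$W, sim$data$W[1:25, ])
  expect_equal(sp$test$data$W, sim$data$W[26:50, ])
  expect_equal(sp$train$z, sim$truth$z[1:25])
  expect_equal(sp$test$z, sim$truth$z[26:50])
  expect_length(intersect(rownames(sp$train$data$W), rownames(sp$test$data$W)), 0)
})

test_that("null effect sizes produce the null structures they should", {
  # c_e = 0: outcome carries no microbiome signal; training AUC of a plain
  # sparse logistic fit stays near chance on held-out data
  sim <- simulate_ecotypes(sim_config(n = 300, p = 20, q = 6, levels = 20,
                                      c_e = 0, n_signal_expert = 5,
                                      n_signal_gating = 3, seed = 8))
  sp <- split_half(sim)
  f <- enet_logistic(sp$train$data$X[[1]], sp$train$data$y,
                     lambda = 0.02 * 300, alpha = 1)
  pr <- plogis(drop(cbind(1, sp$test$data$X[[1]]) %*% f$beta))
  expect_lt(abs(auc_rank(pr, sp$test$data$y) - 0.5), 0.08)

  # eta = 0, mean-shift mode: class carries no nutrition information at all
  sim0 <- simulate_ecotypes(sim_config(n = 400, p = 10, q = 5, levels = 10,
                                       eta = 0, class_mode = "mean_shift",
                                       n_signal_expert = 4, n_signal_gating = 2,
                                       seed = 9))
  w1 <- sim0$data$W[sim0$truth$z == 1, 1:2]
  w2 <- sim0$data$W[sim0$truth$z == 2, 1:2]
  pv <- c(t.test(w1[, 1], w2[, 1])$p.value, t.test(w1[, 2], w2[, 2])$p.value)
  expect_true(all(pv > 0.01))
})

test_that("nutrient correlation rho is realized in the noise", {
  sim <- simulate_ecotypes(sim_config(n = 600, p = 6, q = 8, levels = 6,
                                      rho = 0.4, eta = 0, c_g = 0,
                                      class_mode = "mean_shift",
                                      n_signal_expert = 3, n_signal_gating = 2,
                                      seed = 10))
  cw <- cor(sim$data$W)
  off <- cw[upper.tri(cw)]
  expect_lt(abs(mean(off) - 0.4), 0.05)
})

test_that("configuration validation catches inconsistent settings", {
  expect_error(sim_config(levels = c(10, 5)), "diff")
  expect_error(sim_config(p = 50, levels = c(10, 40)))
  expect_error(sim_config(n_signal_expert = 200))
  expect_error(sim_config(rho = 1))
})

test_that("eta controls the visible nutrient-space separation of the classes", {
  sep <- vapply(c(0, 0.3, 0.8), function(eta) {
    sim <- simulate_ecotypes(sim_config(n = 400, p = 6, q = 8, eta = eta,
                                        levels = 6, n_signal_expert = 3,
                                        n_signal_gating = 2, seed = 17))
    m1 <- colMeans(sim$data$W[sim$truth$z == 1, 1:4])
    m2 <- colMeans(sim$data$W[sim$truth$z == 2, 1:4])
    sqrt(sum((m1 - m2)^2))
  }, 0)
  expect_true(all(diff(sep) > 0))
})

test_that("three-class simulation has distinct expert sign patterns", {
  sim <- simulate_ecotypes(sim_config(n = 50, p = 12, q = 9, K = 3,
                                      levels = c(4, 12), n_signal_gating = 3,
                                      n_signal_expert = 5, seed = 19))
  b <- sim$truth$beta
  expect_equal(ncol(b), 3)
  expect_false(identical(b[, 1], b[, 3]))
  expect_false(identical(b[, 2], b[, 3]))
  expect_true(all(sim$truth$z %in% 1:3))
})
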