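# Small in-code fixtures shared across test files.

# Tiny count table with known structure (4 samples x 3 taxa).
tiny_counts <- function() {
  m <- rbind(s1 = c(2, 2, 0),
             s2 = c(1, 0, 0),
             s3 = c(3, 1, 4),
             s4 = c(5, 5, 10))
  colnames(m) <- c("taxA", "taxB", "taxC")
  m
}

# A small two-level dataset with a planted two-class structure, fast to fit.
small_sim <- function(seed = 42, n = 60, p = 12, q = 4) {
  simulate_ecotypes(sim_config(n = n, p = p, q = q, eta = 0.3,
                               levels = c(5, p), n_signal_gating = 2,
                               n_signal_expert = 6, seed = seed))
}

# Direct transcription of the model probability for one sample: softmax
# gating times expert sigmoids, naive loops (oracle for mixture_prob).
naive_mixture_prob <- function(W, X, gamma, beta) {
  n <- nrow(W); K <- ncol(gamma)
  out <- numeric(n)
  for (i in seq_len(n)) {
    e <- numeric(K)
    for (k in seq_len(K)) e[k] <- exp(sum(c(1, W[i, ]) * gamma[, k]))
    pi_i <- e / sum(e)
    acc <- 0
    for (k in seq_len(K)) {
      eta <- sum(c(1, X[i, ]) * beta[, k])
      acc <- acc + pi_i[k] * exp(eta) / (1 + exp(eta))
    }
    out[i] <- acc
  }
  out
}

expect_rows_sum_to_one <- function(m, tol = 1e-12) {
  expect_true(max(abs(rowSums(m) - 1)) < tol)
}
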