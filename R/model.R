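#' Multi-level dataset container
#'
#' Bundles the standardized nutrition matrix `W` (n x q), one or more
#' standardized abundance matrices `X` (each n x p_l, coarsest to finest),
#' and the binary outcome `y`.  All matrices must share the sample ordering.
#'
#' @param W Nutrition matrix (samples x nutrients).
#' @param X Abundance matrix or list of abundance matrices, one per
#'   taxonomic level.
#' @param y Binary outcome vector (0 = healthy, 1 = disease); both classes
#'   must be present.
#' @param level_names Optional character names for the levels.
#' @return Object of class `"nutrimoe_data"`: a list with elements `W`, `X`
#'   (always a list), `y`, `level_names`.
#' @export
nutrimoe_data <- function(W, X, y, level_names = NULL) {
  W <- as_num_matrix(W)
  if (is.matrix(X) || is.data.frame(X)) X <- list(X)
  X <- lapply(X, as_num_matrix, arg = "X")
  y <- as.numeric(y)
  n <- nrow(W)
  if (!all(vapply(X, nrow, 0L) == n) || length(y) != n) {
    stop("W, X and y must describe the same samples in the same order")
  }
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2) stop("y must contain both classes")
  if (anyNA(W) || any(!vapply(X, function(m) all(is.finite(m)), TRUE))) {
    stop("non-finite entries in W or X")
  }
  level_names <- level_names %||% names(X) %||%
    paste0("level", seq_along(X))
  names(X) <- level_names
  structure(list(W = W, X = X, y = y, level_names = level_names),
            class = "nutrimoe_data")
}

#' @export
print.nutrimoe_data <- function(x, ...) {
  cat(sprintf("nutrimoe_data: %d samples, %d nutrients, %d level(s)\n",
              nrow(x$W), ncol(x$W), length(x$X)))
  for (l in seq_along(x$X)) {
    cat(sprintf("  %s: %d taxa\n", x$level_names[l], ncol(x$X[[l]])))
  }
  cat(sprintf("  outcome: %d cases / %d controls\n", sum(x$y), sum(1 - x$y)))
  invisible(x)
}

#' Model parameters for the diet-gated mixture of experts
#'
#' @param gamma Gating coefficient matrix, (q + 1) x K with the intercept in
#'   the first row; the last class is the softmax reference and its column
#'   must be identically zero.
#' @param betas List over levels; each element a (p_l + 1) x K matrix of
#'   expert coefficients (intercept first row), one column per latent class.
#' @param level_names Optional level names.
#' @return Object of class `"nutrimoe_params"` with elements `gamma`,
#'   `betas`, `K`, `L`, `level_names`.
#' @export
nutrimoe_params <- function(gamma, betas, level_names = NULL) {
  gamma <- as_num_matrix(gamma)
  if (is.matrix(betas)) betas <- list(betas)
  betas <- lapply(betas, as_num_matrix, arg = "betas")
  K <- ncol(gamma)
  if (any(!is.finite(gamma)) || any(!vapply(betas, function(b) all(is.finite(b)), TRUE))) {
    stop("non-finite parameter values")
  }
  if (max(abs(gamma[, K])) > 1e-12) {
    stop("reference-class gating coefficients (last column) must be zero")
  }
  if (!all(vapply(betas, ncol, 0L) == K)) {
    stop("each expert coefficient matrix needs one column per class")
  }
  level_names <- level_names %||% names(betas) %||%
    paste0("level", seq_along(betas))
  names(betas) <- level_names
  structure(list(gamma = gamma, betas = betas, K = K, L = length(betas),
                 level_names = level_names),
            class = "nutrimoe_params")
}

add_intercept <- function(M) cbind(1, M)

#' Gating-network class probabilities
#'
#' Softmax membership probabilities `pi_k = exp(w'gamma_k) / sum_j
#' exp(w'gamma_j)` for each sample, computed with max-subtraction for
#' overflow safety.  An intercept column is prepended to `W` internally.
#'
#' @param W Nutrition matrix (n x q).
#' @param gamma Gating coefficients, (q + 1) x K.
#' @return n x K matrix of probabilities; rows sum to 1.
#' @export
gating_probs <- function(W, gamma) {
  W <- as_num_matrix(W)
  gamma <- as_num_matrix(gamma)
  if (any(!is.finite(gamma))) stop("non-finite gating coefficients")
  if (nrow(gamma) != ncol(W) + 1) stop("gamma must be (q + 1) x K")
  eta <- add_intercept(W) %*% gamma
  eta <- eta - apply(eta, 1, max)
  e <- exp(eta)
  e / rowSums(e)
}

expert_linpred <- function(X, beta) drop(add_intercept(X) %*% beta)

#' Mixture probability of disease at one taxonomic level
#'
#' `P_l(Y = 1 | X^(l), W) = sum_k pi_k(W) * sigmoid(x^(l)' beta_k^(l))`.
#'
#' @param params A [nutrimoe_params()] object.
#' @param W Nutrition matrix.
#' @param X Abundance matrix of the requested level.
#' @param level Level index or name.
#' @return Vector of probabilities in (0, 1).
#' @export
mixture_prob <- function(params, W, X, level = 1L) {
  if (is.character(level)) level <- match(level, params$level_names)
  if (is.na(level) || level < 1 || level > params$L) stop("level out of range")
  pi_mat <- gating_probs(W, params$gamma)
  beta <- params$betas[[level]]
  mu <- plogis(add_intercept(as_num_matrix(X)) %*% beta)  # n x K
  rowSums(pi_mat * mu)
}

#' Elastic-net penalty
#'
#' `phi(lambda, alpha, beta) = lambda * (alpha * sum|beta_j| +
#' 0.5 * (1 - alpha) * sum beta_j^2)`.  Intercepts must be excluded from
#' `beta` by the caller.
#'
#' @param lambda Non-negative penalty strength.
#' @param alpha Mixing weight in \[0, 1\] (1 = lasso, 0 = ridge).
#' @param beta Coefficient vector or matrix (all entries penalized).
#' @return Non-negative scalar.
#' @export
enet_penalty <- function(lambda, alpha, beta) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  lambda * (alpha * sum(abs(beta)) + 0.5 * (1 - alpha) * sum(beta^2))
}

#' Penalty configuration
#'
#' Expert penalties may differ by level and class: `lambda1` / `alpha1`
#' accept a scalar (broadcast everywhere), a vector of length L, or a list
#' of length L of K-vectors.  `lambda2` / `alpha2` penalize the gating
#' network.
#'
#' @param lambda1,alpha1 Expert elastic-net parameters.
#' @param lambda2,alpha2 Gating elastic-net parameters.
#' @return Object of class `"penalty_config"`.
#' @export
penalty_config <- function(lambda1 = 0, alpha1 = 1, lambda2 = 0, alpha2 = 1) {
  stopifnot(all(unlist(lambda1) >= 0), all(unlist(lambda2) >= 0),
            all(unlist(alpha1) >= 0), all(unlist(alpha1) <= 1),
            all(unlist(alpha2) >= 0), all(unlist(alpha2) <= 1))
  structure(list(lambda1 = lambda1, alpha1 = alpha1,
                 lambda2 = lambda2, alpha2 = alpha2),
            class = "penalty_config")
}

# Expand a scalar / length-L vector / list-of-K-vectors spec to an L x K matrix.
expand_penalty <- function(x, L, K) {
  if (is.list(x)) {
    stopifnot(length(x) == L)
    out <- do.call(rbind, lapply(x, function(v) rep_len(v, K)))
  } else if (length(x) == 1) {
    out <- matrix(x, L, K)
  } else {
    stopifnot(length(x) == L)
    out <- matrix(rep(x, K), L, K)
  }
  out
}

penalty_total <- function(params, penalty) {
  L <- params$L; K <- params$K
  l1 <- expand_penalty(penalty$lambda1, L, K)
  a1 <- expand_penalty(penalty$alpha1, L, K)
  tot <- 0
  for (l in seq_len(L)) {
    for (k in seq_len(K)) {
      tot <- tot + enet_penalty(l1[l, k], a1[l, k], params$betas[[l]][-1, k])
    }
  }
  tot + enet_penalty(penalty$lambda2, penalty$alpha2, params$gamma[-1, , drop = FALSE])
}

# Per-sample, per-class Bernoulli log-likelihood at one level:
# y log sigma(eta_k) + (1 - y) log(1 - sigma(eta_k)), computed in log-space.
level_class_loglik <- function(X, y, beta) {
  eta <- add_intercept(X) %*% beta  # n x K
  y * plogis(eta, log.p = TRUE) + (1 - y) * plogis(-eta, log.p = TRUE)
}

log_row_sums <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Regularized log-likelihood of a fitted or candidate model
#'
#' By default returns the sum over levels of the per-level mixture
#' log-likelihood minus all elastic-net penalties:
#' `sum_l sum_i log(sum_k pi_ik Bern(y_i; sigmoid(x_i^(l)' beta_k^(l)))) -
#' sum_{l,k} phi(lambda1, alpha1, beta_k^(l)) - phi(lambda2, alpha2, gamma)`.
#'
#' With `likelihood = "joint"` the levels are treated as conditionally
#' independent given one shared latent class, giving the joint-model
#' objective `sum_i log(sum_k pi_ik prod_l Bern_ikl)` minus the same
#' penalties; this is the quantity the EM fitter ascends and the two agree
#' for a single level.  `literal_class_sum = TRUE` counts the data
#' log-likelihood once per class (K times), for comparison with the summed
#' objective written with the likelihood term inside the class sum.
#'
#' @param data A [nutrimoe_data()] object.
#' @param params A [nutrimoe_params()] object.
#' @param penalty A [penalty_config()] object.
#' @param level_weights Optional non-negative weights over levels
#'   (default equal, 1 each).
#' @param likelihood `"per_level"` (default) or `"joint"`.
#' @param literal_class_sum Multiply the likelihood term by K.
#' @return Scalar value of the penalized objective.
#' @export
regularized_loglik <- function(data, params, penalty = penalty_config(),
                               level_weights = NULL,
                               likelihood = c("per_level", "joint"),
                               literal_class_sum = FALSE) {
  likelihood <- match.arg(likelihood)
  lw <- level_weights %||% rep(1, params$L)
  log_pi <- log(gating_probs(data$W, params$gamma))
  if (likelihood == "per_level") {
    ll <- 0
    for (l in seq_len(params$L)) {
      lc <- level_class_loglik(data$X[[l]], data$y, params$betas[[l]])
      ll <- ll + lw[l] * sum(log_row_sums(log_pi + lc))
    }
  } else {
    acc <- log_pi
    for (l in seq_len(params$L)) {
      acc <- acc + lw[l] * level_class_loglik(data$X[[l]], data$y, params$betas[[l]])
    }
    ll <- sum(log_row_sums(acc))
  }
  if (literal_class_sum) ll <- ll * params$K
  ll - penalty_total(params, penalty)
}

#' Serialize model parameters to JSON
#'
#' @param params A [nutrimoe_params()] object.
#' @param path Output file path.
#' @param penalty Optional [penalty_config()] stored alongside.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path, penalty = NULL) {
  doc <- list(
    gamma = params$gamma,
    betas = params$betas,
    K = params$K,
    level_names = params$level_names,
    penalty = if (!is.null(penalty)) unclass(penalty)
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read model parameters from JSON
#'
#' @param path File written by [write_params_json()].
#' @return List with `params` ([nutrimoe_params()]) and `penalty`
#'   ([penalty_config()] or `NULL`).
#' @export
read_params_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  betas <- doc$betas
  if (is.matrix(betas)) betas <- list(betas)
  params <- nutrimoe_params(doc$gamma, betas, level_names = doc$level_names)
  pen <- NULL
  if (!is.null(doc$penalty)) {
    pen <- penalty_config(doc$penalty$lambda1, doc$penalty$alpha1,
                          doc$penalty$lambda2, doc$penalty$alpha2)
  }
  list(params = params, penalty = pen)
}
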