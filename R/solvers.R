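# Penalized M-step solvers: proximal-Newton outer loops around the C++
# coordinate-descent quadratic subproblem (cd_wls).  Both solvers only ever
# accept iterates that do not increase their penalized objective, which is
# what makes the surrounding EM provably monotone.

#' Objective of the weighted elastic-net logistic subproblem
#'
#' Weighted negative Bernoulli log-likelihood plus elastic-net penalty on the
#' non-intercept coefficients.
#'
#' @param beta Coefficient vector, intercept first.
#' @param X Design matrix without intercept column.
#' @param y Binary response.
#' @param weights Non-negative observation weights.
#' @param lambda,alpha Elastic-net parameters.
#' @return Scalar objective value (to be minimized).
#' @export
penalized_logistic_obj <- function(beta, X, y, weights, lambda, alpha) {
  eta <- drop(add_intercept(X) %*% beta)
  nll <- -sum(weights * (y * plogis(eta, log.p = TRUE) +
                         (1 - y) * plogis(-eta, log.p = TRUE)))
  nll + enet_penalty(lambda, alpha, beta[-1])
}

# Step-halve from `old` toward `new` until the objective does not increase.
# Returns the accepted iterate (possibly `old` itself).
accept_or_halve <- function(old, new, obj_fun, obj_old, max_halvings = 25) {
  step <- new - old
  for (h in 0:max_halvings) {
    cand <- old + step / 2^h
    if (obj_fun(cand) <= obj_old + 1e-12) return(cand)
  }
  old
}

#' Weighted elastic-net logistic regression
#'
#' Minimizes the weighted negative Bernoulli log-likelihood plus
#' `phi(lambda, alpha, beta)` (intercept unpenalized) by a proximal-Newton
#' scheme: an iteratively reweighted quadratic approximation solved by cyclic
#' coordinate descent with soft-thresholding, with step-halving on the exact
#' objective.  With a warm start the returned objective never exceeds the
#' starting one.
#'
#' @param X Design matrix (n x p), no intercept column.
#' @param y Binary response.
#' @param weights Non-negative observation weights, not all zero.
#' @param lambda,alpha Elastic-net parameters.
#' @param beta_init Optional warm start, length p + 1 (intercept first).
#' @param tol Convergence tolerance on the relative objective change.
#' @param max_newton Maximum outer (reweighting) iterations.
#' @param cd_tol,max_sweeps Inner coordinate-descent control.
#' @return List with `beta` (named, intercept first), `objective`,
#'   `converged`, `n_iter`.  Non-convergence yields a warning and the best
#'   iterate found.
#' @export
enet_logistic <- function(X, y, weights = rep(1, length(y)), lambda = 0,
                          alpha = 1, beta_init = NULL, tol = 1e-9,
                          max_newton = 100, cd_tol = 1e-10, max_sweeps = 1000) {
  X <- as_num_matrix(X)
  y <- as.numeric(y)
  p <- ncol(X)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative and not all zero")
  }
  beta <- beta_init %||% numeric(p + 1)
  obj <- function(b) penalized_logistic_obj(b, X, y, weights, lambda, alpha)
  f <- obj(beta)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_newton)) {
    eta <- drop(add_intercept(X) %*% beta)
    mu <- plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-5)
    z <- eta + (y - mu) / v
    cand <- cd_wls(X, z, weights * v, lambda, alpha, beta, cd_tol, max_sweeps)$beta
    beta_new <- accept_or_halve(beta, cand, obj, f)
    f_new <- obj(beta_new)
    done <- abs(f - f_new) <= tol * (abs(f) + 1)
    beta <- beta_new
    f <- f_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged) warning("enet_logistic: maximum iterations reached")
  names(beta) <- c("(Intercept)", colnames(X) %||% paste0("x", seq_len(p)))
  list(beta = beta, objective = f, converged = converged, n_iter = it)
}

#' KKT residuals of the weighted elastic-net logistic solution
#'
#' For each non-intercept coordinate returns the stationarity violation:
#' `max(|g_j| - lambda * alpha, 0)` where the coefficient is zero, and
#' `|g_j + lambda * alpha * sign(b_j) + lambda * (1 - alpha) * b_j|`
#' otherwise (`g` the gradient of the weighted negative log-likelihood).
#' The first element is the intercept gradient.
#'
#' @inheritParams enet_logistic
#' @param beta Solution vector, intercept first.
#' @return Vector of non-negative violations, length p + 1.
#' @export
enet_logistic_kkt <- function(beta, X, y, weights, lambda, alpha) {
  eta <- drop(add_intercept(X) %*% beta)
  mu <- plogis(eta)
  g <- drop(crossprod(add_intercept(X), -weights * (y - mu)))
  b <- beta[-1]
  gj <- g[-1]
  viol <- ifelse(b == 0,
                 pmax(abs(gj) - lambda * alpha, 0),
                 abs(gj + lambda * alpha * sign(b) + lambda * (1 - alpha) * b))
  c(abs(g[1]), viol)
}

#' Objective of the soft-label multinomial gating subproblem
#'
#' Negative expected complete-data gating log-likelihood
#' `-sum_i sum_k r_ik log pi_k(w_i)` plus the elastic-net penalty on the
#' non-intercept rows of `gamma`.
#'
#' @param gamma Gating matrix (q + 1) x K, last column zero.
#' @param W Nutrition matrix.
#' @param r Responsibility matrix (rows sum to 1).
#' @param lambda2,alpha2 Elastic-net parameters.
#' @param ll_weight Scalar multiplier of the log-likelihood term (the
#'   multi-level fit passes the total level weight, since the gating network
#'   collects soft counts from every level).
#' @return Scalar objective (to be minimized).
#' @export
gating_obj <- function(gamma, W, r, lambda2, alpha2, ll_weight = 1) {
  eta <- add_intercept(W) %*% gamma
  eta <- eta - apply(eta, 1, max)
  log_pi <- eta - log(rowSums(exp(eta)))
  -ll_weight * sum(r * log_pi) +
    enet_penalty(lambda2, alpha2, gamma[-1, , drop = FALSE])
}

#' Soft-label multinomial logistic gating fit
#'
#' Maximizes `sum_i sum_k r_ik log pi_k(w_i) - phi(lambda2, alpha2, gamma)`
#' with the last class fixed as the softmax reference (`gamma_K = 0`).  Each
#' sweep solves one proximal-Newton quadratic subproblem per non-reference
#' class (diagonal Hessian approximation `pi_k (1 - pi_k)`), with
#' step-halving on the exact objective.
#'
#' @param W Nutrition matrix (n x q), no intercept column.
#' @param r n x K responsibility matrix; rows must sum to 1.
#' @param lambda2,alpha2 Elastic-net parameters for the gating network.
#' @param gamma_init Optional warm start, (q + 1) x K.
#' @param ll_weight Scalar multiplier of the log-likelihood term relative to
#'   the penalty (see [gating_obj()]).
#' @param tol Relative objective-change tolerance.
#' @param max_newton Maximum sweeps over the classes.
#' @param cd_tol,max_sweeps Inner coordinate-descent control.
#' @return List with `gamma`, `objective`, `converged`, `n_iter`.
#' @export
gating_fit <- function(W, r, lambda2 = 0, alpha2 = 1, gamma_init = NULL,
                       ll_weight = 1, tol = 1e-9, max_newton = 200,
                       cd_tol = 1e-10, max_sweeps = 1000) {
  W <- as_num_matrix(W)
  r <- as_num_matrix(r)
  if (max(abs(rowSums(r) - 1)) > 1e-8) stop("responsibility rows must sum to 1")
  K <- ncol(r)
  q <- ncol(W)
  gamma <- gamma_init %||% matrix(0, q + 1, K)
  if (K == 1) {
    return(list(gamma = matrix(0, q + 1, 1), objective = 0,
                converged = TRUE, n_iter = 0L))
  }
  obj <- function(g) gating_obj(g, W, r, lambda2, alpha2, ll_weight)
  f <- obj(gamma)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_newton)) {
    for (k in seq_len(K - 1)) {
      eta <- add_intercept(W) %*% gamma
      eta <- eta - apply(eta, 1, max)
      pi_mat <- exp(eta) / rowSums(exp(eta))
      pik <- pi_mat[, k]
      v <- pmax(pik * (1 - pik), 1e-5)
      eta_k <- drop(add_intercept(W) %*% gamma[, k])
      z <- eta_k + (r[, k] - pik) / v
      cand_k <- cd_wls(W, z, ll_weight * v, lambda2, alpha2, gamma[, k],
                       cd_tol, max_sweeps)$beta
      cand <- gamma
      cand[, k] <- cand_k
      gamma <- accept_or_halve(gamma, cand, obj, f)
      f <- obj(gamma)
    }
    f_new <- obj(gamma)
    if (it > 1 && abs(f_prev - f_new) <= tol * (abs(f_new) + 1)) {
      converged <- TRUE; break
    }
    f_prev <- f_new
  }
  if (!converged && max_newton > 2) warning("gating_fit: maximum iterations reached")
  dimnames(gamma) <- list(c("(Intercept)", colnames(W) %||% paste0("w", seq_len(q))),
                          paste0("class", seq_len(K)))
  list(gamma = gamma, objective = f, converged = converged, n_iter = it)
}
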