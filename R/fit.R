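# EM fitter: shared-gating mixture of experts over one or more taxonomic
# levels.  The objective is the sum over levels of the penalized marginal
# mixture log-likelihood; the levels are coupled only through the shared
# gating network.  The E-step therefore computes per-level responsibilities,
# the expert M-steps are per level and class, and the gating M-step collects
# the soft class counts of every level.  Each M-step only accepts
# improvements of its penalized subproblem, so the objective trace is
# non-decreasing by construction (generalized EM).

#' Posterior latent-class responsibilities (E-step)
#'
#' Pooled over levels (default), `r_ik` is proportional to
#' `pi_k(w_i) * prod_l Bern(y_i; sigmoid(x_i^(l)' beta_k^(l)))`, the
#' posterior of one latent class given the evidence of every level; this is
#' what the fitted model reports as its class assignment.  With
#' `pool = FALSE` a list of per-level responsibility matrices
#' `r_ik^(l) ~ pi_k(w_i) * Bern(y_i; sigmoid(x_i^(l)' beta_k^(l)))` is
#' returned instead — these are the EM working quantities, since the
#' objective sums the marginal mixture likelihood of each level.  All
#' computation is in log-space.
#'
#' @param data A [nutrimoe_data()] object.
#' @param params A [nutrimoe_params()] object.
#' @param level_weights Optional non-negative level weights (default 1 each).
#' @param pool Pool the evidence of all levels into one posterior
#'   (default) or return per-level responsibilities.
#' @return n x K matrix with rows summing to 1 (attribute `"loglik"`:
#'   pooled-model log-likelihood), or a list of such matrices when
#'   `pool = FALSE` (attribute `"loglik"`: sum of per-level marginal
#'   log-likelihoods, the unpenalized EM objective).
#' @export
e_step <- function(data, params, level_weights = NULL, pool = TRUE) {
  lw <- level_weights %||% rep(1, params$L)
  log_pi <- log(gating_probs(data$W, params$gamma))
  if (pool) {
    acc <- log_pi
    for (l in seq_len(params$L)) {
      acc <- acc + lw[l] * level_class_loglik(data$X[[l]], data$y, params$betas[[l]])
    }
    lse <- log_row_sums(acc)
    r <- exp(acc - lse)
    attr(r, "loglik") <- sum(lse)
    return(r)
  }
  total_ll <- 0
  r <- vector("list", params$L)
  for (l in seq_len(params$L)) {
    acc <- log_pi + level_class_loglik(data$X[[l]], data$y, params$betas[[l]])
    lse <- log_row_sums(acc)
    r[[l]] <- exp(acc - lse)
    total_ll <- total_ll + lw[l] * sum(lse)
  }
  attr(r, "loglik") <- total_ll
  r
}

# Smoothed hard assignment: the winning class gets 0.8, the rest share 0.2.
smooth_hard_r <- function(cl, n, K) {
  r <- matrix(0.2 / max(K - 1, 1), n, K)
  r[cbind(seq_len(n), cl)] <- 0.8
  r
}

# Spectral pre-classification from the outcome-weighted diet/microbiome
# cross-moment matrix M = X' diag(y - ybar) W / n.  Under the model, M is
# approximately rank-(K - 1): its left singular vectors span the
# expert-difference directions and its right singular vectors the gating
# directions, so the per-sample scores (2y - 1) * X u_j and W v_j separate
# the latent classes.  For K = 2 the sign of the combined score assigns the
# class; for K > 2 the score matrix is clustered by k-means.
spectral_init_r <- function(data, K) {
  y <- data$y
  n <- length(y)
  Xs <- do.call(cbind, data$X)
  M <- crossprod(Xs, (y - mean(y)) * data$W) / n
  d <- min(K - 1, ncol(M), nrow(M))
  sv <- svd(M, nu = d, nv = d)
  f_x <- (2 * y - 1) * (Xs %*% sv$u)
  f_w <- data$W %*% sv$v
  feats <- scale(cbind(f_x, f_w))
  cl <- if (K == 2) {
    ifelse(rowSums(feats) > 0, 1L, 2L)
  } else {
    kmeans(feats, centers = K, nstart = 10)$cluster
  }
  smooth_hard_r(cl, n, K)
}

make_init_r <- function(data, K, method) {
  n <- length(data$y)
  switch(method,
    spectral = spectral_init_r(data, K),
    kmeans = smooth_hard_r(kmeans(data$W, centers = K, nstart = 10)$cluster,
                           n, K),
    random = {
      r <- matrix(runif(n * K, 0.2, 1), n, K)
      r / rowSums(r)
    }
  )
}

#' Fit the diet-gated mixture-of-experts model
#'
#' Maximizes the elastic-net regularized log-likelihood — the sum over
#' taxonomic levels of the marginal mixture log-likelihood minus all
#' penalties — by EM.  The E-step computes per-level responsibilities, the
#' expert M-steps solve one weighted elastic-net logistic problem per level
#' and class, and the gating M-step solves one soft-label multinomial
#' elastic-net problem on the soft class counts collected from every level
#' (the parameter-sharing constraint: a single gating network, hence one
#' coherent latent-class structure across levels).  Several restarts
#' (k-means on `W`, then random soft assignments) guard against local
#' optima; the restart with the best final objective is returned, with
#' classes relabeled by decreasing size (ties broken by gating intercept).
#'
#' @param W Standardized nutrition matrix (n x q).
#' @param X Standardized abundance matrix, or list of matrices (one per
#'   taxonomic level, coarsest first).
#' @param y Binary outcome (0/1).
#' @param K Number of latent classes.
#' @param lambda1,alpha1 Expert elastic-net penalties (scalar, length-L
#'   vector, or list of K-vectors per level).  `lambda1 = NULL` defaults to
#'   `0.01 * n` on the total-likelihood scale (i.e. 0.01 per observation).
#' @param lambda2,alpha2 Gating elastic-net penalties; `lambda2 = NULL`
#'   defaults to `0.002 * n`.
#' @param penalty_scale `"total"` (default): penalties weigh against the
#'   summed log-likelihood, as in the model objective.  `"per_obs"`:
#'   supplied lambdas are multiplied by n, matching the convention of
#'   per-observation-averaged elastic-net software.
#' @param level_weights Optional non-negative weights of the levels in the
#'   joint objective (default equal).
#' @param n_restarts Number of initializations.  The first uses `init`;
#'   the second (if any) uses k-means on `W`; the rest are random soft
#'   assignments.
#' @param init `"spectral"` (default; outcome-weighted cross-moment
#'   pre-classification, see Details), `"kmeans"`, `"random"`, or
#'   `"provided"` (then `init_responsibilities` must be given).
#' @param init_responsibilities n x K matrix used when `init = "provided"`.
#' @param max_em_iter,em_tol EM iteration cap and relative objective-change
#'   tolerance.
#' @param inner_tol,max_inner Control of the proximal-Newton M-step solvers.
#' @param seed Mandatory integer seed; all stochasticity (restarts, k-means)
#'   derives from it and the caller's RNG state is left untouched.
#' @param verbose Print the objective per EM iteration.
#' @return Object of class `"nutrimoe"`: list with `params`
#'   ([nutrimoe_params()]), `responsibilities` (pooled posterior over all
#'   levels), `cluster` (hard assignments from the pooled posterior),
#'   `rll_trace` (penalized objective per EM iteration, non-decreasing),
#'   `converged`, `n_iter`, `restart_scores`, `penalty`, `level_weights`,
#'   `config`.
#' @export
nutrimoe <- function(W, X, y, K = 2, lambda1 = NULL, alpha1 = 1,
                     lambda2 = NULL, alpha2 = 1,
                     penalty_scale = c("total", "per_obs"),
                     level_weights = NULL, n_restarts = 2,
                     init = c("spectral", "kmeans", "random", "provided"),
                     init_responsibilities = NULL,
                     max_em_iter = 100, em_tol = 1e-6,
                     inner_tol = 1e-9, max_inner = 1000,
                     seed, verbose = FALSE) {
  penalty_scale <- match.arg(penalty_scale)
  init <- match.arg(init)
  if (missing(seed)) stop("`seed` is required for a reproducible fit")
  data <- nutrimoe_data(W, X, y)
  n <- nrow(data$W)
  L <- length(data$X)
  lw <- level_weights %||% rep(1, L)
  stopifnot(length(lw) == L, all(lw >= 0), K >= 1,
            max_em_iter >= 1, em_tol > 0)

  lambda1 <- lambda1 %||% (0.01 * n)
  lambda2 <- lambda2 %||% (0.002 * n)
  if (penalty_scale == "per_obs") {
    lambda1 <- rapply(as.list(lambda1), function(v) v * n, how = "unlist")
    lambda2 <- lambda2 * n
  }
  penalty <- penalty_config(lambda1, alpha1, lambda2, alpha2)
  l1 <- expand_penalty(penalty$lambda1, L, K)
  a1 <- expand_penalty(penalty$alpha1, L, K)

  # r_levels: list of per-level responsibility matrices
  m_step <- function(r_levels, params) {
    betas <- params$betas
    for (l in seq_len(L)) {
      for (k in seq_len(K)) {
        fit <- enet_logistic(data$X[[l]], data$y,
                             weights = r_levels[[l]][, k] * lw[l],
                             lambda = l1[l, k], alpha = a1[l, k],
                             beta_init = betas[[l]][, k], tol = inner_tol,
                             max_sweeps = max_inner)
        betas[[l]][, k] <- fit$beta
      }
    }
    # shared gating: soft counts averaged over levels, likelihood term
    # weighted by the total level weight
    r_bar <- Reduce(`+`, Map(`*`, r_levels, lw)) / sum(lw)
    g <- gating_fit(data$W, r_bar, penalty$lambda2, penalty$alpha2,
                    gamma_init = params$gamma, ll_weight = sum(lw),
                    tol = inner_tol, max_sweeps = max_inner)
    nutrimoe_params(g$gamma, betas, level_names = data$level_names)
  }

  run_one <- function(r0) {
    params <- nutrimoe_params(
      gamma = matrix(0, ncol(data$W) + 1, K),
      betas = lapply(data$X, function(Xl) matrix(0, ncol(Xl) + 1, K)),
      level_names = data$level_names
    )
    trace <- numeric(0)
    r_levels <- rep(list(r0), L)
    converged <- FALSE
    for (it in seq_len(max_em_iter)) {
      params <- m_step(r_levels, params)
      r_levels <- e_step(data, params, lw, pool = FALSE)
      rll <- attr(r_levels, "loglik") - penalty_total(params, penalty)
      trace <- c(trace, rll)
      if (verbose) message(sprintf("  EM iter %d: rLL = %.6f", it, rll))
      if (any(vapply(r_levels, function(r) any(apply(r, 2, max) < 1e-6), TRUE))) {
        return(list(degenerate = TRUE, rll = -Inf))
      }
      if (it > 1 && abs(trace[it] - trace[it - 1]) <=
            em_tol * (abs(trace[it - 1]) + 1)) {
        converged <- TRUE
        break
      }
    }
    list(degenerate = FALSE, params = params,
         r = e_step(data, params, lw, pool = TRUE), trace = trace,
         rll = trace[length(trace)], converged = converged,
         n_iter = length(trace))
  }

  runs <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(s) {
      r0 <- if (K == 1) {
        matrix(1, n, 1)
      } else if (s == 1 && init == "provided") {
        stopifnot(!is.null(init_responsibilities))
        init_responsibilities
      } else if (s == 1) {
        make_init_r(data, K, init)
      } else if (s == 2 && init != "kmeans") {
        make_init_r(data, K, "kmeans")
      } else {
        make_init_r(data, K, "random")
      }
      run_one(r0)
    })
  })

  scores <- vapply(runs, function(z) z$rll, 0)
  if (all(!is.finite(scores))) {
    stop("all restarts degenerate (an expert class emptied); ",
         "try different penalties or more restarts")
  }
  best <- runs[[which.max(scores)]]

  out <- relabel_by_size(best$params, best$r)
  fit <- structure(list(
    params = out$params,
    responsibilities = out$r,
    cluster = apply(out$r, 1, which.max),
    rll_trace = best$trace,
    converged = best$converged,
    n_iter = best$n_iter,
    restart_scores = scores,
    penalty = penalty,
    level_weights = lw,
    config = list(K = K, penalty_scale = penalty_scale, seed = seed,
                  n_restarts = n_restarts, init = init,
                  max_em_iter = max_em_iter, em_tol = em_tol,
                  inner_tol = inner_tol, max_inner = max_inner)
  ), class = "nutrimoe")
  fit
}

# Reorder latent classes by decreasing size (sum of responsibilities), ties
# broken by gating intercept; restore the reference-class constraint by
# subtracting the new last column of gamma.
relabel_by_size <- function(params, r) {
  K <- params$K
  if (K == 1) return(list(params = params, r = r))
  size <- colSums(r)
  ord <- order(-size, -params$gamma[1, ])
  gamma <- params$gamma[, ord, drop = FALSE]
  gamma <- gamma - gamma[, K]
  betas <- lapply(params$betas, function(b) b[, ord, drop = FALSE])
  list(params = nutrimoe_params(gamma, betas, params$level_names),
       r = r[, ord, drop = FALSE])
}

#' @export
print.nutrimoe <- function(x, ...) {
  p <- x$params
  cat(sprintf("nutrimoe fit: K = %d latent classes, %d level(s)\n", p$K, p$L))
  cat(sprintf("  class sizes: %s\n",
              paste(round(colSums(x$responsibilities), 1), collapse = " / ")))
  nz <- vapply(p$betas, function(b) sum(b[-1, , drop = FALSE] != 0), 0L)
  cat(sprintf("  selected expert coefficients per level: %s\n",
              paste(sprintf("%s=%d", p$level_names, nz), collapse = ", ")))
  cat(sprintf("  final rLL = %.4f after %d EM iterations (%s)\n",
              x$rll_trace[length(x$rll_trace)], x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Predict disease probability for new samples
#'
#' Per-level mixture probability, or their (weighted) average across levels.
#'
#' @param object A fitted [nutrimoe()] model.
#' @param W Nutrition matrix for the new samples.
#' @param X Abundance matrix or list of matrices matching the training
#'   levels.
#' @param level Level index / name, or `"aggregate"` (default) for the
#'   level-weighted mean.
#' @param ... Unused.
#' @return Vector of probabilities.
#' @export
predict.nutrimoe <- function(object, W, X, level = "aggregate", ...) {
  params <- object$params
  if (is.matrix(X) || is.data.frame(X)) X <- list(X)
  if (identical(level, "aggregate")) {
    stopifnot(length(X) == params$L)
    lw <- object$level_weights / sum(object$level_weights)
    probs <- 0
    for (l in seq_len(params$L)) {
      probs <- probs + lw[l] * mixture_prob(params, W, X[[l]], l)
    }
    probs
  } else {
    idx <- if (is.character(level)) match(level, params$level_names) else level
    Xl <- if (length(X) == params$L) X[[idx]] else X[[1]]
    mixture_prob(params, W, Xl, idx)
  }
}
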