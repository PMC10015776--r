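#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same samples,
#' computed from the contingency table under the permutation model.
#'
#' @param labels_a,labels_b Cluster labels (any atomic type), equal length
#'   at least 2.
#' @return Scalar in \[-1, 1\]; 1 for identical partitions, about 0 for
#'   independent ones.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  n <- length(labels_a)
  if (n < 2) stop("need at least two samples")
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(n)
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Rank-based AUC with tie correction
#'
#' Area under the ROC curve by the Mann-Whitney statistic: concordant
#' case/control score pairs count 1, ties count 1/2.
#'
#' @param scores Numeric predicted scores.
#' @param labels Binary labels (1 = case).
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points from scores
#'
#' @param scores,labels As in [auc_rank()].
#' @return Data frame with columns `fpr`, `tpr` ordered from (0,0) to (1,1).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.numeric(labels)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1)
  fp <- cumsum(labels[ord] == 0)
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  data.frame(fpr = c(0, fp[keep] / sum(labels == 0)),
             tpr = c(0, tp[keep] / sum(labels == 1)))
}

#' Leave-one-out cross-validated AUC
#'
#' For each sample, fits the chosen model on the remaining n - 1 samples
#' (mixing the fold index into the seed so each fold is reproducible) and
#' predicts the held-out probability; the n held-out scores are summarized
#' by the tie-corrected rank AUC.
#'
#' @param data A [nutrimoe_data()] object.
#' @param method `"nutrimoe"`, `"two_stage"`, or `"sparse_logistic"`
#'   (single elastic-net logistic on the finest level).
#' @param K Latent classes for the mixture / two-stage methods.
#' @param seed Base seed; fold i uses `seed + i`.
#' @param ... Further arguments to the underlying fitter
#'   ([nutrimoe()], [two_stage_fit()], or [enet_logistic()] penalties
#'   `lambda`, `alpha`).
#' @return List with `auc`, `scores` (held-out probabilities) and `roc`
#'   (data frame of ROC points).
#' @export
loocv_auc <- function(data, method = c("nutrimoe", "two_stage", "sparse_logistic"),
                      K = 2, seed = 1, ...) {
  method <- match.arg(method)
  n <- nrow(data$W)
  if (n < 10) stop("leave-one-out evaluation needs at least 10 samples")
  L <- length(data$X)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    y_tr <- data$y[idx]
    if (length(unique(y_tr)) < 2) stop("degenerate fold: training set has one class")
    W_tr <- data$W[idx, , drop = FALSE]
    X_tr <- lapply(data$X, function(m) m[idx, , drop = FALSE])
    W_te <- data$W[i, , drop = FALSE]
    X_te <- lapply(data$X, function(m) m[i, , drop = FALSE])
    scores[i] <- switch(method,
      nutrimoe = {
        fit <- nutrimoe(W_tr, X_tr, y_tr, K = K, seed = seed + i, ...)
        predict(fit, W_te, X_te)
      },
      two_stage = {
        fit <- two_stage_fit(W_tr, X_tr[[L]], y_tr, K = K, seed = seed + i, ...)
        predict(fit, W_te, X_te[[L]])
      },
      sparse_logistic = {
        dots <- list(...)
        fit <- enet_logistic(X_tr[[L]], y_tr,
                             lambda = dots$lambda %||% (0.02 * length(y_tr)),
                             alpha = dots$alpha %||% 1)
        plogis(drop(add_intercept(X_te[[L]]) %*% fit$beta))
      }
    )
  }
  list(auc = auc_rank(scores, data$y), scores = scores,
       roc = roc_points(scores, data$y))
}

#' Naive two-stage baseline: k-means on diet, per-cluster sparse logistic
#'
#' Clusters the nutrition matrix with k-means (ignoring the outcome), then
#' fits an independent elastic-net logistic model of the outcome on the
#' microbiome within each cluster.  New samples are routed to the nearest
#' centroid and scored by that cluster's model.
#'
#' @param W Nutrition matrix.
#' @param X Abundance matrix (single level).
#' @param y Binary outcome.
#' @param K Number of clusters.
#' @param lambda,alpha Elastic-net penalty of the per-cluster classifiers
#'   (glmnet convention: per-observation scale).
#' @param seed Seed for k-means (10 restarts).
#' @return Object of class `"two_stage"` with `cluster`, `centers`,
#'   `models`, and the training `fitted` probabilities.
#' @export
two_stage_fit <- function(W, X, y, K = 2, lambda = 0.02, alpha = 1, seed = 1) {
  W <- as_num_matrix(W); X <- as_num_matrix(X)
  y <- as.numeric(y)
  km <- with_seed(seed, {
    for (attempt in 1:5) {
      km <- kmeans(W, centers = K, nstart = 10)
      if (all(km$size > 0)) break
    }
    if (any(km$size == 0)) stop("k-means produced an empty cluster")
    km
  })
  models <- vector("list", K)
  fitted <- numeric(length(y))
  for (k in seq_len(K)) {
    idx <- which(km$cluster == k)
    yk <- y[idx]
    if (length(unique(yk)) < 2 || length(idx) < 3) {
      # single-class or tiny cluster: constant-rate model
      models[[k]] <- list(type = "constant", prob = mean(yk))
      fitted[idx] <- mean(yk)
    } else {
      gf <- glmnet::glmnet(X[idx, , drop = FALSE], yk, family = "binomial",
                           alpha = alpha, lambda = lambda)
      models[[k]] <- list(type = "glmnet", fit = gf, lambda = lambda)
      fitted[idx] <- as.numeric(predict(gf, X[idx, , drop = FALSE],
                                        s = lambda, type = "response"))
    }
  }
  structure(list(cluster = km$cluster, centers = km$centers, models = models,
                 fitted = fitted, K = K),
            class = "two_stage")
}

#' @export
predict.two_stage <- function(object, W, X, ...) {
  W <- as_num_matrix(W); X <- as_num_matrix(X)
  d2 <- vapply(seq_len(object$K), function(k) {
    rowSums(sweep(W, 2, object$centers[k, ])^2)
  }, numeric(nrow(W)))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  cl <- apply(d2, 1, which.min)
  out <- numeric(nrow(W))
  for (k in unique(cl)) {
    idx <- which(cl == k)
    m <- object$models[[k]]
    out[idx] <- if (m$type == "constant") m$prob else {
      as.numeric(predict(m$fit, X[idx, , drop = FALSE],
                         s = m$lambda, type = "response"))
    }
  }
  out
}

#' Bootstrap confidence intervals for differential relative abundance
#'
#' For each taxon, resamples both groups with replacement at their original
#' sizes and recomputes the difference of mean relative abundance
#' (disease minus control); the 2.5 and 97.5 percentiles of the replicates
#' form the confidence interval.
#'
#' @param props_disease,props_control TSS proportion matrices
#'   (samples x taxa) with matching columns; each group needs at least 3
#'   samples.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Seed for the resampling stream.
#' @return Data frame with one row per taxon: `taxon`, `observed` mean
#'   difference, `lower95`, `upper95`, `n_boot`, and `significant`
#'   (interval excludes 0).
#' @export
bootstrap_diff_abundance <- function(props_disease, props_control,
                                     n_boot = 10000, seed = 1) {
  props_disease <- as_num_matrix(props_disease)
  props_control <- as_num_matrix(props_control)
  if (ncol(props_disease) != ncol(props_control)) stop("taxon sets differ")
  n1 <- nrow(props_disease); n0 <- nrow(props_control)
  if (n1 < 3 || n0 < 3) stop("each group needs at least 3 samples")
  p <- ncol(props_disease)
  observed <- colMeans(props_disease) - colMeans(props_control)
  reps <- with_seed(seed, {
    out <- matrix(0, n_boot, p)
    for (b in seq_len(n_boot)) {
      i1 <- sample.int(n1, n1, replace = TRUE)
      i0 <- sample.int(n0, n0, replace = TRUE)
      out[b, ] <- colMeans(props_disease[i1, , drop = FALSE]) -
        colMeans(props_control[i0, , drop = FALSE])
    }
    out
  })
  ci <- apply(reps, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(
    taxon = colnames(props_disease) %||% paste0("taxon", seq_len(p)),
    observed = observed,
    lower95 = ci[1, ],
    upper95 = ci[2, ],
    n_boot = n_boot,
    significant = ci[1, ] > 0 | ci[2, ] < 0,
    row.names = NULL
  )
}

#' Five-way diet-specificity categories of microbial signatures
#'
#' For a two-class fit, classifies every retained taxon at every level by
#' the selection pattern of its expert coefficients: selected in both
#' classes with different or the same direction, selected in exactly one
#' class, or not selected.  "Selected" means a nonzero coefficient after
#' the elastic-net fit (optionally with an absolute threshold).
#'
#' @param fit A fitted [nutrimoe()] model with `K = 2`.
#' @param threshold Absolute coefficient magnitude above which a taxon
#'   counts as selected (default 0, i.e. any nonzero value).
#' @return Data frame with columns `level`, `taxon`, `beta1`, `beta2`,
#'   `selected1`, `selected2`, `category` (one of `different_direction`,
#'   `same_direction`, `class1_only`, `class2_only`, `not_selected`).
#' @export
categorize_signatures <- function(fit, threshold = 0) {
  params <- if (inherits(fit, "nutrimoe")) fit$params else fit
  if (params$K != 2) stop("signature categories are defined for K = 2 fits")
  rows <- lapply(seq_len(params$L), function(l) {
    b <- params$betas[[l]][-1, , drop = FALSE]
    s1 <- abs(b[, 1]) > threshold
    s2 <- abs(b[, 2]) > threshold
    category <- ifelse(s1 & s2 & sign(b[, 1]) != sign(b[, 2]), "different_direction",
                ifelse(s1 & s2, "same_direction",
                ifelse(s1, "class1_only",
                ifelse(s2, "class2_only", "not_selected"))))
    data.frame(level = params$level_names[l],
               taxon = rownames(b) %||% paste0("taxon", seq_len(nrow(b))),
               beta1 = b[, 1], beta2 = b[, 2],
               selected1 = s1, selected2 = s2,
               category = category, row.names = NULL)
  })
  do.call(rbind, rows)
}
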