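# Synthetic multi-level data generator.  Between-class heterogeneity lives
# in the X -> Y link: abundance scores are class-independent and the outcome
# follows a class-specific sparse logistic model at the finest level, while
# diet gates the latent class (softmax on the nutrient vector, plus an eta
# mean shift controlling visible separation).  Coarser levels are aggregates
# of the finest through a random nested taxonomy, so multi-level fits can
# share one latent class across levels.

#' Simulation configuration
#'
#' Knobs of the synthetic-data generator.  Defaults correspond to the
#' multi-level evaluation setting: n = 500 (2n = 1000 samples generated,
#' half train / half test), finest level p = 100 taxa, q = 30 nutrients,
#' class-separation eta = 0.1, expert effect size c_e = 2, gating effect
#' size c_g = 2, K = 2 classes, nutrient correlation rho = 0, and level
#' dimensions 30/50/80/100.
#'
#' @param n Training-set size; `2 * n` samples are generated.
#' @param p Number of taxa at the finest level; must equal the last entry
#'   of `levels`.
#' @param q Number of nutrient features.
#' @param eta Class-separation magnitude of the nutrient mean shift
#'   (`"mean_shift"` mode).
#' @param c_e Expert effect size: nonzero expert coefficients are
#'   `+/- c_e`.
#' @param c_g Gating effect size (used by the `"softmax"` class mode; kept
#'   in the truth record in either mode).
#' @param K Number of true latent classes.
#' @param rho Pairwise correlation of the nutrient noise (equicorrelation).
#' @param levels Integer vector of per-level taxon counts, coarsest to
#'   finest (non-decreasing); `NULL` for a single level of `p` taxa.
#' @param n_signal_gating Nutrients carrying the class mean shift per class.
#' @param n_signal_expert Taxa with nonzero expert coefficients.
#' @param class_mode `"combined"` (default): nutrient vectors are drawn
#'   first, the class follows `softmax(W gamma_true)` with
#'   `gamma_true = c_g * mu_k` (so `c_g` controls how strongly diet gates
#'   the class), and `eta * mu_k` is then added to the class's nutrient
#'   vector (so `eta` controls the visible separation of the classes in
#'   nutrient space; at `eta = 0` the class marginals of W overlap almost
#'   completely, the non-separable regime).  `"mean_shift"`: classes drawn
#'   uniformly, W shifted by `eta * mu_k`, diet carries no gating signal
#'   beyond the shift.  `"softmax"`: gating draw only, `eta` unused.
#' @param level_agg Aggregation of child scores into parents: `"mean"`
#'   (default, score scale) or `"sum"`.
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   configuration.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n = 500, p = 100, q = 30, eta = 0.1, c_e = 2,
                       c_g = 2, K = 2, rho = 0,
                       levels = c(30, 50, 80, 100),
                       n_signal_gating = 5, n_signal_expert = 30,
                       class_mode = c("combined", "mean_shift", "softmax"),
                       level_agg = c("mean", "sum"), seed = 1) {
  class_mode <- match.arg(class_mode)
  level_agg <- match.arg(level_agg)
  if (is.null(levels)) levels <- p
  stopifnot(n >= 2, p >= 1, q >= 1, eta >= 0, rho >= 0, rho < 1, K >= 1,
            all(diff(levels) >= 0), levels[length(levels)] == p,
            n_signal_expert <= p, n_signal_gating * K <= q)
  structure(list(n = n, p = p, q = q, eta = eta, c_e = c_e, c_g = c_g,
                 K = K, rho = rho, levels = levels,
                 n_signal_gating = n_signal_gating,
                 n_signal_expert = n_signal_expert,
                 class_mode = class_mode, level_agg = level_agg,
                 seed = seed),
            class = "sim_config")
}

#' Random nested taxonomy over the configured levels
#'
#' Builds parent maps linking each level to the next coarser one: every
#' finest-level taxon has exactly one ancestor per level and every parent
#' has at least one child.
#'
#' @param levels Per-level taxon counts, coarsest to finest.
#' @return List of integer vectors `maps`; `maps[[l]][j]` is the parent (in
#'   level `l`) of taxon `j` of level `l + 1`.  Empty list for one level.
#' @export
random_nested_taxonomy <- function(levels) {
  L <- length(levels)
  if (L == 1) return(list())
  maps <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    n_child <- levels[l + 1]
    n_parent <- levels[l]
    # each parent claims one child; remaining children attach at random
    assign <- integer(n_child)
    assign[sample.int(n_child, n_parent)] <- sample.int(n_parent)
    extra <- assign == 0
    assign[extra] <- sample.int(n_parent, sum(extra), replace = TRUE)
    maps[[l]] <- assign
  }
  maps
}

#' Aggregate a finest-level table to all coarser levels
#'
#' @param X_finest Samples x taxa matrix at the finest level.
#' @param taxonomy List of nested parent maps, coarsest pair first, as
#'   returned by [random_nested_taxonomy()]; each element is either an
#'   integer vector (`map[j]` = parent of child taxon `j`) or a two-column
#'   child/parent edge table whose child ids match the child level's column
#'   names.
#' @param fun `"sum"` (proportion scale) or `"mean"` (score scale).
#' @return List of matrices, coarsest to finest (the finest is `X_finest`
#'   itself).
#' @export
aggregate_levels <- function(X_finest, taxonomy, fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  X_finest <- as_num_matrix(X_finest)
  L <- length(taxonomy) + 1
  out <- vector("list", L)
  out[[L]] <- X_finest
  for (l in rev(seq_len(L - 1))) {
    child <- out[[l + 1]]
    conv <- as_parent_map(taxonomy[[l]], colnames(child))
    map <- conv$map
    if (length(map) != ncol(child)) {
      stop("taxonomy map does not match the number of child taxa")
    }
    n_parent <- max(map)
    agg <- matrix(0, nrow(child), n_parent)
    for (j in seq_along(map)) agg[, map[j]] <- agg[, map[j]] + child[, j]
    if (fun == "mean") {
      counts <- tabulate(map, n_parent)
      agg <- sweep(agg, 2, counts, "/")
    }
    colnames(agg) <- conv$parent_names %||% paste0("L", l, "_T", seq_len(n_parent))
    rownames(agg) <- rownames(child)
    out[[l]] <- agg
  }
  out
}

# Accept either an integer parent vector or a two-column (child, parent)
# edge table; reject children with several parents (non-nested map).
as_parent_map <- function(m, child_names = NULL) {
  if (is.data.frame(m) || (is.matrix(m) && ncol(m) == 2)) {
    m <- as.data.frame(m)
    if (anyDuplicated(m[[1]])) {
      stop("non-nested taxonomy: a child maps to several parents")
    }
    if (!is.null(child_names)) {
      idx <- match(child_names, as.character(m[[1]]))
      if (anyNA(idx)) stop("taxonomy map is missing some child taxa")
      m <- m[idx, ]
    }
    parent <- factor(as.character(m[[2]]), levels = unique(as.character(m[[2]])))
    return(list(map = as.integer(parent), parent_names = levels(parent)))
  }
  list(map = as.integer(m), parent_names = NULL)
}

#' Generate a synthetic multi-level dataset with known truth
#'
#' Draws `2n` samples: correlated nutrient vectors, a latent class per
#' sample gated by diet through a softmax on `c_g`-scaled orthogonal unit
#' directions (plus an `eta` mean shift; see [sim_config()] for the three
#' class modes), class-independent standard-normal abundance scores at the
#' finest level (aggregated upward through a random nested taxonomy and
#' z-scored per level), and outcomes from a class-specific sparse logistic
#' model on the finest level: nonzero coefficients `+/- c_e` on
#' `n_signal_expert` taxa, with class 2 carrying the opposite sign pattern
#' of class 1 (maximally different microbiome-outcome relationships).
#'
#' @param config A [sim_config()] object (or arguments forwarded to it).
#' @param ... Passed to [sim_config()] when `config` is missing.
#' @return Object of class `"nutrimoe_sim"`: list with `data`
#'   (a [nutrimoe_data()] holding all 2n samples), `truth` (true class
#'   `z`, `gamma`, finest-level `beta`, aggregation-projected reference
#'   `beta_levels`, signal index sets), `taxonomy` and `config`.
#' @export
simulate_ecotypes <- function(config = NULL, ...) {
  config <- config %||% sim_config(...)
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  N <- 2 * cf$n
  L <- length(cf$levels)

  with_seed(cf$seed, {
    # gating truth: disjoint blocks of signal nutrients per class; mu_k are
    # the orthogonal unit mean-shift directions, while the gating
    # coefficients carry effect size c_g per signal nutrient (mirroring the
    # per-taxon expert effect size c_e)
    s <- cf$n_signal_gating
    mu <- matrix(0, cf$q, cf$K)
    for (k in seq_len(cf$K)) mu[(k - 1) * s + seq_len(s), k] <- 1 / sqrt(s)
    gamma_true <- rbind(0, cf$c_g * sqrt(s) * mu)
    gamma_true <- gamma_true - gamma_true[, cf$K]

    # nutrient noise: unit-variance equicorrelated gaussian
    noise <- sqrt(cf$rho) * rnorm(N) +
      sqrt(1 - cf$rho) * matrix(rnorm(N * cf$q), N, cf$q)

    if (cf$class_mode == "mean_shift") {
      z <- sample.int(cf$K, N, replace = TRUE)
      W <- cf$eta * t(mu)[z, , drop = FALSE] + noise
    } else {
      W <- noise
      # gamma_true already carries the c_g scaling
      eta_g <- add_intercept(W) %*% gamma_true
      eta_g <- eta_g - apply(eta_g, 1, max)
      pz <- exp(eta_g) / rowSums(exp(eta_g))
      z <- vapply(seq_len(N), function(i) {
        sample.int(cf$K, 1, prob = pz[i, ])
      }, 0L)
      if (cf$class_mode == "combined") {
        W <- W + cf$eta * t(mu)[z, , drop = FALSE]
      }
    }
    colnames(W) <- paste0("nutrient", seq_len(cf$q))
    rownames(W) <- paste0("S", seq_len(N))

    taxonomy <- random_nested_taxonomy(cf$levels)
    X_f <- matrix(rnorm(N * cf$p), N, cf$p)
    colnames(X_f) <- paste0("L", L, "_T", seq_len(cf$p))
    X <- aggregate_levels(X_f, taxonomy, fun = cf$level_agg)
    X <- lapply(X, zscore_cols)
    X <- lapply(X, function(m) { attr(m, "scaling") <- NULL; m })
    for (l in seq_len(L)) rownames(X[[l]]) <- rownames(W)

    # expert truth at the finest level; the signal taxa are chosen as whole
    # descendant groups of coarse-level ancestors, with one sign per
    # ancestor (phylogenetically coherent effects), so aggregation
    # concentrates rather than cancels the signal and every level carries
    # it.  Class 2 flips the signs of class 1; further classes alternate
    # random sign patterns.
    if (L > 1) {
      anc <- seq_len(cf$p)
      for (l in rev(seq_len(L - 1))) anc <- taxonomy[[l]][anc]
      fams <- split(seq_len(cf$p), anc)
      fams <- fams[sample.int(length(fams))]
      supp <- integer(0)
      fam_sign <- integer(cf$p)
      for (f in fams) {
        if (length(supp) >= cf$n_signal_expert) break
        take <- f[seq_len(min(length(f), cf$n_signal_expert - length(supp)))]
        fam_sign[take] <- sample(c(-1L, 1L), 1)
        supp <- c(supp, take)
      }
      supp <- sort(supp)
      base_sign <- fam_sign[supp]
    } else {
      supp <- sort(sample.int(cf$p, cf$n_signal_expert))
      base_sign <- sample(c(-1, 1), cf$n_signal_expert, replace = TRUE)
    }
    beta_true <- matrix(0, cf$p + 1, cf$K)
    for (k in seq_len(cf$K)) {
      sgn <- if (k == 1) base_sign
             else if (k == 2) -base_sign
             else base_sign * sample(c(-1, 1), cf$n_signal_expert, replace = TRUE)
      beta_true[1 + supp, k] <- cf$c_e * sgn
    }

    eta_all <- add_intercept(X[[L]]) %*% beta_true
    eta_y <- eta_all[cbind(seq_len(N), z)]
    y <- rbinom(N, 1, plogis(eta_y))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)  # degenerate draw guard

    level_names <- paste0("level", seq_len(L))
    data <- nutrimoe_data(W, X, y, level_names = level_names)

    structure(list(
      data = data,
      truth = list(z = z, gamma = gamma_true, beta = beta_true,
                   beta_levels = project_beta_levels(beta_true, taxonomy, cf),
                   expert_support = supp,
                   gating_support = seq_len(s * cf$K)),
      taxonomy = taxonomy,
      config = cf
    ), class = "nutrimoe_sim")
  })
}

# Reference-only coarse-level "truth": sum child coefficients into their
# parent (the aggregation-induced projection; not used to generate data).
project_beta_levels <- function(beta_true, taxonomy, cf) {
  L <- length(cf$levels)
  out <- vector("list", L)
  out[[L]] <- beta_true
  b <- beta_true
  for (l in rev(seq_len(L - 1))) {
    map <- taxonomy[[l]]
    n_parent <- cf$levels[l]
    bl <- matrix(0, n_parent + 1, cf$K)
    bl[1, ] <- b[1, ]
    for (j in seq_along(map)) bl[1 + map[j], ] <- bl[1 + map[j], ] + b[-1, , drop = FALSE][j, ]
    out[[l]] <- bl
    b <- bl
  }
  out
}

#' Deterministic first-half / second-half split of a simulated dataset
#'
#' The first `n` of the `2n` generated samples form the training set, the
#' remainder the test set.
#'
#' @param sim A [simulate_ecotypes()] result.
#' @return List with elements `train` and `test`, each holding `data`
#'   (a [nutrimoe_data()]) and the matching true classes `z`.
#' @export
split_half <- function(sim) {
  stopifnot(inherits(sim, "nutrimoe_sim"))
  N <- nrow(sim$data$W)
  if (N %% 2 != 0) stop("simulated dataset must have an even sample count")
  n <- N / 2
  take <- function(idx) {
    d <- nutrimoe_data(sim$data$W[idx, , drop = FALSE],
                       lapply(sim$data$X, function(m) m[idx, , drop = FALSE]),
                       sim$data$y[idx],
                       level_names = sim$data$level_names)
    list(data = d, z = sim$truth$z[idx])
  }
  list(train = take(seq_len(n)), test = take(n + seq_len(n)))
}
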