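#' Total-sum scaling of a count or proportion table
#'
#' Converts each row (sample) of a samples-by-taxa table to proportions by
#' dividing by its row total.  Idempotent on proportion input.
#'
#' @param counts Numeric matrix, samples in rows, taxa in columns.
#'   Non-negative entries; every row total must be positive.
#' @return Matrix of the same shape whose rows sum to 1.
#' @examples
#' tss_normalize(rbind(a = c(2, 2, 0), b = c(3, 1, 4)))
#' @export
tss_normalize <- function(counts) {
  counts <- as_num_matrix(counts)
  if (any(counts < 0)) stop("abundance table has negative entries")
  totals <- rowSums(counts)
  bad <- which(totals <= 0)
  if (length(bad)) {
    ids <- rownames(counts)[bad] %||% as.character(bad)
    stop("zero total abundance for sample(s): ", paste(ids, collapse = ", "))
  }
  counts / totals
}

#' Retain core taxa by zero-fraction and variance thresholds
#'
#' Drops taxa with more than `max_zero_frac` zero entries across samples or
#' with sample variance below `min_variance`.  Both thresholds are strict
#' (a taxon with zero fraction exactly 0.30 or variance exactly 1e-5 is
#' kept).  Retained columns are untouched and keep their order.
#'
#' @param props Matrix of TSS proportions (samples x taxa).
#' @param max_zero_frac Maximum tolerated fraction of zeros per taxon.
#' @param min_variance Minimum sample variance (n-1 denominator) per taxon.
#' @return The filtered matrix, with an attribute `"dropped"` naming removed
#'   taxa.
#' @export
filter_core_taxa <- function(props, max_zero_frac = 0.30, min_variance = 1e-5) {
  props <- as_num_matrix(props)
  zero_frac <- colMeans(props == 0)
  v <- apply(props, 2, var)
  keep <- zero_frac <= max_zero_frac & v >= min_variance
  if (!any(keep)) stop("all taxa removed by core-feature filtering")
  out <- props[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(props)[!keep] %||% which(!keep)
  out
}

#' Arcsine-square-root transform for proportions
#'
#' Variance-stabilizing transform `asin(sqrt(p))` applied entrywise; maps
#' \[0, 1\] to \[0, pi/2\] monotonically.
#'
#' @param props Matrix (or vector) with entries in \[0, 1\].
#' @return Transformed object of the same shape.
#' @export
asin_sqrt <- function(props) {
  if (any(props < 0 | props > 1)) {
    stop("arcsine-square-root transform requires entries in [0, 1]")
  }
  asin(sqrt(props))
}

#' Column-wise standardization to mean zero, unit variance
#'
#' @param x Numeric matrix; every column must have nonzero variance.
#' @param sample_sd Use the n-1 (sample) standard deviation (default) or the
#'   population (n denominator) convention.
#' @return Standardized matrix with attribute `"scaling"` recording the
#'   convention, centers and scales used.
#' @export
zscore_cols <- function(x, sample_sd = TRUE) {
  x <- as_num_matrix(x)
  ctr <- colMeans(x)
  n <- nrow(x)
  s <- apply(x, 2, sd)
  if (!sample_sd) s <- s * sqrt((n - 1) / n)
  bad <- which(!is.finite(s) | s == 0)
  if (length(bad)) {
    ids <- colnames(x)[bad] %||% as.character(bad)
    stop("zero-variance column(s), cannot standardize: ",
         paste(ids, collapse = ", "))
  }
  out <- sweep(sweep(x, 2, ctr), 2, s, "/")
  attr(out, "scaling") <- list(
    convention = if (sample_sd) "sample (n-1)" else "population (n)",
    center = ctr, scale = s
  )
  out
}

#' Centered log-ratio transform with half-minimum pseudocount
#'
#' Alternative to [asin_sqrt()]: `log(p + c) - mean(log(p + c))` per sample,
#' where the pseudocount `c` defaults to half the smallest nonzero proportion
#' in the table.
#'
#' @param props Matrix of TSS proportions.
#' @param pseudocount Optional positive offset; default half the minimum
#'   nonzero entry.
#' @return CLR-transformed matrix (rows sum to 0).
#' @export
clr_transform <- function(props, pseudocount = NULL) {
  props <- as_num_matrix(props)
  if (any(props < 0)) stop("proportions must be non-negative")
  if (is.null(pseudocount)) {
    nz <- props[props > 0]
    if (!length(nz)) stop("all-zero table")
    pseudocount <- min(nz) / 2
  }
  lg <- log(props + pseudocount)
  lg - rowMeans(lg)
}

#' Full abundance preprocessing pipeline
#'
#' Applies, in this fixed order: total-sum scaling, core-taxon filtering on
#' the proportion scale, a variance-stabilizing transform (arcsine square
#' root by default, or CLR), and column z-scoring.
#'
#' @param counts Count or proportion matrix, samples x taxa.
#' @param max_zero_frac,min_variance Passed to [filter_core_taxa()].
#' @param transform `"asin_sqrt"` (default) or `"clr"`.
#' @param sample_sd Passed to [zscore_cols()].
#' @return Model-ready standardized matrix; attributes `"dropped"` and
#'   `"scaling"` record the filtering and standardization applied.
#' @export
preprocess_abundance <- function(counts, max_zero_frac = 0.30,
                                 min_variance = 1e-5,
                                 transform = c("asin_sqrt", "clr"),
                                 sample_sd = TRUE) {
  transform <- match.arg(transform)
  props <- tss_normalize(counts)
  props <- filter_core_taxa(props, max_zero_frac, min_variance)
  dropped <- attr(props, "dropped")
  tr <- switch(transform,
    asin_sqrt = asin_sqrt(props),
    clr = clr_transform(props)
  )
  out <- zscore_cols(tr, sample_sd = sample_sd)
  attr(out, "dropped") <- dropped
  attr(out, "transform") <- transform
  out
}

#' Derived energy-ratio nutrition features
#'
#' Appends four standard nutri-omics variables to a nutrient-intake table:
#' percentage of energy from protein (`pct_energy_protein`), fat
#' (`pct_energy_fat`) and carbohydrate (`pct_energy_carb`), plus the
#' protein-to-carbohydrate intake ratio (`protein_carb_ratio`).  Energy
#' conversions use Atwater-type factors (kJ per gram), by default 17 for
#' protein, 37 for fat and 17 for carbohydrate.  A 23-feature macronutrient
#' table becomes a 27-feature table.
#'
#' @param nutrition Numeric matrix or data frame, samples x nutrients, with
#'   named columns.
#' @param energy_col,protein_col,fat_col,carb_col Column names of total
#'   energy (kJ) and protein / fat / carbohydrate intake (g).
#' @param kj_per_g Named numeric vector of energy conversion factors with
#'   entries `protein`, `fat`, `carb`.
#' @param zscore Standardize all output features (default `TRUE`).
#' @return Matrix with four appended columns (z-scored when `zscore = TRUE`,
#'   with scaling metadata as in [zscore_cols()]).
#' @export
derive_energy_features <- function(nutrition, energy_col = "energy",
                                   protein_col = "protein", fat_col = "fat",
                                   carb_col = "carbohydrate",
                                   kj_per_g = c(protein = 17, fat = 37, carb = 17),
                                   zscore = TRUE) {
  nutrition <- as_num_matrix(nutrition)
  need <- c(energy_col, protein_col, fat_col, carb_col)
  miss <- setdiff(need, colnames(nutrition))
  if (length(miss)) stop("missing nutrition column(s): ", paste(miss, collapse = ", "))

  energy <- nutrition[, energy_col]
  protein <- nutrition[, protein_col]
  fat <- nutrition[, fat_col]
  carb <- nutrition[, carb_col]

  check_pos <- function(x, what) {
    bad <- which(!(x > 0))
    if (length(bad)) {
      ids <- rownames(nutrition)[bad] %||% as.character(bad)
      stop(sprintf("non-positive %s for sample(s): %s", what,
                   paste(ids, collapse = ", ")))
    }
  }
  check_pos(energy, energy_col)
  check_pos(carb, carb_col)

  extra <- cbind(
    pct_energy_protein = 100 * protein * kj_per_g[["protein"]] / energy,
    pct_energy_fat     = 100 * fat * kj_per_g[["fat"]] / energy,
    pct_energy_carb    = 100 * carb * kj_per_g[["carb"]] / energy,
    protein_carb_ratio = protein / carb
  )
  out <- cbind(nutrition, extra)
  if (zscore) out <- zscore_cols(out)
  attr(out, "kj_per_g") <- kj_per_g
  out
}

#' Sample-level exclusions by energy intake, read depth and missing nutrition
#'
#' Removes samples with daily energy intake above `max_energy_kj` (strictly),
#' total microbial read count below `min_reads` (strictly), or any missing
#' nutrition value, and reports every exclusion with its reason.
#'
#' @param counts Count matrix, samples x taxa (used for read totals).
#' @param nutrition Nutrition matrix, same samples in the same order; may
#'   contain `NA`.
#' @param energy_kj Numeric vector of per-sample energy intake (kJ/day).
#' @param max_energy_kj,min_reads Exclusion thresholds; boundary values are
#'   retained.
#' @return List with the filtered `counts` and `nutrition` and an
#'   `exclusions` data frame (`sample`, `reason` in
#'   `"energy"`/`"reads"`/`"missing nutrition"`).  An empty result is allowed
#'   but signalled with a warning.
#' @export
filter_samples <- function(counts, nutrition, energy_kj,
                           max_energy_kj = 20000, min_reads = 10000) {
  counts <- as_num_matrix(counts)
  nutrition <- as_num_matrix(nutrition)
  n <- nrow(counts)
  stopifnot(nrow(nutrition) == n, length(energy_kj) == n)
  ids <- rownames(counts) %||% as.character(seq_len(n))

  reads <- rowSums(counts)
  reasons <- character(0); who <- character(0)
  add <- function(idx, reason) {
    who <<- c(who, ids[idx]); reasons <<- c(reasons, rep(reason, length(idx)))
  }
  add(which(!is.na(energy_kj) & energy_kj > max_energy_kj), "energy")
  add(which(reads < min_reads), "reads")
  add(which(is.na(energy_kj) | rowSums(is.na(nutrition)) > 0), "missing nutrition")

  exclusions <- unique(data.frame(sample = who, reason = reasons,
                                  stringsAsFactors = FALSE))
  keep <- !(ids %in% exclusions$sample)
  if (!any(keep)) warning("all samples excluded")
  list(counts = counts[keep, , drop = FALSE],
       nutrition = nutrition[keep, , drop = FALSE],
       exclusions = exclusions)
}
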