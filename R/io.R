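# File-based glue: CSV/TSV readers with sample ids in the first column,
# id-aligned dataset assembly, and an end-to-end pipeline runner.

read_id_matrix <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, check.names = FALSE, row.names = 1)
  if (anyDuplicated(rownames(df))) {
    stop("duplicate sample ids in ", path)
  }
  as.matrix(df)
}

#' Read a samples-by-taxa abundance table (CSV/TSV)
#'
#' First column sample ids, header row taxon ids.
#'
#' @param path File path; tab-separated when the name ends in `.tsv`.
#' @return Numeric matrix with dimnames.
#' @export
read_abundance_table <- function(path) {
  read_id_matrix(path, sep = if (grepl("\\.tsv$", path)) "\t" else ",")
}

#' Read a samples-by-nutrients table (CSV)
#'
#' Missing values are permitted (samples can be excluded later with reason
#' "missing nutrition").
#'
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_nutrition_table <- function(path) read_id_matrix(path)

#' Read a per-sample binary label file (CSV)
#'
#' Two columns: sample id, label (0/1).
#'
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_labels <- function(path) {
  m <- read_id_matrix(path)
  y <- as.numeric(m[, 1])
  names(y) <- rownames(m)
  y
}

#' Read a two-column child/parent taxonomy edge list (TSV)
#'
#' @param path File path with a header line and columns `child`, `parent`.
#' @return Data frame with character columns `child` and `parent`.
#' @export
read_taxonomy_edges <- function(path) {
  df <- read.csv(path, sep = "\t", check.names = FALSE,
                 colClasses = "character")
  names(df)[1:2] <- c("child", "parent")
  df
}

#' Assemble an id-aligned multi-level dataset from files
#'
#' Reads one abundance table per level, the nutrition table and the labels,
#' intersects their sample ids (order taken from the nutrition table) and
#' reports dropped ids.
#'
#' @param abundance Named character vector of file paths, one per taxonomic
#'   level (coarsest first); names become level names.
#' @param nutrition Path of the nutrition CSV.
#' @param labels Path of the label CSV.
#' @return A [nutrimoe_data()] object; the ids dropped from each source are
#'   reported via `message()` and attached as attribute `"dropped_ids"`.
#' @export
load_dataset <- function(abundance, nutrition, labels) {
  X <- lapply(abundance, read_abundance_table)
  W <- read_nutrition_table(nutrition)
  y <- read_labels(labels)
  id_sets <- c(list(rownames(W), names(y)), lapply(X, rownames))
  ids <- Reduce(intersect, id_sets)
  if (!length(ids)) stop("no samples shared across the input files")
  dropped <- unique(unlist(lapply(id_sets, setdiff, ids)))
  if (length(dropped)) {
    message(length(dropped), " sample id(s) dropped (not present in all files): ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  }
  out <- nutrimoe_data(W[ids, , drop = FALSE],
                       lapply(X, function(m) m[ids, , drop = FALSE]),
                       y[ids],
                       level_names = names(abundance) %||% NULL)
  attr(out, "dropped_ids") <- dropped
  out
}

#' Run the full pipeline: preprocess, fit, evaluate, write outputs
#'
#' Executes preprocessing (optional), the mixture-of-experts fit and the
#' standard evaluations, writing all results into a run directory:
#' `params.json`, `responsibilities.csv`, `rll_trace.csv`,
#' `signatures.csv` (for K = 2), `metrics.json`, and a machine-readable
#' `provenance.json` (configuration, seed, package and R versions).
#'
#' @param config A list (or path to a JSON file holding one) with entries:
#'   `out_dir`; `seed`; either `files` (list with `abundance`, `nutrition`,
#'   `labels` for [load_dataset()]) or `data` (a [nutrimoe_data()]);
#'   optional `preprocess = TRUE` to run [preprocess_abundance()] on each
#'   level; `fit` (arguments for [nutrimoe()]: `K`, `lambda1`, ...);
#'   optional `truth_z` (true classes, adds ARI to the metrics).
#' @return The run directory path, invisibly; metrics are also returned as
#'   attribute `"metrics"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config), !is.null(config$out_dir), !is.null(config$seed))
  stage <- "configuration"
  result <- tryCatch({
    stage <- "load"
    data <- if (!is.null(config$data)) {
      config$data
    } else {
      load_dataset(config$files$abundance, config$files$nutrition,
                   config$files$labels)
    }
    if (isTRUE(config$preprocess)) {
      stage <- "preprocess"
      X <- lapply(data$X, preprocess_abundance)
      W <- zscore_cols(data$W)
      data <- nutrimoe_data(W, X, data$y, level_names = data$level_names)
    }
    stage <- "fit"
    fit_args <- config$fit %||% list()
    fit_args$seed <- fit_args$seed %||% config$seed
    fit <- do.call(nutrimoe, c(list(W = data$W, X = data$X, y = data$y), fit_args))

    stage <- "evaluate"
    metrics <- list(
      final_rll = fit$rll_trace[length(fit$rll_trace)],
      n_iter = fit$n_iter,
      converged = fit$converged,
      class_sizes = as.numeric(table(factor(fit$cluster,
                                            levels = seq_len(fit$params$K))))
    )
    train_prob <- predict(fit, data$W, data$X)
    metrics$train_auc <- auc_rank(train_prob, data$y)
    if (!is.null(config$truth_z)) {
      metrics$ari_vs_truth <- adjusted_rand_index(fit$cluster, config$truth_z)
    }

    stage <- "write"
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_params_json(fit$params, out("params.json"), penalty = fit$penalty)
    write.csv(data.frame(sample = rownames(data$W) %||% seq_len(nrow(data$W)),
                         fit$responsibilities, cluster = fit$cluster),
              out("responsibilities.csv"), row.names = FALSE)
    write.csv(data.frame(iteration = seq_along(fit$rll_trace),
                         rll = fit$rll_trace),
              out("rll_trace.csv"), row.names = FALSE)
    if (fit$params$K == 2) {
      write.csv(categorize_signatures(fit), out("signatures.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(metrics, out("metrics.json"), digits = NA,
                         auto_unbox = TRUE)
    jsonlite::write_json(
      list(seed = config$seed,
           fit = fit$config,
           penalty = unclass(fit$penalty),
           package_version = as.character(packageVersion("nutrimoe")),
           r_version = R.version.string),
      out("provenance.json"), digits = NA, auto_unbox = TRUE)
    invisible(structure(config$out_dir, metrics = metrics))
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}
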