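# Readers and writers for the package's external formats: Newick trees,
# trait and pool CSVs, curve exports and the JSON run manifest.

#' Read one or more Newick trees
#'
#' @param path a Newick file; one tree per line is accepted.
#' @return A list of `phylo` trees (length 1 for a single tree).
#' @export
read_tree_file <- function(path) {
  if (!file.exists(path)) stop("cannot read tree file: ", path, call. = FALSE)
  trees <- ape::read.tree(path)
  if (is_phylo(trees)) trees <- list(trees)
  for (tr in trees)
    stop_if_not(!is.null(tr$edge.length),
                "trees must carry branch lengths: ", path)
  trees
}

#' Read a trait table from CSV
#'
#' The first column is taken as the species id. Character columns
#' become unordered factors; `trait_types` can override any column to
#' `"numeric"`, `"categorical"` or `"ordinal"` (ordered factor with
#' levels in sort order).
#'
#' @param path CSV file with a header row.
#' @param trait_types optional named character vector of type
#'   declarations.
#' @return A `data.frame` with species ids as row names.
#' @export
read_trait_table <- function(path, trait_types = NULL) {
  if (!file.exists(path)) stop("cannot read trait file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stop_if_not(ncol(df) >= 2, "trait CSV needs a species column and >= 1 trait")
  ids <- as.character(df[[1]])
  stop_if_not(!anyDuplicated(ids), "duplicated species ids in ", path)
  df <- df[, -1, drop = FALSE]
  rownames(df) <- ids
  for (col in names(df)) {
    declared <- if (!is.null(trait_types) && col %in% names(trait_types))
      trait_types[[col]] else NA
    if (identical(declared, "numeric")) {
      df[[col]] <- as.numeric(df[[col]])
    } else if (identical(declared, "ordinal")) {
      df[[col]] <- factor(df[[col]], levels = sort(unique(df[[col]])),
                          ordered = TRUE)
    } else if (identical(declared, "categorical") || is.character(df[[col]])) {
      df[[col]] <- factor(df[[col]])
    }
  }
  df
}

#' Read a pool-membership table from CSV
#'
#' @param path CSV with columns `pool_id` and `species`.
#' @return A long-format `data.frame`.
#' @export
read_pool_table <- function(path) {
  if (!file.exists(path)) stop("cannot read pool file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if_not(all(c("pool_id", "species") %in% names(df)),
              "pool CSV must have columns pool_id and species")
  df
}

#' Export accumulation curves in long format
#'
#' @param curves the `"curves"` attribute of a results table (a list of
#'   per-pool lists of `"accumulation_curve"` objects) or a flat list of
#'   curves.
#' @return A long `data.frame` with columns `pool_id`, `strategy`,
#'   `decile`, `fd_mean`, `n_replicates`.
#' @export
curves_to_table <- function(curves) {
  flat <- list()
  for (cv in curves) {
    if (inherits(cv, "accumulation_curve")) flat <- c(flat, list(cv))
    else flat <- c(flat, unname(cv))
  }
  do.call(rbind, lapply(flat, function(cv)
    data.frame(pool_id = cv$pool_id, strategy = cv$strategy,
               decile = cv$deciles, fd_mean = cv$fd_values,
               n_replicates = cv$n_replicates,
               stringsAsFactors = FALSE)))
}

# results + curves + manifest under config$output_dir
write_experiment <- function(results, config, hash) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  res_path <- file.path(config$output_dir, "surrogacy_results.csv")
  utils::write.csv(as.data.frame(results), res_path, row.names = FALSE)
  cv <- attr(results, "curves")
  if (length(cv) > 0)
    utils::write.csv(curves_to_table(cv),
                     file.path(config$output_dir, "curves.csv"),
                     row.names = FALSE)
  sk <- attr(results, "skipped")
  if (!is.null(sk) && nrow(sk) > 0)
    utils::write.csv(sk, file.path(config$output_dir, "skipped_pools.csv"),
                     row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- list(config_hash = hash, seed = config$seed,
                     mode = config$mode, n_pools = nrow(results),
                     n_skipped = if (is.null(sk)) 0L else nrow(sk),
                     deciles = config$deciles,
                     n_random = config$n_random,
                     sets_per_tree = config$sets_per_tree,
                     n_param_draws = config$n_param_draws,
                     variance_threshold = config$variance_threshold,
                     surrogacy_form = config$surrogacy_form)
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(res_path)
}

#' Write synthetic inputs to disk
#'
#' Materializes a synthetic scenario as the package's external formats:
#' `trees.nwk` (Newick, one tree per line), `traits.csv` (first column
#' `species`) and `pools.csv` (`pool_id, species`), ready for a
#' files-mode [run_experiment()].
#'
#' @param config a [run_config()] in synthetic mode with `output_dir`
#'   set.
#' @return Invisibly, the output directory.
#' @export
write_synthetic_inputs <- function(config) {
  stop_if_not(inherits(config, "run_config") &&
                config$mode == "synthetic" && !is.null(config$output_dir),
              "need a synthetic-mode run_config with an output_dir")
  inputs <- load_inputs(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  trees <- inputs$trees
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file.path(config$output_dir, "trees.nwk"))
  traits <- data.frame(species = rownames(inputs$traits), inputs$traits,
                       stringsAsFactors = FALSE)
  utils::write.csv(traits, file.path(config$output_dir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(inputs$pools, file.path(config$output_dir, "pools.csv"),
                   row.names = FALSE)
  invisible(config$output_dir)
}
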