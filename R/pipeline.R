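# End-to-end orchestration: from trees + traits + pools (synthetic or
# user-supplied) to a per-pool table of surrogacy indices, reliability
# fractions and tree/trait covariates, plus Spearman correlates.

#' Configuration of a full surrogacy experiment
#'
#' @param mode `"synthetic"` (generate trees/traits/pools from `sim`)
#'   or `"files"` (read them from `trees_file`, `traits_file`,
#'   `pools_file`).
#' @param sim a [simulation_config()] (synthetic mode).
#' @param trees_file Newick file with one or more trees (files mode).
#' @param traits_file CSV of traits, first column the species id (files
#'   mode).
#' @param pools_file CSV with columns `pool_id, species` (files mode).
#' @param trait_types optional named character vector mapping trait
#'   columns to `"numeric"`, `"categorical"` or `"ordinal"` (files
#'   mode; unlisted columns keep their parsed type).
#' @param pool_sizes integer vector of synthetic pool sizes; `NULL`
#'   (default) makes a single pool of all species.
#' @param pool_overlap overlap fraction passed to [make_pools()].
#' @param deciles richness fractions of the accumulation curves.
#' @param n_random random sets per decile (default 1000).
#' @param sets_per_tree maxPD tie-break sets per tree (default 10).
#' @param n_param_draws penalty-parameter pairs tested per decile
#'   (default 1000).
#' @param variance_threshold PCoA retained-variance threshold
#'   (default 0.70).
#' @param pcoa_correction `"none"`, `"cailliez"` or `"lingoes"`.
#' @param surrogacy_form `"area_ratio"` (default) or `"pointwise"`.
#' @param min_pool_size pools below this size are skipped (default 10).
#' @param log_columns,rescale_columns trait columns to preprocess with
#'   [preprocess_traits()].
#' @param seed master seed; all stage seeds are derived from it with
#'   [derive_seed()].
#' @param output_dir optional directory to write result CSVs and a JSON
#'   run manifest.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       sim = NULL,
                       trees_file = NULL, traits_file = NULL,
                       pools_file = NULL, trait_types = NULL,
                       pool_sizes = NULL, pool_overlap = 0,
                       deciles = seq(0.1, 1, by = 0.1),
                       n_random = 1000, sets_per_tree = 10,
                       n_param_draws = 1000,
                       variance_threshold = 0.70,
                       pcoa_correction = "none",
                       surrogacy_form = c("area_ratio", "pointwise"),
                       min_pool_size = 10,
                       log_columns = character(),
                       rescale_columns = character(),
                       seed = 1L, output_dir = NULL) {
  mode <- match.arg(mode)
  surrogacy_form <- match.arg(surrogacy_form)
  if (mode == "synthetic")
    stop_if_not(inherits(sim, "simulation_config"),
                "synthetic mode requires a simulation_config in `sim`")
  if (mode == "files")
    stop_if_not(!is.null(trees_file) && !is.null(traits_file) &&
                  !is.null(pools_file),
                "files mode requires trees_file, traits_file and pools_file")
  stop_if_not(n_random >= 1 && sets_per_tree >= 1 && n_param_draws >= 1,
              "all replicate counts must be >= 1")
  stop_if_not(variance_threshold > 0 && variance_threshold <= 1,
              "variance_threshold must lie in (0, 1]")
  stop_if_not(all(diff(deciles) > 0) && all(deciles > 0) &&
                all(deciles <= 1),
              "deciles must be increasing fractions in (0, 1]")
  structure(list(mode = mode, sim = sim, trees_file = trees_file,
                 traits_file = traits_file, pools_file = pools_file,
                 trait_types = trait_types,
                 pool_sizes = pool_sizes, pool_overlap = pool_overlap,
                 deciles = deciles, n_random = as.integer(n_random),
                 sets_per_tree = as.integer(sets_per_tree),
                 n_param_draws = as.integer(n_param_draws),
                 variance_threshold = variance_threshold,
                 pcoa_correction = pcoa_correction,
                 surrogacy_form = surrogacy_form,
                 min_pool_size = as.integer(min_pool_size),
                 log_columns = log_columns,
                 rescale_columns = rescale_columns,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' MD5 hash of a run configuration
#'
#' Hashes the deparsed configuration (excluding the output directory) so
#' every result row is traceable to the exact settings that produced it;
#' changing any replicate count, threshold or seed changes the hash.
#'
#' @param config a `"run_config"`.
#' @return A 32-character hex string.
#' @export
config_hash <- function(config) {
  hashable <- config[setdiff(names(config), "output_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(hashable), tmp)
  unname(tools::md5sum(tmp))
}

load_inputs <- function(config) {
  if (config$mode == "synthetic") {
    base <- simulate_tree(config$sim)
    trees <- if (config$sim$n_posterior_trees > 0)
      jitter_tree_set(base, config$sim$n_posterior_trees,
                      config$sim$branch_jitter_sd,
                      seed = derive_seed(config$seed, "jitter"))
    else list(base)
    traits <- simulate_traits(base, config$sim)
    sizes <- if (is.null(config$pool_sizes)) config$sim$n_species
             else config$pool_sizes
    pools <- make_pools(base$tip.label, sizes, config$pool_overlap,
                        seed = derive_seed(config$seed, "pools"))
    list(base_tree = base, trees = trees, traits = traits, pools = pools)
  } else {
    trees <- read_tree_file(config$trees_file)
    traits <- read_trait_table(config$traits_file, config$trait_types)
    pools <- read_pool_table(config$pools_file)
    missing <- setdiff(pools$species, rownames(traits))
    if (length(missing) > 0)
      stop("pool species absent from the trait table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    list(base_tree = trees[[1]], trees = trees, traits = traits,
         pools = pools)
  }
}

#' Run the full surrogacy experiment
#'
#' For every pool: trait preprocessing, Gower distance, PCoA embedding,
#' Blomberg's K per retained axis (on the pool-pruned first tree), the
#' three FD accumulation curves, the surrogacy index and the reliability
#' fraction. Pools that are too small or fail (e.g. degenerate
#' distances) are skipped with a logged reason, never fatal. The whole
#' run is a deterministic function of the inputs, the configuration and
#' the master seed.
#'
#' @param config a [run_config()].
#' @param verbose print per-pool progress to stderr (default `TRUE`).
#' @return A `data.frame` of class `"surrogacy_results"`, one row per
#'   analysed pool, with columns `pool_id`, `richness`, `retained_d`,
#'   `mean_k` (mean Blomberg's K over retained axes), `gamma`, `beta`,
#'   `s_pd_fd` (percent), `reliability_loss`, `n_trees`, `seed` and
#'   `config_hash`. Skipped pools are recorded in the `"skipped"`
#'   attribute (`pool_id`, `reason`), and the three curves of every
#'   analysed pool in the `"curves"` attribute. If
#'   `config$output_dir` is set, results, curves and a JSON manifest
#'   are written there.
#' @export
run_experiment <- function(config, verbose = TRUE) {
  stop_if_not(inherits(config, "run_config"), "config must be a run_config")
  inputs <- load_inputs(config)
  hash <- config_hash(config)
  pool_ids <- unique(inputs$pools$pool_id)
  say <- function(...) if (verbose) message(...)

  rows <- list()
  curves <- list()
  skipped <- data.frame(pool_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (pid in pool_ids) {
    members <- sort(inputs$pools$species[inputs$pools$pool_id == pid])
    say("pool ", pid, ": ", length(members), " species")
    res <- tryCatch(
      analyse_pool(pid, members, inputs, config, hash),
      error = function(e) e)
    if (inherits(res, "error")) {
      say("  skipped: ", conditionMessage(res))
      skipped <- rbind(skipped,
                       data.frame(pool_id = pid,
                                  reason = conditionMessage(res),
                                  stringsAsFactors = FALSE))
    } else {
      rows[[pid]] <- res$row
      curves[[pid]] <- res$curves
    }
  }
  results <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(pool_id = character(0))
  rownames(results) <- NULL
  attr(results, "skipped") <- skipped
  attr(results, "curves") <- curves
  class(results) <- c("surrogacy_results", class(results))
  if (!is.null(config$output_dir))
    write_experiment(results, config, hash)
  results
}

analyse_pool <- function(pid, members, inputs, config, hash) {
  check_pool_size(members, config$min_pool_size)
  traits <- preprocess_traits(inputs$traits[members, , drop = FALSE],
                              config$log_columns, config$rescale_columns)
  space <- pcoa_embed(gower_distance(traits),
                      variance_threshold = config$variance_threshold,
                      correction = config$pcoa_correction)

  sub <- ape::keep.tip(inputs$base_tree, members)
  ks <- apply(space$coordinates, 2, function(ax)
    blomberg_k(sub, stats::setNames(ax, space$species_ids)))
  gam <- tryCatch(gamma_stat(sub), error = function(e) NA_real_)
  bet <- tryCatch(beta_imbalance(sub)$beta, error = function(e) NA_real_)

  rc <- random_curve(space, members, deciles = config$deciles,
                     n_rep = config$n_random,
                     seed = derive_seed(config$seed, pid, "random"),
                     min_pool_size = config$min_pool_size, pool_id = pid)
  pc <- maxpd_curve(inputs$trees, space, members,
                    deciles = config$deciles,
                    sets_per_tree = config$sets_per_tree,
                    seed = derive_seed(config$seed, pid, "pd"),
                    min_pool_size = config$min_pool_size, pool_id = pid)
  fc <- maxfd_curve(space, members, deciles = config$deciles,
                    n_draws = config$n_param_draws,
                    seed = derive_seed(config$seed, pid, "fd"),
                    min_pool_size = config$min_pool_size, pool_id = pid)

  s <- surrogacy_index(rc, pc, fc, form = config$surrogacy_form)
  rel <- reliability_fraction(rc, pc)
  list(row = data.frame(pool_id = pid, richness = length(members),
                        retained_d = space$retained_d,
                        mean_k = mean(ks), gamma = gam, beta = bet,
                        s_pd_fd = as.numeric(s),
                        reliability_loss = rel,
                        n_trees = length(inputs$trees),
                        seed = config$seed, config_hash = hash,
                        stringsAsFactors = FALSE),
       curves = list(random = rc, maxpd = pc, maxfd = fc))
}

#' Spearman correlates of the surrogacy index
#'
#' Rank-correlates `s_pd_fd` with each pool covariate (richness, mean
#' Blomberg's K over retained axes, gamma, beta, retained
#' dimensionality). Constant covariates have no defined rank
#' correlation and are reported as `NA`.
#'
#' @param results a `"surrogacy_results"` table with >= 5 rows.
#' @return A `data.frame` with columns `covariate`, `rho`, `p_value`,
#'   `n`.
#' @export
correlate_surrogacy <- function(results) {
  stop_if_not(is.data.frame(results) && nrow(results) >= 5,
              "need results for at least 5 pools")
  covariates <- c("richness", "mean_k", "gamma", "beta", "retained_d")
  out <- lapply(covariates, function(cv) {
    x <- results[[cv]]
    y <- results$s_pd_fd
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 5 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(covariate = cv, rho = NA_real_,
                        p_value = NA_real_, n = sum(ok)))
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    data.frame(covariate = cv, rho = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok))
  })
  do.call(rbind, out)
}
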