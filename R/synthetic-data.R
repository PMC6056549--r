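# Synthetic phylogenies, trait tables and species pools with the
# statistical structure the surrogacy analysis assumes: calibrated
# ultrametric trees, a pseudo-posterior tree set, and traits whose
# phylogenetic signal is tunable from pure Brownian motion to white noise.

#' Configuration for the synthetic-data generator
#'
#' Bundles and validates all knobs of the generator. The defaults emulate
#' a typical vertebrate clade analysis: an ultrametric pure-birth tree, a
#' set of pseudo-posterior trees obtained by jittering branch lengths,
#' and a small mixed trait table (continuous + categorical) with strong
#' but imperfect phylogenetic signal.
#'
#' @param n_species number of tips (>= 4).
#' @param tree_model `"pure_birth"` (default) or `"birth_death"`.
#' @param extinction_fraction relative extinction rate (death/birth) in
#'   `[0, 1)`; ignored for `"pure_birth"`.
#' @param n_posterior_trees number of jittered trees emulating a
#'   posterior sample of phylogenetic hypotheses (0 = use the single
#'   generating tree).
#' @param branch_jitter_sd standard deviation, on the log scale, of the
#'   multiplicative lognormal noise applied to branch lengths when
#'   building the pseudo-posterior.
#' @param n_continuous_traits,n_categorical_traits how many traits of
#'   each kind to simulate; their sum must be >= 1.
#' @param n_categories number of (equal-frequency) levels per
#'   categorical trait (>= 2).
#' @param signal_mix fraction of trait variance contributed by Brownian
#'   motion on the tree (1 = pure Brownian, 0 = white noise).
#' @param seed integer seed; every generator below is a pure function of
#'   its configuration and this seed.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_species,
                              tree_model = c("pure_birth", "birth_death"),
                              extinction_fraction = 0,
                              n_posterior_trees = 100,
                              branch_jitter_sd = 0.1,
                              n_continuous_traits = 2,
                              n_categorical_traits = 2,
                              n_categories = 3,
                              signal_mix = 0.8,
                              seed = 1L) {
  tree_model <- match.arg(tree_model)
  stop_if_not(is.numeric(n_species) && length(n_species) == 1 &&
                n_species >= 4,
              "invalid config: n_species must be a single integer >= 4")
  stop_if_not(extinction_fraction >= 0 && extinction_fraction < 1,
              "invalid config: extinction_fraction must lie in [0, 1)")
  stop_if_not(n_posterior_trees >= 0 && branch_jitter_sd >= 0,
              "invalid config: posterior settings must be non-negative")
  stop_if_not(n_continuous_traits >= 0 && n_categorical_traits >= 0 &&
                n_continuous_traits + n_categorical_traits >= 1,
              "invalid config: at least one trait is required")
  stop_if_not(n_categories >= 2,
              "invalid config: n_categories must be >= 2")
  stop_if_not(signal_mix >= 0 && signal_mix <= 1,
              "invalid config: signal_mix must lie in [0, 1]")
  structure(list(n_species = as.integer(n_species),
                 tree_model = tree_model,
                 extinction_fraction = extinction_fraction,
                 n_posterior_trees = as.integer(n_posterior_trees),
                 branch_jitter_sd = branch_jitter_sd,
                 n_continuous_traits = as.integer(n_continuous_traits),
                 n_categorical_traits = as.integer(n_categorical_traits),
                 n_categories = as.integer(n_categories),
                 signal_mix = signal_mix,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a calibrated ultrametric phylogeny
#'
#' Draws a birth--death tree conditioned on the number of extant tips
#' (via [ape::rphylo()]; birth rate 1, death rate
#' `extinction_fraction`). Tips are relabelled `sp001, sp002, ...` so
#' that species identifiers sort lexicographically.
#'
#' @param config a [simulation_config()].
#' @return An ultrametric `phylo` tree with `n_species` tips.
#' @export
simulate_tree <- function(config) {
  stop_if_not(inherits(config, "simulation_config"),
              "config must be a simulation_config")
  death <- if (config$tree_model == "birth_death")
    config$extinction_fraction else 0
  tree <- with_seed(config$seed,
                    ape::rphylo(config$n_species, birth = 1, death = death))
  tree$tip.label <- sprintf("sp%03d", seq_len(config$n_species))
  stopifnot(ape::is.ultrametric(tree, tol = 1e-8 * max(node_depths(tree))))
  tree
}

#' Jitter branch lengths into a pseudo-posterior tree set
#'
#' Emulates a posterior sample of phylogenetic hypotheses sharing one
#' topology: each branch length is multiplied by an independent
#' lognormal(0, `sd`) factor, then each terminal branch is extended so
#' that all root-to-tip distances equal the maximum post-jitter depth,
#' restoring ultrametricity while preserving the noise on internal
#' edges.
#'
#' @param tree an ultrametric `phylo` tree.
#' @param n number of trees to produce (>= 1).
#' @param sd lognormal standard deviation of the multiplicative noise;
#'   `sd = 0` returns `n` copies of the input.
#' @param seed integer seed.
#' @return A list of `n` ultrametric `phylo` trees (class `multiPhylo`).
#' @export
jitter_tree_set <- function(tree, n, sd, seed = 1L) {
  stop_if_not(is_phylo(tree), "tree must be a phylo object")
  stop_if_not(n >= 1 && sd >= 0, "need n >= 1 and sd >= 0")
  ntip <- ape::Ntip(tree)
  terminal <- match(seq_len(ntip), tree$edge[, 2])
  out <- with_seed(seed, lapply(seq_len(n), function(i) {
    tr <- tree
    tr$edge.length <- tr$edge.length *
      exp(stats::rnorm(length(tr$edge.length), 0, sd))
    depths <- node_depths(tr)[seq_len(ntip)]
    tr$edge.length[terminal] <- tr$edge.length[terminal] +
      (max(depths) - depths)
    tr
  }))
  class(out) <- "multiPhylo"
  out
}

#' Simulate traits with tunable phylogenetic signal
#'
#' Each continuous trait is `sqrt(signal_mix) * z_BM +
#' sqrt(1 - signal_mix) * z_WN`, where `z_BM` is a Brownian-motion
#' realization on the tree standardized to zero mean and unit variance
#' and `z_WN` is i.i.d. standard normal. Categorical traits bin an
#' independent latent trait of the same construction into
#' `n_categories` equal-frequency levels, so one knob (`signal_mix`)
#' controls the signal of every trait.
#'
#' @param tree a `phylo` tree with >= 4 tips.
#' @param config a [simulation_config()]; only the trait fields and the
#'   seed are used.
#' @return A `data.frame` with species ids as row names; continuous
#'   traits are numeric columns `cont1, ...`, categorical traits are
#'   factor columns `cat1, ...`.
#' @export
simulate_traits <- function(tree, config) {
  stop_if_not(is_phylo(tree) && ape::Ntip(tree) >= 4,
              "tree must be a phylo object with >= 4 tips")
  stop_if_not(inherits(config, "simulation_config"),
              "config must be a simulation_config")
  n <- ape::Ntip(tree)
  s <- config$signal_mix
  latent <- function() {
    z_bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    z_bm <- (z_bm - mean(z_bm)) / stats::sd(z_bm)
    sqrt(s) * z_bm + sqrt(1 - s) * stats::rnorm(n)
  }
  # trait stream offset from the tree stream; modulo keeps it in int range
  with_seed(as.integer((as.numeric(config$seed) + 1) %% 2147483647), {
    out <- list()
    for (j in seq_len(config$n_continuous_traits))
      out[[paste0("cont", j)]] <- latent()
    for (j in seq_len(config$n_categorical_traits)) {
      z <- latent()
      br <- stats::quantile(z, probs = seq(0, 1,
                                           length.out = config$n_categories + 1))
      out[[paste0("cat", j)]] <-
        cut(z, breaks = br, include.lowest = TRUE,
            labels = paste0("c", seq_len(config$n_categories)))
    }
    df <- as.data.frame(out, row.names = tree$tip.label)
    df
  })
}

#' Assemble species pools
#'
#' Builds named species pools (subsets of the species list) emulating
#' assemblages or clades. With `overlap = 0` pools are drawn without
#' replacement across pools, so they are disjoint; with `overlap > 0`
#' that fraction of each pool (after the first) is drawn from species
#' already used by earlier pools.
#'
#' @param species character vector of species ids.
#' @param pool_sizes integer vector, one pool per entry; every size must
#'   be <= `length(species)`.
#' @param overlap fraction in `[0, 1]` of each pool drawn from
#'   previously used species.
#' @param seed integer seed.
#' @return A long-format `data.frame` with columns `pool_id` and
#'   `species`.
#' @export
make_pools <- function(species, pool_sizes, overlap = 0, seed = 1L) {
  stop_if_not(all(pool_sizes >= 1) && all(pool_sizes <= length(species)),
              "every pool size must lie in [1, number of species]")
  stop_if_not(overlap >= 0 && overlap <= 1, "overlap must lie in [0, 1]")
  with_seed(seed, {
    unused <- species
    used <- character(0)
    rows <- list()
    for (i in seq_along(pool_sizes)) {
      size <- pool_sizes[i]
      n_shared <- if (i == 1) 0 else min(round(overlap * size), length(used))
      n_new <- size - n_shared
      if (n_new > length(unused))
        stop("pool ", i, " of size ", size,
             " cannot be filled without replacement; ",
             "increase overlap or reduce pool sizes", call. = FALSE)
      shared <- if (n_shared > 0) sample(used, n_shared) else character(0)
      fresh <- if (n_new > 0) sample(unused, n_new) else character(0)
      members <- sort(c(shared, fresh))
      unused <- setdiff(unused, fresh)
      used <- union(used, members)
      rows[[i]] <- data.frame(pool_id = sprintf("pool%02d", i),
                              species = members,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
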