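# Faith's phylogenetic diversity, the greedy PD-maximizing selector
# (exact for rooted PD), and tree-shape covariates: the gamma statistic
# of node-depth distribution and Aldous' beta imbalance parameter.

# edge index whose child is each node (NA for the root)
parent_edge <- function(tree) {
  match(seq_len(ape::Ntip(tree) + tree$Nnode), tree$edge[, 2])
}

#' Faith's phylogenetic diversity of a species set
#'
#' Sum of the branch lengths of the minimal subtree connecting the given
#' species *and the root* (rooted PD): a singleton's PD is its
#' root-to-tip path length, and the full tip set recovers the total tree
#' length.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param subset non-empty character vector of tip labels.
#' @return PD in the branch-length units of the tree.
#' @export
faith_pd <- function(tree, subset) {
  stop_if_not(is_phylo(tree), "tree must be a phylo object")
  stop_if_not(length(subset) >= 1, "subset must be non-empty")
  tips <- match(subset, tree$tip.label)
  if (anyNA(tips))
    stop("unknown species: ",
         paste(subset[is.na(tips)], collapse = ", "), call. = FALSE)
  pe <- parent_edge(tree)
  marked <- logical(nrow(tree$edge))
  total <- 0
  for (v in tips) {
    while (!is.na(pe[v])) {
      e <- pe[v]
      if (marked[e]) break
      marked[e] <- TRUE
      total <- total + tree$edge.length[e]
      v <- tree$edge[e, 1]
    }
  }
  total
}

#' Greedy selection of species maximizing phylogenetic diversity
#'
#' Iteratively adds the pool species whose inclusion yields the largest
#' PD increment. For rooted PD this greedy strategy is exact: the
#' returned PD equals the maximum over all size-`k` subsets of the pool.
#' Increment ties (within a relative tolerance of 1e-9 of the total tree
#' length) are broken uniformly at random, and `n_sets` independent
#' tie-break streams give up to `n_sets` distinct co-optimal sets; when
#' fewer distinct optima exist duplicates are returned so that
#' downstream averages stay uniformly weighted.
#'
#' @param tree a `phylo` tree.
#' @param pool character vector of candidate tip labels.
#' @param k number of species to select, `1 <= k <= length(pool)`.
#' @param n_sets number of (possibly duplicated) co-optimal sets.
#' @param seed integer seed for tie sampling.
#' @return An object of class `"pd_selection"`: list with
#'   `species_sets` (each in selection order, so prefixes are the greedy
#'   solutions for smaller `k`), `pd_value`, `k`.
#' @export
greedy_max_pd <- function(tree, pool, k, n_sets = 1, seed = 1L) {
  stop_if_not(is_phylo(tree), "tree must be a phylo object")
  tips <- match(pool, tree$tip.label)
  if (anyNA(tips))
    stop("unknown species: ",
         paste(pool[is.na(tips)], collapse = ", "), call. = FALSE)
  stop_if_not(k >= 1 && k <= length(pool),
              "k must lie in [1, pool size]")
  stop_if_not(n_sets >= 1, "n_sets must be >= 1")
  pe <- parent_edge(tree)
  len <- tree$edge.length
  par <- tree$edge[, 1]
  tol <- 1e-9 * sum(len)

  one_run <- function() {
    marked <- logical(nrow(tree$edge))
    chosen <- integer(0)
    pd <- 0
    cand <- tips
    for (step in seq_len(k)) {
      gains <- vapply(cand, function(v) {
        g <- 0
        while (!is.na(pe[v])) {
          e <- pe[v]
          if (marked[e]) break
          g <- g + len[e]
          v <- par[e]
        }
        g
      }, numeric(1))
      best <- max(gains)
      ties <- which(gains >= best - tol)
      pick <- if (length(ties) > 1) sample(ties, 1) else ties
      v <- cand[pick]
      chosen <- c(chosen, v)
      pd <- pd + gains[pick]
      while (!is.na(pe[v]) && !marked[pe[v]]) {
        marked[pe[v]] <- TRUE
        v <- par[pe[v]]
      }
      cand <- cand[-pick]
    }
    list(set = tree$tip.label[chosen], pd = pd)
  }

  runs <- with_seed(seed, lapply(seq_len(n_sets), function(i) one_run()))
  pds <- vapply(runs, `[[`, numeric(1), "pd")
  stopifnot(max(pds) - min(pds) <= tol * 10)
  structure(list(species_sets = lapply(runs, `[[`, "set"),
                 pd_value = max(pds), k = as.integer(k)),
            class = "pd_selection")
}

#' Gamma statistic of internode intervals
#'
#' Pybus & Harvey's standardized measure of the temporal distribution of
#' internal nodes in an ultrametric tree ("tipiness"); approximately
#' standard normal under a constant-rate pure-birth process.
#'
#' @param tree an ultrametric `phylo` tree with >= 3 tips.
#' @return The gamma statistic.
#' @export
gamma_stat <- function(tree) {
  stop_if_not(is_phylo(tree) && ape::Ntip(tree) >= 3,
              "tree must be a phylo object with >= 3 tips")
  if (!ape::is.ultrametric(tree, tol = 1e-6 * max(node_depths(tree))))
    stop("tree is not ultrametric within tolerance", call. = FALSE)
  ape::gammaStat(tree)
}

# log-likelihood of the observed binary splits under Aldous'
# beta-splitting model; split size normalizers are cached per clade size
beta_split_loglik <- function(splits, beta) {
  ll <- 0
  for (n in unique(splits$n)) {
    i_all <- seq_len(n - 1)
    lp <- lgamma(beta + i_all + 1) + lgamma(beta + n - i_all + 1) -
      lgamma(i_all + 1) - lgamma(n - i_all + 1)
    m <- max(lp)
    lognorm <- m + log(sum(exp(lp - m)))
    idx <- splits$i[splits$n == n]
    ll <- ll + sum(lp[idx] - lognorm)
  }
  ll
}

# (n, i) split sizes of every binary internal node
tree_splits <- function(tree) {
  ntip <- ape::Ntip(tree)
  sizes <- integer(ntip + tree$Nnode)
  sizes[seq_len(ntip)] <- 1L
  # postorder so children are processed before parents
  for (e in ape::postorder(tree)) {
    sizes[tree$edge[e, 1]] <- sizes[tree$edge[e, 1]] + sizes[tree$edge[e, 2]]
  }
  nodes <- ntip + seq_len(tree$Nnode)
  n <- integer(0); i <- integer(0)
  for (v in nodes) {
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    if (length(kids) != 2)
      stop("beta imbalance requires a fully bifurcating tree", call. = FALSE)
    n <- c(n, sizes[v])
    i <- c(i, sizes[kids[1]])
  }
  list(n = n, i = i)
}

#' Aldous' beta imbalance parameter (maximum likelihood)
#'
#' Fits the beta-splitting model of tree topology by maximizing the
#' split log-likelihood over `beta` in `[-1.999, 10]` with bounded
#' scalar optimization (golden-section/parabolic via
#' [stats::optimize()]), falling back to a grid search if the optimizer
#' fails. Beta is 0 under the Yule model, positive for balanced trees,
#' and approaches -2 for fully pectinate (caterpillar) trees.
#'
#' @param tree a fully bifurcating `phylo` tree with >= 4 tips.
#' @return A list with `beta` (the ML estimate) and `loglik`.
#' @export
beta_imbalance <- function(tree) {
  stop_if_not(is_phylo(tree) && ape::Ntip(tree) >= 4,
              "tree must be a phylo object with >= 4 tips")
  splits <- tree_splits(tree)
  f <- function(b) beta_split_loglik(splits, b)
  opt <- tryCatch(stats::optimize(f, c(-1.999, 10), maximum = TRUE,
                                  tol = 1e-9),
                  error = function(e) NULL)
  grid <- seq(-1.99, 10, by = 0.05)
  gl <- vapply(grid, f, numeric(1))
  gbest <- which.max(gl)
  if (is.null(opt) || !is.finite(opt$objective) ||
      gl[gbest] > opt$objective + 1e-9) {
    refine <- tryCatch(
      stats::optimize(f, c(grid[max(1, gbest - 1)],
                           grid[min(length(grid), gbest + 1)]),
                      maximum = TRUE, tol = 1e-9),
      error = function(e) list(maximum = grid[gbest],
                               objective = gl[gbest]))
    opt <- refine
  }
  if (!is.finite(opt$objective))
    stop("beta optimization failed: non-finite likelihood", call. = FALSE)
  list(beta = opt$maximum, loglik = opt$objective)
}
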