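# Accumulation curves of functional richness under the three
# prioritization strategies (random, maxPD, maxFD), the area-ratio
# surrogacy index S_PD-FD, and the reliability fraction (how often a
# random set beats the PD-maximized set).

#' Construct an FD accumulation curve
#'
#' Container for an FD-by-richness-fraction curve under one selection
#' strategy. [random_curve()], [maxpd_curve()] and [maxfd_curve()] build
#' these from data; this constructor lets curves be assembled directly
#' from known values (e.g. for calibration of the surrogacy index).
#'
#' @param pool_id label of the species pool.
#' @param strategy `"random"`, `"maxPD"` or `"maxFD"`.
#' @param deciles strictly increasing richness fractions in `(0, 1]`.
#' @param fd_values mean FD at each decile (non-negative, same length
#'   as `deciles`).
#' @param n_replicates how many selections each mean averages over.
#' @param fd_samples optional list (one numeric vector per decile) of
#'   per-replicate FD values, needed by [reliability_fraction()].
#' @return An object of class `"accumulation_curve"`.
#' @export
accumulation_curve <- function(pool_id, strategy, deciles, fd_values,
                               n_replicates = 1L, fd_samples = NULL) {
  stop_if_not(strategy %in% c("random", "maxPD", "maxFD"),
              "strategy must be one of random, maxPD, maxFD")
  stop_if_not(length(deciles) == length(fd_values) &&
                all(diff(deciles) > 0) && all(deciles > 0) &&
                all(deciles <= 1),
              "deciles must be increasing fractions matching fd_values")
  stop_if_not(all(fd_values >= 0), "fd_values must be non-negative")
  if (!is.null(fd_samples))
    stop_if_not(length(fd_samples) == length(deciles),
                "fd_samples must have one entry per decile")
  new_curve(pool_id, strategy, deciles, fd_values, n_replicates,
            fd_samples)
}

new_curve <- function(pool_id, strategy, deciles, fd_values,
                      n_replicates, fd_samples) {
  structure(list(pool_id = pool_id, strategy = strategy,
                 deciles = deciles, fd_values = fd_values,
                 n_replicates = as.integer(n_replicates),
                 fd_samples = fd_samples),
            class = "accumulation_curve")
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat(sprintf("FD accumulation curve [%s, %s]: %d deciles, %d replicates\n",
              x$pool_id, x$strategy, length(x$deciles), x$n_replicates))
  print(stats::setNames(round(x$fd_values, 4), x$deciles))
  invisible(x)
}

# number of species selected at a richness fraction: round, but never
# fewer than 2 (hulls and the pair-seeded selector need >= 2 species)
decile_k <- function(fraction, n) {
  pmax(2L, pmin(n, as.integer(round(fraction * n))))
}

check_pool_size <- function(pool, min_pool_size) {
  if (length(pool) < min_pool_size)
    stop(structure(class = c("pool_too_small", "error", "condition"),
                   list(message = sprintf(
                     "pool of %d species is below the minimum of %d",
                     length(pool), min_pool_size), call = NULL)))
}

#' FD accumulation curve under random selection
#'
#' For each richness decile, draws `n_rep` uniform subsets of the pool
#' and records their mean functional richness (the rarefaction curve of
#' FRic). At decile 1.0 the subset is the whole pool, so the mean equals
#' the pool FRic with zero variance.
#'
#' @param space a `"trait_space"` object.
#' @param pool character vector of species ids present in `space`.
#' @param deciles increasing richness fractions in `(0, 1]`; default the
#'   ten standard deciles.
#' @param n_rep random subsets per decile (default 1000).
#' @param seed integer seed.
#' @param min_pool_size pools smaller than this raise a classed
#'   condition (`"pool_too_small"`) so pipelines can skip them.
#' @param pool_id label carried into the curve.
#' @return An `"accumulation_curve"` with per-replicate samples retained
#'   in `fd_samples` (one numeric vector per decile).
#' @export
random_curve <- function(space, pool, deciles = seq(0.1, 1, by = 0.1),
                         n_rep = 1000, seed = 1L, min_pool_size = 10,
                         pool_id = "pool") {
  check_pool_size(pool, min_pool_size)
  x <- coords_for(space, pool)
  n <- nrow(x)
  ks <- decile_k(deciles, n)
  full <- hull_volume_cpp(x)
  samples <- with_seed(seed, lapply(ks, function(k) {
    if (k == n) return(rep(full, n_rep))
    vapply(seq_len(n_rep), function(r)
      hull_volume_cpp(x[sample.int(n, k), , drop = FALSE]), numeric(1))
  }))
  new_curve(pool_id, "random", deciles,
            vapply(samples, mean, numeric(1)), n_rep, samples)
}

#' FD accumulation curve under greedy PD maximization
#'
#' For each tree and each of `sets_per_tree` tie-break streams, runs the
#' greedy maxPD selector once to the largest decile and takes nested
#' prefixes for the smaller deciles; the curve value at each decile is
#' the mean FRic over all trees x sets. Using several trees propagates
#' phylogenetic uncertainty into the surrogacy estimate.
#'
#' @param trees a list of `phylo` trees (or a single tree) whose tips
#'   include every pool species.
#' @param space a `"trait_space"` object.
#' @param pool,deciles,seed,min_pool_size,pool_id as in [random_curve()].
#' @param sets_per_tree co-optimal maxPD sets sampled per tree
#'   (default 10).
#' @return An `"accumulation_curve"` with trees x sets replicates per
#'   decile.
#' @export
maxpd_curve <- function(trees, space, pool,
                        deciles = seq(0.1, 1, by = 0.1),
                        sets_per_tree = 10, seed = 1L,
                        min_pool_size = 10, pool_id = "pool") {
  if (is_phylo(trees)) trees <- list(trees)
  check_pool_size(pool, min_pool_size)
  for (ti in seq_along(trees)) {
    miss <- setdiff(pool, trees[[ti]]$tip.label)
    if (length(miss) > 0)
      stop("species missing from tree ", ti, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  x <- coords_for(space, pool)
  n <- nrow(x)
  ks <- decile_k(deciles, n)
  kmax <- max(ks)
  samples <- lapply(seq_along(ks), function(i) numeric(0))
  for (ti in seq_along(trees)) {
    sel <- greedy_max_pd(trees[[ti]], pool, kmax, n_sets = sets_per_tree,
                         seed = derive_seed(seed, pool_id, "maxpd", ti))
    for (set in sel$species_sets) {
      idx <- match(set, pool)
      for (i in seq_along(ks)) {
        samples[[i]] <- c(samples[[i]],
                          hull_volume_cpp(x[idx[seq_len(ks[i])], ,
                                            drop = FALSE]))
      }
    }
  }
  new_curve(pool_id, "maxPD", deciles,
            vapply(samples, mean, numeric(1)),
            length(trees) * sets_per_tree, samples)
}

#' FD accumulation curve under direct (greedy) FD maximization
#'
#' The optimal-strategy benchmark: at each decile the penalized greedy
#' selector is run with [tune_and_select()] and the best set's FRic is
#' recorded. There is a single maxFD set per decile, so the curve has
#' one replicate.
#'
#' @param space a `"trait_space"` object.
#' @param pool,deciles,seed,min_pool_size,pool_id as in [random_curve()].
#' @param n_draws penalty-parameter pairs tested per decile
#'   (default 1000).
#' @return An `"accumulation_curve"` with `n_replicates = 1`.
#' @export
maxfd_curve <- function(space, pool, deciles = seq(0.1, 1, by = 0.1),
                        n_draws = 1000, seed = 1L, min_pool_size = 10,
                        pool_id = "pool") {
  check_pool_size(pool, min_pool_size)
  x <- coords_for(space, pool)
  n <- nrow(x)
  ks <- decile_k(deciles, n)
  vals <- vapply(seq_along(ks), function(i) {
    if (ks[i] == n) return(hull_volume_cpp(x))
    tune_and_select(space, pool, ks[i], n_draws = n_draws,
                    seed = derive_seed(seed, pool_id, "maxfd", i))$fd_value
  }, numeric(1))
  new_curve(pool_id, "maxFD", deciles, vals, 1L, as.list(vals))
}

check_curves_match <- function(...) {
  curves <- list(...)
  d <- curves[[1]]$deciles
  for (cv in curves[-1]) {
    if (length(cv$deciles) != length(d) ||
        any(abs(cv$deciles - d) > 1e-12))
      stop("curves were computed on different decile grids", call. = FALSE)
  }
  d
}

#' Surrogacy index of PD for FD
#'
#' `S = 100 * A / (A + B)` where `A` is the area between the maxPD and
#' random accumulation curves and `A + B` the area between the maxFD and
#' random curves, both by trapezoidal quadrature over the decile grid.
#' S is 100% when PD-maximized sets capture FD as well as direct FD
#' maximization, 0% when they do no better than random sets, and
#' negative when they do worse than random. Deciles where the maxFD
#' curve is 0 (degenerate hulls at small k) are excluded. When the
#' denominator area is below `1e-12 x` pool FRic (random selection
#' already saturates FD) the index is undefined and `NA` is returned
#' with attribute `undefined = TRUE`.
#'
#' The alternative `form = "pointwise"` averages the per-decile ratio
#' `(FD_maxPD - FD_random) / (FD_maxFD - FD_random)` instead (the final
#' decile, where all strategies coincide, is excluded there).
#'
#' @param random,maxpd,maxfd `"accumulation_curve"` objects on the same
#'   decile grid.
#' @param form `"area_ratio"` (default) or `"pointwise"`.
#' @return S in percent.
#' @export
surrogacy_index <- function(random, maxpd, maxfd,
                            form = c("area_ratio", "pointwise")) {
  form <- match.arg(form)
  d <- check_curves_match(random, maxpd, maxfd)
  keep <- maxfd$fd_values > 0
  r <- random$fd_values[keep]
  p <- maxpd$fd_values[keep]
  f <- maxfd$fd_values[keep]
  dk <- d[keep]
  pool_fric <- max(maxfd$fd_values)
  if (form == "area_ratio") {
    a <- trapz(dk, p - r)
    ab <- trapz(dk, f - r)
    if (ab <= 1e-12 * pool_fric)
      return(structure(NA_real_, undefined = TRUE))
    100 * a / ab
  } else {
    inner <- keep & d < max(d) - 1e-12
    denom <- maxfd$fd_values[inner] - random$fd_values[inner]
    ok <- denom > 1e-12 * pool_fric
    if (!any(ok)) return(structure(NA_real_, undefined = TRUE))
    100 * mean((maxpd$fd_values[inner][ok] -
                  random$fd_values[inner][ok]) / denom[ok])
  }
}

# pairs (r, m) with r > m counted by sorting m and binary search;
# findInterval(..., left.open = TRUE) returns, for each r, the number
# of m strictly below it
count_exceed <- function(r, m) {
  sum(findInterval(r, sort(m), left.open = TRUE))
}

#' Reliability fraction: how often random beats maxPD
#'
#' For each decile, every retained random-set FD sample is compared with
#' every maxPD-set FD sample, and the fraction of strictly greater
#' random values is recorded (sort-and-count, equal to the naive
#' all-pairs double loop). The result is the mean over deciles; the
#' final decile, where both strategies select the whole pool and tie
#' structurally, is excluded by default.
#'
#' @param random,maxpd `"accumulation_curve"` objects with per-replicate
#'   `fd_samples` on the same decile grid.
#' @param include_last include the 100% decile in the average
#'   (default `FALSE`).
#' @return Fraction in `[0, 1]` of comparisons where the random set held
#'   more FD than the PD-maximized set.
#' @export
reliability_fraction <- function(random, maxpd, include_last = FALSE) {
  d <- check_curves_match(random, maxpd)
  if (is.null(random$fd_samples) || is.null(maxpd$fd_samples))
    stop("curves must retain per-replicate fd_samples", call. = FALSE)
  use <- if (include_last) seq_along(d) else which(d < max(d) - 1e-12)
  fracs <- vapply(use, function(i) {
    r <- random$fd_samples[[i]]
    m <- maxpd$fd_samples[[i]]
    count_exceed(r, m) / (length(r) * length(m))
  }, numeric(1))
  mean(fracs)
}
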