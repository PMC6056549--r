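# Functional richness (FRic, convex hull volume in the retained trait
# space) and the penalized greedy FD-maximizing selector: candidates are
# scored by their distance to the centroid of the already-selected set
# plus an exponential penalty K * exp(L * minD) in their distance to the
# nearest selected neighbour, so that isolated species are favoured over
# species that are far from the centroid but redundant with a selected
# one.

#' Penalty parameters for the greedy FD selector
#'
#' @param K,L strictly positive reals; the candidate penalty is
#'   `K * exp(L * minD)` where `minD` is the candidate's distance to the
#'   nearest already-selected species.
#' @return A validated list of class `"penalty_params"`.
#' @export
penalty_params <- function(K = 1, L = 1) {
  stop_if_not(is.numeric(K) && length(K) == 1 && is.finite(K) && K > 0,
              "K must be a single finite positive number")
  stop_if_not(is.numeric(L) && length(L) == 1 && is.finite(L) && L > 0,
              "L must be a single finite positive number")
  structure(list(K = K, L = L), class = "penalty_params")
}

coords_for <- function(space, subset) {
  idx <- match(subset, space$species_ids)
  if (anyNA(idx))
    stop("unknown species: ",
         paste(subset[is.na(idx)], collapse = ", "), call. = FALSE)
  space$coordinates[idx, , drop = FALSE]
}

#' Functional richness (convex hull volume) of a species set
#'
#' Volume of the convex hull of the subset's coordinates in the retained
#' trait space. In one dimension this is the range of values. Subsets
#' with at most `d` points, or whose points are affinely dependent
#' (rank < `d`), span zero `d`-volume and return 0.
#'
#' @param space a `"trait_space"` object from [pcoa_embed()] (or any
#'   list with `species_ids` and a `coordinates` matrix).
#' @param subset non-empty character vector of species ids.
#' @return Hull volume in (retained-axis units)^d.
#' @export
fric <- function(space, subset) {
  stop_if_not(length(subset) >= 1, "subset must be non-empty")
  hull_volume_cpp(coords_for(space, subset))
}

#' Penalized candidate score of the greedy FD selector
#'
#' `score = ||x_candidate - centroid(selected)|| + K * exp(L * minD)`,
#' where the centroid is the unweighted mean of the selected
#' coordinates and `minD` is the distance from the candidate to its
#' nearest selected neighbour.
#'
#' @param candidate a species id not yet selected.
#' @param selected non-empty character vector of selected species ids.
#' @param space a `"trait_space"` object.
#' @param params a [penalty_params()] pair.
#' @return The penalized score (a single number).
#' @export
penalized_score <- function(candidate, selected, space, params) {
  stop_if_not(inherits(params, "penalty_params"),
              "params must be penalty_params")
  stop_if_not(length(selected) >= 1, "selected set must be non-empty")
  if (candidate %in% selected)
    stop("candidate '", candidate, "' is already selected", call. = FALSE)
  x <- drop(coords_for(space, candidate))
  sel <- coords_for(space, selected)
  centroid <- colMeans(sel)
  min_d <- min(sqrt(rowSums((sel - rep(x, each = nrow(sel)))^2)))
  sqrt(sum((x - centroid)^2)) + params$K * exp(params$L * min_d)
}

#' Greedy selection of species maximizing functional richness
#'
#' Seeds the selection with the pool's farthest pair in trait space
#' (ties broken by lexicographic species id), then repeatedly adds the
#' candidate with the highest penalized score (distance to the centroid
#' of the selected set plus `K * exp(L * minD)`), recomputing the
#' centroid after every addition, until `k` species are selected.
#'
#' @param space a `"trait_space"` object.
#' @param pool character vector of candidate species ids.
#' @param k number of species to select, `2 <= k <= length(pool)`.
#' @param params a [penalty_params()] pair.
#' @return An object of class `"fd_selection"`: list with `species_set`
#'   (in selection order), `fd_value` (FRic of the final set), `params`
#'   and `k`.
#' @export
greedy_max_fd <- function(space, pool, k, params = penalty_params()) {
  stop_if_not(inherits(params, "penalty_params"),
              "params must be penalty_params")
  stop_if_not(k >= 2, "k must be >= 2 (the selector is pair-seeded)")
  stop_if_not(k <= length(pool), "k must be <= pool size")
  pool <- sort(pool) # lexicographic candidate order fixes tie-breaks
  x <- coords_for(space, pool)
  n <- nrow(x)

  dmat <- as.matrix(stats::dist(x))
  far <- which(dmat == max(dmat), arr.ind = TRUE)
  far <- far[far[, 1] < far[, 2], , drop = FALSE]
  seed_pair <- far[order(far[, 1], far[, 2])[1], ] # lexicographic tie-break
  sel <- as.integer(seed_pair)

  remaining <- setdiff(seq_len(n), sel)
  min_d <- pmin(dmat[remaining, sel[1]], dmat[remaining, sel[2]])
  while (length(sel) < k) {
    centroid <- colMeans(x[sel, , drop = FALSE])
    cen_d <- sqrt(rowSums((x[remaining, , drop = FALSE] -
                             rep(centroid, each = length(remaining)))^2))
    score <- cen_d + params$K * exp(params$L * min_d)
    pick <- which.max(score) # first index wins ties -> lexicographic
    sel <- c(sel, remaining[pick])
    new <- remaining[pick]
    remaining <- remaining[-pick]
    min_d <- pmin(min_d[-pick], dmat[remaining, new])
  }
  structure(list(species_set = pool[sel],
                 fd_value = hull_volume_cpp(x[sel, , drop = FALSE]),
                 params = params, k = as.integer(k)),
            class = "fd_selection")
}

# normal(1, 0.5) truncated to (0, Inf), by inverse-CDF sampling
rtrunc_pos_normal <- function(n, mean = 1, sd = 0.5) {
  plo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, plo, 1), mean, sd)
}

#' Tune the penalty parameters and return the best FD selection
#'
#' Draws `n_draws` `(K, L)` pairs from a normal(1, 0.5) truncated to the
#' positive half-line, runs [greedy_max_fd()] with each pair, and
#' returns the selection with the highest functional richness (ties keep
#' the earliest draw). This parameter search replaces an arbitrary
#' choice of penalty strength.
#'
#' @param space a `"trait_space"` object.
#' @param pool character vector of candidate species ids.
#' @param k number of species to select (>= 2).
#' @param n_draws number of parameter pairs to test (default 1000).
#' @param seed integer seed for the parameter draws.
#' @return The best `"fd_selection"`, with the vector of per-draw FD
#'   values in attribute `"fd_values"` and the draws in attribute
#'   `"draws"`.
#' @export
tune_and_select <- function(space, pool, k, n_draws = 1000, seed = 1L) {
  stop_if_not(n_draws >= 1, "n_draws must be >= 1")
  draws <- with_seed(seed, list(K = rtrunc_pos_normal(n_draws),
                                L = rtrunc_pos_normal(n_draws)))
  best <- NULL
  fd_values <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    cand <- greedy_max_fd(space, pool, k,
                          penalty_params(draws$K[i], draws$L[i]))
    fd_values[i] <- cand$fd_value
    if (is.null(best) || cand$fd_value > best$fd_value) best <- cand
  }
  attr(best, "fd_values") <- fd_values
  attr(best, "draws") <- draws
  best
}
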