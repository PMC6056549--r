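# Functional trait space: mixed-trait Gower distance, principal
# coordinates ordination with an explained-variance retention rule, and
# Blomberg's K phylogenetic signal per retained axis.

#' Preprocess trait columns (log transform and range rescaling)
#'
#' Applies the standard body-mass style preprocessing: named columns are
#' natural-log transformed and/or rescaled to `[0, 1]` by the range
#' observed in the pool. Log transformation, when requested together
#' with rescaling, happens first.
#'
#' @param table a trait `data.frame` (species ids as row names).
#' @param log_columns,rescale_columns character vectors of column names;
#'   they must name numeric columns, and log columns must be strictly
#'   positive.
#' @return The transformed `data.frame`. Columns rescaled despite having
#'   zero range are set to constant 0 and recorded in the
#'   `"zero_range_columns"` attribute (with a warning).
#' @export
preprocess_traits <- function(table, log_columns = character(),
                              rescale_columns = character()) {
  stop_if_not(is.data.frame(table), "table must be a data.frame")
  for (col in unique(c(log_columns, rescale_columns))) {
    stop_if_not(col %in% names(table), "column not found: ", col)
    stop_if_not(is.numeric(table[[col]]),
                "column is not numeric: ", col)
  }
  for (col in log_columns) {
    x <- table[[col]]
    if (any(x <= 0, na.rm = TRUE))
      stop("log transform requested for column '", col,
           "' which has non-positive values", call. = FALSE)
    table[[col]] <- log(x)
  }
  zero_range <- character(0)
  for (col in rescale_columns) {
    x <- table[[col]]
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) == 0) {
      warning("column '", col, "' has zero range; set to constant 0",
              call. = FALSE)
      table[[col]] <- ifelse(is.na(x), NA_real_, 0)
      zero_range <- c(zero_range, col)
    } else {
      table[[col]] <- (x - rng[1]) / diff(rng)
    }
  }
  attr(table, "zero_range_columns") <- zero_range
  table
}

#' Gower distance between species with mixed trait types
#'
#' Computes the Gower dissimilarity (in `[0, 1]`) between all species
#' pairs via [cluster::daisy()]: numeric traits contribute absolute
#' differences scaled by the pool range, unordered factors contribute a
#' 0/1 mismatch, and ordered factors are rank-scaled and treated as
#' numeric. Missing values are handled by Gower's pairwise-deletion
#' weighting; a pair of species sharing no non-missing trait is an
#' error.
#'
#' @param table a trait `data.frame` with species ids as row names, at
#'   least 4 species, and columns typed as numeric, `factor` or
#'   `ordered`.
#' @return A symmetric numeric matrix with zero diagonal, species ids as
#'   dimnames, and entries in `[0, 1]`.
#' @export
gower_distance <- function(table) {
  stop_if_not(is.data.frame(table) && nrow(table) >= 4,
              "table must be a data.frame with >= 4 species")
  stop_if_not(ncol(table) >= 1, "table must have at least one trait")
  all_missing <- apply(table, 1, function(r) all(is.na(r)))
  if (any(all_missing))
    stop("species with all traits missing: ",
         paste(rownames(table)[all_missing], collapse = ", "),
         call. = FALSE)
  d <- as.matrix(cluster::daisy(table, metric = "gower",
                                warnBin = FALSE, warnAsym = FALSE,
                                warnConst = FALSE))
  if (anyNA(d)) {
    bad <- which(is.na(d), arr.ind = TRUE)[1, ]
    stop("species pair shares no non-missing trait: ",
         rownames(d)[bad[1]], " / ", colnames(d)[bad[2]], call. = FALSE)
  }
  dimnames(d) <- list(rownames(table), rownames(table))
  d
}

#' Principal coordinates embedding of a distance matrix
#'
#' Classical PCoA: the squared distances are double-centered and
#' eigendecomposed; axes are ordered by decreasing eigenvalue and scaled
#' by the square root of their eigenvalue. Negative eigenvalues (which
#' Gower distances on mixed traits can produce) are discarded and
#' variance fractions are computed over positive eigenvalues only; the
#' number of retained axes is the smallest for which the cumulative
#' fraction reaches `variance_threshold`. A Cailliez or Lingoes
#' correction can be requested instead of dropping negative eigenvalues.
#'
#' @param dist a symmetric distance matrix with species ids as dimnames.
#' @param variance_threshold fraction of (positive-eigenvalue) variance
#'   the retained axes must explain, in `(0, 1]`; default 0.70.
#' @param correction `"none"` (drop negative eigenvalues; default),
#'   `"cailliez"` or `"lingoes"` (delegated to [ape::pcoa()]).
#' @return An object of class `"trait_space"`: a list with
#'   `species_ids`, `coordinates` (species x retained axes),
#'   `eigenvalues` (all positive ones), `variance_explained` (cumulative
#'   fractions) and `retained_d`.
#' @export
pcoa_embed <- function(dist, variance_threshold = 0.70,
                       correction = c("none", "cailliez", "lingoes")) {
  correction <- match.arg(correction)
  stop_if_not(variance_threshold > 0 && variance_threshold <= 1,
              "variance_threshold must lie in (0, 1]")
  d <- as.matrix(dist)
  stop_if_not(nrow(d) == ncol(d) && isTRUE(all.equal(d, t(d))),
              "dist must be a symmetric matrix")
  ids <- rownames(d)
  n <- nrow(d)
  if (correction == "none") {
    j <- diag(n) - matrix(1 / n, n, n)
    b <- -0.5 * j %*% (d * d) %*% j
    e <- eigen((b + t(b)) / 2, symmetric = TRUE)
    pos <- e$values > max(e$values) * 1e-8
    if (!any(pos))
      stop("degenerate distances: no positive eigenvalue", call. = FALSE)
    ev <- e$values[pos]
    coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev), sum(pos))
  } else {
    p <- ape::pcoa(stats::as.dist(d), correction = correction)
    col <- if (!is.null(p$vectors.cor)) p$vectors.cor else p$vectors
    evcol <- if ("Corr_eig" %in% names(p$values)) p$values$Corr_eig
             else p$values$Eigenvalues
    keep <- evcol > max(evcol) * 1e-8
    ev <- evcol[keep]
    coords <- col[, seq_len(sum(keep)), drop = FALSE]
  }
  cumfrac <- cumsum(ev) / sum(ev)
  retained_d <- which(cumfrac >= variance_threshold - 1e-12)[1]
  coords <- coords[, seq_len(retained_d), drop = FALSE]
  dimnames(coords) <- list(ids, paste0("axis", seq_len(retained_d)))
  structure(list(species_ids = ids,
                 coordinates = coords,
                 eigenvalues = ev,
                 variance_explained = cumfrac,
                 retained_d = retained_d,
                 variance_threshold = variance_threshold),
            class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat("Trait space:", length(x$species_ids), "species,",
      x$retained_d, "retained axes",
      sprintf("(%.1f%% of positive-eigenvalue variance)\n",
              100 * x$variance_explained[x$retained_d]))
  invisible(x)
}

#' Blomberg's K phylogenetic signal
#'
#' Variance-ratio measure of phylogenetic signal for a continuous trait:
#' the ratio of the mean squared error of the trait around the
#' phylogenetic (GLS) mean to the mean squared error under the tree's
#' Brownian covariance, divided by its analytic Brownian expectation
#' computed from the covariance matrix. K has expectation 1 when the
#' trait evolved by Brownian motion on the tree; values well below 1
#' indicate that close relatives are no more similar than distant ones.
#'
#' @param tree a `phylo` tree with >= 4 tips.
#' @param trait named numeric vector covering every tip; must not be
#'   constant.
#' @return K (a single non-negative number).
#' @export
blomberg_k <- function(tree, trait) {
  stop_if_not(is_phylo(tree) && ape::Ntip(tree) >= 4,
              "tree must be a phylo object with >= 4 tips")
  stop_if_not(!is.null(names(trait)) &&
                setequal(names(trait), tree$tip.label) &&
                !anyNA(trait),
              "trait must be a complete named vector over the tree's tips")
  x <- trait[tree$tip.label]
  if (stats::sd(x) == 0)
    stop("trait is constant; K is undefined", call. = FALSE)
  n <- length(x)
  v <- ape::vcv(tree)
  vinv <- solve(v)
  ones <- rep(1, n)
  a_hat <- as.numeric((ones %*% vinv %*% x) / (ones %*% vinv %*% ones))
  dev <- x - a_hat
  mse0 <- sum(dev^2) / (n - 1)
  mse <- as.numeric(dev %*% vinv %*% dev) / (n - 1)
  expected <- (sum(diag(v)) -
                 n / as.numeric(ones %*% vinv %*% ones)) / (n - 1)
  (mse0 / mse) / expected
}
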