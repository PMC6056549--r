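# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (enumeration, closed forms) and share no code with the package's
# own implementations.

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# trait space directly from a coordinate matrix (bypasses Gower/PCoA)
make_space <- function(coords, ids = NULL) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  if (is.null(ids)) ids <- sprintf("sp%02d", seq_len(nrow(coords)))
  dimnames(coords) <- list(ids, paste0("axis", seq_len(ncol(coords))))
  structure(list(species_ids = ids, coordinates = coords,
                 eigenvalues = rep(1, ncol(coords)),
                 variance_explained = seq_len(ncol(coords)) / ncol(coords),
                 retained_d = ncol(coords)),
            class = "trait_space")
}

# polygon area of the 2-d convex hull by the shoelace formula
shoelace_area <- function(pts) {
  h <- grDevices::chull(pts)
  p <- pts[h, , drop = FALSE]
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# exhaustive maximum PD over all size-k subsets
brute_max_pd <- function(tree, pool, k) {
  max(apply(utils::combn(pool, k), 2, function(s) faith_pd(tree, s)))
}

# exhaustive maximum FRic over all size-k subsets
brute_max_fric <- function(space, pool, k) {
  max(apply(utils::combn(pool, k), 2, function(s) fric(space, s)))
}

# all-pairs comparison fraction (naive double loop)
naive_exceed_fraction <- function(r, m) mean(outer(r, m, ">"))

# gamma statistic evaluated directly from its definition: ordered
# internode intervals g_k during which k lineages exist
gamma_direct <- function(tree) {
  n <- ape::Ntip(tree)
  depths <- sort(ape::node.depth.edgelength(tree)[n + seq_len(tree$Nnode)])
  total <- max(ape::node.depth.edgelength(tree)[seq_len(n)])
  times <- c(depths, total)
  g <- diff(c(0, times))[-1] # g_2 ... g_n: interval with k lineages
  k <- 2:n
  bigt <- sum(k * g)
  inner <- sapply(2:(n - 1), function(i) sum((2:i) * g[seq_len(i - 1)]))
  (mean(inner) - bigt / 2) / (bigt * sqrt(1 / (12 * (n - 2))))
}

# Gower dissimilarity of two rows computed straight from the definition
gower_pair_direct <- function(table, i, j) {
  contribs <- vapply(names(table), function(col) {
    xi <- table[[col]][i]; xj <- table[[col]][j]
    if (is.na(xi) || is.na(xj)) return(NA_real_)
    if (is.ordered(table[[col]])) {
      # ordinal: level codes rescaled to [0, 1], then numeric Gower
      z <- as.integer(table[[col]])
      zr <- (z - min(z, na.rm = TRUE)) /
        max(1e-300, max(z, na.rm = TRUE) - min(z, na.rm = TRUE))
      return(abs(zr[i] - zr[j]))
    }
    if (is.factor(table[[col]])) return(as.numeric(xi != xj))
    rng <- diff(range(table[[col]], na.rm = TRUE))
    if (rng == 0) return(0)
    abs(xi - xj) / rng
  }, numeric(1))
  mean(contribs, na.rm = TRUE)
}

# small seeded random ultrametric tree
random_tree <- function(n, seed) {
  cfg <- simulation_config(n_species = n, seed = seed)
  simulate_tree(cfg)
}
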