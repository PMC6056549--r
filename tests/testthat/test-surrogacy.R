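three_curves <- function(r, p, f, deciles = NULL) {
  if (is.null(deciles)) deciles <- seq_len(length(r)) / length(r)
  list(random = accumulation_curve("pool", "random", deciles, r),
       maxpd = accumulation_curve("pool", "maxPD", deciles, p),
       maxfd = accumulation_curve("pool", "maxFD", deciles, f))
}

test_that("surrogacy index hits its analytic calibration points", {
  # maxPD identical to maxFD -> perfect surrogate, S = 100%
  cv <- three_curves(c(1, 2, 3), c(3, 3, 3), c(3, 3, 3))
  expect_equal(surrogacy_index(cv$random, cv$maxpd, cv$maxfd), 100)
  # maxPD identical to random -> no better than chance, S = 0%
  cv <- three_curves(c(1, 2, 3), c(1, 2, 3), c(3, 3, 3))
  expect_equal(surrogacy_index(cv$random, cv$maxpd, cv$maxfd), 0)
  # maxPD below random everywhere -> negative
  cv <- three_curves(c(2, 2.5, 3), c(1, 2, 3), c(3, 3, 3))
  expect_lt(surrogacy_index(cv$random, cv$maxpd, cv$maxfd), 0)
})

test_that("surrogacy index matches the hand trapezoid computation", {
  cv <- three_curves(c(1, 2, 3), c(2, 3, 3), c(3, 3, 3))
  # on an equally spaced grid: A = 1.5 dx, A+B = 2.0 dx -> 75%
  expect_equal(surrogacy_index(cv$random, cv$maxpd, cv$maxfd), 75)
  # invariant to a common affine rescaling of all curves
  cv2 <- three_curves(10 + 4 * c(1, 2, 3), 10 + 4 * c(2, 3, 3),
                      10 + 4 * c(3, 3, 3))
  expect_equal(surrogacy_index(cv2$random, cv2$maxpd, cv2$maxfd), 75)
  # mismatched grids are an error
  other <- accumulation_curve("pool", "maxFD", c(0.5, 1), c(3, 3))
  expect_error(surrogacy_index(cv$random, cv$maxpd, other),
               "decile grids")
})

test_that("degenerate maxFD deciles are excluded and saturation is flagged", {
  # first decile has a zero (degenerate hull) maxFD value: excluded
  cv <- three_curves(c(0, 2, 3), c(0, 3, 3), c(0, 3, 3),
                     deciles = c(0.2, 0.6, 1))
  expect_equal(surrogacy_index(cv$random, cv$maxpd, cv$maxfd), 100)
  # random already saturates FD: undefined surrogacy
  cv <- three_curves(c(3, 3, 3), c(3, 3, 3), c(3, 3, 3))
  s <- surrogacy_index(cv$random, cv$maxpd, cv$maxfd)
  expect_true(is.na(s))
  expect_true(attr(s, "undefined"))
})

test_that("pointwise form agrees with the per-decile ratio average", {
  cv <- three_curves(c(1, 2, 3), c(2, 3, 3), c(3, 3, 3))
  # deciles below 1.0: ratios (2-1)/(3-1) and (3-2)/(3-2) -> mean 75%
  expect_equal(surrogacy_index(cv$random, cv$maxpd, cv$maxfd,
                               form = "pointwise"), 75)
})

test_that("random curve matches exhaustive enumeration on a 4-point pool", {
  sp <- make_space(rbind(c(0, 0), c(1, 0), c(0, 1), c(2, 2)))
  ids <- sp$species_ids
  cv <- random_curve(sp, ids, deciles = c(0.5, 1), n_rep = 4000,
                     seed = 1, min_pool_size = 4)
  # decile 1.0: whole pool, exactly, with zero variance
  expect_equal(cv$fd_values[2], fric(sp, ids))
  expect_equal(var(cv$fd_samples[[2]]), 0)
  # decile 0.5 (k = 2): hulls of pairs are all degenerate in 2-d
  pair_mean <- mean(apply(combn(ids, 2), 2, function(s) fric(sp, s)))
  expect_equal(cv$fd_values[1], pair_mean, tolerance = 1e-12)
  # determinism of the whole curve
  cv2 <- random_curve(sp, ids, deciles = c(0.5, 1), n_rep = 4000,
                      seed = 1, min_pool_size = 4)
  expect_identical(cv, cv2)
})

test_that("random curve enumerates 3-subset means correctly", {
  set.seed(3)
  sp <- make_space(matrix(rnorm(12), ncol = 2))
  ids <- sp$species_ids # 6 species; k = 3 -> 20 subsets
  cv <- random_curve(sp, ids, deciles = c(0.5, 1), n_rep = 20000,
                     seed = 2, min_pool_size = 4)
  exact <- mean(apply(combn(ids, 3), 2, function(s) fric(sp, s)))
  expect_equal(cv$fd_values[1], exact, tolerance = 0.02)
})

test_that("maxPD curve is deterministic without ties and reaches pool FRic", {
  tr <- random_tree(12, seed = 61)
  cfg <- simulation_config(n_species = 12, n_continuous_traits = 2,
                           n_categorical_traits = 0, signal_mix = 1,
                           seed = 3)
  traits <- simulate_traits(tr, cfg)
  sp <- pcoa_embed(gower_distance(traits), variance_threshold = 1)
  cv <- maxpd_curve(tr, sp, tr$tip.label, deciles = c(0.5, 1),
                    sets_per_tree = 5, seed = 1, min_pool_size = 4)
  # continuous branch lengths -> no PD ties -> all sets identical
  expect_equal(var(cv$fd_samples[[1]]), 0, tolerance = 1e-20)
  expect_equal(cv$fd_values[2], fric(sp, tr$tip.label))
  expect_error(
    maxpd_curve(tr, sp, c(tr$tip.label, "ghost"), deciles = c(0.5, 1),
                min_pool_size = 4),
    "missing from tree")
})

test_that("maxFD curve dominates the random curve and hits the pool value", {
  set.seed(71)
  sp <- make_space(matrix(rnorm(2 * 14), ncol = 2))
  ids <- sp$species_ids
  dec <- seq(0.2, 1, by = 0.2)
  rc <- random_curve(sp, ids, dec, n_rep = 300, seed = 1,
                     min_pool_size = 4)
  fc <- maxfd_curve(sp, ids, dec, n_draws = 100, seed = 1,
                    min_pool_size = 4)
  expect_equal(fc$fd_values[length(dec)], fric(sp, ids))
  expect_true(all(fc$fd_values >= rc$fd_values - 1e-9))
  # and on an 8-point pool it matches the exhaustive optimum closely
  sp8 <- make_space(matrix(rnorm(16), ncol = 2))
  fc8 <- maxfd_curve(sp8, sp8$species_ids, c(0.5, 1), n_draws = 300,
                     seed = 2, min_pool_size = 4)
  expect_gte(fc8$fd_values[1],
             0.8 * brute_max_fric(sp8, sp8$species_ids, 4))
  expect_lte(fc8$fd_values[1],
             brute_max_fric(sp8, sp8$species_ids, 4) + 1e-9)
})

test_that("maxPD and maxFD curves coincide when trait space mirrors the phylogeny", {
  # perfectly symmetric tree; traits are the full PCoA embedding of the
  # patristic distances, so trait distance equals tree distance
  tr <- ape::compute.brlen(ape::stree(8, "balanced"))
  tr$tip.label <- sprintf("sp%02d", 1:8)
  pat <- ape::cophenetic.phylo(tr)
  sp <- pcoa_embed(pat[tr$tip.label, tr$tip.label], variance_threshold = 1)
  dec <- c(0.25, 0.5, 1)
  pc <- maxpd_curve(tr, sp, tr$tip.label, dec, sets_per_tree = 8,
                    seed = 1, min_pool_size = 4)
  fc <- maxfd_curve(sp, tr$tip.label, dec, n_draws = 200, seed = 1,
                    min_pool_size = 4)
  expect_equal(pc$fd_values, fc$fd_values, tolerance = 1e-9)
})

test_that("reliability fraction matches exhaustive pair counting", {
  mk <- function(samples, strategy) {
    accumulation_curve("p", strategy, deciles = c(0.5, 1),
                       fd_values = c(mean(samples), 1),
                       n_replicates = length(samples),
                       fd_samples = list(samples, rep(1, length(samples))))
  }
  r <- mk(c(1, 3), "random")
  m <- mk(c(2, 2), "maxPD")
  expect_equal(reliability_fraction(r, m), 0.5)
  same <- mk(c(2, 2), "random")
  expect_equal(reliability_fraction(same, m), 0) # strict inequality
  # sort-and-count equals the naive double loop on random instances
  set.seed(83)
  for (i in 1:100) {
    a <- round(runif(sample(5:60, 1)), sample(1:3, 1))
    b <- round(runif(sample(5:60, 1)), sample(1:3, 1))
    expect_equal(phylogambit:::count_exceed(a, b) /
                   (length(a) * length(b)),
                 naive_exceed_fraction(a, b))
  }
  # last decile (structural tie) excluded by default, includable on demand
  r2 <- mk(c(5, 6), "random")
  m2 <- mk(c(4, 4), "maxPD")
  expect_equal(reliability_fraction(r2, m2), 1)
  expect_equal(reliability_fraction(r2, m2, include_last = TRUE), 0.5)
  bare <- accumulation_curve("p", "maxPD", c(0.5, 1), c(1, 2))
  expect_error(reliability_fraction(r2, bare), "fd_samples")
})
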