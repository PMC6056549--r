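test_that("FRic equals the range in one dimension and known areas in two", {
  sp1 <- make_space(c(0.2, 0.9, 0.5))
  expect_equal(fric(sp1, sp1$species_ids), 0.7)
  square <- make_space(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  expect_equal(fric(square, square$species_ids), 1.0)
  expect_error(fric(square, "nope"), "unknown species")
})

test_that("FRic matches the shoelace oracle on random 2-d point sets", {
  set.seed(17)
  for (i in 1:25) {
    pts <- matrix(rnorm(2 * sample(5:30, 1)), ncol = 2)
    sp <- make_space(pts)
    expect_equal(fric(sp, sp$species_ids), shoelace_area(pts),
                 tolerance = 1e-9)
  }
})

test_that("FRic matches closed-form volumes in three and four dimensions", {
  # random tetrahedra: V = |det(v2-v1, v3-v1, v4-v1)| / 3!
  set.seed(19)
  for (i in 1:20) {
    pts <- matrix(rnorm(12), ncol = 3)
    sp <- make_space(pts)
    v_det <- abs(det(t(pts[-1, ]) - pts[1, ])) / 6
    expect_equal(fric(sp, sp$species_ids), v_det, tolerance = 1e-10)
  }
  # unit hypercubes, with and without interior points
  cube3 <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  sp3 <- make_space(cube3)
  expect_equal(fric(sp3, sp3$species_ids), 1)
  sp3i <- make_space(rbind(cube3, matrix(runif(15), ncol = 3)))
  expect_equal(fric(sp3i, sp3i$species_ids), 1, tolerance = 1e-10)
  cube4 <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
  sp4 <- make_space(cube4)
  expect_equal(fric(sp4, sp4$species_ids), 1, tolerance = 1e-10)
})

test_that("FRic is zero for degenerate subsets and monotone under addition", {
  sq <- make_space(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(2, 2),
                         c(0.5, 0.5)))
  ids <- sq$species_ids
  expect_equal(fric(sq, ids[1:2]), 0)            # <= d points
  expect_equal(fric(sq, c(ids[1], ids[5], ids[6])), 0) # collinear
  set.seed(23)
  sp <- make_space(matrix(rnorm(3 * 15), ncol = 3))
  for (i in 1:20) {
    s <- sample(sp$species_ids, sample(4:12, 1))
    t_set <- union(s, sample(sp$species_ids, sample(1:3, 1)))
    expect_lte(fric(sp, s), fric(sp, t_set) + 1e-12)
    expect_lte(fric(sp, s), fric(sp, sp$species_ids) + 1e-12)
  }
})

test_that("FRic scales as c^d under coordinate scaling", {
  set.seed(29)
  pts <- matrix(rnorm(24), ncol = 3)
  v <- fric(make_space(pts), make_space(pts)$species_ids)
  v3 <- fric(make_space(3 * pts), make_space(pts)$species_ids)
  expect_equal(v3, 27 * v, tolerance = 1e-9)
})

test_that("penalized score follows its closed form and is monotone in minD", {
  # candidate at the centroid with zero nearest-neighbour distance
  sp <- make_space(rbind(c(0, 0), c(2, 0), c(1, 0), c(5, 5)),
                   ids = c("a", "b", "mid", "far"))
  expect_equal(penalized_score("mid", c("a", "b"), sp, penalty_params(1, 1)),
               0 + 1 * exp(1 * 1)) # centroid (1,0); minD = 1
  # centroid distance 2, minD = ln 2 -> 2 + 2 = 4
  sp2 <- make_space(rbind(c(0, 0), c(2 - log(2), 0), c(2, 0)),
                    ids = c("o", "near", "cand"))
  expect_equal(penalized_score("cand", c("o", "near"), sp2,
                               penalty_params(1, 1)),
               sqrt(sum((c(2, 0) - c((2 - log(2)) / 2, 0))^2)) + 2)
  expect_error(penalized_score("a", c("a", "b"), sp, penalty_params()),
               "already selected")
  # strictly increasing in minD at fixed centroid distance
  scores <- vapply(seq(0.1, 3, by = 0.1), function(md)
    md * 0 + penalty_params(1, 1)$K * exp(1 * md), numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("greedy FD selection seeds with the farthest pair and handles k bounds", {
  sp <- make_space(c(0, 1, 10), ids = c("a", "b", "c"))
  sel <- greedy_max_fd(sp, c("a", "b", "c"), k = 2)
  expect_setequal(sel$species_set, c("a", "c"))
  expect_equal(sel$fd_value, 10)
  sel_all <- greedy_max_fd(sp, c("a", "b", "c"), k = 3)
  expect_setequal(sel_all$species_set, c("a", "b", "c"))
  expect_error(greedy_max_fd(sp, c("a", "b", "c"), k = 1), "pair-seeded")
  expect_error(greedy_max_fd(sp, c("a", "b"), k = 3), "pool size")
})

test_that("tuned greedy FD is adequate on average against the exhaustive maximum", {
  # the selector optimizes dispersion, not volume, so individual
  # instances (especially k near d+1) can fall short of the optimum;
  # adequacy is a statement about the ensemble
  set.seed(37)
  ratios <- c()
  for (i in 1:10) {
    d <- sample(2:3, 1)
    n <- sample(8:10, 1)
    sp <- make_space(matrix(rnorm(n * d), ncol = d))
    for (k in c(4, 6)) {
      best <- tune_and_select(sp, sp$species_ids, k, n_draws = 1000,
                              seed = i)
      bf <- brute_max_fric(sp, sp$species_ids, k)
      expect_lte(best$fd_value, bf + 1e-9) # brute force is an upper bound
      if (bf > 0) ratios <- c(ratios, best$fd_value / bf)
    }
  }
  expect_gte(mean(ratios), 0.8)
})

test_that("parameter tuning is seeded, positive and returns the max over draws", {
  set.seed(43)
  sp <- make_space(matrix(rnorm(30), ncol = 2))
  b1 <- tune_and_select(sp, sp$species_ids, 6, n_draws = 50, seed = 9)
  b2 <- tune_and_select(sp, sp$species_ids, 6, n_draws = 50, seed = 9)
  expect_identical(b1$species_set, b2$species_set)
  expect_equal(b1$fd_value, b2$fd_value)
  draws <- attr(b1, "draws")
  expect_true(all(draws$K > 0) && all(draws$L > 0))
  expect_equal(b1$fd_value, max(attr(b1, "fd_values")))
  expect_gte(b1$fd_value,
             min(attr(b1, "fd_values"))) # dominates any single run
})
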