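test_that("grey-matter mask keeps high-signal voxels and drops dropout", {
  dims <- c(4, 4, 2)
  nt <- 10
  flat <- matrix(100, prod(dims), nt)
  s <- bold_session(aperm(array(t(flat), c(nt, dims)), c(2, 3, 4, 1)), 3, 2,
                    "s", 1, 0, matrix(0, nt, 6))
  expect_true(all(make_gm_mask(s, 0.5)))
  expect_true(all(make_gm_mask(s, 0)))
  flat[1:4, ] <- 10  # dropout block at 0.1x
  s2 <- bold_session(aperm(array(t(flat), c(nt, dims)), c(2, 3, 4, 1)), 3, 2,
                     "s", 1, 0, matrix(0, nt, 6))
  m <- make_gm_mask(s2, 0.5)
  expect_false(any(m[1:4]))
  expect_true(all(m[5:prod(dims)]))
  s3 <- s; s3$data[] <- 0
  expect_error(make_gm_mask(s3), "all-zero")
})

test_that("global FCD counts supra-threshold partners (tiny examples)", {
  nt <- 30
  set.seed(41)
  base <- rnorm(nt)
  series <- cbind(base, base, rnorm(nt))
  s <- session_from_series(series, c(3, 1, 1))
  mask <- array(TRUE, c(3, 1, 1))
  g <- compute_global_fcd(s, mask)
  expect_equal(as.integer(g), c(1L, 1L, 0L))
  # complete graph: all identical
  s2 <- session_from_series(cbind(base, base, base), c(3, 1, 1))
  expect_equal(as.integer(compute_global_fcd(s2, mask)), rep(2L, 3))
  # independent noise at study length: virtually no connections
  set.seed(42)
  s3 <- session_from_series(matrix(rnorm(170 * 64), 170), c(4, 4, 4))
  g3 <- compute_global_fcd(s3, array(TRUE, c(4, 4, 4)))
  expect_equal(sum(g3), 0L)
})

test_that("tiling block size does not change FCD results", {
  rs <- random_small_session(7)
  s <- session_from_series(rs$series, rs$dims, rs$mask)
  for (bs in c(1L, 7L, 512L)) {
    cfgb <- fcd_config(block_size = bs)
    expect_equal(suppressWarnings(compute_global_fcd(s, rs$mask, cfgb)),
                 suppressWarnings(compute_global_fcd(s, rs$mask, fcd_config())))
    expect_equal(suppressWarnings(compute_short_fcd(s, rs$mask, cfgb)),
                 suppressWarnings(compute_short_fcd(s, rs$mask, fcd_config())))
  }
})

test_that("short-range growth follows spatial contiguity", {
  nt <- 30
  set.seed(43)
  base <- rnorm(nt)
  # 1-D chain of 5 identical voxels: middle voxel grows the whole chain
  s <- session_from_series(matrix(base, nt, 5), c(5, 1, 1))
  mask <- array(TRUE, c(5, 1, 1))
  sh <- compute_short_fcd(s, mask)
  expect_equal(as.integer(sh), rep(4L, 5))
  # correlated but spatially distant: global 1, short 0, long 1
  series <- matrix(rnorm(nt * 7, sd = 1), nt, 7)
  series[, 1] <- base; series[, 7] <- base
  s2 <- session_from_series(series, c(7, 1, 1))
  mask2 <- array(TRUE, c(7, 1, 1))
  g2 <- compute_global_fcd(s2, mask2)
  sh2 <- compute_short_fcd(s2, mask2)
  expect_equal(g2[1, 1, 1], 1L)
  expect_equal(sh2[1, 1, 1], 0L)
  expect_equal(g2[1, 1, 1] - sh2[1, 1, 1], 1L)  # long-range partner
  # isolated single in-mask voxel has no neighbours to grow
  mask3 <- array(FALSE, c(5, 1, 1)); mask3[c(1, 3, 5)] <- TRUE
  s3 <- session_from_series(matrix(base, nt, 3), c(5, 1, 1), mask3)
  expect_equal(as.integer(compute_short_fcd(s3, mask3)[c(1, 3, 5)]),
               rep(0L, 3))
})

test_that("FCD matches the brute-force oracle on randomized grids", {
  for (seed in 1:12) {
    rs <- random_small_session(seed)
    s <- session_from_series(rs$series, rs$dims, rs$mask)
    for (nb in c(6, 26)) {
      cfg <- fcd_config(neighborhood = nb)
      oracle <- bf_fcd(rs$series, rs$dims, rs$mask, 0.6, nb)
      g <- suppressWarnings(compute_global_fcd(s, rs$mask, cfg))
      sh <- suppressWarnings(compute_short_fcd(s, rs$mask, cfg))
      expect_identical(g[oracle$vox], oracle$global)
      expect_identical(sh[oracle$vox], oracle$short)
      expect_true(all(g[oracle$vox] - sh[oracle$vox] >= 0L))
    }
  }
})

test_that("lowering the threshold never decreases global FCD", {
  rs <- random_small_session(31)
  s <- session_from_series(rs$series, rs$dims, rs$mask)
  g_hi <- suppressWarnings(compute_global_fcd(s, rs$mask, fcd_config(r_threshold = 0.7)))
  g_lo <- suppressWarnings(compute_global_fcd(s, rs$mask, fcd_config(r_threshold = 0.4)))
  expect_true(all(g_lo >= g_hi))
})

test_that("offset enumeration order does not change component growth", {
  rs <- random_small_session(17)
  s <- session_from_series(rs$series, rs$dims, rs$mask)
  sh <- suppressWarnings(compute_short_fcd(s, rs$mask))
  # same computation with the frontier rule on a fully self-consistent case:
  # identical series everywhere -> both rules give the connected component
  nt <- 30; base <- rnorm(nt)
  s2 <- session_from_series(matrix(base, nt, 8), c(2, 2, 2))
  mask2 <- array(TRUE, c(2, 2, 2))
  seedr <- compute_short_fcd(s2, mask2, fcd_config(growth_rule = "seed_correlation"))
  front <- compute_short_fcd(s2, mask2, fcd_config(growth_rule = "frontier_correlation"))
  expect_equal(seedr, front)
  expect_equal(as.integer(seedr), rep(7L, 8))
})

test_that("frontier rule can admit voxels the seed rule excludes", {
  # chain x1 - x2 - x3 where r(x1,x2) and r(x2,x3) exceed the threshold but
  # r(x1,x3) does not: frontier growth from x1 admits x3, seed growth stops.
  nt <- 400
  set.seed(55)
  a <- rnorm(nt); b <- rnorm(nt); c <- rnorm(nt)
  x2 <- a
  x1 <- 0.8 * a + sqrt(1 - 0.8^2) * b
  x3 <- 0.8 * a - sqrt(1 - 0.8^2) * b + 0.1 * c
  series <- cbind(x1, x2, x3)
  R <- cor(series)
  skip_if_not(R[1, 2] > 0.6 && R[2, 3] > 0.6 && R[1, 3] < 0.6)
  s <- session_from_series(series, c(3, 1, 1))
  mask <- array(TRUE, c(3, 1, 1))
  seedr <- compute_short_fcd(s, mask, fcd_config(growth_rule = "seed_correlation"))
  front <- compute_short_fcd(s, mask, fcd_config(growth_rule = "frontier_correlation"))
  expect_equal(seedr[1, 1, 1], 1L)
  expect_equal(front[1, 1, 1], 2L)
})

test_that("scaled maps average one over the mask; smoothing stays in-mask", {
  cfg <- small_sim_config()
  s <- simulate_session(cfg, "p1", 3, subject_index = 1)
  p <- preprocess_session(s)
  mask <- make_gm_mask(s)
  maps <- compute_fcd_maps(p, mask, fcd_config())
  expect_equal(mean(maps$short_scaled[mask]), 1.0)
  expect_equal(mean(maps$long_scaled[mask]), 1.0)
  expect_equal(mean(maps$global_scaled[mask]), 1.0)
  expect_true(all(maps$long >= 0L))
  expect_true(all(maps$short_scaled_smooth[!mask] == 0))
  expect_true(all(maps$global[!mask] == 0L))
  # short-range FCD peaks inside the injected hubs
  hub <- cfg$communities[[1]]$voxels
  bg <- setdiff(which(mask), unlist(lapply(cfg$communities, `[[`, "voxels")))
  expect_gt(mean(maps$short_scaled[hub]), 10 * mean(maps$short_scaled[bg]) + 1)
})

test_that("constant in-mask series warn and count as unconnected", {
  nt <- 30
  set.seed(61)
  series <- cbind(matrix(rnorm(nt * 3), nt, 3), 7)
  s <- session_from_series(series, c(4, 1, 1))
  mask <- array(TRUE, c(4, 1, 1))
  expect_warning(g <- compute_global_fcd(s, mask), "constant")
  expect_equal(g[4, 1, 1], 0L)
})
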