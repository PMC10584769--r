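# Tract density imaging, binarisation and group probability maps.

test_that("one straight streamline marks exactly the voxels it traverses", {
  tmpl <- scalar_map(array(0, c(10, 5, 5)), diag(4), "density")
  # runs along x through voxel centres y=2, z=2, from x=1 to x=7: 7 voxels
  sl <- cbind(seq(1, 7, by = 0.25), 2, 2)
  d <- tract_density(streamline_set(list(sl)), tmpl)
  expect_equal(sum(d$grid), 7)
  expect_true(all(d$grid[2:8, 3, 3] == 1))

  # duplicated streamline doubles every nonzero voxel
  d2 <- tract_density(streamline_set(list(sl, sl)), tmpl)
  expect_equal(d2$grid, 2 * d$grid)

  # a loop revisiting a voxel still counts once per streamline
  t <- seq(0, 4 * pi, length.out = 200)
  loop <- cbind(4 + 1.2 * cos(t), 2 + 1.2 * sin(t), 2)
  dl <- tract_density(streamline_set(list(loop)), tmpl)
  expect_lte(max(dl$grid), 1)
})

test_that("points outside the template are ignored with a warning", {
  tmpl <- scalar_map(array(0, c(4, 4, 4)), diag(4), "density")
  sl <- cbind(seq(-5, 3, by = 0.5), 1, 1)
  expect_warning(d <- tract_density(streamline_set(list(sl)), tmpl),
                 "outside")
  expect_gt(sum(d$grid), 0)
})

test_that("binarize applies the K >= k_min rule", {
  g <- array(0L, c(3, 3, 3)); g[1, 1, 1] <- 0L; g[2, 1, 1] <- 1L; g[3, 1, 1] <- 5L
  d <- scalar_map(g, diag(4), "density")
  b <- binarize(d)
  expect_equal(b$grid[, 1, 1], c(0, 1, 1))
  expect_equal(sum(binarize(scalar_map(array(0L, c(3, 3, 3)), diag(4),
                                       "density"))$grid), 0)
  expect_equal(sum(binarize(d, k_min = 6)$grid), 0)
  expect_error(binarize(mask3(array(0, c(2, 2, 2)))), "density")
})

test_that("binarized density equals the union of per-streamline voxel sets", {
  set.seed(12)
  tmpl <- scalar_map(array(0, c(12, 12, 12)), diag(4), "density")
  sls <- lapply(1:8, function(i) {
    start <- stats::runif(3, 4, 7)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    start + outer(seq(0, 4, by = 0.1), dir)   # stays inside the 12^3 grid
  })
  d <- tract_density(streamline_set(sls), tmpl)
  b <- binarize(d)
  # independent set-theoretic oracle: voxelise each streamline separately
  oracle <- array(FALSE, dim(tmpl$grid))
  for (s in sls) {
    ds <- tract_density(streamline_set(list(s)), tmpl)
    oracle <- oracle | (ds$grid > 0)
  }
  expect_equal(b$grid != 0, oracle)
  # and the counts never exceed the number of streamlines
  expect_lte(max(d$grid), 8)
})

test_that("halving the supersampling spacing does not change the binarized map", {
  sls <- fx_tracked_bundle()
  tmpl <- fx_tracking_phantom()$template
  b1 <- binarize(tract_density(sls, tmpl))
  b2 <- binarize(tract_density(sls, tmpl,
                               supersample_mm = min(voxel_dims_mm(tmpl$affine)) / 8))
  expect_identical(b1$grid, b2$grid)
})

test_that("probability maps average binarized indicator maps", {
  g <- array(0, c(4, 4, 4))
  m1 <- mask3(`[<-`(g, 1:2, 1, 1, 1))
  m2 <- mask3(`[<-`(g, 2:3, 1, 1, 1))
  m0 <- mask3(g)
  bundle <- probability_map(list(m1, m2, m0, m0))
  expect_equal(bundle$map$grid[2, 1, 1], 0.5)   # present in 2 of 4
  expect_equal(bundle$map$grid[1, 1, 1], 0.25)
  expect_equal(bundle$n_subjects, 4L)
  # probabilities times n are integral
  expect_true(all(abs(bundle$map$grid * 4 - round(bundle$map$grid * 4)) < 1e-12))

  # identical subjects reproduce the single map; one subject is 0/1-valued
  same <- probability_map(list(m1, m1, m1))
  expect_equal(same$map$grid, m1$grid)
  single <- probability_map(list(m2))
  expect_true(all(single$map$grid %in% c(0, 1)))
})

test_that("confidence thresholds nest and 1/n recovers the union", {
  set.seed(13)
  maps <- lapply(1:5, function(i) random_mask(c(6, 6, 6), p = 0.3))
  bundle <- probability_map(maps)
  m90 <- threshold_probability(bundle, 0.90)
  m50 <- threshold_probability(bundle, 0.50)
  m05 <- threshold_probability(bundle, 0.05)
  expect_true(all(m90$grid <= m50$grid))
  expect_true(all(m50$grid <= m05$grid))
  union <- Reduce(mask_union, maps)
  expect_equal(threshold_probability(bundle, 1 / 5)$grid, union$grid)
  expect_error(threshold_probability(bundle, 0), "confidence")
  expect_error(threshold_probability(bundle, 1.2), "confidence")

  # direct comparison on a three-level map
  pm <- scalar_map(array(c(0, 0.5, 1, rep(0, 24 - 3)), c(3, 4, 2)),
                   diag(4), "probability")
  kept <- threshold_probability(pm, 0.5)
  expect_equal(sum(kept$grid), 2)
})
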