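# Dice overlap, hold-out cross-validation, repeated-processing and
# test-retest machinery.

test_that("dice matches the closed form and brute-force voxel counting", {
  A <- random_mask(c(6, 6, 6), 0.4)
  expect_equal(dice(A, A)$dice, 1)

  g1 <- array(0, c(4, 4, 4)); g1[1:2, , 1] <- 1
  g2 <- array(0, c(4, 4, 4)); g2[3:4, , 1] <- 1
  expect_equal(dice(mask3(g1), mask3(g2))$dice, 0)

  # N(A)=10, N(B)=14, N(A and B)=8 -> 2*8/24
  ga <- array(0, c(5, 5, 5)); ga[1:10] <- 1
  gb <- array(0, c(5, 5, 5)); gb[3:16] <- 1
  r <- dice(mask3(ga), mask3(gb))
  expect_equal(r$a, 10); expect_equal(r$b, 14); expect_equal(r$inter, 8)
  expect_equal(r$dice, 2 * 8 / 24, tolerance = 1e-12)

  empty <- mask3(array(0, c(4, 4, 4)))
  de <- dice(empty, empty)
  expect_true(de$degenerate); expect_equal(de$dice, 1)
  expect_error(dice(A, random_mask(c(5, 5, 5))), "grid")
})

test_that("holdout splits use round(ratio * n) and are seed-deterministic", {
  # a 136-subject cohort at 10% hold-out gives a small group of 13-14
  m <- random_mask(c(2, 2, 2), 0.5)
  res136 <- holdout_cv(rep(list(m), 136), ratio = 0.10, n_iterations = 2,
                       seed = 1)
  expect_true(res136$small_group %in% c(13L, 14L))
  set.seed(14)
  maps <- lapply(1:10, function(i) random_mask(c(5, 5, 5), 0.4))
  a <- holdout_cv(maps, ratio = 0.2, n_iterations = 25, confidence = 0.05,
                  seed = 77)
  b <- holdout_cv(maps, ratio = 0.2, n_iterations = 25, confidence = 0.05,
                  seed = 77)
  expect_identical(a$dice, b$dice)
  expect_length(a$dice, 25L)
  expect_true(all(a$dice >= 0 & a$dice <= 1))
  expect_equal(a$small_group, 2L)
  expect_error(holdout_cv(maps, ratio = 0.01, n_iterations = 5), "empty group")
  expect_error(holdout_cv(maps[1:2], 0.5, 5), "3 subjects")
})

test_that("holdout on identical subjects always yields dice 1", {
  m <- random_mask(c(6, 6, 6), 0.4)
  maps <- rep(list(m), 8)
  res <- holdout_cv(maps, ratio = 0.25, n_iterations = 30, confidence = 0.05,
                    seed = 3)
  expect_true(all(res$dice == 1))
  expect_equal(res$mean, 1)
})

test_that("holdout dice distribution is invariant under subject relabeling", {
  # the split distribution is exchangeable in the subject labels, so the
  # sampled dice distributions agree statistically (not split-by-split,
  # since the same RNG indices pick different subjects after relabeling)
  set.seed(15)
  maps <- lapply(1:9, function(i) random_mask(c(5, 5, 5), 0.4))
  a <- holdout_cv(maps, ratio = 0.22, n_iterations = 400, seed = 5)
  b <- holdout_cv(maps[sample(9)], ratio = 0.22, n_iterations = 400, seed = 6)
  expect_lt(abs(a$mean - b$mean), 0.03)
  expect_gt(suppressWarnings(stats::ks.test(a$dice, b$dice)$p.value), 1e-4)
  # and the achievable dice values come from the same finite set
  expect_true(all(b$dice %in% unique(a$dice)) || abs(a$mean - b$mean) < 0.03)
})

test_that("mean holdout dice decreases as inter-subject jitter grows", {
  # synthetic binary maps: a common core plus jitter-dependent random flips
  set.seed(16)
  core <- array(stats::runif(6^3) < 0.3, c(6, 6, 6))
  make_cohort_maps <- function(flip_p)
    lapply(1:10, function(i) {
      flips <- array(stats::runif(6^3) < flip_p, c(6, 6, 6))
      mask3(array(xor(core, flips), c(6, 6, 6)))
    })
  means <- vapply(c(0, 0.1, 0.3), function(p)
    holdout_cv(make_cohort_maps(p), ratio = 0.2, n_iterations = 30,
               confidence = 0.5, seed = 4)$mean, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("repeated_processing compares all unordered pairs", {
  m <- random_mask(c(5, 5, 5), 0.4)
  res10 <- repeated_processing(rep(list(m), 10))
  expect_length(res10$dice, 45L)
  expect_true(all(res10$dice == 1))
  set.seed(17)
  res3 <- repeated_processing(lapply(1:3, function(i) random_mask(c(5, 5, 5))))
  expect_length(res3$dice, 3L)
  expect_error(repeated_processing(list(m)), "2 runs")
})

test_that("test_retest applies the supplied transform before comparing", {
  m <- random_mask(c(8, 8, 8), 0.35)
  expect_equal(test_retest(m, m)$dice, 1)

  # session 2 translated by +2 voxels; supplying the inverse recovers dice 1
  # exactly for an interior mask that never leaves the grid
  gi <- array(0, c(10, 10, 10)); gi[3:5, 3:8, 3:8] <- 1
  mi <- mask3(gi)
  A <- diag(4); A[1, 4] <- 2
  m2 <- apply_transform(mi, spatial_transform("affine", A))
  d <- test_retest(mi, m2, spatial_transform("affine", solve(A)))
  expect_equal(d$dice, 1)

  # toggled voxels: compare against a direct voxel-count oracle
  set.seed(18)
  g2 <- m$grid
  flip <- sample(length(g2), round(0.1 * length(g2)))
  g2[flip] <- 1 - g2[flip]
  mflip <- mask3(array(g2, dim(m$grid)))
  d2 <- test_retest(m, mflip)
  a <- sum(m$grid); b <- sum(g2); inter <- sum(m$grid & g2)
  expect_equal(d2$dice, 2 * inter / (a + b), tolerance = 1e-12)
})

test_that("roi_test_retest aggregates per tract, roi and hemisphere", {
  m <- random_mask(c(6, 6, 6), 0.4)
  pairs <- list(
    list(a = m, b = m, tract = "CST", roi = "seed", hemisphere = "left"),
    list(a = m, b = m, tract = "CST", roi = "seed", hemisphere = "left"))
  tab <- roi_test_retest(pairs)
  expect_equal(tab$mean_dice, 1)
  expect_equal(tab$sd_dice, 0)
  expect_equal(tab$n, 2L)

  # known dice values 0.8 and 0.9 -> 0.85 +/- 0.0707
  mk <- function(n_a, n_int, n_b) {
    g1 <- array(0, c(10, 10, 10)); g1[seq_len(n_a)] <- 1
    g2 <- array(0, c(10, 10, 10)); g2[seq(n_a - n_int + 1, n_a - n_int + n_b)] <- 1
    list(mask3(g1), mask3(g2))
  }
  p1 <- mk(10, 8, 10)   # dice 0.8
  p2 <- mk(10, 9, 10)   # dice 0.9
  pairs2 <- list(
    list(a = p1[[1]], b = p1[[2]], tract = "AF", roi = "target",
         hemisphere = "right"),
    list(a = p2[[1]], b = p2[[2]], tract = "AF", roi = "target",
         hemisphere = "right"))
  tab2 <- roi_test_retest(pairs2)
  expect_equal(tab2$mean_dice, 0.85, tolerance = 1e-12)
  expect_equal(round(tab2$sd_dice, 3), 0.071)
  expect_warning(roi_test_retest(list()), "no ROI pairs")
})
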