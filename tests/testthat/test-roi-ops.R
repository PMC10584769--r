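# Geometric ROI operators: label selection, axis splits, slabs, Gaussian
# dilation, sphere placement, plane splits, volume statistics.

unit_label_vol <- function() {
  g <- array(0L, c(10, 10, 10))
  g[2:4, 2:4, 2:4] <- 1L          # A: 27 voxels
  g[7:9, 7:9, 7:9] <- 2L          # B: 27 voxels
  label_volume(g, diag(4), c(A = 1L, B = 2L))
}

test_that("select_labels unions disjoint labels and is idempotent", {
  vol <- unit_label_vol()
  ab <- select_labels(vol, c("A", "B"))
  expect_equal(sum(ab$grid), 54)
  expect_equal(sum(select_labels(vol, "A")$grid), 27)
  expect_equal(select_labels(vol, "A")$grid, select_labels(vol, "A")$grid)
  expect_equal(sum(select_labels(vol, character(0))$grid), 0)
  expect_error(select_labels(vol, "C"), "unresolvable")
})

test_that("split_axis keeps the stated side of the bounding-box plane", {
  g <- array(0, c(4, 12, 4)); g[2:3, 2:11, 2:3] <- 1   # 10 voxels deep in y
  m <- mask3(g)
  ant <- split_axis(m, "AP", "anterior", 0.5)
  post <- split_axis(m, "AP", "posterior", 0.5)
  expect_equal(sum(ant$grid), sum(m$grid) / 2)
  expect_equal(sum(post$grid), sum(m$grid) / 2)
  # the two complementary halves partition the mask
  expect_equal(ant$grid + post$grid, m$grid)
  # fraction 0 keeps everything
  expect_equal(split_axis(m, "AP", "anterior", 0)$grid, m$grid)
  expect_error(split_axis(mask3(array(0, c(2, 2, 2))), "AP", "anterior"),
               "empty")
})

test_that("split_axis fraction 1/3 posterior keeps the posterior two thirds", {
  g <- array(0, c(3, 9, 3)); g[2, , 2] <- 1           # y centers 0..8
  m <- mask3(g)
  post23 <- split_axis(m, "AP", "posterior", 1 / 3)
  w <- which(post23$grid != 0, arr.ind = TRUE)
  expect_equal(sum(post23$grid), 6)                    # y <= 8 - 8/3 -> 0..5
  expect_true(all(w[, 2] <= 6))
})

test_that("axial_slab keeps voxels within half a thickness of the reference midpoint", {
  # reference spans z in [10, 20] mm -> midpoint 15, 4 mm slab keeps [13, 17]
  aff <- diag(4)
  g <- array(0, c(3, 3, 25)); g[2, 2, ] <- 1
  m <- mask3(g, aff)
  gr <- array(0, c(3, 3, 25)); gr[1, 1, 11:21] <- 1    # z centers 10..20
  ref <- mask3(gr, aff)
  slab <- axial_slab(m, ref, 4)
  zkept <- which(slab$grid != 0, arr.ind = TRUE)[, 3] - 1
  expect_setequal(zkept, 13:17)
  # thickness covering the whole extent keeps the full mask
  expect_equal(axial_slab(m, ref, 100)$grid, m$grid)
  # disjoint slab warns and returns empty
  gfar <- array(0, c(3, 3, 25)); gfar[2, 2, 1:2] <- 1
  expect_warning(res <- axial_slab(mask3(gfar, aff), ref, 1), "slab")
  expect_equal(sum(res$grid), 0)
  expect_error(axial_slab(m, mask3(array(0, c(3, 3, 25))), 4), "empty")
})

test_that("gaussian_dilate enlarges, is monotone in sigma, and respects constraints", {
  g <- array(0, c(9, 9, 9)); g[5, 5, 5] <- 1
  m <- mask3(g)
  d <- gaussian_dilate(m, 1.5)           # 1 mm grid
  expect_true(all(d$grid[m$grid != 0] == 1))
  expect_gt(sum(d$grid), sum(m$grid))    # strictly larger
  # near-zero sigma leaves the mask unchanged
  expect_equal(gaussian_dilate(m, 1e-6)$grid, m$grid)
  # monotone in sigma
  prev <- m
  for (s in c(0.5, 1, 1.5, 2.5)) {
    cur <- gaussian_dilate(m, s)
    expect_true(all(cur$grid >= prev$grid))
    prev <- cur
  }
  # constraint equal to the original absorbs the dilation
  expect_equal(gaussian_dilate(m, 2, constraint = m)$grid, m$grid)
})

test_that("gaussian_dilate radius matches the kernel-threshold closed form", {
  # voxels kept iff max-kernel value >= 0.3, i.e. distance <= sigma*sqrt(2 ln(1/0.3))
  g <- array(0, c(11, 11, 11)); g[6, 6, 6] <- 1
  m <- mask3(g)
  sigma <- 1.5
  d <- gaussian_dilate(m, sigma)
  r <- sigma * sqrt(2 * log(1 / 0.3))
  idx <- which(array(TRUE, dim(g)), arr.ind = TRUE) - 1
  dist <- sqrt(rowSums((idx - matrix(5, nrow(idx), 3))^2))
  expect_equal(as.vector(d$grid) != 0, dist <= r + 1e-12)
})

test_that("sphere_between places the right ball at the snapped midpoint", {
  g <- array(0, c(11, 5, 5))
  ga <- g; ga[1, 3, 3] <- 1                 # centroid (0, 2, 2)
  gb <- g; gb[11, 3, 3] <- 1                # centroid (10, 2, 2)
  wm <- mask3(array(1, dim(g)))
  ball <- sphere_between(mask3(ga), mask3(gb), 24, wm)
  # r = (3*24/4pi)^(1/3) = 1.789 mm; independent enumeration of voxel centres
  r <- (3 * 24 / (4 * pi))^(1 / 3)
  idx <- which(array(TRUE, dim(g)), arr.ind = TRUE) - 1
  inside <- sqrt(rowSums((idx - matrix(c(5, 2, 2), nrow(idx), 3,
                                       byrow = TRUE))^2)) <= r
  expect_equal(as.vector(ball$grid) != 0, inside)
  # centre + 6 faces + 12 edges + 8 corners all lie within 1.789 mm
  expect_equal(sum(ball$grid), 27)

  # a one-voxel volume on a 2 mm grid yields exactly the snapped centre voxel
  aff2 <- diag(c(2, 2, 2, 1))
  ball2 <- sphere_between(mask3(ga, aff2), mask3(gb, aff2), 8,
                          mask3(array(1, dim(g)), aff2))
  expect_equal(sum(ball2$grid), 1)

  # identical masks centre the ball on the common centroid
  gc <- g; gc[6, 3, 3] <- 1                 # interior voxel (5, 2, 2)
  ball3 <- sphere_between(mask3(gc), mask3(gc), 24, wm)
  w <- which(ball3$grid != 0, arr.ind = TRUE) - 1
  expect_equal(unname(colMeans(w)), c(5, 2, 2), tolerance = 1e-9)
  expect_error(sphere_between(mask3(g), mask3(ga), 24, wm), "empty")
})

test_that("split_by_plane splits at the landmark's anterior-most y and partitions", {
  g <- array(0, c(3, 21, 3)); g[2, , 2] <- 1          # y centers 0..20
  m <- mask3(g)
  gl <- array(0, c(3, 21, 3)); gl[2, 7:9, 2] <- 1     # landmark, max y = 8
  parts <- split_by_plane(m, mask3(gl))
  ypost <- which(parts$posterior$grid != 0, arr.ind = TRUE)[, 2] - 1
  yant <- which(parts$anterior$grid != 0, arr.ind = TRUE)[, 2] - 1
  expect_true(all(ypost <= 8))
  expect_true(all(yant > 8))
  expect_equal(parts$posterior$grid + parts$anterior$grid, m$grid)
  # landmark anterior to the whole mask -> (full, empty)
  gfar <- array(0, c(3, 21, 3)); gfar[2, 21, 2] <- 1
  parts2 <- split_by_plane(m, mask3(gfar))
  expect_equal(parts2$posterior$grid, m$grid)
  expect_equal(sum(parts2$anterior$grid), 0)
  expect_error(split_by_plane(m, mask3(array(0, dim(g)))), "empty")
})

test_that("roi_volume_stats reports mean, sd and scale-invariant sd percent", {
  m100 <- mask3(array(c(rep(1, 100), rep(0, 25^3 - 100)), c(25, 25, 25)))
  expect_equal(roi_volume_stats(list(m100, m100))$sd_percent, 0)

  m80 <- mask3(array(c(rep(1, 80), rep(0, 25^3 - 80)), c(25, 25, 25)))
  m120 <- mask3(array(c(rep(1, 120), rep(0, 25^3 - 120)), c(25, 25, 25)))
  st <- roi_volume_stats(list(m80, m120))
  expect_equal(st$mean_mm3, 100)
  expect_equal(st$sd_percent, 100 * stats::sd(c(80, 120)) / 100,
               tolerance = 1e-12)
  expect_equal(round(st$sd_percent, 2), 28.28)

  # doubling the voxel volume scales mm^3 but not the percentage
  aff2 <- diag(c(2, 1, 1, 1))
  st2 <- roi_volume_stats(list(mask3(m80$grid, aff2), mask3(m120$grid, aff2)))
  expect_equal(st2$sd_percent, st$sd_percent)
  expect_error(roi_volume_stats(list(m80)), "2 subjects")
})
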