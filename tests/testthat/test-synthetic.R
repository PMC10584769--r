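# Phantom generators: determinism, disjointness, mirror symmetry, fODF
# structure, bundles, spurious injection, cohorts.

test_that("the default phantom is deterministic with disjoint mirrored structures", {
  v1 <- fx_phantom()
  v2 <- make_phantom()
  expect_identical(v1$grid, v2$grid)
  expect_length(v1$absent, 0L)

  # left/right instances are exact mirrors (x axis flip)
  flipped <- v1$grid[dim(v1$grid)[1]:1, , ]
  for (nm in c("thalamus", "precentral_gyrus", "lgn", "supramarginal_gyrus")) {
    l <- v1$labels[paste0(nm, "_L")]; r <- v1$labels[paste0(nm, "_R")]
    expect_identical(which(flipped == l), which(v1$grid == r))
  }
})

test_that("every label in the default phantom occupies disjoint voxels", {
  v <- fx_phantom()
  # labels partition by construction; spot-check the total accounting
  expect_equal(sum(v$grid > 0),
               sum(vapply(v$labels, function(l) sum(v$grid == l), numeric(1))))
})

test_that("make_fodf concentrates amplitude along tangents and superposes crossings", {
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- -11
  tmpl <- scalar_map(array(0, c(12, 12, 12)), aff, "density")
  lx <- cbind(seq(-10, 10), 0, 0)
  lz <- cbind(0, 0, seq(-10, 10))
  f1 <- make_fodf(list(lx), tmpl, background = 0.01)
  expect_gt(fodf_amplitude(f1, c(0, 0, 0), c(1, 0, 0)),
            fodf_amplitude(f1, c(0, 0, 0), c(0, 0, 1)))

  # two crossing centerlines give a two-lobed fODF at the crossing voxel
  f2 <- make_fodf(list(lx, lz), tmpl, background = 0.01)
  ax <- fodf_amplitude(f2, c(0, 0, 0), c(1, 0, 0))
  az <- fodf_amplitude(f2, c(0, 0, 0), c(0, 0, 1))
  ad <- fodf_amplitude(f2, c(0, 0, 0), c(1, 0, 1) / sqrt(2))
  expect_gt(ax, ad); expect_gt(az, ad)

  # background only: isotropic
  fb <- make_fodf(list(lx), tmpl, background = 0.3, weights = 0)
  dirs <- fibonacci_sphere(24)
  amps <- fodf_amplitude(fb, c(4, 4, 4), dirs)
  expect_lt(diff(range(amps)), 1e-6)
  expect_error(make_fodf(list(), tmpl), "centerline")
})

test_that("make_bundle lays parallel streamlines with aligned tangents", {
  cl <- cbind(seq(0, 30, length.out = 40), 0, 0)
  b <- make_bundle(cl, 9, tube_radius_mm = 2, jitter_mm = 0, seed = 2)
  expect_length(b$streamlines, 9L)
  # jitter 0: all offsets constant -> pairwise constant differences
  d12 <- b$streamlines[[1]] - b$streamlines[[2]]
  expect_lt(max(abs(sweep(d12, 2, d12[1, ]))), 1e-9)
  # tangent alignment at matched arc length below 15 degrees
  tangs <- lapply(b$streamlines, function(s) {
    d <- diff(s); d / sqrt(rowSums(d^2))
  })
  for (i in 2:9) {
    cosang <- rowSums(tangs[[1]] * tangs[[i]])
    expect_lt(max(acos(pmin(pmax(cosang, -1), 1))) * 180 / pi, 15)
  }
  expect_identical(make_bundle(cl, 5, seed = 7)$streamlines,
                   make_bundle(cl, 5, seed = 7)$streamlines)
})

test_that("inject_spurious adds labelled, well-separated streamlines", {
  cl <- cbind(seq(0, 30, length.out = 30), 0, 0)
  b <- make_bundle(cl, 50, seed = 1)
  expect_identical(inject_spurious(b, 0)$streamlines, b$streamlines)

  s <- inject_spurious(b, 0.2, seed = 3)
  expect_length(s$streamlines, 60L)
  expect_equal(sum(s$meta$ground_truth == "spurious"), 10L)
  # injected midpoints sit beyond the separation floor from the bundle
  allpts <- do.call(rbind, b$streamlines)
  for (i in 51:60) {
    sp <- s$streamlines[[i]]
    mid <- sp[ceiling(nrow(sp) / 2), ]
    dmin <- min(sqrt(colSums((t(allpts) - mid)^2)))
    expect_gt(dmin, 10)
  }
  expect_error(inject_spurious(b, 1), "fraction")
})

test_that("a jitter-free cohort is identical with identity transforms", {
  base <- fx_phantom()
  cohort <- make_cohort(3, base_vol = base, seed = 5)
  for (su in cohort) {
    expect_identical(su$vol$grid, base$grid)
    expect_equal(su$transform$kind, "identity")
  }
})

test_that("jittered cohorts vary and ship exact inverse transforms", {
  base <- fx_phantom()
  cohort <- make_cohort(2, base_vol = base, jitter_mm = 2, jitter_deg = 4,
                        jitter_scale = 0.05, seed = 6)
  expect_false(identical(cohort[[1]]$vol$grid, base$grid))
  expect_false(identical(cohort[[1]]$vol$grid, cohort[[2]]$vol$grid))
  # ROI volumes vary across subjects (the anatomical variability emulated)
  vols <- vapply(cohort, function(su)
    sum(su$vol$grid == base$labels["thalamus_L"]), numeric(1))
  expect_true(length(unique(vols)) > 1 ||
                vols[1] != sum(base$grid == base$labels["thalamus_L"]))
})

test_that("the tracking phantom presets share geometry contracts", {
  ph <- fx_tracking_phantom()
  expect_equal(sum(ph$rois$seed$grid), 12)
  expect_gt(sum(ph$rois$targets[[1]]$grid), 0)
  short <- make_tracking_phantom(size = "short")
  expect_lt(dim(short$field$coef)[3], dim(ph$field$coef)[3])
  wall <- make_tracking_phantom(exclusion_wall = TRUE)
  expect_length(wall$rois$excludes, 1L)
})
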