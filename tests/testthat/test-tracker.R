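# Probabilistic tracker: step geometry, direction sampling, propagation and
# tractogram-level contracts.

test_that("max_step_angle follows the chord closed form", {
  expect_equal(max_step_angle(0.2, 1), 2 * asin(0.1) * 180 / pi)
  expect_equal(round(max_step_angle(0.2, 1), 3), 11.478)
  expect_equal(max_step_angle(1e-9, 1), 0, tolerance = 1e-6)
  expect_equal(max_step_angle(2, 1), 180)
  expect_error(max_step_angle(2.1, 1), "curvature")
  expect_error(tracking_params(step_mm = 3, curvature_radius_mm = 1), "twice")
})

test_that("direction sampling on an isotropic field is uniform over octants", {
  bg <- 0.5
  coef <- array(0, c(3, 3, 3, 45)); coef[, , , 1] <- bg * sqrt(4 * pi)
  f <- fodf_field(coef, 8L, diag(4))
  params <- tracking_params(max_amp = bg)
  set.seed(1)
  n <- 4000
  dirs <- t(replicate(n, sample_direction(f, c(1, 1, 1), cutoff_fraction = 0.1,
                                          params = params)))
  octant <- 1 + (dirs[, 1] > 0) + 2 * (dirs[, 2] > 0) + 4 * (dirs[, 3] > 0)
  counts <- tabulate(octant, 8)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 1e-4)
})

test_that("sampling fails when all amplitudes sit below the cutoff", {
  coef <- array(0, c(3, 3, 3, 45)); coef[, , , 1] <- 0.01 * sqrt(4 * pi)
  f <- fodf_field(coef, 8L, diag(4))
  params <- tracking_params(max_amp = 1)
  set.seed(2)
  expect_null(sample_direction(f, c(1, 1, 1), cutoff_fraction = 0.5,
                               params = params))
})

test_that("a strong axial lobe concentrates sampled directions around its axis", {
  dirs200 <- fibonacci_sphere(200)
  lobe <- exp(25 * (dirs200[, 1]^2 - 1))
  cf <- as.vector(sh_projector(dirs200, 8) %*% lobe)
  coef <- array(rep(cf, each = 27), c(3, 3, 3, 45))
  f <- fodf_field(coef, 8L, diag(4))
  params <- tracking_params(max_amp = fodf_max_amplitude(f))
  set.seed(3)
  smp <- t(replicate(300, sample_direction(f, c(1, 1, 1),
                                           cone_spec = list(axis = c(1, 0, 0),
                                                            half_angle_deg = 45),
                                           cutoff_fraction = 0.05,
                                           params = params)))
  mean_dir <- colMeans(smp)
  mean_dir <- mean_dir / sqrt(sum(mean_dir^2))
  angle <- acos(sum(mean_dir * c(1, 0, 0))) * 180 / pi
  expect_lt(angle, 5)
})

test_that("propagate accepts across the straight bundle with near-straight paths", {
  ph <- fx_tracking_phantom()
  params <- tracking_params(max_length_mm = 120,
                            max_amp = fodf_max_amplitude(ph$field))
  set.seed(4)
  res <- NULL
  for (i in 1:20) {
    res <- propagate(c(0, 0, -24), ph$field, ph$rois, params,
                     cutoff_fraction = 0.1,
                     cone_spec = list(axis = c(0, 0, 1), half_angle_deg = 45))
    if (res$accepted) break
  }
  expect_true(res$accepted)
  sl <- res$streamline
  len <- sum(sqrt(rowSums(diff(sl)^2)))
  e2e <- sqrt(sum((sl[nrow(sl), ] - sl[1, ])^2))
  expect_lt(len / e2e, 1.1)
  expect_error(propagate(c(14, 14, 0), ph$field, ph$rois, params),
               "seed")
})

test_that("an exclusion wall rejects every crossing attempt", {
  ph <- fx_tracking_phantom()
  ph2 <- make_tracking_phantom(exclusion_wall = TRUE)
  params <- tracking_params(max_length_mm = 120,
                            max_amp = fodf_max_amplitude(ph2$field))
  set.seed(5)
  reasons <- character(30)
  for (i in 1:30) {
    res <- propagate(c(0, 0, -24), ph2$field, ph2$rois, params,
                     cutoff_fraction = 0.1,
                     cone_spec = list(axis = c(0, 0, 1), half_angle_deg = 45))
    expect_false(res$accepted)
    reasons[i] <- res$reason
  }
  expect_true("entered_exclusion" %in% reasons)
  expect_false(any(reasons == "accepted"))
})

test_that("a target adjacent to the seed yields a minimal streamline", {
  ph <- fx_tracking_phantom()
  rois <- ph$rois
  # move the target right on top of the seed's neighbouring slab
  g <- array(0, dim(ph$template$grid))
  idx <- which(rois$seed$grid != 0, arr.ind = TRUE)
  g[cbind(idx[, 1], idx[, 2], idx[, 3] + 1L)] <- 1
  rois$targets <- list(mask3(g, ph$template$affine))
  params <- tracking_params(max_amp = fodf_max_amplitude(ph$field))
  set.seed(6)
  res <- propagate(c(0, 0, -24), ph$field, rois, params, cutoff_fraction = 0.1,
                   cone_spec = list(axis = c(0, 0, 1), half_angle_deg = 45))
  expect_true(res$accepted)
  expect_lte(nrow(res$streamline), 12)     # about one voxel of travel
})

test_that("tracked streamlines honour the seed/target/step/curvature contract", {
  sls <- fx_tracked_bundle()
  ph <- fx_tracking_phantom()
  expect_length(sls$streamlines, 50L)
  starts <- do.call(rbind, lapply(sls$streamlines, function(s) s[1, , drop = FALSE]))
  ends <- do.call(rbind, lapply(sls$streamlines, function(s) s[nrow(s), , drop = FALSE]))
  expect_true(all(points_in_mask(starts, ph$rois$seed)))
  expect_true(all(points_in_mask(ends, ph$rois$targets[[1]])))
  limit <- max_step_angle(0.2, 1)
  for (s in sls$streamlines) {
    seg <- diff(s)
    expect_lt(max(abs(sqrt(rowSums(seg^2)) - 0.2)), 1e-6)
    u <- seg / sqrt(rowSums(seg^2))
    if (nrow(u) > 1) {
      cosang <- rowSums(u[-1, , drop = FALSE] * u[-nrow(u), , drop = FALSE])
      expect_lte(max(acos(pmin(pmax(cosang, -1), 1))) * 180 / pi,
                 limit + 1e-9)
    }
  }
})

test_that("tracking is bit-identical under a fixed seed", {
  ph <- fx_tracking_phantom()
  a <- track(bundle_protocol(8L), ph$field, ph$rois, seed = 21L)
  b <- track(bundle_protocol(8L), ph$field, ph$rois, seed = 21L)
  expect_identical(a$streamlines, b$streamlines)
})

test_that("raising the amplitude cutoff shrinks the acceptable direction set", {
  # direction-level monotonicity: the per-call success probability of the
  # sampler is non-increasing in the cutoff, and a cutoff above the lobe
  # peak admits nothing
  dirs200 <- fibonacci_sphere(200)
  cf <- as.vector(sh_projector(dirs200, 8) %*% exp(12 * (dirs200[, 3]^2 - 1)))
  coef <- array(rep(cf, each = 27), c(3, 3, 3, 45))
  f <- fodf_field(coef, 8L, diag(4))
  params <- tracking_params(trials_per_step = 20L,
                            max_amp = fodf_max_amplitude(f))
  success_rate <- function(cutoff) {
    set.seed(30)
    mean(vapply(1:300, function(i)
      !is.null(sample_direction(f, c(1, 1, 1), cutoff_fraction = cutoff,
                                params = params)), logical(1)))
  }
  rates <- vapply(c(0.05, 0.4, 0.8, 0.98), success_rate, numeric(1))
  expect_true(all(diff(rates) <= 0.05))
  # near the lobe peak the acceptable set is a narrow cone: success within
  # the same trial budget drops far below the permissive-cutoff rate
  expect_lt(rates[4], rates[1] - 0.3)

  # streamline-level: a permissive cutoff tracks; a cutoff at the lobe peak
  # admits (nearly) nothing within a small budget
  ph <- make_tracking_phantom(size = "short")
  low <- track(bundle_protocol(999L, amplitude_cutoff_fraction = 0.05,
                               max_length_mm = 60,
                               max_attempts_per_seed = 10L),
               ph$field, ph$rois, seed = 8L)
  expect_gt(low$meta$acceptance_rate, 0.1)
  high <- tryCatch(track(bundle_protocol(999L,
                                         amplitude_cutoff_fraction = 0.99,
                                         max_length_mm = 60,
                                         max_attempts_per_seed = 10L),
                         ph$field, ph$rois, seed = 8L),
                   error = function(e) NULL)
  high_rate <- if (is.null(high)) 0 else high$meta$acceptance_rate
  expect_lt(high_rate, low$meta$acceptance_rate / 2)
})

test_that("an unreachable target fails with the dominant rejection reason", {
  ph <- make_tracking_phantom(exclusion_wall = TRUE)
  expect_error(track(bundle_protocol(5L, max_attempts_per_seed = 15L),
                     ph$field, ph$rois, seed = 9L),
               "dominant rejection")
})
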