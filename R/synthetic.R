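# Synthetic phantom generators: a schematic labelled "head" containing every
# structure the six tract protocols reference, analytic bundle centerlines
# connecting each tract's seed to its target, fODF fields concentrated along
# those centerlines, streamline bundles with injected spurious fibres, and
# jittered multi-subject cohorts. Anatomy is deliberately schematic (boxes
# and tubes in anatomically plausible relative positions); the phantoms test
# the computation, not anatomy.

#' Default phantom specification
#'
#' A 40 x 48 x 40 grid of 2 mm isotropic voxels (world extents roughly
#' x,z in [-40, 40] mm, y in [-48, 48] mm, RAS+). Structures are axis-aligned
#' boxes; per-hemisphere structures are specified for the right hemisphere
#' (x > 0) and mirrored. All structures are pairwise disjoint.
#'
#' @return A phantom spec list (`dim`, `voxel_mm`, `structures`).
#' @export
default_phantom_spec <- function() {
  box <- function(x1, x2, y1, y2, z1, z2)
    matrix(c(x1, x2, y1, y2, z1, z2), nrow = 2L)
  structures <- list(
    # midline / unpaired
    list(name = "brainstem",            hemi = FALSE, box = box(-8, 8, -12, 4, -36, -12)),
    list(name = "fourth_ventricle",     hemi = FALSE, box = box(-4, 4, -16, -12, -30, -18)),
    list(name = "basal_forebrain",      hemi = FALSE, box = box(-8, 8, 4, 10, -10, -4)),
    list(name = "corpus_callosum_genu", hemi = FALSE, box = box(-4, 4, 8, 14, 0, 8)),
    # paired (right-hemisphere boxes; left is the x-mirror)
    list(name = "thalamus",                 hemi = TRUE, box = box(6, 16, -10, 0, -8, 4)),
    list(name = "lgn",                      hemi = TRUE, box = box(16, 20, -14, -10, -6, -2)),
    list(name = "putamen",                  hemi = TRUE, box = box(16, 22, -6, 6, -6, 6)),
    list(name = "posterior_insula",         hemi = TRUE, box = box(26, 30, -6, 2, -6, 6)),
    list(name = "anterior_insula",          hemi = TRUE, box = box(26, 30, 2, 10, -6, 6)),
    list(name = "precentral_gyrus",         hemi = TRUE, box = box(10, 30, 2, 10, 8, 32)),
    list(name = "pars_opercularis",         hemi = TRUE, box = box(20, 28, 10, 16, 0, 10)),
    list(name = "pars_triangularis",        hemi = TRUE, box = box(20, 28, 16, 22, 0, 10)),
    list(name = "pars_orbitalis",           hemi = TRUE, box = box(18, 26, 22, 28, -8, 0)),
    list(name = "anterior_orbital_gyrus",   hemi = TRUE, box = box(8, 16, 26, 34, -10, -2)),
    list(name = "posterior_orbital_gyrus",  hemi = TRUE, box = box(8, 16, 18, 26, -10, -2)),
    list(name = "frontal_pole",             hemi = TRUE, box = box(2, 14, 36, 44, -4, 12)),
    list(name = "sma",                      hemi = TRUE, box = box(2, 10, -6, 6, 26, 34)),
    list(name = "pre_sma",                  hemi = TRUE, box = box(2, 10, 6, 18, 26, 34)),
    list(name = "superior_temporal_gyrus",  hemi = TRUE, box = box(22, 32, -30, 6, -14, -6)),
    list(name = "middle_temporal_gyrus",    hemi = TRUE, box = box(22, 32, -30, 6, -22, -14)),
    list(name = "supramarginal_gyrus",      hemi = TRUE, box = box(22, 32, -28, -18, 10, 22)),
    list(name = "angular_gyrus",            hemi = TRUE, box = box(22, 32, -38, -30, 10, 22)),
    list(name = "calcarine_cortex",         hemi = TRUE, box = box(2, 8, -44, -36, -4, 4)),
    list(name = "precuneus",                hemi = TRUE, box = box(2, 10, -38, -28, 14, 24)),
    list(name = "lingual_gyrus",            hemi = TRUE, box = box(2, 10, -44, -36, -14, -6)),
    list(name = "inferior_occipital_gyrus", hemi = TRUE, box = box(10, 20, -46, -38, -16, -8)),
    list(name = "middle_occipital_gyrus",   hemi = TRUE, box = box(10, 20, -46, -38, -8, 0)),
    list(name = "superior_occipital_gyrus", hemi = TRUE, box = box(10, 20, -46, -38, 0, 8))
  )
  list(dim = c(40L, 48L, 40L), voxel_mm = 2,
       brain_box = matrix(c(-36, 36, -48, 48, -38, 36), nrow = 2L),
       structures = structures)
}

phantom_affine <- function(spec) {
  v <- spec$voxel_mm
  aff <- diag(c(v, v, v, 1))
  aff[1:3, 4] <- -v * (spec$dim - 1) / 2
  aff
}

#' Build the labelled phantom parcellation
#'
#' Paints each structure's box into an integer grid (per-hemisphere
#' structures as mirrored `_L`/`_R` pairs), checks pairwise disjointness,
#' and fills the remaining brain volume with a `white_matter` label.
#'
#' @param spec Phantom spec; see [default_phantom_spec()].
#' @return A [label_volume] including the `white_matter` label.
#' @export
make_phantom <- function(spec = default_phantom_spec()) {
  dm <- spec$dim
  aff <- phantom_affine(spec)
  idx <- as.matrix(expand.grid(x = 0:(dm[1] - 1), y = 0:(dm[2] - 1),
                               z = 0:(dm[3] - 1)))
  w <- voxel_to_world(idx, aff)
  grid <- array(0L, dm)
  labels <- integer(0)
  next_label <- 1L
  paint <- function(grid, box, label) {
    inside <- w[, 1] >= box[1, 1] & w[, 1] < box[2, 1] &
              w[, 2] >= box[1, 2] & w[, 2] < box[2, 2] &
              w[, 3] >= box[1, 3] & w[, 3] < box[2, 3]
    if (any(grid[inside] != 0L))
      stop("phantom structures overlap at label ", label, call. = FALSE)
    grid[inside] <- label
    grid
  }
  mirror_box <- function(box) {
    out <- box
    out[1, 1] <- -box[2, 1]
    out[2, 1] <- -box[1, 1]
    out
  }
  for (s in spec$structures) {
    if (s$hemi) {
      for (side in c("R", "L")) {
        b <- if (side == "R") s$box else mirror_box(s$box)
        nm <- paste0(s$name, "_", side)
        labels[nm] <- next_label
        grid <- paint(grid, b, next_label)
        next_label <- next_label + 1L
      }
    } else {
      labels[s$name] <- next_label
      grid <- paint(grid, s$box, next_label)
      next_label <- next_label + 1L
    }
  }
  bb <- spec$brain_box
  brain <- w[, 1] >= bb[1, 1] & w[, 1] < bb[2, 1] &
           w[, 2] >= bb[1, 2] & w[, 2] < bb[2, 2] &
           w[, 3] >= bb[1, 3] & w[, 3] < bb[2, 3]
  wm <- brain & grid == 0L
  labels["white_matter"] <- next_label
  grid[wm] <- next_label
  label_volume(grid, aff, labels)
}

#' Analytic bundle centerlines for the six shipped tracts
#'
#' Smooth curves (cubic splines through control points, sampled at the given
#' spacing) connecting each tract's seed to its target through anatomically
#' plausible waypoints, e.g. the corticospinal line rising from the anterior
#' brainstem to the precentral gyrus and the optic radiation leaving the LGN
#' laterally before sweeping back to the calcarine cortex.
#'
#' @param hemisphere `"left"` or `"right"`.
#' @param spacing_mm Sample spacing along each curve.
#' @return Named list of n x 3 point matrices (CST, IFOF, OR, AF, FAT, SLF3).
#' @export
default_centerlines <- function(hemisphere = c("left", "right"),
                                spacing_mm = 1) {
  hemisphere <- match.arg(hemisphere)
  s <- if (hemisphere == "right") 1 else -1
  ctrl <- list(
    CST  = cbind(s * c(4, 6, 12, 18, 20),
                 c(0, 2, 4, 6, 6),
                 c(-26, -8, 8, 20, 30)),
    IFOF = cbind(s * c(22, 23, 23, 20, 15, 15),
                 c(18, 8, -1, -14, -30, -42),
                 c(4, 0, -1, -2, -4, -4)),
    # frontal fan of the IFOF: branches from the frontal pole and the
    # orbital gyri joining the main trunk
    IFOF_frontal = cbind(s * c(8, 16, 22, 23),
                         c(40, 30, 18, 8),
                         c(4, 4, 4, 0)),
    IFOF_orbital = cbind(s * c(12, 18, 22, 23, 23),
                         c(28, 26, 22, 14, 8),
                         c(-6, -5, -4, -2, 0)),
    OR   = cbind(s * c(18, 26, 24, 14, 5),
                 c(-12, -16, -28, -38, -40),
                 c(-4, -2, 0, 0, 0)),
    AF   = cbind(s * c(24, 27, 28, 28, 27),
                 c(14, 6, -8, -16, -12),
                 c(6, 14, 18, 4, -7)),
    FAT  = cbind(s * c(6, 10, 16, 22),
                 c(2, 8, 12, 14),
                 c(30, 24, 16, 6)),
    SLF3 = cbind(s * c(24, 26, 27, 27),
                 c(12, 0, -12, -22),
                 c(8, 12, 16, 16))
  )
  lapply(ctrl, resample_curve, spacing_mm = spacing_mm)
}

# cubic-spline resample of a control polygon at uniform arc-length spacing
resample_curve <- function(ctrl, spacing_mm = 1) {
  seg <- sqrt(rowSums(diff(ctrl)^2))
  t0 <- c(0, cumsum(seg))
  total <- t0[length(t0)]
  tt <- seq(0, total, by = spacing_mm)
  if (tt[length(tt)] < total) tt <- c(tt, total)
  out <- sapply(1:3, function(k)
    stats::spline(t0, ctrl[, k], xout = tt, method = "natural")$y)
  matrix(out, ncol = 3L)
}

#' Build an fODF field concentrated along bundle centerlines
#'
#' Each voxel within `tube_radius_mm` of a centerline receives an antipodal
#' orientation lobe `exp(kappa ((d . t)^2 - 1))` along the local tangent `t`
#' of the nearest centerline sample, weighted by a Gaussian radial falloff;
#' voxels near several centerlines superpose lobes (crossing-fibre
#' configurations arise naturally). A small isotropic background is added
#' inside the domain mask, and optional orientation noise adds a weak
#' random-direction lobe per voxel. The resulting spherical function is
#' projected onto the real even-order SH basis by least squares.
#'
#' @param centerlines List of n x 3 world-mm polylines.
#' @param template A [scalar_map] or [label_volume] defining grid and affine.
#' @param lobe_sharpness Orientation concentration `kappa` of each lobe.
#' @param background Isotropic background amplitude relative to the unit lobe
#'   peak.
#' @param tube_radius_mm Lobe support radius around each centerline.
#' @param lmax SH order of the output field.
#' @param domain Optional binary mask restricting background support;
#'   defaults to the whole grid.
#' @param noise Amplitude of per-voxel random-direction noise lobes (0 = none).
#' @param noise_seed RNG seed for the noise lobes.
#' @param weights Per-centerline lobe weights (default 1 for each); weaker
#'   bundles get proportionally lower amplitude.
#' @return A [fodf_field].
#' @export
make_fodf <- function(centerlines, template, lobe_sharpness = 12,
                      background = 0.02, tube_radius_mm = 3, lmax = 8,
                      domain = NULL, noise = 0, noise_seed = 1L,
                      weights = NULL) {
  if (!length(centerlines)) stop("no centerlines given", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(centerlines))
  if (length(weights) != length(centerlines))
    stop("weights must match centerlines", call. = FALSE)
  dm <- dim(template$grid)
  aff <- template$affine
  nvox <- prod(dm)
  vdim <- voxel_dims_mm(aff)
  sigma_r <- tube_radius_mm / 2

  # per centerline: nearest-sample distance and tangent for voxels in tube
  lobes <- list()   # each: list(lin, w, tangent)
  for (ci in seq_along(centerlines)) {
    cl <- centerlines[[ci]]
    if (nrow(cl) < 3L) stop("centerline needs at least 3 points", call. = FALSE)
    tang <- rbind(cl[2, ] - cl[1, ],
                  cl[-(1:2), , drop = FALSE] - cl[1:(nrow(cl) - 2), , drop = FALSE],
                  cl[nrow(cl), ] - cl[nrow(cl) - 1, ])
    tang <- tang / sqrt(rowSums(tang^2))
    best_d2 <- rep(Inf, nvox)
    best_i <- rep(NA_integer_, nvox)
    rad_vox <- ceiling(tube_radius_mm / vdim)
    offs <- as.matrix(expand.grid(dx = -rad_vox[1]:rad_vox[1],
                                  dy = -rad_vox[2]:rad_vox[2],
                                  dz = -rad_vox[3]:rad_vox[3]))
    for (i in seq_len(nrow(cl))) {
      cvox <- floor(world_to_voxel(cl[i, , drop = FALSE], aff) + 0.5)
      cand <- sweep(offs, 2L, as.integer(cvox), "+")
      lin <- voxel_linear(cand, dm)
      ok <- !is.na(lin)
      if (!any(ok)) next
      cand <- cand[ok, , drop = FALSE]; lin <- lin[ok]
      cw <- voxel_to_world(cand, aff)
      d2 <- colSums((t(cw) - cl[i, ])^2)
      upd <- d2 < best_d2[lin] & d2 <= tube_radius_mm^2
      if (any(upd)) {
        best_d2[lin[upd]] <- d2[upd]
        best_i[lin[upd]] <- i
      }
    }
    act <- which(is.finite(best_d2))
    if (length(act))
      lobes[[length(lobes) + 1L]] <-
        list(lin = act,
             w = weights[ci] * exp(-best_d2[act] / (2 * sigma_r^2)),
             tangent = tang[best_i[act], , drop = FALSE])
  }

  dirs <- fibonacci_sphere(100L)
  proj <- sh_projector(dirs, lmax)
  active <- sort(unique(unlist(lapply(lobes, `[[`, "lin"))))
  coef <- matrix(0, nvox, sh_ncoef(lmax))
  if (length(active)) {
    f <- matrix(0, length(active), nrow(dirs))
    for (lb in lobes) {
      rows <- match(lb$lin, active)
      dots2 <- (lb$tangent %*% t(dirs))^2
      f[rows, ] <- f[rows, ] + lb$w * exp(lobe_sharpness * (dots2 - 1))
    }
    coef[active, ] <- f %*% t(proj)
  }
  if (noise > 0) {
    withr::with_seed(as.integer(noise_seed), {
      dom_lin <- if (is.null(domain)) seq_len(nvox) else which(domain$grid != 0)
      nd <- length(dom_lin)
      ndirs <- matrix(stats::rnorm(3 * nd), ncol = 3L)
      ndirs <- ndirs / sqrt(rowSums(ndirs^2))
      wts <- stats::runif(nd, 0, noise)
      fn <- wts * exp(lobe_sharpness * ((ndirs %*% t(dirs))^2 - 1))
      coef[dom_lin, ] <- coef[dom_lin, ] + fn %*% t(proj)
    })
  }
  if (background > 0) {
    dom_lin <- if (is.null(domain)) seq_len(nvox) else which(domain$grid != 0)
    coef[dom_lin, 1] <- coef[dom_lin, 1] + background * sqrt(4 * pi)
  }
  fodf_field(array(coef, c(dm, sh_ncoef(lmax))), lmax, aff)
}

#' Default phantom fODF field for the six shipped tracts
#'
#' Convenience wrapper: builds the field from both hemispheres' default
#' centerlines on the default phantom grid, with background support inside
#' the brain (so propagation terminates outside).
#'
#' @param vol Phantom [label_volume] from [make_phantom()].
#' @param hemispheres Which hemispheres' centerlines to include.
#' @param ... Passed to [make_fodf()].
#' @return A [fodf_field].
#' @export
default_phantom_fodf <- function(vol = make_phantom(),
                                 hemispheres = c("left", "right"), ...) {
  cls <- unlist(lapply(hemispheres, default_centerlines), recursive = FALSE)
  brain <- scalar_map(array(as.numeric(vol$grid != 0), dim(vol$grid)),
                      vol$affine, "binary")
  make_fodf(cls, vol, domain = brain, ...)
}

#' Straight-bundle tracking phantom
#'
#' A minimal phantom for exercising the tracker contract: a straight bundle
#' along +z on a small grid, a seed box at the bottom end, a target wall at
#' the top, and optionally an exclusion wall fully crossing the bundle
#' between them.
#'
#' @param exclusion_wall Insert an exclusion wall at the bundle midpoint.
#' @param noise,noise_seed Orientation noise passed to [make_fodf()].
#' @param lobe_sharpness Lobe concentration of the bundle fODF.
#' @param background Isotropic background amplitude; raised above the
#'   tracker's amplitude cutoff it lets stray streamlines wander off the
#'   bundle and occasionally reach the target at random positions --
#'   isolated spurious members of the tractogram.
#' @param background_radius_mm Radius of the cylindrical background support
#'   around the bundle axis; strays leaving it terminate.
#' @param distractors Number of weak off-axis distractor corridors that
#'   branch from the bundle and also reach the target; streamlines that
#'   stray into one become spatially isolated deviating members of the
#'   tractogram (the kind of spurious streamline FBC filtering removes).
#' @param distractor_weight Lobe weight of the distractor corridors
#'   relative to the main bundle.
#' @param size `"long"` (60 mm grid, ~45 mm seed-to-target span) or
#'   `"short"` (32 mm grid) for cheaper repeated runs.
#' @return List with `field` ([fodf_field]), `rois` (seed/targets/excludes
#'   lists of binary [scalar_map]s), `centerline`, `template`.
#' @export
make_tracking_phantom <- function(exclusion_wall = FALSE, noise = 0,
                                  noise_seed = 1L, lobe_sharpness = 12,
                                  background = 0.02, background_radius_mm = Inf,
                                  distractors = 0L, distractor_weight = 0.3,
                                  size = c("long", "short")) {
  size <- match.arg(size)
  dm <- if (size == "long") c(16L, 16L, 30L) else c(16L, 16L, 16L)
  v <- 2
  aff <- diag(c(v, v, v, 1))
  aff[1:3, 4] <- -v * (dm - 1) / 2
  template <- scalar_map(array(0, dm), aff, "density")
  zmax <- v * (dm[3] - 1) / 2
  centerline <- cbind(0, 0, seq(-zmax + 2, zmax - 2, by = 1))
  box_mask <- function(x1, x2, y1, y2, z1, z2) {
    idx <- as.matrix(expand.grid(x = 0:(dm[1] - 1), y = 0:(dm[2] - 1),
                                 z = 0:(dm[3] - 1)))
    w <- voxel_to_world(idx, aff)
    inside <- w[, 1] >= x1 & w[, 1] < x2 & w[, 2] >= y1 & w[, 2] < y2 &
              w[, 3] >= z1 & w[, 3] < z2
    scalar_map(array(as.numeric(inside), dm), aff, "binary")
  }
  seed <- box_mask(-2, 2, -2, 2, -zmax + 3, -zmax + 9)
  # target spans the whole cross-section so that deviating stray paths can
  # also terminate there (they are what the FBC filter removes)
  target <- box_mask(-16, 16, -16, 16, zmax - 9, zmax - 3)
  excludes <- list()
  if (exclusion_wall)
    excludes <- list(box_mask(-16, 16, -16, 16, -2, 2))
  cls <- list(centerline)
  weights <- 1
  if (distractors > 0L) {
    # corridors leave from the tube fringe (not the core) so only a small,
    # run-varying number of streamlines slide into one
    for (k in seq_len(distractors)) {
      phi <- 2 * pi * (k - 1) / distractors + pi / 4
      rr <- c(2.5, 6, 11, 12.5, 12.5)
      branch <- cbind(rr * cos(phi), rr * sin(phi),
                      c(-16, -6, 6, 14, 23))
      cls[[length(cls) + 1L]] <- resample_curve(branch, spacing_mm = 1)
      weights <- c(weights, distractor_weight)
    }
  }
  domain <- NULL
  if (is.finite(background_radius_mm)) {
    idx <- as.matrix(expand.grid(x = 0:(dm[1] - 1), y = 0:(dm[2] - 1),
                                 z = 0:(dm[3] - 1)))
    w <- voxel_to_world(idx, aff)
    cyl <- w[, 1]^2 + w[, 2]^2 <= background_radius_mm^2
    domain <- scalar_map(array(as.numeric(cyl), dm), aff, "binary")
  }
  field <- make_fodf(cls, template,
                     lobe_sharpness = lobe_sharpness, weights = weights,
                     background = background, domain = domain,
                     noise = noise, noise_seed = noise_seed)
  list(field = field, rois = list(seed = seed, targets = list(target),
                                  excludes = excludes, includes = list()),
       centerline = centerline, template = template)
}

#' Minimal protocol for the straight-bundle phantom
#' @param n_streamlines Streamline count.
#' @param rfbc_threshold RFBC filter setting.
#' @param ... Overrides passed to [tract_protocol()].
#' @return A [tract_protocol()] whose ROI recipes are unused (ROIs come from
#'   [make_tracking_phantom()]).
#' @export
bundle_protocol <- function(n_streamlines = 50L, rfbc_threshold = "none", ...) {
  args <- utils::modifyList(
    list(name = "bundle", seed = NULL, targets = list(),
         n_streamlines = n_streamlines,
         amplitude_cutoff_fraction = 0.1,
         rfbc_threshold = rfbc_threshold, hemisphere = "left",
         max_length_mm = 120),
    list(...))
  do.call(tract_protocol, args)
}

#' Generate a coherent streamline bundle along a centerline
#'
#' Streamlines are parallel transports of the centerline offset on a regular
#' lattice within a tube cross-section, plus optional smooth transverse
#' jitter.
#'
#' @param centerline n x 3 world-mm polyline.
#' @param n Number of streamlines.
#' @param tube_radius_mm Bundle radius.
#' @param jitter_mm Standard deviation of smooth transverse jitter (0 = none).
#' @param seed RNG seed.
#' @return A [streamline_set] with `meta$ground_truth = "coherent"` flags.
#' @export
make_bundle <- function(centerline, n, tube_radius_mm = 2, jitter_mm = 0,
                        seed = 1L) {
  stopifnot(n > 0)
  # orthonormal frame at each point (normal/binormal of smoothed tangent)
  tang <- resample_curve(centerline, spacing_mm = 1)
  cl <- tang
  tv <- rbind(cl[2, ] - cl[1, ],
              cl[-(1:2), , drop = FALSE] - cl[1:(nrow(cl) - 2), , drop = FALSE],
              cl[nrow(cl), ] - cl[nrow(cl) - 1, ])
  tv <- tv / sqrt(rowSums(tv^2))
  ref <- if (abs(tv[1, 3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- t(apply(tv, 1, function(t) {
    v <- ref - sum(ref * t) * t
    v / sqrt(sum(v^2))
  }))
  e2 <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
              tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
              tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
  # regular lattice of offsets within the tube cross-section
  k <- ceiling(sqrt(n))
  g <- seq(-tube_radius_mm, tube_radius_mm, length.out = max(k, 2))
  lattice <- as.matrix(expand.grid(u = g, v = g))
  lattice <- lattice[order(rowSums(lattice^2)), , drop = FALSE]
  lattice <- lattice[seq_len(n), , drop = FALSE]
  withr::with_seed(as.integer(seed), {
    sls <- lapply(seq_len(n), function(i) {
      off_u <- lattice[i, 1]; off_v <- lattice[i, 2]
      if (jitter_mm > 0) {
        # smooth jitter: low-frequency sinusoids with random phase/amplitude
        tpar <- seq(0, 1, length.out = nrow(cl))
        off_u <- off_u + jitter_mm * sum(stats::rnorm(1)) *
          sin(2 * pi * (tpar + stats::runif(1)))
        off_v <- off_v + jitter_mm * stats::rnorm(1) *
          sin(2 * pi * (tpar + stats::runif(1)))
      }
      cl + off_u * e1 + off_v * e2
    })
    streamline_set(sls, meta = list(ground_truth = rep("coherent", n),
                                    seed = seed))
  })
}

#' Inject spurious streamlines into a set
#'
#' Adds `round(fraction * n)` straight streamlines that are far from the
#' originals (beyond `min_distance_mm`) and/or near-orthogonal to the set's
#' mean orientation; every streamline carries a coherent/spurious
#' ground-truth flag in `meta$ground_truth`.
#'
#' @param set A [streamline_set].
#' @param fraction Fraction in `[0, 1)` of `length(set)` to add.
#' @param min_distance_mm Minimum separation of injected midpoints from all
#'   original points.
#' @param seed RNG seed.
#' @return A [streamline_set] with ground-truth labels.
#' @export
inject_spurious <- function(set, fraction, min_distance_mm = 10, seed = 1L) {
  if (fraction < 0 || fraction >= 1)
    stop("fraction must be in [0, 1)", call. = FALSE)
  n0 <- length(set$streamlines)
  n_add <- round(fraction * n0)
  gt <- set$meta$ground_truth %||% rep("coherent", n0)
  if (n_add == 0L) {
    set$meta$ground_truth <- gt
    return(set)
  }
  allpts <- do.call(rbind, set$streamlines)
  centre <- colMeans(allpts)
  # mean orientation of the set (principal axis of tangents)
  tangs <- do.call(rbind, lapply(set$streamlines, function(s) {
    d <- diff(s); d / sqrt(rowSums(d^2))
  }))
  main_axis <- eigen(crossprod(tangs))$vectors[, 1]
  perp <- if (abs(main_axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  perp <- perp - sum(perp * main_axis) * main_axis
  perp <- perp / sqrt(sum(perp^2))
  len <- mean(vapply(set$streamlines, function(s)
    sum(sqrt(rowSums(diff(s)^2))), numeric(1)))
  withr::with_seed(as.integer(seed), {
    binormal <- c(main_axis[2] * perp[3] - main_axis[3] * perp[2],
                  main_axis[3] * perp[1] - main_axis[1] * perp[3],
                  main_axis[1] * perp[2] - main_axis[2] * perp[1])
    added <- lapply(seq_len(n_add), function(i) {
      # each injected streamline is offset radially from the bundle axis
      # (every one of its points stays beyond the offset), runs orthogonally
      # to the bundle, and differs from its fellows in azimuth and axial
      # position so the injected set is mutually incoherent as well
      phi <- 2 * pi * (i - 1) / n_add
      u_i <- cos(phi) * perp + sin(phi) * binormal
      v_i <- -sin(phi) * perp + cos(phi) * binormal
      off <- min_distance_mm + 4 + stats::runif(1, 0, 8)
      axial <- (if (i %% 2 == 0) 1 else -1) * (len / 2 + 5 + 2 * i)
      mid <- centre + off * u_i + axial * main_axis
      npts <- max(nrow(set$streamlines[[1]]), 5L)
      tt <- seq(-len / 2, len / 2, length.out = npts)
      t(vapply(tt, function(s) mid + s * v_i, numeric(3)))
    })
  })
  streamline_set(c(set$streamlines, added),
                 meta = utils::modifyList(set$meta, list(
                   ground_truth = c(gt, rep("spurious", n_add)))))
}

#' Generate a jittered multi-subject cohort from a base phantom
#'
#' Each subject is a copy of the base phantom resampled under a small random
#' rigid-plus-scale affine (the anatomical jitter); the exact inverse affine
#' is returned as the subject's normalisation transform back to base space.
#' The subject fODF is regenerated from the affine-transformed centerlines,
#' which keeps the orientation content consistent with the deformed anatomy.
#'
#' @param n_subjects Number of subjects.
#' @param base_vol Base [label_volume] (default phantom).
#' @param jitter_mm SD of random translations (mm).
#' @param jitter_deg SD of random rotations about each axis (degrees).
#' @param jitter_scale SD of the isotropic log-scale perturbation.
#' @param seed RNG seed.
#' @param centerlines Optional centerlines for fODF regeneration; `NULL`
#'   skips fODF generation (volumes and transforms only).
#' @param fodf_args List of extra arguments for [make_fodf()].
#' @return List of subjects, each `(vol, fodf, transform)` with `transform`
#'   the [spatial_transform] mapping subject space to base space.
#' @export
make_cohort <- function(n_subjects, base_vol = make_phantom(), jitter_mm = 0,
                        jitter_deg = 0, jitter_scale = 0, seed = 1L,
                        centerlines = NULL, fodf_args = list()) {
  stopifnot(n_subjects >= 1)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_subjects), function(i) {
      if (jitter_mm == 0 && jitter_deg == 0 && jitter_scale == 0) {
        A <- diag(4)
      } else {
        ang <- stats::rnorm(3, 0, jitter_deg) * pi / 180
        sc <- exp(stats::rnorm(1, 0, jitter_scale))
        tr <- stats::rnorm(3, 0, jitter_mm)
        Rx <- rot3(1, ang[1]); Ry <- rot3(2, ang[2]); Rz <- rot3(3, ang[3])
        A <- diag(4)
        A[1:3, 1:3] <- sc * (Rz %*% Ry %*% Rx)
        A[1:3, 4] <- tr
      }
      fwd <- spatial_transform(if (all(A == diag(4))) "identity" else "affine",
                               if (all(A == diag(4))) NULL else A,
                               direction = "base->subject")
      vol <- apply_transform(base_vol, fwd)
      back <- if (fwd$kind == "identity") fwd else invert_transform(fwd)
      back$direction <- "subject->base"
      fodf <- NULL
      if (!is.null(centerlines)) {
        sub_cls <- lapply(centerlines, transform_points, transform = fwd)
        fodf <- do.call(make_fodf, c(list(centerlines = sub_cls,
                                          template = vol), fodf_args))
      }
      list(vol = vol, fodf = fodf, transform = back)
    })
  })
}

rot3 <- function(axis, theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  m <- diag(3)
  ix <- setdiff(1:3, axis)
  m[ix[1], ix[1]] <- c_; m[ix[2], ix[2]] <- c_
  m[ix[1], ix[2]] <- -s_; m[ix[2], ix[1]] <- s_
  m
}
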