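# Geometric mask operators used by the tract protocols. All operate on
# binary scalar_maps in world mm; axes follow RAS+ (x: left->right,
# y: posterior->anterior, z: inferior->superior).

axis_column <- function(axis) switch(axis, LR = 1L, AP = 2L, IS = 3L,
                                     stop("axis must be AP, IS or LR", call. = FALSE))

# which end of the axis a side keeps: +1 = high-coordinate end
side_sign <- function(side) switch(side,
  anterior = , superior = , right = +1,
  posterior = , inferior = , left = -1,
  stop("unknown side: ", side, call. = FALSE))

#' Union mask of named labels
#'
#' @param vol A [label_volume].
#' @param names Character vector of structure names; an empty vector yields an
#'   empty mask.
#' @return Binary [scalar_map] of the union of the named labels.
#' @export
select_labels <- function(vol, names) {
  unknown <- setdiff(names, names(vol$labels))
  if (length(unknown))
    stop("unresolvable label name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vals <- vol$labels[names]
  grid <- array(as.numeric(vol$grid %in% vals), dim = dim(vol$grid))
  scalar_map(grid, vol$affine, "binary")
}

#' Keep one side of a mask split by a plane along an anatomical axis
#'
#' The plane is placed along the given axis at `fraction` of the mask's
#' bounding extent, measured from the edge opposite the kept side, so
#' `fraction = 0.5` bisects the bounding box and `fraction = 0` keeps the
#' whole mask.
#'
#' @param mask Non-empty binary [scalar_map].
#' @param axis `"AP"`, `"IS"` or `"LR"`.
#' @param side Which part to keep: `"anterior"`/`"posterior"` (AP),
#'   `"inferior"`/`"superior"` (IS), `"left"`/`"right"` (LR).
#' @param fraction Plane position as a fraction of the bounding extent.
#' @return Binary [scalar_map]. Voxels exactly on the plane belong to the
#'   high-coordinate side, so complementary calls at `fraction` and
#'   `1 - fraction` partition the mask.
#' @export
split_axis <- function(mask, axis = c("AP", "IS", "LR"), side, fraction = 0.5) {
  axis <- match.arg(axis)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]", call. = FALSE)
  w <- mask_world_coords(mask)
  if (nrow(w) == 0L) stop("split_axis: mask is empty", call. = FALSE)
  col <- axis_column(axis)
  coord <- w[, col]
  lo <- min(coord); hi <- max(coord)
  keep_high <- side_sign(side) > 0
  plane <- if (keep_high) lo + fraction * (hi - lo) else hi - fraction * (hi - lo)
  keep <- if (keep_high) coord >= plane else coord < plane
  mask_from_coords(w[keep, , drop = FALSE], mask)
}

#' Keep mask voxels within an axial slab centred on a reference structure
#'
#' The slab is centred at the midpoint of the reference mask's z-extent
#' (e.g. "the anatomical midpoint of the fourth ventricle") and spans
#' `thickness_mm` in total.
#'
#' @param mask Binary [scalar_map] to slice.
#' @param reference Non-empty binary [scalar_map] providing the z midpoint.
#' @param thickness_mm Total slab thickness in mm.
#' @return Binary [scalar_map]; a warning is emitted when the slab misses the
#'   mask entirely.
#' @export
axial_slab <- function(mask, reference, thickness_mm) {
  wref <- mask_world_coords(reference)
  if (nrow(wref) == 0L) stop("axial_slab: reference mask is empty", call. = FALSE)
  mid <- (min(wref[, 3]) + max(wref[, 3])) / 2
  w <- mask_world_coords(mask)
  keep <- abs(w[, 3] - mid) <= thickness_mm / 2
  if (!any(keep)) warning("axial slab does not intersect the mask", call. = FALSE)
  mask_from_coords(w[keep, , drop = FALSE], mask)
}

#' Dilate a mask with a Gaussian structuring element
#'
#' The mask's indicator is correlated with an unnormalised isotropic Gaussian
#' (value 1 at zero distance): each voxel receives
#' `max over mask voxels q of exp(-||p - q||^2 / (2 sigma^2))`, and the
#' result is thresholded at `threshold`. This dilates the mask by a shell of
#' width `sigma * sqrt(2 log(1/threshold))` (about `1.55 sigma` at the
#' default threshold) and is monotone in `sigma`. The original mask is always
#' retained; if a constraint mask is supplied, the result is intersected with
#' it (the original mask within the constraint is retained).
#'
#' @param mask Binary [scalar_map].
#' @param sigma_mm Gaussian standard deviation in mm (> 0).
#' @param constraint Optional binary [scalar_map] (e.g. grey matter) limiting
#'   the dilation.
#' @param threshold Kernel value cutoff in (0, 1).
#' @return Binary [scalar_map] containing `mask` (intersected with the
#'   constraint, if given).
#' @export
gaussian_dilate <- function(mask, sigma_mm, constraint = NULL, threshold = 0.3) {
  if (sigma_mm <= 0) stop("sigma_mm must be positive", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)", call. = FALSE)
  w <- mask_world_coords(mask)
  if (nrow(w) == 0L) return(empty_like(mask))
  radius <- sigma_mm * sqrt(2 * log(1 / threshold))
  dm <- dim(mask$grid)
  # candidate voxels: everything within the dilation radius of the bounding box
  all_idx <- which(array(TRUE, dm), arr.ind = TRUE) - 1L
  all_w <- voxel_to_world(all_idx, mask$affine)
  bb_lo <- apply(w, 2, min) - radius; bb_hi <- apply(w, 2, max) + radius
  cand <- all_w[, 1] >= bb_lo[1] & all_w[, 1] <= bb_hi[1] &
          all_w[, 2] >= bb_lo[2] & all_w[, 2] <= bb_hi[2] &
          all_w[, 3] >= bb_lo[3] & all_w[, 3] <= bb_hi[3]
  grid <- array(0, dm)
  if (any(cand)) {
    cw <- all_w[cand, , drop = FALSE]
    # min squared distance to any mask voxel, chunked to bound memory
    keep <- logical(nrow(cw))
    chunk <- 4000L
    for (start in seq(1L, nrow(cw), chunk)) {
      end <- min(start + chunk - 1L, nrow(cw))
      block <- cw[start:end, , drop = FALSE]
      d2 <- outer(rowSums(block^2), rowSums(w^2), "+") - 2 * block %*% t(w)
      keep[start:end] <- apply(d2, 1, min) <= radius^2 + 1e-12
    }
    grid[which(cand)[keep]] <- 1
  }
  grid[mask$grid != 0] <- 1
  out <- scalar_map(grid, mask$affine, "binary")
  if (!is.null(constraint)) out <- mask_intersect(out, constraint)
  out
}

#' Spherical include region between two structures
#'
#' Places a ball of the given volume at the midpoint of the two masks'
#' centroids, with the centre snapped to the nearest constraint voxel
#' (ties broken by lowest linear index), e.g. a white-matter sphere between
#' the posterior insula and the putamen.
#'
#' @param maskA,maskB Non-empty binary [scalar_map]s.
#' @param volume_mm3 Ball volume in mm^3; radius is `(3 V / (4 pi))^(1/3)`.
#' @param constraint Non-empty binary [scalar_map] the centre snaps to.
#' @return Binary [scalar_map] of grid voxels whose centres lie within the
#'   ball.
#' @export
sphere_between <- function(maskA, maskB, volume_mm3, constraint) {
  wa <- mask_world_coords(maskA); wb <- mask_world_coords(maskB)
  wc <- mask_world_coords(constraint)
  if (!nrow(wa) || !nrow(wb) || !nrow(wc))
    stop("sphere_between: empty input mask", call. = FALSE)
  mid <- (colMeans(wa) + colMeans(wb)) / 2
  d2 <- colSums((t(wc) - mid)^2)
  # mask_world_coords enumerates voxels in ascending linear-index order and
  # which.min returns the first minimum, so ties break at the lowest index
  centre <- wc[which.min(d2), , drop = FALSE]
  r <- (3 * volume_mm3 / (4 * pi))^(1 / 3)
  dm <- dim(maskA$grid)
  all_idx <- which(array(TRUE, dm), arr.ind = TRUE) - 1L
  all_w <- voxel_to_world(all_idx, maskA$affine)
  inside <- colSums((t(all_w) - as.vector(centre))^2) <= r^2 + 1e-12
  grid <- array(as.numeric(inside), dm)
  scalar_map(grid, maskA$affine, "binary")
}

#' Split a mask by a coronal plane through a landmark
#'
#' The plane is placed at the landmark mask's anterior-most world y (e.g. a
#' vertical plane through the genu of the corpus callosum bounding the
#' pre-SMA anteriorly).
#'
#' @param mask Binary [scalar_map] to split.
#' @param landmark Non-empty binary [scalar_map] defining the plane.
#' @return List `(posterior, anterior)` of binary [scalar_map]s partitioning
#'   `mask`: `posterior` holds voxels with `y <= plane`, `anterior` the rest.
#' @export
split_by_plane <- function(mask, landmark) {
  wl <- mask_world_coords(landmark)
  if (nrow(wl) == 0L) stop("split_by_plane: landmark mask is empty", call. = FALSE)
  plane_y <- max(wl[, 2])
  w <- mask_world_coords(mask)
  post <- w[w[, 2] <= plane_y, , drop = FALSE]
  ant <- w[w[, 2] > plane_y, , drop = FALSE]
  list(posterior = mask_from_coords(post, mask),
       anterior = mask_from_coords(ant, mask))
}

#' ROI volume statistics across subjects
#'
#' Computes the mean and standard deviation of mask volumes across subjects,
#' and the coefficient of variation as a percentage (`100 * sd / mean`).
#'
#' @param masks List (>= 2) of binary [scalar_map]s, one per subject.
#' @return List with `mean_mm3`, `sd_mm3`, `sd_percent` (sample sd).
#' @export
roi_volume_stats <- function(masks) {
  if (length(masks) < 2L) stop("need at least 2 subjects", call. = FALSE)
  vols <- vapply(masks, function(m) sum(m$grid != 0) * voxel_volume_mm3(m$affine),
                 numeric(1))
  m <- mean(vols); s <- stats::sd(vols)
  list(mean_mm3 = m, sd_mm3 = s,
       sd_percent = if (m > 0) 100 * s / m else 0)
}

# ---- small mask algebra -------------------------------------------------

#' Union / intersection of binary masks
#' @param a,b Binary [scalar_map]s on one grid.
#' @return Binary [scalar_map].
#' @export
mask_union <- function(a, b) {
  stopifnot(same_grid(a, b))
  scalar_map(array(as.numeric(a$grid != 0 | b$grid != 0), dim(a$grid)),
             a$affine, "binary")
}

#' @rdname mask_union
#' @export
mask_intersect <- function(a, b) {
  stopifnot(same_grid(a, b))
  scalar_map(array(as.numeric(a$grid != 0 & b$grid != 0), dim(a$grid)),
             a$affine, "binary")
}

# rebuild a binary mask from world coordinates of kept voxels
mask_from_coords <- function(w, template) {
  grid <- array(0, dim = dim(template$grid))
  if (nrow(w)) {
    idx <- world_to_nearest_voxel(w, template$affine)
    grid[voxel_linear(idx, dim(template$grid))] <- 1
  }
  scalar_map(grid, template$affine, "binary")
}
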