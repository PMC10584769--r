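# Spatial normalisation is consumed, never estimated: a transform arrives from
# outside (identity for phantoms, a known affine for synthetic cohorts) and is
# applied to maps and streamlines. Maps with binary/label roles are resampled
# nearest-neighbour so they stay binary; density/probability maps trilinear.

#' A consumed spatial transform
#'
#' @param kind `"identity"`, `"affine"` or `"displacement"`.
#' @param payload For `affine`: an invertible 4x4 matrix acting on world
#'   coordinates (source mm -> target mm). For `displacement`: a list with a
#'   4D array `field` (x,y,z,3) of mm displacement vectors added to source
#'   points, and the `affine` of the grid the field is sampled on.
#' @param direction Free-text note of what maps to what (e.g.
#'   `"subject->template"`); informational.
#' @return An object of class `spatial_transform`.
#' @export
spatial_transform <- function(kind = c("identity", "affine", "displacement"),
                              payload = NULL, direction = "source->target") {
  kind <- match.arg(kind)
  if (kind == "affine") {
    check_affine(payload)
  } else if (kind == "displacement") {
    if (!is.list(payload) || length(dim(payload$field)) != 4L ||
        dim(payload$field)[4] != 3L)
      stop("displacement payload needs a (x,y,z,3) field and its affine",
           call. = FALSE)
    check_affine(payload$affine)
  }
  structure(list(kind = kind, payload = payload, direction = direction),
            class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat(sprintf("<spatial_transform %s %s>\n", x$kind, x$direction))
  invisible(x)
}

transform_points <- function(points, transform) {
  points <- rbind3(points)
  switch(transform$kind,
    identity = points,
    affine = {
      out <- cbind(points, 1) %*% t(transform$payload)
      out[, 1:3, drop = FALSE]
    },
    displacement = {
      disp <- interp_displacement(points, transform$payload)
      points + disp
    })
}

interp_displacement <- function(points, payload) {
  dm <- dim(payload$field)[1:3]
  idx <- world_to_voxel(points, payload$affine)
  out <- matrix(0, nrow(points), 3L)
  for (k in 1:3)
    out[, k] <- trilinear_sample(payload$field[, , , k], idx)
  out
}

# trilinear sample of 3D array at continuous 0-based indices; clamped at edges
trilinear_sample <- function(arr, idx) {
  dm <- dim(arr)
  idx[, 1] <- pmin(pmax(idx[, 1], 0), dm[1] - 1)
  idx[, 2] <- pmin(pmax(idx[, 2], 0), dm[2] - 1)
  idx[, 3] <- pmin(pmax(idx[, 3], 0), dm[3] - 1)
  i0 <- pmin(floor(idx), rep(dm, each = nrow(idx)) - 2)
  i0 <- matrix(pmax(i0, 0), ncol = 3L)
  f <- idx - i0
  acc <- numeric(nrow(idx))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    lin <- 1L + (i0[, 1] + dx) + dm[1] * ((i0[, 2] + dy) + dm[2] * (i0[, 3] + dz))
    acc <- acc + w * arr[lin]
  }
  acc
}

#' Apply a spatial transform to a map or streamline set
#'
#' Streamline points are mapped pointwise. Grids are resampled onto a target
#' grid: for each target voxel centre the source location is found by
#' inverting the transform, and the source map is sampled there
#' (nearest-neighbour for binary/label roles, trilinear for density and
#' probability roles).
#'
#' @param x A [scalar_map], [label_volume] or [streamline_set].
#' @param transform A [spatial_transform] mapping source to target space.
#' @param target_grid Optional [scalar_map]/[label_volume] defining the output
#'   grid; defaults to the input's own grid.
#' @return Object of the same class as `x`, in target space.
#' @export
apply_transform <- function(x, transform, target_grid = NULL) {
  if (inherits(x, "streamline_set")) {
    out <- x
    out$streamlines <- lapply(x$streamlines, transform_points,
                              transform = transform)
    return(out)
  }
  if (!inherits(x, c("scalar_map", "label_volume")))
    stop("apply_transform expects a map, label volume or streamline set",
         call. = FALSE)
  if (transform$kind == "identity" && is.null(target_grid)) return(x)

  grid_ref <- if (is.null(target_grid)) x else target_grid
  dm <- dim(grid_ref$grid)
  tg_idx <- as.matrix(expand.grid(x = 0:(dm[1] - 1), y = 0:(dm[2] - 1),
                                  z = 0:(dm[3] - 1)))
  tg_world <- voxel_to_world(tg_idx, grid_ref$affine)
  src_world <- invert_points(tg_world, transform)
  src_idx <- world_to_voxel(src_world, x$affine)

  nearest <- inherits(x, "label_volume") || x$role == "binary"
  sdm <- dim(x$grid)
  if (nearest) {
    ni <- matrix(as.integer(floor(src_idx + 0.5)), ncol = 3L)
    lin <- voxel_linear(ni, sdm)
    vals <- numeric(nrow(ni))
    ok <- !is.na(lin)
    vals[ok] <- x$grid[lin[ok]]
  } else {
    inside <- points_in_domain(src_world, x$affine, sdm)
    vals <- numeric(nrow(src_idx))
    if (any(inside))
      vals[inside] <- trilinear_sample(x$grid, src_idx[inside, , drop = FALSE])
  }
  out_grid <- array(vals, dim = dm)
  if (inherits(x, "label_volume")) {
    suppressWarnings(label_volume(array(as.integer(out_grid), dim = dm),
                                  grid_ref$affine, x$labels))
  } else {
    if (x$role == "probability") out_grid <- pmin(pmax(out_grid, 0), 1)
    scalar_map(out_grid, grid_ref$affine, x$role)
  }
}

# map target-space points back to source space
invert_points <- function(points, transform) {
  switch(transform$kind,
    identity = points,
    affine = {
      inv <- solve(transform$payload)
      out <- cbind(points, 1) %*% t(inv)
      out[, 1:3, drop = FALSE]
    },
    displacement = {
      # fixed-point inversion of x_t = x_s + d(x_s); few iterations suffice
      # for the small smooth fields used here
      src <- points
      for (i in 1:8)
        src <- points - interp_displacement(src, transform$payload)
      src
    })
}

#' Invert an identity or affine transform
#' @param transform A [spatial_transform].
#' @return The inverse transform.
#' @export
invert_transform <- function(transform) {
  switch(transform$kind,
    identity = transform,
    affine = spatial_transform("affine", solve(transform$payload),
                               direction = paste0("inverse(", transform$direction, ")")),
    stop("displacement fields are not analytically invertible", call. = FALSE))
}
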