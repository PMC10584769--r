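# All internal coordinates are world millimetres in RAS+ orientation.
# Voxel indices are 0-based; a voxel with index i occupies the half-open
# cell [i - 0.5, i + 0.5) along each axis in index space, so the voxel
# centre sits exactly at the integer index.

#' Scalar volume with an affine and a role
#'
#' A `scalar_map` is the one grid type used throughout the pipeline,
#' parameterised by what its values mean: streamline counts (`density`),
#' a mask (`binary`) or a per-voxel probability (`probability`).
#'
#' @param grid 3D numeric array.
#' @param affine 4x4 matrix mapping 0-based voxel indices to world mm (RAS+).
#' @param role One of `"density"`, `"binary"`, `"probability"`.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(grid, affine, role = c("binary", "density", "probability")) {
  role <- match.arg(role)
  if (length(dim(grid)) != 3L) stop("scalar_map grid must be 3D", call. = FALSE)
  check_affine(affine)
  vals <- as.vector(grid)
  if (role == "binary" && !all(vals %in% c(0, 1)))
    stop("binary scalar_map must contain only 0/1 values", call. = FALSE)
  if (role == "density" && (any(vals < 0) || any(vals != round(vals))))
    stop("density scalar_map must contain non-negative integer counts", call. = FALSE)
  if (role == "probability" && (any(vals < 0) || any(vals > 1)))
    stop("probability scalar_map values must lie in [0, 1]", call. = FALSE)
  structure(list(grid = grid, affine = affine, role = role), class = "scalar_map")
}

#' Integer parcellation volume with a name-to-label map
#'
#' @param grid 3D array of non-negative integer labels (0 = unlabelled).
#' @param affine 4x4 voxel-to-world matrix (RAS+).
#' @param labels Named integer vector mapping structure names to label values.
#' @return An object of class `label_volume`. Names in `labels` whose value
#'   does not occur in `grid` are recorded in the `absent` field and a warning
#'   is emitted.
#' @export
label_volume <- function(grid, affine, labels) {
  if (length(dim(grid)) != 3L) stop("label_volume grid must be 3D", call. = FALSE)
  check_affine(affine)
  if (any(grid < 0) || any(grid != round(grid)))
    stop("label_volume grid must hold non-negative integers", call. = FALSE)
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("labels must be a fully named integer vector", call. = FALSE)
  present <- sort(unique(as.integer(grid)))
  absent <- names(labels)[!(as.integer(labels) %in% present)]
  if (length(absent))
    warning("labels absent from grid: ", paste(absent, collapse = ", "), call. = FALSE)
  structure(list(grid = grid, affine = affine,
                 labels = stats::setNames(as.integer(labels), names(labels)),
                 absent = absent),
            class = "label_volume")
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  d <- det(affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < .Machine$double.eps)
    stop("affine must be invertible", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("<scalar_map role=%s dim=%s nonzero=%d>\n", x$role,
              paste(dim(x$grid), collapse = "x"), sum(x$grid != 0)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume dim=%s labels=%d absent=%d>\n",
              paste(dim(x$grid), collapse = "x"), length(x$labels), length(x$absent)))
  invisible(x)
}

# ---- coordinate transforms ---------------------------------------------

#' Convert world-mm points to continuous 0-based voxel indices
#' @param points n x 3 matrix of world coordinates (mm).
#' @param affine 4x4 voxel-to-world matrix.
#' @return n x 3 matrix of continuous voxel indices.
#' @export
world_to_voxel <- function(points, affine) {
  points <- rbind3(points)
  inv <- solve(affine)
  out <- cbind(points, 1) %*% t(inv)
  out[, 1:3, drop = FALSE]
}

#' Convert 0-based voxel indices to world mm
#' @param idx n x 3 matrix of (possibly continuous) voxel indices.
#' @param affine 4x4 voxel-to-world matrix.
#' @return n x 3 matrix of world coordinates.
#' @export
voxel_to_world <- function(idx, affine) {
  idx <- rbind3(idx)
  out <- cbind(idx, 1) %*% t(affine)
  out[, 1:3, drop = FALSE]
}

rbind3 <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  storage.mode(p) <- "double"
  p
}

# nearest voxel of each world point under half-open cell membership;
# returns 0-based integer indices (n x 3)
world_to_nearest_voxel <- function(points, affine) {
  cont <- world_to_voxel(points, affine)
  matrix(as.integer(floor(cont + 0.5)), ncol = 3L)
}

# 0-based (n x 3) -> 1-based linear index into array of dim dm, NA outside
voxel_linear <- function(idx, dm) {
  ok <- idx[, 1] >= 0L & idx[, 1] < dm[1] &
        idx[, 2] >= 0L & idx[, 2] < dm[2] &
        idx[, 3] >= 0L & idx[, 3] < dm[3]
  lin <- 1L + idx[, 1] + dm[1] * (idx[, 2] + dm[2] * idx[, 3])
  lin[!ok] <- NA_integer_
  lin
}

# world coordinates of every voxel with grid != 0 (n x 3)
mask_world_coords <- function(mask) {
  idx <- which(mask$grid != 0, arr.ind = TRUE) - 1L
  if (nrow(idx) == 0L) return(matrix(numeric(0), ncol = 3L))
  voxel_to_world(idx, mask$affine)
}

# volume of one voxel in mm^3
voxel_volume_mm3 <- function(affine) abs(det(affine[1:3, 1:3]))

# per-axis voxel edge lengths in mm
voxel_dims_mm <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

# TRUE for each world point that falls inside a non-zero voxel of mask
points_in_mask <- function(points, mask) {
  idx <- world_to_nearest_voxel(points, mask$affine)
  lin <- voxel_linear(idx, dim(mask$grid))
  inside <- !is.na(lin)
  res <- logical(nrow(idx))
  res[inside] <- mask$grid[lin[inside]] != 0
  res
}

# TRUE for world points inside the grid extent (any voxel, value irrelevant)
points_in_domain <- function(points, affine, dm) {
  cont <- world_to_voxel(points, affine)
  cont[, 1] >= -0.5 & cont[, 1] < dm[1] - 0.5 &
    cont[, 2] >= -0.5 & cont[, 2] < dm[2] - 0.5 &
    cont[, 3] >= -0.5 & cont[, 3] < dm[3] - 0.5
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$grid) == dim(b$grid)) && max(abs(a$affine - b$affine)) < tol
}

empty_like <- function(mask, role = "binary") {
  scalar_map(array(0, dim = dim(mask$grid)), mask$affine, role)
}
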