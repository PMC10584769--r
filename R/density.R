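# Tract density imaging: per-voxel streamline traversal counts, binarised
# maps (K >= 1), and group tractogram probability maps (voxelwise average of
# normalised binarised maps = fraction of subjects with at least one
# streamline in the voxel).

#' Tract density image of a streamline set
#'
#' Counts, per voxel, the number of distinct streamlines with at least one
#' point or segment crossing in it; each streamline contributes at most one
#' count per voxel. Segments are supersampled at no more than a quarter of
#' the voxel spacing so that traversed voxels cannot be skipped. Points
#' outside the template domain are ignored with a warning.
#'
#' @param set A [streamline_set].
#' @param template A [scalar_map] or [label_volume] defining the output grid.
#' @param supersample_mm Supersampling spacing; defaults to a quarter of the
#'   smallest voxel edge.
#' @return A [scalar_map] with role `density`.
#' @export
tract_density <- function(set, template, supersample_mm = NULL) {
  dm <- dim(template$grid)
  aff <- template$affine
  if (is.null(supersample_mm))
    supersample_mm <- min(voxel_dims_mm(aff)) / 4
  counts <- array(0L, dm)
  any_outside <- FALSE
  for (s in set$streamlines) {
    pts <- supersample_polyline(s, supersample_mm)
    idx <- world_to_nearest_voxel(pts, aff)
    lin <- voxel_linear(idx, dm)
    if (anyNA(lin)) { any_outside <- TRUE; lin <- lin[!is.na(lin)] }
    if (!length(lin)) next
    vox <- unique(lin)
    counts[vox] <- counts[vox] + 1L
  }
  if (any_outside)
    warning("streamline points outside the template domain were ignored",
            call. = FALSE)
  scalar_map(counts, aff, "density")
}

# insert intermediate points so consecutive spacing <= spacing_mm
supersample_polyline <- function(pts, spacing_mm) {
  if (nrow(pts) < 2L) return(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  if (all(seg <= spacing_mm)) return(pts)
  out <- vector("list", nrow(pts) - 1L)
  for (i in seq_len(nrow(pts) - 1L)) {
    k <- max(1L, ceiling(seg[i] / spacing_mm))
    tt <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out[[i]] <- cbind(pts[i, 1] + tt * (pts[i + 1L, 1] - pts[i, 1]),
                      pts[i, 2] + tt * (pts[i + 1L, 2] - pts[i, 2]),
                      pts[i, 3] + tt * (pts[i + 1L, 3] - pts[i, 3]))
  }
  rbind(do.call(rbind, out), pts[nrow(pts), , drop = FALSE])
}

#' Binarise a density map
#'
#' Voxels with count `K >= k_min` become one, all others zero.
#'
#' @param density A [scalar_map] with role `density`.
#' @param k_min Minimum streamline count.
#' @return A binary [scalar_map].
#' @export
binarize <- function(density, k_min = 1) {
  if (!inherits(density, "scalar_map") || density$role != "density")
    stop("binarize expects a density scalar_map", call. = FALSE)
  scalar_map(array(as.numeric(density$grid >= k_min), dim(density$grid)),
             density$affine, "binary")
}

#' Group tractogram probability map
#'
#' Normalises each subject's binarised map to a common grid (nearest-
#' neighbour, preserving binarity) and averages voxelwise: the value is the
#' fraction of subjects whose tract density image contains at least one
#' streamline in the voxel.
#'
#' @param binary_maps List of binary [scalar_map]s, one per subject.
#' @param transforms Optional list of [spatial_transform]s (subject -> group
#'   space), one per subject; identity when omitted.
#' @param template Optional [scalar_map] defining the group grid; defaults to
#'   the first subject's grid.
#' @return List of class `probability_map_bundle`: `map` (probability
#'   [scalar_map]), `n_subjects`.
#' @export
probability_map <- function(binary_maps, transforms = NULL, template = NULL) {
  n <- length(binary_maps)
  if (n < 1L) stop("need at least one subject map", call. = FALSE)
  if (is.null(template)) template <- binary_maps[[1]]
  norm <- lapply(seq_len(n), function(i) {
    m <- binary_maps[[i]]
    tr <- if (is.null(transforms)) NULL else transforms[[i]]
    if (!is.null(tr) && tr$kind != "identity")
      m <- apply_transform(m, tr, target_grid = template)
    else if (!same_grid(m, template))
      stop("subject map ", i, " is not on the group grid", call. = FALSE)
    m
  })
  acc <- array(0, dim(template$grid))
  for (m in norm) acc <- acc + (m$grid != 0)
  structure(list(map = scalar_map(acc / n, template$affine, "probability"),
                 n_subjects = n),
            class = "probability_map_bundle")
}

#' @export
print.probability_map_bundle <- function(x, ...) {
  cat(sprintf("<probability_map_bundle n_subjects=%d nonzero=%d>\n",
              x$n_subjects, sum(x$map$grid > 0)))
  invisible(x)
}

#' Threshold a probability map at a confidence level
#'
#' @param bundle A `probability_map_bundle` (or probability [scalar_map]).
#' @param confidence Minimal confidence in (0, 1], e.g. 0.05, 0.50, 0.90.
#' @return Binary [scalar_map] of voxels with probability >= confidence.
#'   Masks are nested: higher confidence gives a subset.
#' @export
threshold_probability <- function(bundle, confidence) {
  if (!is.numeric(confidence) || confidence <= 0 || confidence > 1)
    stop("confidence must lie in (0, 1]", call. = FALSE)
  map <- if (inherits(bundle, "probability_map_bundle")) bundle$map else bundle
  if (!inherits(map, "scalar_map") || map$role != "probability")
    stop("expected a probability map", call. = FALSE)
  scalar_map(array(as.numeric(map$grid >= confidence), dim(map$grid)),
             map$affine, "binary")
}
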