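# Probabilistic streamline propagation. One streamline grows unidirectionally
# from a random position in a random seed voxel with a fixed step length;
# each step draws a direction by rejection sampling proportional to the fODF
# amplitude, restricted to the curvature cone around the previous direction.
# Directions whose amplitude falls below a fraction of the field's global
# maximum amplitude are never accepted, which terminates propagation in
# regions of poor support.

#' Maximum angle between consecutive steps
#'
#' For a polyline with fixed step length inscribed in a circle of the given
#' radius, consecutive segments deviate by at most `2*asin(step/(2*radius))`.
#'
#' @param step_mm Step length (mm).
#' @param curvature_radius_mm Minimum radius of curvature (mm).
#' @return Angle in degrees.
#' @export
max_step_angle <- function(step_mm, curvature_radius_mm) {
  if (step_mm > 2 * curvature_radius_mm)
    stop("step exceeds the curvature diameter: no such polyline exists",
         call. = FALSE)
  2 * asin(step_mm / (2 * curvature_radius_mm)) * 180 / pi
}

# K directions uniform on the spherical cap of half-angle alpha (radians)
# around unit axis; alpha = pi gives the full sphere
sample_cone_dirs <- function(axis, alpha, k) {
  cos_t <- stats::runif(k, min = cos(alpha), max = 1)
  sin_t <- sqrt(pmax(1 - cos_t^2, 0))
  phi <- stats::runif(k, 0, 2 * pi)
  local <- cbind(sin_t * cos(phi), sin_t * sin(phi), cos_t)
  rotate_from_z(local, axis)
}

# rotate vectors given in a frame with +z = axis into world coordinates
rotate_from_z <- function(v, axis) {
  axis <- axis / sqrt(sum(axis^2))
  if (abs(axis[3]) > 0.999999) {
    if (axis[3] > 0) return(v)
    return(cbind(v[, 1], -v[, 2], -v[, 3]))
  }
  # orthonormal frame (e1, e2, axis)
  e1 <- c(-axis[2], axis[1], 0)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  v %*% rbind(e1, e2, axis)
}

#' Sample one propagation direction at a point
#'
#' Rejection-samples a unit direction with probability proportional to the
#' fODF amplitude, restricted to a cone: the curvature cone around `prev_dir`
#' during propagation, or a seed cone (e.g. half-angle 45 degrees for a
#' 90-degree cone) at the first step, or the whole sphere if neither is
#' given. Directions with amplitude below `cutoff_fraction` times the field's
#' global maximum amplitude are rejected outright.
#'
#' @param field A [fodf_field].
#' @param point World-mm position.
#' @param prev_dir Previous unit direction, or `NULL` at the first step.
#' @param cone_spec Optional list `(axis, half_angle_deg)` restricting the
#'   first step.
#' @param cutoff_fraction Fraction of the global maximum amplitude below which
#'   directions are unacceptable.
#' @param params Tracking parameters (see [tracking_params()]).
#' @return Unit 3-vector, or `NULL` when the trial budget is exhausted.
#' @export
sample_direction <- function(field, point, prev_dir = NULL, cone_spec = NULL,
                             cutoff_fraction = 0.1,
                             params = tracking_params()) {
  max_amp <- params$max_amp %||% fodf_max_amplitude(field)
  coef <- as.vector(interp_coef(field, point))
  sample_direction_coef(coef, field$lmax, prev_dir, cone_spec,
                        cutoff_fraction * max_amp, max_amp, params)
}

# Upper bound on the SH amplitude from the coefficient vector alone:
# by Cauchy-Schwarz and the addition theorem, for each degree l
# |sum_m c_lm Y_lm(d)| <= ||c_l|| sqrt((2l+1)/(4 pi)), so voxels without
# support are rejected without sampling a single direction.
.sh_cache <- new.env(parent = emptyenv())

sh_degree_blocks <- function(lmax) {
  key <- as.character(lmax)
  if (!is.null(.sh_cache[[key]])) return(.sh_cache[[key]])
  l_of <- integer(sh_ncoef(lmax))
  col <- 1L
  for (l in seq(0L, lmax, 2L)) for (m in (-l):l) {
    l_of[col] <- l
    col <- col + 1L
  }
  ls <- seq(0L, lmax, 2L)
  blocks <- list(idx = lapply(ls, function(l) which(l_of == l)),
                 fac = sqrt((2 * ls + 1) / (4 * pi)))
  .sh_cache[[key]] <- blocks
  blocks
}

amplitude_upper_bound <- function(coef, lmax) {
  b <- sh_degree_blocks(lmax)
  s <- 0
  for (k in seq_along(b$idx))
    s <- s + b$fac[k] * sqrt(sum(coef[b$idx[[k]]]^2))
  s
}

sample_direction_coef <- function(coef, lmax, prev_dir, cone_spec,
                                  cutoff_abs, max_amp, params) {
  if (amplitude_upper_bound(coef, lmax) < cutoff_abs) return(NULL)
  if (!is.null(prev_dir)) {
    axis <- prev_dir
    alpha <- max_step_angle(params$step_mm, params$curvature_radius_mm) * pi / 180
  } else if (!is.null(cone_spec)) {
    axis <- cone_spec$axis / sqrt(sum(cone_spec$axis^2))
    alpha <- (cone_spec$half_angle_deg %||% 45) * pi / 180
  } else {
    axis <- c(0, 0, 1)
    alpha <- pi
  }
  trials <- 0L
  batch <- 8L
  while (trials < params$trials_per_step) {
    k <- min(batch, params$trials_per_step - trials)
    dirs <- sample_cone_dirs(axis, alpha, k)
    amp <- amplitude_from_coef(coef, dirs, lmax)
    u <- stats::runif(k, 0, max_amp)
    hit <- which(amp >= cutoff_abs & u <= amp)
    if (length(hit)) return(dirs[hit[1L], ])
    trials <- trials + k
    batch <- min(4L * batch, 256L)
  }
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tracking parameter set
#'
#' @param step_mm Step length in mm.
#' @param curvature_radius_mm Minimum radius of curvature in mm.
#' @param max_length_mm Maximum streamline length in mm.
#' @param trials_per_step Direction-sampling trial budget per step.
#' @param max_attempts_per_seed Attempt budget multiplier: tracking stops
#'   after `max_attempts_per_seed * n_seed_voxels` total attempts.
#' @param max_amp Optional precomputed global maximum amplitude.
#' @return A named list of parameters.
#' @export
tracking_params <- function(step_mm = 0.2, curvature_radius_mm = 1.0,
                            max_length_mm = 250, trials_per_step = 300L,
                            max_attempts_per_seed = 10000L, max_amp = NULL) {
  if (step_mm <= 0 || curvature_radius_mm <= 0)
    stop("step and curvature radius must be positive", call. = FALSE)
  if (step_mm > 2 * curvature_radius_mm)
    stop("step must not exceed twice the curvature radius", call. = FALSE)
  list(step_mm = step_mm, curvature_radius_mm = curvature_radius_mm,
       max_length_mm = max_length_mm, trials_per_step = as.integer(trials_per_step),
       max_attempts_per_seed = as.integer(max_attempts_per_seed),
       max_amp = max_amp)
}

# combine ROI masks into a zone lookup grid on the field grid:
# 0 free, 1 target, 2 exclude (exclusion wins where overlapping)
build_zone_grid <- function(rois, field) {
  ref <- if (length(rois$targets)) rois$targets[[1]] else rois$seed
  dm <- dim(ref$grid)
  if (!all(dm == field$dim) || max(abs(ref$affine - field$affine)) > 1e-6)
    stop("ROI masks and fODF field must share one grid", call. = FALSE)
  zone <- array(0L, dim = dm)
  for (tg in rois$targets) zone[tg$grid != 0] <- 1L
  for (ex in rois$excludes %||% list()) zone[ex$grid != 0] <- 2L
  zone
}

#' Propagate a single streamline from a seed point
#'
#' Grows unidirectionally with fixed step length until a target is entered
#' (acceptance), an exclusion region is entered, the domain is left, the
#' length budget is exhausted, or no acceptable direction is found. Accepted
#' streamlines must additionally intersect every include region (checked
#' after termination).
#'
#' @param seed_point World-mm position inside the seed mask.
#' @param field A [fodf_field].
#' @param rois List with `seed` (binary [scalar_map]), `targets` (list of
#'   masks), optional `excludes` and `includes` lists.
#' @param params See [tracking_params()].
#' @param cutoff_fraction Amplitude cutoff as fraction of the global maximum.
#' @param cone_spec Optional seed-direction cone, list `(axis, half_angle_deg)`.
#' @return List with `accepted` (logical), `streamline` (matrix or `NULL`)
#'   and `reason` (`"accepted"`, `"entered_exclusion"`, `"missed_include"`,
#'   `"no_direction"`, `"max_length"`, `"left_domain"`).
#' @export
propagate <- function(seed_point, field, rois, params = tracking_params(),
                      cutoff_fraction = 0.1, cone_spec = NULL) {
  if (!points_in_mask(rbind3(seed_point), rois$seed))
    stop("seed point lies outside the seed mask", call. = FALSE)
  zone <- rois$.zone %||% build_zone_grid(rois, field)
  max_amp <- params$max_amp %||% fodf_max_amplitude(field)
  params$max_amp <- max_amp
  propagate_internal(seed_point, field, rois, zone, params,
                     cutoff_fraction * max_amp, cone_spec)
}

propagate_internal <- function(seed_point, field, rois, zone, params,
                               cutoff_abs, cone_spec) {
  step <- params$step_mm
  max_steps <- ceiling(params$max_length_mm / step)
  pts <- matrix(NA_real_, max_steps + 1L, 3L)
  pts[1L, ] <- seed_point
  p <- seed_point
  dm <- field$dim
  inv_aff <- solve(field$affine)
  dir <- NULL
  outcome <- "max_length"
  n <- 1L
  for (i in seq_len(max_steps)) {
    coef <- as.vector(interp_coef(field, p))
    dir <- sample_direction_coef(coef, field$lmax,
                                 prev_dir = dir,
                                 cone_spec = if (i == 1L) cone_spec else NULL,
                                 cutoff_abs = cutoff_abs,
                                 max_amp = params$max_amp, params = params)
    if (is.null(dir)) { outcome <- "no_direction"; break }
    p <- p + step * dir
    vox <- floor(inv_aff[1:3, 1:3] %*% p + inv_aff[1:3, 4] + 0.5)
    if (any(vox < 0) || any(vox >= dm)) { outcome <- "left_domain"; break }
    z <- zone[1L + vox[1] + dm[1] * (vox[2] + dm[2] * vox[3])]
    if (z == 2L) { outcome <- "entered_exclusion"; break }
    n <- n + 1L
    pts[n, ] <- p
    if (z == 1L) { outcome <- "accepted"; break }
  }
  if (outcome != "accepted")
    return(list(accepted = FALSE, streamline = NULL, reason = outcome))
  sl <- pts[seq_len(n), , drop = FALSE]
  for (inc in rois$includes %||% list()) {
    if (!any(points_in_mask(sl, inc)))
      return(list(accepted = FALSE, streamline = NULL,
                  reason = "missed_include"))
  }
  list(accepted = TRUE, streamline = sl, reason = "accepted")
}

#' Track a full tractogram for one protocol
#'
#' Repeatedly draws a uniform random seed voxel and a uniform position within
#' its cell, propagates one streamline, and accumulates accepted streamlines
#' until the protocol's count is reached or the attempt budget
#' (`max_attempts_per_seed * n_seed_voxels`) is exhausted.
#'
#' @param protocol A [tract_protocol()] (supplies streamline count, amplitude
#'   cutoff, seed cone and tracking parameters).
#' @param field A [fodf_field].
#' @param rois ROI list as produced by [build_rois()].
#' @param seed Optional integer RNG seed; with a fixed seed the output is
#'   bit-identical across runs.
#' @param n_streamlines Optional override of the protocol's streamline count.
#' @return A [streamline_set] with acceptance statistics in `meta`.
#' @export
track <- function(protocol, field, rois, seed = NULL, n_streamlines = NULL) {
  run <- function() track_impl(protocol, field, rois, seed, n_streamlines)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

track_impl <- function(protocol, field, rois, seed, n_streamlines) {
  cone_spec <- protocol$seed_cone
  if (!is.null(cone_spec) && is.character(cone_spec$axis))
    stop("seed cone axis '", cone_spec$axis, "' is unresolved; apply ",
         "resolve_hemisphere() to the protocol first", call. = FALSE)
  n_want <- as.integer(n_streamlines %||% protocol$n_streamlines)
  params <- tracking_params(step_mm = protocol$step_mm,
                            curvature_radius_mm = protocol$curvature_radius_mm,
                            max_length_mm = protocol$max_length_mm %||% 250,
                            trials_per_step = protocol$trials_per_step %||% 300L,
                            max_attempts_per_seed = protocol$max_attempts_per_seed %||% 10000L)
  params$max_amp <- fodf_max_amplitude(field)
  cutoff_abs <- protocol$amplitude_cutoff_fraction * params$max_amp
  zone <- build_zone_grid(rois, field)

  seed_idx <- which(rois$seed$grid != 0, arr.ind = TRUE) - 1L
  if (nrow(seed_idx) == 0L) stop("empty seed region", call. = FALSE)
  has_target <- any(vapply(rois$targets, function(t) any(t$grid != 0), logical(1)))
  if (!length(rois$targets) || !has_target)
    stop("empty target region", call. = FALSE)

  budget <- params$max_attempts_per_seed * nrow(seed_idx)
  accepted <- vector("list", n_want)
  n_acc <- 0L
  attempts <- 0L
  reasons <- c(accepted = 0L, entered_exclusion = 0L, missed_include = 0L,
               no_direction = 0L, max_length = 0L, left_domain = 0L)
  while (n_acc < n_want && attempts < budget) {
    attempts <- attempts + 1L
    vi <- seed_idx[sample.int(nrow(seed_idx), 1L), ]
    pos_idx <- vi + stats::runif(3, -0.5, 0.5)
    seed_point <- as.vector(voxel_to_world(pos_idx, rois$seed$affine))
    res <- propagate_internal(seed_point, field, rois, zone, params,
                              cutoff_abs, cone_spec)
    reasons[res$reason] <- reasons[res$reason] + 1L
    if (res$accepted) {
      n_acc <- n_acc + 1L
      accepted[[n_acc]] <- res$streamline
    }
  }
  if (n_acc == 0L) {
    dominant <- names(which.max(reasons[-1L]))
    stop(sprintf("tracking failed for '%s': 0 of %d attempts accepted (dominant rejection: %s)",
                 protocol$name %||% "tract", attempts, dominant), call. = FALSE)
  }
  streamline_set(accepted[seq_len(n_acc)],
                 meta = list(tract = protocol$name, rng_seed = seed,
                             attempts = attempts,
                             acceptance_rate = n_acc / attempts,
                             rejection_reasons = as.list(reasons),
                             step_mm = params$step_mm,
                             curvature_radius_mm = params$curvature_radius_mm,
                             amplitude_cutoff_fraction = protocol$amplitude_cutoff_fraction))
}
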