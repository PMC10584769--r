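# Declarative tract protocols. A protocol names a tract and carries ROI
# recipes (operator trees over the geometric primitives) plus the tracking
# and filtering parameters. Recipes are plain lists, so protocols serialise
# to/from YAML. Label names may contain the placeholders {h} / {ch}
# (ipsilateral / contralateral hemisphere suffix) and side arguments may use
# {hside} / {chside}; these are resolved when a hemisphere is chosen.

#' Construct a tract protocol
#'
#' @param name Tract name (e.g. `"CST"`).
#' @param seed ROI recipe (see Details) for the seed region.
#' @param targets List of target recipes (streamlines stop and are accepted
#'   on entering any of them).
#' @param excludes List of exclusion recipes (entering any rejects the
#'   streamline).
#' @param includes List of inclusion recipes (accepted streamlines must
#'   intersect all of them).
#' @param n_streamlines Number of streamlines to accept.
#' @param amplitude_cutoff_fraction fODF amplitude cutoff as a fraction of
#'   the field's global maximum amplitude, in (0, 1).
#' @param seed_cone Optional list `(axis, half_angle_deg)`; `axis` may be a
#'   3-vector or `"lateral"` (resolved to +x / -x for the right / left
#'   hemisphere).
#' @param rfbc_threshold RFBC filtering threshold: `"none"` or a
#'   non-negative number (the shipped settings are 1e-3 and 1e-1).
#' @param hemisphere `"left"`, `"right"` or `"both"` (unresolved template).
#' @param step_mm,curvature_radius_mm,max_attempts_per_seed,max_length_mm
#'   Tracking parameters.
#' @details A recipe is a named list with an `op` field:
#'   `select` (labels), `split_axis` (of, axis, side, fraction),
#'   `axial_slab` (of, reference, thickness_mm), `dilate` (of, sigma_mm,
#'   optional constraint), `sphere_between` (a, b, volume_mm3, within),
#'   `plane_split` (of, landmark, keep = posterior/anterior),
#'   `union` / `intersect` (of = list of recipes).
#' @return An object of class `tract_protocol`.
#' @export
tract_protocol <- function(name, seed, targets, excludes = list(),
                           includes = list(), n_streamlines,
                           amplitude_cutoff_fraction, seed_cone = NULL,
                           rfbc_threshold = "none", hemisphere = "both",
                           step_mm = 0.2, curvature_radius_mm = 1.0,
                           max_attempts_per_seed = 10000L,
                           max_length_mm = 250, trials_per_step = 300L) {
  if (n_streamlines <= 0) stop("n_streamlines must be positive", call. = FALSE)
  if (amplitude_cutoff_fraction <= 0 || amplitude_cutoff_fraction >= 1)
    stop("amplitude_cutoff_fraction must be in (0, 1)", call. = FALSE)
  if (step_mm > 2 * curvature_radius_mm)
    stop("step_mm must not exceed 2 * curvature_radius_mm", call. = FALSE)
  if (!identical(rfbc_threshold, "none") &&
      (!is.numeric(rfbc_threshold) || rfbc_threshold < 0))
    stop("rfbc_threshold must be \"none\" or a non-negative number", call. = FALSE)
  structure(list(name = name, seed = seed, targets = targets,
                 excludes = excludes, includes = includes,
                 n_streamlines = as.integer(n_streamlines),
                 amplitude_cutoff_fraction = amplitude_cutoff_fraction,
                 seed_cone = seed_cone, rfbc_threshold = rfbc_threshold,
                 hemisphere = hemisphere, step_mm = step_mm,
                 curvature_radius_mm = curvature_radius_mm,
                 max_attempts_per_seed = as.integer(max_attempts_per_seed),
                 max_length_mm = max_length_mm,
                 trials_per_step = as.integer(trials_per_step)),
            class = "tract_protocol")
}

#' @export
print.tract_protocol <- function(x, ...) {
  cat(sprintf("<tract_protocol %s (%s) n=%d cutoff=%.3f rfbc=%s>\n",
              x$name, x$hemisphere, x$n_streamlines,
              x$amplitude_cutoff_fraction,
              if (identical(x$rfbc_threshold, "none")) "none"
              else format(x$rfbc_threshold)))
  invisible(x)
}

# ---- hemisphere templating ---------------------------------------------

#' Resolve a protocol template to one hemisphere
#'
#' Substitutes `{h}`/`{ch}` label-name placeholders and `{hside}`/`{chside}`
#' side arguments, and resolves a `"lateral"` seed-cone axis to the
#' ipsilateral +/- x direction.
#'
#' @param protocol A [tract_protocol()] with `hemisphere = "both"`.
#' @param hemisphere `"left"` or `"right"`.
#' @return The resolved [tract_protocol()].
#' @export
resolve_hemisphere <- function(protocol, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  h <- if (hemisphere == "left") "L" else "R"
  ch <- if (hemisphere == "left") "R" else "L"
  subst <- function(x) {
    if (is.character(x)) {
      x <- gsub("{h}", h, x, fixed = TRUE)
      x <- gsub("{ch}", ch, x, fixed = TRUE)
      x <- gsub("{hside}", hemisphere, x, fixed = TRUE)
      x <- gsub("{chside}", if (hemisphere == "left") "right" else "left",
                x, fixed = TRUE)
    } else if (is.list(x)) {
      x <- lapply(x, subst)
    }
    x
  }
  out <- protocol
  for (f in c("seed", "targets", "excludes", "includes"))
    out[[f]] <- subst(out[[f]])
  if (!is.null(out$seed_cone) && identical(out$seed_cone$axis, "lateral"))
    out$seed_cone$axis <- if (hemisphere == "left") c(-1, 0, 0) else c(1, 0, 0)
  out$hemisphere <- hemisphere
  out
}

# ---- recipe evaluation --------------------------------------------------

eval_recipe <- function(recipe, vol) {
  op <- recipe$op %||% stop("recipe has no op", call. = FALSE)
  switch(op,
    select = select_labels(vol, unlist(recipe$labels)),
    split_axis = split_axis(eval_recipe(recipe$of, vol), recipe$axis,
                            recipe$side, recipe$fraction %||% 0.5),
    axial_slab = axial_slab(eval_recipe(recipe$of, vol),
                            eval_recipe(recipe$reference, vol),
                            recipe$thickness_mm),
    dilate = gaussian_dilate(eval_recipe(recipe$of, vol), recipe$sigma_mm,
                             constraint = if (!is.null(recipe$constraint))
                               eval_recipe(recipe$constraint, vol),
                             threshold = recipe$threshold %||% 0.3),
    sphere_between = sphere_between(eval_recipe(recipe$a, vol),
                                    eval_recipe(recipe$b, vol),
                                    recipe$volume_mm3,
                                    eval_recipe(recipe$within, vol)),
    plane_split = {
      parts <- split_by_plane(eval_recipe(recipe$of, vol),
                              eval_recipe(recipe$landmark, vol))
      parts[[recipe$keep %||% "posterior"]]
    },
    union = Reduce(mask_union, lapply(recipe$of, eval_recipe, vol = vol)),
    intersect = Reduce(mask_intersect, lapply(recipe$of, eval_recipe, vol = vol)),
    stop("unknown recipe op: ", op, call. = FALSE))
}

#' Build all ROI masks for a tract protocol
#'
#' Evaluates the protocol's seed/target/exclude/include recipes against a
#' parcellation. Protocols holding hemisphere placeholders are resolved
#' first with [resolve_hemisphere] semantics via the `hemisphere` argument.
#'
#' @param protocol A [tract_protocol()].
#' @param vol A [label_volume].
#' @param hemisphere `"left"` or `"right"`; required when the protocol is an
#'   unresolved `"both"` template.
#' @return List with binary [scalar_map]s: `seed`, `targets` (list),
#'   `excludes` (list), `includes` (list).
#' @export
build_rois <- function(protocol, vol, hemisphere = NULL) {
  if (identical(protocol$hemisphere, "both")) {
    if (is.null(hemisphere))
      stop("protocol '", protocol$name,
           "' is a hemisphere template; pass hemisphere=", call. = FALSE)
    protocol <- resolve_hemisphere(protocol, hemisphere)
  }
  seed <- eval_recipe(protocol$seed, vol)
  targets <- lapply(protocol$targets, eval_recipe, vol = vol)
  excludes <- lapply(protocol$excludes, eval_recipe, vol = vol)
  includes <- lapply(protocol$includes, eval_recipe, vol = vol)
  if (sum(seed$grid) == 0)
    stop("tract '", protocol$name, "': seed region is empty", call. = FALSE)
  if (!length(targets) || all(vapply(targets, function(t) sum(t$grid) == 0, logical(1))))
    stop("tract '", protocol$name, "': target region is empty", call. = FALSE)
  list(seed = seed, targets = targets, excludes = excludes, includes = includes)
}

# ---- shipped protocols --------------------------------------------------

#' Load tract protocols from a YAML file
#'
#' @param path YAML file; defaults to the six shipped tract protocols.
#' @param hemisphere Optional `"left"`/`"right"` to resolve hemisphere
#'   placeholders immediately.
#' @return Named list of [tract_protocol()] objects.
#' @export
load_protocols <- function(path = default_protocol_path(), hemisphere = NULL) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw$tracts, function(p) {
    pr <- tract_protocol(
      name = p$name, seed = p$seed, targets = p$targets,
      excludes = p$excludes %||% list(), includes = p$includes %||% list(),
      n_streamlines = p$n_streamlines,
      amplitude_cutoff_fraction = p$amplitude_cutoff_fraction,
      seed_cone = p$seed_cone,
      rfbc_threshold = if (identical(p$rfbc_threshold, "none")) "none"
                       else as.numeric(p$rfbc_threshold %||% "none"),
      hemisphere = p$hemisphere %||% "both",
      step_mm = p$step_mm %||% 0.2,
      curvature_radius_mm = p$curvature_radius_mm %||% 1.0,
      max_attempts_per_seed = p$max_attempts_per_seed %||% 10000L,
      max_length_mm = p$max_length_mm %||% 250)
    if (!is.null(hemisphere)) pr <- resolve_hemisphere(pr, hemisphere)
    pr
  })
  stats::setNames(out, vapply(out, function(p) p$name, character(1)))
}

#' @rdname load_protocols
#' @export
default_protocol_path <- function() {
  system.file("protocols", "default_six_tracts.yaml", package = "fibreflow",
              mustWork = TRUE)
}

#' The six shipped tract protocols
#' @param hemisphere Optional hemisphere to resolve placeholders.
#' @return Named list of [tract_protocol()]s for CST, IFOF, OR, AF, FAT and
#'   SLF III.
#' @export
default_protocols <- function(hemisphere = NULL)
  load_protocols(default_protocol_path(), hemisphere)
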