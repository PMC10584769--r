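# End-to-end orchestration: for each tract protocol, build ROIs -> track ->
# FBC-filter -> density map -> binarised map, writing all artifacts plus a
# run manifest (config snapshot, seeds, timings, checksums). One global seed
# fans out to per-stage child seeds through a counter so each stage is
# independently reproducible.

child_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 1009 + counter * 9973) %% 2147483647)
}

#' Run the tract-reconstruction pipeline
#'
#' @param config List (or path to a YAML file) with entries:
#'   \describe{
#'     \item{label_volume}{Path to a label NIfTI, or a [label_volume]
#'       object. `synthetic: true` generates the default phantom instead.}
#'     \item{label_table}{Label table (named list or path) when
#'       `label_volume` is a path.}
#'     \item{fodf}{Path to a 4D SH NIfTI or a [fodf_field]; generated from
#'       the default centerlines when `synthetic: true`.}
#'     \item{protocols}{Path to a protocol YAML or a list of
#'       [tract_protocol()]s; defaults to the six shipped protocols.}
#'     \item{hemisphere}{`"left"` or `"right"` (default `"left"`).}
#'     \item{n_streamlines}{Optional per-run override of every protocol's
#'       streamline count (phantom runs use small counts).}
#'     \item{out_dir}{Output directory.}
#'   }
#' @param seed Integer RNG seed; all stochastic stages derive child seeds
#'   from it, so identical config + seed reproduces identical outputs.
#' @return Invisible list with per-tract results (`streamlines`, `density`,
#'   `binary`, `rois`, or `error`) and the `manifest`.
#' @export
run_pipeline <- function(config, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  t_start <- Sys.time()
  if (is.null(config$out_dir)) stop("config needs out_dir", call. = FALSE)
  synthetic <- isTRUE(config$synthetic)
  if (!synthetic && is.null(config$fodf))
    stop("config needs an fODF field (or synthetic: true)", call. = FALSE)
  if (!synthetic && is.null(config$label_volume))
    stop("config needs a label volume (or synthetic: true)", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hemisphere <- config$hemisphere %||% "left"

  timings <- list()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  if (synthetic) {
    vol <- make_phantom()
    field <- default_phantom_fodf(vol, hemispheres = hemisphere)
  } else {
    vol <- if (inherits(config$label_volume, "label_volume")) config$label_volume
           else read_label_volume(config$label_volume, config$label_table)
    field <- if (inherits(config$fodf, "fodf_field")) config$fodf
             else read_fodf_field(config$fodf)
  }
  timings$inputs <- toc(t0)

  protocols <- config$protocols %||% default_protocol_path()
  if (is.character(protocols)) protocols <- load_protocols(protocols)
  protocols <- lapply(protocols, function(p)
    if (identical(p$hemisphere, "both")) resolve_hemisphere(p, hemisphere) else p)

  results <- list()
  outputs <- character()
  counter <- 0L
  for (pr in protocols) {
    counter <- counter + 1L
    tract_seed <- child_seed(seed, counter)
    t0 <- tic()
    res <- tryCatch({
      rois <- build_rois(pr, vol, hemisphere = hemisphere)
      sls <- track(pr, field, rois, seed = tract_seed,
                   n_streamlines = config$n_streamlines)
      sls <- fbc_filter(sls, pr$rfbc_threshold)
      dens <- tract_density(sls, vol)
      bin <- binarize(dens, k_min = 1)
      base <- file.path(config$out_dir, paste0(pr$name, "_", hemisphere))
      write_streamlines(sls, paste0(base, ".tck"))
      write_nifti_volume(dens, paste0(base, "_tdi.nii"))
      write_nifti_volume(bin, paste0(base, "_mask.nii"))
      outputs <- c(outputs, paste0(base, ".tck"), paste0(base, "_tdi.nii"),
                   paste0(base, "_mask.nii"))
      list(streamlines = sls, density = dens, binary = bin, rois = rois,
           seed = tract_seed)
    }, error = function(e) {
      warning(sprintf("tract %s failed: %s", pr$name, conditionMessage(e)),
              call. = FALSE)
      list(error = conditionMessage(e), stage = "pipeline", seed = tract_seed)
    })
    timings[[pr$name]] <- toc(t0)
    results[[pr$name]] <- res
  }

  manifest <- list(
    tool = "fibreflow",
    version = as.character(utils::packageVersion("fibreflow")),
    seed = seed,
    hemisphere = hemisphere,
    config = config[setdiff(names(config), c("label_volume", "fodf"))],
    tract_seeds = stats::setNames(
      lapply(seq_along(protocols), function(i) child_seed(seed, i)),
      names(protocols)),
    timings_sec = timings,
    total_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    outputs = as.list(stats::setNames(
      as.vector(tools::md5sum(outputs[file.exists(outputs)])),
      basename(outputs[file.exists(outputs)])))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(list(results = results, manifest = manifest,
                 manifest_path = manifest_path))
}

#' Run one of the evaluation experiments on synthetic data
#'
#' \describe{
#'   \item{probability_maps}{Builds per-subject binarised maps on a
#'     synthetic cohort, normalises to base space and averages into a group
#'     probability map; also reports seed/target ROI volume statistics.}
#'   \item{holdout}{Hold-out cross-validation over the cohort's binarised
#'     maps.}
#'   \item{repeat}{Runs tracking repeatedly with identical settings and
#'     reports all pairwise Dice overlaps per filtering strength.}
#'   \item{retest}{Two jittered sessions of one subject; Dice after
#'     normalising with the known inverse transform.}
#' }
#'
#' @param which Experiment name.
#' @param config List of experiment settings (tract, hemisphere,
#'   n_subjects/n_runs, jitter, n_streamlines, holdout ratio/iterations/
#'   confidence, rfbc settings, out_dir).
#' @param seed Integer RNG seed.
#' @return Experiment-specific result list; written as JSON when `out_dir`
#'   is set.
#' @export
run_experiment <- function(which = c("probability_maps", "holdout", "repeat",
                                     "retest"),
                           config = list(), seed = 1L) {
  which <- match.arg(which)
  out <- switch(which,
    probability_maps = experiment_probability_maps(config, seed),
    holdout = experiment_holdout(config, seed),
    "repeat" = experiment_repeat(config, seed),
    retest = experiment_retest(config, seed))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(strip_heavy(out),
                         file.path(config$out_dir, paste0(which, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  out
}

strip_heavy <- function(x) {
  drop <- c("maps", "bundle", "subjects", "runs")
  if (is.list(x)) x[setdiff(names(x), drop)] else x
}

# shared helper: track one tract on one subject and return the binarised map
track_binary_map <- function(protocol, vol, field, hemisphere, seed,
                             n_streamlines, rfbc = NULL) {
  rois <- build_rois(protocol, vol, hemisphere = hemisphere)
  sls <- track(protocol, field, rois, seed = seed,
               n_streamlines = n_streamlines)
  sls <- fbc_filter(sls, rfbc %||% protocol$rfbc_threshold)
  binarize(tract_density(sls, vol))
}

experiment_cohort <- function(config, seed) {
  n <- config$n_subjects %||% 5L
  hemisphere <- config$hemisphere %||% "left"
  cls <- default_centerlines(hemisphere)
  base <- make_phantom()
  make_cohort(n, base_vol = base,
              jitter_mm = config$jitter_mm %||% 1,
              jitter_deg = config$jitter_deg %||% 2,
              jitter_scale = config$jitter_scale %||% 0.02,
              seed = child_seed(seed, 101L),
              centerlines = cls,
              fodf_args = list(domain = NULL))
}

experiment_probability_maps <- function(config, seed) {
  tract <- config$tract %||% "CST"
  hemisphere <- config$hemisphere %||% "left"
  protocol <- resolve_hemisphere(default_protocols()[[tract]], hemisphere)
  subjects <- experiment_cohort(config, seed)
  maps <- list(); transforms <- list(); seeds_rois <- list(); target_rois <- list()
  for (i in seq_along(subjects)) {
    su <- subjects[[i]]
    rois <- build_rois(protocol, su$vol, hemisphere = hemisphere)
    sls <- track(protocol, su$fodf, rois, seed = child_seed(seed, 200L + i),
                 n_streamlines = config$n_streamlines %||% 15L)
    sls <- fbc_filter(sls, protocol$rfbc_threshold)
    maps[[i]] <- binarize(tract_density(sls, su$vol))
    transforms[[i]] <- su$transform
    seeds_rois[[i]] <- rois$seed
    target_rois[[i]] <- Reduce(mask_union, rois$targets)
  }
  bundle <- probability_map(maps, transforms, template = maps[[1]])
  list(experiment = "probability_maps", tract = tract,
       n_subjects = length(subjects),
       bundle = bundle, maps = maps,
       seed_roi_stats = roi_volume_stats(seeds_rois),
       target_roi_stats = roi_volume_stats(target_rois),
       confidence_voxels = vapply(c(0.05, 0.5, 0.9), function(cf)
         sum(threshold_probability(bundle, cf)$grid), numeric(1)))
}

experiment_holdout <- function(config, seed) {
  exp1 <- experiment_probability_maps(config, seed)
  transforms <- NULL
  res <- holdout_cv(exp1$maps,
                    ratio = config$ratio %||% 0.10,
                    n_iterations = config$n_iterations %||% 300L,
                    confidence = config$confidence %||% 0.05,
                    seed = child_seed(seed, 301L))
  list(experiment = "holdout", tract = exp1$tract, holdout = res,
       mean_dice = res$mean, summary = as.list(res$summary))
}

experiment_repeat <- function(config, seed) {
  tract <- config$tract %||% "bundle"
  hemisphere <- config$hemisphere %||% "left"
  n_runs <- config$n_runs %||% 10L
  if (identical(tract, "bundle")) {
    ph <- make_tracking_phantom(background = config$background %||% 0.1,
                                noise = config$fodf_noise %||% 0,
                                noise_seed = child_seed(seed, 401L),
                                distractors = config$distractors %||% 0L,
                                size = config$phantom_size %||% "short")
    protocol <- bundle_protocol(config$n_streamlines %||% 15L,
                                max_length_mm = 60, trials_per_step = 60L)
    vol <- ph$template
    field <- ph$field
    rois <- ph$rois
  } else {
    protocol <- resolve_hemisphere(default_protocols()[[tract]], hemisphere)
    vol <- make_phantom()
    field <- default_phantom_fodf(vol, hemispheres = hemisphere,
                                  noise = config$fodf_noise %||% 0.25,
                                  noise_seed = child_seed(seed, 401L))
    rois <- build_rois(protocol, vol, hemisphere = hemisphere)
  }
  settings <- config$rfbc_settings %||% list("none", 1e-3, 1e-1)
  runs <- lapply(seq_len(n_runs), function(r)
    track(protocol, field, rois, seed = child_seed(seed, 500L + r),
          n_streamlines = config$n_streamlines %||% 40L))
  per_setting <- lapply(settings, function(eps) {
    maps <- lapply(runs, function(sls)
      binarize(tract_density(fbc_filter(sls, eps), vol)))
    repeated_processing(maps)
  })
  names(per_setting) <- vapply(settings, function(e)
    if (identical(e, "none")) "none" else format(e, scientific = TRUE),
    character(1))
  list(experiment = "repeat", tract = tract, n_runs = n_runs,
       runs = runs,
       settings = names(per_setting),
       mean_dice = vapply(per_setting, `[[`, numeric(1), "mean"),
       n_pairs = vapply(per_setting, function(r) length(r$dice), numeric(1)),
       results = lapply(per_setting, function(r)
         list(mean = r$mean, summary = as.list(r$summary))))
}

experiment_retest <- function(config, seed) {
  tract <- config$tract %||% "CST"
  hemisphere <- config$hemisphere %||% "left"
  protocol <- resolve_hemisphere(default_protocols()[[tract]], hemisphere)
  config$n_subjects <- 2L
  sessions <- experiment_cohort(config, seed)
  maps <- list(); rois_list <- list()
  for (i in 1:2) {
    se <- sessions[[i]]
    rois <- build_rois(protocol, se$vol, hemisphere = hemisphere)
    sls <- track(protocol, se$fodf, rois, seed = child_seed(seed, 600L + i),
                 n_streamlines = config$n_streamlines %||% 15L)
    sls <- fbc_filter(sls, protocol$rfbc_threshold)
    maps[[i]] <- binarize(tract_density(sls, se$vol))
    rois_list[[i]] <- rois
  }
  # normalise both sessions to base space with the known inverse transforms,
  # then compare
  m1 <- apply_transform(maps[[1]], sessions[[1]]$transform)
  m2 <- apply_transform(maps[[2]], sessions[[2]]$transform,
                        target_grid = m1)
  rep_map <- dice(m1, m2)
  roi_pairs <- list(
    list(a = apply_transform(rois_list[[1]]$seed, sessions[[1]]$transform),
         b = apply_transform(rois_list[[2]]$seed, sessions[[2]]$transform),
         tract = tract, roi = "seed", hemisphere = hemisphere),
    list(a = apply_transform(Reduce(mask_union, rois_list[[1]]$targets),
                             sessions[[1]]$transform),
         b = apply_transform(Reduce(mask_union, rois_list[[2]]$targets),
                             sessions[[2]]$transform),
         tract = tract, roi = "target", hemisphere = hemisphere))
  list(experiment = "retest", tract = tract,
       map_dice = rep_map$dice,
       roi_table = roi_test_retest(roi_pairs))
}
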