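# Robustness and reliability evaluation: Dice overlap, hold-out cross-
# validation of group probability maps, repeated-processing comparison and
# test-retest analysis.

#' Dice overlap of two binary maps
#'
#' `dice = 2 N(A intersect B) / (N(A) + N(B))` with `N` the nonzero-voxel
#' count. When both masks are empty the coefficient is defined as 1 and
#' flagged degenerate so batch runs do not fail on edge cases.
#'
#' @param A,B Binary [scalar_map]s on the same grid.
#' @return List of class `dice_report`: `a`, `b`, `inter`, `dice`,
#'   `degenerate`.
#' @export
dice <- function(A, B) {
  if (!same_grid(A, B)) stop("masks are not on the same grid", call. = FALSE)
  a <- sum(A$grid != 0); b <- sum(B$grid != 0)
  inter <- sum(A$grid != 0 & B$grid != 0)
  if (a + b == 0L)
    return(structure(list(a = 0L, b = 0L, inter = 0L, dice = 1,
                          degenerate = TRUE), class = "dice_report"))
  structure(list(a = a, b = b, inter = inter, dice = 2 * inter / (a + b),
                 degenerate = FALSE), class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("<dice %.4f a=%d b=%d inter=%d%s>\n", x$dice, x$a, x$b,
              x$inter, if (x$degenerate) " degenerate" else ""))
  invisible(x)
}

#' Hold-out cross-validation of tractogram probability maps
#'
#' Repeatedly splits subjects at random into a small group of
#' `round(ratio * n)` and its complement, builds each group's probability
#' map, thresholds both at the confidence level, and records the Dice
#' overlap. A low spread signals that a robust probability map can be built
#' from a small subset, i.e. there are no major outliers.
#'
#' @param subject_maps List (>= 3) of binary [scalar_map]s on one grid.
#' @param ratio Hold-out ratio (default 0.10).
#' @param n_iterations Number of random splits (default 300).
#' @param confidence Minimal confidence level for thresholding (default
#'   0.05).
#' @param seed Optional RNG seed.
#' @return List of class `holdout_result`: per-iteration `dice` values,
#'   `mean`, Tukey box-whisker `summary` (quartiles and 1.5 IQR whiskers),
#'   and the parameters.
#' @export
holdout_cv <- function(subject_maps, ratio = 0.10, n_iterations = 300L,
                       confidence = 0.05, seed = NULL) {
  n <- length(subject_maps)
  if (n < 3L) stop("hold-out needs at least 3 subjects", call. = FALSE)
  k <- round(ratio * n)
  if (k < 1L || k >= n)
    stop(sprintf("ratio %.3f yields an empty group for n=%d", ratio, n),
         call. = FALSE)
  template <- subject_maps[[1]]
  for (m in subject_maps[-1]) if (!same_grid(m, template))
    stop("subject maps are not on one grid", call. = FALSE)
  grids <- vapply(subject_maps, function(m) as.numeric(m$grid != 0),
                  numeric(length(template$grid)))
  run <- function() {
    vapply(seq_len(n_iterations), function(i) {
      small <- sample.int(n, k)
      pa <- rowMeans(grids[, small, drop = FALSE]) >= confidence
      pb <- rowMeans(grids[, -small, drop = FALSE]) >= confidence
      sa <- sum(pa); sb <- sum(pb)
      if (sa + sb == 0L) return(1)
      2 * sum(pa & pb) / (sa + sb)
    }, numeric(1))
  }
  vals <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  structure(list(dice = vals, mean = mean(vals),
                 summary = box_whisker(vals),
                 ratio = ratio, n_iterations = as.integer(n_iterations),
                 confidence = confidence, n_subjects = n, small_group = k),
            class = "holdout_result")
}

#' @export
print.holdout_result <- function(x, ...) {
  cat(sprintf("<holdout_result n=%d ratio=%.2f iters=%d mean dice=%.3f [%.3f, %.3f]>\n",
              x$n_subjects, x$ratio, x$n_iterations, x$mean,
              x$summary["lower_whisker"], x$summary["upper_whisker"]))
  invisible(x)
}

box_whisker <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lw <- min(v[v >= q[1] - 1.5 * iqr])
  uw <- max(v[v <= q[3] + 1.5 * iqr])
  c(lower_whisker = lw, q1 = q[1], median = q[2], q3 = q[3],
    upper_whisker = uw)
}

#' Repeated-processing reliability
#'
#' Dice overlap for every unordered pair of runs of the pipeline on
#' identical input (R runs yield choose(R, 2) values; 10 runs give 45).
#'
#' @param run_maps List (>= 2) of binary [scalar_map]s, one per run.
#' @return List of class `reliability_result` with `mode`, pairwise `dice`
#'   values, `pairs` (index matrix), `mean`, `summary`.
#' @export
repeated_processing <- function(run_maps) {
  r <- length(run_maps)
  if (r < 2L) stop("need at least 2 runs", call. = FALSE)
  pairs <- utils::combn(r, 2L)
  vals <- apply(pairs, 2L, function(p)
    dice(run_maps[[p[1]]], run_maps[[p[2]]])$dice)
  structure(list(mode = "repeated_processing", dice = vals, pairs = t(pairs),
                 mean = mean(vals), summary = box_whisker(vals)),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability_result %s pairs=%d mean dice=%.3f>\n",
              x$mode, length(x$dice), x$mean))
  invisible(x)
}

#' Test-retest overlap of two sessions
#'
#' Applies the supplied session-2 to session-1 transform (identity for
#' phantoms) and computes the Dice overlap.
#'
#' @param map_t1,map_t2 Binary [scalar_map]s of the two sessions.
#' @param transform_t2_to_t1 A [spatial_transform]; identity by default.
#' @return A `dice_report`.
#' @export
test_retest <- function(map_t1, map_t2,
                        transform_t2_to_t1 = spatial_transform("identity")) {
  m2 <- apply_transform(map_t2, transform_t2_to_t1, target_grid = map_t1)
  dice(map_t1, m2)
}

#' Test-retest table for seed and target ROIs
#'
#' Per ROI type, tract and hemisphere: mean and sample SD of the Dice
#' overlap across subject pairs, mirroring a per-cell mean +/- sd layout.
#'
#' @param pairs List of entries, each a list with `a` and `b` (binary
#'   [scalar_map]s of the two sessions), `tract`, `roi` (e.g. `"seed"` or
#'   `"target"`) and `hemisphere`.
#' @return data.frame with columns tract, roi, hemisphere, n, mean_dice,
#'   sd_dice. Cells with no pairs are omitted with a warning.
#' @export
roi_test_retest <- function(pairs) {
  if (!length(pairs)) {
    warning("no ROI pairs supplied; empty table", call. = FALSE)
    return(data.frame(tract = character(), roi = character(),
                      hemisphere = character(), n = integer(),
                      mean_dice = numeric(), sd_dice = numeric()))
  }
  df <- do.call(rbind, lapply(pairs, function(p)
    data.frame(tract = p$tract, roi = p$roi, hemisphere = p$hemisphere,
               dice = dice(p$a, p$b)$dice)))
  agg <- do.call(rbind, lapply(split(df, df[c("tract", "roi", "hemisphere")],
                                     drop = TRUE), function(g)
    data.frame(tract = g$tract[1], roi = g$roi[1], hemisphere = g$hemisphere[1],
               n = nrow(g), mean_dice = mean(g$dice),
               sd_dice = if (nrow(g) > 1) stats::sd(g$dice) else 0)))
  rownames(agg) <- NULL
  agg
}
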