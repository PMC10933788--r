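#' Did a result map hit its target?
#'
#' TRUE iff the significant voxel set intersects the target ROI (ROI
#' targets) or contains the target voxel (voxel targets). An empty
#' significant set is never a hit.
#'
#' @param zmap an `lsm_zmap` (or an integer vector of significant voxel
#'   indices).
#' @param target a [target_spec()].
#' @param atlas a `lesion_atlas` (ROI targets).
#' @return logical flag.
#' @export
hit <- function(zmap, target, atlas = NULL) {
  sig <- if (inherits(zmap, "lsm_zmap")) zmap$significant_idx
         else as_voxel_idx(zmap)
  if (!length(sig)) return(FALSE)
  tgt <- target_indices(target, atlas)
  length(intersect(sig, tgt)) > 0L
}

target_indices <- function(target, atlas = NULL) {
  if (target$kind == "roi") {
    if (is.null(atlas)) stop("ROI target requires an atlas")
    atlas_roi_indices(atlas, target$roi_label)
  } else target$voxel
}

#' Peak voxel set of a z-map
#'
#' All tested voxels attaining the maximum z; ties are kept as a set
#' (result maps routinely carry multi-voxel peak plateaus).
#'
#' @param zmap an `lsm_zmap`.
#' @return Integer vector of linear voxel indices.
#' @export
peak_voxel_set <- function(zmap) {
  ok <- !is.na(zmap$z)
  if (!any(ok)) stop("no tested voxel carries a statistic")
  mx <- max(zmap$z[ok])
  zmap$tested_idx[ok & zmap$z == mx]
}

#' Distance from the centroid of a voxel set to a target voxel
#'
#' Euclidean distance in mm between the unweighted centroid of the voxel
#' centers and the target voxel center.
#'
#' @param sig_idx non-empty integer vector of voxel indices.
#' @param target_voxel linear index of the target voxel.
#' @param grid a [grid_spec()].
#' @return distance in mm (`NA` for an empty set).
#' @export
com_distance <- function(sig_idx, target_voxel, grid) {
  if (!length(sig_idx)) return(NA_real_)
  com <- colMeans(voxel_coords_mm(sig_idx, grid))
  tc <- voxel_coords_mm(target_voxel, grid)[1, ]
  sqrt(sum((com - tc)^2))
}

# Mean distance (mm) of each voxel in a set to the target voxel.
mean_distance_to_target <- function(idx, target_voxel, grid) {
  if (!length(idx)) return(NA_real_)
  co <- voxel_coords_mm(idx, grid)
  tc <- voxel_coords_mm(target_voxel, grid)[1, ]
  mean(sqrt(rowSums(sweep(co, 2, tc, `-`)^2)))
}

#' Cluster-size-weighted displacement
#'
#' Standardizes a displacement by the equivalent-sphere radius of the
#' cluster: distance / r with r = (3 V / 4 pi)^(1/3) and V = cluster voxel
#' count x voxel volume (mm3). Dimensionless; a displacement of one
#' equivalent radius scores 1.
#'
#' @param distance_mm displacement in mm.
#' @param cluster_n_voxels cluster size in voxels (>= 1).
#' @param grid a [grid_spec()].
#' @return dimensionless weighted displacement.
#' @export
weighted_displacement <- function(distance_mm, cluster_n_voxels, grid) {
  stopifnot(all(cluster_n_voxels >= 1))
  v <- cluster_n_voxels * voxel_volume_mm3(grid)
  distance_mm / (3 * v / (4 * pi))^(1 / 3)
}

#' Maximum achievable Dice for unequal set sizes
#'
#' 2 min(|A|, |B|) / (|A| + |B|): the Dice bound imposed when one result
#' map is larger than the other (a 2:1 size ratio bounds Dice at 2/3).
#'
#' @param n_a,n_b positive set sizes.
#' @return real in (0, 1].
#' @export
max_achievable_dice <- function(n_a, n_b) {
  stopifnot(all(n_a >= 1), all(n_b >= 1))
  2 * pmin(n_a, n_b) / (n_a + n_b)
}

#' Evaluate one result map against its ground-truth target
#'
#' @param zmap an `lsm_zmap`.
#' @param target a [target_spec()].
#' @param atlas a `lesion_atlas` (ROI targets).
#' @return One-row data.frame: `hit`, `n_significant`, `dice_vs_target`,
#'   `com_distance_mm`, `n_peak`, `peak_distance_mm`,
#'   `weighted_displacement`, `peak_in_target`, `peak_target_overlap`.
#'   Distance/Dice fields are `NA` exactly when the significant set is
#'   empty; voxel-distance fields are `NA` for ROI targets. The "cluster"
#'   for size weighting is the entire significant set.
#' @export
evaluate_zmap <- function(zmap, target, atlas = NULL) {
  sig <- zmap$significant_idx
  tgt <- target_indices(target, atlas)
  n_sig <- length(sig)
  d <- if (n_sig) dice(sig, tgt)$dice else NA_real_
  pk <- tryCatch(peak_voxel_set(zmap), error = function(e) integer(0))
  if (target$kind == "voxel") {
    comd <- if (n_sig) com_distance(sig, tgt, zmap$grid) else NA_real_
    pkd <- if (n_sig && length(pk))
      mean_distance_to_target(pk, tgt, zmap$grid) else NA_real_
    wdisp <- if (n_sig && !is.na(pkd))
      weighted_displacement(pkd, n_sig, zmap$grid) else NA_real_
    pov <- NA_real_
    pin <- NA
  } else {
    comd <- pkd <- wdisp <- NA_real_
    pov <- if (length(pk)) length(intersect(pk, tgt)) / length(pk)
           else NA_real_
    pin <- if (length(pk) && n_sig) pov > 0 else NA
  }
  data.frame(hit = hit(zmap, target, atlas), n_significant = n_sig,
             dice_vs_target = d, com_distance_mm = comd,
             n_peak = length(pk), peak_distance_mm = pkd,
             weighted_displacement = wdisp, peak_in_target = pin,
             peak_target_overlap = pov)
}

#' Dice agreement of two z-maps over a threshold grid
#'
#' Holds arm B at its own threshold (its stored significant set) and
#' re-binarizes arm A's z-map at `k` evenly spaced thresholds between
#' `lower` and arm B's threshold (both endpoints included).
#'
#' @param zmap_a the swept z-map.
#' @param zmap_b the fixed z-map (typically at its Bonferroni threshold).
#' @param lower lowest threshold (default 3; must lie below the fixed arm's
#'   threshold).
#' @param k number of thresholds (>= 2, default 50).
#' @return data.frame with one row per threshold: `threshold`, `dice`,
#'   `n_a`, `n_b`, `max_achievable`.
#' @export
threshold_sweep <- function(zmap_a, zmap_b, lower = 3, k = 50) {
  stopifnot(k >= 2)
  upper <- zmap_b$threshold_z
  if (!is.finite(upper) || lower >= upper)
    stop("`lower` must lie below the fixed arm's threshold")
  th <- seq(lower, upper, length.out = k)
  sig_b <- zmap_b$significant_idx
  za <- zmap_a$z
  rows <- lapply(th, function(t0) {
    sig_a <- zmap_a$tested_idx[!is.na(za) & za >= t0]
    dr <- dice(sig_a, sig_b)
    data.frame(threshold = t0, dice = dr$dice, n_a = dr$n_a, n_b = dr$n_b,
               max_achievable = if (dr$n_a >= 1 && dr$n_b >= 1)
                 max_achievable_dice(dr$n_a, dr$n_b) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Summarize threshold sweeps over all paired analyses
#'
#' Means per threshold exclude pairs whose Dice is undefined (both maps
#' empty); the best threshold is the argmax of the mean Dice, ties broken
#' toward the lowest threshold.
#'
#' @param rows long data.frame: [threshold_sweep()] rows stacked over pairs,
#'   with a `pair` identifier column.
#' @return Object of class `sweep_result`: `thresholds`, `mean_dice`,
#'   `best_threshold`, `best_mean_dice`, `max_achievable_dice_mean` (mean
#'   over pairs at the best threshold), `n_pairs`.
#' @export
sweep_summary <- function(rows) {
  stopifnot(all(c("pair", "threshold", "dice") %in% names(rows)))
  th <- sort(unique(rows$threshold))
  mean_dice <- vapply(th, function(t0) {
    v <- rows$dice[rows$threshold == t0]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(mean_dice))) {
    warning("all thresholds have undefined mean Dice")
    best_i <- 1L
  } else {
    best_i <- which(mean_dice == max(mean_dice, na.rm = TRUE))[1]
  }
  at_best <- rows[rows$threshold == th[best_i], ]
  structure(list(thresholds = th, mean_dice = mean_dice,
                 best_threshold = th[best_i],
                 best_mean_dice = mean_dice[best_i],
                 max_achievable_dice_mean =
                   mean(at_best$max_achievable, na.rm = TRUE),
                 n_pairs = length(unique(rows$pair))),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "<sweep_result> %d pairs, %d thresholds [%.3f, %.3f]\n  best mean Dice %.3f at z = %.3f (mean max-achievable %.3f)\n",
    x$n_pairs, length(x$thresholds), min(x$thresholds), max(x$thresholds),
    x$best_mean_dice, x$best_threshold, x$max_achievable_dice_mean))
  invisible(x)
}

#' Compare hit proportions between two arms
#'
#' Pearson chi-squared (df = 1, no continuity correction) on the 2x2 table
#' of hits/misses by arm.
#'
#' @param hits_a,n_a hits and analyses in arm A.
#' @param hits_b,n_b hits and analyses in arm B.
#' @return List with `chi_square` and `p` (`NA` with a warning on
#'   degenerate margins).
#' @export
compare_hit_proportions <- function(hits_a, n_a, hits_b, n_b) {
  stopifnot(n_a >= 1, n_b >= 1, hits_a <= n_a, hits_b <= n_b)
  tab <- rbind(c(hits_a, n_a - hits_a), c(hits_b, n_b - hits_b))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    warning("degenerate margins; chi-squared undefined")
    return(list(chi_square = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi_square = unname(ct$statistic), p = unname(ct$p.value))
}
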