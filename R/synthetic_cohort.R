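#' Vascular-territory model for the synthetic lesion generator
#'
#' Lesions in stroke cohorts cluster in vascular territories rather than
#' falling uniformly over the brain. The generator emulates this with a
#' small set of ellipsoidal territories, sampled by weight. The default
#' model places six territories (two middle-, two anterior- and two
#' posterior-circulation analogues, one per hemisphere) inside an
#' ellipsoidal brain region, with middle-circulation territories weighted
#' heaviest.
#'
#' @param centers_mm matrix (one row per territory) of territory centers in
#'   mm offsets from the grid center.
#' @param axes_mm matrix of per-territory ellipsoid radii (mm).
#' @param weights sampling probabilities; non-negative, normalized to sum 1.
#' @return Object of class `territory_model`.
#' @export
territory_model <- function(centers_mm, axes_mm, weights) {
  centers_mm <- matrix(centers_mm, ncol = 3)
  axes_mm <- matrix(axes_mm, ncol = 3)
  if (nrow(centers_mm) < 1L) stop("need at least one territory")
  if (nrow(axes_mm) != nrow(centers_mm) ||
      length(weights) != nrow(centers_mm))
    stop("centers, axes and weights must have one entry per territory")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and sum to a positive value")
  structure(list(centers_mm = centers_mm, axes_mm = axes_mm,
                 weights = weights / sum(weights)),
            class = "territory_model")
}

#' @rdname territory_model
#' @param grid a [grid_spec()] used to scale the default layout.
#' @export
default_territories <- function(grid) {
  fov <- grid$shape * grid$voxel_size_mm       # field of view, mm
  sc <- fov / c(128, 160, 128)                 # scale from the reference FOV
  centers <- rbind(
    c(-32,   0,  0), c(32,   0,  0),           # middle circulation L/R
    c(-16, -44, -8), c(16, -44, -8),           # posterior L/R
    c(-10,  36, 16), c(10,  36, 16))           # anterior L/R
  axes <- rbind(
    c(36, 44, 36), c(36, 44, 36),
    c(24, 28, 24), c(24, 28, 24),
    c(20, 30, 24), c(20, 30, 24))
  territory_model(sweep(centers, 2, sc, `*`), sweep(axes, 2, sc, `*`),
                  weights = c(0.35, 0.35, 0.06, 0.06, 0.09, 0.09))
}

#' Parameters of the synthetic paired-lesion cohort
#'
#' The generator emulates the statistical structure of a paired two-modality
#' stroke cohort: territory-clustered lesion placement, log-normal lesion
#' volumes, and per-patient cross-modality disagreement (boundary noise,
#' center jitter, size inflation of arm B, occasional dropped components).
#' The disagreement magnitude is calibrated so the default cohort achieves a
#' mean pair Dice near 0.420 and a paired-volume Pearson correlation near
#' 0.778, with roughly 30% of union voxels shared, 30% exclusive to arm A
#' and 40% exclusive to arm B, and more voxels passing the coverage filter
#' in arm B than arm A.
#'
#' @param n_patients cohort size (default 85).
#' @param grid shared [grid_spec()] (default 32 x 40 x 32 at 4 mm).
#' @param territory_model a [territory_model()]; default layout if `NULL`.
#' @param target_pair_dice_mean,target_pair_dice_sd calibration targets for
#'   the cross-arm Dice distribution (defaults 0.420 / 0.275).
#' @param median_volume_mm3 median lesion volume (default 18000 mm3).
#' @param size_log_sd SD of log lesion volume (default 1.1).
#' @param arm_b_size_inflation mean multiplicative size inflation of arm B
#'   relative to the shared base lesion (default 1.33, >= 1).
#' @param arm_size_noise_sd SD of each arm's log size multiplier; drives the
#'   paired-volume correlation (default 0.45).
#' @param perturb_mag magnitude of the smoothed boundary noise added per arm
#'   before re-thresholding; drives the pair Dice (default 1.0, fixed by a
#'   one-dimensional pilot calibration against `target_pair_dice_mean`).
#' @param perturb_mag_log_sd SD of the per-patient log magnitude multiplier
#'   (default 0.6); spreads the pair-Dice distribution the way per-patient
#'   scan-interval and quality differences spread real cross-modality
#'   agreement.
#' @param jitter_sd_vox SD (voxels) of the per-arm integer center jitter
#'   (default 0.8).
#' @param false_negative_rate per-arm probability of dropping one connected
#'   component when the degraded mask has several (default 0.05, in [0,1)).
#' @param shape_noise smoothed-noise amplitude shaping each base lesion
#'   (default 0.35).
#' @param seed root seed; patient i derives a child stream from (seed, i),
#'   so cohorts are stable under `n_patients` changes up to the shared
#'   prefix.
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 85,
                          grid = grid_spec(c(32, 40, 32), c(4, 4, 4)),
                          territory_model = NULL,
                          target_pair_dice_mean = 0.420,
                          target_pair_dice_sd = 0.275,
                          median_volume_mm3 = 18000,
                          size_log_sd = 1.1,
                          arm_b_size_inflation = 1.33,
                          arm_size_noise_sd = 0.45,
                          perturb_mag = 1.0,
                          perturb_mag_log_sd = 0.6,
                          jitter_sd_vox = 0.8,
                          false_negative_rate = 0.05,
                          shape_noise = 0.35,
                          seed = 42L) {
  if (is.null(territory_model)) territory_model <- default_territories(grid)
  stopifnot(n_patients >= 1, inherits(grid, "grid_spec"),
            inherits(territory_model, "territory_model"),
            target_pair_dice_mean > 0, target_pair_dice_mean < 1,
            target_pair_dice_sd >= 0, size_log_sd >= 0,
            arm_b_size_inflation >= 1, arm_size_noise_sd >= 0,
            perturb_mag >= 0, perturb_mag_log_sd >= 0, jitter_sd_vox >= 0,
            false_negative_rate >= 0, false_negative_rate < 1,
            median_volume_mm3 > 0)
  structure(list(n_patients = as.integer(n_patients), grid = grid,
                 territory_model = territory_model,
                 target_pair_dice_mean = target_pair_dice_mean,
                 target_pair_dice_sd = target_pair_dice_sd,
                 median_volume_mm3 = median_volume_mm3,
                 size_log_sd = size_log_sd,
                 arm_b_size_inflation = arm_b_size_inflation,
                 arm_size_noise_sd = arm_size_noise_sd,
                 perturb_mag = perturb_mag,
                 perturb_mag_log_sd = perturb_mag_log_sd,
                 jitter_sd_vox = jitter_sd_vox,
                 false_negative_rate = false_negative_rate,
                 shape_noise = shape_noise,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

# Deterministic child seed for (root seed, patient index, stage).
child_seed <- function(seed, i, stage = 0L) {
  s <- (as.double(seed %% 2147483647L) * 48271 + i * 1009 + stage * 7919) %%
    2147483647
  as.integer(s) + 1L
}

#' Brain region of a grid
#'
#' Ellipsoid centered on the grid with semi-axes 0.44 of each extent; all
#' synthetic lesions, atlas labels and territory centers live inside it.
#'
#' @param grid a [grid_spec()].
#' @return Sorted integer vector of in-brain linear voxel indices.
#' @export
brain_region <- function(grid) {
  d <- grid$shape
  ctr <- (d + 1) / 2
  ax <- 0.44 * d
  i <- (seq_len(d[1]) - ctr[1]) / ax[1]
  j <- (seq_len(d[2]) - ctr[2]) / ax[2]
  k <- (seq_len(d[3]) - ctr[3]) / ax[3]
  r2 <- outer(outer(i^2, j^2, `+`), k^2, `+`)
  which(r2 <= 1)
}

# Shift a 3D array by an integer voxel offset, zero fill.
shift_array <- function(arr, shift) {
  if (all(shift == 0L)) return(arr)
  d <- dim(arr)
  out <- array(0, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    s <- shift[ax]
    if (abs(s) >= d[ax]) return(out)
    if (s >= 0) { dst[[ax]] <- (1 + s):d[ax]; src[[ax]] <- 1:(d[ax] - s) }
    else        { dst[[ax]] <- 1:(d[ax] + s); src[[ax]] <- (1 - s):d[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Toy ROI atlas
#'
#' Partitions the brain region into `n_rois` non-empty, connected integer
#' labels by multi-source breadth-first region growing from randomly placed
#' seeds (a stand-in parcellation for testing ROI-level designs; it carries
#' no anatomical meaning).
#'
#' @param grid a [grid_spec()].
#' @param n_rois number of ROIs (>= 1, <= number of in-brain voxels).
#' @param seed integer seed; the atlas is deterministic given (grid, n_rois,
#'   seed).
#' @return A `lesion_atlas` (see [read_atlas()]).
#' @export
make_toy_atlas <- function(grid, n_rois = 24, seed = 1L) {
  brain <- brain_region(grid)
  n_rois <- as.integer(n_rois)
  if (n_rois < 1L || n_rois > length(brain))
    stop("n_rois infeasible for this grid (brain has ",
         length(brain), " voxels)")
  labels <- array(0L, dim = grid$shape)
  if (n_rois == 1L) {
    labels[brain] <- 1L
  } else {
    set.seed(child_seed(seed, 0L, 101L))
    seeds <- sample(brain, n_rois)
    lab_full <- integer(n_voxels(grid))
    lab_full[brain] <- -1L
    lab_full[seeds] <- seq_len(n_rois)
    frontier <- as.list(seeds)
    remaining <- length(brain) - n_rois
    while (remaining > 0L) {
      grew <- FALSE
      for (r in seq_len(n_rois)) {
        if (!length(frontier[[r]])) next
        nb <- unique(neighbors6(frontier[[r]], grid))
        nb <- nb[lab_full[nb] == -1L]
        lab_full[nb] <- r
        frontier[[r]] <- nb
        remaining <- remaining - length(nb)
        if (length(nb)) grew <- TRUE
      }
      if (!grew) break   # isolated brain voxels (should not occur)
    }
    lab_full[lab_full == -1L] <- 0L
    labels[seq_along(lab_full)] <- lab_full
  }
  structure(list(grid = grid, labels = labels), class = "lesion_atlas")
}

#' @export
print.lesion_atlas <- function(x, ...) {
  labs <- x$labels[x$labels > 0]
  cat(sprintf("<lesion_atlas> %d ROIs over %d voxels\n",
              length(unique(labs)), length(labs)))
  invisible(x)
}

#' @rdname make_toy_atlas
#' @param atlas a `lesion_atlas`.
#' @param label an ROI label.
#' @return `atlas_roi_indices`: linear voxel indices carrying `label`.
#' @export
atlas_roi_indices <- function(atlas, label) {
  idx <- which(atlas$labels == as.integer(label))
  if (!length(idx)) stop("ROI label ", label, " is empty or absent")
  idx
}

#' @rdname make_toy_atlas
#' @export
atlas_labels <- function(atlas) sort(unique(atlas$labels[atlas$labels > 0L]))

#' Sample one synthetic base lesion
#'
#' Picks a territory by weight, places an anisotropic blob with smoothed
#' shape noise around a jittered center, and keeps the top-V in-brain voxels
#' by blob score (V drawn log-normally), restricted to the connected
#' component containing the blob peak. Uses the current RNG state; seed
#' outside for reproducibility.
#'
#' @param params a [cohort_params()].
#' @param brain optional precomputed [brain_region()] index vector.
#' @return List with `idx` (linear voxel indices of the lesion) and
#'   `territory` (sampled territory index).
#' @export
sample_lesion <- function(params, brain = NULL) {
  grid <- params$grid
  tm <- params$territory_model
  if (is.null(brain)) brain <- brain_region(grid)
  d <- grid$shape
  ctr_mm <- (d - 1) / 2 * grid$voxel_size_mm
  coords <- voxel_coords_mm(brain, grid)

  terr <- sample.int(length(tm$weights), 1L, prob = tm$weights)
  # tight center spread concentrates lesions in territory cores, giving the
  # deep overlay maxima (several tens of patients per voxel) that stroke
  # cohorts show
  center <- ctr_mm + tm$centers_mm[terr, ] +
    stats::rnorm(3, 0, tm$axes_mm[terr, ] / 8)

  vol_vox <- length(brain)
  target_n <- round(exp(stats::rnorm(1, log(params$median_volume_mm3 /
                                             voxel_volume_mm3(grid)),
                                     params$size_log_sd)))
  target_n <- max(4L, min(as.integer(target_n), as.integer(0.4 * vol_vox)))

  ax <- tm$axes_mm[terr, ] * exp(stats::rnorm(3, 0, 0.3))
  dd <- sweep(coords, 2, center, `-`)
  d2 <- rowSums(sweep(dd, 2, ax, `/`)^2)
  noise <- smooth3(array(stats::rnorm(n_voxels(grid)), dim = d), 1.5)
  ns <- noise[brain]
  # normalize the distance term to the target lesion's own radius so shape
  # noise perturbs the boundary without detaching the blob from its core
  d2_scale <- sort(d2, partial = target_n)[target_n]
  score <- -d2 / max(d2_scale, 1e-9) +
    params$shape_noise * (ns / stats::sd(ns))
  ord <- order(score, decreasing = TRUE)
  lesion <- brain[ord[seq_len(target_n)]]
  comp <- label_components(lesion, grid)
  keep <- comp[match(brain[ord[1L]], attr(comp, "idx"))]
  list(idx = attr(comp, "idx")[comp == keep], territory = terr)
}

#' Degrade a base lesion into a discordant two-arm pair
#'
#' Each arm is an independent perturbation of the base lesion: the base is
#' smoothed, shifted by a small integer center jitter, mixed with smoothed
#' noise of magnitude `perturb_mag`, and re-thresholded to a log-normally
#' drawn target size (arm B inflated by `arm_b_size_inflation` on average).
#' With probability `false_negative_rate` an arm drops one connected
#' component when several exist, emulating single-modality false negatives
#' in multi-focal lesions. Zero perturbation, unit inflation, zero size
#' noise and zero false-negative rate return the base unchanged in both
#' arms. Uses the current RNG state.
#'
#' @param base_idx linear voxel indices of the base lesion (non-empty).
#' @param params a [cohort_params()].
#' @param brain optional precomputed [brain_region()].
#' @return List with `A` and `B` index vectors.
#' @export
degrade_to_pair <- function(base_idx, params, brain = NULL) {
  grid <- params$grid
  if (!length(base_idx)) stop("base lesion is empty")
  if (is.null(brain)) brain <- brain_region(grid)
  base_arr <- array(0, dim = grid$shape)
  base_arr[base_idx] <- 1
  basef <- smooth3(base_arr, 1.2)
  # one disagreement magnitude per patient, shared by both arms
  pat_mag <- params$perturb_mag *
    exp(stats::rnorm(1, 0, params$perturb_mag_log_sd))
  out <- list()
  # boundary-localized disagreement: relative volume error shrinks with
  # lesion size roughly as V^(-1/3) (surface-to-volume), so large lesions
  # agree more tightly across arms than small ones
  ref_n <- params$median_volume_mm3 / voxel_volume_mm3(grid)
  size_scale <- min((ref_n / length(base_idx))^(1 / 6), 2)
  for (arm in c("A", "B")) {
    infl <- if (arm == "B") params$arm_b_size_inflation else 1
    sn <- params$arm_size_noise_sd * size_scale
    # truncated at +/- 1.8 SD: unbounded multiplicative size errors would
    # let a single giant lesion pair dominate the volume correlation
    zmul <- max(min(stats::rnorm(1), 1.8), -1.8)
    mult <- infl * exp(sn * zmul - sn^2 / 2)
    n_arm <- max(1L, round(length(base_idx) * mult))
    shift <- as.integer(round(stats::rnorm(3, 0, params$jitter_sd_vox)))
    noise_amp <- pat_mag
    if (noise_amp == 0 && all(shift == 0L) && n_arm == length(base_idx)) {
      idx <- base_idx
    } else {
      f <- shift_array(basef, shift)
      if (noise_amp > 0) {
        nz <- smooth3(array(stats::rnorm(n_voxels(grid)), dim = grid$shape),
                      1.2)
        nb <- nz[brain]
        f <- f + noise_amp * stats::sd(basef[brain]) *
          array(as.numeric(nz / stats::sd(nb)), dim = grid$shape)
      }
      # plain rank threshold: degraded masks may be multi-focal (the base
      # must be connected, its per-arm delineations need not be)
      v <- f[brain]
      ord <- order(v, decreasing = TRUE)
      idx <- sort(brain[ord[seq_len(min(n_arm, length(brain)))]])
    }
    if (params$false_negative_rate > 0 &&
        stats::runif(1) < params$false_negative_rate) {
      comp <- label_components(idx, grid)
      k <- attr(comp, "n_components")
      if (k >= 2L) {
        drop <- sample.int(k, 1L)
        idx <- attr(comp, "idx")[comp != drop]
      }
    }
    out[[arm]] <- idx
  }
  out
}

#' Generate a paired two-arm synthetic cohort
#'
#' Pure function of its parameters (including the seed): per-patient child
#' RNG streams make the cohort reproducible and stable under `n_patients`
#' changes up to the shared prefix. Achieved summary statistics (pair Dice
#' mean/SD, paired-volume Pearson correlation, mean exclusive fractions,
#' per-arm voxel counts) are recomputed from the emitted masks and stored.
#'
#' @param params a [cohort_params()].
#' @return Object of class `cohort_pair`: list with `patients` (each a list
#'   of `patient_id`, `mask_A`, `mask_B`), `params`, `grid`, and
#'   `achieved_stats`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  grid <- params$grid
  brain <- brain_region(grid)
  patients <- vector("list", params$n_patients)
  for (i in seq_len(params$n_patients)) {
    set.seed(child_seed(params$seed, i, 1L))
    base <- sample_lesion(params, brain)
    pair <- degrade_to_pair(base$idx, params, brain)
    mk <- function(idx, arm) {
      arr <- array(0L, dim = grid$shape)
      arr[idx] <- 1L
      lesion_mask(arr, grid, sprintf("p%03d", i), arm)
    }
    patients[[i]] <- list(patient_id = sprintf("p%03d", i),
                          territory = base$territory,
                          mask_A = mk(pair$A, "A"), mask_B = mk(pair$B, "B"))
  }
  cohort <- structure(list(patients = patients, params = params, grid = grid),
                      class = "cohort_pair")
  cohort$achieved_stats <- cohort_stats(cohort)
  cohort
}

#' @rdname generate_cohort
#' @param cohort a `cohort_pair`.
#' @export
cohort_stats <- function(cohort) {
  ds <- lapply(cohort$patients, function(p) dice(p$mask_A, p$mask_B))
  dv <- vapply(ds, `[[`, numeric(1), "dice")
  vol_a <- vapply(cohort$patients, function(p) mask_volume_mm3(p$mask_A),
                  numeric(1))
  vol_b <- vapply(cohort$patients, function(p) mask_volume_mm3(p$mask_B),
                  numeric(1))
  list(pair_dice_mean = mean(dv, na.rm = TRUE),
       pair_dice_sd = stats::sd(dv, na.rm = TRUE),
       volume_correlation = stats::cor(vol_a, vol_b),
       frac_both_mean = mean(vapply(ds, `[[`, numeric(1), "frac_both"),
                             na.rm = TRUE),
       frac_a_only_mean = mean(vapply(ds, `[[`, numeric(1), "frac_a_only"),
                               na.rm = TRUE),
       frac_b_only_mean = mean(vapply(ds, `[[`, numeric(1), "frac_b_only"),
                               na.rm = TRUE),
       mean_volume_a_mm3 = mean(vol_a), mean_volume_b_mm3 = mean(vol_b))
}

#' @export
print.cohort_pair <- function(x, ...) {
  s <- x$achieved_stats
  cat(sprintf(
    "<cohort_pair> %d patients on %dx%dx%d grid\n  pair Dice %.3f (SD %.3f), volume r %.3f, both/A/B %.0f%%/%.0f%%/%.0f%%\n",
    length(x$patients), x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
    s$pair_dice_mean, s$pair_dice_sd, s$volume_correlation,
    100 * s$frac_both_mean, 100 * s$frac_a_only_mean, 100 * s$frac_b_only_mean))
  invisible(x)
}

#' @rdname generate_cohort
#' @param arm `"A"` or `"B"`.
#' @return `cohort_arm`: list of [lesion_mask()] for one arm.
#' @export
cohort_arm <- function(cohort, arm = c("A", "B")) {
  arm <- match.arg(arm)
  lapply(cohort$patients, function(p) p[[paste0("mask_", arm)]])
}

#' Calibrate the pair-degradation magnitude
#'
#' One-dimensional pilot search: evaluates the achieved mean pair Dice over
#' a grid of `perturb_mag` values (expected Dice decreases monotonically in
#' the magnitude) and returns the magnitude whose pilot cohort lands closest
#' to `target_pair_dice_mean`. Used once to fix the default; not run as part
#' of cohort generation.
#'
#' @param params a [cohort_params()] (its `perturb_mag` is ignored).
#' @param magnitudes candidate magnitudes.
#' @param n_pilot pilot cohort size per magnitude.
#' @return data.frame of magnitudes and achieved mean Dice, with the chosen
#'   magnitude in attribute `"best"`.
#' @export
calibrate_perturbation <- function(params, magnitudes = seq(0.2, 1.6, by = 0.2),
                                   n_pilot = 60) {
  res <- vapply(magnitudes, function(m) {
    p <- params
    p$perturb_mag <- m
    p$n_patients <- as.integer(n_pilot)
    generate_cohort(p)$achieved_stats$pair_dice_mean
  }, numeric(1))
  out <- data.frame(perturb_mag = magnitudes, mean_pair_dice = res)
  attr(out, "best") <-
    magnitudes[which.min(abs(res - params$target_pair_dice_mean))]
  out
}

#' Write a cohort as NIfTI fixtures plus a CSV manifest
#'
#' @param cohort a `cohort_pair`.
#' @param dir output directory (created if needed).
#' @return The manifest data.frame (patient_id, arm, file, volume_mm3),
#'   invisibly; written as `manifest.csv` alongside the masks.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (p in cohort$patients) {
    for (arm in c("A", "B")) {
      m <- p[[paste0("mask_", arm)]]
      f <- file.path(dir, sprintf("%s_%s.nii.gz", p$patient_id, arm))
      write_mask(m, f)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p$patient_id, arm = arm, file = basename(f),
        volume_mm3 = mask_volume_mm3(m))
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and the masks.
#' @param grid optional expected [grid_spec()].
#' @return A `cohort_pair` (without generator params).
#' @export
read_cohort <- function(dir, grid = NULL) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"),
                        stringsAsFactors = FALSE)
  ids <- unique(mf$patient_id)
  patients <- lapply(ids, function(id) {
    row_a <- mf[mf$patient_id == id & mf$arm == "A", ]
    row_b <- mf[mf$patient_id == id & mf$arm == "B", ]
    if (nrow(row_a) != 1L || nrow(row_b) != 1L)
      stop("manifest must list exactly one mask per arm for ", id)
    list(patient_id = id,
         mask_A = read_mask(file.path(dir, row_a$file), grid, id, "A"),
         mask_B = read_mask(file.path(dir, row_b$file), grid, id, "B"))
  })
  g <- patients[[1]]$mask_A$grid
  cohort <- structure(list(patients = patients, params = NULL, grid = g),
                      class = "cohort_pair")
  cohort$achieved_stats <- cohort_stats(cohort)
  cohort
}
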