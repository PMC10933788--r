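#' Default configuration of the full simulation study
#'
#' Desk-scale defaults: 32 x 40 x 32 grid at 4 mm, 85 patients, n_min 8,
#' 24 toy ROIs, 500 permutations for the ROI stage (a flag raises it to the
#' conventional 2000), CT-like arm A swept against the MR-like arm B fixed
#' at its Bonferroni threshold over 50 thresholds from z = 3.
#'
#' @param ... overrides of the default fields.
#' @return A named list (class `run_config`).
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 42L,
    input = "synthetic",            # or "directory"
    mask_dir = NULL,                # directory mode: write_cohort() layout
    atlas_path = NULL,              # NULL = toy atlas
    grid_shape = c(32L, 40L, 32L),
    voxel_size_mm = c(4, 4, 4),
    n_patients = 85L,
    n_rois = 24L,
    n_min = 8L,
    alpha = 0.05,
    roi_n_permutations = 500L,
    volume_control = TRUE,          # ROI stage: residualize on volume
    sweep_lower = 3,
    sweep_k = 50L,
    max_voxel_targets = Inf,        # subsample voxel-stage targets if finite
    stages = c("masks", "roi", "voxel", "sweep"),
    write_masks = FALSE,
    out_dir = NULL)
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm)
    cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' @rdname default_run_config
#' @param path YAML config file; listed fields override the defaults.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), names(default_run_config()))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(default_run_config, y)
}

run_grid <- function(config) grid_spec(config$grid_shape, config$voxel_size_mm)

#' Descriptive comparison of the two mask arms
#'
#' Per-patient volumes, pair Dice and exclusive overlap fractions, plus
#' cohort-level paired Wilcoxon signed-rank test on volumes, Pearson
#' correlation of volumes, and summary means/SDs. With fewer than 3
#' patients only the descriptives are produced.
#'
#' @param cohort a `cohort_pair`.
#' @return List with `per_patient` (data.frame) and `summary` (list).
#' @export
stage_mask_comparison <- function(cohort) {
  rows <- lapply(cohort$patients, function(p) {
    dr <- dice(p$mask_A, p$mask_B)
    data.frame(patient_id = p$patient_id,
               volume_a_mm3 = mask_volume_mm3(p$mask_A),
               volume_b_mm3 = mask_volume_mm3(p$mask_B),
               dice = dr$dice, frac_both = dr$frac_both,
               frac_a_only = dr$frac_a_only, frac_b_only = dr$frac_b_only)
  })
  tab <- do.call(rbind, rows)
  summary <- list(
    n_patients = nrow(tab),
    mean_volume_a_mm3 = mean(tab$volume_a_mm3),
    mean_volume_b_mm3 = mean(tab$volume_b_mm3),
    mean_dice = mean(tab$dice, na.rm = TRUE),
    sd_dice = stats::sd(tab$dice, na.rm = TRUE),
    mean_frac_both = mean(tab$frac_both, na.rm = TRUE),
    mean_frac_a_only = mean(tab$frac_a_only, na.rm = TRUE),
    mean_frac_b_only = mean(tab$frac_b_only, na.rm = TRUE))
  if (nrow(tab) >= 3) {
    wt <- stats::wilcox.test(tab$volume_a_mm3, tab$volume_b_mm3,
                             paired = TRUE, exact = FALSE)
    ct <- stats::cor.test(tab$volume_a_mm3, tab$volume_b_mm3)
    summary$wilcoxon_v <- unname(wt$statistic)
    summary$wilcoxon_p <- wt$p.value
    summary$volume_correlation <- unname(ct$estimate)
    summary$volume_correlation_p <- ct$p.value
  }
  list(per_patient = tab, summary = summary)
}

#' ROI-level simulation stage
#'
#' For every ROI x arm x correction: simulate percent-damage behavior, run
#' the pooled-t LSM, and evaluate hit / Dice-vs-target / peak overlap.
#' ROIs are analyzable only when at least one tested voxel exists after the
#' n_min filter and the behavior vector has non-zero variance; other rows
#' are flagged excluded with a reason. Cross-arm result Dice is recorded
#' per ROI and correction.
#'
#' @param cohort a `cohort_pair`.
#' @param atlas a `lesion_atlas` on the cohort grid.
#' @param config a [default_run_config()] list.
#' @param corrections character subset of `c("bonferroni", "permutation")`.
#' @return List with `results` (long data.frame) and `cross_arm`
#'   (data.frame of cross-arm Dice per ROI x correction).
#' @export
stage_roi_simulations <- function(cohort, atlas, config = default_run_config(),
                                  corrections = c("bonferroni", "permutation")) {
  stopifnot(grid_equal(atlas$grid, cohort$grid))
  labels <- atlas_labels(atlas)
  arms <- c("A", "B")
  res <- list(); cross <- list()
  sig_store <- list()
  for (arm in arms) {
    masks <- cohort_arm(cohort, arm)
    ov <- lesion_overlay(masks)
    tested <- included_voxels(ov, config$n_min)
    for (li in seq_along(labels)) {
      lab <- labels[li]
      target <- target_spec("roi", roi_label = lab)
      beh <- simulate_behavior(masks, target, atlas)
      excluded <- NA_character_
      if (!length(tested)) excluded <- "no voxels pass n_min"
      else if (stats::var(beh$scores) == 0) excluded <- "constant behavior"
      for (corr in corrections) {
        key <- paste(arm, lab, corr, sep = "/")
        if (!is.na(excluded)) {
          res[[key]] <- data.frame(
            arm = arm, roi_label = lab, correction = corr, included = FALSE,
            reason = excluded, hit = NA, n_significant = NA_integer_,
            dice_vs_target = NA_real_, peak_in_target = NA,
            peak_target_overlap = NA_real_, threshold_z = NA_real_,
            n_tested = length(tested))
          next
        }
        cfg <- lsm_config(
          n_min = config$n_min, alpha = config$alpha, correction = corr,
          n_permutations = config$roi_n_permutations,
          volume_control = config$volume_control, statistic = "pooled_t",
          seed = child_seed(config$seed, li,
                            10L + match(arm, arms) * length(corrections) +
                              match(corr, corrections)))
        zm <- run_lsm(masks, beh, cfg)
        ev <- evaluate_zmap(zm, target, atlas)
        sig_store[[key]] <- zm$significant_idx
        res[[key]] <- cbind(
          data.frame(arm = arm, roi_label = lab, correction = corr,
                     included = TRUE, reason = NA_character_),
          ev[, c("hit", "n_significant", "dice_vs_target", "peak_in_target",
                 "peak_target_overlap")],
          data.frame(threshold_z = zm$threshold_z, n_tested = zm$n_tested))
      }
    }
  }
  for (lab in labels) {
    for (corr in corrections) {
      ka <- paste("A", lab, corr, sep = "/")
      kb <- paste("B", lab, corr, sep = "/")
      if (!is.null(sig_store[[ka]]) && !is.null(sig_store[[kb]])) {
        dr <- dice(sig_store[[ka]], sig_store[[kb]])
        cross[[paste(lab, corr)]] <- data.frame(
          roi_label = lab, correction = corr, cross_arm_dice = dr$dice,
          n_sig_a = dr$n_a, n_sig_b = dr$n_b)
      }
    }
  }
  list(results = do.call(rbind, c(res, list(make.row.names = FALSE))),
       cross_arm = if (length(cross))
         do.call(rbind, c(cross, list(make.row.names = FALSE))) else NULL)
}

# Voxel-stage engine shared by stage_voxel_simulations / stage_sweep /
# acceptance: z columns for target voxels of one arm, computed chunk-wise
# from the co-occurrence construction (crossprod of the binary design gives
# exact integer lesioned-and-impaired counts per voxel).
voxel_stage_design <- function(masks, n_min, alpha) {
  design <- build_design(masks, n_min)
  design$threshold_z <- if (length(design$tested_idx))
    bonferroni_z_threshold(alpha, length(design$tested_idx)) else Inf
  design
}

# z matrix (tested voxels x chosen targets) for voxel-level behavior
# planted at each target (targets indexed by their position in tested_idx).
voxel_target_z <- function(design, target_pos) {
  X <- design$X
  n <- nrow(X)
  A <- crossprod(X, X[, target_pos, drop = FALSE])
  m <- design$counts[target_pos]
  Mm <- matrix(m, nrow(A), ncol(A), byrow = TRUE)
  p <- stats::phyper(A, Mm + 1, n - Mm + 1, design$counts + 1,
                     lower.tail = FALSE)
  p_to_z(p)
}

#' Voxel-level simulation stage
#'
#' Every voxel passing the n_min filter in an arm is taken in turn as the
#' critical target: binary impairment behavior, Liebermeister statistics
#' over all tested voxels of that arm, Bonferroni threshold, and the full
#' evaluation row (hit, cluster size, center-of-mass and peak displacement,
#' size-weighted displacement). The paired subtable restricts to targets
#' tested in both arms.
#'
#' @param cohort a `cohort_pair`.
#' @param config a [default_run_config()] list; `max_voxel_targets` (with
#'   the run seed) subsamples targets for scaled-down runs.
#' @param chunk targets processed per block (memory/time trade-off).
#' @return Object of class `voxel_stage`: per-arm `tables` (data.frames),
#'   `designs`, `paired_targets` (linear indices tested in both arms).
#' @export
stage_voxel_simulations <- function(cohort, config = default_run_config(),
                                    chunk = 256L) {
  out <- list(tables = list(), designs = list())
  for (arm in c("A", "B")) {
    masks <- cohort_arm(cohort, arm)
    design <- voxel_stage_design(masks, config$n_min, config$alpha)
    V <- length(design$tested_idx)
    if (!V) stop("no voxels pass n_min in arm ", arm)
    target_pos <- seq_len(V)
    if (is.finite(config$max_voxel_targets) &&
        config$max_voxel_targets < V) {
      set.seed(child_seed(config$seed, 0L, 20L + (arm == "B")))
      target_pos <- sort(sample.int(V, config$max_voxel_targets))
    }
    coords <- voxel_coords_mm(design$tested_idx, design$grid)
    thr <- design$threshold_z
    rows <- vector("list", ceiling(length(target_pos) / chunk))
    ci <- 0L
    for (start in seq(1L, length(target_pos), by = chunk)) {
      pos <- target_pos[start:min(start + chunk - 1L, length(target_pos))]
      Z <- voxel_target_z(design, pos)
      S <- !is.na(Z) & Z >= thr
      nsig <- colSums(S)
      sums <- crossprod(S, coords)                   # C x 3
      comd <- rep(NA_real_, length(pos))
      pkd <- comd; npk <- integer(length(pos)); zt <- comd
      for (j in seq_along(pos)) {
        tgt_row <- pos[j]
        zt[j] <- Z[tgt_row, j]
        if (nsig[j] > 0) {
          com <- sums[j, ] / nsig[j]
          comd[j] <- sqrt(sum((com - coords[tgt_row, ])^2))
        }
        pk <- which(Z[, j] == max(Z[, j]))
        npk[j] <- length(pk)
        pkd[j] <- mean(sqrt(rowSums(
          sweep(coords[pk, , drop = FALSE], 2, coords[tgt_row, ], `-`)^2)))
      }
      ci <- ci + 1L
      rows[[ci]] <- data.frame(
        target_idx = design$tested_idx[pos], coverage = design$counts[pos],
        z_at_target = zt, hit = !is.na(zt) & zt >= thr, n_significant = nsig,
        com_distance_mm = comd, n_peak = npk, peak_distance_mm = pkd,
        weighted_displacement = ifelse(nsig > 0,
          weighted_displacement(pkd, pmax(nsig, 1), design$grid), NA_real_))
    }
    out$tables[[arm]] <- do.call(rbind, rows)
    out$designs[[arm]] <- design
  }
  out$paired_targets <- intersect(out$designs$A$tested_idx,
                                  out$designs$B$tested_idx)
  class(out) <- "voxel_stage"
  out
}

#' Paired z-map threshold sweep stage
#'
#' For every target tested in both arms, arm B's map is fixed at its
#' Bonferroni threshold while arm A's threshold is varied over `sweep_k`
#' evenly spaced values from `sweep_lower` up to arm B's threshold; the
#' cross-arm Dice is recorded per pair and threshold and summarized with
#' [sweep_summary()].
#'
#' @param voxstage a [stage_voxel_simulations()] result.
#' @param config a [default_run_config()] list.
#' @param max_pairs optional subsample of pairs (uses the run seed).
#' @param chunk pairs per block.
#' @return List with `rows` (long pair x threshold data.frame) and
#'   `summary` (a `sweep_result`).
#' @export
stage_sweep <- function(voxstage, config = default_run_config(),
                        max_pairs = Inf, chunk = 256L) {
  dA <- voxstage$designs$A; dB <- voxstage$designs$B
  pairs <- voxstage$paired_targets
  if (!length(pairs)) stop("no targets tested in both arms")
  if (is.finite(max_pairs) && max_pairs < length(pairs)) {
    set.seed(child_seed(config$seed, 0L, 31L))
    pairs <- sort(sample(pairs, max_pairs))
  }
  th <- seq(config$sweep_lower, dB$threshold_z,
            length.out = config$sweep_k)
  if (config$sweep_lower >= dB$threshold_z)
    stop("sweep lower bound must lie below arm B's threshold")
  posA <- match(pairs, dA$tested_idx)
  posB <- match(pairs, dB$tested_idx)
  common <- intersect(dA$tested_idx, dB$tested_idx)
  rowsA <- match(common, dA$tested_idx)   # positions of shared voxels
  rowsB <- match(common, dB$tested_idx)
  out <- vector("list", ceiling(length(pairs) / chunk))
  ci <- 0L
  for (start in seq(1L, length(pairs), by = chunk)) {
    sel <- start:min(start + chunk - 1L, length(pairs))
    ZA <- voxel_target_z(dA, posA[sel])
    ZB <- voxel_target_z(dB, posB[sel])
    SB <- !is.na(ZB) & ZB >= dB$threshold_z
    nB <- colSums(SB)
    SBc <- SB[rowsB, , drop = FALSE]
    ZAc <- ZA[rowsA, , drop = FALSE]
    blocks <- vector("list", length(th))
    for (ti in seq_along(th)) {
      SA <- !is.na(ZA) & ZA >= th[ti]
      nA <- colSums(SA)
      ov <- colSums((!is.na(ZAc) & ZAc >= th[ti]) & SBc)
      dice_v <- ifelse(nA + nB > 0, 2 * ov / (nA + nB), NA_real_)
      ma <- rep(NA_real_, length(nA))
      ok <- nA >= 1 & nB >= 1
      ma[ok] <- max_achievable_dice(nA[ok], nB[ok])
      blocks[[ti]] <- data.frame(
        pair = pairs[sel], threshold = th[ti], dice = dice_v,
        n_a = nA, n_b = nB, max_achievable = ma)
    }
    ci <- ci + 1L
    out[[ci]] <- do.call(rbind, blocks)
  }
  rows <- do.call(rbind, out)
  list(rows = rows, summary = sweep_summary(rows))
}

#' Run the full simulation study
#'
#' Orchestrates cohort generation (or loading), the descriptive mask
#' comparison, ROI-level simulations under both corrections, voxel-level
#' simulations, and the paired z-map threshold sweep. Every stochastic
#' stage derives a child seed from the root seed and the stage name, so
#' toggling stages does not shift other stages' random streams; given the
#' config (including the seed) every output is deterministic.
#'
#' @param config a [default_run_config()] list (or path handled by
#'   [read_run_config()]).
#' @return Object of class `study_report` with elements `cohort`, `atlas`,
#'   `mask_comparison`, `roi`, `voxel`, `sweep`, `config`. When
#'   `config$out_dir` is set, tables are written as CSV with a JSON
#'   manifest (and masks as NIfTI when `write_masks`).
#' @export
run_study <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  grid <- run_grid(config)
  if (identical(config$input, "directory")) {
    if (is.null(config$mask_dir)) stop("directory mode requires `mask_dir`")
    cohort <- read_cohort(config$mask_dir, grid)
  } else {
    params <- cohort_params(n_patients = config$n_patients, grid = grid,
                            seed = config$seed)
    cohort <- generate_cohort(params)
  }
  atlas <- if (!is.null(config$atlas_path)) {
    read_atlas(config$atlas_path, cohort$grid)
  } else {
    make_toy_atlas(cohort$grid, config$n_rois, config$seed)
  }
  report <- list(cohort = cohort, atlas = atlas, config = config)
  if ("masks" %in% config$stages)
    report$mask_comparison <- stage_mask_comparison(cohort)
  if ("roi" %in% config$stages)
    report$roi <- stage_roi_simulations(cohort, atlas, config)
  if ("voxel" %in% config$stages)
    report$voxel <- stage_voxel_simulations(cohort, config)
  if ("sweep" %in% config$stages) {
    if (is.null(report$voxel))
      stop("sweep stage requires the voxel stage (persisted z-maps absent)")
    report$sweep <- stage_sweep(report$voxel, config)
  }
  class(report) <- "study_report"
  if (!is.null(config$out_dir)) write_study(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  if (!is.null(x$mask_comparison)) {
    s <- x$mask_comparison$summary
    cat(sprintf("  masks: mean pair Dice %.3f (SD %.3f), volume r %.3f\n",
                s$mean_dice, s$sd_dice,
                if (!is.null(s$volume_correlation)) s$volume_correlation
                else NA))
  }
  if (!is.null(x$roi)) {
    r <- x$roi$results[x$roi$results$included %in% TRUE, ]
    for (corr in unique(r$correction)) {
      rr <- r[r$correction == corr, ]
      cat(sprintf("  roi/%s: hits A %d/%d, B %d/%d\n", corr,
                  sum(rr$hit[rr$arm == "A"]), sum(rr$arm == "A"),
                  sum(rr$hit[rr$arm == "B"]), sum(rr$arm == "B")))
    }
  }
  if (!is.null(x$voxel)) {
    for (arm in c("A", "B")) {
      t0 <- x$voxel$tables[[arm]]
      cat(sprintf(
        "  voxel/%s: %d targets, hit rate %.3f, mean peak dist %.2f mm\n",
        arm, nrow(t0), mean(t0$hit), mean(t0$peak_distance_mm, na.rm = TRUE)))
    }
  }
  if (!is.null(x$sweep)) print(x$sweep$summary)
  invisible(x)
}

#' @rdname run_study
#' @param report a `study_report`.
#' @param dir output directory.
#' @export
write_study <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(format(df, digits = 10), file.path(dir, name),
                     row.names = FALSE)
  }
  if (!is.null(report$mask_comparison)) {
    wcsv(report$mask_comparison$per_patient, "mask_comparison.csv")
    jsonlite::write_json(report$mask_comparison$summary,
                         file.path(dir, "mask_comparison_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$roi)) {
    wcsv(report$roi$results, "roi_results.csv")
    if (!is.null(report$roi$cross_arm))
      wcsv(report$roi$cross_arm, "roi_cross_arm.csv")
  }
  if (!is.null(report$voxel)) {
    wcsv(report$voxel$tables$A, "voxel_results_A.csv")
    wcsv(report$voxel$tables$B, "voxel_results_B.csv")
  }
  if (!is.null(report$sweep)) {
    wcsv(report$sweep$rows, "sweep_rows.csv")
    s <- report$sweep$summary
    jsonlite::write_json(
      list(best_threshold = s$best_threshold,
           best_mean_dice = s$best_mean_dice,
           max_achievable_dice_mean = s$max_achievable_dice_mean,
           n_pairs = s$n_pairs,
           thresholds = s$thresholds, mean_dice = s$mean_dice),
      file.path(dir, "sweep_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  if (isTRUE(report$config$write_masks))
    write_cohort(report$cohort, file.path(dir, "masks"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("lsmsim")),
    config = unclass(report$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
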