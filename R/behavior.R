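#' Ground-truth target specification
#'
#' The "critical lesion site" a simulation plants behavior on: either an
#' atlas ROI (continuous percent-damage scores) or a single voxel (binary
#' impaired/unimpaired classification).
#'
#' @param kind `"roi"` or `"voxel"`.
#' @param roi_label atlas label (kind = "roi").
#' @param voxel linear voxel index or (i,j,k) triple (kind = "voxel").
#' @param grid a [grid_spec()], required to validate a voxel target given as
#'   a triple.
#' @return Object of class `target_spec`.
#' @export
target_spec <- function(kind = c("roi", "voxel"), roi_label = NULL,
                        voxel = NULL, grid = NULL) {
  kind <- match.arg(kind)
  if (kind == "roi") {
    if (is.null(roi_label) || !is.null(voxel))
      stop("roi target needs `roi_label` and no `voxel`")
    roi_label <- as.integer(roi_label)
  } else {
    if (is.null(voxel) || !is.null(roi_label))
      stop("voxel target needs `voxel` and no `roi_label`")
    if (length(voxel) == 3L && !is.null(grid))
      voxel <- ijk_to_idx(matrix(voxel, ncol = 3), grid)
    voxel <- as.integer(voxel)
    if (length(voxel) != 1L) stop("`voxel` must resolve to a single index")
  }
  structure(list(kind = kind, roi_label = roi_label, voxel = voxel),
            class = "target_spec")
}

#' Behavioral score vector
#'
#' @param patient_ids ordered patient identifiers (matching the cohort arm).
#' @param scores numeric scores, one per patient; binary vectors take values
#'   0/1, ROI percent-damage scores lie in [0, 100].
#' @param is_binary flag.
#' @return Object of class `behavior_vector`.
#' @export
behavior_vector <- function(patient_ids, scores, is_binary = FALSE) {
  if (length(patient_ids) != length(scores))
    stop("patient_ids and scores must align")
  if (is_binary && !all(scores %in% c(0, 1)))
    stop("binary scores must be 0/1")
  structure(list(patient_ids = as.character(patient_ids),
                 scores = as.numeric(scores), is_binary = isTRUE(is_binary)),
            class = "behavior_vector")
}

#' Percent of an ROI impacted by a lesion
#'
#' 100 x |lesion intersect ROI| / |ROI|. A lesion covering 60% of the target
#' ROI yields a score of 60.
#'
#' @param mask a [lesion_mask()].
#' @param atlas a `lesion_atlas`.
#' @param roi_label ROI label present in the atlas (error if empty).
#' @return numeric in [0, 100].
#' @export
roi_overlap_score <- function(mask, atlas, roi_label) {
  roi <- atlas_roi_indices(atlas, roi_label)
  100 * sum(mask$voxels[roi]) / length(roi)
}

#' Impairment status at a single critical voxel
#'
#' A patient whose lesion overlaps the critical voxel is impaired (1); all
#' others are unimpaired (0).
#'
#' @param mask a [lesion_mask()].
#' @param voxel linear voxel index (or (i,j,k) triple).
#' @return 0 or 1.
#' @export
voxel_impairment <- function(mask, voxel) {
  if (length(voxel) == 3L) voxel <- ijk_to_idx(matrix(voxel, ncol = 3),
                                               mask$grid)
  voxel <- as.integer(voxel)
  if (voxel < 1L || voxel > n_voxels(mask$grid)) stop("voxel off the grid")
  as.integer(mask$voxels[voxel] == 1L)
}

#' Simulate noiseless behavior for one cohort arm and target
#'
#' Deterministic, noise-free scoring: percent ROI damage for ROI targets,
#' binary impairment for voxel targets. Higher score means more deficit, so
#' one-tailed tests downstream test lesioned > intact.
#'
#' @param arm_masks list of [lesion_mask()] (one cohort arm, in order).
#' @param target a [target_spec()].
#' @param atlas a `lesion_atlas` (required for ROI targets).
#' @return A [behavior_vector()] aligned with `arm_masks`.
#' @export
simulate_behavior <- function(arm_masks, target, atlas = NULL) {
  stopifnot(inherits(target, "target_spec"))
  ids <- vapply(arm_masks, `[[`, character(1), "patient_id")
  if (target$kind == "roi") {
    if (is.null(atlas)) stop("ROI target requires an atlas")
    sc <- vapply(arm_masks, roi_overlap_score, numeric(1),
                 atlas = atlas, roi_label = target$roi_label)
    behavior_vector(ids, sc, is_binary = FALSE)
  } else {
    sc <- vapply(arm_masks, voxel_impairment, integer(1),
                 voxel = target$voxel)
    behavior_vector(ids, sc, is_binary = TRUE)
  }
}
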