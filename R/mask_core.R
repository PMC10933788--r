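#' Binary lesion mask
#'
#' One patient's binary lesion segmentation on the shared grid, tagged by
#' modality arm ("A" and "B" stand for the two imaging arms of a paired
#' cohort, e.g. CT and MR).
#'
#' @param voxels 3D array; any values are strictly binarized at >= 0.5.
#' @param grid a [grid_spec()]. If missing, a 1 mm grid matching `dim(voxels)`.
#' @param patient_id opaque identifier string.
#' @param modality `"A"` or `"B"`.
#' @return An object of class `lesion_mask` with elements `patient_id`,
#'   `modality`, `grid`, `voxels` (integer 0/1 array).
#' @export
lesion_mask <- function(voxels, grid = NULL, patient_id = "p", modality = "A") {
  if (length(dim(voxels)) != 3L) stop("`voxels` must be a 3D array")
  if (is.null(grid)) grid <- grid_spec(dim(voxels))
  if (!identical(as.integer(dim(voxels)), grid$shape))
    stop("`voxels` dimensions do not match `grid`")
  modality <- match.arg(modality, c("A", "B"))
  v <- array(as.integer(voxels >= 0.5), dim = grid$shape)
  structure(list(patient_id = as.character(patient_id), modality = modality,
                 grid = grid, voxels = v),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s [%s]: %d voxels (%.1f mm3) on %dx%dx%d grid\n",
              x$patient_id, x$modality, sum(x$voxels), mask_volume_mm3(x),
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}

#' @rdname lesion_mask
#' @param mask a `lesion_mask`.
#' @export
mask_volume_mm3 <- function(mask) sum(mask$voxels) * voxel_volume_mm3(mask$grid)

#' @rdname lesion_mask
#' @export
mask_indices <- function(mask) which(mask$voxels == 1L)

# Coerce a mask / 3D array / linear-index vector to sorted voxel indices.
as_voxel_idx <- function(x) {
  if (inherits(x, "lesion_mask")) return(which(x$voxels == 1L))
  if (is.array(x) && length(dim(x)) == 3L) return(which(x >= 0.5))
  if (is.logical(x)) return(which(x))
  sort(unique(as.integer(x)))
}

#' Read a binary lesion mask from a NIfTI file
#'
#' Values are strictly thresholded to \{0,1\} at >= 0.5 on read (any input
#' datatype is accepted); the grid is taken from the header. Orientation
#' codes are trusted and no reorientation is performed.
#'
#' @param path path to a 3D NIfTI volume (.nii or .nii.gz).
#' @param expected_grid optional [grid_spec()]; a mismatching header is an
#'   error (it signals a cohort that is not co-registered).
#' @inheritParams lesion_mask
#' @return A [lesion_mask()].
#' @export
read_mask <- function(path, expected_grid = NULL, patient_id = NULL,
                      modality = "A") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L) {
    if (any(d[-(1:3)] > 1L)) stop("4D input: ", path, " is not a 3D mask")
    dim(img) <- d[1:3]
  }
  if (length(dim(img)) != 3L) stop("not a 3D volume: ", path)
  pd <- RNifti::pixdim(img)[1:3]
  grid <- grid_spec(dim(img), pd)
  if (!is.null(expected_grid) && !grid_equal(grid, expected_grid))
    stop("grid mismatch for ", path,
         ": header does not match the expected grid (cohort not co-registered?)")
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  lesion_mask(array(as.numeric(img), dim = dim(img)), grid,
              patient_id = patient_id, modality = modality)
}

#' Write masks, atlases and z-maps as NIfTI
#'
#' Binary masks round-trip bit-exactly through [read_mask()]; z-maps are
#' stored as 32-bit floats.
#'
#' @param mask a [lesion_mask()] (or 3D 0/1 array plus `grid`).
#' @param path output path (.nii or .nii.gz).
#' @param grid required when a bare array is given.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, grid = NULL) {
  if (inherits(mask, "lesion_mask")) {
    arr <- mask$voxels; grid <- mask$grid
  } else {
    if (is.null(grid)) stop("`grid` required when writing a bare array")
    arr <- array(as.integer(mask >= 0.5), dim = grid$shape)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @param values numeric vector of z values over `tested_idx`, or a full 3D
#'   array. Untested voxels are written as 0.
#' @param tested_idx linear voxel indices corresponding to `values`.
#' @export
write_zmap <- function(values, path, grid, tested_idx = NULL) {
  if (is.array(values) && length(dim(values)) == 3L) {
    arr <- values
  } else {
    if (is.null(tested_idx)) stop("`tested_idx` required for a value vector")
    arr <- array(0, dim = grid$shape)
    arr[tested_idx] <- values
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read an integer-labeled ROI atlas from NIfTI
#'
#' @inheritParams read_mask
#' @return An object of class `lesion_atlas`: list with `grid` and integer
#'   `labels` array (0 = background).
#' @export
read_atlas <- function(path, expected_grid = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("atlas must be a 3D volume")
  grid <- grid_spec(dim(img), RNifti::pixdim(img)[1:3])
  if (!is.null(expected_grid) && !grid_equal(grid, expected_grid))
    stop("atlas grid mismatch for ", path)
  structure(list(grid = grid,
                 labels = array(as.integer(round(img)), dim = dim(img))),
            class = "lesion_atlas")
}

#' @rdname read_atlas
#' @param atlas a `lesion_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  img <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(img) <- atlas$grid$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

# --- Gaussian smoothing -----------------------------------------------------

# Discrete Gaussian kernel, truncated at `radius` voxels (default 4 sigma)
# and normalized to sum 1 over the truncated support.
gaussian_kernel <- function(sigma_voxels, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(4 * sigma_voxels))
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma_voxels^2))
  k / sum(k)
}

# 1-D Gaussian convolution along one axis of a 3D array, zero-padded
# boundaries (signal assumed absent outside the volume).
smooth_axis <- function(arr, sigma_voxels, axis) {
  if (sigma_voxels <= 0) return(arr)
  d <- dim(arr)
  if (axis == 2L) {
    ap <- aperm(arr, c(2L, 1L, 3L))
    return(aperm(smooth_axis(ap, sigma_voxels, 1L), c(2L, 1L, 3L)))
  }
  n <- d[axis]
  kern <- gaussian_kernel(sigma_voxels)
  r <- (length(kern) - 1L) / 2L
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) {
    w <- numeric(length(i))
    ok <- abs(i - j) <= r
    w[ok] <- kern[(j - i)[ok] + r + 1L]
    w
  })
  if (axis == 3L) {
    out <- matrix(arr, d[1] * d[2], d[3]) %*% K
  } else {
    out <- K %*% matrix(arr, d[1], d[2] * d[3])
  }
  array(out, d)
}

# Isotropic (per-axis) smoothing helper used by the synthetic generator.
smooth3 <- function(arr, sigma_voxels) {
  for (ax in 1:3) arr <- smooth_axis(arr, sigma_voxels, ax)
  arr
}

#' Smooth a mask along z and re-binarize
#'
#' Standard mask preprocessing: 1-D Gaussian smoothing along the z axis only
#' (sigma = FWHM / (2 sqrt(2 ln 2)) / voxel size), zero-padded boundaries,
#' then re-binarization at >= 0.5. x and y are untouched. Isolated voxels
#' thinner than roughly half the kernel mass are removed; solid columns are
#' preserved (the half-maximum point of a step edge stays at the edge).
#'
#' @param mask a [lesion_mask()].
#' @param fwhm_mm kernel full width at half maximum in mm (default 5).
#' @return A new [lesion_mask()].
#' @export
smooth_z_binarize <- function(mask, fwhm_mm = 5) {
  stopifnot(inherits(mask, "lesion_mask"), fwhm_mm > 0)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / mask$grid$voxel_size_mm[3]
  sm <- smooth_axis(array(as.numeric(mask$voxels), dim = mask$grid$shape),
                    sigma_vox, 3L)
  lesion_mask(array(as.integer(sm >= 0.5), dim = mask$grid$shape),
              mask$grid, mask$patient_id, mask$modality)
}

# --- Overlay and inclusion --------------------------------------------------

#' Lesion overlay map
#'
#' Voxel-wise count of how many patients' lesions include each voxel. The
#' overlay determines statistical power and drives the minimum-coverage
#' voxel inclusion filter.
#'
#' @param masks non-empty list of [lesion_mask()] objects on a shared grid.
#' @return An object of class `overlay_map`: list with `grid` and integer
#'   `counts` array.
#' @export
lesion_overlay <- function(masks) {
  if (length(masks) == 0L) stop("empty cohort")
  grid <- masks[[1]]$grid
  for (m in masks)
    if (!grid_equal(m$grid, grid)) stop("grid mismatch within cohort")
  counts <- array(0L, dim = grid$shape)
  for (m in masks) counts <- counts + m$voxels
  structure(list(grid = grid, counts = counts), class = "overlay_map")
}

#' @export
print.overlay_map <- function(x, ...) {
  cat(sprintf("<overlay_map> max count %d, %d voxels lesioned in >= 1 patient\n",
              max(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' Voxels passing the minimum-coverage inclusion filter
#'
#' @param ov an [lesion_overlay()] result.
#' @param n_min minimum number of lesioned patients per voxel (default 8).
#' @return Sorted integer vector of linear voxel indices with
#'   `counts >= n_min`.
#' @export
included_voxels <- function(ov, n_min = 8) {
  stopifnot(inherits(ov, "overlay_map"), n_min >= 1)
  which(ov$counts >= n_min)
}

# --- Dice -------------------------------------------------------------------

#' Dice similarity of two binary voxel sets
#'
#' Dice = overlap size divided by the average of the two set sizes, i.e.
#' 2|A∩B| / (|A|+|B|). When both sets are empty the coefficient is undefined
#' and reported as `NA` (not 0 or 1), avoiding spurious perfect agreement
#' between empty result maps. Exclusive fractions are computed over the
#' union.
#'
#' @param a,b [lesion_mask()] objects, 3D arrays, logical vectors, or
#'   integer vectors of linear voxel indices (all on the same grid).
#' @return An object of class `dice_result`: list with `dice`, `n_overlap`,
#'   `n_a`, `n_b`, `frac_both`, `frac_a_only`, `frac_b_only`.
#' @examples
#' dice(1:100, 1:100)$dice        # 1
#' dice(1:10, 11:20)$dice         # 0
#' dice(1:50, 1:100)$dice         # 2/3
#' @export
dice <- function(a, b) {
  ia <- as_voxel_idx(a); ib <- as_voxel_idx(b)
  n_a <- length(ia); n_b <- length(ib)
  n_overlap <- length(intersect(ia, ib))
  n_union <- n_a + n_b - n_overlap
  d <- if (n_a + n_b == 0L) NA_real_ else 2 * n_overlap / (n_a + n_b)
  structure(list(
    dice = d, n_overlap = n_overlap, n_a = n_a, n_b = n_b,
    frac_both  = if (n_union > 0) n_overlap / n_union else NA_real_,
    frac_a_only = if (n_union > 0) (n_a - n_overlap) / n_union else NA_real_,
    frac_b_only = if (n_union > 0) (n_b - n_overlap) / n_union else NA_real_),
    class = "dice_result")
}

#' @export
print.dice_result <- function(x, ...) {
  cat(sprintf(
    "<dice_result> dice=%.3f  |A|=%d |B|=%d overlap=%d  both/A-only/B-only = %.1f%%/%.1f%%/%.1f%%\n",
    x$dice, x$n_a, x$n_b, x$n_overlap,
    100 * x$frac_both, 100 * x$frac_a_only, 100 * x$frac_b_only))
  invisible(x)
}

# --- Connected components ---------------------------------------------------

# 6-connected neighbors of linear indices (within-grid only).
neighbors6 <- function(idx, grid) {
  d <- grid$shape
  ijk <- idx_to_ijk(idx, grid)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  out <- vector("list", 6L)
  for (o in seq_len(6L)) {
    nb <- sweep(ijk, 2, offs[o, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    out[[o]] <- if (any(ok)) ijk_to_idx(nb[ok, , drop = FALSE], grid)
                else integer(0)
  }
  unlist(out, use.names = FALSE)
}

#' Label 6-connected components of a voxel set
#'
#' Breadth-first flood fill over face (6-) connectivity.
#'
#' @param idx integer vector of linear voxel indices (or mask/array, see
#'   [dice()] for accepted forms).
#' @param grid a [grid_spec()] (taken from the mask when omitted).
#' @return Integer vector of component labels (1..k), parallel to the sorted
#'   voxel index vector, with attribute `"idx"` carrying those indices.
#' @export
label_components <- function(idx, grid = NULL) {
  if (inherits(idx, "lesion_mask")) {
    grid <- idx$grid; idx <- which(idx$voxels == 1L)
  }
  if (is.null(grid)) stop("`grid` required")
  idx <- sort(unique(as.integer(idx)))
  lab_full <- integer(n_voxels(grid))       # 0 = not in set / unvisited
  lab_full[idx] <- -1L                      # in set, unvisited
  lab <- 0L
  for (s in idx) {
    if (lab_full[s] != -1L) next
    lab <- lab + 1L
    frontier <- s
    lab_full[s] <- lab
    while (length(frontier)) {
      nb <- unique(neighbors6(frontier, grid))
      nb <- nb[lab_full[nb] == -1L]
      lab_full[nb] <- lab
      frontier <- nb
    }
  }
  structure(lab_full[idx], idx = idx, n_components = lab)
}
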