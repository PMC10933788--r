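#' Voxel grid specification
#'
#' A `grid_spec` records the shape (voxels per axis) and voxel size (mm) of
#' the shared reference grid that every mask, atlas, overlay and z-map in a
#' run must live on. Masks are assumed pre-registered to this grid; no affine
#' handling beyond voxel size is performed.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm numeric vector of length 3, mm per voxel (all > 0).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(32, 40, 32), c(4, 4, 4))
#' n_voxels(g)
#' @export
grid_spec <- function(shape, voxel_size_mm = c(1, 1, 1)) {
  shape <- as.integer(shape)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be 3 integers, all >= 1")
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive numbers")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels at %g x %g x %g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' @rdname grid_spec
#' @param g,a,b `grid_spec` objects.
#' @export
grid_equal <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm))
}

#' @rdname grid_spec
#' @export
n_voxels <- function(g) prod(g$shape)

#' @rdname grid_spec
#' @export
voxel_volume_mm3 <- function(g) prod(g$voxel_size_mm)

# Linear voxel index (1-based, column-major) <-> (i,j,k) triples.
idx_to_ijk <- function(idx, grid) {
  d <- grid$shape
  idx0 <- as.integer(idx) - 1L
  i <- idx0 %% d[1]
  j <- (idx0 %/% d[1]) %% d[2]
  k <- idx0 %/% (d[1] * d[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

ijk_to_idx <- function(ijk, grid) {
  d <- grid$shape
  ijk <- matrix(as.integer(ijk), ncol = 3)
  if (any(ijk < 1L) || any(ijk[, 1] > d[1]) || any(ijk[, 2] > d[2]) ||
      any(ijk[, 3] > d[3]))
    stop("voxel coordinates outside the grid")
  (ijk[, 1]) + (ijk[, 2] - 1L) * d[1] + (ijk[, 3] - 1L) * d[1] * d[2]
}

#' World coordinates (mm) of voxel centers
#'
#' Distances are Euclidean distances of voxel-index differences scaled
#' per-axis by the voxel size; the first voxel sits at the origin.
#'
#' @param idx integer vector of linear voxel indices.
#' @param grid a `grid_spec`.
#' @return numeric matrix, one row per voxel, columns x/y/z in mm.
#' @export
voxel_coords_mm <- function(idx, grid) {
  ijk <- idx_to_ijk(idx, grid)
  sweep(ijk - 1, 2, grid$voxel_size_mm, `*`)
}
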