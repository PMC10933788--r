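test_that("NIfTI masks round-trip bit-exactly and binarize at 0.5 on read", {
  g <- tiny_grid()
  set.seed(11)
  m <- random_masks(1, g, p = 0.4, seed = 11)[[1]]
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(m, f)
  r <- read_mask(f, expected_grid = g)
  expect_identical(r$voxels, m$voxels)
  expect_equal(r$grid$voxel_size_mm, g$voxel_size_mm)

  # fractional values: strictly >= 0.5 survives
  arr <- array(0, dim = g$shape)
  arr[1:4] <- c(0, 0.4, 0.6, 1)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- g$voxel_size_mm
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f2, datatype = "float")
  r2 <- read_mask(f2)
  expect_identical(which(r2$voxels == 1L), c(3L, 4L))

  # empty mask round-trips empty
  f3 <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(mask_from_idx(integer(0), g), f3)
  expect_identical(sum(read_mask(f3)$voxels), 0L)
})

test_that("read_mask rejects grid mismatches and 4D volumes", {
  g <- tiny_grid()
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(mask_from_idx(1:5, g), f)
  expect_error(read_mask(f, expected_grid = grid_spec(c(8, 8, 8), c(1, 1, 1))),
               "grid mismatch")
  f4 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, dim = c(4, 4, 4, 2))), f4)
  expect_error(read_mask(f4), "4D")
})

test_that("z-maps round-trip through float32 NIfTI within rounding", {
  g <- tiny_grid()
  set.seed(2)
  tested <- sort(sample(n_voxels(g), 40))
  z <- rnorm(40, 2, 3)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_zmap(z, f, g, tested)
  back <- RNifti::readNifti(f)
  expect_equal(back[tested], z, tolerance = 1e-6)
  expect_true(all(back[-tested] == 0))
})

test_that("z-direction smoothing matches an independent 1-D convolution oracle", {
  g <- grid_spec(c(4, 4, 24), c(1, 1, 1))
  set.seed(3)
  m <- random_masks(1, g, p = 0.35, seed = 3)[[1]]
  sm <- smooth_z_binarize(m, fwhm_mm = 5)
  sigma <- 5 / (2 * sqrt(2 * log(2)))
  for (i in 1:4) for (j in 1:4) {
    expect_identical(sm$voxels[i, j, ],
                     as.integer(conv1d_oracle(m$voxels[i, j, ], sigma) >= 0.5),
                     info = sprintf("column (%d,%d)", i, j))
  }
})

test_that("smoothing removes isolated voxels but keeps solid columns; x,y untouched", {
  g <- grid_spec(c(5, 5, 21), c(1, 1, 1))
  # single isolated voxel at 5 mm FWHM: center weight of the normalized
  # kernel is ~0.188 < 0.5, so the voxel is removed
  iso <- mask_from_idx(ijk_to_idx(cbind(3, 3, 11), g), g)
  expect_identical(sum(smooth_z_binarize(iso, 5)$voxels), 0L)

  # a full-z column stays set everywhere (zero-padding keeps edge >= 0.5)
  col <- array(0L, dim = g$shape); col[2, 4, ] <- 1L
  smc <- smooth_z_binarize(lesion_mask(col, g), 5)
  expect_identical(smc$voxels, col)

  # all-zero in, all-zero out
  expect_identical(sum(smooth_z_binarize(mask_from_idx(integer(0), g), 5)$voxels), 0L)
})

test_that("z-smoothing commutes with x/y translation", {
  g <- grid_spec(c(10, 10, 16), c(1, 1, 1))
  set.seed(4)
  arr <- array(0L, dim = g$shape)
  arr[3:5, 3:6, 4:12] <- array(as.integer(runif(3 * 4 * 9) < 0.5), c(3, 4, 9))
  shift_xy <- function(a, dx, dy) {
    out <- array(0L, dim = dim(a))
    out[(1 + dx):dim(a)[1], (1 + dy):dim(a)[2], ] <-
      a[1:(dim(a)[1] - dx), 1:(dim(a)[2] - dy), ]
    out
  }
  sm_then_shift <- shift_xy(smooth_z_binarize(lesion_mask(arr, g), 5)$voxels, 3, 2)
  shift_then_sm <- smooth_z_binarize(lesion_mask(shift_xy(arr, 3, 2), g), 5)$voxels
  expect_identical(sm_then_shift, shift_then_sm)
})

test_that("overlay counts patients per voxel and sums to total lesion load", {
  g <- tiny_grid()
  m1 <- mask_from_idx(1:20, g)
  m2 <- mask_from_idx(11:40, g)
  ov <- lesion_overlay(list(m1, m2))
  expect_identical(ov$counts[1:10], rep(1L, 10))
  expect_identical(ov$counts[11:20], rep(2L, 10))
  expect_identical(sum(ov$counts), sum(m1$voxels) + sum(m2$voxels))
  expect_identical(lesion_overlay(list(m1))$counts, m1$voxels)
  expect_error(lesion_overlay(list()), "empty")
  expect_error(lesion_overlay(list(m1, mask_from_idx(1, grid_spec(c(8, 8, 8))))),
               "grid mismatch")

  masks <- random_masks(12, g, p = 0.4, seed = 7)
  ovr <- lesion_overlay(masks)
  expect_identical(sum(ovr$counts),
                   sum(vapply(masks, function(m) sum(m$voxels), integer(1))))
})

test_that("voxel inclusion is a sharp >= n_min cut and monotone in n_min", {
  g <- tiny_grid()
  masks <- lapply(1:9, function(i) mask_from_idx(1:i, g))
  ov <- lesion_overlay(masks)   # voxel v is covered by 10 - v masks (v <= 9)
  expect_true(2L %in% included_voxels(ov, 8))    # count 8
  expect_false(3L %in% included_voxels(ov, 8))   # count 7
  expect_identical(included_voxels(ov, 1), which(ov$counts >= 1L))
  for (nm in 2:8)
    expect_true(all(included_voxels(ov, nm) %in% included_voxels(ov, nm - 1)))
})

test_that("dice matches its definition, is symmetric and bounded", {
  expect_equal(dice(1:100, 1:100)$dice, 1)
  expect_equal(dice(1:10, 21:40)$dice, 0)
  d <- dice(1:50, 1:100)
  expect_equal(d$dice, 2 / 3)
  expect_equal(d$frac_both + d$frac_a_only + d$frac_b_only, 1)
  expect_true(is.na(dice(integer(0), integer(0))$dice))
  expect_equal(dice(integer(0), 1:5)$dice, 0)

  set.seed(8)
  for (rep in 1:20) {
    a <- sample(500, sample(0:80, 1))
    b <- sample(500, sample(1:80, 1))
    dab <- dice(a, b); dba <- dice(b, a)
    expect_equal(dab$dice, dba$dice)
    expect_true(dab$dice >= 0 && dab$dice <= 1)
    if (dab$dice == 1) expect_setequal(a, b)
    if (length(a) && dab$dice == 0) expect_length(intersect(a, b), 0)
  }
})

test_that("connected-component labeling agrees with an igraph oracle", {
  skip_if_not_installed("igraph")
  g <- tiny_grid(c(10, 10, 10), c(1, 1, 1))
  set.seed(9)
  for (rep in 1:5) {
    idx <- sort(sample(n_voxels(g), 120))
    lab <- label_components(idx, g)
    # oracle: graph over 6-adjacent voxel pairs
    ijk <- cbind(idx_to_ijk(idx, g))
    pairs <- which(outer(idx, idx, function(a, b) a < b), arr.ind = TRUE)
    adj <- abs(ijk[pairs[, 1], , drop = FALSE] -
                 ijk[pairs[, 2], , drop = FALSE])
    is_nb <- rowSums(adj) == 1
    gr <- igraph::graph_from_edgelist(
      cbind(pairs[is_nb, 1], pairs[is_nb, 2]), directed = FALSE)
    gr <- igraph::add_vertices(gr, length(idx) - igraph::vcount(gr))
    oracle <- igraph::components(gr)$membership
    # same partition (labels may differ)
    expect_equal(attr(lab, "n_components"), max(oracle))
    expect_true(all(tapply(oracle, as.integer(lab),
                           function(x) length(unique(x))) == 1))
  }
})
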