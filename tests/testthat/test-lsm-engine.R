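test_that("pooled-variance t matches hand computation and is antisymmetric", {
  r <- pooled_t(c(1, 3), c(2, 4))
  expect_equal(r$t, (2 - 3) / sqrt(2 * (1 / 2 + 1 / 2)))  # -0.7071
  expect_identical(r$df, 2L)
  expect_equal(pooled_t(c(1, 2, 3), c(2, 2, 2.0001))$df, 4L)
  expect_equal(pooled_t(c(5, 7), c(5, 7))$t, 0)
  fwd <- pooled_t(c(1, 4, 2), c(3, 5, 6))
  rev <- pooled_t(c(3, 5, 6), c(1, 4, 2))
  expect_equal(fwd$t, -rev$t)
  expect_identical(fwd$df, rev$df)
  expect_error(pooled_t(1, c(2, 3)), ">= 2")
  expect_error(pooled_t(c(2, 2), c(2, 2)), "zero pooled variance")
})

test_that("Liebermeister p matches exact hypergeometric enumeration on small tables", {
  expect_equal(liebermeister_p(2, 0, 0, 2), 1 / choose(6, 3))   # 0.05
  expect_equal(liebermeister_p(0, 2, 2, 0), 1 - 1 / choose(6, 3))

  # brute-force oracle: enumerate the PMF of the incremented table
  lieb_oracle <- function(a, b, c, d) {
    N <- a + b + c + d + 2; K <- a + c + 1; m <- a + b + 1
    js <- max(0, m - (N - K)):min(K, m)
    pmf <- choose(K, js) * choose(N - K, m - js) / choose(N, m)
    sum(pmf[js >= a + 1])
  }
  for (n in 2:8) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      expect_equal(liebermeister_p(a, b, cc, d), lieb_oracle(a, b, cc, d),
                   tolerance = 1e-13)
    }
  }
})

test_that("Liebermeister p strictly decreases as association strengthens", {
  # fixed margins: 10 lesioned / 10 intact, 10 impaired / 10 unimpaired
  p <- vapply(0:10, function(a) liebermeister_p(a, 10 - a, 10 - a, a),
              numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("p-to-z conversion and Bonferroni thresholds behave as inverse-normal cuts", {
  expect_equal(p_to_z(0.5), 0)
  expect_equal(p_to_z(0.05), 1.6449, tolerance = 1e-4)
  expect_equal(p_to_z(0.05), -p_to_z(0.95))
  expect_true(is.finite(p_to_z(0)) && is.finite(p_to_z(1)))
  expect_equal(bonferroni_z_threshold(0.05, 1), 1.6449, tolerance = 1e-4)
  ns <- c(1, 10, 100, 1e4, 1e6)
  expect_true(all(diff(vapply(ns, bonferroni_z_threshold, numeric(1),
                              alpha = 0.05)) > 0))
  expect_true(all(diff(vapply(c(0.1, 0.05, 0.01, 0.001),
                              function(a) bonferroni_z_threshold(a, 100),
                              numeric(1))) > 0))
})

test_that("volume residualization is a least-squares projection", {
  vol <- c(10, 20, 30, 40, 55)
  b_lin <- behavior_vector(letters[1:5], 3 + 2 * vol)
  expect_equal(residualize_volume(b_lin, vol)$scores, rep(0, 5),
               tolerance = 1e-10)
  set.seed(5)
  sc <- rnorm(5)
  sc_orth <- sc - mean(sc)
  sc_orth <- sc_orth - sum(sc_orth * (vol - mean(vol))) /
    sum((vol - mean(vol))^2) * (vol - mean(vol))
  b <- behavior_vector(letters[1:5], sc_orth + 7)
  r <- residualize_volume(b, vol)
  expect_equal(r$scores, sc_orth, tolerance = 1e-10)
  expect_equal(sum(r$scores * vol), 0, tolerance = 1e-8)
  expect_equal(mean(r$scores), 0, tolerance = 1e-10)
  expect_warning(residualize_volume(b, rep(3, 5)), "zero volume variance")
})

naive_lsm_z <- function(masks, behavior, n_min, statistic) {
  ov <- lesion_overlay(masks)
  tested <- included_voxels(ov, n_min)
  n <- length(masks)
  vapply(tested, function(v) {
    lesioned <- vapply(masks, function(m) m$voxels[v] == 1L, logical(1))
    if (statistic == "liebermeister") {
      y <- behavior$scores
      a <- sum(lesioned & y == 1); b <- sum(lesioned & y == 0)
      cc <- sum(!lesioned & y == 1); d <- sum(!lesioned & y == 0)
      p_to_z(liebermeister_p(a, b, cc, d))
    } else {
      g1 <- behavior$scores[lesioned]; g0 <- behavior$scores[!lesioned]
      if (length(g1) < 2 || length(g0) < 2) return(NA_real_)
      tt <- tryCatch(pooled_t(g1, g0), error = function(e) NULL)
      if (is.null(tt)) return(NA_real_)
      p_to_z(stats::pt(tt$t, tt$df, lower.tail = FALSE))
    }
  }, numeric(1))
}

test_that("vectorized z computation equals the naive per-voxel loop", {
  g <- tiny_grid(c(6, 6, 6), c(2, 2, 2))
  masks <- random_masks(10, g, p = 0.35, seed = 14)
  ov <- lesion_overlay(masks)
  v <- included_voxels(ov, 3)[5]
  beh_bin <- simulate_behavior(masks, target_spec("voxel", voxel = v))
  cfg <- lsm_config(n_min = 3, statistic = "auto")
  zm <- run_lsm(masks, beh_bin, cfg)
  expect_identical(zm$statistic, "liebermeister")
  expect_identical(zm$z, naive_lsm_z(masks, beh_bin, 3, "liebermeister"))

  set.seed(15)
  beh_cont <- behavior_vector(vapply(masks, `[[`, character(1), "patient_id"),
                              rnorm(10))
  zm2 <- run_lsm(masks, beh_cont, lsm_config(n_min = 3))
  expect_equal(zm2$z, naive_lsm_z(masks, beh_cont, 3, "pooled_t"),
               tolerance = 1e-12)
})

test_that("LSM output is invariant to patient ordering (Bonferroni)", {
  g <- tiny_grid(c(6, 6, 6), c(2, 2, 2))
  masks <- random_masks(12, g, p = 0.35, seed = 16)
  set.seed(17)
  beh <- behavior_vector(vapply(masks, `[[`, character(1), "patient_id"),
                         rnorm(12))
  zm <- run_lsm(masks, beh, lsm_config(n_min = 3))
  perm <- sample(12)
  beh_p <- behavior_vector(beh$patient_ids[perm], beh$scores[perm])
  zm_p <- run_lsm(masks[perm], beh_p, lsm_config(n_min = 3))
  expect_equal(zm$z, zm_p$z, tolerance = 1e-12)
  expect_identical(zm$significant_idx, zm_p$significant_idx)
})

test_that("perfect voxel-level association is maximal for its coverage", {
  co <- small_cohort(n = 20, seed = 19)
  arm <- cohort_arm(co, "A")
  ov <- lesion_overlay(arm)
  tested <- included_voxels(ov, 5)
  tgt <- tested[which.max(ov$counts[tested])]
  beh <- simulate_behavior(arm, target_spec("voxel", voxel = tgt))
  zm <- run_lsm(arm, beh, lsm_config(n_min = 5))
  z_tgt <- zm$z[match(tgt, zm$tested_idx)]
  same_cov <- ov$counts[zm$tested_idx] == ov$counts[tgt]
  expect_equal(z_tgt, max(zm$z[same_cov]))
  expect_equal(z_tgt, max(zm$z))
})

test_that("constant behavior yields an empty, flagged result", {
  g <- tiny_grid(c(6, 6, 6), c(2, 2, 2))
  masks <- random_masks(8, g, p = 0.4, seed = 20)
  beh <- behavior_vector(vapply(masks, `[[`, character(1), "patient_id"),
                         rep(2, 8))
  zm <- run_lsm(masks, beh, lsm_config(n_min = 2))
  expect_length(zm$significant_idx, 0)
  expect_match(zm$message, "no significant")
})

test_that("permutation threshold is the empirical max-z quantile and is seedable", {
  g <- tiny_grid(c(6, 6, 6), c(2, 2, 2))
  masks <- random_masks(12, g, p = 0.35, seed = 22)
  ids <- vapply(masks, `[[`, character(1), "patient_id")
  set.seed(23)
  beh <- behavior_vector(ids, rnorm(12))
  cfg <- lsm_config(n_min = 3, correction = "permutation",
                    n_permutations = 60, seed = 99)
  thr1 <- permutation_fwe_threshold(masks, beh, cfg)
  thr2 <- permutation_fwe_threshold(masks, beh, cfg)
  expect_identical(thr1, thr2)

  # alpha = 1 boundary: threshold equals the minimum of the null maxima
  cfg_lo <- lsm_config(n_min = 3, correction = "permutation",
                       n_permutations = 60, alpha = 1 - 1e-12, seed = 99)
  thr_lo <- permutation_fwe_threshold(masks, beh, cfg_lo)
  expect_lte(thr_lo, thr1)

  # constant binary behavior: every permutation identical, threshold equals
  # the degenerate observed max
  beh_const <- behavior_vector(ids, rep(1, 12), is_binary = TRUE)
  cfg_b <- lsm_config(n_min = 3, correction = "permutation",
                      n_permutations = 20, statistic = "liebermeister",
                      seed = 7)
  thr_c <- permutation_fwe_threshold(masks, beh_const, cfg_b)
  zm_c <- run_lsm(masks, beh_const, cfg_b)
  expect_equal(thr_c, max(zm_c$z, na.rm = TRUE))

  # permutation threshold dominates the uncorrected cutoff in null runs
  above <- vapply(1:20, function(i) {
    set.seed(200 + i)
    b <- behavior_vector(ids, rnorm(12))
    cfgi <- lsm_config(n_min = 3, correction = "permutation",
                       n_permutations = 50, seed = 300 + i)
    permutation_fwe_threshold(masks, b, cfgi) >= p_to_z(0.05)
  }, logical(1))
  expect_gte(mean(above), 0.95)
})

test_that("binary volume control via GLM produces finite one-tailed z maps", {
  co <- small_cohort(n = 20, seed = 25)
  arm <- cohort_arm(co, "A")
  ov <- lesion_overlay(arm)
  tgt <- included_voxels(ov, 5)[1]
  beh <- simulate_behavior(arm, target_spec("voxel", voxel = tgt))
  cfg <- lsm_config(n_min = 5, binary_volume_control = "glm")
  zm <- run_lsm(arm, beh, cfg)
  expect_identical(zm$statistic, "glm_volume")
  expect_true(all(is.finite(zm$z) | is.na(zm$z)))
  expect_true(zm$z[match(tgt, zm$tested_idx)] > 0)
})
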