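#' Configuration of a mass-univariate LSM analysis
#'
#' @param n_min minimum patients lesioned per tested voxel (default 8).
#' @param alpha family-wise significance level (default 0.05).
#' @param correction `"bonferroni"` or `"permutation"` (max-statistic FWE).
#' @param n_permutations permutations for the max-statistic null (default
#'   2000).
#' @param volume_control for continuous behavior: residualize scores on
#'   total lesion volume before testing. For binary behavior the exact 2x2
#'   test admits no covariate, so `binary_volume_control = "glm"` substitutes
#'   an OLS fit of impairment on (lesion status, volume) using the lesion
#'   coefficient's t; the default `"none"` runs the exact test on raw tables.
#' @param binary_volume_control `"none"` or `"glm"`.
#' @param statistic `"auto"` (pooled t for continuous, Liebermeister for
#'   binary behavior), `"pooled_t"`, or `"liebermeister"`.
#' @param seed seed for the permutation stream.
#' @return Object of class `lsm_config`.
#' @export
lsm_config <- function(n_min = 8, alpha = 0.05,
                       correction = c("bonferroni", "permutation"),
                       n_permutations = 2000, volume_control = FALSE,
                       binary_volume_control = c("none", "glm"),
                       statistic = c("auto", "pooled_t", "liebermeister"),
                       seed = 1L) {
  stopifnot(n_min >= 1, alpha > 0, alpha < 1, n_permutations >= 1)
  structure(list(n_min = as.integer(n_min), alpha = alpha,
                 correction = match.arg(correction),
                 n_permutations = as.integer(n_permutations),
                 volume_control = isTRUE(volume_control),
                 binary_volume_control = match.arg(binary_volume_control),
                 statistic = match.arg(statistic), seed = as.integer(seed)),
            class = "lsm_config")
}

#' Two-sample pooled-variance t statistic
#'
#' Classical equal-variance t for mean(lesioned) - mean(intact) with
#' df = n1 + n2 - 2.
#'
#' @param scores_lesioned,scores_intact numeric score vectors (each of
#'   length >= 2; pooled variance must be positive).
#' @return List with `t` and `df`.
#' @examples
#' pooled_t(c(1, 3), c(2, 4))   # t = -0.7071, df = 2
#' @export
pooled_t <- function(scores_lesioned, scores_intact) {
  n1 <- length(scores_lesioned); n2 <- length(scores_intact)
  if (n1 < 2L || n2 < 2L) stop("both groups need >= 2 members")
  sp2 <- ((n1 - 1) * stats::var(scores_lesioned) +
            (n2 - 1) * stats::var(scores_intact)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  list(t = (mean(scores_lesioned) - mean(scores_intact)) /
         sqrt(sp2 * (1 / n1 + 1 / n2)),
       df = n1 + n2 - 2L)
}

#' Liebermeister quasi-exact one-tailed p for a 2x2 table
#'
#' For the table (a = lesioned & impaired, b = lesioned & unimpaired,
#' c = intact & impaired, d = intact & unimpaired), the Liebermeister
#' measure is the hypergeometric upper-tail probability of the table with
#' both concordant cells incremented by one, i.e. with N = n + 2,
#' K = a + c + 1 impaired, m = a + b + 1 lesioned,
#' p = P(X >= a + 1) for X ~ hypergeometric(N, K, m). It tests positive
#' lesion-impairment association; smaller p means stronger association.
#' Vectorized over table cells.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return One-tailed p in (0, 1).
#' @examples
#' liebermeister_p(2, 0, 0, 2)   # 0.05
#' liebermeister_p(0, 2, 2, 0)   # 0.95
#' @export
liebermeister_p <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  stats::phyper(a, a + c + 1, b + d + 1, a + b + 1, lower.tail = FALSE)
}

# p clamp before normal inversion: perfect associations must not yield
# infinite z.
P_MIN <- 1e-300
P_MAX <- 1 - 1e-16

#' Convert a one-tailed p-value to a z score
#'
#' z = inverse standard normal CDF of (1 - p), monotone decreasing in p.
#' p is clamped to [1e-300, 1 - 1e-16] so that perfect associations map to
#' a large finite z.
#'
#' @param p one-tailed p value(s).
#' @return z score(s).
#' @examples
#' p_to_z(0.5)    # 0
#' p_to_z(0.05)   # 1.6449
#' @export
p_to_z <- function(p) {
  stats::qnorm(pmin(pmax(p, P_MIN), P_MAX), lower.tail = FALSE)
}

#' One-tailed Bonferroni z threshold
#'
#' z = inverse standard normal CDF of (1 - alpha / n_tests); strictly
#' increasing in `n_tests` and decreasing in `alpha`.
#'
#' @param alpha family-wise level in (0, 1).
#' @param n_tests number of tested voxels (>= 1).
#' @return z threshold.
#' @examples
#' bonferroni_z_threshold(0.05, 1)   # 1.6449, the uncorrected cutoff
#' @export
bonferroni_z_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  stats::qnorm(alpha / n_tests, lower.tail = FALSE)
}

#' Residualize behavior on total lesion volume
#'
#' Least-squares residuals of the scores regressed on lesion volume
#' (intercept included); residuals have mean zero and are orthogonal to the
#' volumes. With zero volume variance the behavior is returned unchanged
#' with a warning.
#'
#' @param behavior a [behavior_vector()].
#' @param volumes numeric lesion volumes, one per patient (>= 3 patients).
#' @return A [behavior_vector()] of residual scores (`is_binary = FALSE`).
#' @export
residualize_volume <- function(behavior, volumes) {
  stopifnot(inherits(behavior, "behavior_vector"),
            length(volumes) == length(behavior$scores))
  if (length(volumes) < 3L) stop("need >= 3 patients to residualize")
  if (stats::var(volumes) == 0) {
    warning("zero volume variance; behavior returned unchanged")
    return(behavior)
  }
  r <- stats::lm.fit(cbind(1, volumes), behavior$scores)$residuals
  behavior_vector(behavior$patient_ids, as.numeric(r), is_binary = FALSE)
}

# --- internal design construction ------------------------------------------

# Patient x tested-voxel binary design for one cohort arm.
build_design <- function(arm_masks, n_min) {
  ov <- lesion_overlay(arm_masks)
  tested <- included_voxels(ov, n_min)
  n <- length(arm_masks)
  X <- matrix(0, n, length(tested))
  for (i in seq_len(n)) X[i, ] <- arm_masks[[i]]$voxels[tested]
  list(X = X, tested_idx = tested, counts = ov$counts[tested],
       grid = arm_masks[[1]]$grid,
       volumes = vapply(arm_masks, mask_volume_mm3, numeric(1)),
       patient_ids = vapply(arm_masks, `[[`, character(1), "patient_id"))
}

# Voxel-wise z for one or more score vectors. X: n x V binary design;
# S: n x P score matrix. Returns V x P matrix of z (NA = skipped voxel).
voxelwise_z <- function(X, S, statistic, volumes = NULL) {
  S <- as.matrix(S)
  n <- nrow(X)
  k <- colSums(X)
  if (statistic == "liebermeister") {
    if (!all(S %in% c(0, 1))) stop("liebermeister requires binary behavior")
    m <- colSums(S)                       # impaired per permutation
    A <- crossprod(X, S)                  # V x P lesioned-and-impaired
    Mm <- matrix(m, nrow(A), ncol(A), byrow = TRUE)
    p <- stats::phyper(A, Mm + 1, n - Mm + 1, k + 1, lower.tail = FALSE)
    return(p_to_z(p))
  }
  if (statistic == "glm_volume") {
    # OLS impairment ~ lesion + volume; one-tailed t on the lesion
    # coefficient, partialled-out form.
    H <- cbind(1, volumes)
    Q <- qr.Q(qr(H))
    RX <- X - Q %*% crossprod(Q, X)       # X residualized on (1, volume)
    RS <- S - Q %*% crossprod(Q, S)
    rxx <- colSums(RX^2)
    num <- crossprod(RX, RS)              # V x P
    ryy <- matrix(colSums(RS^2), nrow(num), ncol(num), byrow = TRUE)
    rxxM <- matrix(rxx, nrow(num), ncol(num))
    sse <- pmax(ryy - num^2 / rxxM, 0)
    df <- n - 3L
    # perfect fits (sse = 0) map to an infinite t and hence the clamped
    # maximal z; only a degenerate regressor invalidates the voxel
    tval <- (num / sqrt(rxxM)) / sqrt(sse / df)
    tval[rxxM <= 1e-12] <- NA_real_
    return(p_to_z(stats::pt(tval, df, lower.tail = FALSE)))
  }
  # pooled t
  valid <- k >= 2 & (n - k) >= 2
  XtS <- crossprod(X, S)                  # V x P group-1 sums
  tot <- matrix(colSums(S), nrow(XtS), ncol(XtS), byrow = TRUE)
  Q1 <- crossprod(X, S^2)
  Qtot <- matrix(colSums(S^2), nrow(XtS), ncol(XtS), byrow = TRUE)
  m1 <- XtS / k
  m0 <- (tot - XtS) / (n - k)
  ss1 <- Q1 - k * m1^2
  ss0 <- (Qtot - Q1) - (n - k) * m0^2
  sp2 <- (ss1 + ss0) / (n - 2)
  denom <- sqrt(sp2 * (1 / k + 1 / (n - k)))
  tval <- (m1 - m0) / denom
  scale <- pmax(Qtot / n, .Machine$double.eps)
  tval[!valid | sp2 <= 1e-12 * scale] <- NA_real_
  p_to_z(stats::pt(tval, n - 2L, lower.tail = FALSE))
}

resolve_statistic <- function(cfg, behavior) {
  stat <- cfg$statistic
  if (stat == "auto")
    stat <- if (behavior$is_binary) "liebermeister" else "pooled_t"
  if (stat == "liebermeister" && behavior$is_binary &&
      cfg$binary_volume_control == "glm")
    stat <- "glm_volume"
  stat
}

#' Max-statistic permutation FWE threshold
#'
#' For each permutation the behavior vector is shuffled across patients and
#' the voxel-wise maximum z recomputed; the threshold is the empirical
#' 100(1 - alpha) percentile (linear-interpolation quantile) of the max-z
#' distribution. The observed statistic is not appended to the null sample.
#'
#' @param arm_masks list of [lesion_mask()] for one cohort arm.
#' @param behavior a [behavior_vector()] aligned with `arm_masks`.
#' @param cfg an [lsm_config()]; `n_permutations`, `alpha` and `seed` are
#'   used.
#' @return The z threshold (scalar). `Inf` with a warning when no
#'   permutation yields a valid statistic.
#' @export
permutation_fwe_threshold <- function(arm_masks, behavior, cfg = lsm_config()) {
  design <- build_design(arm_masks, cfg$n_min)
  stat <- resolve_statistic(cfg, behavior)
  scores <- prepare_scores(design, behavior, cfg, stat)
  perm_threshold(design, scores, stat, cfg)
}

prepare_scores <- function(design, behavior, cfg, stat) {
  scores <- behavior$scores
  if (cfg$volume_control && stat == "pooled_t")
    scores <- residualize_volume(behavior, design$volumes)$scores
  scores
}

perm_threshold <- function(design, scores, stat, cfg) {
  n <- length(scores)
  set.seed(cfg$seed)
  P <- cfg$n_permutations
  S <- matrix(0, n, P)
  for (j in seq_len(P)) S[, j] <- scores[sample.int(n)]
  Z <- voxelwise_z(design$X, S, stat, design$volumes)
  maxz <- suppressWarnings(apply(Z, 2, max, na.rm = TRUE))
  maxz <- maxz[is.finite(maxz)]
  if (!length(maxz)) {
    warning("no permutation produced a valid statistic; threshold is Inf")
    return(Inf)
  }
  stats::quantile(maxz, 1 - cfg$alpha, type = 7, names = FALSE)
}

#' Run a mass-univariate lesion-symptom mapping analysis
#'
#' Voxels lesioned in at least `n_min` patients are tested; per tested voxel
#' the patients are split by lesion status and the configured statistic
#' (pooled-variance t for continuous scores, Liebermeister quasi-exact test
#' for binary impairment) is converted to a z score; the requested
#' correction produces the z threshold and the significant voxel set. All
#' thresholds live on one z scale regardless of statistic. Voxels with
#' degenerate groups or zero pooled variance are skipped and counted in
#' `n_skipped`; all-constant behavior yields an empty result flagged
#' "no significant results".
#'
#' @inheritParams permutation_fwe_threshold
#' @return Object of class `lsm_zmap`: `grid`, `tested_idx`, `z` (per tested
#'   voxel, NA for skipped), `threshold_z`, `significant_idx`, `correction`,
#'   `n_tested`, `n_skipped`, `alpha`, `n_min`, `statistic`, `message`.
#' @export
run_lsm <- function(arm_masks, behavior, cfg = lsm_config()) {
  stopifnot(inherits(behavior, "behavior_vector"))
  ids <- vapply(arm_masks, `[[`, character(1), "patient_id")
  if (!identical(ids, behavior$patient_ids))
    stop("behavior vector does not match the cohort arm (ids/order)")
  design <- build_design(arm_masks, cfg$n_min)
  if (!length(design$tested_idx))
    stop("no voxels survive the n_min filter")
  stat <- resolve_statistic(cfg, behavior)
  scores <- prepare_scores(design, behavior, cfg, stat)
  msg <- NULL
  if (stats::var(scores) == 0) msg <- "no significant results (constant behavior)"
  z <- voxelwise_z(design$X, matrix(scores, ncol = 1), stat,
                   design$volumes)[, 1]
  n_valid <- sum(!is.na(z))
  thr <- if (cfg$correction == "bonferroni") {
    bonferroni_z_threshold(cfg$alpha, max(n_valid, 1L))
  } else {
    perm_threshold(design, scores, stat, cfg)
  }
  sig <- design$tested_idx[!is.na(z) & z >= thr]
  if (is.null(msg) && !length(sig)) msg <- "no significant results"
  structure(list(grid = design$grid, tested_idx = design$tested_idx, z = z,
                 threshold_z = thr, significant_idx = sig,
                 correction = cfg$correction,
                 n_tested = length(design$tested_idx),
                 n_skipped = length(design$tested_idx) - n_valid,
                 alpha = cfg$alpha, n_min = cfg$n_min, statistic = stat,
                 seed = cfg$seed, message = msg),
            class = "lsm_zmap")
}

#' @export
print.lsm_zmap <- function(x, ...) {
  cat(sprintf(
    "<lsm_zmap> %s/%s: %d tested (%d skipped), threshold z >= %.4f, %d significant\n",
    x$statistic, x$correction, x$n_tested, x$n_skipped, x$threshold_z,
    length(x$significant_idx)))
  if (!is.null(x$message)) cat(" ", x$message, "\n")
  invisible(x)
}

#' Persist a z-map as NIfTI with a JSON sidecar
#'
#' @param zmap an `lsm_zmap`.
#' @param path output NIfTI path; the sidecar replaces the extension with
#'   `.json` (threshold, n_tested, correction, alpha, n_min, seed).
#' @export
save_zmap <- function(zmap, path) {
  vals <- zmap$z
  vals[is.na(vals)] <- 0
  write_zmap(vals, path, zmap$grid, zmap$tested_idx)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(threshold_z = zmap$threshold_z, n_tested = zmap$n_tested,
         correction = zmap$correction, alpha = zmap$alpha,
         n_min = zmap$n_min, statistic = zmap$statistic, seed = zmap$seed),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
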