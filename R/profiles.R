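# Lineage linear-profile quantification: background subtraction, slab maximum
# projections, profile sampling/normalization/aggregation, pointwise Welch
# testing, boundary position/integrity statistics, and chamber-wise signal
# area fractions.
#
# Conventions: profile positions are micrometres, 0 at the anchored midline,
# negative = anatomical right, positive = anatomical left.  A "leftward
# shift" of the boundary is therefore an increase of the intensity-weighted
# mean position m.

# ---- background subtraction -------------------------------------------------

#' Rolling-ball background subtraction
#'
#' Estimates the background of a 2-D single-channel image by grayscale
#' opening with a ball structuring element of the given radius (the classical
#' rolling-ball procedure) and subtracts it; output is clipped at zero.
#'
#' @param image numeric matrix.
#' @param radius_px ball radius in pixels (default 50).
#' @return matrix of the same shape, nonnegative.
#' @export
subtract_background <- function(image, radius_px = 50) {
  assert_that(is.matrix(image), "shape_error", "image must be a 2-D matrix")
  assert_that(is_scalar_num(radius_px) && radius_px >= 1, "invalid_spec",
              "radius_px must be >= 1")
  bg <- rolling_ball_background(image, radius_px)
  pmax(image - bg, 0)
}

# ---- slab projections -------------------------------------------------------

#' Maximum Z-projections over contiguous slabs
#'
#' Partitions the stack into contiguous non-overlapping slabs of `slab_um`
#' along z and returns one maximum projection per slab (the per-stage
#' equivalent of projecting optical sections every 50 um at E13.5-E14.0 or
#' every 100 um at E14.5).
#'
#' @param volume an [mc_volume()].
#' @param slab_um slab thickness in micrometres (>= one z-step).
#' @param channel channel name or index.
#' @return list of 2-D matrices `[y, x]`, one per slab.
#' @export
slab_max_projection <- function(volume, slab_um, channel) {
  assert_that(inherits(volume, "mc_volume"), "invalid_spec",
              "volume must be an mc_volume")
  arr <- volume$channels[[channel]]
  assert_that(!is.null(arr), "invalid_spec", "unknown channel")
  dz <- volume$voxel_size_um[["z"]]
  assert_that(slab_um >= dz, "invalid_spec",
              "slab_um must be at least one z voxel (%g um)", dz)
  nz <- dim(arr)[1L]
  per_slab <- max(1L, floor(slab_um / dz))
  if (per_slab >= nz) {
    sq_warn("slab (%g um) covers the whole stack; returning one projection", slab_um)
    per_slab <- nz
  }
  starts <- seq(1L, nz, by = per_slab)
  lapply(starts, function(s) {
    zi <- s:min(s + per_slab - 1L, nz)
    apply(arr[zi, , , drop = FALSE], c(2L, 3L), max)
  })
}

# ---- profile containers -----------------------------------------------------

#' Linear intensity profile
#'
#' @param positions_um strictly increasing positions (um), 0 at the anchor.
#' @param intensities intensities (arbitrary units), same length.
#' @param normalized whether intensities are max-normalized.
#' @export
linear_profile <- function(positions_um, intensities, normalized = FALSE) {
  assert_that(length(positions_um) == length(intensities) &&
                length(positions_um) >= 2L, "invalid_spec",
              "positions and intensities must be equal-length (>= 2)")
  assert_that(all(diff(positions_um) > 0), "invalid_spec",
              "positions must be strictly increasing")
  if (normalized) {
    assert_that(isTRUE(all.equal(max(intensities), 1)), "invalid_spec",
                "normalized profile must have max 1")
  }
  structure(list(positions_um = as.numeric(positions_um),
                 intensities = as.numeric(intensities),
                 normalized = isTRUE(normalized)),
            class = "linear_profile")
}

#' Profile sampling line on a 2-D image
#'
#' @param start,end `(x, y)` endpoints in pixel coordinates (1-based centres).
#' @param anchor_um arc-length position (um from `start`) mapped to 0; the
#'   paper anchors at the septal midline.
#' @param sampling_step_um sampling step along the line.
#' @export
profile_line <- function(start, end, anchor_um = 0, sampling_step_um = 1) {
  assert_that(length(start) == 2L && length(end) == 2L, "invalid_spec",
              "start/end must be (x, y) pairs")
  assert_that(!all(start == end), "invalid_spec", "line must have nonzero length")
  assert_that(sampling_step_um > 0, "invalid_spec", "sampling step must be > 0")
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 anchor_um = anchor_um, sampling_step_um = sampling_step_um),
            class = "profile_line")
}

bilinear_sample <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  x0 <- pmin(pmax(floor(x), 1L), nc - 1L)
  y0 <- pmin(pmax(floor(y), 1L), nr - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- image[cbind(y0, x0)]
  i01 <- image[cbind(y0, x0 + 1L)]
  i10 <- image[cbind(y0 + 1L, x0)]
  i11 <- image[cbind(y0 + 1L, x0 + 1L)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Sample an intensity profile along a line
#'
#' Intensities are bilinearly interpolated every `sampling_step_um` along the
#' line; positions are arc length minus the anchor.
#'
#' @param image numeric matrix `[y, x]`.
#' @param line a [profile_line()].
#' @param pixel_size_um image pixel size (isotropic in-plane).
#' @return a [linear_profile()].
#' @export
sample_profile <- function(image, line, pixel_size_um = 1) {
  assert_that(is.matrix(image), "shape_error", "image must be 2-D")
  assert_that(inherits(line, "profile_line"), "invalid_spec",
              "line must be a profile_line")
  p0 <- line$start; p1 <- line$end
  in_bounds <- function(p) p[1L] >= 1 && p[1L] <= ncol(image) &&
    p[2L] >= 1 && p[2L] <= nrow(image)
  assert_that(in_bounds(p0) && in_bounds(p1), "bounds_error",
              "profile line exceeds image bounds")
  len_um <- sqrt(sum((p1 - p0)^2)) * pixel_size_um
  s <- seq(0, len_um, by = line$sampling_step_um)
  tfrac <- s / len_um
  xs <- p0[1L] + tfrac * (p1[1L] - p0[1L])
  ys <- p0[2L] + tfrac * (p1[2L] - p0[2L])
  linear_profile(s - line$anchor_um, bilinear_sample(image, xs, ys))
}

#' Normalize a profile to its maximum
#'
#' @param profile a [linear_profile()].
#' @return the profile with intensities divided by their maximum (idempotent).
#' @export
normalize_profile <- function(profile) {
  assert_that(inherits(profile, "linear_profile"), "invalid_spec",
              "profile must be a linear_profile")
  mx <- max(profile$intensities)
  assert_that(mx > 0, "degenerate_profile", "all-zero profile cannot be normalized")
  linear_profile(profile$positions_um, profile$intensities / mx, normalized = TRUE)
}

#' Aggregate normalized profiles onto a common grid
#'
#' Each profile is linearly resampled onto a common anchored grid covering
#' the overlap of all position ranges; per-position mean, s.e.m. and n are
#' computed.
#'
#' @param profiles list of normalized [linear_profile()]s.
#' @param grid_step_um resampling step (default 1 um).
#' @return an object of class `profile_ensemble` with fields `positions_um`,
#'   `matrix` (profiles x positions), `mean`, `sem`, `n`.
#' @export
aggregate_profiles <- function(profiles, grid_step_um = 1) {
  assert_that(length(profiles) >= 1L, "invalid_spec", "need at least one profile")
  assert_that(all(vapply(profiles, function(p)
    inherits(p, "linear_profile") && p$normalized, TRUE)),
    "invalid_spec", "all profiles must be normalized linear_profiles")
  lo <- max(vapply(profiles, function(p) min(p$positions_um), 0))
  hi <- min(vapply(profiles, function(p) max(p$positions_um), 0))
  assert_that(lo < hi, "alignment_error", "profiles have no common overlap")
  grid <- seq(ceiling(lo / grid_step_um) * grid_step_um, hi, by = grid_step_um)
  mat <- t(vapply(profiles, function(p)
    stats::approx(p$positions_um, p$intensities, xout = grid)$y,
    numeric(length(grid))))
  n <- colSums(!is.na(mat))
  mu <- colMeans(mat)
  sem <- apply(mat, 2L, stats::sd) / sqrt(n)
  structure(list(positions_um = grid, matrix = mat, mean = mu, sem = sem, n = n),
            class = "profile_ensemble")
}

# ---- pointwise Welch test ---------------------------------------------------

# Vectorized Welch two-sample t-test over matrix columns.
welch_cols <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- colSums(sweep(A, 2L, mA)^2) / (nA - 1)
  vB <- colSums(sweep(B, 2L, mB)^2) / (nB - 1)
  se2 <- vA / nA + vB / nB
  t_stat <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  zero_b <- se2 == 0
  p[zero_b & mA == mB] <- 1
  p[zero_b & mA != mB] <- 0
  list(t = t_stat, df = df, p = p)
}

#' Pointwise Welch tests along the right-left axis
#'
#' Welch's two-sample t-test at every common grid position; raw p-values
#' (no multiplicity correction by default) and contiguous significant runs.
#'
#' @param ensembleA,ensembleB `profile_ensemble` objects on a common grid
#'   (their overlap is used).
#' @param alpha significance level for the mask (default 0.05).
#' @param adjust `"none"` (default, raw p) or `"BH"`.
#' @return object of class `positionwise_test` with `positions_um`, `p`,
#'   `significant` mask and `runs` (data.frame of contiguous runs, um).
#' @export
pointwise_welch <- function(ensembleA, ensembleB, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  gA <- ensembleA$positions_um; gB <- ensembleB$positions_um
  common <- intersect(gA, gB)
  assert_that(length(common) > 0L, "alignment_error", "no common positions")
  A <- ensembleA$matrix[, match(common, gA), drop = FALSE]
  B <- ensembleB$matrix[, match(common, gB), drop = FALSE]
  res <- welch_cols(A, B)
  p <- res$p
  p[colSums(!is.na(A)) < 2L | colSums(!is.na(B)) < 2L] <- NA_real_
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  sig <- !is.na(p) & p < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start_um = common[starts[r$values]],
                     end_um = common[ends[r$values]])
  structure(list(positions_um = common, t = res$t, p = p,
                 alpha = alpha, significant = sig, runs = runs),
            class = "positionwise_test")
}

# ---- boundary statistics ----------------------------------------------------

#' Intensity-weighted boundary position and spread
#'
#' For a normalized nonnegative profile with intensities `w` at positions
#' `x`: position `m = sum(w x) / sum(w)` and spread
#' `s = sqrt(sum(w (x - m)^2) / sum(w))`.
#'
#' @param profile a [linear_profile()] (normalized, nonnegative).
#' @return object of class `boundary_stat` with `m`, `s`, `total_intensity`.
#' @export
boundary_stats <- function(profile) {
  assert_that(inherits(profile, "linear_profile"), "invalid_spec",
              "profile must be a linear_profile")
  w <- profile$intensities
  assert_that(all(w >= 0), "invalid_spec", "intensities must be nonnegative")
  tot <- sum(w)
  assert_that(tot > 0, "degenerate_profile", "zero total intensity")
  x <- profile$positions_um
  m <- sum(w * x) / tot
  s <- sqrt(sum(w * (x - m)^2) / tot)
  structure(list(m = m, s = s, total_intensity = tot), class = "boundary_stat")
}

#' Compare boundary positions between two groups of profiles
#'
#' Two-sided Welch t-test on the per-profile intensity-weighted positions
#' `m_i` (boundary shift) and two-sided F-test on their variance (boundary
#' integrity / broadening).  `spread_operand = "profile_s"` instead compares
#' the mean per-profile spread `s_i` by t-test on `s_i` and runs the F-test
#' on `s_i` (the alternative reading of the variance comparison).
#'
#' @param statsA,statsB lists of [boundary_stats()] results (>= 2 each).
#' @param spread_operand `"m_variance"` (default) or `"profile_s"`.
#' @return object of class `boundary_comparison` with `t`, `p_t`,
#'   `F`, `df`, `p_F`, `n_A`, `n_B`.
#' @export
compare_boundaries <- function(statsA, statsB,
                               spread_operand = c("m_variance", "profile_s")) {
  spread_operand <- match.arg(spread_operand)
  get <- function(ss, f) vapply(ss, function(s) s[[f]], 0)
  assert_that(length(statsA) >= 2L && length(statsB) >= 2L, "invalid_spec",
              "need >= 2 boundary stats per group")
  mA <- get(statsA, "m"); mB <- get(statsB, "m")
  tt <- welch_two_sample(mA, mB)
  op_A <- if (spread_operand == "m_variance") mA else get(statsA, "s")
  op_B <- if (spread_operand == "m_variance") mB else get(statsB, "s")
  vA <- stats::var(op_A); vB <- stats::var(op_B)
  if (vA == 0 && vB == 0) {
    Fs <- NA_real_; pF <- NA_real_
    sq_warn("zero variance in both groups; F-test undefined")
  } else if (vB == 0 || vA == 0) {
    Fs <- if (vB == 0) Inf else 0
    pF <- 0
  } else {
    Fs <- vA / vB
    df1 <- length(op_A) - 1L; df2 <- length(op_B) - 1L
    pF <- 2 * min(stats::pf(Fs, df1, df2), 1 - stats::pf(Fs, df1, df2))
  }
  structure(list(t = tt$t, df_t = tt$df, p_t = tt$p,
                 F = Fs, df = c(length(op_A) - 1L, length(op_B) - 1L),
                 p_F = pF, n_A = length(statsA), n_B = length(statsB),
                 spread_operand = spread_operand),
            class = "boundary_comparison")
}

welch_two_sample <- function(a, b) {
  res <- welch_cols(matrix(a, ncol = 1L), matrix(b, ncol = 1L))
  if (stats::var(a) + stats::var(b) == 0) {
    res$t <- if (mean(a) == mean(b)) 0 else res$t
  }
  list(t = res$t[1L], df = res$df[1L], p = res$p[1L])
}

# ---- chamber area fractions -------------------------------------------------

#' Per-slice LV/RV signal area fractions
#'
#' Thresholds the signal channel per slice and expresses the thresholded area
#' inside each ventricular ROI as a percentage of the total signal area
#' across both ventricles (per-slice normalization to 100).
#'
#' @param image 2-D matrix or 3-D array `[z, y, x]` of the signal channel.
#' @param roi_LV,roi_RV disjoint logical masks `[y, x]`.
#' @param threshold_method `"otsu"` or a numeric threshold.
#' @return object of class `chamber_fractions`: data.frame `per_slice`
#'   (slice, LV_pct, RV_pct) and the threshold used per slice.
#' @export
chamber_area_fractions <- function(image, roi_LV, roi_RV,
                                   threshold_method = "otsu") {
  assert_that(!any(roi_LV & roi_RV), "invalid_spec", "ROIs must be disjoint")
  if (is.matrix(image)) image <- array(image, c(1L, dim(image)))
  nz <- dim(image)[1L]
  rows <- list(); thr_used <- numeric(0)
  for (k in seq_len(nz)) {
    sl <- image[k, , ]
    thr <- if (identical(threshold_method, "otsu")) {
      otsu_threshold(sl[roi_LV | roi_RV])
    } else as.numeric(threshold_method)
    signal <- sl > thr
    aLV <- sum(signal & roi_LV); aRV <- sum(signal & roi_RV)
    if (aLV + aRV == 0) {
      sq_warn("slice %d: no signal in either ROI; excluded", k)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      slice = k, LV_pct = 100 * aLV / (aLV + aRV),
      RV_pct = 100 * aRV / (aLV + aRV))
    thr_used <- c(thr_used, thr)
  }
  assert_that(length(rows) > 0L, "degenerate_profile",
              "no slice contained signal in either ROI")
  structure(list(per_slice = do.call(rbind, rows), threshold = thr_used),
            class = "chamber_fractions")
}

#' Compare chamber fractions between groups
#'
#' Two-sided Welch t-test on per-slice RV (default) or LV percentages.
#'
#' @param groupA,groupB `chamber_fractions` objects or numeric vectors of
#'   per-slice percentages.
#' @param side `"RV"` or `"LV"`.
#' @return list with `t`, `df`, `p`, group means.
#' @export
compare_chamber_fractions <- function(groupA, groupB, side = c("RV", "LV")) {
  side <- match.arg(side)
  pull <- function(g) {
    if (inherits(g, "chamber_fractions")) g$per_slice[[paste0(side, "_pct")]]
    else as.numeric(g)
  }
  a <- pull(groupA); b <- pull(groupB)
  assert_that(length(a) >= 2L && length(b) >= 2L, "invalid_spec",
              "need >= 2 per-slice values per group")
  tt <- welch_two_sample(a, b)
  list(t = tt$t, df = tt$df, p = tt$p, mean_A = mean(a), mean_B = mean(b),
       side = side)
}
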