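# Lineage profile quantification: background, projections, sampling,
# aggregation, pointwise tests, boundary statistics, chamber fractions.

test_that("rolling-ball background subtraction behaves like the procedure", {
  # flat field is removed entirely
  flat <- matrix(3.7, 40, 40)
  expect_true(all(subtract_background(flat, 10) == 0))
  expect_error(subtract_background(array(0, c(4, 4, 4))), class = "shape_error")

  # a narrow bright peak on a flat field survives within 5% at radius 50
  img <- matrix(10, 120, 120)
  img[60:62, 60:62] <- 110
  out <- subtract_background(img, 50)
  expect_gt(max(out), 0.95 * 100)

  # a large-scale smooth gradient is background: residual < 10% of amplitude
  ramp <- outer(seq(0, 50, length.out = 200), rep(1, 200))
  res <- subtract_background(ramp, 20)
  expect_lt(max(res), 0.1 * 50)
})

test_that("slab projections partition the stack", {
  vol <- mc_volume(list(sig = array(0, c(20, 8, 8))), c(10, 4, 4))
  # 200 um stack in 50 um slabs -> 4 projections
  expect_length(slab_max_projection(vol, 50, "sig"), 4L)
  # constant stack projects to constants
  vol$channels$sig[] <- 2.5
  projs <- slab_max_projection(vol, 50, "sig")
  expect_true(all(vapply(projs, function(p) all(p == 2.5), TRUE)))
  # a single bright voxel appears in exactly one projection
  vol$channels$sig[] <- 0
  vol$channels$sig[7, 3, 5] <- 9
  projs <- slab_max_projection(vol, 50, "sig")
  expect_equal(sum(vapply(projs, max, 0) == 9), 1L)
  # slab covering the whole stack: single projection with warning
  expect_warning(p1 <- slab_max_projection(vol, 1000, "sig"), "whole stack")
  expect_length(p1, 1L)
})

test_that("profile sampling reproduces on-grid and analytic values", {
  img <- matrix(0, 5, 5)
  img[3, ] <- c(1, 3, 7, 9, 2)
  ln <- profile_line(c(2, 3), c(4, 3), anchor_um = 0, sampling_step_um = 1)
  pr <- sample_profile(img, ln, pixel_size_um = 1)
  expect_equal(pr$intensities, c(3, 7, 9))
  # anchoring at the midpoint of a 100 um line spans [-50, 50]
  img2 <- matrix(1, 10, 120)
  ln2 <- profile_line(c(5, 5), c(105, 5), anchor_um = 50, sampling_step_um = 1)
  pr2 <- sample_profile(img2, ln2, pixel_size_um = 1)
  expect_equal(range(pr2$positions_um), c(-50, 50))
  # diagonal line on a bilinear ramp I(x, y) = 2x + 3y: interpolation exact
  ramp <- outer(seq_len(20), seq_len(20), function(y, x) 2 * x + 3 * y)
  ln3 <- profile_line(c(2, 2), c(12, 12), anchor_um = 0,
                      sampling_step_um = sqrt(2))
  pr3 <- sample_profile(ramp, ln3, pixel_size_um = 1)
  tpos <- pr3$positions_um / sqrt(2)  # steps along the diagonal
  expect_equal(pr3$intensities, 2 * (2 + tpos) + 3 * (2 + tpos))
  # out-of-bounds rejected
  expect_error(sample_profile(img, profile_line(c(1, 1), c(99, 1))),
               class = "bounds_error")
})

test_that("normalization is exact, idempotent and guards degeneracy", {
  pr <- linear_profile(c(0, 1, 2), c(2, 4, 8))
  np <- normalize_profile(pr)
  expect_equal(np$intensities, c(0.25, 0.5, 1))
  expect_true(np$normalized)
  expect_equal(normalize_profile(np), np)
  expect_error(normalize_profile(linear_profile(c(0, 1, 2), c(0, 0, 0))),
               class = "degenerate_profile")
})

test_that("aggregation matches hand-resampling and is order-independent", {
  p1 <- normalize_profile(linear_profile(c(0, 10, 20), c(0.2, 1, 0.4)))
  p2 <- normalize_profile(linear_profile(c(5, 15, 25), c(1, 0.5, 0.25)))
  ens <- aggregate_profiles(list(p1, p2), grid_step_um = 5)
  # overlap is [5, 20]; hand-interpolated values at 5, 10, 15, 20
  hand1 <- approx(p1$positions_um, p1$intensities, c(5, 10, 15, 20))$y
  hand2 <- approx(p2$positions_um, p2$intensities, c(5, 10, 15, 20))$y
  expect_equal(ens$positions_um, c(5, 10, 15, 20))
  expect_equal(ens$mean, (hand1 + hand2) / 2)
  # identical profiles: zero dispersion
  ens2 <- aggregate_profiles(list(p1, p1))
  expect_true(all(ens2$sem == 0))
  # permutation invariance
  ens3 <- aggregate_profiles(list(p2, p1), grid_step_um = 5)
  expect_equal(ens3$mean, ens$mean)
  expect_equal(ens3$sem, ens$sem)
  # empty overlap errors
  p3 <- normalize_profile(linear_profile(c(100, 110), c(1, 0.5)))
  expect_error(aggregate_profiles(list(p1, p3)), class = "alignment_error")
})

test_that("pointwise Welch flags the region between shifted boundaries", {
  # logistic (step) ensembles centred at 0 vs +40 um, sigma-noise 0.05
  grid <- seq(-100, 100, by = 2)
  logistic_profiles <- function(center, n, seed) {
    withr::with_seed(seed, lapply(seq_len(n), function(i) {
      y <- plogis((grid - center) / 20) + rnorm(length(grid), 0, 0.05)
      normalize_profile(linear_profile(grid, pmax(y, 1e-6)))
    }))
  }
  ensA <- aggregate_profiles(logistic_profiles(0, 20, 1L), grid_step_um = 2)
  ensB <- aggregate_profiles(logistic_profiles(40, 20, 2L), grid_step_um = 2)
  res <- pointwise_welch(ensA, ensB)
  # identical ensembles show nothing
  none <- pointwise_welch(ensA, ensA)
  expect_false(any(none$significant))
  expect_true(all(none$p[!is.na(none$p)] == 1))
  # the interval between the two centres is significant
  mid <- res$positions_um >= 10 & res$positions_um <= 30
  expect_true(all(res$significant[mid]))
  expect_true(nrow(res$runs) >= 1L)
})

test_that("boundary statistics match closed forms and are equivariant", {
  delta <- linear_profile(c(-20, -10, 0, 10, 20), c(0, 0, 1, 0, 0))
  bs <- boundary_stats(delta)
  expect_equal(bs$m, 0)
  expect_equal(bs$s, 0)
  unif <- normalize_profile(linear_profile(c(-20, -10, 0, 10, 20), rep(1, 5)))
  expect_equal(boundary_stats(unif)$s, sqrt(200))
  bim <- linear_profile(seq(-30, 30, 10), c(1, 0.2, 0, 0, 0, 0.2, 1))
  expect_equal(boundary_stats(bim)$m, 0)
  # equivariance under position shift and intensity scaling
  set.seed(42)
  for (i in 1:5) {
    x <- sort(runif(30, -50, 50))
    w <- runif(30)
    b0 <- boundary_stats(linear_profile(x, w))
    bshift <- boundary_stats(linear_profile(x + 13.5, w))
    expect_equal(bshift$m, b0$m + 13.5)
    expect_equal(bshift$s, b0$s)
    bscale <- boundary_stats(linear_profile(x, 3 * w))
    expect_equal(bscale$m, b0$m)
    expect_equal(bscale$s, b0$s)
  }
  expect_error(boundary_stats(linear_profile(c(0, 1), c(0, 0))),
               class = "degenerate_profile")
})

test_that("group comparison detects shifts and broadening", {
  mk_stats <- function(ms) lapply(ms, function(m)
    structure(list(m = m, s = 5, total_intensity = 1), class = "boundary_stat"))
  a <- mk_stats(c(-3, 1, 0, 2, -1, 0.5, -0.5, 1.5, -2, 0.2,
                  0.8, -1.2, 2.2, -0.7, 0.3, 1.1, -1.8, 0.9, -0.4, 0.6))
  ident <- compare_boundaries(a, a)
  expect_equal(ident$t, 0)
  expect_equal(ident$p_t, 1)
  expect_equal(ident$F, 1)
  # +30 um constant shift
  b <- mk_stats(vapply(a, `[[`, 0, "m") + 30)
  shift <- compare_boundaries(a, b)
  expect_lt(shift$p_t, 0.01)
  # 4x the spread of m_i (sd scaled 2x => F ~ 1/4 here, two-sided detects it)
  set.seed(7)
  base <- rnorm(50, 0, 5)
  wide <- rnorm(50, 0, 10)
  cmp <- compare_boundaries(mk_stats(base), mk_stats(wide))
  expect_equal(cmp$F, var(base) / var(wide), tolerance = 1e-12)
  expect_lt(cmp$p_F, 0.01)
  # alternative spread operand: constant per-profile s in both groups is a
  # degenerate variance comparison and must be flagged
  expect_warning(alt <- compare_boundaries(a, b, spread_operand = "profile_s"),
                 "F-test undefined")
  expect_true(is.finite(alt$p_t))
})

test_that("chamber fractions recover constructed splits", {
  img <- matrix(0, 40, 60)
  roi_LV <- matrix(FALSE, 40, 60); roi_LV[, 31:60] <- TRUE
  roi_RV <- matrix(FALSE, 40, 60); roi_RV[, 1:30] <- TRUE
  img[10:19, 35:44] <- 1  # all signal in LV
  res <- chamber_area_fractions(img, roi_LV, roi_RV, threshold_method = 0.5)
  expect_equal(res$per_slice$LV_pct, 100)
  expect_equal(res$per_slice$RV_pct, 0)
  # constructed 70/30 split
  img2 <- matrix(0, 40, 60)
  img2[1:10, 31:44] <- 1   # 140 px LV
  img2[1:10, 1:6] <- 1     # 60 px RV
  res2 <- chamber_area_fractions(img2, roi_LV, roi_RV, threshold_method = 0.5)
  expect_equal(res2$per_slice$LV_pct, 70, tolerance = 0.02)
  # per-slice normalization sums to 100
  expect_equal(res2$per_slice$LV_pct + res2$per_slice$RV_pct, 100)
  # comparison: identical groups p = 1; labels swap keeps two-sided p
  a <- c(5, 6, 4, 5.5, 5, 4.5, 6, 5, 4, 5.2)
  b <- c(30, 28, 33, 29, 31, 30, 27, 32, 29, 30)
  expect_equal(compare_chamber_fractions(a, a)$p, 1)
  cab <- compare_chamber_fractions(a, b)
  expect_lt(cab$p, 0.01)
  expect_equal(cab$p, compare_chamber_fractions(b, a)$p)
})
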