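# Orientation scoring of cell arrangement: structure-tensor orientation and
# coherency, gradient-weighted directionality histograms, alignment to the
# dominant direction, pooled angle-bin scores, the two-sample Watson U2
# circular statistic, and the Wilcoxon rank-sum test.
#
# Orientation convention: 0 degrees = image x-axis, counter-clockwise
# positive (y up), axial period 180, values reported in (-90, 90].

# ---- structure tensor -------------------------------------------------------

#' Structure-tensor orientation field
#'
#' Gaussian-derivative gradients (scale `gradient_sigma`) are combined into
#' the structure tensor smoothed over a Gaussian window (`window_sigma`).
#' The per-pixel orientation is the iso-intensity (structure) direction
#' `theta = 0.5 * atan2(2 Jxy, Jxx - Jyy) + 90` wrapped to `(-90, 90]`;
#' coherency `C = (l1 - l2) / (l1 + l2)` and energy `E = l1 + l2` (tensor
#' trace), with `C = 0` where `E = 0`.
#'
#' @param image numeric matrix.
#' @param gradient_sigma derivative-of-Gaussian scale (pixels).
#' @param window_sigma tensor smoothing window (pixels).  The default (4) is
#'   wide enough that the per-pixel eigen-anisotropy of an isotropic field is
#'   not dominated by small-sample bias (a sigma = 2 window leaves white
#'   noise with apparent coherency above 0.2 for any gradient estimator).
#' @return object of class `orientation_field` with matrices `theta_deg`,
#'   `coherency`, `energy`.
#' @export
structure_tensor_field <- function(image, gradient_sigma = 1, window_sigma = 4) {
  assert_that(is.matrix(image), "shape_error", "image must be 2-D")
  assert_that(min(dim(image)) >= 4 * window_sigma, "size_error",
              "image smaller than 4 * window_sigma")
  g <- gaussian_kernel1d(gradient_sigma)
  dg <- gaussian_kernel1d(gradient_sigma, derivative = TRUE)
  gx <- conv1d(conv1d(image, dg, "x"), g, "y")
  gy <- -conv1d(conv1d(image, g, "x"), dg, "y")  # y-up sign convention
  Jxx <- gaussian_blur(gx * gx, window_sigma)
  Jyy <- gaussian_blur(gy * gy, window_sigma)
  Jxy <- gaussian_blur(gx * gy, window_sigma)
  energy <- Jxx + Jyy
  # suppress floating-point residue: a constant image has zero gradients
  tiny <- 1e-18 * max(1, max(abs(image))^2)
  zero <- energy < tiny
  energy[zero] <- 0
  Jxy[zero] <- 0
  delta <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2)
  coherency <- ifelse(energy > .Machine$double.eps * max(energy, 1),
                      delta / energy, 0)
  phi_grad <- 0.5 * atan2(2 * Jxy, Jxx - Jyy) * 180 / pi
  theta <- wrap_axial(phi_grad + 90)
  theta[energy == 0] <- 0
  structure(list(theta_deg = theta, coherency = coherency, energy = energy,
                 gradient_sigma = gradient_sigma, window_sigma = window_sigma),
            class = "orientation_field")
}

#' Energy-weighted mean coherency over a region
#'
#' @param field an [structure_tensor_field()] result.
#' @param mask optional logical matrix selecting the region (default: all).
#' @return scalar in `[0, 1]`; 0 (with a warning) when the region has no
#'   gradient energy.
#' @export
region_coherency <- function(field, mask = NULL) {
  assert_that(inherits(field, "orientation_field"), "invalid_spec",
              "field must be an orientation_field")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(field$energy), ncol(field$energy))
  assert_that(any(mask), "invalid_spec", "mask must be nonempty")
  w <- field$energy[mask]
  if (sum(w) == 0) {
    sq_warn("zero gradient energy in region; coherency reported as 0")
    return(0)
  }
  sum(field$coherency[mask] * w) / sum(w)
}

# ---- directionality histogram -----------------------------------------------

#' Gradient-weighted directionality histogram
#'
#' Histogram of per-pixel structure orientations weighted by squared gradient
#' magnitude, normalized to sum 1, on the axial range `(-90, 90]` with bins
#' centred on multiples of `bin_deg` (so 0 is always a bin centre).  The
#' dominant direction is the peak bin centre.
#'
#' @param image numeric matrix, or an `orientation_field`.
#' @param bin_deg bin width in degrees (default 2).
#' @param gradient_sigma derivative scale when `image` is a matrix.
#' @return object of class `directionality_histogram` with `centers_deg`,
#'   `weights`, `dominant_direction_deg`, `bin_deg`.
#' @export
directionality_histogram <- function(image, bin_deg = 2, gradient_sigma = 1) {
  if (inherits(image, "orientation_field")) {
    theta <- image$theta_deg
    w <- image$energy
  } else {
    assert_that(is.matrix(image), "shape_error", "image must be 2-D")
    g <- gaussian_kernel1d(gradient_sigma)
    dg <- gaussian_kernel1d(gradient_sigma, derivative = TRUE)
    gx <- conv1d(conv1d(image, dg, "x"), g, "y")
    gy <- -conv1d(conv1d(image, g, "x"), dg, "y")
    w <- gx^2 + gy^2
    w[w < 1e-18 * max(1, max(abs(image))^2)] <- 0
    theta <- wrap_axial(atan2(gy, gx) * 180 / pi + 90)
  }
  assert_that(sum(w) > 0, "empty_histogram", "image has zero gradient energy")
  n_bins <- round(180 / bin_deg)
  assert_that(n_bins * bin_deg == 180, "invalid_spec",
              "bin_deg must divide 180")
  # centres k * bin_deg for k = -(n/2 - 1) .. n/2; -90 wraps onto +90
  idx <- round(theta / bin_deg)
  idx[idx == -n_bins / 2] <- n_bins / 2
  centers <- seq(-(n_bins / 2 - 1L), n_bins / 2) * bin_deg
  weights <- vapply(centers / bin_deg, function(k) sum(w[idx == k]), 0)
  weights <- weights / sum(weights)
  structure(list(centers_deg = centers, weights = weights,
                 dominant_direction_deg = centers[which.max(weights)],
                 bin_deg = bin_deg),
            class = "directionality_histogram")
}

#' Rotate a histogram so the dominant direction sits at 0 degrees
#'
#' Bin centres are shifted by the dominant direction under the axial wrap;
#' weights are unchanged.  Idempotent.
#'
#' @param hist a [directionality_histogram()].
#' @return aligned `directionality_histogram`.
#' @export
align_to_dominant <- function(hist) {
  assert_that(inherits(hist, "directionality_histogram"), "invalid_spec",
              "hist must be a directionality_histogram")
  shift <- hist$dominant_direction_deg
  centers <- wrap_axial(hist$centers_deg - shift)
  ord <- order(centers)
  structure(list(centers_deg = centers[ord], weights = hist$weights[ord],
                 dominant_direction_deg = 0, bin_deg = hist$bin_deg),
            class = "directionality_histogram")
}

#' Pool histogram weight around an angle
#'
#' Sum of weights whose bin centres lie within `center_deg +/- halfwidth_deg`
#' under the axial wrap; pooling around 90 degrees therefore collects both
#' the +90 and -90 neighbourhoods (e.g. 85..95 and -85..-95).
#'
#' @param hist an (aligned) [directionality_histogram()].
#' @param center_deg pooling centre.
#' @param halfwidth_deg pooling half-width.
#' @return scalar pooled weight.
#' @export
pool_angle_scores <- function(hist, center_deg, halfwidth_deg) {
  assert_that(inherits(hist, "directionality_histogram"), "invalid_spec",
              "hist must be a directionality_histogram")
  if (halfwidth_deg < hist$bin_deg / 2) {
    sq_warn("halfwidth below bin width; pooling a single bin")
  }
  sel <- axial_distance(hist$centers_deg, center_deg) <= halfwidth_deg + 1e-9
  sum(hist$weights[sel])
}

# ---- Watson two-sample U2 ---------------------------------------------------

# U2 from pooled cumulative-fraction differences, ties pooled (midrank
# handling): unique sorted pooled values t_k with multiplicities w_k,
# d_k = F_A(t_k) - F_B(t_k), dbar = sum(w d) / N,
# U2 = (n m / N^2) * sum(w (d - dbar)^2).
watson_u2_stat <- function(a, b) {
  n <- length(a); m <- length(b); N <- n + m
  vals <- sort(unique(c(a, b)))
  cA <- cumsum(vapply(vals, function(v) sum(a == v), 0)) / n
  cB <- cumsum(vapply(vals, function(v) sum(b == v), 0)) / m
  w <- vapply(vals, function(v) sum(a == v) + sum(b == v), 0)
  d <- cA - cB
  dbar <- sum(w * d) / N
  (n * m / N^2) * sum(w * (d - dbar)^2)
}

# Faster internal version on pre-encoded numeric angles.
watson_u2_stat_fast <- function(pooled_sorted, is_a_sorted, n, m) {
  N <- n + m
  if (!anyDuplicated(pooled_sorted)) {
    ia <- as.numeric(is_a_sorted)
    d <- cumsum(ia) / n - cumsum(1 - ia) / m
    dbar <- sum(d) / N
    return((n * m / N^2) * sum((d - dbar)^2))
  }
  # group ties
  grp <- cumsum(c(TRUE, diff(pooled_sorted) != 0))
  cntA <- as.numeric(rowsum(as.numeric(is_a_sorted), grp))
  cnt <- tabulate(grp)
  d <- cumsum(cntA) / n - cumsum(cnt - cntA) / m
  dbar <- sum(cnt * d) / N
  (n * m / N^2) * sum(cnt * (d - dbar)^2)
}

#' Two-sample Watson U2 test for circular or axial data
#'
#' Rank-based two-sample U2 with midrank handling of ties.  The p-value is
#' obtained by label permutation (exhaustive enumeration of all label
#' assignments when there are no more than `n_perm`, otherwise `n_perm`
#' random permutations with the `(k + 1) / (B + 1)` estimator) or by the
#' asymptotic series.
#'
#' @param angles_A,angles_B angle samples in degrees.
#' @param method `"permutation"` (default) or `"asymptotic"`.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutation draw.
#' @param period_deg period of the data (360 circular, 180 axial).
#' @return object of class `watson_result` with `u2`, `p`, `method`,
#'   `n_A`, `n_B`.
#' @export
watson_u2_two_sample <- function(angles_A, angles_B,
                                 method = c("permutation", "asymptotic"),
                                 n_perm = 10000L, seed = 1L,
                                 period_deg = 360) {
  method <- match.arg(method)
  assert_that(length(angles_A) >= 2L && length(angles_B) >= 2L,
              "invalid_spec", "each sample needs >= 2 angles")
  a <- angles_A %% period_deg
  b <- angles_B %% period_deg
  n <- length(a); m <- length(b); N <- n + m
  pooled <- c(a, b)
  lab <- c(rep(TRUE, n), rep(FALSE, m))
  ord <- order(pooled)
  u2 <- watson_u2_stat_fast(pooled[ord], lab[ord], n, m)
  if (length(unique(pooled)) == 1L) {
    return(structure(list(u2 = 0, p = 1, method = method, n_A = n, n_B = m),
                     class = "watson_result"))
  }
  if (method == "asymptotic") {
    p <- watson_u2_pvalue_asymptotic(u2)
  } else {
    ps <- pooled[ord]
    n_total <- choose(N, n)
    if (n_total <= n_perm) {
      combs <- utils::combn(N, n)
      stats_all <- apply(combs, 2L, function(ix) {
        la <- logical(N); la[ix] <- TRUE
        watson_u2_stat_fast(ps, la, n, m)
      })
      p <- mean(stats_all >= u2 - 1e-12)
      method <- "permutation"  # exhaustive enumeration
    } else {
      stats_perm <- run_seeded(seed, vapply(seq_len(n_perm), function(i) {
        la <- logical(N); la[sample.int(N, n)] <- TRUE
        watson_u2_stat_fast(ps, la, n, m)
      }, 0))
      p <- (1 + sum(stats_perm >= u2 - 1e-12)) / (n_perm + 1)
    }
  }
  structure(list(u2 = u2, p = p, method = method, n_A = n, n_B = m),
            class = "watson_result")
}

# Asymptotic tail of the Watson U2 null distribution.
watson_u2_pvalue_asymptotic <- function(u2, k_max = 50L) {
  k <- seq_len(k_max)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * pi^2 * u2))
  min(max(p, 0), 1)
}

# ---- Wilcoxon rank-sum ------------------------------------------------------

#' Wilcoxon rank-sum test (normal approximation, continuity corrected)
#'
#' Two-sided two-sample rank-sum test with midranks for ties, tie-corrected
#' variance and continuity correction, matching the classical large-sample
#' procedure.
#'
#' @param a,b numeric samples.
#' @return object of class `ranksum_result` with `statistic` (Mann-Whitney
#'   U of `a`), `rank_sum_a`, `z`, `p`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  assert_that(length(a) >= 1L && length(b) >= 1L, "invalid_spec",
              "each sample needs >= 1 value")
  n <- length(a); m <- length(b); N <- n + m
  r <- rank(c(a, b))
  ra <- sum(r[seq_len(n)])
  U <- ra - n * (n + 1) / 2
  mu <- n * m / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  v <- n * m / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v == 0) {
    return(structure(list(statistic = U, rank_sum_a = ra, z = 0, p = 1),
                     class = "ranksum_result"))
  }
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(v)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  structure(list(statistic = U, rank_sum_a = ra, z = z, p = p),
            class = "ranksum_result")
}
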