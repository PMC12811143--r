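# Low-level raster operations shared by the analysis modules: separable
# Gaussian (derivative) filtering, grayscale morphology with a ball element,
# exact Euclidean distance transform, local thickness, connected-component
# labelling, and non-maximum suppression.  Matrices are indexed [row = y,
# col = x]; 3-D arrays are [z, y, x].

# ---- shifting and padding ---------------------------------------------------

# Shift a matrix by (dy, dx), filling vacated cells with `fill`.
shift_mat <- function(m, dy, dx, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr) - dy
  xs <- seq_len(nc) - dx
  yk <- ys >= 1L & ys <= nr
  xk <- xs >= 1L & xs <= nc
  if (any(yk) && any(xk)) out[yk, xk] <- m[ys[yk], xs[xk], drop = FALSE]
  out
}

# ---- separable convolution --------------------------------------------------

gaussian_kernel1d <- function(sigma, derivative = FALSE) {
  if (sigma <= 0) {
    return(if (derivative) c(0.5, 0, -0.5) else 1)
  }
  half <- max(1L, ceiling(3 * sigma))
  x <- seq(-half, half)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (derivative) -x / sigma^2 * g else g
}

# 1-D convolution along rows (axis = "x") or columns (axis = "y") with
# replicate edge padding.
conv1d <- function(m, kernel, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "y") return(t(conv1d(t(m), kernel, "x")))
  half <- (length(kernel) - 1L) %/% 2L
  nc <- ncol(m)
  pad_idx <- c(rep(1L, half), seq_len(nc), rep(nc, half))
  mp <- m[, pad_idx, drop = FALSE]
  out <- matrix(0, nrow(m), nc)
  for (i in seq_along(kernel)) {
    if (kernel[i] != 0)
      out <- out + kernel[i] * mp[, seq(i, i + nc - 1L), drop = FALSE]
  }
  out
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel1d(sigma)
  conv1d(conv1d(m, k, "x"), k, "y")
}

# ---- grayscale morphology with a ball ---------------------------------------

disk_offsets <- function(radius) {
  r <- floor(radius)
  dy <- rep(seq(-r, r), each = 2L * r + 1L)
  dx <- rep(seq(-r, r), times = 2L * r + 1L)
  keep <- dy^2 + dx^2 <= radius^2
  cbind(dy = dy[keep], dx = dx[keep])
}

# Non-flat erosion/dilation: height[k] is the structuring-element height at
# offsets[k, ]. Outside-image samples are ignored (padding with +/- Inf).
gray_erode <- function(m, offsets, height) {
  out <- matrix(Inf, nrow(m), ncol(m))
  for (k in seq_len(nrow(offsets))) {
    out <- pmin(out, shift_mat(m, -offsets[k, 1L], -offsets[k, 2L], Inf) - height[k])
  }
  out
}

gray_dilate <- function(m, offsets, height) {
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (k in seq_len(nrow(offsets))) {
    out <- pmax(out, shift_mat(m, offsets[k, 1L], offsets[k, 2L], -Inf) + height[k])
  }
  out
}

# Rolling-ball background: grayscale opening with a ball of the given radius
# (element height sqrt(r^2 - d^2)), the morphological equivalent of rolling a
# ball under the intensity surface.
rolling_ball_background <- function(m, radius) {
  off <- disk_offsets(radius)
  h <- sqrt(pmax(radius^2 - off[, 1L]^2 - off[, 2L]^2, 0))
  gray_dilate(gray_erode(m, off, h), off, h)
}

# ---- Euclidean distance transform -------------------------------------------

# Felzenszwalb & Huttenlocher 1-D squared distance transform.
dt1d_sq <- function(f) {
  n <- length(f)
  BIG <- 1e15
  f <- pmin(f, BIG)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  if (n > 1L) {
    for (q in 2L:n) {
      repeat {
        s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
        if (k > 1L && s <= z[k]) k <- k - 1L else break
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1L] <- Inf
    }
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Exact Euclidean distance transform of a logical mask: distance (in pixels)
# from each TRUE pixel to the nearest FALSE pixel. Image border counts as
# background when `border_background` (the usual convention for wall
# thickness is FALSE).
edt2d <- function(mask, border_background = FALSE) {
  f <- matrix(ifelse(mask, 1e15, 0), nrow(mask), ncol(mask))
  if (border_background) {
    # pad handled implicitly: clamp distances to border distance afterwards
  }
  g <- apply(f, 2L, dt1d_sq)
  d <- t(apply(g, 1L, dt1d_sq))
  d <- sqrt(d)
  if (border_background) {
    nr <- nrow(mask); nc <- ncol(mask)
    bd <- outer(pmin(seq_len(nr) - 0L, nr + 1L - seq_len(nr)),
                pmin(seq_len(nc) - 0L, nc + 1L - seq_len(nc)), pmin)
    d <- pmin(d, bd)
  }
  d * mask
}

# Local thickness: for each foreground pixel, the diameter of the largest
# inscribed disk containing it.  Dilation-based algorithm over descending
# distance-map ridges.  Distances are between pixel centres, so a disk of
# centre-distance radius r spans 2r - 1 pixels: a slab of w pixels reads w
# (odd w) or w - 1 (even w), i.e. nominal thickness within one pixel.
local_thickness2d <- function(mask, border_background = FALSE) {
  dt <- edt2d(mask, border_background = border_background)
  lt <- matrix(0, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lt)
  ord <- idx[order(dt[idx], decreasing = TRUE)]
  nr <- nrow(mask)
  ys <- (ord - 1L) %% nr + 1L
  xs <- (ord - 1L) %/% nr + 1L
  for (i in seq_along(ord)) {
    r <- dt[ord[i]]
    if (r <= 0) next
    ri <- ceiling(r - 1e-9)
    y0 <- max(1L, ys[i] - ri); y1 <- min(nr, ys[i] + ri)
    x0 <- max(1L, xs[i] - ri); x1 <- min(ncol(mask), xs[i] + ri)
    suby <- y0:y1; subx <- x0:x1
    val <- 2 * r - 1
    dd <- outer((suby - ys[i])^2, (subx - xs[i])^2, "+")
    sel <- dd < r^2
    blk <- lt[suby, subx, drop = FALSE]
    blk[sel & blk < val] <- val
    lt[suby, subx] <- blk
  }
  lt * mask
}

# ---- connected components ---------------------------------------------------

neighbor_offsets <- function(ndim, connectivity) {
  grid <- as.matrix(expand.grid(rep(list(-1:1), ndim)))
  grid <- grid[rowSums(abs(grid)) > 0L, , drop = FALSE]
  if (ndim == 2L) {
    if (connectivity == 4L) grid <- grid[rowSums(abs(grid)) == 1L, , drop = FALSE]
  } else if (ndim == 3L) {
    if (connectivity == 6L) grid <- grid[rowSums(abs(grid)) == 1L, , drop = FALSE]
    else if (connectivity == 18L) grid <- grid[rowSums(abs(grid)) <= 2L, , drop = FALSE]
  }
  grid
}

# Label connected components of a logical array (2-D or 3-D). Returns an
# integer array of the same shape; 0 = background.
label_components <- function(mask, connectivity = NULL) {
  dm <- dim(mask)
  ndim <- length(dm)
  assert_that(ndim %in% c(2L, 3L), "shape_error", "mask must be 2-D or 3-D")
  if (is.null(connectivity)) connectivity <- if (ndim == 2L) 8L else 26L
  off <- neighbor_offsets(ndim, as.integer(connectivity))
  lab <- array(0L, dm)
  idx_true <- which(mask)
  if (!length(idx_true)) return(lab)
  # linear-index offsets with coordinate guards
  mult <- cumprod(c(1L, dm[-ndim]))
  lin_off <- as.integer(off %*% mult)
  coords <- arrayInd(idx_true, dm)
  in_mask <- array(FALSE, dm)
  in_mask[idx_true] <- TRUE
  visited <- array(FALSE, dm)
  current <- 0L
  for (seed in idx_true) {
    if (visited[seed]) next
    current <- current + 1L
    frontier <- seed
    visited[seed] <- TRUE
    lab[seed] <- current
    while (length(frontier)) {
      fc <- arrayInd(frontier, dm)
      cand_idx <- rep(frontier, each = nrow(off)) + rep(lin_off, times = length(frontier))
      # coordinate-wise bounds check to prevent wrap-around
      ok <- rep(TRUE, length(cand_idx))
      for (d in seq_len(ndim)) {
        cd <- rep(fc[, d], each = nrow(off)) + rep(off[, d], times = length(frontier))
        ok <- ok & cd >= 1L & cd <= dm[d]
      }
      cand_idx <- unique(cand_idx[ok])
      cand_idx <- cand_idx[in_mask[cand_idx] & !visited[cand_idx]]
      visited[cand_idx] <- TRUE
      lab[cand_idx] <- current
      frontier <- cand_idx
    }
  }
  lab
}

# ---- peak detection ---------------------------------------------------------

max_filter <- function(m, radius) {
  off <- disk_offsets(radius)
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (k in seq_len(nrow(off))) {
    out <- pmax(out, shift_mat(m, off[k, 1L], off[k, 2L], -Inf))
  }
  out
}

otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L])
  br <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1L] + br[-length(br)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b)]
}
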