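# Independent oracles and small fixture builders shared across test files.

wrap_axial <- septaquant:::wrap_axial

# Naive O(N^2) two-sample Watson U2 from the step-function definition:
# at each pooled point, d = F_A - F_B; U2 = nm/N^2 (sum d^2 - (sum d)^2 / N).
naive_watson_u2 <- function(a, b) {
  n <- length(a); m <- length(b); N <- n + m
  pooled <- sort(c(a, b))
  d <- vapply(pooled, function(v) sum(a <= v) / n - sum(b <= v) / m, 0)
  (n * m / N^2) * (sum(d^2) - sum(d)^2 / N)
}

# Exhaustive label-assignment p-value for the two-sample Watson U2.
enumerate_watson_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(a)
  obs <- naive_watson_u2(a, b)
  combs <- utils::combn(length(pool), n)
  stats <- apply(combs, 2L, function(ix) naive_watson_u2(pool[ix], pool[-ix]))
  mean(stats >= obs - 1e-12)
}

# Minimal hand-built label stack: a vertical septum between two lumens.
# Geometry in pixels; optional aperture (gap rows, per slice list).
tiny_septum_stack <- function(n_slices = 3L, ny = 40L, nx = 30L,
                              sep_cols = 13:18, gap_rows = NULL,
                              pixel_size_um = 2, slice_thickness_um = 5,
                              avco_rows = NULL) {
  cls <- SECTION_CLASSES
  labels <- array(cls[["background"]], c(n_slices, ny, nx))
  labels[, , seq_len(min(sep_cols) - 1L)] <- cls[["RV_lumen"]]
  labels[, , (max(sep_cols) + 1L):nx] <- cls[["LV_lumen"]]
  labels[, , sep_cols] <- cls[["IVS"]]
  if (!is.null(avco_rows)) labels[, avco_rows, sep_cols] <- cls[["AVco"]]
  if (!is.null(gap_rows)) {
    for (k in seq_along(gap_rows)) {
      rows <- gap_rows[[k]]
      if (is.null(rows)) next
      mid <- sep_cols[seq_len(ceiling(length(sep_cols) / 2))]
      labels[k, rows, mid] <- cls[["RV_lumen"]]
      labels[k, rows, setdiff(sep_cols, mid)] <- cls[["LV_lumen"]]
    }
  }
  section_label_stack(labels, pixel_size_um, slice_thickness_um)
}

# Build a profile_ensemble directly from an intensity matrix (rows =
# profiles) on a given grid, bypassing resampling.
ensemble_from_matrix <- function(mat, grid) {
  structure(list(positions_um = grid, matrix = mat,
                 mean = colMeans(mat),
                 sem = apply(mat, 2L, stats::sd) / sqrt(nrow(mat)),
                 n = rep(nrow(mat), ncol(mat))),
            class = "profile_ensemble")
}
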