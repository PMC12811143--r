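# Synthetic cardiac phantom generators.  Every downstream analysis stage can
# be exercised against these ground-truthed inputs: two-lineage reporter
# volumes with a parameterized right-left boundary, oriented 2-D textures,
# serial heart-like label stacks with optional septal holes, elliptical cell
# masks, and binomial incidence tables drawn from an allele-dose log-odds
# model.  All generators are pure functions of (spec, seed).

# ---- boundary reporter volumes ----------------------------------------------

#' Specification of a two-lineage boundary phantom
#'
#' Describes a dual-reporter volume in which one channel (`lineage`) fills the
#' territory left of a compartment boundary as a logistic step along the
#' right-left axis, and a second channel (`boundary`) marks the boundary zone
#' itself as a Gaussian band.  Cells are rendered as Gaussian blobs retained
#' per-channel with the stated labeling efficiency (recombination in dual
#' reporter crosses is mosaic, so efficiency < 1 thins and dims the signal).
#'
#' @param shape_px integer `(z, y, x)` voxel counts.
#' @param voxel_size_um numeric `(z, y, x)` voxel sizes, micrometres.
#' @param boundary_center_um boundary position on the right-left axis
#'   (0 = volume midline; positive = anatomical left).
#' @param boundary_width_um logistic length scale of the transition (> 0).
#' @param labeling_efficiency per-channel retention probability in `[0, 1]`,
#'   length 2 `(lineage, boundary)`.
#' @param background_level additive background intensity.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param cells render discrete cell blobs (`TRUE`) or the smooth expectation
#'   field only (`FALSE`); the smooth field is the noiseless analytic phantom.
#' @param cell_sigma_um Gaussian blob sigma (default 4 um).
#' @param cell_spacing_um mean spacing of candidate cell centres.
#' @param plateau peak intensity of the lineage plateau.
#' @param seed integer RNG seed.
#' @return an object of class `boundary_phantom_spec`.
#' @export
boundary_phantom_spec <- function(shape_px = c(z = 12L, y = 48L, x = 200L),
                                  voxel_size_um = c(5, 4, 4),
                                  boundary_center_um = 0,
                                  boundary_width_um = 20,
                                  labeling_efficiency = c(lineage = 0.8, boundary = 0.8),
                                  background_level = 0.05,
                                  noise_sd = 0.05,
                                  cells = TRUE,
                                  cell_sigma_um = 4,
                                  cell_spacing_um = 12,
                                  plateau = 1,
                                  seed = 1L) {
  shape_px <- as.integer(shape_px)
  assert_that(length(shape_px) == 3L && all(shape_px > 0L),
              "invalid_spec", "shape_px must be 3 positive integers (z, y, x)")
  assert_that(is_scalar_num(boundary_width_um) && boundary_width_um > 0,
              "invalid_spec", "boundary_width_um must be > 0")
  labeling_efficiency <- rep_len(as.numeric(labeling_efficiency), 2L)
  assert_that(all(labeling_efficiency >= 0 & labeling_efficiency <= 1),
              "invalid_spec", "labeling_efficiency must lie in [0, 1]")
  assert_that(all(as.numeric(voxel_size_um) > 0), "invalid_spec",
              "voxel sizes must be positive")
  structure(list(
    shape_px = stats::setNames(shape_px, c("z", "y", "x")),
    voxel_size_um = stats::setNames(as.numeric(voxel_size_um), c("z", "y", "x")),
    boundary_center_um = boundary_center_um,
    boundary_width_um = boundary_width_um,
    labeling_efficiency = stats::setNames(labeling_efficiency, c("lineage", "boundary")),
    background_level = background_level,
    noise_sd = noise_sd,
    cells = isTRUE(cells),
    cell_sigma_um = cell_sigma_um,
    cell_spacing_um = cell_spacing_um,
    plateau = plateau,
    seed = as.integer(seed)
  ), class = "boundary_phantom_spec")
}

# Render Gaussian blobs at the given (z, y, x) um centres into a volume grid.
render_blobs <- function(centers_um, shape_px, voxel_size_um, sigma_um) {
  vol <- array(0, shape_px)
  if (!nrow(centers_um)) return(vol)
  zc <- (seq_len(shape_px[1L]) - 0.5) * voxel_size_um[1L]
  yc <- (seq_len(shape_px[2L]) - 0.5) * voxel_size_um[2L]
  xc <- (seq_len(shape_px[3L]) - 0.5) * voxel_size_um[3L]
  half <- 2.5 * sigma_um
  for (i in seq_len(nrow(centers_um))) {
    c3 <- centers_um[i, ]
    zi <- which(abs(zc - c3[1L]) <= half)
    yi <- which(abs(yc - c3[2L]) <= half)
    xi <- which(abs(xc - c3[3L]) <= half)
    if (!length(zi) || !length(yi) || !length(xi)) next
    gz <- exp(-(zc[zi] - c3[1L])^2 / (2 * sigma_um^2))
    gy <- exp(-(yc[yi] - c3[2L])^2 / (2 * sigma_um^2))
    gx <- exp(-(xc[xi] - c3[3L])^2 / (2 * sigma_um^2))
    vol[zi, yi, xi] <- vol[zi, yi, xi] + outer(gz, outer(gy, gx))
  }
  vol
}

#' Generate a two-lineage boundary reporter volume
#'
#' @param spec a [boundary_phantom_spec()].
#' @return a list with elements `volume` ([mc_volume()] with channels
#'   `lineage` and `boundary`) and `truth` (a `ground_truth` record carrying
#'   the generating spec plus the analytic boundary centre and width).
#' @export
make_boundary_volume <- function(spec) {
  assert_that(inherits(spec, "boundary_phantom_spec"), "invalid_spec",
              "spec must be a boundary_phantom_spec")
  sp <- spec$shape_px
  vs <- spec$voxel_size_um
  x_um <- (seq_len(sp[["x"]]) - (sp[["x"]] + 1) / 2) * vs[["x"]]
  s_lineage <- stats::plogis((x_um - spec$boundary_center_um) / spec$boundary_width_um)
  s_boundary <- exp(-(x_um - spec$boundary_center_um)^2 / (2 * spec$boundary_width_um^2))
  field <- function(sx) {
    a <- array(0, sp)
    for (k in seq_len(sp[["x"]])) a[, , k] <- sx[k]
    a
  }
  run_seeded(spec$seed, {
    chans <- list()
    profiles <- list(lineage = s_lineage, boundary = s_boundary)
    for (ci in 1:2) {
      nm <- names(profiles)[ci]
      smooth <- spec$plateau * field(profiles[[nm]])
      if (spec$cells) {
        ext_um <- sp * vs
        lambda <- prod(ext_um) / spec$cell_spacing_um^3
        n_cells <- stats::rpois(1L, lambda)
        centers <- cbind(stats::runif(n_cells, 0, ext_um[1L]),
                         stats::runif(n_cells, 0, ext_um[2L]),
                         stats::runif(n_cells, 0, ext_um[3L]))
        keep <- stats::runif(n_cells) < spec$labeling_efficiency[[ci]]
        tex <- render_blobs(centers[keep, , drop = FALSE], sp, vs, spec$cell_sigma_um)
        # normalize so a fully labeled dense texture has unit mean
        full_mean <- lambda * (2 * pi * spec$cell_sigma_um^2)^1.5 / prod(ext_um)
        img <- smooth * (tex / full_mean)
      } else {
        img <- smooth
      }
      img <- img + spec$background_level
      if (spec$noise_sd > 0) {
        img <- img + array(stats::rnorm(prod(sp), 0, spec$noise_sd), sp)
      }
      chans[[nm]] <- img
    }
    vol <- mc_volume(chans, vs)
    truth <- ground_truth(spec = unclass(spec),
                          true_center_um = spec$boundary_center_um,
                          true_width_um = spec$boundary_width_um)
    list(volume = vol, truth = truth)
  })
}

# ---- oriented textures ------------------------------------------------------

#' Generate a 2-D texture with a known dominant orientation and coherency
#'
#' Sinusoidal stripes whose iso-intensity lines run along `angle_deg`
#' (0 degrees = image x-axis, counter-clockwise positive, axial period 180)
#' are mixed with smoothed isotropic noise; measured coherency increases
#' monotonically with `coherency_level`.
#'
#' @param angle_deg stripe (structure) direction; values outside `(-90, 90]`
#'   are wrapped with a warning.
#' @param coherency_level mixing weight in `[0, 1]` (1 = pure stripes).
#' @param shape_px `(rows, cols)` image size.
#' @param wavelength_px stripe wavelength in pixels.
#' @param seed RNG seed.
#' @return numeric matrix `[row = y (down), col = x]`.
#' @export
make_oriented_texture <- function(angle_deg, coherency_level,
                                  shape_px = c(256L, 256L),
                                  wavelength_px = 8, seed = 1L) {
  assert_that(is_scalar_num(coherency_level) && coherency_level >= 0 &&
                coherency_level <= 1, "invalid_spec",
              "coherency_level must lie in [0, 1]")
  if (angle_deg <= -90 || angle_deg > 90) {
    angle_deg <- wrap_axial(angle_deg)
    sq_warn("angle outside (-90, 90]; wrapped to %.1f degrees", angle_deg)
  }
  nr <- as.integer(shape_px[1L]); nc <- as.integer(shape_px[2L])
  th <- angle_deg * pi / 180
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(-(seq_len(nr)), times = nc), nr, nc)  # y-up convention
  phase <- (-xs * sin(th) + ys * cos(th)) * 2 * pi / wavelength_px
  stripe <- sin(phase)
  run_seeded(seed, {
    # white (unsmoothed) noise: isotropic at every scale
    noise <- matrix(stats::rnorm(nr * nc), nr, nc)
    noise <- noise / stats::sd(noise) / sqrt(2)  # match stripe RMS
    coherency_level * stripe + (1 - coherency_level) * noise
  })
}

# ---- serial-section heart phantoms ------------------------------------------

#' Class legend used by all serial-section label stacks
#' @export
SECTION_CLASSES <- c(background = 0L, compact_myocardium = 1L, trabeculae = 2L,
                     IVS = 3L, AVco = 4L, atria = 5L, LV_lumen = 6L,
                     RV_lumen = 7L, other_tissue = 8L)

#' Specification of a serial-section heart phantom
#'
#' A simplified four-chamber geometry: an outer compact-myocardium shell, a
#' vertical interventricular septum separating LV and RV lumens, an
#' atrioventricular complex block at the basal end of the septum, an atrial
#' band at the base, and optional trabecular ridges attached to (or detached
#' from) the walls.  Optional cylindrical holes of known radius perforate the
#' septum, joining the two lumens; their analytic in-plane area is pi r^2.
#'
#' @param pixel_size_um in-plane pixel size (default 2).
#' @param slice_thickness_um section thickness (default 5, the standard
#'   histological slide thickness).
#' @param n_slices number of serial sections.
#' @param lumen_width_um,septum_thickness_um,compact_thickness_um,
#'   ventricle_height_um,atria_height_um,avco_height_um geometry, micrometres.
#' @param hole_specs list of holes, each `list(y_um =, z_um =, radius_um =)`
#'   with `y_um` measured from the basal edge of the septal wall and `z_um`
#'   along the stack; holes must lie within the septal wall.
#' @param trabecula_specs list of ridges, each
#'   `list(side = "LV"|"RV", y_um =, size_um =, attached = TRUE|FALSE)`.
#' @return an object of class `heart_phantom_spec`.
#' @export
heart_phantom_spec <- function(pixel_size_um = 2,
                               slice_thickness_um = 5,
                               n_slices = 24L,
                               lumen_width_um = 300,
                               septum_thickness_um = 100,
                               compact_thickness_um = 80,
                               ventricle_height_um = 500,
                               atria_height_um = 100,
                               avco_height_um = 80,
                               hole_specs = list(),
                               trabecula_specs = list()) {
  assert_that(is_scalar_num(slice_thickness_um) && slice_thickness_um > 0,
              "invalid_spec", "slice_thickness_um must be > 0")
  assert_that(is_scalar_num(pixel_size_um) && pixel_size_um > 0,
              "invalid_spec", "pixel_size_um must be > 0")
  n_slices <- as.integer(n_slices)
  assert_that(n_slices > 0L, "invalid_spec", "n_slices must be positive")
  wall_y0 <- avco_height_um
  wall_y1 <- ventricle_height_um - compact_thickness_um
  z_extent <- n_slices * slice_thickness_um
  for (h in hole_specs) {
    assert_that(all(c("y_um", "z_um", "radius_um") %in% names(h)),
                "invalid_spec", "each hole needs y_um, z_um, radius_um")
    inside <- h$y_um - h$radius_um >= wall_y0 &&
      h$y_um + h$radius_um <= wall_y1 &&
      h$z_um - h$radius_um >= 0 && h$z_um + h$radius_um <= z_extent
    assert_that(inside, "invalid_spec",
                "hole at y=%g, z=%g (r=%g) lies outside the septal wall",
                h$y_um, h$z_um, h$radius_um)
  }
  structure(list(
    pixel_size_um = pixel_size_um, slice_thickness_um = slice_thickness_um,
    n_slices = n_slices, lumen_width_um = lumen_width_um,
    septum_thickness_um = septum_thickness_um,
    compact_thickness_um = compact_thickness_um,
    ventricle_height_um = ventricle_height_um,
    atria_height_um = atria_height_um, avco_height_um = avco_height_um,
    hole_specs = hole_specs, trabecula_specs = trabecula_specs
  ), class = "heart_phantom_spec")
}

#' Serial-section label stack container
#'
#' @param labels integer 3-D array `[slice, y, x]` of class codes.
#' @param pixel_size_um in-plane pixel size.
#' @param slice_thickness_um section thickness.
#' @param legend named integer vector mapping class names to codes.
#' @param side_map optional integer array like `labels` (1 = right/RV side,
#'   2 = left/LV side) used for per-side thickness measurements.
#' @export
section_label_stack <- function(labels, pixel_size_um, slice_thickness_um,
                                legend = SECTION_CLASSES, side_map = NULL) {
  assert_that(length(dim(labels)) == 3L, "shape_error",
              "labels must be [slice, y, x]")
  assert_that(slice_thickness_um > 0 && pixel_size_um > 0, "invalid_spec",
              "pixel size and slice thickness must be positive")
  used <- sort(unique(as.vector(labels)))
  assert_that(all(used %in% legend), "format_error",
              "labels contain codes missing from the legend: %s",
              paste(setdiff(used, legend), collapse = ", "))
  structure(list(labels = labels, pixel_size_um = pixel_size_um,
                 slice_thickness_um = slice_thickness_um,
                 legend = legend, side_map = side_map,
                 base_apex_axis = "y"),
            class = "section_label_stack")
}

#' @export
print.section_label_stack <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<section_label_stack> %d slices of %d x %d px, %g um/px, %g um slices\n",
              d[1L], d[2L], d[3L], x$pixel_size_um, x$slice_thickness_um))
  invisible(x)
}

#' Generate a serial-section heart label stack
#'
#' @param spec a [heart_phantom_spec()].
#' @return list with `stack` (a [section_label_stack()]) and `truth`
#'   (a `ground_truth` carrying each hole's analytic in-plane area
#'   `pi * r^2` and slice index range).
#' @export
make_section_stack <- function(spec) {
  assert_that(inherits(spec, "heart_phantom_spec"), "invalid_spec",
              "spec must be a heart_phantom_spec")
  px <- spec$pixel_size_um
  t_um <- spec$slice_thickness_um
  cls <- SECTION_CLASSES
  width_um <- 2 * spec$compact_thickness_um + 2 * spec$lumen_width_um +
    spec$septum_thickness_um
  height_um <- spec$atria_height_um + spec$ventricle_height_um
  nx <- ceiling(width_um / px)
  ny <- ceiling(height_um / px)
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px   # y = 0 at the base (top of the image)
  # x landmarks (right -> left): compact | RV lumen | IVS | LV lumen | compact
  x_rv0 <- spec$compact_thickness_um
  x_ivs0 <- x_rv0 + spec$lumen_width_um
  x_ivs1 <- x_ivs0 + spec$septum_thickness_um
  x_lv1 <- x_ivs1 + spec$lumen_width_um
  y_vent0 <- spec$atria_height_um
  y_apex_wall <- height_um - spec$compact_thickness_um
  septum_mid <- (x_ivs0 + x_ivs1) / 2
  base <- matrix(cls[["background"]], ny, nx)
  in_x <- function(a, b) xc > a & xc <= b
  in_y <- function(a, b) yc > a & yc <= b
  vent_rows <- in_y(y_vent0, height_um)
  base[vent_rows, ] <- cls[["compact_myocardium"]]
  lum_rows <- in_y(y_vent0, y_apex_wall)
  base[lum_rows, in_x(x_rv0, x_ivs0)] <- cls[["RV_lumen"]]
  base[lum_rows, in_x(x_ivs1, x_lv1)] <- cls[["LV_lumen"]]
  base[lum_rows, in_x(x_ivs0, x_ivs1)] <- cls[["IVS"]]
  # AV complex caps the basal end of the septum
  base[in_y(y_vent0, y_vent0 + spec$avco_height_um), in_x(x_ivs0, x_ivs1)] <-
    cls[["AVco"]]
  base[in_y(0, spec$atria_height_um), ] <- cls[["atria"]]
  # trabecular ridges
  for (tr in spec$trabecula_specs) {
    side <- match.arg(tr$side, c("LV", "RV"))
    sz <- tr$size_um
    rows <- in_y(y_vent0 + tr$y_um, y_vent0 + tr$y_um + sz)
    if (isTRUE(tr$attached)) {
      colsel <- if (side == "RV") in_x(x_ivs0 - sz, x_ivs0) else in_x(x_ivs1, x_ivs1 + sz)
    } else {
      mid_lum <- if (side == "RV") (x_rv0 + x_ivs0) / 2 else (x_ivs1 + x_lv1) / 2
      colsel <- in_x(mid_lum - sz / 2, mid_lum + sz / 2)
    }
    base[rows, colsel] <- cls[["trabeculae"]]
  }
  labels <- array(0L, c(spec$n_slices, ny, nx))
  z_centers <- (seq_len(spec$n_slices) - 0.5) * t_um
  ivs_cols <- which(in_x(x_ivs0, x_ivs1))
  left_cols <- ivs_cols[xc[ivs_cols] > septum_mid]
  right_cols <- setdiff(ivs_cols, left_cols)
  hole_truth <- list()
  for (k in seq_len(spec$n_slices)) {
    sl <- base
    for (hi in seq_along(spec$hole_specs)) {
      h <- spec$hole_specs[[hi]]
      dz <- z_centers[k] - h$z_um
      if (abs(dz) >= h$radius_um) next
      half_chord <- sqrt(h$radius_um^2 - dz^2)
      rows <- which(abs(yc - (y_vent0 + h$y_um)) <= half_chord)
      rows <- rows[sl[rows, ivs_cols[1L]] %in%
                     c(cls[["IVS"]], cls[["AVco"]])]
      if (!length(rows)) next
      sl[rows, right_cols] <- cls[["RV_lumen"]]
      sl[rows, left_cols] <- cls[["LV_lumen"]]
    }
    labels[k, , ] <- sl
  }
  for (hi in seq_along(spec$hole_specs)) {
    h <- spec$hole_specs[[hi]]
    covered <- which(abs(z_centers - h$z_um) < h$radius_um)
    # analytic closing-chord sum at this slice grid: the value the
    # fixed-slice-thickness chord estimator converges to as pixel size -> 0
    chords <- 2 * sqrt(h$radius_um^2 - (z_centers[covered] - h$z_um)^2)
    hole_truth[[hi]] <- list(y_um = h$y_um, z_um = h$z_um,
                             radius_um = h$radius_um,
                             area_um2 = pi * h$radius_um^2,
                             chord_area_um2 = sum(chords) * t_um,
                             slice_range = range(covered))
  }
  side_map <- array(1L, dim(labels))
  for (k in seq_len(spec$n_slices)) {
    side_map[k, , xc > septum_mid] <- 2L
  }
  stack <- section_label_stack(labels, px, t_um, side_map = side_map)
  truth <- ground_truth(spec = unclass(spec), holes = hole_truth)
  list(stack = stack, truth = truth)
}

# ---- elliptical cell masks --------------------------------------------------

#' Generate a mask of non-overlapping elliptical cells with ground truth
#'
#' @param n number of cells to place.
#' @param length_dist,width_dist sampling functions `f(n)` returning axis
#'   lengths in micrometres (major and minor; pairs with W > L are swapped).
#' @param seed RNG seed.
#' @param canvas_px `(rows, cols)` canvas size.
#' @param pixel_size_um pixel size.
#' @param max_tries placement attempts per cell before a placement error.
#' @return list with `mask` (logical matrix) and `truth` (data.frame with
#'   one row per cell: centre, axes, angle).
#' @export
make_cell_mask_set <- function(n,
                               length_dist = function(k) stats::runif(k, 14, 24),
                               width_dist = function(k) stats::runif(k, 7, 12),
                               seed = 1L,
                               canvas_px = c(256L, 256L),
                               pixel_size_um = 1,
                               max_tries = 200L) {
  nr <- canvas_px[1L]; nc <- canvas_px[2L]
  run_seeded(seed, {
    L <- length_dist(n); W <- width_dist(n)
    swap <- W > L
    tmp <- L[swap]; L[swap] <- W[swap]; W[swap] <- tmp
    assert_that(all(W > 0), "invalid_spec", "axis distributions must yield W > 0")
    ang <- stats::runif(n, -90, 90)
    placed <- matrix(NA_real_, n, 2L)  # centre (y_um, x_um)
    gap_um <- 2 * pixel_size_um
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cy <- stats::runif(1, L[i] / 2 + gap_um, nr * pixel_size_um - L[i] / 2 - gap_um)
        cx <- stats::runif(1, L[i] / 2 + gap_um, nc * pixel_size_um - L[i] / 2 - gap_um)
        if (i == 1L) { ok <- TRUE } else {
          prev <- seq_len(i - 1L)
          dist <- sqrt((placed[prev, 1L] - cy)^2 + (placed[prev, 2L] - cx)^2)
          ok <- all(dist > (L[prev] + L[i]) / 2 + gap_um)
        }
        if (ok) { placed[i, ] <- c(cy, cx); break }
      }
      assert_that(ok, "placement_error",
                  "could not place %d non-overlapping cells (failed at cell %d)", n, i)
    }
    mask <- matrix(FALSE, nr, nc)
    ycm <- (seq_len(nr) - 0.5) * pixel_size_um
    xcm <- (seq_len(nc) - 0.5) * pixel_size_um
    for (i in seq_len(n)) {
      a <- L[i] / 2; b <- W[i] / 2
      th <- ang[i] * pi / 180
      ri <- which(abs(ycm - placed[i, 1L]) <= a)
      ci <- which(abs(xcm - placed[i, 2L]) <= a)
      dy <- ycm[ri] - placed[i, 1L]
      dx <- xcm[ci] - placed[i, 2L]
      # y-up convention: flip row displacement sign
      u <- outer(-dy, dx, function(yy, xx) (xx * cos(th) + yy * sin(th)) / a)
      v <- outer(-dy, dx, function(yy, xx) (-xx * sin(th) + yy * cos(th)) / b)
      mask[ri, ci] <- mask[ri, ci] | (u^2 + v^2 <= 1)
    }
    truth <- data.frame(cell = seq_len(n),
                        y_um = placed[, 1L], x_um = placed[, 2L],
                        L_um = L, W_um = W, angle_deg = ang)
    list(mask = mask, truth = truth)
  })
}

# ---- allele-dose incidence tables -------------------------------------------

#' Allele-dose log-odds incidence model
#'
#' Defect probability per genotype group follows
#' `logit(p) = beta0 + beta_tbx5 * tbx5_dose + beta_gene * gene_dose +
#' beta_int * tbx5_dose * gene_dose`.
#'
#' @param beta0 baseline log-odds.
#' @param beta_tbx5 log-odds per Tbx5 mutant allele (dose 0/1).
#' @param beta_gene log-odds per second-gene mutant allele (dose 0/1/2).
#' @param beta_int interaction log-odds.
#' @export
allele_dose_model <- function(beta0, beta_tbx5, beta_gene, beta_int) {
  b <- c(beta0 = beta0, beta_tbx5 = beta_tbx5,
         beta_gene = beta_gene, beta_int = beta_int)
  assert_that(all(is.finite(b)), "invalid_spec", "all coefficients must be finite")
  structure(as.list(b), class = "allele_dose_model")
}

#' Draw a binomial incidence table from an allele-dose model
#'
#' @param model an [allele_dose_model()].
#' @param group_sizes data.frame with columns `tbx5_dose`, `gene_dose`,
#'   `total` (litter sizes per genotype group) and optionally
#'   `genotype_label`.
#' @param seed RNG seed.
#' @return a [genotype_counts()] table with drawn `affected` counts.
#' @export
sample_incidence <- function(model, group_sizes, seed = 1L) {
  assert_that(inherits(model, "allele_dose_model"), "invalid_spec",
              "model must be an allele_dose_model")
  assert_that(all(c("tbx5_dose", "gene_dose", "total") %in% names(group_sizes)),
              "invalid_spec", "group_sizes needs tbx5_dose, gene_dose, total")
  assert_that(all(group_sizes$total >= 0), "invalid_input",
              "group sizes must be >= 0")
  eta <- model$beta0 + model$beta_tbx5 * group_sizes$tbx5_dose +
    model$beta_gene * group_sizes$gene_dose +
    model$beta_int * group_sizes$tbx5_dose * group_sizes$gene_dose
  p <- stats::plogis(eta)
  aff <- run_seeded(seed, stats::rbinom(nrow(group_sizes), group_sizes$total, p))
  lab <- if ("genotype_label" %in% names(group_sizes)) group_sizes$genotype_label
         else sprintf("t%d_g%d", group_sizes$tbx5_dose, group_sizes$gene_dose)
  genotype_counts(data.frame(genotype_label = lab,
                             tbx5_dose = group_sizes$tbx5_dose,
                             gene_dose = group_sizes$gene_dose,
                             affected = aff,
                             total = group_sizes$total))
}

# ---- profile-level generator (fast fixtures for power experiments) ----------

#' Generate a set of boundary-band linear profiles
#'
#' Draws `n` profiles of a Gaussian boundary band on a common grid, with
#' per-profile centre jitter (lineage mixing broadens the across-profile
#' spread of centres) and additive intensity noise.  This is the
#' profile-level counterpart of [make_boundary_volume()], used where whole
#' volumes would be wasteful (e.g. repeated power simulations).
#'
#' @param n number of profiles.
#' @param center_um mean boundary centre.
#' @param center_sd_um across-profile standard deviation of centres.
#' @param width_um Gaussian band width.
#' @param noise_sd additive intensity noise (on the unit-peak scale).
#' @param grid_um position grid (micrometres).
#' @param seed RNG seed.
#' @return list of [linear_profile()] objects.
#' @export
make_profile_set <- function(n, center_um = 0, center_sd_um = 10,
                             width_um = 20, noise_sd = 0.05,
                             grid_um = seq(-200, 200, by = 2), seed = 1L) {
  run_seeded(seed, {
    centers <- stats::rnorm(n, center_um, center_sd_um)
    lapply(seq_len(n), function(i) {
      y <- exp(-(grid_um - centers[i])^2 / (2 * width_um^2))
      if (noise_sd > 0) y <- y + stats::rnorm(length(grid_um), 0, noise_sd)
      linear_profile(grid_um, pmax(y, 0))
    })
  })
}

# ---- ground truth records ---------------------------------------------------

#' Ground-truth record attached to every generated object
#'
#' A named list (generating spec plus derived analytic values) that
#' round-trips losslessly through JSON via [write_ground_truth()] /
#' [read_ground_truth()].
#'
#' @param ... named fields.
#' @export
ground_truth <- function(...) {
  structure(list(...), class = "ground_truth")
}

#' @rdname ground_truth
#' @param truth a `ground_truth`.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname ground_truth
#' @export
read_ground_truth <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE),
            class = "ground_truth")
}
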