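# Serial-section morphometry: fill, trabeculation, thickness, VSD
# detection/area/subtype, and cell morphometry.

test_that("ivs_fill counts tissue over the full region including pores", {
  stack <- tiny_septum_stack()
  ivs_mask <- array(stack$labels == SECTION_CLASSES[["IVS"]], dim(stack$labels))
  expect_equal(ivs_fill(stack, ivs_region = ivs_mask), 1)
  # exact checkerboard of tissue/empty inside the region
  chk <- stack
  sel <- which(ivs_mask, arr.ind = TRUE)
  odd <- (sel[, 2L] + sel[, 3L]) %% 2L == 1L
  chk$labels[sel[odd, , drop = FALSE]] <- SECTION_CLASSES[["background"]]
  expect_equal(ivs_fill(chk, ivs_region = ivs_mask), 0.5)
  # 25% drilled porosity recovered within 2%
  set.seed(12)
  por <- stack
  drill <- sel[sample(nrow(sel), round(nrow(sel) * 0.25)), , drop = FALSE]
  por$labels[drill] <- SECTION_CLASSES[["background"]]
  expect_equal(ivs_fill(por, ivs_region = ivs_mask), 0.75, tolerance = 0.02)
  # the default closed region also sees the pores
  expect_lt(ivs_fill(por), 1)
  # RGB dark-pixel rule
  rgb <- array(255, c(20, 20, 3))
  rgb[6:15, 6:15, ] <- 40
  roi <- matrix(FALSE, 20, 20); roi[6:15, 1:20] <- TRUE
  expect_equal(ivs_fill(rgb, ivs_region = roi), 0.5)
  expect_error(ivs_fill(rgb), class = "undefined_region")
})

test_that("trabeculation fraction counts only attached components", {
  stack <- tiny_septum_stack(ny = 40, nx = 40, sep_cols = 18:23)
  expect_equal(trabeculation_fraction(stack), 0)
  # one attached ridge (touching IVS) and one detached blob
  tr <- stack
  tr$labels[, 10:14, 15:17] <- SECTION_CLASSES[["trabeculae"]]   # attached
  tr$labels[, 30:33, 5:7] <- SECTION_CLASSES[["trabeculae"]]     # detached
  v_att <- sum(tr$labels[, 10:14, 15:17] == SECTION_CLASSES[["trabeculae"]])
  v_ivs <- sum(tr$labels == SECTION_CLASSES[["IVS"]])
  expect_equal(trabeculation_fraction(tr), v_att / (v_att + v_ivs))
  # arithmetic contract: 100 attached vs 900 septal voxels -> 0.1
  lab <- array(SECTION_CLASSES[["background"]], c(1L, 40L, 60L))
  lab[1, 1:30, 11:40] <- SECTION_CLASSES[["IVS"]]          # 900 voxels
  lab[1, 1:10, 41:50] <- SECTION_CLASSES[["trabeculae"]]   # 100, attached
  small <- section_label_stack(lab, 2, 5)
  expect_equal(sum(small$labels == SECTION_CLASSES[["IVS"]]), 900)
  expect_equal(sum(small$labels == SECTION_CLASSES[["trabeculae"]]), 100)
  expect_equal(trabeculation_fraction(small), 0.1)
  # in-plane 90-degree rotation invariance
  rot <- tr
  rot$labels <- aperm(tr$labels[, rev(seq_len(dim(tr$labels)[2L])), ,
                                drop = FALSE], c(1L, 3L, 2L))
  expect_equal(trabeculation_fraction(rot), trabeculation_fraction(tr))
  f <- trabeculation_fraction(tr)
  expect_true(f >= 0 && f <= 1)
})

test_that("compact thickness equals nominal slab thickness", {
  cls <- SECTION_CLASSES
  # slab walls surrounded by background margins (borders are continuation)
  mk_slab <- function(px, wall_px) {
    ny <- wall_px + 30L
    labels <- array(cls[["background"]], c(2L, ny, 60L))
    labels[, 16L:(15L + wall_px), ] <- cls[["compact_myocardium"]]
    section_label_stack(labels, px, 5)
  }
  # 50 um wall at 2 um pixels
  st <- mk_slab(2, 25L)
  expect_equal(compact_thickness(st), 50, tolerance = 2 / 50)
  # doubling the wall doubles the result
  st2 <- mk_slab(2, 50L)
  expect_equal(compact_thickness(st2) / compact_thickness(st), 2,
               tolerance = 0.05)
  # left/right symmetry of a symmetric phantom
  labels <- array(cls[["background"]], c(2L, 60L, 60L))
  labels[, 36:55, ] <- cls[["compact_myocardium"]]
  side <- array(1L, dim(labels)); side[, , 31:60] <- 2L
  sym <- section_label_stack(labels, 2, 5, side_map = side)
  expect_equal(compact_thickness(sym, "LV"), compact_thickness(sym, "RV"),
               tolerance = 0.02)
  expect_error(compact_thickness(tiny_septum_stack()),
               class = "undefined_region")
})

test_that("VSD detection matches the generated holes", {
  # intact septum
  intact <- make_section_stack(heart_phantom_spec(pixel_size_um = 4,
                                                  n_slices = 16))
  expect_length(detect_vsds(intact$stack), 0L)
  # one cylindrical hole: one record over the hole's slice range
  one <- make_section_stack(heart_phantom_spec(
    pixel_size_um = 4, n_slices = 24,
    hole_specs = list(list(y_um = 200, z_um = 60, radius_um = 40))))
  recs <- detect_vsds(one$stack)
  expect_length(recs, 1L)
  expect_equal(recs[[1L]]$slice_range, one$truth$holes[[1L]]$slice_range)
  # two holes separated along z: two records
  two <- make_section_stack(heart_phantom_spec(
    pixel_size_um = 4, n_slices = 40,
    hole_specs = list(list(y_um = 180, z_um = 50, radius_um = 30),
                      list(y_um = 250, z_um = 150, radius_um = 30))))
  expect_length(detect_vsds(two$stack), 2L)
  # missing lumen class
  bad <- tiny_septum_stack()
  bad$labels[bad$labels == SECTION_CLASSES[["LV_lumen"]]] <-
    SECTION_CLASSES[["background"]]
  expect_error(detect_vsds(bad), class = "labeling_error")
})

test_that("closing-path area: single-slice slit gives chord x thickness", {
  # one slice, 30 um aperture (15 rows at 2 um), t = 5 -> A = 150 um^2
  st <- tiny_septum_stack(n_slices = 1L, ny = 60, nx = 30,
                          gap_rows = list(21:35))
  recs <- detect_vsds(st)
  expect_length(recs, 1L)
  r <- vsd_area(st, recs[[1L]])
  expect_equal(r$chords_um, 30)
  expect_equal(r$area_um2, 150)
  # straight chord agrees on a convex aperture
  r2 <- vsd_area(st, recs[[1L]], path = "chord")
  expect_equal(r2$area_um2, 150)
})

test_that("cylindrical hole area is within 5% of pi r^2", {
  res <- make_section_stack(heart_phantom_spec(
    pixel_size_um = 2, n_slices = 24,
    hole_specs = list(list(y_um = 200, z_um = 60, radius_um = 50))))
  recs <- detect_vsds(res$stack)
  r <- vsd_area(res$stack, recs[[1L]])
  expect_equal(r$area_um2, pi * 50^2, tolerance = 0.05)
})

test_that("VSD subtype follows AVco proximity with manual override", {
  near <- make_section_stack(heart_phantom_spec(
    pixel_size_um = 4, n_slices = 24,
    hole_specs = list(list(y_um = 120, z_um = 60, radius_um = 30))))
  rec <- detect_vsds(near$stack)[[1L]]
  cl <- classify_vsd(near$stack, rec)
  expect_equal(cl$subtype, "membranous")
  far <- make_section_stack(heart_phantom_spec(
    pixel_size_um = 4, n_slices = 24,
    hole_specs = list(list(y_um = 280, z_um = 60, radius_um = 30))))
  recf <- detect_vsds(far$stack)[[1L]]
  expect_equal(classify_vsd(far$stack, recf)$subtype, "muscular")
  # override recorded with provenance
  ov <- classify_vsd(far$stack, recf, override = "membranous")
  expect_equal(ov$subtype, "membranous")
  expect_equal(ov$subtype_provenance, "manual_override")
  # no AVco class -> unassigned
  st <- tiny_septum_stack(gap_rows = list(NULL, 15:20, NULL))
  recs <- detect_vsds(st)
  expect_equal(classify_vsd(st, recs[[1L]])$subtype, "unassigned")
})

test_that("cell shape descriptors match closed forms", {
  circ <- cell_shape_from_axes(10, 10)
  expect_equal(circ$eccentricity, 0)
  expect_equal(circ$area_um2, 78.540, tolerance = 1e-5)
  expect_equal(circ$diameter_um, 10)
  ell <- cell_shape_from_axes(20, 10)
  expect_equal(ell$area_um2, 157.080, tolerance = 1e-5)
  expect_equal(ell$eccentricity, 0.8660, tolerance = 1e-4)
  # eccentricity is scale invariant
  expect_equal(cell_shape_from_axes(40, 20)$eccentricity, ell$eccentricity)
  expect_warning(sw <- cell_shape_from_axes(10, 20), "swapped")
  expect_equal(sw$L_um, 20)
  expect_error(cell_shape_from_axes(-1, 1), class = "invalid_spec")
})

test_that("nucleus detection and density behave on constructed fields", {
  blob_at <- function(img, y, x, s = 3) {
    ys <- seq_len(nrow(img)); xs <- seq_len(ncol(img))
    img + exp(-outer((ys - y)^2, (xs - x)^2, "+") / (2 * s^2))
  }
  img <- matrix(0, 80, 80)
  img <- blob_at(img, 40, 40)
  det <- detect_nuclei(img, smoothing_sigma = 2, min_distance_um = 5)
  expect_equal(nrow(det), 1L)
  expect_lt(max(abs(c(det$y - 40, det$x - 40))), 2)
  # k well-separated blobs
  img2 <- matrix(0, 80, 80)
  pts <- cbind(c(15, 15, 60, 60), c(15, 60, 15, 60))
  for (i in 1:4) img2 <- blob_at(img2, pts[i, 1], pts[i, 2])
  expect_equal(nrow(detect_nuclei(img2, 2, 5)), 4L)
  # flat image: nothing
  expect_equal(nrow(detect_nuclei(matrix(1, 40, 40), 2, 5)), 0L)
  # density arithmetic: 10 points in 100 x 100 um
  roi <- matrix(TRUE, 100, 100)
  coords <- data.frame(y = seq(5, 95, by = 10), x = seq(5, 95, by = 10))
  expect_equal(nuclei_density(coords, roi, 1), 0.001)
  expect_equal(nuclei_density(coords[0, ], roi, 1), 0)
  expect_error(nuclei_density(coords, matrix(FALSE, 4, 4), 1),
               class = "undefined_region")
})
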