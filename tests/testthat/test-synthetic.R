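# Phantom generators: determinism, spec validation, analytic ground truth.

test_that("generators are pure functions of spec + seed", {
  spec <- boundary_phantom_spec(shape_px = c(4, 16, 40), noise_sd = 0.05,
                                seed = 7L)
  v1 <- make_boundary_volume(spec)
  v2 <- make_boundary_volume(spec)
  expect_identical(v1$volume$channels, v2$volume$channels)

  expect_identical(make_oriented_texture(30, 0.5, c(32, 32), seed = 3L),
                   make_oriented_texture(30, 0.5, c(32, 32), seed = 3L))

  m1 <- make_cell_mask_set(5, seed = 11L, canvas_px = c(96L, 96L))
  m2 <- make_cell_mask_set(5, seed = 11L, canvas_px = c(96L, 96L))
  expect_identical(m1$truth, m2$truth)
  expect_identical(m1$mask, m2$mask)

  model <- allele_dose_model(-1, 1, 0.5, -0.5)
  gs <- data.frame(tbx5_dose = c(0, 1), gene_dose = c(0, 1), total = c(20, 20))
  expect_identical(sample_incidence(model, gs, seed = 5L),
                   sample_incidence(model, gs, seed = 5L))
})

test_that("invalid phantom specifications are rejected", {
  expect_error(boundary_phantom_spec(boundary_width_um = 0), class = "invalid_spec")
  expect_error(boundary_phantom_spec(shape_px = c(0, 4, 4)), class = "invalid_spec")
  expect_error(boundary_phantom_spec(labeling_efficiency = c(1.2, 0.5)),
               class = "invalid_spec")
  # hole outside the septal wall
  expect_error(heart_phantom_spec(hole_specs = list(
    list(y_um = 10, z_um = 60, radius_um = 50))), class = "invalid_spec")
  expect_error(heart_phantom_spec(slice_thickness_um = 0), class = "invalid_spec")
  model <- allele_dose_model(0, 0, 0, 0)
  expect_error(sample_incidence(model, data.frame(
    tbx5_dose = 0, gene_dose = 0, total = -2)), class = "invalid_input")
  expect_error(allele_dose_model(Inf, 0, 0, 0), class = "invalid_spec")
})

test_that("boundary phantom follows its analytic intensity model", {
  # noiseless smooth field: logistic midpoint at the boundary centre
  spec <- boundary_phantom_spec(shape_px = c(4, 10, 201),
                                voxel_size_um = c(5, 4, 2),
                                boundary_center_um = 120,
                                boundary_width_um = 10,
                                noise_sd = 0, background_level = 0,
                                cells = FALSE)
  res <- make_boundary_volume(spec)
  nx <- 201
  xs <- (seq_len(nx) - (nx + 1) / 2) * 2   # even micrometre grid: 120 on-grid
  ic <- which(xs == 120)
  expect_equal(res$volume$channels$lineage[2, 5, ic], 0.5)
  # boundary channel peaks at the centre
  expect_equal(which.max(res$volume$channels$boundary[2, 5, ]), ic)
  # ground truth records the generating spec
  expect_equal(res$truth$true_center_um, 120)
  expect_equal(res$truth$spec$boundary_width_um, 10)
})

test_that("noisy boundary phantom round-trips through boundary_stats", {
  spec <- boundary_phantom_spec(shape_px = c(6, 24, 301),
                                voxel_size_um = c(5, 4, 2),
                                boundary_center_um = 120,
                                boundary_width_um = 10,
                                noise_sd = 0.05, background_level = 0,
                                cells = FALSE, seed = 2L)
  res <- make_boundary_volume(spec)
  proj <- slab_max_projection(res$volume, 15, "boundary")[[1L]]
  px <- res$volume$voxel_size_um[["x"]]
  ln <- profile_line(c(1, 12), c(301, 12), anchor_um = 300,
                     sampling_step_um = px)
  pr <- sample_profile(proj, ln, pixel_size_um = px)
  pr$intensities <- pmax(pr$intensities, 0)
  m <- boundary_stats(normalize_profile(pr))$m
  # noise spreads weight; recovery within one grid step of the truth is the
  # contract once the band is re-localized by restricting to the peak region
  peak <- which.max(pr$intensities)
  win <- max(1, peak - 30):min(length(pr$positions_um), peak + 30)
  pr2 <- linear_profile(pr$positions_um[win], pr$intensities[win])
  m2 <- boundary_stats(normalize_profile(pr2))$m
  expect_lt(abs(m2 - 120), 2 * px)
})

test_that("oriented texture wraps out-of-range angles with a warning", {
  expect_warning(img <- make_oriented_texture(120, 1, c(48, 48)),
                 "wrapped")
  ref <- make_oriented_texture(-60, 1, c(48, 48))
  expect_identical(img, ref)
})

test_that("section stack stores analytic hole truth and label legend", {
  spec <- heart_phantom_spec(pixel_size_um = 4, n_slices = 24,
                             hole_specs = list(
                               list(y_um = 200, z_um = 60, radius_um = 50)))
  res <- make_section_stack(spec)
  expect_s3_class(res$stack, "section_label_stack")
  expect_equal(res$truth$holes[[1]]$area_um2, pi * 50^2, tolerance = 1e-12)
  expect_equal(res$truth$holes[[1]]$area_um2, 7853.98, tolerance = 1e-5)
  used <- unique(as.vector(res$stack$labels))
  expect_true(all(used %in% SECTION_CLASSES))
  # hole truth agrees with brute-force voxel measurement (within
  # discretization error <= 5%): drilled voxels x pixel area, per septal
  # column, against the analytic chord-sum reference
  intact <- make_section_stack(heart_phantom_spec(pixel_size_um = 4,
                                                  n_slices = 24))
  removed <- sum(intact$stack$labels %in%
                   SECTION_CLASSES[c("IVS", "AVco")]) -
    sum(res$stack$labels %in% SECTION_CLASSES[c("IVS", "AVco")])
  n_sep_cols <- spec$septum_thickness_um / 4
  # drilled in-plane rows x pixel size x slice thickness = estimator of the
  # chord-sum area (z-discretized cylinder cross-section)
  est_area <- (removed / n_sep_cols) * 4 * 5
  expect_equal(est_area, res$truth$holes[[1]]$chord_area_um2,
               tolerance = 0.05)
})

test_that("cell mask set matches its truth table", {
  one <- make_cell_mask_set(1, length_dist = function(k) rep(10, k),
                            width_dist = function(k) rep(10, k),
                            canvas_px = c(48L, 48L), seed = 2L)
  expect_equal(one$truth$L_um, 10)
  expect_equal(one$truth$W_um, 10)
  shape <- cell_shape_from_axes(one$truth$L_um, one$truth$W_um)
  expect_equal(shape$eccentricity, 0)

  many <- make_cell_mask_set(50, canvas_px = c(400L, 400L), seed = 4L)
  lab <- septaquant:::label_components(many$mask, connectivity = 8L)
  expect_equal(max(lab), 50L)
  expect_equal(nrow(many$truth), 50L)

  expect_error(make_cell_mask_set(400, canvas_px = c(64L, 64L), seed = 1L),
               class = "placement_error")
})

test_that("incidence sampler follows the allele-dose model", {
  gs <- data.frame(tbx5_dose = c(0, 1, 0, 1), gene_dose = c(0, 0, 1, 1),
                   total = rep(4000L, 4))
  null_model <- allele_dose_model(0, 0, 0, 0)
  counts <- sample_incidence(null_model, gs, seed = 9L)
  expect_true(all(abs(counts$affected / counts$total - 0.5) < 0.03))
  floor_model <- allele_dose_model(-20, 0, 0, 0)
  expect_true(all(sample_incidence(floor_model, gs, seed = 9L)$affected == 0))
})

test_that("increasing boundary width increases recovered spread (noiseless)", {
  s_of_width <- function(w) {
    spec <- boundary_phantom_spec(shape_px = c(2, 6, 301),
                                  voxel_size_um = c(5, 4, 2),
                                  boundary_center_um = 0,
                                  boundary_width_um = w,
                                  noise_sd = 0, background_level = 0,
                                  cells = FALSE)
    res <- make_boundary_volume(spec)
    proj <- slab_max_projection(res$volume, 5, "boundary")[[1L]]
    ln <- profile_line(c(1, 3), c(301, 3), anchor_um = 300, sampling_step_um = 2)
    boundary_stats(normalize_profile(sample_profile(proj, ln, pixel_size_um = 2)))$s
  }
  spreads <- vapply(c(5, 10, 20, 40), s_of_width, 0)
  expect_true(all(diff(spreads) > 0))
})

test_that("ground truth round-trips losslessly through JSON", {
  spec <- heart_phantom_spec(pixel_size_um = 4, n_slices = 12,
                             hole_specs = list(
                               list(y_um = 150, z_um = 30, radius_um = 20)))
  truth <- make_section_stack(spec)$truth
  path <- tempfile(fileext = ".json")
  write_ground_truth(truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$holes[[1]]$area_um2, truth$holes[[1]]$area_um2)
  expect_equal(back$spec$septum_thickness_um, spec$septum_thickness_um)
})
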