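# Readers/writers for label stacks, run configuration, and the end-to-end
# pipeline.  Label stacks are stored as one 8-bit PNG per slice plus a
# legend JSON sidecar; configurations and provenance are JSON.

#' Write / read a serial-section label stack
#'
#' One grayscale 8-bit PNG per slice (`slice_0001.png`, ...) plus
#' `legend.json` recording the class legend, pixel size, slice thickness and
#' shape.  Reads validate shape consistency and reject class codes missing
#' from the legend.
#'
#' @param stack a [section_label_stack()].
#' @param dir directory.
#' @export
write_label_stack <- function(stack, dir) {
  assert_that(inherits(stack, "section_label_stack"), "invalid_spec",
              "stack must be a section_label_stack")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(stack$labels)
  files <- sprintf("slice_%04d.png", seq_len(d[1L]))
  for (k in seq_len(d[1L])) {
    m <- matrix(stack$labels[k, , ], d[2L], d[3L])
    png::writePNG(m / 255, file.path(dir, files[k]))
  }
  meta <- list(format = "septaquant-labels-v1",
               shape = as.integer(d),
               pixel_size_um = stack$pixel_size_um,
               slice_thickness_um = stack$slice_thickness_um,
               legend = as.list(stack$legend),
               files = files)
  jsonlite::write_json(meta, file.path(dir, "legend.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_label_stack
#' @export
read_label_stack <- function(dir) {
  sidecar <- file.path(dir, "legend.json")
  assert_that(file.exists(sidecar), "format_error",
              "missing legend.json in %s", dir)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  assert_that(identical(meta$format, "septaquant-labels-v1"),
              "format_error", "unrecognized label-stack format")
  d <- as.integer(meta$shape)
  labels <- array(0L, d)
  for (k in seq_len(d[1L])) {
    f <- file.path(dir, meta$files[k])
    assert_that(file.exists(f), "format_error", "missing slice file %s", f)
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    assert_that(nrow(m) == d[2L] && ncol(m) == d[3L], "format_error",
                "slice %d has shape %d x %d, expected %d x %d",
                k, nrow(m), ncol(m), d[2L], d[3L])
    labels[k, , ] <- as.integer(round(m * 255))
  }
  legend <- unlist(meta$legend)
  storage.mode(legend) <- "integer"
  section_label_stack(labels, meta$pixel_size_um, meta$slice_thickness_um,
                      legend = legend)
}

# ---- run configuration ------------------------------------------------------

CONFIG_KEYS <- c("seed", "out_dir", "log_level", "stages")
STAGE_NAMES <- c("simulate", "profiles", "orient", "morpho", "vsd", "glm")

#' Validate a pipeline run configuration
#'
#' @param config named list (typically from JSON) with keys `seed`,
#'   `out_dir`, optional `log_level`, and `stages`: a named list of stage
#'   parameter lists keyed by stage name
#'   (`simulate`, `profiles`, `orient`, `morpho`, `vsd`, `glm`).
#'   Unknown keys or stage names are rejected.
#' @return validated config of class `run_config`.
#' @export
run_config <- function(config) {
  assert_that(is.list(config), "config_error", "config must be a list")
  unknown <- setdiff(names(config), CONFIG_KEYS)
  assert_that(length(unknown) == 0L, "config_error",
              "unknown config keys: %s", paste(unknown, collapse = ", "))
  assert_that(!is.null(config$seed) && !is.null(config$out_dir),
              "config_error", "config requires seed and out_dir")
  assert_that(is.list(config$stages) && length(config$stages) >= 1L,
              "config_error", "config requires at least one stage")
  bad <- setdiff(names(config$stages), STAGE_NAMES)
  assert_that(length(bad) == 0L, "config_error",
              "unknown stage name(s): %s", paste(bad, collapse = ", "))
  if (is.null(config$log_level)) config$log_level <- "info"
  structure(config, class = "run_config")
}

#' @rdname run_config
#' @param path JSON config path.
#' @export
read_run_config <- function(path) {
  run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

log_msg <- function(level, config, msg, ...) {
  lv <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (lv[[level]] >= lv[[config$log_level %||% "info"]]) {
    message(sprintf("[%s] %s", level, sprintf(msg, ...)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- pipeline ---------------------------------------------------------------

#' Run the end-to-end analysis pipeline
#'
#' Executes the selected stages in canonical order
#' (simulate, profiles, orient, morpho, vsd, glm), writes CSV/JSON outputs
#' under `out_dir`, and records machine-readable provenance (config hash,
#' seed, package and R versions).  Deterministic given config + seed.
#'
#' @param config a [run_config()] (or plain list, validated on entry).
#' @return invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  results <- list()
  for (stage in intersect(STAGE_NAMES, names(config$stages))) {
    log_msg("info", config, "running stage %s", stage)
    params <- config$stages[[stage]]
    results[[stage]] <- tryCatch(
      switch(stage,
             simulate = stage_simulate(params, seed, out),
             profiles = stage_profiles(params, seed, out),
             orient = stage_orient(params, out),
             morpho = stage_morpho(params, out),
             vsd = stage_vsd(params, out),
             glm = stage_glm(params, out)),
      error = function(e) {
        sq_stop("stage_error", "stage '%s' failed: %s", stage, conditionMessage(e))
      })
  }
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json"); writeLines(cfg_json, tf)
  provenance <- list(package = "septaquant",
                     version = as.character(utils::packageVersion("septaquant")),
                     r_version = R.version.string,
                     seed = seed,
                     config_md5 = unname(tools::md5sum(tf)),
                     stages = names(results))
  unlink(tf)
  jsonlite::write_json(provenance, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

stage_simulate <- function(params, seed, out) {
  what <- params$what %||% "boundary"
  sub <- file.path(out, paste0("sim_", what))
  if (what == "boundary") {
    spec_args <- params[setdiff(names(params), "what")]
    spec_args$seed <- spec_args$seed %||% seed
    spec <- do.call(boundary_phantom_spec, spec_args)
    res <- make_boundary_volume(spec)
    write_volume(res$volume, sub)
    write_ground_truth(res$truth, file.path(sub, "truth.json"))
  } else if (what == "sections") {
    spec_args <- params[setdiff(names(params), "what")]
    spec <- do.call(heart_phantom_spec, spec_args)
    res <- make_section_stack(spec)
    write_label_stack(res$stack, sub)
    write_ground_truth(res$truth, file.path(sub, "truth.json"))
  } else if (what == "incidence") {
    model <- do.call(allele_dose_model, params$model)
    gs <- as.data.frame(params$group_sizes)
    counts <- sample_incidence(model, gs, seed = params$seed %||% seed)
    dir.create(sub, showWarnings = FALSE, recursive = TRUE)
    write_genotype_counts(counts, file.path(sub, "counts.csv"))
  } else {
    sq_stop("config_error", "unknown simulate target '%s'", what)
  }
  sub
}

stage_profiles <- function(params, seed, out) {
  vol <- read_volume(params$volume_dir %||% file.path(out, "sim_boundary"))
  channel <- params$channel %||% "boundary"
  slab_um <- params$slab_um %||% 50
  projections <- slab_max_projection(vol, slab_um, channel)
  ny <- dim(vol$channels[[1L]])[2L]
  rows <- params$rows %||% round(ny * c(0.25, 0.5, 0.75))
  px <- vol$voxel_size_um[["x"]]
  nx <- dim(vol$channels[[1L]])[3L]
  profs <- list()
  for (proj in projections) {
    for (r in rows) {
      ln <- profile_line(c(1, r), c(nx, r),
                         anchor_um = (nx - 1) * px / 2,
                         sampling_step_um = params$step_um %||% px)
      profs[[length(profs) + 1L]] <-
        normalize_profile(sample_profile(proj, ln, pixel_size_um = px))
    }
  }
  ens <- aggregate_profiles(profs, grid_step_um = params$grid_step_um %||% 1)
  stats <- lapply(profs, boundary_stats)
  df <- data.frame(position_um = ens$positions_um, mean = ens$mean,
                   sem = ens$sem, n = ens$n)
  utils::write.csv(df, file.path(out, "profile_ensemble.csv"), row.names = FALSE)
  bdf <- data.frame(profile = seq_along(stats),
                    m_um = vapply(stats, `[[`, 0, "m"),
                    s_um = vapply(stats, `[[`, 0, "s"))
  utils::write.csv(bdf, file.path(out, "boundary_stats.csv"), row.names = FALSE)
  list(ensemble = ens, boundary = stats)
}

stage_orient <- function(params, out) {
  vol <- read_volume(params$volume_dir)
  channel <- params$channel %||% names(vol$channels)[1L]
  k <- params$slice %||% 1L
  img <- matrix(vol$channels[[channel]][k, , ],
                dim(vol$channels[[channel]])[2L],
                dim(vol$channels[[channel]])[3L])
  field <- structure_tensor_field(img,
                                  gradient_sigma = params$gradient_sigma %||% 1,
                                  window_sigma = params$window_sigma %||% 2)
  hist <- align_to_dominant(directionality_histogram(field,
                                                     bin_deg = params$bin_deg %||% 2))
  coh <- region_coherency(field)
  df <- data.frame(angle_deg = hist$centers_deg, weight = hist$weights)
  utils::write.csv(df, file.path(out, "directionality.csv"), row.names = FALSE)
  pools <- params$pools %||% list(c(0, 5), c(90, 5))
  scores <- vapply(pools, function(p) pool_angle_scores(hist, p[1L], p[2L]), 0)
  sdf <- data.frame(center_deg = vapply(pools, `[[`, 0, 1L),
                    halfwidth_deg = vapply(pools, `[[`, 0, 2L),
                    pooled_weight = scores, coherency = coh)
  utils::write.csv(sdf, file.path(out, "orientation_scores.csv"), row.names = FALSE)
  list(field = field, histogram = hist, coherency = coh, scores = sdf)
}

stage_morpho <- function(params, out) {
  stack <- read_label_stack(params$stack_dir %||% file.path(out, "sim_sections"))
  metrics <- params$metrics %||% c("fill", "trabeculation", "thickness")
  row <- list()
  if ("fill" %in% metrics) row$ivs_fill <- ivs_fill(stack)
  if ("trabeculation" %in% metrics)
    row$trabeculation_fraction <- trabeculation_fraction(stack)
  if ("thickness" %in% metrics)
    row$compact_thickness_um <- compact_thickness(stack, side = "both")
  df <- as.data.frame(row)
  utils::write.csv(df, file.path(out, "morphometry.csv"), row.names = FALSE)
  row
}

stage_vsd <- function(params, out) {
  stack <- read_label_stack(params$stack_dir %||% file.path(out, "sim_sections"))
  records <- detect_vsds(stack)
  records <- lapply(records, function(r) {
    r <- vsd_area(stack, r, path = params$path %||% "geodesic")
    classify_vsd(stack, r, avco_distance_um = params$avco_distance_um %||% 50)
  })
  df <- if (length(records)) {
    do.call(rbind, lapply(records, function(r) data.frame(
      id = r$id, slice_start = r$slice_range[1L], slice_end = r$slice_range[2L],
      area_um2 = r$area_um2, subtype = r$subtype)))
  } else {
    data.frame(id = integer(0), slice_start = integer(0),
               slice_end = integer(0), area_um2 = numeric(0),
               subtype = character(0))
  }
  utils::write.csv(df, file.path(out, "vsd_records.csv"), row.names = FALSE)
  records
}

stage_glm <- function(params, out) {
  counts <- read_genotype_counts(params$counts_csv)
  fit <- fit_allele_dose(counts)
  eff <- reported_effects(fit)
  df <- data.frame(term = names(fit$coefficients),
                   log_OR = unname(fit$coefficients),
                   OR = exp(unname(fit$coefficients)),
                   se = unname(fit$se), p = unname(fit$p))
  utils::write.csv(df, file.path(out, "glm_coefficients.csv"), row.names = FALSE)
  jsonlite::write_json(eff, file.path(out, "glm_effects.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(fit = fit, effects = eff)
}
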