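# Serial-section 3-D morphometry of the interventricular septum: IVS fill,
# attached-trabeculation fraction, apical compact-layer thickness, VSD
# detection by lumen contact, closing-path defect area, subtype assignment,
# and WGA/DAPI cell morphometry.

TISSUE_CLASSES <- c("compact_myocardium", "trabeculae", "IVS", "AVco",
                    "atria", "other_tissue")

stack_class_mask <- function(stack, classes) {
  codes <- stack$legend[classes]
  array(stack$labels %in% codes, dim(stack$labels))
}

# ---- IVS fill ---------------------------------------------------------------

#' IVS fill (solidity of the septal muscle layer)
#'
#' Fraction of the IVS region occupied by tissue, counting empty space inside
#' the region in the denominator.  For a label stack, tissue is any tissue
#' class and the region is either a supplied mask or the per-slice
#' morphological closing of the IVS class (which fills internal pores).  For
#' an RGB section (array `[y, x, 3]`, 0..255), tissue is the dark-pixel rule:
#' mean channel value below `darkness_threshold`.
#'
#' @param x a [section_label_stack()] or an RGB array `[y, x, 3]`.
#' @param ivs_region optional logical mask (same shape as the labels, or
#'   `[y, x]` for RGB) delimiting the IVS region including its empty space.
#' @param darkness_threshold dark-pixel cutoff for RGB input (default 200).
#' @param close_radius_px structuring radius for the default region closing.
#' @return fill fraction in `[0, 1]`.
#' @export
ivs_fill <- function(x, ivs_region = NULL, darkness_threshold = 200,
                     close_radius_px = 6) {
  if (inherits(x, "section_label_stack")) {
    tissue <- stack_class_mask(x, TISSUE_CLASSES)
    if (is.null(ivs_region)) {
      ivs <- stack_class_mask(x, "IVS")
      ivs_region <- array(FALSE, dim(ivs))
      off <- disk_offsets(close_radius_px)
      h <- rep(0, nrow(off))
      for (k in seq_len(dim(ivs)[1L])) {
        m <- matrix(as.numeric(ivs[k, , ]), dim(ivs)[2L], dim(ivs)[3L])
        closed <- gray_erode(gray_dilate(m, off, h), off, h)
        ivs_region[k, , ] <- closed >= 0.5
      }
    }
    assert_that(sum(ivs_region) > 0, "undefined_region", "empty IVS region")
    return(sum(tissue & ivs_region) / sum(ivs_region))
  }
  assert_that(is.array(x) && length(dim(x)) == 3L && dim(x)[3L] == 3L,
              "shape_error", "RGB input must be [y, x, 3]")
  assert_that(!is.null(ivs_region), "undefined_region",
              "RGB input requires an explicit ivs_region mask")
  assert_that(sum(ivs_region) > 0, "undefined_region", "empty IVS region")
  dark <- (x[, , 1L] + x[, , 2L] + x[, , 3L]) / 3 < darkness_threshold
  sum(dark & ivs_region) / sum(ivs_region)
}

# ---- trabeculation fraction -------------------------------------------------

#' Fraction of septal volume contributed by attached trabeculae
#'
#' `V_att / (V_att + V_IVS)` where `V_att` is the volume of trabecular
#' connected components (26-connectivity) that touch the IVS class
#' (face adjacency).
#'
#' @param stack a [section_label_stack()].
#' @return fraction in `[0, 1]`.
#' @export
trabeculation_fraction <- function(stack) {
  assert_that(inherits(stack, "section_label_stack"), "invalid_spec",
              "stack must be a section_label_stack")
  ivs <- stack_class_mask(stack, "IVS")
  assert_that(any(ivs), "undefined_region", "stack contains no IVS class")
  trab <- stack_class_mask(stack, "trabeculae")
  v_ivs <- sum(ivs)
  if (!any(trab)) return(0)
  lab <- label_components(trab, connectivity = 26L)
  touch <- dilate_mask_face(ivs) & trab
  attached_ids <- unique(lab[touch])
  attached_ids <- attached_ids[attached_ids > 0L]
  v_att <- sum(lab %in% attached_ids)
  v_att / (v_att + v_ivs)
}

# Binary dilation by one voxel, face (6) connectivity.
dilate_mask_face <- function(mask) {
  dm <- dim(mask)
  out <- mask
  shift3 <- function(m, dz, dy, dx) {
    res <- array(FALSE, dm)
    zi <- seq_len(dm[1L]) - dz; yi <- seq_len(dm[2L]) - dy; xi <- seq_len(dm[3L]) - dx
    zk <- zi >= 1L & zi <= dm[1L]; yk <- yi >= 1L & yi <= dm[2L]
    xk <- xi >= 1L & xi <= dm[3L]
    res[zk, yk, xk] <- m[zi[zk], yi[yk], xi[xk], drop = FALSE]
    res
  }
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    out <- out | shift3(mask, d[1L], d[2L], d[3L])
  }
  out
}

# ---- compact thickness ------------------------------------------------------

#' Apical compact-myocardium thickness
#'
#' Local thickness (diameter of the largest inscribed disk, per slice) of the
#' compact myocardium restricted to the apical `apex_fraction` of the
#' base-apex extent, averaged over pixels, reported per side in micrometres.
#'
#' @param stack a [section_label_stack()] with a `side_map` (1 = right,
#'   2 = left) when `side` is requested.
#' @param side `"LV"`, `"RV"`, or `"both"`.
#' @param apex_fraction apical window as a fraction of the base-apex extent
#'   (default 0.2, the bottom 20% of the ventricles).
#' @return mean thickness in micrometres.
#' @export
compact_thickness <- function(stack, side = c("both", "LV", "RV"),
                              apex_fraction = 0.2) {
  side <- match.arg(side)
  assert_that(inherits(stack, "section_label_stack"), "invalid_spec",
              "stack must be a section_label_stack")
  compact <- stack_class_mask(stack, "compact_myocardium")
  assert_that(any(compact), "undefined_region", "no compact myocardium in stack")
  if (side != "both") {
    assert_that(!is.null(stack$side_map), "undefined_region",
                "per-side thickness requires a side_map")
    want <- if (side == "LV") 2L else 1L
    side_sel <- stack$side_map == want
  } else {
    side_sel <- array(TRUE, dim(compact))
  }
  # base-apex window: rows (y) containing any compact tissue
  rows_any <- which(apply(compact, 2L, any))
  y0 <- min(rows_any); y1 <- max(rows_any)
  win_lo <- y1 - ceiling(apex_fraction * (y1 - y0 + 1L)) + 1L
  vals <- numeric(0)
  for (k in seq_len(dim(compact)[1L])) {
    m <- matrix(compact[k, , ], dim(compact)[2L], dim(compact)[3L])
    if (!any(m)) next
    # image borders are treated as continuation (cropped sections), so the
    # wall must be surrounded by labelled background to be measurable
    lt <- local_thickness2d(m)
    sel <- matrix(side_sel[k, , ], nrow(m), ncol(m))
    sel[seq_len(win_lo - 1L), ] <- FALSE
    sel <- sel & m
    if (any(sel)) vals <- c(vals, lt[sel])
  }
  assert_that(length(vals) > 0, "undefined_region",
              "empty apical compact region")
  mean(vals) * stack$pixel_size_um
}

# ---- VSD detection ----------------------------------------------------------

#' Detect ventricular septal defects by lumen contact
#'
#' Contact voxels are LV-lumen voxels face-adjacent (6-connectivity) to
#' RV-lumen voxels and vice versa; connected components of contact voxels
#' (26-connectivity across slices) become candidate defects.
#'
#' @param stack a [section_label_stack()] containing both lumen classes.
#' @return list of `vsd_record` objects (empty when the septum is intact),
#'   each with `id`, `slice_range`, `n_voxels`, `voxels` (index matrix),
#'   `subtype = "unassigned"`.
#' @export
detect_vsds <- function(stack) {
  assert_that(inherits(stack, "section_label_stack"), "invalid_spec",
              "stack must be a section_label_stack")
  lv <- stack_class_mask(stack, "LV_lumen")
  rv <- stack_class_mask(stack, "RV_lumen")
  assert_that(any(lv) && any(rv), "labeling_error",
              "both lumen classes must be present")
  contact <- (lv & dilate_mask_face(rv)) | (rv & dilate_mask_face(lv))
  if (!any(contact)) return(list())
  lab <- label_components(contact, connectivity = 26L)
  ids <- sort(unique(lab[lab > 0L]))
  lapply(seq_along(ids), function(i) {
    vox <- which(lab == ids[i])
    coords <- arrayInd(vox, dim(lab))
    structure(list(id = i,
                   slice_range = range(coords[, 1L]),
                   n_voxels = nrow(coords),
                   voxels = coords,
                   chords_um = NULL, area_um2 = NULL,
                   subtype = "unassigned",
                   subtype_provenance = NA_character_),
              class = "vsd_record")
  })
}

#' @export
print.vsd_record <- function(x, ...) {
  cat(sprintf("<vsd_record #%d> slices %d-%d, %d contact voxels, subtype %s%s\n",
              x$id, x$slice_range[1L], x$slice_range[2L], x$n_voxels, x$subtype,
              if (!is.null(x$area_um2)) sprintf(", area %.0f um^2", x$area_um2) else ""))
  invisible(x)
}

# Geodesic distance (8-connected, diagonal sqrt(2)) between two pixels
# through an allowed region; Inf when unreachable.
geodesic_distance <- function(allowed, from, to) {
  nr <- nrow(allowed); nc <- ncol(allowed)
  dist <- matrix(Inf, nr, nc)
  dist[from[1L], from[2L]] <- 0
  active <- matrix(c(from[1L], from[2L]), 1L, 2L)
  moves <- cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  cost <- sqrt(moves[, 1L]^2 + moves[, 2L]^2)
  while (nrow(active)) {
    nxt <- NULL
    for (mv in seq_len(8L)) {
      ny <- active[, 1L] + moves[mv, 1L]
      nx <- active[, 2L] + moves[mv, 2L]
      ok <- ny >= 1L & ny <= nr & nx >= 1L & nx <= nc
      if (!any(ok)) next
      ny <- ny[ok]; nx <- nx[ok]
      src <- active[ok, , drop = FALSE]
      nd <- dist[src] + cost[mv]
      upd <- allowed[cbind(ny, nx)] & nd < dist[cbind(ny, nx)] - 1e-12
      if (any(upd)) {
        dist[cbind(ny, nx)[upd, , drop = FALSE]] <-
          pmin(dist[cbind(ny, nx)[upd, , drop = FALSE]], nd[upd])
        nxt <- rbind(nxt, cbind(ny, nx)[upd, , drop = FALSE])
      }
    }
    active <- if (is.null(nxt)) matrix(0, 0L, 2L) else unique(nxt)
  }
  dist[to[1L], to[2L]]
}

#' Measure a defect's closing-path area
#'
#' For each slice spanned by the defect, the closing chord `c_k` is the
#' length of the minimal path closing the aperture: the geodesic through
#' non-tissue space between the two septal rim endpoints bounding the
#' contact region (minus one pixel, measuring the open gap between the rim
#' faces).  The defect area is `A = sum(c_k) * slice_thickness`.  Where the
#' two rim endpoints cannot be identified the maximal contact-region caliper
#' width is used and the slice is flagged.
#'
#' @param stack a [section_label_stack()].
#' @param record a `vsd_record` from [detect_vsds()].
#' @param path `"geodesic"` (default) or `"chord"` (straight segment).
#' @return the updated `vsd_record` with `chords_um`, `area_um2`,
#'   `fallback_slices`.
#' @export
vsd_area <- function(stack, record, path = c("geodesic", "chord")) {
  path <- match.arg(path)
  assert_that(inherits(record, "vsd_record"), "invalid_spec",
              "record must come from detect_vsds")
  px <- stack$pixel_size_um
  tissue_codes <- stack$legend[c("IVS", "AVco")]
  slices <- record$slice_range[1L]:record$slice_range[2L]
  chords <- numeric(0)
  fallback <- integer(0)
  for (k in slices) {
    vox <- record$voxels[record$voxels[, 1L] == k, , drop = FALSE]
    if (!nrow(vox)) next
    sl <- matrix(stack$labels[k, , ], dim(stack$labels)[2L], dim(stack$labels)[3L])
    contact <- matrix(FALSE, nrow(sl), ncol(sl))
    contact[vox[, 2:3, drop = FALSE]] <- TRUE
    tissue_sl <- matrix(sl %in% tissue_codes, nrow(sl), ncol(sl))
    rim <- find_rim_endpoints(tissue_sl, contact)
    if (is.null(rim)) {
      # caliper fallback
      d <- as.matrix(stats::dist(vox[, 2:3, drop = FALSE]))
      chords <- c(chords, (max(d) + 1) * px)
      fallback <- c(fallback, k)
      next
    }
    if (path == "chord") {
      g <- sqrt(sum((rim$a - rim$b)^2))
    } else {
      allowed <- matrix(!(sl %in% stack$legend[TISSUE_CLASSES]), nrow(sl), ncol(sl))
      allowed[rim$a[1L], rim$a[2L]] <- TRUE
      allowed[rim$b[1L], rim$b[2L]] <- TRUE
      # restrict the search to the defect neighbourhood
      span <- ceiling(sqrt(sum((rim$a - rim$b)^2))) + 5L
      y0 <- max(1L, min(rim$a[1L], rim$b[1L], vox[, 2L]) - span)
      y1 <- min(nrow(sl), max(rim$a[1L], rim$b[1L], vox[, 2L]) + span)
      x0 <- max(1L, min(rim$a[2L], rim$b[2L], vox[, 3L]) - span)
      x1 <- min(ncol(sl), max(rim$a[2L], rim$b[2L], vox[, 3L]) + span)
      g <- geodesic_distance(allowed[y0:y1, x0:x1, drop = FALSE],
                             c(rim$a[1L] - y0 + 1L, rim$a[2L] - x0 + 1L),
                             c(rim$b[1L] - y0 + 1L, rim$b[2L] - x0 + 1L))
      if (!is.finite(g)) g <- sqrt(sum((rim$a - rim$b)^2))
    }
    chords <- c(chords, max(g - 1, 0) * px)
  }
  record$chords_um <- chords
  record$area_um2 <- sum(chords) * stack$slice_thickness_um
  record$fallback_slices <- fallback
  record$path <- path
  record
}

# Identify the two septal rim endpoints bounding a contact region on one
# slice: tissue pixels 8-adjacent to the contact region are clustered; with
# exactly two clusters the endpoint of each is the pixel nearest the contact
# centroid.  Returns NULL when the rim is not bipartite.
find_rim_endpoints <- function(tissue, contact) {
  off <- neighbor_offsets(2L, 8L)
  dil <- contact
  for (i in seq_len(nrow(off))) {
    dil <- dil | shift_mat(contact, off[i, 1L], off[i, 2L], FALSE)
  }
  rim <- tissue & dil & !contact
  if (!any(rim)) return(NULL)
  lab <- label_components(rim, connectivity = 8L)
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) != 2L) return(NULL)
  cen <- colMeans(which(contact, arr.ind = TRUE))
  pick <- function(id) {
    pts <- which(lab == id, arr.ind = TRUE)
    d <- (pts[, 1L] - cen[1L])^2 + (pts[, 2L] - cen[2L])^2
    as.integer(pts[which.min(d), ])
  }
  list(a = pick(ids[1L]), b = pick(ids[2L]))
}

#' Assign a VSD subtype from proximity to the AV complex
#'
#' Membranous if any contact voxel lies within `avco_distance_um` of
#' AVco-class tissue, else muscular; `"unassigned"` when the stack has no
#' AVco class.  A manual override is accepted and recorded with provenance.
#'
#' @param stack a [section_label_stack()].
#' @param record a `vsd_record`.
#' @param avco_distance_um membranous cutoff (default 50).
#' @param override optional `"membranous"` or `"muscular"` manual call.
#' @return the updated `vsd_record`.
#' @export
classify_vsd <- function(stack, record, avco_distance_um = 50, override = NULL) {
  assert_that(inherits(record, "vsd_record"), "invalid_spec",
              "record must come from detect_vsds")
  if (!is.null(override)) {
    record$subtype <- match.arg(override, c("membranous", "muscular"))
    record$subtype_provenance <- "manual_override"
    return(record)
  }
  avco <- stack_class_mask(stack, "AVco")
  if (!any(avco)) {
    record$subtype <- "unassigned"
    record$subtype_provenance <- "no_AVco_class"
    return(record)
  }
  px <- stack$pixel_size_um
  t_um <- stack$slice_thickness_um
  nz <- dim(stack$labels)[1L]
  # per-slice in-plane distance to AVco, combined with z offsets
  d2d <- vector("list", nz)
  slices_with <- which(apply(avco, 1L, any))
  for (k in slices_with) {
    m <- matrix(avco[k, , ], dim(avco)[2L], dim(avco)[3L])
    d2d[[k]] <- edt2d(!m) * px
  }
  mind <- Inf
  for (k in slices_with) {
    dz_um <- abs(record$voxels[, 1L] - k) * t_um
    cand <- dz_um <= avco_distance_um + 1e-9 | dz_um < mind
    if (!any(cand)) next
    dpix <- d2d[[k]][record$voxels[cand, 2:3, drop = FALSE]]
    mind <- min(mind, min(sqrt(dpix^2 + dz_um[cand]^2)))
  }
  record$subtype <- if (mind <= avco_distance_um) "membranous" else "muscular"
  record$subtype_provenance <- "distance_rule"
  record$avco_distance_um <- mind
  record
}

# ---- cell morphometry -------------------------------------------------------

#' Elliptical cell shape descriptors from measured axes
#'
#' Area `pi L W / 4`, eccentricity `sqrt(1 - (W/L)^2)`, and diameter of the
#' equivalent-area circle `sqrt(L W)`.
#'
#' @param L,W major and minor axis lengths (micrometres); swapped with a
#'   warning if `W > L`.
#' @param angle_deg optional axis angle.
#' @return object of class `cell_shape`.
#' @export
cell_shape_from_axes <- function(L, W, angle_deg = NA_real_) {
  assert_that(is_scalar_num(L) && is_scalar_num(W) && L > 0 && W > 0,
              "invalid_spec", "axes must be positive")
  if (W > L) {
    sq_warn("W > L; axes swapped")
    tmp <- L; L <- W; W <- tmp
  }
  structure(list(L_um = L, W_um = W, angle_deg = angle_deg,
                 area_um2 = pi * L * W / 4,
                 eccentricity = sqrt(1 - (W / L)^2),
                 diameter_um = sqrt(L * W)),
            class = "cell_shape")
}

#' Detect nuclei as smoothed intensity peaks
#'
#' Local maxima of the Gaussian-smoothed image with non-maximum suppression
#' at `min_distance_um` and a relative intensity floor.
#'
#' @param image numeric matrix.
#' @param smoothing_sigma Gaussian sigma in pixels.
#' @param min_distance_um minimal peak separation.
#' @param pixel_size_um pixel size.
#' @param threshold_rel peaks must exceed
#'   `min + threshold_rel * (max - min)` of the smoothed image.
#' @return data.frame with columns `y`, `x` (pixel coordinates); zero rows
#'   for a flat image.
#' @export
detect_nuclei <- function(image, smoothing_sigma = 2, min_distance_um = 5,
                          pixel_size_um = 1, threshold_rel = 0.1) {
  assert_that(is.matrix(image), "shape_error", "image must be 2-D")
  sm <- gaussian_blur(image, smoothing_sigma)
  rng <- range(sm)
  if (diff(rng) == 0) return(data.frame(y = integer(0), x = integer(0)))
  r <- max(1, min_distance_um / pixel_size_um)
  mf <- max_filter(sm, r)
  thr <- rng[1L] + threshold_rel * diff(rng)
  peaks <- which(sm >= mf - 1e-12 & sm > thr, arr.ind = TRUE)
  data.frame(y = peaks[, 1L], x = peaks[, 2L])
}

#' Nuclei density inside a region of interest
#'
#' @param coordinates data.frame with `y`, `x` pixel coordinates.
#' @param roi_mask logical matrix.
#' @param pixel_size_um pixel size.
#' @return detections per square micrometre.
#' @export
nuclei_density <- function(coordinates, roi_mask, pixel_size_um = 1) {
  area <- sum(roi_mask) * pixel_size_um^2
  assert_that(area > 0, "undefined_region", "zero-area ROI")
  if (!nrow(coordinates)) return(0)
  inside <- roi_mask[cbind(coordinates$y, coordinates$x)]
  sum(inside) / area
}
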