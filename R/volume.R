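# MultiChannelVolume: a calibrated multi-channel voxel stack.
#
# Axis convention (fixed package-wide, recorded in every sidecar):
#   arrays are [z, y, x]; z = anterior -> posterior, y = base -> apex,
#   x = anatomical right -> left (x increases leftward).  Profile positions
#   are in micrometres with 0 at the volume x-midline, so positive positions
#   are anatomically left.

#' Construct a multi-channel calibrated volume
#'
#' @param channels named list of numeric 3-D arrays, all of identical
#'   dimension `[z, y, x]`.
#' @param voxel_size_um numeric length-3 vector of voxel sizes in micrometres,
#'   in `(z, y, x)` order.
#' @return an object of class `mc_volume`.
#' @export
mc_volume <- function(channels, voxel_size_um) {
  assert_that(is.list(channels) && length(channels) >= 1L,
              "invalid_spec", "channels must be a non-empty named list")
  nm <- names(channels)
  assert_that(!is.null(nm) && !anyDuplicated(nm) && all(nzchar(nm)),
              "invalid_spec", "channel names must be unique and non-empty")
  dims <- lapply(channels, dim)
  assert_that(all(vapply(dims, length, 1L) == 3L),
              "shape_error", "each channel must be a 3-D array [z, y, x]")
  assert_that(all(vapply(dims, function(d) identical(d, dims[[1L]]), TRUE)),
              "shape_error", "all channels must share one shape")
  voxel_size_um <- as.numeric(voxel_size_um)
  assert_that(length(voxel_size_um) == 3L && all(voxel_size_um > 0),
              "invalid_spec", "voxel_size_um must be 3 positive numbers (z, y, x)")
  channels <- lapply(channels, function(ch) {
    dim(ch) <- unname(dim(ch))
    ch
  })
  structure(list(
    channels = channels,
    voxel_size_um = stats::setNames(voxel_size_um, c("z", "y", "x")),
    axes = c(z = "anterior_posterior", y = "base_apex", x = "right_left"),
    note = "x increases anatomically leftward; positions in um, 0 = x midline"
  ), class = "mc_volume")
}

#' @export
print.mc_volume <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<mc_volume> %d channel(s) [%s], %d x %d x %d voxels (z,y,x), voxel %s um\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1L], d[2L], d[3L],
              paste(signif(x$voxel_size_um, 4), collapse = " x ")))
  invisible(x)
}

vol_dim <- function(vol) dim(vol$channels[[1L]])

# x coordinates (um) of voxel centres, 0 at the volume midline.
vol_x_um <- function(vol) {
  nx <- vol_dim(vol)[3L]
  (seq_len(nx) - (nx + 1) / 2) * vol$voxel_size_um[["x"]]
}

#' Write / read a multi-channel volume
#'
#' Volumes are stored as one raw little-endian float64 plane file per channel
#' plus a `volume.json` sidecar holding shape, axis order, voxel sizes and
#' channel names.  The pairing round-trips bit-exactly.  A missing or
#' inconsistent sidecar is an error, never a silent default.
#'
#' @param vol an [mc_volume()].
#' @param dir output directory (created if needed).
#' @return `write_volume` returns `dir` invisibly; `read_volume` returns the
#'   validated [mc_volume()].
#' @export
write_volume <- function(vol, dir) {
  assert_that(inherits(vol, "mc_volume"), "invalid_spec", "vol must be an mc_volume")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- vol_dim(vol)
  files <- character(0)
  for (nm in names(vol$channels)) {
    f <- paste0("channel_", nm, ".f64")
    con <- file(file.path(dir, f), "wb")
    writeBin(as.vector(vol$channels[[nm]]), con, size = 8L, endian = "little")
    close(con)
    files <- c(files, f)
  }
  meta <- list(
    format = "septaquant-volume-v1",
    shape_zyx = as.integer(d),
    axis_order = "z,y,x (column-major payload)",
    axes = as.list(vol$axes),
    voxel_size_um = as.list(vol$voxel_size_um),
    channels = names(vol$channels),
    files = files
  )
  jsonlite::write_json(meta, file.path(dir, "volume.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_volume
#' @export
read_volume <- function(dir) {
  sidecar <- file.path(dir, "volume.json")
  assert_that(file.exists(sidecar), "format_error",
              "missing sidecar volume.json in %s", dir)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  assert_that(identical(meta$format, "septaquant-volume-v1"),
              "format_error", "unrecognized volume format")
  d <- as.integer(meta$shape_zyx)
  assert_that(length(d) == 3L && all(d > 0), "format_error", "bad shape in sidecar")
  n <- prod(d)
  channels <- list()
  for (i in seq_along(meta$channels)) {
    f <- file.path(dir, meta$files[i])
    assert_that(file.exists(f), "format_error", "missing channel file %s", f)
    assert_that(file.size(f) == 8 * n, "format_error",
                "channel file %s does not match sidecar shape", f)
    con <- file(f, "rb")
    v <- readBin(con, "double", n = n, size = 8L, endian = "little")
    close(con)
    channels[[meta$channels[i]]] <- array(v, d)
  }
  mc_volume(channels, as.numeric(unlist(meta$voxel_size_um)))
}
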