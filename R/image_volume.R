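#' HU image volumes
#'
#' `image_volume()` is the raster carrier used throughout the package: a 2-D
#' slice (or a stack of slices) of CT numbers in Hounsfield units, together
#' with voxel spacing, physical origin and the acquisition modality. The
#' modality fixes the representable HU range: kilovoltage CT (and synthetic
#' CT derived from it) spans \[-1000, 3000\] HU, megavoltage CBCT spans
#' \[-1000, 1400\] HU.
#'
#' Coordinate convention: voxel indices are 0-based and physical position =
#' origin + index * spacing (voxel-centre convention). 2-D slices are stored
#' as plain matrices; a `(1, H, W)` array input is accepted and squeezed.
#'
#' @param values numeric matrix (one slice) or 3-D array of HU values.
#' @param spacing numeric, mm per axis (length 2 for a slice: row, col).
#' @param origin numeric, physical position of voxel (0, 0) in mm.
#' @param modality one of `"kvct"`, `"mvcbct"`, `"sct"`.
#' @return an object of class `mvmar_volume`.
#' @examples
#' v <- image_volume(matrix(0, 8, 8), spacing = c(1, 1), modality = "kvct")
#' hu_range(v)
#' @export
image_volume <- function(values, spacing = c(1, 1), origin = c(0, 0),
                         modality = c("kvct", "mvcbct", "sct")) {
  modality <- match.arg(modality)
  if (is.array(values) && length(dim(values)) == 3L) {
    if (dim(values)[1L] != 1L)
      stop("3-D input must be a single-slice (1, H, W) array")
    values <- matrix(values[1L, , ], nrow = dim(values)[2L])
  }
  if (!is.matrix(values)) stop("`values` must be a matrix or (1, H, W) array")
  storage.mode(values) <- "double"
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be strictly positive on every axis")
  if (length(origin) == 1L) origin <- rep(origin, 2L)
  structure(
    list(values = values, spacing = as.numeric(spacing[1:2]),
         origin = as.numeric(origin[1:2]), modality = modality),
    class = "mvmar_volume"
  )
}

#' @export
print.mvmar_volume <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<mvmar_volume> %s  %d x %d px  %.3g x %.3g mm  HU [%.0f, %.0f]\n",
              x$modality, nrow(x$values), ncol(x$values),
              x$spacing[1], x$spacing[2], rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.mvmar_volume <- function(x) dim(x$values)

#' Representable HU range of a modality
#'
#' @param x an `mvmar_volume` or a modality string.
#' @return numeric length-2 `(lo, hi)` in HU.
#' @export
hu_range <- function(x) {
  modality <- if (inherits(x, "mvmar_volume")) x$modality else x
  switch(modality,
    kvct   = c(-1000, 3000),
    sct    = c(-1000, 3000),
    mvcbct = c(-1000, 1400),
    stop("unknown modality: ", modality)
  )
}

#' Clamp a volume to its modality HU range
#'
#' MV-CBCT values are clipped to at most 1400 HU and kV-CT / sCT values to at
#' most 3000 HU (floor -1000 HU in both cases). Idempotent and monotone.
#'
#' @param vol an `mvmar_volume`.
#' @return the clamped volume.
#' @export
clamp_hu <- function(vol) {
  stopifnot(inherits(vol, "mvmar_volume"))
  rng <- hu_range(vol)
  vol$values <- pmin(pmax(vol$values, rng[1]), rng[2])
  vol
}

#' Named boolean region-of-interest mask
#'
#' @param name ROI label (e.g. `"mandible"`, `"oral_cavity"`, `"metal"`).
#' @param mask logical matrix aligned with the associated image grid.
#' @return an object of class `mvmar_mask`.
#' @export
structure_mask <- function(name, mask) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1, NA))) stop("mask must be strictly boolean")
    mask <- mask > 0
  }
  structure(list(name = as.character(name), mask = mask),
            class = "mvmar_mask")
}

#' @export
print.mvmar_mask <- function(x, ...) {
  cat(sprintf("<mvmar_mask> '%s'  %d x %d px  %d set\n",
              x$name, nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

# Error unless two volumes (or a volume and a mask) share grid shape.
check_same_geometry <- function(a, b, what = "inputs") {
  da <- if (inherits(a, "mvmar_mask")) dim(a$mask) else dim(a$values)
  db <- if (inherits(b, "mvmar_mask")) dim(b$mask) else dim(b$values)
  if (!identical(da, db))
    stop(sprintf("geometry mismatch between %s: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(TRUE)
}

#' Resample and crop a slice to a target grid
#'
#' Resamples with bilinear interpolation onto a grid of `target_shape` pixels
#' at `target_spacing` mm, centred on `center` (physical mm; defaults to the
#' centre of the input field of view). Pixels that fall outside the original
#' field of view are filled with -1000 HU (air). Masks should be resampled
#' with `interpolation = "nearest"` so they stay boolean.
#'
#' @param vol an `mvmar_volume`.
#' @param target_spacing numeric, mm (scalar or length 2).
#' @param target_shape integer length 2, output pixels (rows, cols).
#' @param center physical centre of the output grid in mm, or `NULL`.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill fill value for out-of-field pixels (default -1000 HU).
#' @return a resampled `mvmar_volume`.
#' @export
resample_crop <- function(vol, target_spacing, target_shape, center = NULL,
                          interpolation = c("linear", "nearest"),
                          fill = -1000) {
  stopifnot(inherits(vol, "mvmar_volume"))
  interpolation <- match.arg(interpolation)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 2L)
  if (any(target_spacing <= 0)) stop("target_spacing must be > 0")
  target_shape <- as.integer(target_shape)
  d <- dim(vol$values)
  if (is.null(center))
    center <- vol$origin + (d - 1) / 2 * vol$spacing
  # physical coordinates of output voxel centres
  out_origin <- center - (target_shape - 1) / 2 * target_spacing
  rr <- out_origin[1] + (seq_len(target_shape[1]) - 1) * target_spacing[1]
  cc <- out_origin[2] + (seq_len(target_shape[2]) - 1) * target_spacing[2]
  # to 0-based input pixel coordinates
  ri <- (rr - vol$origin[1]) / vol$spacing[1]
  ci <- (cc - vol$origin[2]) / vol$spacing[2]
  grid_r <- rep(ri, times = target_shape[2])
  grid_c <- rep(ci, each = target_shape[1])
  if (interpolation == "nearest") {
    grid_r <- round(grid_r)
    grid_c <- round(grid_c)
  }
  v <- cpp_bilinear_sample(vol$values, grid_r, grid_c, fill)
  out <- image_volume(matrix(v, nrow = target_shape[1]),
                      spacing = target_spacing, origin = out_origin,
                      modality = vol$modality)
  out
}
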