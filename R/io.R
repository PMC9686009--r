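#' Read an HU volume from disk
#'
#' Supports NIfTI (`.nii` / `.nii.gz`) files and DICOM: either a single
#' `.dcm` file or a directory containing a single-frame CT series. DICOM
#' stored values are converted to HU with the mandatory rescale tags
#' (HU = RescaleSlope * SV + RescaleIntercept); a file missing either tag is
#' rejected with an error naming the tag. The package operates slice-wise:
#' a multi-slice DICOM directory must be read with [read_dicom_series()].
#'
#' @param path file (NIfTI, DICOM) or directory (DICOM series) path.
#' @param format `"nifti"` or `"dicom-series"`; guessed from `path` if omitted.
#' @param modality modality tag to attach (`"kvct"`, `"mvcbct"`, `"sct"`).
#' @return an [image_volume()].
#' @export
read_volume <- function(path, format = NULL,
                        modality = c("kvct", "mvcbct", "sct")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (is.null(format)) {
    format <- if (dir.exists(path) || grepl("\\.dcm$", path, ignore.case = TRUE))
      "dicom-series" else "nifti"
  }
  switch(format,
    nifti = {
      img <- RNifti::readNifti(path)
      arr <- as.array(img)
      pd <- RNifti::pixdim(img)
      if (length(dim(arr)) == 3L && dim(arr)[3L] == 1L)
        arr <- arr[, , 1L]
      arr <- matrix(as.numeric(arr), nrow(arr))  # drop NIfTI attributes
      image_volume(arr, spacing = pd[1:2], modality = modality)
    },
    `dicom-series` = ,
    dicom = {
      if (dir.exists(path)) {
        files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE,
                            ignore.case = TRUE)
        if (length(files) == 0L)
          stop("DICOM series directory contains 0 slices: ", path)
        if (length(files) > 1L) {
          slices <- read_dicom_series(path, modality = modality)
          if (length(slices) > 1L)
            stop("multi-slice series: use read_dicom_series() for slice lists")
          return(slices[[1L]])
        }
        path <- files[[1L]]
      }
      read_dicom_slice(path, modality = modality)
    },
    stop("unsupported format: ", format)
  )
}

#' Write an HU volume to disk
#'
#' NIfTI output is int16-quantised (HU values are integral in practice), so
#' a write/read round trip reproduces values within int16 quantisation.
#' DICOM output writes a minimal single-frame Explicit-VR little-endian CT
#' file with RescaleSlope 1 / RescaleIntercept -1024.
#'
#' @param vol an [image_volume()]; must be free of NaN/NA.
#' @param path output file path.
#' @param format `"nifti"` or `"dicom"`; guessed from the extension if omitted.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  stopifnot(inherits(vol, "mvmar_volume"))
  if (any(!is.finite(vol$values)))
    stop("refusing to write volume containing non-finite values")
  if (is.null(format)) {
    format <- if (grepl("\\.dcm$", path, ignore.case = TRUE)) "dicom" else "nifti"
  }
  switch(format,
    nifti = {
      img <- RNifti::asNifti(round(vol$values))  # nearest-int quantisation
      RNifti::pixdim(img) <- vol$spacing
      RNifti::writeNifti(img, path, datatype = "int16")
    },
    dicom = write_dicom_slice(vol, path),
    stop("unsupported format: ", format)
  )
  invisible(path)
}

# ---- minimal DICOM (Explicit VR Little Endian, single-frame MONOCHROME2) ----
# No R DICOM package is available in this stack, so the package carries its
# own reader/writer for the small subset it needs: uncompressed int16 CT
# slices with rescale, spacing, position and orientation tags.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

dcm_element <- function(group, element, vr, value) {
  con <- raw(0)
  hdr <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
           writeBin(as.integer(element), raw(), size = 2, endian = "little"),
           charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    body <- value
    c(hdr, as.raw(c(0, 0)),
      writeBin(length(body), raw(), size = 4, endian = "little"), body)
  } else {
    body <- if (vr %in% c("US", "UL")) {
      writeBin(as.integer(value), raw(), size = if (vr == "US") 2 else 4,
               endian = "little")
    } else {
      s <- as.character(value)
      if (nchar(s) %% 2 == 1) s <- paste0(s, " ")  # even length padding
      charToRaw(s)
    }
    c(hdr, writeBin(length(body), raw(), size = 2, endian = "little"), body)
  }
}

#' @rdname write_volume
#' @export
write_dicom_slice <- function(vol, path) {
  stopifnot(inherits(vol, "mvmar_volume"))
  v <- round(vol$values)
  sv <- v + 1024  # slope 1, intercept -1024
  if (any(sv < -32768 | sv > 32767)) stop("HU out of int16 stored range")
  nr <- nrow(v); nc <- ncol(v)
  # DICOM pixel order is row-major
  pix <- writeBin(as.integer(t(sv)), raw(), size = 2, endian = "little")
  meta <- dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  header <- c(
    raw(128), charToRaw("DICM"),
    dcm_element(0x0002, 0x0000, "UL", length(meta)),
    meta,
    dcm_element(0x0008, 0x0060, "CS", toupper(substr(vol$modality, 1, 2))),
    dcm_element(0x0020, 0x0032, "DS",
                sprintf("%g\\%g\\0", vol$origin[2], vol$origin[1])),
    dcm_element(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
    dcm_element(0x0028, 0x0010, "US", nr),
    dcm_element(0x0028, 0x0011, "US", nc),
    dcm_element(0x0028, 0x0030, "DS",
                sprintf("%g\\%g", vol$spacing[1], vol$spacing[2])),
    dcm_element(0x0028, 0x0100, "US", 16),
    dcm_element(0x0028, 0x0101, "US", 16),
    dcm_element(0x0028, 0x0102, "US", 15),
    dcm_element(0x0028, 0x0103, "US", 1),
    dcm_element(0x0028, 0x1052, "DS", "-1024"),
    dcm_element(0x0028, 0x1053, "DS", "1"),
    dcm_element(0x7FE0, 0x0010, "OW", pix)
  )
  writeBin(header, path)
  invisible(path)
}

# Parse one Explicit-VR little-endian DICOM file into a tag -> value list.
dcm_parse <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  u16 <- function(i) as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  while (pos + 8L <= length(bytes) + 1L) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); data_at <- pos + 12L
    } else {
      len <- u16(pos + 6L); data_at <- pos + 8L
    }
    if (vr == "SQ") stop("unsupported DICOM element (sequence) in ", path)
    if (!is.finite(len) || data_at + len - 1L > length(bytes))
      stop("truncated DICOM element in ", path)
    tag <- dcm_tag(group, element)
    raw_val <- if (len > 0) bytes[data_at:(data_at + len - 1L)] else raw(0)
    out[[tag]] <- list(vr = vr, raw = raw_val)
    pos <- data_at + len
  }
  out
}

dcm_string <- function(el) trimws(rawToChar(el$raw))
dcm_numbers <- function(el) as.numeric(strsplit(dcm_string(el), "\\\\")[[1]])
dcm_us <- function(el) readBin(el$raw, "integer", size = 2, signed = FALSE,
                               endian = "little")

#' Read a single DICOM slice
#'
#' @inheritParams read_volume
#' @return an [image_volume()] in HU.
#' @export
read_dicom_slice <- function(path, modality = c("kvct", "mvcbct", "sct")) {
  modality <- match.arg(modality)
  el <- dcm_parse(path)
  need <- function(tag, what) {
    if (is.null(el[[tag]]))
      stop(sprintf("DICOM file missing required tag (%s) %s: %s",
                   tag, what, path))
    el[[tag]]
  }
  slope <- dcm_numbers(need("0028,1053", "RescaleSlope"))
  intercept <- dcm_numbers(need("0028,1052", "RescaleIntercept"))
  if (!is.finite(slope) || !is.finite(intercept))
    stop("non-numeric rescale tags in ", path)
  nr <- dcm_us(need("0028,0010", "Rows"))
  nc <- dcm_us(need("0028,0011", "Columns"))
  spacing <- dcm_numbers(need("0028,0030", "PixelSpacing"))
  pix <- need("7FE0,0010", "PixelData")
  sv <- readBin(pix$raw, "integer", n = nr * nc, size = 2, signed = TRUE,
                endian = "little")
  hu <- matrix(sv, nrow = nc, ncol = nr)  # row-major on disk
  hu <- t(hu) * slope + intercept
  origin <- c(0, 0)
  if (!is.null(el[["0020,0032"]])) {
    ipp <- dcm_numbers(el[["0020,0032"]])
    origin <- c(ipp[2], ipp[1])
  }
  image_volume(hu, spacing = spacing, origin = origin, modality = modality)
}

#' Read a DICOM series directory as an ordered list of slices
#'
#' Slices are ordered by the z component of ImagePositionPatient. A series
#' with inconsistent ImageOrientationPatient across slices is rejected.
#'
#' @param path directory containing `.dcm` files.
#' @inheritParams read_volume
#' @return list of [image_volume()] slices, inferior to superior.
#' @export
read_dicom_series <- function(path, modality = c("kvct", "mvcbct", "sct")) {
  modality <- match.arg(modality)
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L)
    stop("DICOM series directory contains 0 slices: ", path)
  parsed <- lapply(files, dcm_parse)
  orient <- vapply(parsed, function(el) {
    if (is.null(el[["0020,0037"]])) "" else dcm_string(el[["0020,0037"]])
  }, character(1))
  if (length(unique(orient)) > 1L)
    stop("mixed ImageOrientationPatient across series: ", path)
  z <- vapply(parsed, function(el) {
    if (is.null(el[["0020,0032"]])) 0 else dcm_numbers(el[["0020,0032"]])[3]
  }, numeric(1))
  lapply(files[order(z)], read_dicom_slice, modality = modality)
}

#' Write / read a boolean mask as NIfTI
#'
#' @param mask an [structure_mask()].
#' @param path NIfTI file path.
#' @return `path` (write) or an `mvmar_mask` (read).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mvmar_mask"))
  RNifti::writeNifti(RNifti::asNifti(mask$mask * 1L), path,
                     datatype = "int16")
  invisible(path)
}

#' @rdname write_mask
#' @param name ROI label to attach on read.
#' @export
read_mask <- function(path, name = "roi") {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 3L && dim(arr)[3L] == 1L) arr <- arr[, , 1L]
  structure_mask(name, arr > 0)
}
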