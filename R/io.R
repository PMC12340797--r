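# File formats: MRC (minimal MRC2014 single-section reader/writer, mode
# 0/1/2/6, little-endian), TIFF via the tiff package (32-bit float images,
# 16-bit label masks), CSV tables and JSON manifests.

#' Write a 2D image as a single-section MRC file
#'
#' Mode 2 (float32), little-endian, pixel size recorded in the standard
#' cella/mx header fields. Matrix rows are image y, columns x.
#'
#' @param x a [micrograph()], [diffraction_frame()] or numeric matrix.
#' @param path output path.
#' @param pixel_size_A pixel size written to the header; defaults to the
#'   micrograph's calibration (1.0 for bare matrices).
#' @return The path, invisibly.
#' @export
write_mrc <- function(x, path, pixel_size_A = NULL) {
  if (inherits(x, "micrograph")) {
    M <- x$intensities
    if (is.null(pixel_size_A)) pixel_size_A <- x$pixel_size_A
  } else if (inherits(x, "diffraction_frame")) {
    M <- x$intensities
  } else {
    M <- as.matrix(x)
  }
  if (is.null(pixel_size_A)) pixel_size_A <- 1
  nx <- ncol(M); ny <- nrow(M)
  con <- file(path, "wb"); on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wi(c(nx, ny, 1L, 2L))                 # nx ny nz, mode 2 = float32
  wi(c(0L, 0L, 0L))                     # nxstart nystart nzstart
  wi(c(nx, ny, 1L))                     # mx my mz
  wf(c(nx, ny, 1) * pixel_size_A)       # cella (Angstrom)
  wf(c(90, 90, 90))                     # cellb
  wi(c(1L, 2L, 3L))                     # mapc mapr maps
  wf(c(min(M), max(M), mean(M)))        # dmin dmax dmean
  wi(c(0L, 0L))                         # ispg, nsymbt
  writeBin(raw(100L), con)              # extra words 25-49
  wf(c(0, 0, 0))                        # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(M)))           # rms
  wi(0L)                                # nlabl
  writeBin(raw(800L), con)              # labels
  writeBin(as.numeric(t(M)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a single-section MRC file
#'
#' Supports modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16),
#' little-endian, one section. The pixel size is `cella.x / mx` when both are
#' present in the header.
#'
#' @param path MRC file path.
#' @return A list with `intensities` (numeric matrix, rows = y) and
#'   `pixel_size_A` (NA when the header carries no calibration).
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("corrupt input: file not found: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 1024L)
  if (length(hdr) < 1024L) stop("corrupt input: truncated MRC header")
  geti <- function(w) readBin(hdr[(4L * (w - 1L) + 1L):(4L * w)], "integer",
                              1L, size = 4L, endian = "little")
  getf <- function(w) readBin(hdr[(4L * (w - 1L) + 1L):(4L * w)], "numeric",
                              1L, size = 4L, endian = "little")
  nx <- geti(1); ny <- geti(2); nz <- geti(3); mode <- geti(4)
  if (nx <= 0 || ny <= 0 || nz <= 0 || nx > 1e5 || ny > 1e5)
    stop("corrupt input: implausible MRC dimensions")
  if (nz != 1L) stop("only single-section MRC is supported (nz = ", nz, ")")
  mx <- geti(8); xlen <- getf(11)
  apix <- if (mx > 0 && is.finite(xlen) && xlen > 0) xlen / mx else NA_real_
  nsymbt <- geti(24)
  if (nsymbt > 0) invisible(readBin(con, "raw", nsymbt))
  n <- nx * ny
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2L, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n, size = 2L, signed = FALSE,
                             endian = "little")),
    stop("corrupt input: unsupported MRC mode ", mode)
  )
  if (length(vals) < n) stop("corrupt input: truncated MRC data block")
  list(intensities = matrix(vals, nrow = ny, ncol = nx, byrow = TRUE),
       pixel_size_A = apix)
}

resolve_pixel_size <- function(header_apix, flag_apix, what = "micrograph") {
  if (!is.null(flag_apix) && !is.na(flag_apix)) {
    if (!is.na(header_apix) &&
        abs(header_apix - flag_apix) / header_apix > 0.01)
      warning(sprintf(
        "pixel size conflict: header %.4g A/px vs flag %.4g A/px; flag wins",
        header_apix, flag_apix))
    return(flag_apix)
  }
  if (is.na(header_apix))
    stop("uncalibrated ", what,
         ": no pixel size in file and none supplied")
  header_apix
}

#' Read a micrograph from MRC or TIFF
#'
#' The pixel size is taken from the MRC header when present and can be
#' overridden; a conflict of more than 1% between header and override emits a
#' warning (the override wins). TIFF files carry no calibration here and
#' require `pixel_size_A`.
#'
#' @param path MRC (.mrc) or TIFF (.tif/.tiff) file.
#' @param pixel_size_A optional pixel size override in Angstrom/pixel.
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path, pixel_size_A = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mrc") {
    m <- read_mrc(path)
    apix <- resolve_pixel_size(m$pixel_size_A, pixel_size_A)
    micrograph(m$intensities, apix, metadata = list(source = path))
  } else if (ext %in% c("tif", "tiff")) {
    M <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) stop("corrupt input: ",
                                           conditionMessage(e)))
    if (length(dim(M)) == 3L) M <- M[, , 1L]
    apix <- resolve_pixel_size(NA_real_, pixel_size_A)
    micrograph(M, apix, metadata = list(source = path))
  } else {
    stop("corrupt input: unsupported extension '", ext, "'")
  }
}

#' Read a diffraction frame from MRC or TIFF
#'
#' @param path MRC or TIFF file.
#' @param q_nyquist_invA reciprocal-space calibration (1/Angstrom at half the
#'   image width); taken from a sidecar `<path>.json` (field
#'   `q_nyquist_invA`) when not supplied.
#' @return A [diffraction_frame()].
#' @export
read_diffraction_frame <- function(path, q_nyquist_invA = NULL) {
  if (is.null(q_nyquist_invA)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      q_nyquist_invA <- meta$q_nyquist_invA
    }
  }
  if (is.null(q_nyquist_invA))
    stop("uncalibrated diffraction frame: supply q_nyquist_invA")
  ext <- tolower(tools::file_ext(path))
  M <- if (ext == "mrc") {
    read_mrc(path)$intensities
  } else if (ext %in% c("tif", "tiff")) {
    tryCatch(tiff::readTIFF(path, as.is = TRUE),
             error = function(e) stop("corrupt input: ", conditionMessage(e)))
  } else {
    stop("corrupt input: unsupported extension '", ext, "'")
  }
  diffraction_frame(M, q_nyquist_invA)
}

#' Write / read an integer label image as 16-bit TIFF
#'
#' Labels 0 (background) to 65535 are stored losslessly.
#'
#' @param label_image integer matrix of region labels.
#' @param path TIFF path.
#' @return `write_label_tiff`: the path, invisibly. `read_label_tiff`: the
#'   integer label matrix.
#' @export
write_label_tiff <- function(label_image, path) {
  if (max(label_image) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(label_image / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  M <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                error = function(e) stop("corrupt input: ",
                                         conditionMessage(e)))
  matrix(as.integer(round(M)), nrow = nrow(M))
}

#' Split a label image into per-region masks
#'
#' @param label_image integer matrix, 0 = background.
#' @return List of [region_mask()], one per positive label present.
#' @export
masks_from_label_image <- function(label_image) {
  labs <- sort(setdiff(unique(as.vector(label_image)), 0L))
  lapply(labs, function(i) region_mask(label_image == i, label = i))
}

#' Write a ratio profile as CSV
#'
#' Columns: `q_invA`, `d_A`, `ratio`, `masked`.
#'
#' @param ratio a `ratio_profile`.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_ratio_csv <- function(ratio, path) {
  utils::write.csv(data.frame(
    q_invA = ratio$q_invA, d_A = ratio$d_A,
    ratio = ratio$ratio, masked = ratio$masked
  ), path, row.names = FALSE)
  invisible(path)
}

#' Read a per-group area table from CSV
#'
#' Expects columns `group` and `area_nm2` (comma-separated, header row,
#' '.' decimal separator).
#'
#' @param path CSV path.
#' @return A data frame with columns `group`, `area_nm2`.
#' @export
read_group_areas_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("group", "area_nm2") %in% names(tab)))
    stop("corrupt input: CSV must have columns 'group' and 'area_nm2'")
  tab
}
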