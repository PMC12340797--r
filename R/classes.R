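#' Micrograph container
#'
#' A calibrated 2D electron micrograph: an intensity matrix (rows = y, columns
#' = x) plus the pixel size in Angstrom per pixel and free-form acquisition
#' metadata (defocus, dose, source file, ...).
#'
#' @param intensities numeric matrix of pixel intensities.
#' @param pixel_size_A pixel size in Angstrom per pixel (> 0).
#' @param metadata named list of acquisition metadata.
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(intensities, pixel_size_A, metadata = list()) {
  intensities <- as.matrix(intensities)
  if (!is.numeric(intensities) || length(intensities) == 0L)
    stop("intensities must be a non-empty numeric matrix")
  if (!is.numeric(pixel_size_A) || length(pixel_size_A) != 1L ||
      !is.finite(pixel_size_A) || pixel_size_A <= 0)
    stop("pixel_size_A must be a single positive number")
  structure(
    list(intensities = intensities, pixel_size_A = as.numeric(pixel_size_A),
         metadata = metadata),
    class = "micrograph"
  )
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px, %.4g A/px\n",
              nrow(x$intensities), ncol(x$intensities), x$pixel_size_A))
  invisible(x)
}

#' Binary region mask for one candidate aggregate
#'
#' Marks the manually (or synthetically) delineated region containing a single
#' aggregate. Must be congruent in shape with its micrograph.
#'
#' @param pixels logical matrix, `TRUE` inside the region.
#' @param label integer region identifier.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(pixels, label = 1L) {
  pixels <- as.matrix(pixels)
  if (is.numeric(pixels)) pixels <- pixels > 0
  if (!is.logical(pixels)) stop("pixels must be logical (or 0/1 numeric)")
  if (!any(pixels)) stop("mask must contain at least one TRUE pixel")
  structure(list(label = as.integer(label), pixels = pixels),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> label %d, %d px of %d x %d\n",
              x$label, sum(x$pixels), nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

#' Electron diffraction frame
#'
#' A 2D diffraction intensity grid with its reciprocal-space calibration: the
#' spatial frequency (Angstrom^-1) reached at half the image width
#' (the Nyquist frequency of the detector at the chosen camera length).
#'
#' @param intensities non-negative numeric matrix.
#' @param q_nyquist_invA spatial frequency in Angstrom^-1 at half the image
#'   width (default 1.75, the 670 mm camera-length calibration).
#' @param camera_length_mm optional camera length, kept as metadata only.
#' @param center_px optional known beam center `c(row, col)` (1-based).
#' @return An object of class `diffraction_frame`.
#' @export
diffraction_frame <- function(intensities, q_nyquist_invA = 1.75,
                              camera_length_mm = NULL, center_px = NULL) {
  intensities <- as.matrix(intensities)
  if (!is.numeric(intensities) || length(intensities) == 0L)
    stop("intensities must be a non-empty numeric matrix")
  if (!is.numeric(q_nyquist_invA) || q_nyquist_invA <= 0)
    stop("q_nyquist_invA must be positive")
  if (!is.null(center_px)) {
    if (length(center_px) != 2L ||
        center_px[1] < 1 || center_px[1] > nrow(intensities) ||
        center_px[2] < 1 || center_px[2] > ncol(intensities))
      stop("center_px must lie inside the grid")
  }
  structure(
    list(intensities = intensities, q_nyquist_invA = as.numeric(q_nyquist_invA),
         camera_length_mm = camera_length_mm, center_px = center_px),
    class = "diffraction_frame"
  )
}

#' @export
print.diffraction_frame <- function(x, ...) {
  cat(sprintf("<diffraction_frame> %d x %d px, q_Nyquist = %.3g 1/A\n",
              nrow(x$intensities), ncol(x$intensities), x$q_nyquist_invA))
  invisible(x)
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %d bins, q in [%.4g, %.4g] 1/A%s\n",
              length(x$q_invA), min(x$q_invA), max(x$q_invA),
              if (is.null(x$normalization_band)) "" else
                sprintf(", normalized on [%.3g, %.3g]",
                        x$normalization_band[1], x$normalization_band[2])))
  invisible(x)
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat(sprintf("<ratio_profile> %d bins (%d masked), d in [%.3g, %.3g] A\n",
              length(x$ratio), sum(x$masked),
              min(x$d_A[!x$masked]), max(x$d_A[!x$masked])))
  invisible(x)
}

#' @export
print.band_summary <- function(x, ...) {
  cat(sprintf("<band_summary> window %.2f-%.2f A: peak at %.3f A, ratio %.3f, band %s\n",
              x$window_d_A[1], x$window_d_A[2], x$peak_d_A, x$peak_ratio,
              if (x$band_present) "PRESENT" else "absent"))
  invisible(x)
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("<fisher_result> OR = %.4g (95%% CI %.3g-%.3g), two-sided p = %.4g\n",
              x$odds_ratio, x$ci_95[1], x$ci_95[2], x$p_two_sided))
  cat(" ", x$method_note, "\n")
  invisible(x)
}
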