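# LDSAED radial-profile analysis.
#
# Frames are centered, radially averaged into equal-width q bins, normalized
# on the 0.094-0.113 1/A band, divided by a matched background profile to
# dampen the non-specific vitreous-ice maxima (~3.71 and ~2.15 A), converted
# to d-spacing, and scanned for the broad OCP-like band in the 2.5-3.2 A
# window. Calibration is linear in pixel radius: q reaches q_nyquist_invA at
# half the image width; camera length is metadata only.

#' Estimate the beam center of a diffraction frame
#'
#' Intensity-weighted centroid over the central quarter of the image, refined
#' by maximizing the correlation between the frame and its 180-degree
#' rotation about the candidate center over a +/-5 px search grid at 0.5 px
#' steps. Centers on the half-pixel grid map the pixel lattice onto itself,
#' so the rotation correlation is computed exactly, without interpolation.
#'
#' @param frame a [diffraction_frame()].
#' @return Numeric `c(row, col)` center (1-based pixel coordinates).
#' @export
find_center <- function(frame) {
  stopifnot(inherits(frame, "diffraction_frame"))
  I <- frame$intensities
  nr <- nrow(I); nc <- ncol(I)
  if (all(I == 0)) stop("no signal: frame is identically zero")
  # centroid over the central quarter (middle half of each dimension)
  ri <- seq.int(floor(nr / 4) + 1L, ceiling(3 * nr / 4))
  ci <- seq.int(floor(nc / 4) + 1L, ceiling(3 * nc / 4))
  Ic <- I[ri, ci, drop = FALSE]
  w <- sum(Ic)
  cand <- if (w > 0) {
    c(sum(rowSums(Ic) * ri) / w, sum(colSums(Ic) * ci) / w)
  } else {
    c((nr + 1) / 2, (nc + 1) / 2)
  }
  # snap to the half-pixel grid, then search +/-5 px at 0.5 px steps
  cand <- round(cand * 2) / 2
  offs <- seq(-5, 5, by = 0.5)
  best <- cand; best_score <- -Inf
  for (dy in offs) for (dx in offs) {
    cy <- cand[1] + dy; cx <- cand[2] + dx
    if (cy < 1 || cy > nr || cx < 1 || cx > nc) next
    Y <- round(2 * cy); X <- round(2 * cx)
    i0 <- max(1L, Y - nr); i1 <- min(nr, Y - 1L)
    j0 <- max(1L, X - nc); j1 <- min(nc, X - 1L)
    if (i0 > i1 || j0 > j1) next
    A <- I[i0:i1, j0:j1, drop = FALSE]
    B <- I[Y - (i0:i1), X - (j0:j1), drop = FALSE]
    if (length(A) < 16L) next
    s <- suppressWarnings(stats::cor(as.vector(A), as.vector(B)))
    if (is.na(s)) next
    if (s > best_score) { best_score <- s; best <- c(cy, cx) }
  }
  best
}

#' Radially average a diffraction frame
#'
#' Each pixel at Euclidean radius `r` (pixel centers) from `center` maps to
#' `q = r * q_nyquist_invA / (half image width)`; bins are equal-width in q
#' from 0 to `q_nyquist_invA`, and pixels beyond the Nyquist frequency are
#' dropped. Bin intensity is the arithmetic mean over its pixels.
#'
#' @param frame a [diffraction_frame()].
#' @param center `c(row, col)` beam center; defaults to [find_center()].
#' @param n_bins number of q bins (>= 2); default one bin per pixel of radial
#'   extent (half the image width).
#' @param central_exclusion_q bins below this q (1/Angstrom) are excluded
#'   from band normalization and band detection downstream (beam-stop /
#'   saturated region); default 0.03.
#' @return An object of class `radial_profile` with fields `q_invA` (bin
#'   centers), `mean_intensity` (NA for empty bins), `n_pixels`,
#'   `normalization_band` (NULL until normalized), `central_exclusion_q` and
#'   `q_nyquist_invA`.
#' @export
radial_average <- function(frame, center = NULL, n_bins = NULL,
                           central_exclusion_q = 0.03) {
  stopifnot(inherits(frame, "diffraction_frame"))
  I <- frame$intensities
  nr <- nrow(I); nc <- ncol(I)
  if (is.null(center)) center <- find_center(frame)
  if (center[1] < 1 || center[1] > nr || center[2] < 1 || center[2] > nc)
    stop("center must lie inside the grid")
  if (is.null(n_bins)) n_bins <- max(2L, floor(nc / 2))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be at least 2")
  q_nyq <- frame$q_nyquist_invA
  rr <- sqrt(outer((seq_len(nr) - center[1])^2, (seq_len(nc) - center[2])^2, `+`))
  q <- rr * q_nyq / (nc / 2)
  keep <- q <= q_nyq
  qk <- q[keep]; vk <- I[keep]
  dq <- q_nyq / n_bins
  bin <- pmin(n_bins, floor(qk / dq) + 1L)
  n_pixels <- tabulate(bin, nbins = n_bins)
  sums <- as.numeric(rowsum(vk, bin, reorder = TRUE))
  # rowsum drops empty bins; rebuild a full-length vector
  present <- sort(unique(bin))
  full <- numeric(n_bins); full[present] <- sums
  mean_intensity <- ifelse(n_pixels > 0, full / pmax(n_pixels, 1L), NA_real_)
  structure(list(
    q_invA = (seq_len(n_bins) - 0.5) * dq,
    mean_intensity = mean_intensity,
    n_pixels = n_pixels,
    normalization_band = NULL,
    central_exclusion_q = central_exclusion_q,
    q_nyquist_invA = q_nyq
  ), class = "radial_profile")
}

#' Normalize a radial profile on a q band
#'
#' Divides all bin intensities by the mean intensity over the occupied bins
#' inside `[q_lo, q_hi]` (default 0.094--0.113 1/Angstrom), making full,
#' partial and background profiles mutually comparable before the ratio.
#'
#' @param profile a `radial_profile`.
#' @param q_lo,q_hi normalization band limits in 1/Angstrom.
#' @return The profile, normalized, with `normalization_band` recorded.
#' @export
normalize_band <- function(profile, q_lo = 0.094, q_hi = 0.113) {
  stopifnot(inherits(profile, "radial_profile"))
  if (q_lo >= q_hi) stop("normalization band must have q_lo < q_hi")
  sel <- profile$q_invA >= q_lo & profile$q_invA <= q_hi &
    profile$n_pixels > 0 & profile$q_invA >= profile$central_exclusion_q
  if (!any(sel)) stop("normalization band unoccupied")
  band_mean <- mean(profile$mean_intensity[sel])
  if (!is.finite(band_mean) || band_mean == 0)
    stop("degenerate normalization: band mean is zero")
  profile$mean_intensity <- profile$mean_intensity / band_mean
  profile$normalization_band <- c(q_lo, q_hi)
  profile
}

#' Divide a target radial profile by a background profile
#'
#' Computes the per-bin intensity ratio that dampens structure shared by
#' target and background (the vitreous-ice maxima). Bins unoccupied in either
#' profile, or whose background falls below a floor, are masked rather than
#' fabricated. A d-spacing axis `d = 1/q` is attached.
#'
#' @param target,background `radial_profile`s with identical binning and
#'   normalization band.
#' @param background_floor_frac background bins below `background_floor_frac`
#'   times the background's band mean (1 after normalization) are masked;
#'   default 1e-6.
#' @return An object of class `ratio_profile` with fields `q_invA`, `d_A`,
#'   `ratio`, `masked`, `central_exclusion_q`, `normalization_band`.
#' @export
background_ratio <- function(target, background, background_floor_frac = 1e-6) {
  stopifnot(inherits(target, "radial_profile"),
            inherits(background, "radial_profile"))
  if (length(target$q_invA) != length(background$q_invA) ||
      max(abs(target$q_invA - background$q_invA)) > 1e-9)
    stop("incompatible profiles: q binning differs")
  if (!identical(is.null(target$normalization_band),
                 is.null(background$normalization_band)) ||
      (!is.null(target$normalization_band) &&
       max(abs(target$normalization_band - background$normalization_band)) > 1e-12))
    stop("incompatible profiles: normalization bands differ")
  band_mean_bg <- if (is.null(background$normalization_band)) {
    sel <- background$n_pixels > 0
    mean(background$mean_intensity[sel])
  } else 1
  floor_val <- background_floor_frac * band_mean_bg
  masked <- target$n_pixels == 0 | background$n_pixels == 0 |
    !is.finite(target$mean_intensity) | !is.finite(background$mean_intensity) |
    background$mean_intensity < floor_val
  ratio <- rep(NA_real_, length(target$q_invA))
  ratio[!masked] <- target$mean_intensity[!masked] /
    background$mean_intensity[!masked]
  d_A <- ifelse(target$q_invA > 0, 1 / target$q_invA, Inf)
  masked <- masked | !is.finite(d_A)
  structure(list(
    q_invA = target$q_invA, d_A = d_A, ratio = ratio, masked = masked,
    central_exclusion_q = max(target$central_exclusion_q,
                              background$central_exclusion_q),
    normalization_band = target$normalization_band
  ), class = "ratio_profile")
}

#' Detect the diagnostic d-spacing band in a ratio profile
#'
#' Applies a centered moving-average smoothing to the unmasked ratio values
#' and locates the smoothed maximum within the d window (default 2.5--3.2
#' Angstrom, the OCP-like signature). Ties are broken toward the lowest d.
#' The band is called present when the smoothed peak ratio exceeds
#' `1 + margin`.
#'
#' @param ratio a `ratio_profile`.
#' @param window_d_A `c(lo, hi)` d window in Angstrom.
#' @param smooth_width_bins moving-average width in bins (default 3).
#' @param margin presence margin above ratio 1 (default 0.05).
#' @return An object of class `band_summary` with `window_d_A`, `peak_d_A`,
#'   `peak_ratio`, `band_present`.
#' @export
detect_band <- function(ratio, window_d_A = c(2.5, 3.2),
                        smooth_width_bins = 3L, margin = 0.05) {
  stopifnot(inherits(ratio, "ratio_profile"))
  if (window_d_A[1] >= window_d_A[2]) stop("window must have lo < hi")
  w <- max(1L, as.integer(smooth_width_bins))
  h_lo <- w %/% 2L; h_hi <- (w - 1L) %/% 2L
  n <- length(ratio$ratio)
  usable <- !ratio$masked & ratio$q_invA >= ratio$central_exclusion_q
  smoothed <- rep(NA_real_, n)
  for (i in which(usable)) {
    idx <- max(1L, i - h_lo):min(n, i + h_hi)
    idx <- idx[usable[idx]]
    smoothed[i] <- mean(ratio$ratio[idx])
  }
  sel <- which(usable & ratio$d_A >= window_d_A[1] & ratio$d_A <= window_d_A[2])
  if (length(sel) == 0L) stop("window unoccupied")
  sel <- sel[order(ratio$d_A[sel])]   # ties break toward lowest d
  k <- sel[which.max(smoothed[sel])]
  peak_ratio <- smoothed[k]
  structure(list(
    window_d_A = window_d_A,
    peak_d_A = ratio$d_A[k],
    peak_ratio = peak_ratio,
    band_present = is.finite(peak_ratio) && peak_ratio > 1 + margin,
    margin = margin,
    smooth_width_bins = w
  ), class = "band_summary")
}

#' Full / partial / background diffraction analysis
#'
#' Mirrors the acquisition design: one frame with an aggregate centered in
#' the selected area ("full"), one where only a small amount of aggregate is
#' visible ("partial"), and a nearby control background region. Each frame is
#' centered, radially averaged and band-normalized; full and partial profiles
#' are then divided by the background, and the diagnostic band is summarized
#' on the full-frame ratio.
#'
#' @param full,partial,background [diffraction_frame()]s sharing shape and
#'   q calibration.
#' @param n_bins bins for [radial_average()] (default: half image width).
#' @param q_lo,q_hi normalization band (1/Angstrom).
#' @param window_d_A band-detection window in Angstrom.
#' @param smooth_width_bins,margin see [detect_band()].
#' @return A list with `full_ratio`, `partial_ratio` (both `ratio_profile`)
#'   and `band` (the full-frame `band_summary`).
#' @export
full_partial_background_run <- function(full, partial, background,
                                        n_bins = NULL,
                                        q_lo = 0.094, q_hi = 0.113,
                                        window_d_A = c(2.5, 3.2),
                                        smooth_width_bins = 3L,
                                        margin = 0.05) {
  frames <- list(full = full, partial = partial, background = background)
  dims <- lapply(frames, function(f) dim(f$intensities))
  qs <- vapply(frames, function(f) f$q_nyquist_invA, numeric(1))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])) ||
      max(qs) - min(qs) > 1e-12)
    stop("frames do not share calibration")
  profs <- lapply(frames, function(f) {
    normalize_band(radial_average(f, center = find_center(f), n_bins = n_bins),
                   q_lo = q_lo, q_hi = q_hi)
  })
  full_ratio <- background_ratio(profs$full, profs$background)
  partial_ratio <- background_ratio(profs$partial, profs$background)
  band <- detect_band(full_ratio, window_d_A = window_d_A,
                      smooth_width_bins = smooth_width_bins, margin = margin)
  list(full_ratio = full_ratio, partial_ratio = partial_ratio, band = band)
}
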