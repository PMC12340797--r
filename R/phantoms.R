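# Synthetic phantoms with exact ground truth.
#
# Sheet aggregates are ~1.85 nm thick calcium-phosphate plates that project as
# curvilinear dark strokes in 2D micrographs; here they are rendered as
# constant-width random-walk strokes confined to an elliptical membrane-bounded
# region, depressed below a flat background. Diffraction phantoms are radially
# symmetric frames with Gaussian bands in q plus the two vitreous-ice maxima.

#' Specification for a synthetic sheet-aggregate micrograph
#'
#' @param image_size_px integer pair `c(rows, cols)`, each >= 32.
#' @param pixel_size_A pixel size in Angstrom/pixel (default 3.21, the
#'   area-measurement acquisition setting).
#' @param n_aggregates number of aggregates to place (>= 0).
#' @param sheet_thickness_nm rendered stroke width in nm (default 1.85, the
#'   plate thickness; apparent widths up to ~7 nm occur in projection and can
#'   be emulated by raising this).
#' @param aggregate_contrast intensity depression of aggregate pixels below
#'   background (dimensionless intensity units).
#' @param background_level flat background intensity.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param blur_sigma_px optional Gaussian point-spread blur (0 = none).
#' @param stroke_shape `"walk"` for curvilinear random-walk strokes (the
#'   realistic rendering) or `"rect"` for an axis-aligned rectangle of exactly
#'   `stroke_length_px x width` pixels (useful for exact-area checks).
#' @param stroke_length_px stroke length in pixels.
#' @param mask_margin_px dilation radius (px) used to derive each region mask
#'   from the true aggregate pixels, emulating a hand-drawn mask that hugs the
#'   aggregate with a small background margin.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return A validated list of class `sheet_phantom_spec`.
#' @export
sheet_phantom_spec <- function(image_size_px = c(256L, 256L),
                               pixel_size_A = 3.21,
                               n_aggregates = 3L,
                               sheet_thickness_nm = 1.85,
                               aggregate_contrast = 1,
                               background_level = 10,
                               noise_sigma = 0.1,
                               blur_sigma_px = 0,
                               stroke_shape = c("walk", "rect"),
                               stroke_length_px = 60L,
                               mask_margin_px = 4L,
                               seed = 1L) {
  stroke_shape <- match.arg(stroke_shape)
  image_size_px <- as.integer(image_size_px)
  if (length(image_size_px) != 2L || any(image_size_px < 32L))
    stop("image_size_px must be a pair with each dimension >= 32")
  if (pixel_size_A <= 0) stop("pixel_size_A must be positive")
  if (sheet_thickness_nm <= 0) stop("sheet_thickness_nm must be positive")
  if (n_aggregates < 0) stop("n_aggregates must be non-negative")
  if (aggregate_contrast <= 0) stop("aggregate_contrast must be positive")
  if (noise_sigma < 0 || blur_sigma_px < 0)
    stop("noise_sigma and blur_sigma_px must be non-negative")
  structure(list(
    image_size_px = image_size_px, pixel_size_A = pixel_size_A,
    n_aggregates = as.integer(n_aggregates),
    sheet_thickness_nm = sheet_thickness_nm,
    aggregate_contrast = aggregate_contrast,
    background_level = background_level,
    noise_sigma = noise_sigma, blur_sigma_px = blur_sigma_px,
    stroke_shape = stroke_shape,
    stroke_length_px = as.integer(stroke_length_px),
    mask_margin_px = as.integer(mask_margin_px),
    seed = as.integer(seed)
  ), class = "sheet_phantom_spec")
}

# width of the rendered stroke in pixels
stroke_width_px <- function(spec) {
  max(1L, as.integer(round(spec$sheet_thickness_nm * 10 / spec$pixel_size_A)))
}

# Mark all pixels within width/2 of any point of a polyline (row, col).
stamp_polyline <- function(nr, nc, pts, width_px) {
  hit <- matrix(FALSE, nr, nc)
  r <- width_px / 2
  for (k in seq_len(nrow(pts))) {
    y <- pts[k, 1]; x <- pts[k, 2]
    i0 <- max(1L, floor(y - r)); i1 <- min(nr, ceiling(y + r))
    j0 <- max(1L, floor(x - r)); j1 <- min(nc, ceiling(x + r))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    d2 <- outer((ii - y)^2, (jj - x)^2, `+`)
    hit[ii, jj] <- hit[ii, jj] | (d2 <= r^2)
  }
  hit
}

# Random-walk stroke confined to an ellipse (semi-axes ax = c(ar, ac)).
walk_stroke <- function(nr, nc, center, ax, n_steps, width_px) {
  inner <- pmax(ax - width_px / 2 - 1, 1)
  ell <- function(p) sum(((p - center) / inner)^2)
  pos <- center + c(stats::runif(1, -1, 1), stats::runif(1, -1, 1))
  heading <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(NA_real_, n_steps + 1L, 2L)
  pts[1L, ] <- pos
  for (k in seq_len(n_steps)) {
    heading <- heading + stats::rnorm(1, 0, 0.25)
    cand <- pos + c(sin(heading), cos(heading))
    if (ell(cand) > 1) {       # steer back toward the membrane center
      heading <- atan2(center[1] - pos[1], center[2] - pos[2]) +
        stats::rnorm(1, 0, 0.3)
      cand <- pos + c(sin(heading), cos(heading))
    }
    pos <- cand
    pts[k + 1L, ] <- pos
  }
  stamp_polyline(nr, nc, pts, width_px)
}

rect_stroke <- function(nr, nc, center, len_px, width_px) {
  hit <- matrix(FALSE, nr, nc)
  i0 <- round(center[1]) - (width_px %/% 2L)
  j0 <- round(center[2]) - (len_px %/% 2L)
  ii <- i0:(i0 + width_px - 1L); jj <- j0:(j0 + len_px - 1L)
  if (any(ii < 1L) || any(ii > nr) || any(jj < 1L) || any(jj > nc))
    return(hit)
  hit[ii, jj] <- TRUE
  hit
}

#' Generate a synthetic sheet-aggregate micrograph with ground truth
#'
#' Places `n_aggregates` non-overlapping strokes (sheet cross-sections) inside
#' elliptical membrane-bounded regions, depresses their pixels by
#' `aggregate_contrast` below the flat background, then applies optional blur
#' and additive Gaussian noise. The ground truth records the exact set of
#' depressed pixels (before blur and noise), a label image, and per-aggregate
#' region masks obtained by dilating each aggregate by `mask_margin_px`.
#'
#' @param spec a [sheet_phantom_spec()].
#' @return A list with elements `micrograph` (a [micrograph()]) and `truth`, a
#'   `sheet_ground_truth` list with `label_image`, `masks` (list of
#'   [region_mask()]), `true_area_px`, `true_area_nm2` and `pixel_size_A`.
#'   Areas satisfy `true_area_nm2 = true_area_px * (pixel_size_A / 10)^2`.
#' @export
generate_sheet_micrograph <- function(spec) {
  stopifnot(inherits(spec, "sheet_phantom_spec"))
  withr::with_seed(spec$seed, {
    nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
    wpx <- stroke_width_px(spec)
    margin <- spec$mask_margin_px
    border <- margin + 2L
    label_img <- matrix(0L, nr, nc)
    # exclusion map keeps dilated masks of distinct aggregates disjoint
    excl <- matrix(FALSE, nr, nc)
    excl_brush <- EBImage::makeBrush(2L * (2L * margin + 1L) + 1L, "disc")
    if (spec$n_aggregates > 0L) {
      for (i in seq_len(spec$n_aggregates)) {
        placed <- FALSE
        for (try in seq_len(200L)) {
          L <- spec$stroke_length_px
          ax <- stats::runif(2, 0.3, 0.55) * L + wpx + 2
          lo <- border + ax; hi <- c(nr, nc) - border - ax
          if (any(lo >= hi)) next
          ctr <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
          px <- if (spec$stroke_shape == "rect")
            rect_stroke(nr, nc, ctr, L, wpx)
          else
            walk_stroke(nr, nc, ctr, ax, L, wpx)
          if (!any(px)) next
          # stay clear of borders and of previously claimed territory
          idx <- which(px, arr.ind = TRUE)
          if (min(idx[, 1]) <= border || max(idx[, 1]) > nr - border ||
              min(idx[, 2]) <= border || max(idx[, 2]) > nc - border) next
          if (any(excl[px])) next
          label_img[px] <- i
          excl <- excl | (EBImage::dilate(px * 1, excl_brush) > 0)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("placement failure: could not place aggregate ", i,
               " without overlap")
      }
    }
    img <- matrix(spec$background_level, nr, nc)
    img[label_img > 0L] <- spec$background_level - spec$aggregate_contrast
    if (spec$blur_sigma_px > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = spec$blur_sigma_px))
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sigma), nr, nc)

    labels <- seq_len(spec$n_aggregates)
    mask_brush <- if (margin > 0L) EBImage::makeBrush(2L * margin + 1L, "disc")
    masks <- lapply(labels, function(i) {
      reg <- label_img == i
      if (!is.null(mask_brush)) reg <- EBImage::dilate(reg * 1, mask_brush) > 0
      region_mask(reg, label = i)
    })
    area_px <- vapply(labels, function(i) sum(label_img == i), integer(1))
    truth <- structure(list(
      label_image = label_img,
      masks = masks,
      true_area_px = area_px,
      true_area_nm2 = area_px * (spec$pixel_size_A / 10)^2,
      pixel_size_A = spec$pixel_size_A
    ), class = "sheet_ground_truth")
    list(
      micrograph = micrograph(img, spec$pixel_size_A,
                              metadata = list(phantom = TRUE, seed = spec$seed,
                                              contrast = spec$aggregate_contrast,
                                              noise_sigma = spec$noise_sigma)),
      truth = truth
    )
  })
}

#' Specification for a synthetic diffraction frame
#'
#' Bands and ice peaks are given in d-spacing: each is `c(center_d_A,
#' width_d_A, amplitude)` where `width_d_A` is the Gaussian sigma in d; it is
#' converted to a sigma in spatial frequency as `width_d / d^2` (first-order
#' |dq/dd| at the band center).
#'
#' @param image_size_px integer pair, each >= 32.
#' @param q_nyquist_invA spatial frequency (1/Angstrom) at half the image
#'   width; default 1.75 (670 mm camera length).
#' @param bands list of `c(center_d_A, width_d_A, amplitude)` triples for the
#'   material bands; default one broad band at 2.85 Angstrom emulating the
#'   OCP-like 2.5--3.2 Angstrom signature.
#' @param ice_peaks like `bands`, for the vitreous-ice maxima; default 3.71
#'   and 2.15 Angstrom.
#' @param center_offset_px signed `c(row, col)` offset of the beam center from
#'   the geometric image center.
#' @param background_level non-negative flat background.
#' @param poisson_noise if `TRUE`, replace intensities by Poisson draws.
#' @param seed integer RNG seed.
#' @return A validated list of class `diffraction_phantom_spec`.
#' @export
diffraction_phantom_spec <- function(image_size_px = c(256L, 256L),
                                     q_nyquist_invA = 1.75,
                                     bands = list(c(2.85, 0.35, 2)),
                                     ice_peaks = list(c(3.71, 0.30, 2),
                                                      c(2.15, 0.30, 2)),
                                     center_offset_px = c(0, 0),
                                     background_level = 10,
                                     poisson_noise = FALSE,
                                     seed = 1L) {
  image_size_px <- as.integer(image_size_px)
  if (length(image_size_px) != 2L || any(image_size_px < 32L))
    stop("image_size_px must be a pair with each dimension >= 32")
  if (q_nyquist_invA <= 0) stop("q_nyquist_invA must be positive")
  if (background_level < 0) stop("background_level must be non-negative")
  chk <- function(trip, what) {
    for (b in trip) {
      if (length(b) != 3L) stop(what, " entries must be (center_d_A, width_d_A, amplitude)")
      if (b[1] <= 0 || 1 / b[1] >= q_nyquist_invA)
        stop("band beyond Nyquist: d = ", b[1], " A maps outside (0, q_Nyquist)")
      if (b[2] <= 0) stop(what, " width must be positive")
      if (b[3] < 0) stop(what, " amplitude must be non-negative")
    }
  }
  chk(bands, "bands"); chk(ice_peaks, "ice_peaks")
  structure(list(
    image_size_px = image_size_px, q_nyquist_invA = q_nyquist_invA,
    bands = bands, ice_peaks = ice_peaks,
    center_offset_px = as.numeric(center_offset_px),
    background_level = background_level,
    poisson_noise = isTRUE(poisson_noise), seed = as.integer(seed)
  ), class = "diffraction_phantom_spec")
}

#' Generate a radially symmetric synthetic diffraction frame
#'
#' Intensity at pixel radius r from the (offset) beam center is
#' `background_level` plus the sum of Gaussian bands evaluated at
#' `q(r) = r * q_nyquist_invA / (half image width)`; optional Poisson noise is
#' applied last.
#'
#' @param spec a [diffraction_phantom_spec()].
#' @return A list with `frame` (a [diffraction_frame()]) and `truth` holding
#'   `true_center_px`, `true_band_centers_d_A` (material bands) and
#'   `true_ice_centers_d_A`.
#' @export
generate_diffraction_frame <- function(spec) {
  stopifnot(inherits(spec, "diffraction_phantom_spec"))
  withr::with_seed(spec$seed, {
    nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
    ctr <- c((nr + 1) / 2, (nc + 1) / 2) + spec$center_offset_px
    if (ctr[1] < 1 || ctr[1] > nr || ctr[2] < 1 || ctr[2] > nc)
      stop("center_offset_px places the beam center outside the grid")
    q_of_r <- spec$q_nyquist_invA / (nc / 2)
    rr <- outer((seq_len(nr) - ctr[1])^2, (seq_len(nc) - ctr[2])^2, `+`)
    q <- sqrt(rr) * q_of_r
    img <- matrix(spec$background_level, nr, nc)
    for (b in c(spec$bands, spec$ice_peaks)) {
      qc <- 1 / b[1]
      sq <- b[2] / b[1]^2
      img <- img + b[3] * exp(-(q - qc)^2 / (2 * sq^2))
    }
    if (spec$poisson_noise)
      img <- matrix(as.numeric(stats::rpois(nr * nc, img)), nr, nc)
    truth <- list(
      true_center_px = ctr,
      true_band_centers_d_A = vapply(spec$bands, `[`, numeric(1), 1L),
      true_ice_centers_d_A = vapply(spec$ice_peaks, `[`, numeric(1), 1L)
    )
    list(frame = diffraction_frame(img, spec$q_nyquist_invA),
         truth = truth)
  })
}

#' Default group-area conditions
#'
#' The four culture conditions of the area experiment, with their reported
#' sample sizes and median areas (nm^2): 1 DIV Neurobasal (n = 107, median
#' 99318), 1 DIV Neurobasal + 10% FBS (n = 100, 88134), 1 DIV F-12 + 10% FBS
#' (n = 94, 66782) and 20 DIV Neurobasal (n = 94, 56475).
#'
#' @param spread log-scale standard deviation of the log-normal area law
#'   (default 0.6, giving an upper/lower quartile ratio of ~2.3, a realistic
#'   dispersion for per-aggregate areas).
#' @return A list of group specifications for [generate_group_areas()].
#' @export
default_group_specs <- function(spread = 0.6) {
  list(
    list(label = "1DIV_NB",      median_nm2 = 99318, spread = spread, n = 107L),
    list(label = "1DIV_NB_FBS",  median_nm2 = 88134, spread = spread, n = 100L),
    list(label = "1DIV_F12_FBS", median_nm2 = 66782, spread = spread, n = 94L),
    list(label = "20DIV_NB",     median_nm2 = 56475, spread = spread, n = 94L)
  )
}

#' Generate synthetic per-group aggregate-area tables
#'
#' Draws each group's areas from a log-normal law with the requested median
#' (`meanlog = log(median_nm2)`, `sdlog = spread`).
#'
#' @param group_specs list of `list(label, median_nm2, spread, n)`; defaults
#'   to [default_group_specs()].
#' @param seed integer RNG seed.
#' @return A data frame with columns `group` and `area_nm2`.
#' @export
generate_group_areas <- function(group_specs = default_group_specs(),
                                 seed = 1L) {
  for (g in group_specs) {
    if (is.null(g$label) || is.null(g$median_nm2) || is.null(g$spread) ||
        is.null(g$n))
      stop("each group spec needs label, median_nm2, spread and n")
    if (g$median_nm2 <= 0) stop("median_nm2 must be positive")
    if (g$spread < 0) stop("spread must be non-negative")
    if (g$n < 1) stop("n must be at least 1")
  }
  withr::with_seed(as.integer(seed), {
    do.call(rbind, lapply(group_specs, function(g) {
      data.frame(
        group = rep(g$label, g$n),
        area_nm2 = stats::rlnorm(g$n, meanlog = log(g$median_nm2),
                                 sdlog = g$spread),
        stringsAsFactors = FALSE
      )
    }))
  })
}
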