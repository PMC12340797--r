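phantom_pair <- function(offset = c(0, 0), band_amp = 2, seed = 1,
                         poisson = FALSE, size = 256) {
  target <- generate_diffraction_frame(diffraction_phantom_spec(
    image_size_px = c(size, size),
    bands = if (band_amp > 0) list(c(2.85, 0.35, band_amp)) else list(),
    center_offset_px = offset, poisson_noise = poisson, seed = seed))
  background <- generate_diffraction_frame(diffraction_phantom_spec(
    image_size_px = c(size, size), bands = list(),
    center_offset_px = offset, poisson_noise = poisson, seed = seed + 1000))
  list(target = target, background = background)
}

test_that("beam center is recovered on symmetric and offset phantoms", {
  ctr0 <- generate_diffraction_frame(diffraction_phantom_spec(seed = 1))
  found0 <- find_center(ctr0$frame)
  expect_lt(max(abs(found0 - ctr0$truth$true_center_px)), 0.5 + 1e-12)
  off <- generate_diffraction_frame(
    diffraction_phantom_spec(center_offset_px = c(3, -2), seed = 2))
  found <- find_center(off$frame)
  expect_lt(max(abs(found - off$truth$true_center_px)), 0.5 + 1e-12)
})

test_that("centroid of a uniform frame is the geometric center", {
  fr <- diffraction_frame(matrix(1, 64, 64))
  expect_equal(find_center(fr), c(65 / 2, 65 / 2))
  expect_error(find_center(diffraction_frame(matrix(0, 16, 16))), "no signal")
})

test_that("radial average of a uniform frame is flat and conserves pixels", {
  fr <- diffraction_frame(matrix(3.5, 64, 64), q_nyquist_invA = 1.75)
  ctr <- c(65 / 2, 65 / 2)
  prof <- radial_average(fr, center = ctr, n_bins = 32)
  expect_true(all(prof$mean_intensity[prof$n_pixels > 0] == 3.5))
  # conservation: binned pixels = pixels with q <= q_nyquist
  rr <- sqrt(outer((1:64 - ctr[1])^2, (1:64 - ctr[2])^2, `+`))
  q <- rr * 1.75 / 32
  expect_identical(sum(prof$n_pixels), sum(q <= 1.75))
})

test_that("bin means equal a brute-force per-pixel accumulation", {
  withr::with_seed(5, {
    I <- matrix(runif(32 * 32, 0, 10), 32, 32)
  })
  fr <- diffraction_frame(I, q_nyquist_invA = 1.75)
  ctr <- c(17, 16.5)
  prof <- radial_average(fr, center = ctr, n_bins = 12)
  oracle <- oracle_radial(I, ctr, 1.75, 12)
  expect_identical(prof$n_pixels, oracle$counts)
  expect_equal(prof$mean_intensity, oracle$mean)
})

test_that("the radial profile is invariant under 90-degree rotation", {
  ph <- phantom_pair(seed = 3, poisson = TRUE, size = 128)
  I <- ph$target$frame$intensities
  I90 <- t(I)[, nrow(I):1]               # rotate about the geometric center
  p1 <- radial_average(diffraction_frame(I), center = c(64.5, 64.5))
  p2 <- radial_average(diffraction_frame(I90), center = c(64.5, 64.5))
  expect_identical(p1$n_pixels, p2$n_pixels)
  expect_equal(p1$mean_intensity, p2$mean_intensity)
})

test_that("q calibration maps 0.75 x Nyquist to the matching d-spacing", {
  ph <- phantom_pair(seed = 1)
  prof <- radial_average(ph$target$frame,
                         center = ph$target$truth$true_center_px)
  dq <- prof$q_invA[2] - prof$q_invA[1]
  k <- which.min(abs(prof$q_invA - 0.75 * 1.75))
  expect_lt(abs(1 / prof$q_invA[k] - 1 / (0.75 * 1.75)), 1 / 0.75 / 1.75 * dq)
})

test_that("band normalization rescales to unit band mean and is idempotent", {
  ph <- phantom_pair(seed = 1)
  prof <- radial_average(ph$target$frame,
                         center = ph$target$truth$true_center_px)
  norm <- normalize_band(prof)
  sel <- norm$q_invA >= 0.094 & norm$q_invA <= 0.113 & norm$n_pixels > 0
  expect_equal(mean(norm$mean_intensity[sel]), 1, tolerance = 1e-9)
  expect_equal(normalize_band(norm)$mean_intensity, norm$mean_intensity)
  # scale invariance of the normalized profile
  scaled <- prof; scaled$mean_intensity <- prof$mean_intensity * 37
  expect_equal(normalize_band(scaled)$mean_intensity, norm$mean_intensity)
  # background-only band: normalized background level is ~1
  bg <- normalize_band(radial_average(ph$background$frame,
                                      center = ph$background$truth$true_center_px))
  mid <- bg$q_invA > 0.6 & bg$q_invA < 0.8
  expect_equal(mean(bg$mean_intensity[mid]), 1, tolerance = 0.01)
  expect_error(normalize_band(prof, 2, 3), "unoccupied")
})

test_that("background ratio is 1 for identical profiles and rejects mismatches", {
  ph <- phantom_pair(seed = 2)
  prof <- normalize_band(radial_average(ph$target$frame,
                                        center = ph$target$truth$true_center_px))
  rat <- background_ratio(prof, prof)
  expect_true(all(abs(rat$ratio[!rat$masked] - 1) < 1e-12))
  other <- normalize_band(radial_average(ph$target$frame,
                                         center = ph$target$truth$true_center_px,
                                         n_bins = 100))
  expect_error(background_ratio(prof, other), "incompatible profiles")
})

test_that("background division suppresses shared ice peaks but keeps the band", {
  ph <- phantom_pair(seed = 4)
  tp <- normalize_band(radial_average(ph$target$frame,
                                      center = ph$target$truth$true_center_px))
  bp <- normalize_band(radial_average(ph$background$frame,
                                      center = ph$background$truth$true_center_px))
  rat <- background_ratio(tp, bp)
  at <- function(d) rat$ratio[which.min(abs(rat$d_A - d))]
  expect_lt(abs(at(3.71) - 1), 0.05)
  expect_lt(abs(at(2.15) - 1), 0.05)
  expect_gt(at(2.85), 1.05)
})

test_that("band detection localizes the injected band and rejects null cases", {
  ph <- phantom_pair(seed = 6)
  tp <- normalize_band(radial_average(ph$target$frame,
                                      center = ph$target$truth$true_center_px))
  bp <- normalize_band(radial_average(ph$background$frame,
                                      center = ph$background$truth$true_center_px))
  rat <- background_ratio(tp, bp)
  bs <- detect_band(rat)
  # one-bin tolerance: bin width in d at the band position
  k <- which.min(abs(rat$d_A - bs$peak_d_A))
  dq <- rat$q_invA[2] - rat$q_invA[1]
  d_bin_width <- dq / rat$q_invA[k]^2
  expect_true(bs$band_present)
  expect_lt(abs(bs$peak_d_A - 2.85), d_bin_width)
  # flat ratio: no band
  flat <- background_ratio(bp, bp)
  expect_false(detect_band(flat)$band_present)
  # ice-only target with matched background: no band in the 2.5-3.2 window
  ice <- phantom_pair(seed = 7, band_amp = 0)
  ip <- normalize_band(radial_average(ice$target$frame,
                                      center = ice$target$truth$true_center_px))
  expect_false(detect_band(background_ratio(ip, bp))$band_present)
  # fully masked window errors
  blocked <- rat; blocked$masked[blocked$d_A >= 2.5 & blocked$d_A <= 3.2] <- TRUE
  expect_error(detect_band(blocked), "window unoccupied")
})

test_that("full/partial/background run mirrors the acquisition design", {
  full <- generate_diffraction_frame(diffraction_phantom_spec(
    bands = list(c(2.85, 0.35, 2)), center_offset_px = c(2, -1), seed = 1))
  partial <- generate_diffraction_frame(diffraction_phantom_spec(
    bands = list(c(2.85, 0.35, 0.5)), center_offset_px = c(-1, 2), seed = 2))
  background <- generate_diffraction_frame(diffraction_phantom_spec(
    bands = list(), center_offset_px = c(1, 1), seed = 3))
  res <- full_partial_background_run(full$frame, partial$frame,
                                     background$frame)
  expect_true(res$band$band_present)
  at <- function(r, d) r$ratio[which.min(abs(r$d_A - d))]
  expect_gt(at(res$full_ratio, 2.85), at(res$partial_ratio, 2.85))
  # identical frames: both ratios are 1 everywhere
  same <- full_partial_background_run(full$frame, full$frame, full$frame)
  expect_true(all(abs(same$full_ratio$ratio[!same$full_ratio$masked] - 1) < 1e-12))
  # the largest d corresponds to the lowest occupied q bin
  occ <- which(!res$full_ratio$masked)
  expect_identical(which.max(res$full_ratio$d_A[occ]), which.min(occ * 1))
  # calibration mismatch is rejected
  small <- diffraction_frame(matrix(1, 64, 64))
  expect_error(full_partial_background_run(full$frame, partial$frame, small),
               "calibration")
})
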