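make_micrograph <- function(M, apix = 3.21) micrograph(M, apix)

test_that("masked_pixels returns exactly the masked intensities, row-major", {
  M <- matrix(as.numeric(1:12), nrow = 3, byrow = TRUE)  # rows 1:4, 5:8, 9:12
  mg <- make_micrograph(M)
  full <- region_mask(matrix(TRUE, 3, 4))
  expect_identical(masked_pixels(mg, full), as.numeric(1:12))
  single <- matrix(FALSE, 3, 4); single[2, 3] <- TRUE
  expect_identical(masked_pixels(mg, region_mask(single)), M[2, 3])
  expect_error(masked_pixels(mg, region_mask(matrix(TRUE, 4, 3))),
               "incongruent mask")
})

test_that("masked pixels of a noiseless phantom stroke are all at the depressed level", {
  spec <- sheet_phantom_spec(n_aggregates = 1, noise_sigma = 0,
                             stroke_shape = "rect", stroke_length_px = 40,
                             sheet_thickness_nm = 3.21, seed = 5,
                             mask_margin_px = 0)
  ph <- generate_sheet_micrograph(spec)
  v <- masked_pixels(ph$micrograph, ph$truth$masks[[1]])
  expect_length(v, 400)
  expect_true(all(v == spec$background_level - spec$aggregate_contrast))
})

test_that("compute_threshold matches the closed form and its symmetries", {
  expect_identical(compute_threshold(rep(4.2, 10)), 0)
  v <- c(0, 2, 4, 6, 8, 10)
  expect_equal(compute_threshold(v), 10 - 1.5 * sqrt(mean((v - mean(v))^2)))
  expect_equal(compute_threshold(v), oracle_threshold(v))
  # positive homogeneity: scaling values by k scales t by k
  for (k in c(0.5, 3, 250)) {
    expect_equal(compute_threshold(v * k), k * compute_threshold(v))
  }
  expect_error(compute_threshold(numeric(0)), "empty region")
})

test_that("threshold agrees with brute force on random value lists", {
  withr::with_seed(99, {
    for (i in 1:200) {
      v <- rnorm(sample(2:200, 1), mean = runif(1, -50, 50),
                 sd = runif(1, 0.01, 20))
      expect_equal(compute_threshold(v), oracle_threshold(v),
                   tolerance = 1e-12)
    }
  })
})

test_that("binarization recovers noiseless two-level phantom areas exactly", {
  for (seed in 1:5) {
    ph <- generate_sheet_micrograph(
      sheet_phantom_spec(n_aggregates = 2, noise_sigma = 0, seed = seed))
    for (k in seq_along(ph$truth$masks)) {
      m <- binarize_and_measure(ph$micrograph, ph$truth$masks[[k]])
      expect_identical(m$area_px, sum(ph$truth$label_image == k))
      expect_equal(m$area_nm2, m$area_px * (3.21 / 10)^2)
    }
  }
})

test_that("a constant masked region counts entirely as foreground", {
  mg <- make_micrograph(matrix(5, 8, 8))
  m <- binarize_and_measure(mg, region_mask(matrix(TRUE, 8, 8)))
  expect_identical(m$area_px, 64L)
  expect_identical(m$threshold, 0)
})

test_that("foreground count matches a pixel-by-pixel scan of the rule", {
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- sample(20:400, 1)
      v <- rnorm(n, 10, 2) - 3 * rbinom(n, 1, 0.3)   # bimodal-ish region
      mg <- make_micrograph(matrix(v, nrow = 1))
      m <- binarize_and_measure(mg, region_mask(matrix(TRUE, 1, n)))
      expect_identical(m$area_px, oracle_foreground_count(v))
    }
  })
})

test_that("raising the std multiplier lowers the threshold, never the area", {
  withr::with_seed(21, {
    for (i in 1:10) {
      v <- rnorm(200, 10, 2) - 3 * rbinom(200, 1, 0.4)
      mg <- make_micrograph(matrix(v, nrow = 10))
      mask <- region_mask(matrix(TRUE, 10, 20))
      a15 <- binarize_and_measure(mg, mask, std_multiplier = 1.5)$area_px
      a20 <- binarize_and_measure(mg, mask, std_multiplier = 2.0)$area_px
      expect_lte(a15, a20)
    }
  })
})

test_that("area is invariant to intensity shift and positive scaling", {
  ph <- generate_sheet_micrograph(sheet_phantom_spec(n_aggregates = 1, seed = 8))
  mask <- ph$truth$masks[[1]]
  base <- binarize_and_measure(ph$micrograph, mask)$area_px
  for (tf in list(function(M) M + 123.4, function(M) M * 7.5,
                  function(M) M * 0.01 - 50)) {
    mg2 <- micrograph(tf(ph$micrograph$intensities), 3.21)
    expect_identical(binarize_and_measure(mg2, mask)$area_px, base)
  }
})

test_that("noisy recovery stays within 10% relative error at 10% noise", {
  errs <- vapply(1:10, function(seed) {
    ph <- generate_sheet_micrograph(
      sheet_phantom_spec(n_aggregates = 2, aggregate_contrast = 1,
                         noise_sigma = 0.1, seed = seed))
    measured <- vapply(ph$truth$masks, function(mk)
      binarize_and_measure(ph$micrograph, mk)$area_px, integer(1))
    max(abs(measured - ph$truth$true_area_px) / ph$truth$true_area_px)
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})

test_that("measure_batch maps pairs to rows and records failures", {
  expect_identical(nrow(measure_batch(list())), 0L)
  items <- list()
  for (seed in 1:3) {
    ph <- generate_sheet_micrograph(
      sheet_phantom_spec(n_aggregates = 2, noise_sigma = 0, seed = seed))
    for (mk in ph$truth$masks)
      items[[length(items) + 1L]] <- list(micrograph = ph$micrograph,
                                          mask = mk, condition = paste0("c", seed))
  }
  tab <- measure_batch(items)
  expect_identical(nrow(tab), 6L)
  expect_identical(tab$condition, rep(paste0("c", 1:3), each = 2))
  expect_false(attr(tab, "partial_failure"))
  # ground-truth recovery through the batch interface
  truth <- unlist(lapply(1:3, function(seed)
    generate_sheet_micrograph(
      sheet_phantom_spec(n_aggregates = 2, noise_sigma = 0,
                         seed = seed))$truth$true_area_nm2))
  expect_equal(tab$area_nm2, truth)
  # a failing pair is skipped, not fatal
  bad <- c(items[1:2], list(list(
    micrograph = items[[1]]$micrograph,
    mask = region_mask(matrix(TRUE, 2, 2)), condition = "bad")))
  tab2 <- measure_batch(bad)
  expect_identical(nrow(tab2), 2L)
  expect_true(attr(tab2, "partial_failure"))
  expect_match(attr(tab2, "failures")$message, "incongruent")
})
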