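# Run configuration, pipeline stages and the command-line surface.
#
# Every stage is reproducible from its manifest: the manifest snapshots the
# config (including the seed), digests of all inputs and outputs, the package
# version, per-stage timing and any warnings raised. Calibration is never
# silently defaulted: missing pixel sizes or q calibrations are errors, and
# header-vs-flag substitutions are logged as warnings in the manifest.

#' Build a validated run configuration
#'
#' @param pixel_size_A micrograph pixel size, Angstrom/pixel (default 3.21).
#' @param std_multiplier threshold multiplier (default 1.5).
#' @param q_nyquist_invA diffraction calibration (default 1.75).
#' @param normalization_band `c(q_lo, q_hi)` in 1/Angstrom.
#' @param band_window_d_A `c(lo, hi)` in Angstrom.
#' @param central_exclusion_q beam-stop exclusion in 1/Angstrom.
#' @param seed integer seed for every stochastic stage.
#' @param output_dir directory for stage outputs (created if absent).
#' @return A list of class `run_config`.
#' @export
make_run_config <- function(pixel_size_A = 3.21, std_multiplier = 1.5,
                            q_nyquist_invA = 1.75,
                            normalization_band = c(0.094, 0.113),
                            band_window_d_A = c(2.5, 3.2),
                            central_exclusion_q = 0.03,
                            seed = 1L, output_dir = ".") {
  if (pixel_size_A <= 0 || q_nyquist_invA <= 0 || central_exclusion_q < 0)
    stop("physical quantities must be positive")
  if (std_multiplier < 0) stop("std_multiplier must be non-negative")
  if (normalization_band[1] >= normalization_band[2] ||
      band_window_d_A[1] >= band_window_d_A[2])
    stop("band and window must have lo < hi")
  structure(list(
    pixel_size_A = pixel_size_A, std_multiplier = std_multiplier,
    q_nyquist_invA = q_nyquist_invA,
    normalization_band = as.numeric(normalization_band),
    band_window_d_A = as.numeric(band_window_d_A),
    central_exclusion_q = central_exclusion_q,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "run_config")
}

file_digests <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0L) return(list())
  dg <- tools::md5sum(paths)
  stats::setNames(as.list(unname(dg)), basename(names(dg)))
}

#' Execute a pipeline stage and write its manifest
#'
#' Runs one of the stage subcommands against a [make_run_config()], writes
#' the stage outputs plus a `manifest.json` into `config$output_dir`, and
#' returns the manifest. Identical config + seed + inputs give identical
#' outputs.
#'
#' @param subcommand one of `"simulate-micrographs"`,
#'   `"simulate-diffraction"`, `"measure-areas"`, `"radial-profile"`,
#'   `"compare-groups"`, `"fisher"`.
#' @param config a [make_run_config()].
#' @param inputs named list of stage inputs (see the stage functions).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(subcommand, config = make_run_config(),
                         inputs = list()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_seen <- character(0)
  t0 <- proc.time()[["elapsed"]]
  outputs <- withCallingHandlers(
    switch(subcommand,
      "simulate-micrographs" = stage_simulate_micrographs(config, inputs),
      "simulate-diffraction" = stage_simulate_diffraction(config, inputs),
      "measure-areas"        = stage_measure_areas(config, inputs),
      "radial-profile"       = stage_radial_profile(config, inputs),
      "compare-groups"       = stage_compare_groups(config, inputs),
      "fisher"               = stage_fisher(config, inputs),
      stop("unknown subcommand: ", subcommand)
    ),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  elapsed <- proc.time()[["elapsed"]] - t0
  input_paths <- unlist(Filter(function(x) is.character(x), inputs))
  manifest <- list(
    subcommand = subcommand,
    package_version = as.character(utils::packageVersion("capsheet")),
    config = unclass(config),
    inputs = file_digests(if (length(input_paths)) input_paths else character(0)),
    outputs = file_digests(unlist(outputs)),
    timing_s = list(stage = elapsed),
    warnings = as.list(warnings_seen)
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}

stage_simulate_micrographs <- function(config, inputs) {
  n_images <- if (is.null(inputs$n_images)) 3L else as.integer(inputs$n_images)
  n_aggregates <- if (is.null(inputs$n_aggregates)) 3L else
    as.integer(inputs$n_aggregates)
  noise_sigma <- if (is.null(inputs$noise_sigma)) 0.1 else inputs$noise_sigma
  outs <- character(0)
  for (i in seq_len(n_images)) {
    spec <- sheet_phantom_spec(pixel_size_A = config$pixel_size_A,
                               n_aggregates = n_aggregates,
                               noise_sigma = noise_sigma,
                               seed = config$seed + i - 1L)
    ph <- generate_sheet_micrograph(spec)
    img_path <- file.path(config$output_dir, sprintf("micrograph_%03d.mrc", i))
    lab_path <- file.path(config$output_dir, sprintf("labels_%03d.tif", i))
    truth_path <- file.path(config$output_dir, sprintf("truth_%03d.json", i))
    write_mrc(ph$micrograph, img_path)
    write_label_tiff(ph$truth$label_image, lab_path)
    jsonlite::write_json(list(
      true_area_px = ph$truth$true_area_px,
      true_area_nm2 = ph$truth$true_area_nm2,
      pixel_size_A = ph$truth$pixel_size_A,
      seed = spec$seed
    ), truth_path, auto_unbox = TRUE, digits = NA)
    outs <- c(outs, img_path, lab_path, truth_path)
  }
  outs
}

stage_simulate_diffraction <- function(config, inputs) {
  amp <- if (is.null(inputs$band_amplitude)) 2 else inputs$band_amplitude
  mk <- function(bands, seed_off) diffraction_phantom_spec(
    q_nyquist_invA = config$q_nyquist_invA, bands = bands,
    seed = config$seed + seed_off)
  trio <- list(
    full = mk(list(c(2.85, 0.35, amp)), 0L),
    partial = mk(list(c(2.85, 0.35, amp / 4)), 1L),
    background = mk(list(), 2L)
  )
  outs <- character(0)
  for (nm in names(trio)) {
    fr <- generate_diffraction_frame(trio[[nm]])
    p <- file.path(config$output_dir, paste0(nm, ".mrc"))
    write_mrc(fr$frame, p)
    jsonlite::write_json(list(q_nyquist_invA = config$q_nyquist_invA,
                              true_center_px = fr$truth$true_center_px,
                              true_band_centers_d_A =
                                fr$truth$true_band_centers_d_A),
                         paste0(p, ".json"), auto_unbox = TRUE, digits = NA)
    outs <- c(outs, p, paste0(p, ".json"))
  }
  outs
}

stage_measure_areas <- function(config, inputs) {
  imgs <- inputs$images; labs <- inputs$labels
  if (is.null(imgs) || is.null(labs) || length(imgs) != length(labs))
    stop("measure-areas needs matching 'images' and 'labels' paths")
  conds <- if (is.null(inputs$conditions)) rep(NA_character_, length(imgs))
           else inputs$conditions
  items <- list()
  for (k in seq_along(imgs)) {
    mg <- read_micrograph(imgs[k], pixel_size_A = config$pixel_size_A)
    for (msk in masks_from_label_image(read_label_tiff(labs[k]))) {
      items[[length(items) + 1L]] <-
        list(micrograph = mg, mask = msk, condition = conds[k])
    }
  }
  tab <- measure_batch(items, std_multiplier = config$std_multiplier)
  out <- file.path(config$output_dir, "areas.csv")
  utils::write.csv(tab, out, row.names = FALSE)
  out
}

stage_radial_profile <- function(config, inputs) {
  need <- c("full", "partial", "background")
  if (!all(need %in% names(inputs)))
    stop("radial-profile needs 'full', 'partial' and 'background' frames")
  fr <- lapply(inputs[need], function(p)
    read_diffraction_frame(p, q_nyquist_invA = config$q_nyquist_invA))
  res <- full_partial_background_run(
    fr$full, fr$partial, fr$background,
    q_lo = config$normalization_band[1], q_hi = config$normalization_band[2],
    window_d_A = config$band_window_d_A)
  p1 <- file.path(config$output_dir, "full_ratio.csv")
  p2 <- file.path(config$output_dir, "partial_ratio.csv")
  p3 <- file.path(config$output_dir, "band_summary.json")
  write_ratio_csv(res$full_ratio, p1)
  write_ratio_csv(res$partial_ratio, p2)
  jsonlite::write_json(unclass(res$band), p3, auto_unbox = TRUE, digits = NA)
  c(p1, p2, p3)
}

stage_compare_groups <- function(config, inputs) {
  if (is.null(inputs$areas_csv)) stop("compare-groups needs 'areas_csv'")
  tab <- read_group_areas_csv(inputs$areas_csv)
  res <- compare_groups(tab)
  out <- file.path(config$output_dir, "group_comparisons.csv")
  utils::write.csv(res, out, row.names = FALSE)
  out
}

stage_fisher <- function(config, inputs) {
  if (is.null(inputs$table) || length(inputs$table) != 4L)
    stop("fisher needs 'table' = c(a, b, c, d)")
  tb <- inputs$table
  res <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])
  out <- file.path(config$output_dir, "fisher.json")
  jsonlite::write_json(list(
    table = as.vector(t(res$table)),
    odds_ratio = res$odds_ratio,
    odds_ratio_cmle = res$odds_ratio_cmle,
    p_two_sided = res$p_two_sided,
    ci_95 = res$ci_95,
    proportions_pct = as.list(res$proportions),
    method_note = res$method_note
  ), out, auto_unbox = TRUE, digits = NA, null = "null")
  out
}
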