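# Reproducible end-to-end runs: configuration object (YAML round-trip),
# staged pipeline with a JSON summary and a run manifest.

#' Pipeline run configuration
#'
#' Collects every tunable of the analysis pipeline with documented defaults:
#' calibration anchors, segmentation thresholds, region bands and smoothing,
#' ROI/blob settings, quality weighting and the RNG seed. The object
#' round-trips losslessly through YAML via [write_run_config()] /
#' [read_run_config()].
#'
#' @param juice_grey,air_grey calibration anchors (grey values).
#' @param clip_porosity clamp porosity maps to \[0, 100\]?
#' @param min_volume_mm3,expected_max fruit segmentation settings.
#' @param bands region porosity bands, see [region_bands()].
#' @param smooth_radius_mm,inner_fraction region classification settings.
#' @param include_cavity count cavity voxels in whole-fruit porosity?
#' @param cell_diameter_range_um,pore_diameter_range_um blob admission
#'   ranges.
#' @param threshold_mode blob binarization mode (default `"multi_otsu"`).
#' @param weight_strategy,weight_k quality-weight derivation settings.
#' @param seed RNG seed used for every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(juice_grey = 49, air_grey = -1007,
                       clip_porosity = TRUE,
                       min_volume_mm3 = 500, expected_max = 3L,
                       bands = region_bands(),
                       smooth_radius_mm = 1, inner_fraction = 0.35,
                       include_cavity = TRUE,
                       cell_diameter_range_um = c(30, 150),
                       pore_diameter_range_um = c(10, 200),
                       threshold_mode = "multi_otsu",
                       weight_strategy = "loading_x_variance",
                       weight_k = 2L,
                       seed = 20240830L) {
  structure(
    list(
      juice_grey = juice_grey, air_grey = air_grey,
      clip_porosity = clip_porosity,
      min_volume_mm3 = min_volume_mm3,
      expected_max = as.integer(expected_max),
      bands = bands,
      smooth_radius_mm = smooth_radius_mm,
      inner_fraction = inner_fraction,
      include_cavity = include_cavity,
      cell_diameter_range_um = cell_diameter_range_um,
      pore_diameter_range_um = pore_diameter_range_um,
      threshold_mode = threshold_mode,
      weight_strategy = weight_strategy,
      weight_k = as.integer(weight_k),
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$bands <- do.call(region_bands, lapply(x$bands, unlist))
  x$bands$cavity_min <- x$bands$cavity_min
  cfg <- do.call(run_config, x[setdiff(names(x), character(0))])
  cfg
}

#' Run the low-resolution porosity pipeline end to end
#'
#' Executes calibrate -> segment -> classify regions -> porosity summaries
#' on a grey-value scene, writing volumes (TIFF), tables (CSV) and a JSON
#' summary to `output_dir`. Any stage failure is re-thrown tagged with the
#' stage name; artifacts written before the failure are preserved. The
#' summary contains the configuration hash and seed but no timestamps, so
#' identical inputs give byte-identical summaries.
#'
#' @param input a [grey_volume()], a directory of DICOM files, or a
#'   [fruit_phantom_spec()] (which is simulated with the config's seed).
#' @param config a [run_config()].
#' @param output_dir output directory (created).
#' @param write_volumes write the porosity map / label volumes (default
#'   `TRUE`; tables and summary are always written).
#' @return The summary list, invisibly. Files written: `porosity.tif` (+
#'   sidecar), `regions.tif`, `fruit_summary.csv`, `region_summary.csv`,
#'   `summary.json`, `manifest.json`.
#' @export
run_pipeline <- function(input, config = run_config(), output_dir,
                         write_volumes = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  volume <- stage("input", {
    if (inherits(input, "grey_volume")) {
      input
    } else if (inherits(input, "fruit_phantom_spec")) {
      ph <- make_fruit_phantom(input)
      porosity_to_grey(ph$porosity, fit_two_point(config$juice_grey,
                                                  config$air_grey),
                       noise_sd = 10, seed = config$seed)
    } else if (is.character(input)) {
      read_dicom_series(input)
    } else {
      abort("input must be a grey_volume, phantom spec or DICOM directory")
    }
  })

  calib <- stage("calibrate",
                 fit_two_point(config$juice_grey, config$air_grey))
  pmap <- stage("porosity_map",
                apply_calibration(volume, calib,
                                  clip = config$clip_porosity))
  masks <- stage("segment",
                 segment_fruits(volume,
                                min_volume_mm3 = config$min_volume_mm3,
                                expected_max = config$expected_max))
  regions <- stage("classify",
                   classify_regions(pmap, masks, bands = config$bands,
                                    smooth_radius_mm = config$smooth_radius_mm,
                                    inner_fraction = config$inner_fraction))
  fruit_tab <- stage("porosity", {
    whole_fruit_porosity(pmap, masks,
                         include_cavity = config$include_cavity,
                         regions = regions)
  })
  region_tab <- stage("porosity", regional_summary(pmap, regions, masks))

  artifacts <- character(0)
  add <- function(p) { artifacts <<- c(artifacts, basename(p)); p }
  if (isTRUE(write_volumes)) {
    write_volume(pmap, add(file.path(output_dir, "porosity.tif")),
                 "tiff_stack")
    artifacts <- c(artifacts, "porosity.tif.json")
  }
  write_metrics(fruit_tab, add(file.path(output_dir, "fruit_summary.csv")))
  write_metrics(region_tab, add(file.path(output_dir, "region_summary.csv")))

  summary <- list(
    package_version = as.character(utils::packageVersion("poroct")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    calibration = list(juice_grey = calib$juice_grey,
                       air_grey = calib$air_grey,
                       slope = calib$slope, intercept = calib$intercept),
    volume = list(dim = dim(volume$voxels),
                  spacing_mm = volume$spacing_mm),
    fruit_count = masks$fruit_count,
    whole_fruit = fruit_tab,
    regions = region_tab
  )
  sj <- file.path(output_dir, "summary.json")
  jsonlite::write_json(summary, add(sj), auto_unbox = TRUE, digits = NA,
                       na = "null")
  jsonlite::write_json(
    list(artifacts = sort(unique(artifacts))),
    file.path(output_dir, "manifest.json"),
    auto_unbox = TRUE
  )
  invisible(summary)
}
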