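#' Read and validate a run configuration
#'
#' The pipeline is driven by a single YAML file with sections `geometry`
#' (keys of [display_geometry()] as `*_mm` / `*_um`), `acquisition`
#' (`shots`, `scan_order`, `illumination_time_s`, `gain`), `analysis`
#' (keys of [analysis_config()]; `filter` may name a preset), and
#' `visualization` (`block`, `alpha`, `min_defined_fraction`), plus a
#' top-level integer `seed`. Missing keys fall back to package defaults.
#'
#' @param path YAML config path, or `NULL` for all defaults
#' @return validated config list of class `run_config`
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  g <- cfg$geometry %||% list()
  geom <- display_geometry(
    leds_per_side = g$leds_per_side %||% 256,
    pixel_pitch_mm = g$pixel_pitch_mm %||% 1.8,
    source_sample_distance_mm = g$source_sample_distance_mm %||% 130,
    sample_camera_distance_mm = g$sample_camera_distance_mm %||% 400,
    kernel_size = g$kernel_size %||% 8,
    kernels_per_side = g$kernels_per_side %||% 32,
    object_pixel_size_um = g$object_pixel_size_um %||% 3.0)
  a <- cfg$analysis %||% list()
  ana <- analysis_config(
    delta_phi = a$delta_phi %||% 1,
    filter = a$filter %||% "sli-1deg",
    prominence_threshold = a$prominence_threshold %||% 0.08,
    tip_fraction = a$tip_fraction %||% 0.06,
    pair_tolerance_deg = a$pair_tolerance_deg %||% 35,
    reflex_rotation = a$reflex_rotation %||% 90,
    min_radius_px = a$min_radius_px %||% 4)
  acq <- cfg$acquisition %||% list()
  vis <- cfg$visualization %||% list()
  structure(list(
    geometry = geom,
    acquisition = list(shots = acq$shots %||% 1L,
                       scan_order = acq$scan_order %||% "row-major",
                       illumination_time_s = acq$illumination_time_s %||% 1,
                       gain = acq$gain %||% 1),
    analysis = ana,
    visualization = list(block = vis$block %||% 40,
                         alpha = vis$alpha %||% 0.1,
                         min_defined_fraction = vis$min_defined_fraction %||% 0.08),
    seed = as.integer(cfg$seed %||% 1L)
  ), class = "run_config")
}

#' Derive a per-stage seed from the global run seed
#'
#' Fans the single run seed out to stage seeds by a stable string hash of
#' the stage name, so stages re-run in isolation reproduce their output.
#'
#' @param seed global integer seed
#' @param stage stage name
#' @return integer seed below 2^31
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(seed) * 1000003 + h) %% .Machine$integer.max)
}

#' Write a JSON run manifest
#'
#' Records inputs, outputs, stage, seed, configuration digest and package
#' version so any run can be reproduced.
#'
#' @param path manifest path
#' @param stage stage name
#' @param inputs,outputs character vectors of file paths
#' @param seed integer seed used
#' @param extra optional named list of additional entries
#' @return `path`, invisibly
#' @export
write_manifest <- function(path, stage, inputs = character(0),
                           outputs = character(0), seed = NA_integer_,
                           extra = list()) {
  man <- c(list(stage = stage, inputs = inputs, outputs = outputs,
                seed = seed,
                package = as.character(utils::packageVersion("sliscat")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
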