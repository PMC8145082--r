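#' Full pipeline run configuration
#'
#' Bundles every tunable of the pipeline. The defaults reproduce the
#' published operating point: 0.5-second windows, 5-millisecond audio
#' segments at the highest VAD aggressiveness, and a nose tolerance of half
#' the inter-eye distance.
#'
#' @param window_seconds window duration (default 0.5)
#' @param fps video frame rate (default 30)
#' @param gaze a [gaze_config()]
#' @param vad a [vad_config()]
#' @param index_map keypoint index map, see [default_index_map()]
#' @param seed RNG seed for simulation subcommands
#' @return a `run_config`
#' @export
run_config <- function(window_seconds = 0.5, fps = 30, gaze = gaze_config(),
                       vad = vad_config(), index_map = default_index_map(),
                       seed = 1L) {
  structure(list(window_seconds = window_seconds, fps = fps, gaze = gaze,
                 vad = vad, index_map = index_map, seed = as.integer(seed)),
            class = "run_config")
}

#' Write a run configuration to YAML
#' @param cfg a [run_config()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_run_config <- function(cfg, path) {
  x <- list(
    window_seconds = cfg$window_seconds, fps = cfg$fps,
    gaze = unclass(cfg$gaze),
    vad = unclass(cfg$vad)[c("segment_ms", "aggressiveness", "delta_db",
                             "noise_floor_percentile")],
    index_map = as.list(cfg$index_map), seed = cfg$seed
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML path written by [write_run_config()]
#' @return a [run_config()]
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(
    window_seconds = x$window_seconds %||% 0.5,
    fps = x$fps %||% 30,
    gaze = do.call(gaze_config, x$gaze %||% list()),
    vad = do.call(vad_config, x$vad %||% list()),
    index_map = if (is.null(x$index_map)) default_index_map()
                else unlist(x$index_map),
    seed = x$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
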