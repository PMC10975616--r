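#' Analysis configuration
#'
#' All tunable thresholds and windows of the per-run analysis, with defaults
#' equal to the reference values of the bottleneck-crossing analysis:
#' 0.5 s centred running-mean windows for speed and acceleration, a 1 s
#' duration threshold and a -0.0075 m/s^2 amplitude threshold for the
#' deceleration categories searched in the 0--3.5 m pre-crossing window, a
#' 3.5--1.5 m straight-walking phase for baseline noise estimation, 0.1 m
#' profile bins on \[-1, 4\] m, and a 180-point grid on R in \[0.8, 2.6\] with
#' 0.05-wide intervals at a 0.95 level for the critical-ratio procedure.
#'
#' @param ... named overrides of any default entry (nested lists are merged
#'   shallowly at the top level and deeply one level down).
#'
#' @return A named list of class `bng_config`.
#' @export
#' @examples
#' cfg <- analysis_config(speed = list(window = 0.4))
#' cfg$speed$window
analysis_config <- function(...) {
  cfg <- list(
    fs = 60,                                 # Hz, common resampling rate
    speed = list(
      window = 0.5,                          # s, centred running-mean window
      mean_speed_radius = 3,                 # m, excludes the acceleration phase
      vmax_window = c(0, 3.5)                # m, distance-to-crossing window
    ),
    decel = list(
      window = 0.5,                          # s, acceleration smoothing window
      duration_threshold = 1.0,              # s, long vs short
      amplitude_threshold = -0.0075,         # m/s^2, strong vs weak (3 sigma)
      search_window = c(0, 3.5),             # m, distance-to-crossing window
      magnitude_comparison = TRUE            # "larger" read as larger magnitude
    ),
    rotation = list(
      window = 0.5,                          # s, movement-direction interval
      straight_window = c(1.5, 3.5),         # m, baseline phase
      onset_sigma = 3,                       # onset threshold in sigma units
      center = TRUE,                         # subtract straight-window mean
      min_displacement = 1e-3                # m, COM motion needed for gamma
    ),
    steps = list(
      threshold = NULL,                      # m/s; NULL = relative rule below
      threshold_frac = 0.2,                  # fraction of 95th pct heel speed
      min_stance = 0.1,                      # s, minimal stance duration
      speed_norm = "l1",                     # |vx|+|vy| per the step detector
      polarity = "stance_onset"              # or "swing_onset"
    ),
    profile = list(
      bin = 0.1,                             # m
      range = c(-1, 4)                       # m, distance-to-crossing
    ),
    rcrit = list(
      grid_n = 180,
      r_range = c(0.8, 2.6),
      interval = 0.05,
      level = 0.95
    ),
    crossing = list(
      tolerance = 0.05,                      # m, slack on |x| <= w/2 checks
      max_abs_y = 0.5                        # m, "no crossing" guard
    ),
    r_split = 1.3                            # literature critical ratio
  )
  modify_config(cfg, list(...))
}

modify_config <- function(cfg, overrides) {
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  class(cfg) <- c("bng_config", "list")
  cfg
}

#' Read or write a configuration as YAML
#'
#' @param path file path of the YAML document.
#' @return `read_config()` returns a `bng_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param cfg a `bng_config` list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
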