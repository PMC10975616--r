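#' Synthetic-experiment configuration
#'
#' Defines the experimental conditions emulated by the gait generator: the factorial
#' design grid (seven approach angles, six bottleneck widths, three lengths,
#' two motivation conditions, 13 participants), the participant population
#' (shoulder width mean 0.43 m, sd 0.033 m), per-motivation speed profiles
#' (rest, constant acceleration, cruise with noise), the five-category
#' deceleration mixture with category shapes whose durations and amplitudes
#' clear the classifier thresholds with margin, the shoulder-rotation model
#' (gait-locked baseline oscillation, a turn ramp that starts a fixed lead
#' time before crossing and peaks a fixed lag after it, an exponential
#' amplitude-versus-ratio law, stance-foot coupling), the linear crossing
#' offset law, and band-limited measurement noise.
#'
#' @param ... named overrides; nested lists are merged one level deep.
#' @return A named list of class `bng_synth_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_per_cell = 1, seed = 7)
#' cfg$crossing_law$slope
synthetic_config <- function(...) {
  cfg <- list(
    angles = c(-90, -60, -30, 0, 30, 60, 90),     # deg
    widths = c(0.4, 0.5, 0.6, 0.7, 0.8, 1.0),     # m
    lengths = c(0.2, 1.0, 2.0),                   # m (pooled by the analysis)
    motivations = c("normal", "hurried"),
    n_per_cell = 1,
    seed = 1,
    population = list(n = 13, shoulder_mean = 0.43, shoulder_sd = 0.033),
    speed = list(
      normal = list(a0 = 1.25, t_acc = 1.2, cruise_noise_sd = 0.05),
      hurried = list(a0 = 1.4, t_acc = 1.5, cruise_noise_sd = 0.05)
    ),
    decel_mixture = list(
      normal = c(long_strong = 0.20, short_strong = 0.20, long_weak = 0.16,
                 none = 0.22, none_at_all = 0.22),
      hurried = c(long_strong = 0.34, short_strong = 0.30, long_weak = 0,
                  none = 0.19, none_at_all = 0.17)
    ),
    decel_shapes = list(
      long_strong = list(start_d = 2.4, duration = 1.5, peak = 0.67),
      short_strong = list(start_d = 2.0, duration = 0.2, peak = 0.60),
      long_weak = list(start_d = 2.4, duration = 1.5, peak = 0.005),
      none = list(start_d = 2.0, duration = 0.2, peak = 0.005)
    ),
    rotation = list(
      base_amp_deg = 4,                 # gait-locked oscillation amplitude
      noise_sd_deg = 1,                 # band-limited orientation noise
      onset_lead = c(normal = 0.41, hurried = 0.46),   # s before crossing
      peak_lag = c(normal = 0.075, hurried = 0.02),    # s after crossing
      ramp_slope_deg_s = NULL,          # if set, overrides the amplitude law
      amplitude_law = list(a = 205, b = 1.9, d = 8),   # a e^(-bR) + d, deg
      amplitude_noise_sd = 3,           # deg, per-run amplitude scatter
      p_couple = 0.8                    # P(left turn | right stance foot)
    ),
    gait = list(cadence = 2, stance_frac = 0.6, step_width = 0.12),
    crossing_law = list(slope = 0.176, intercept = -0.078, noise_sd = 0.05),
    noise = list(position_sd = 0.005, smooth_samples = 15),
    geometry = list(start_radius = 4, corner_y = 1.5, fillet_frac = 0.8,
                    exit_length = 2),
    fs = 60
  )
  out <- cfg
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(out[[nm]])) {
      out[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      out[[nm]] <- overrides[[nm]]
    }
  }
  for (m in names(out$decel_mixture)) {
    p <- out$decel_mixture[[m]]
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      stop("deceleration mixture for '", m, "' must be a probability vector")
    }
  }
  stopifnot(out$n_per_cell >= 1, out$population$shoulder_sd >= 0)
  class(out) <- c("bng_synth_config", "list")
  out
}

#' Enumerate the run matrix of a synthetic experiment
#'
#' The full factorial of setups (width x length x motivation) crossed with
#' participants, angles and repetitions. With the default grids this yields
#' the reference design: 36 setups and, with 13 participants and 7 angles,
#' 3276 runs.
#'
#' @param cfg a [synthetic_config()].
#' @return A tibble with one row per run (`run_id`, `participant_id`,
#'   `angle_deg`, `width_w`, `length_l`, `motivation`, `rep`).
#' @export
enumerate_runs <- function(cfg) {
  grid <- expand.grid(rep = seq_len(cfg$n_per_cell),
                      angle_deg = cfg$angles,
                      participant_id = seq_len(cfg$population$n),
                      width_w = cfg$widths,
                      length_l = cfg$lengths,
                      motivation = cfg$motivations,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0) stop("empty design grid")
  grid$run_id <- sprintf("run%05d", seq_len(nrow(grid)))
  tibble::as_tibble(grid[c("run_id", "participant_id", "angle_deg", "width_w",
                           "length_l", "motivation", "rep")])
}

#' Number of experimental setups in a design
#'
#' @param cfg a [synthetic_config()].
#' @return Integer: widths x lengths x motivations.
#' @export
count_setups <- function(cfg) {
  length(cfg$widths) * length(cfg$lengths) * length(cfg$motivations)
}

#' Draw the synthetic participant population
#'
#' Shoulder widths are drawn from the configured normal population
#' (truncated at 0.3 m); footedness alternates right/left through the
#' roster.
#'
#' @param cfg a [synthetic_config()].
#' @return A list of [participant()] objects.
#' @export
sample_participants <- function(cfg) {
  n <- cfg$population$n
  sw <- pmax(stats::rnorm(n, cfg$population$shoulder_mean,
                          cfg$population$shoulder_sd), 0.3)
  lapply(seq_len(n), function(i) {
    participant(sprintf("P%02d", i), sw[i],
                footedness = if (i %% 2 == 1) "right" else "left")
  })
}
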