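law_amplitude <- function(law, R) law$a * exp(-law$b * R) + law$d

draw_crossing_offset <- function(cfg, meta) {
  lw <- cfg$crossing_law
  side <- if (meta$angle_deg > 0) 1 else if (meta$angle_deg < 0) -1 else
    sample(c(-1, 1), 1)
  bound <- meta$width_w / 2 - 0.02
  for (i in 1:20) {
    x <- side * (lw$slope * meta$width_w + lw$intercept) +
      stats::rnorm(1, 0, lw$noise_sd)
    if (abs(x) <= bound) return(list(x_cross = x, side = side))
  }
  list(x_cross = max(-bound, min(bound, x)), side = side)
}

# Heel trajectory of one foot: holds each ground anchor during stance and
# moves to the next anchor with a cosine ease during the swing phase.
heel_track <- function(times, init_pos, strike_times, strike_pos, swing_dur) {
  n <- length(times)
  pos <- matrix(rep(init_pos, each = n), ncol = 2)
  prev_pos <- init_pos
  prev_t <- times[1]
  for (i in seq_along(strike_times)) {
    tk <- strike_times[i]
    sw0 <- max(tk - swing_dur, prev_t)
    target <- strike_pos[i, ]
    u <- (times - sw0) / max(tk - sw0, 1e-9)
    ease <- 0.5 * (1 - cos(pi * pmin(pmax(u, 0), 1)))
    in_or_after <- times >= sw0
    pos[in_or_after, 1] <- prev_pos[1] + (target[1] - prev_pos[1]) * ease[in_or_after]
    pos[in_or_after, 2] <- prev_pos[2] + (target[2] - prev_pos[2]) * ease[in_or_after]
    prev_pos <- target
    prev_t <- tk
  }
  pos
}

#' Generate one synthetic bottleneck run
#'
#' Simulates the centre of mass along a line-arc-line path from the starting
#' area (4 m radius at the approach angle) through a crossing point drawn
#' from the linear offset law, with a rest-acceleration-cruise speed profile
#' and a deceleration pulse drawn from the five-category mixture; shoulders
#' ride on the COM at half the shoulder width on either side of a facing
#' direction composed of the path heading, a gait-locked baseline
#' oscillation, a triangular turn-rotation ramp (starting a fixed lead time
#' before crossing, peaking a fixed lag after it) and band-limited noise;
#' heels alternate stance and swing with the first step on the right foot.
#' COM positions are advanced so that consecutive-sample chord lengths equal
#' the simulated speed times the sample period, making the chord-sum
#' distance metric of the analysis exact on noiseless runs.
#'
#' @param cfg a [synthetic_config()].
#' @param meta a [run_meta()]; `meta$motivation` selects speed, lead/lag and
#'   mixture entries.
#' @param seed integer seed for this run.
#' @return A list with `recording` (a [run_recording()]) and `truth` (list
#'   of ground-truth values: crossing offset, deceleration category and
#'   pulse location, rotation onset/maximum, heel strikes, stance feet).
#' @export
generate_run <- function(cfg, meta, seed = 1) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  dt <- 1 / cfg$fs
  sp <- cfg$speed[[meta$motivation]]
  if (sp$t_acc <= 0) stop("acceleration duration must be positive")
  category <- sample(names(cfg$decel_mixture[[meta$motivation]]), 1,
                     prob = cfg$decel_mixture[[meta$motivation]])
  shape <- cfg$decel_shapes[[category]]
  cross <- draw_crossing_offset(cfg, meta)
  path <- build_path(meta$angle_deg, cross$x_cross, cfg$geometry)

  n_max <- ceiling(30 / dt)
  t_v <- v_v <- s_v <- chord_v <- numeric(n_max)
  v <- 0; s <- 0; chord_sum <- 0
  pulse_t0 <- NA_real_
  k <- 0L
  while (k < n_max) {
    k <- k + 1L
    t <- (k - 1L) / cfg$fs            # exact grid; no accumulated drift
    t_v[k] <- t; v_v[k] <- v; s_v[k] <- s; chord_v[k] <- chord_sum
    d_arc <- path$s_cross - s
    if (!is.null(shape) && is.na(pulse_t0) && d_arc <= shape$start_d) {
      pulse_t0 <- t
    }
    a <- if (t + dt <= sp$t_acc) sp$a0
    else if (t < sp$t_acc) sp$a0 * (sp$t_acc - t) / dt   # partial last step
    else 0
    if (!is.na(pulse_t0) && t >= pulse_t0 && t < pulse_t0 + shape$duration) {
      a <- a - shape$peak *
        0.5 * (1 - cos(2 * pi * (t - pulse_t0) / shape$duration))
    }
    v <- max(v + a * dt, 0)
    step <- max(v + stats::rnorm(1, 0, sp$cruise_noise_sd), 0) * dt
    if (path$total - s < step + 1e-6) break
    s <- step_along_path(path, s, step)
    chord_sum <- chord_sum + step
  }
  n <- k
  times <- t_v[1:n]; s_arc <- s_v[1:n]; chords <- chord_v[1:n]
  com <- path$point(s_arc)
  head_ang <- path$heading(s_arc)

  # crossing time from the sign change of y on the exit segment
  y <- com[, 2]
  j <- which(y[-1] <= 0 & y[-n] > 0)
  j <- j[length(j)] + 1L
  if (length(j) == 0) stop("infeasible geometry: trajectory never crosses y = 0")
  t_cross <- times[j - 1] + dt * y[j - 1] / (y[j - 1] - y[j])
  chord_at <- stats::approxfun(times, chords)
  c_cross <- chord_at(t_cross)
  d_of_t <- function(tt) c_cross - chord_at(tt)

  # heel-strike schedule: constant cadence, first strike on the right foot
  g <- cfg$gait
  step_period <- 1 / g$cadence
  stride <- 2 / g$cadence
  stance_dur <- stride * g$stance_frac
  swing_dur <- stride - stance_dur
  strike_t <- seq(step_period / 2, times[n], by = step_period)
  strike_feet <- rep(c("right", "left"), length.out = length(strike_t))
  s_at <- stats::approxfun(times, s_arc)
  strike_s <- s_at(strike_t)
  strike_head <- path$heading(strike_s)
  strike_base <- path$point(strike_s)
  side_off <- function(hd, side) {
    (g$step_width / 2) * side * cbind(sin(hd), -cos(hd))  # side +1 = right
  }
  pr <- strike_base + side_off(strike_head, 1)
  pl <- strike_base + side_off(strike_head, -1)
  dir0 <- c(cos(head_ang[1]), sin(head_ang[1]))
  init_r <- com[1, ] + drop(side_off(head_ang[1], 1)) - 0.4 * dir0
  init_l <- com[1, ] + drop(side_off(head_ang[1], -1))
  is_r <- strike_feet == "right"
  heel_r <- heel_track(times, init_r, strike_t[is_r], pr[is_r, , drop = FALSE],
                       swing_dur)
  heel_l <- heel_track(times, init_l, strike_t[!is_r], pl[!is_r, , drop = FALSE],
                       swing_dur)

  # shoulder rotation: baseline oscillation + triangular turn ramp + noise
  rt <- cfg$rotation
  lead <- rt$onset_lead[[meta$motivation]]
  lag <- rt$peak_lag[[meta$motivation]]
  t_on <- t_cross - lead
  t_peak <- t_cross + lag
  i_stance <- findInterval(t_peak, strike_t)
  stance_at_peak <- if (i_stance >= 1) strike_feet[i_stance] else "none"
  coupled <- stats::runif(1) < rt$p_couple
  turn_dir <- if (stance_at_peak == "right") 1 else -1
  if (!coupled) turn_dir <- -turn_dir
  sw <- meta$participant$shoulder_width_s
  R <- meta$width_w / sw
  if (!is.null(rt$ramp_slope_deg_s)) {
    amp <- rt$ramp_slope_deg_s * (lead + lag)
  } else {
    amp <- max(law_amplitude(rt$amplitude_law, R) +
                 stats::rnorm(1, 0, rt$amplitude_noise_sd), 0)
  }
  slope <- amp / (lead + lag)
  tri <- if (amp <= 0) numeric(n) else
    ifelse(times < t_on, 0,
           ifelse(times <= t_peak, slope * (times - t_on),
                  pmax(amp - slope * (times - t_peak), 0)))
  t_l1 <- step_period / 2 + step_period       # first left strike
  t_ref <- (t_l1 - swing_dur / 2) - stride / 4
  base_osc <- rt$base_amp_deg * sin(2 * pi * (times - t_ref) / stride)
  gamma_true <- turn_dir * tri + base_osc +
    smooth_noise(n, rt$noise_sd_deg, cfg$noise$smooth_samples)
  orient <- head_ang + gamma_true * pi / 180
  left_dir <- cbind(-sin(orient), cos(orient))
  sh_l <- com + (sw / 2) * left_dir
  sh_r <- com - (sw / 2) * left_dir

  addn <- function(p) {
    p + cbind(smooth_noise(n, cfg$noise$position_sd, cfg$noise$smooth_samples),
              smooth_noise(n, cfg$noise$position_sd, cfg$noise$smooth_samples))
  }
  rec <- run_recording(meta,
                       com = point_series(times, addn(com)),
                       shoulder_left = point_series(times, addn(sh_l)),
                       shoulder_right = point_series(times, addn(sh_r)),
                       heel_left = point_series(times, addn(heel_l)),
                       heel_right = point_series(times, addn(heel_r)))
  i_on <- findInterval(t_on, strike_t)
  truth <- list(
    run_id = meta$run_id,
    x_cross = cross$x_cross, side = cross$side,
    decel_category = category,
    decel_pulse_d = if (is.null(shape) || is.na(pulse_t0)) NA_real_ else
      d_of_t(pulse_t0),
    onset_t = t_on, onset_d = d_of_t(t_on),
    max_t = t_peak, max_d = d_of_t(t_peak),
    max_amplitude = turn_dir * amp,
    direction = if (turn_dir > 0) "left" else "right",
    stance_at_onset = if (i_on >= 1) strike_feet[i_on] else "none",
    stance_at_max = stance_at_peak,
    coupled = coupled,
    strikes = tibble::tibble(time = strike_t, foot = strike_feet),
    t_cross = t_cross,
    R = R
  )
  list(recording = rec, truth = truth)
}

#' Generate a full synthetic experiment
#'
#' Draws the participant roster, enumerates the factorial run matrix and
#' generates every run with a per-run seed derived deterministically from
#' the root seed, so the whole experiment and any single run are exactly
#' reproducible.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with `runs` (list of [generate_run()] results), `truth`
#'   (tibble of per-run ground truth joined with the design), `design`
#'   (the [enumerate_runs()] table) and `participants`.
#' @export
generate_experiment <- function(cfg) {
  design <- enumerate_runs(cfg)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(cfg$seed)
  participants <- sample_participants(cfg)
  run_seeds <- sample.int(.Machine$integer.max - 1, nrow(design))
  runs <- vector("list", nrow(design))
  truth_rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    meta <- run_meta(participants[[row$participant_id]],
                     angle_deg = row$angle_deg, width_w = row$width_w,
                     length_l = row$length_l, motivation = row$motivation,
                     run_id = row$run_id)
    runs[[i]] <- generate_run(cfg, meta, seed = run_seeds[i])
    tr <- runs[[i]]$truth
    truth_rows[[i]] <- tibble::tibble(
      run_id = row$run_id, participant_id = row$participant_id,
      angle_deg = row$angle_deg, width_w = row$width_w,
      length_l = row$length_l, motivation = row$motivation, R = tr$R,
      x_cross = tr$x_cross, side = tr$side,
      decel_category = tr$decel_category, decel_pulse_d = tr$decel_pulse_d,
      onset_d = tr$onset_d, max_d = tr$max_d,
      max_amplitude = tr$max_amplitude, direction = tr$direction,
      stance_at_onset = tr$stance_at_onset, stance_at_max = tr$stance_at_max,
      coupled = tr$coupled
    )
  }
  list(runs = runs, truth = dplyr::bind_rows(truth_rows), design = design,
       participants = participants)
}
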