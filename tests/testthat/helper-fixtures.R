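# Shared fixtures: noiseless configurations and small batch helpers.

noiseless_config <- function(motivation = "normal", category = NULL, ...) {
  cats <- c("long_strong", "short_strong", "long_weak", "none", "none_at_all")
  mix <- if (is.null(category)) NULL else
    stats::setNames(as.numeric(cats == category), cats)
  args <- list(
    speed = stats::setNames(list(list(
      a0 = if (motivation == "normal") 1.25 else 1.4,
      t_acc = if (motivation == "normal") 1.2 else 1.5,
      cruise_noise_sd = 0)), motivation),
    noise = list(position_sd = 0, smooth_samples = 15),
    ...
  )
  if (!is.null(mix)) {
    args$decel_mixture <- stats::setNames(list(mix), motivation)
  }
  do.call(synthetic_config, args)
}

test_participant <- function(sw = 0.43) participant("P01", sw)

gen_one <- function(cfg, angle = 0, width = 0.6, motivation = "normal",
                    seed = 1, sw = 0.43) {
  meta <- run_meta(test_participant(sw), angle, width, 1, motivation, "run")
  generate_run(cfg, meta, seed = seed)
}

# batch of analysed synthetic runs under one config
analyze_batch <- function(cfg, n, motivation = "normal", angle = 0,
                          width = 0.8, seed0 = 1000, config = analysis_config()) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gr <- gen_one(cfg, angle = angle, width = width, motivation = motivation,
                  seed = seed0 + i)
    rows[[i]] <- analyze_run(gr$recording, config)
  }
  dplyr::bind_rows(rows)
}

# analytic gait fixture: heels hold for `stance` s then move at constant
# speed for `swing` s; square-wave heel speed with exact stance onsets
square_gait_heels <- function(fs = 60, n_steps = 6, stance = 0.6,
                              swing = 0.4, step_len = 0.75) {
  dur <- (n_steps + 1) * (stance + swing)
  times <- seq(0, dur, by = 1 / fs)
  one_foot <- function(t0, x0) {
    pos <- matrix(0, length(times), 2)
    x <- x0
    starts <- seq(t0, dur, by = 2 * (stance + swing))
    pos[, 1] <- x
    for (s0 in starts) {
      sw_start <- s0 + stance
      sw_end <- sw_start + swing
      moving <- times > sw_start & times <= sw_end
      pos[times > sw_start, 1] <- x + 2 * step_len *
        pmin((times[times > sw_start] - sw_start) / swing, 1)
      x <- x + 2 * step_len
    }
    pos[, 2] <- 0.06
    pos
  }
  list(times = times,
       right = point_series(times, one_foot(0, 0)),
       left = point_series(times, one_foot(stance + swing, step_len)))
}
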