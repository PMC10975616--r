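na_run_fields <- function() {
  list(x_cross = NA_real_, t_cross = NA_real_, mean_speed = NA_real_,
       vmax = NA_real_, d_at_vmax = NA_real_, vmin = NA_real_,
       decel_category = NA_character_, decel_point_d = NA_real_,
       sigma_straight = NA_real_, onset_d = NA_real_, onset_t = NA_real_,
       max_amplitude = NA_real_, max_d = NA_real_, max_t = NA_real_,
       direction = NA_character_, foot_at_onset = NA_character_,
       foot_at_max = NA_character_, strikes_alternating = NA)
}

#' Analyse a single run
#'
#' Runs the full per-run pipeline — crossing point, distance to crossing,
#' running-mean speed, mean speed, vmax/vmin, smoothed acceleration and
#' five-way deceleration classification, shoulder rotation with onset and
#' maximum, heel strikes and stance-foot assignment — and returns one result
#' row. Per-run degeneracies (no onset, no crossing, missing coverage) never
#' raise: the affected fields are `NA` and a reason code is appended to
#' `reasons`.
#'
#' @param rec a [run_recording()].
#' @param config an [analysis_config()].
#' @return A one-row tibble.
#' @export
analyze_run <- function(rec, config = analysis_config()) {
  meta <- rec$meta
  out <- na_run_fields()
  reasons <- character()
  note <- function(code) reasons <<- c(reasons, code)
  times <- rec$com$times

  crossing <- tryCatch(compute_crossing(rec$com, config$crossing$max_abs_y),
                       error = function(e) { note("no_crossing"); NULL })
  d <- v <- NULL
  if (!is.null(crossing)) {
    out$x_cross <- crossing$x_cross
    out$t_cross <- crossing$t_cross
    d <- distance_to_crossing(rec$com, crossing)
    v <- speed_along_path(d, times, config$speed$window)
    out$mean_speed <- tryCatch(
      mean_speed(rec$com, crossing, config$speed$mean_speed_radius),
      error = function(e) { note("no_mean_speed"); NA_real_ })
    vv <- tryCatch(find_vmax_vmin(v, d, times, config$speed$vmax_window),
                   error = function(e) { note("no_vmax_coverage"); NULL })
    if (!is.null(vv)) {
      out$vmax <- vv$vmax; out$d_at_vmax <- vv$d_at_vmax; out$vmin <- vv$vmin
    }
    a <- smooth_acceleration(raw_path_speed(d, times), times,
                             config$decel$window)
    groups <- group_negative(a, times, d, config$decel$search_window)
    decel <- classify_deceleration(groups, config$decel$duration_threshold,
                                   config$decel$amplitude_threshold)
    out$decel_category <- decel$category
    out$decel_point_d <- decel$decel_point_d

    gamma <- shoulder_rotation(rec$shoulder_left, rec$shoulder_right, rec$com,
                               config$rotation$window,
                               config$rotation$min_displacement)
    onset <- tryCatch(
      rotation_onset(gamma, d, times, config$rotation$straight_window,
                     config$rotation$onset_sigma, config$rotation$center),
      error = function(e) { note("no_straight_phase"); NULL })
    steps <- tryCatch(
      detect_heel_strikes(rec$heel_left, rec$heel_right,
                          config$steps$threshold, config$steps$threshold_frac,
                          config$steps$min_stance, config$steps$speed_norm),
      error = function(e) { note("no_steps"); NULL })
    if (!is.null(steps)) out$strikes_alternating <- steps$alternating
    if (!is.null(onset)) {
      out$sigma_straight <- onset$sigma_straight
      if (onset$detected) {
        out$onset_d <- onset$onset_d
        out$onset_t <- onset$onset_t
        mx <- max_rotation(gamma, d, times, onset)
        out$max_amplitude <- mx$max_amplitude
        out$max_d <- mx$max_d
        out$max_t <- mx$max_t
        out$direction <- mx$direction
        if (!is.null(steps)) {
          out$foot_at_onset <- foot_on_floor(steps, onset$onset_t)
          out$foot_at_max <- foot_on_floor(steps, mx$max_t)
        }
      } else {
        note("no_onset")
      }
    }
  }
  tibble::tibble(
    run_id = meta$run_id, participant_id = meta$participant$id,
    angle_deg = meta$angle_deg, width_w = meta$width_w,
    length_l = meta$length_l, motivation = meta$motivation,
    shoulder_width = meta$participant$shoulder_width_s,
    footedness = meta$participant$footedness,
    R = meta$width_w / meta$participant$shoulder_width_s,
    !!!out,
    reasons = paste(reasons, collapse = ";")
  )
}

#' Analyse a collection of runs
#'
#' Applies [analyze_run()] to every recording and aggregates: deceleration
#' histogram, two-stage mean speed and absolute-rotation profiles per
#' (angle, motivation), the crossing-offset law, per-motivation
#' amplitude-curve fits with critical ratios, and the split correlation
#' matrices. Aggregates that need more data than the collection provides
#' are returned as `NULL` with a note in `notes`.
#'
#' @param recordings list of [run_recording()] objects (or of
#'   [generate_run()] results, whose `$recording` is used).
#' @param config an [analysis_config()].
#' @return A list of class `experiment_results` with `runs` (per-run
#'   table), `decel_histogram`, `speed_profiles`, `rotation_profiles`,
#'   `crossing_law`, `amplitude_fits`, `correlations`, `notes`.
#' @export
analyze_experiment <- function(recordings, config = analysis_config()) {
  if (length(recordings) == 0) stop("empty run collection")
  recs <- lapply(recordings, function(r) {
    if (inherits(r, "run_recording")) r else r$recording
  })
  run_table <- dplyr::bind_rows(lapply(recs, analyze_run, config = config))
  notes <- character()

  profile_of <- function(rec, what) {
    crossing <- tryCatch(compute_crossing(rec$com, config$crossing$max_abs_y),
                         error = function(e) NULL)
    if (is.null(crossing)) return(NULL)
    d <- distance_to_crossing(rec$com, crossing)
    val <- if (what == "speed") {
      speed_along_path(d, rec$com$times, config$speed$window)
    } else {
      abs(shoulder_rotation(rec$shoulder_left, rec$shoulder_right, rec$com,
                            config$rotation$window,
                            config$rotation$min_displacement))
    }
    bin_profile(val, d, config$profile$bin, config$profile$range)
  }
  group_profiles <- function(what) {
    key <- paste(run_table$angle_deg, run_table$motivation, sep = "|")
    res <- lapply(split(seq_along(recs), key), function(idx) {
      ps <- Filter(Negate(is.null), lapply(recs[idx], profile_of, what = what))
      if (length(ps) == 0) return(NULL)
      mp <- mean_profile(ps)
      mp$angle_deg <- run_table$angle_deg[idx[1]]
      mp$motivation <- run_table$motivation[idx[1]]
      mp$n_runs <- length(ps)
      mp
    })
    dplyr::bind_rows(Filter(Negate(is.null), res))
  }

  crossing_law <- tryCatch(
    fit_crossing_model(data.frame(width = run_table$width_w,
                                  x_cross = run_table$x_cross,
                                  side = sign(run_table$angle_deg))),
    error = function(e) { notes <<- c(notes, paste("crossing_law:",
                                                   conditionMessage(e))); NULL })

  amplitude_fits <- lapply(split(run_table, run_table$motivation), function(sub) {
    pts <- data.frame(R = sub$R, amplitude = abs(sub$max_amplitude))
    fit <- tryCatch(suppressWarnings(fit_max_rotation_curve(pts)),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    cp <- tryCatch(
      critical_point(fit, group_sizes = max(2, floor(fit$n / 36)),
                     grid_n = config$rcrit$grid_n,
                     r_range = config$rcrit$r_range,
                     interval = config$rcrit$interval,
                     level = config$rcrit$level),
      error = function(e) NULL)
    list(fit = fit, critical_point = cp)
  })

  correlations <- tryCatch(
    correlation_matrix(run_table, level = config$rcrit$level,
                       r_split = config$r_split),
    error = function(e) { notes <<- c(notes, paste("correlations:",
                                                   conditionMessage(e))); NULL })

  structure(list(runs = run_table,
                 decel_histogram = deceleration_histogram(run_table),
                 speed_profiles = group_profiles("speed"),
                 rotation_profiles = group_profiles("rotation"),
                 crossing_law = crossing_law,
                 amplitude_fits = amplitude_fits,
                 correlations = correlations,
                 notes = notes),
            class = "experiment_results")
}

#' @export
print.experiment_results <- function(x, ...) {
  cat(sprintf("<experiment_results> %d runs; categories: %s\n",
              nrow(x$runs),
              paste(names(table(x$runs$decel_category)), collapse = ", ")))
  if (!is.null(x$crossing_law)) print(x$crossing_law)
  invisible(x)
}
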