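# Centred shrinking-window running mean on a (uniform) sample grid.
# The half-window shrinks symmetrically towards the edges so the first and
# last samples are always usable; exact on affine signals in the interior.
running_mean <- function(x, times, window) {
  n <- length(x)
  stopifnot(length(times) == n, window > 0)
  dt <- stats::median(diff(times))
  t0 <- times[1]; t1 <- times[n]
  h <- pmin(window / 2, times - t0, t1 - times)
  k <- pmin(floor(h / dt + 1e-9), seq_len(n) - 1, n - seq_len(n))
  cs <- c(0, cumsum(x))
  lo <- seq_len(n) - k
  hi <- seq_len(n) + k
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Smoothed acceleration along the path
#'
#' Central difference of the speed followed by the centred shrinking-window
#' running mean, with the same window as the speed estimator. The intended
#' input is the unsmoothed path speed ([raw_path_speed()]): the result is
#' then the 0.5 s running mean of the instantaneous acceleration, and a
#' braking episode of duration D appears as a negative interval of about
#' D + 0.5 s. Feeding the already-smoothed speed would smear episodes by a
#' further 0.5 s and push every short brake over the 1 s duration
#' threshold.
#'
#' @param v speed vector, normally from [raw_path_speed()].
#' @param times sample times (s).
#' @param window running-mean window (s).
#' @return Acceleration vector (m/s^2) aligned with `times`.
#' @export
smooth_acceleration <- function(v, times, window = 0.5) {
  n <- length(v)
  if (n < 3) stop("need at least 3 samples for acceleration")
  a <- numeric(n)
  a[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (times[3:n] - times[1:(n - 2)])
  a[1] <- (v[2] - v[1]) / (times[2] - times[1])
  a[n] <- (v[n] - v[n - 1]) / (times[n] - times[n - 1])
  running_mean(a, times, window)
}

#' Group contiguous negative-acceleration samples
#'
#' Maximal runs of strictly negative smoothed acceleration, restricted to
#' samples whose distance to crossing lies inside the search window
#' (default 0 m to 3.5 m before the bottleneck), in time order.
#'
#' @param a smoothed acceleration vector.
#' @param times sample times (s).
#' @param d distance-to-crossing vector.
#' @param window d window (m) searched.
#' @param tol numerical floor (m/s^2): samples count as negative only below
#'   `-tol`, so float-level wiggles of a constant-speed signal do not form
#'   groups. Physically negligible against the amplitude threshold.
#' @return A tibble with one row per group: `start`, `end` (sample indices),
#'   `t_start`, `t_end`, `duration` (s, span plus one sample period so a
#'   single sample has nonzero duration), `min_a`, `d_start`.
#' @export
group_negative <- function(a, times, d, window = c(0, 3.5), tol = 1e-9) {
  stopifnot(length(a) == length(times), length(a) == length(d))
  dt <- stats::median(diff(times))
  neg <- a < -tol & d >= window[1] & d <= window[2]
  if (!any(neg)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          t_start = numeric(), t_end = numeric(),
                          duration = numeric(), min_a = numeric(),
                          d_start = numeric()))
  }
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(
    start = starts[keep], end = ends[keep],
    t_start = times[starts[keep]], t_end = times[ends[keep]],
    duration = times[ends[keep]] - times[starts[keep]] + dt,
    min_a = vapply(which(keep), function(i) min(a[starts[i]:ends[i]]), 0),
    d_start = d[starts[keep]]
  )
}

#' Five-way classification of the deceleration behaviour
#'
#' Among the negative-acceleration groups of a run, the first group lasting
#' longer than the duration threshold is evaluated if one exists, otherwise
#' the first group. The evaluated group is rated `long_strong`,
#' `short_strong`, `long_weak` or `none` by whether its duration exceeds 1 s
#' and whether any of its samples is at least as large in magnitude as the
#' (negative) amplitude threshold; a run with no negative sample before
#' crossing is `none_at_all`. The deceleration point is the first sample of
#' the evaluated group (for `none`, the first sample of the first negative
#' group), reported as a distance to crossing.
#'
#' @param groups tibble from [group_negative()].
#' @param duration_threshold s; strictly-greater comparison.
#' @param amplitude_threshold m/s^2 (negative); "stronger" means
#'   `min_a <= amplitude_threshold`.
#' @return A list of class `deceleration_result` with `category`,
#'   `decel_point_d`, `t_start`, `t_end`.
#' @export
classify_deceleration <- function(groups, duration_threshold = 1.0,
                                  amplitude_threshold = -0.0075) {
  stopifnot(duration_threshold > 0, amplitude_threshold < 0)
  if (nrow(groups) == 0) {
    return(structure(list(category = "none_at_all", decel_point_d = NA_real_,
                          t_start = NA_real_, t_end = NA_real_),
                     class = "deceleration_result"))
  }
  long_idx <- which(groups$duration > duration_threshold)
  sel <- if (length(long_idx)) long_idx[1] else 1L
  g <- groups[sel, ]
  long <- g$duration > duration_threshold
  strong <- g$min_a <= amplitude_threshold
  category <- if (long && strong) "long_strong"
  else if (!long && strong) "short_strong"
  else if (long) "long_weak"
  else "none"
  point_row <- if (category == "none") 1L else sel
  structure(list(category = category,
                 decel_point_d = groups$d_start[point_row],
                 t_start = g$t_start, t_end = g$t_end),
            class = "deceleration_result")
}

#' Amplitude threshold from the straight-walking phase
#'
#' Minus three standard deviations of the smoothed acceleration over the
#' straight-walking window (default 3.5 m to 1.5 m before crossing); the
#' rule that yields the -0.0075 m/s^2 default.
#'
#' @param a smoothed acceleration vector.
#' @param d distance-to-crossing vector.
#' @param straight_window d window (m) of straight walking.
#' @return Negative threshold (m/s^2).
#' @export
amplitude_threshold_from_straight <- function(a, d,
                                              straight_window = c(1.5, 3.5)) {
  sel <- d >= straight_window[1] & d <= straight_window[2]
  if (sum(sel) < 2) stop("straight-walking window is empty")
  -3 * stats::sd(a[sel])
}

decel_categories <- function() {
  c("long_strong", "short_strong", "long_weak", "none", "none_at_all")
}

#' Histogram of deceleration categories
#'
#' @param results data frame with columns `angle_deg`, `motivation`,
#'   `decel_category`.
#' @return A tibble of counts per (angle, motivation, category); counts over
#'   all cells sum to the number of runs.
#' @export
deceleration_histogram <- function(results) {
  stopifnot(nrow(results) >= 1)
  df <- as.data.frame(results)
  df$decel_category <- factor(df$decel_category, levels = decel_categories())
  tab <- as.data.frame(table(angle_deg = df$angle_deg,
                             motivation = df$motivation,
                             category = df$decel_category))
  out <- tibble::as_tibble(tab)
  names(out)[4] <- "count"
  out$angle_deg <- as.numeric(as.character(out$angle_deg))
  out$motivation <- as.character(out$motivation)
  out$category <- as.character(out$category)
  out
}
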