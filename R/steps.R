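heel_speed <- function(ps, norm = c("l1", "l2")) {
  norm <- match.arg(norm)
  t <- ps$times
  n <- length(t)
  vxy <- apply(ps$positions[, 1:2, drop = FALSE], 2, function(col) {
    v <- numeric(n)
    v[2:(n - 1)] <- (col[3:n] - col[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    v[1] <- (col[2] - col[1]) / (t[2] - t[1])
    v[n] <- (col[n] - col[n - 1]) / (t[n] - t[n - 1])
    v
  })
  if (norm == "l1") abs(vxy[, 1]) + abs(vxy[, 2]) else sqrt(rowSums(vxy^2))
}

stance_starts <- function(speed, times, threshold, min_stance) {
  below <- speed < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (times[ends] - times[starts]) >= min_stance
  # a stance already in progress at the first sample has no observable
  # onset; it only counts when the foot is static through the whole series
  keep <- keep & (starts > 1 | ends == length(times))
  starts[keep]
}

#' Detect heel strikes
#'
#' Per heel, the planar speed (by default the L1 sum |vx| + |vy| of the
#' coordinate derivatives) is compared to a threshold; maximal intervals
#' below the threshold lasting at least `min_stance` are stance phases, and
#' each stance onset is a heel strike. A stance already in progress at the
#' first sample has no observable onset and is not an event (unless the
#' foot is static through the entire recording). Strikes of both feet are
#' merged in time order. When `threshold` is `NULL` it is set per run to
#' `threshold_frac` of the 95th percentile of the pooled heel speed.
#'
#' @param heel_left,heel_right [point_series()] of the heels.
#' @param threshold absolute speed threshold (m/s), or `NULL` for the
#'   relative rule.
#' @param threshold_frac fraction used by the relative rule.
#' @param min_stance minimal stance duration (s).
#' @param speed_norm `"l1"` (sum of |vx| and |vy|) or `"l2"`.
#' @return A list of class `step_events` with `times`, `feet`
#'   (`"left"`/`"right"`), `alternating` and `threshold`.
#' @export
detect_heel_strikes <- function(heel_left, heel_right, threshold = NULL,
                                threshold_frac = 0.2, min_stance = 0.1,
                                speed_norm = "l1") {
  sl <- heel_speed(heel_left, speed_norm)
  sr <- heel_speed(heel_right, speed_norm)
  if (is.null(threshold)) {
    threshold <- threshold_frac * stats::quantile(c(sl, sr), 0.95, names = FALSE)
  }
  if (threshold >= max(sl) && threshold >= max(sr)) {
    stop("threshold too high: no swing phases detectable")
  }
  il <- stance_starts(sl, heel_left$times, threshold, min_stance)
  ir <- stance_starts(sr, heel_right$times, threshold, min_stance)
  times <- c(heel_left$times[il], heel_right$times[ir])
  feet <- c(rep("left", length(il)), rep("right", length(ir)))
  o <- order(times)
  times <- times[o]; feet <- feet[o]
  alternating <- length(feet) < 2 || all(feet[-1] != feet[-length(feet)])
  structure(list(times = times, feet = feet, alternating = alternating,
                 threshold = threshold),
            class = "step_events")
}

#' @export
print.step_events <- function(x, ...) {
  cat(sprintf("<step_events> %d strikes (%s), alternating: %s\n",
              length(x$times), paste(substr(x$feet, 1, 1), collapse = ""),
              x$alternating))
  invisible(x)
}

#' Foot on the floor at an event time
#'
#' The label of the latest heel strike at or before `t_event`. No foot is
#' assigned (`"none"`) when the strike sequence does not alternate strictly
#' between feet — a missed ground contact cannot be ruled out then — or
#' when the event precedes the first strike.
#'
#' @param events a [detect_heel_strikes()] result.
#' @param t_event event time (s).
#' @return `"left"`, `"right"` or `"none"`.
#' @export
foot_on_floor <- function(events, t_event) {
  stopifnot(length(events$times) >= 1)
  i <- findInterval(t_event, events$times)
  if (i == 0) return("none")
  feet <- events$feet[seq_len(i)]
  if (length(feet) >= 2 && any(feet[-1] == feet[-length(feet)])) return("none")
  feet[i]
}
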