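rot90cw <- function(v) c(v[2], -v[1])    # rotate a planar vector by -90 deg

#' Shoulder-rotation signal
#'
#' The shoulder line is the vector from the right to the left shoulder
#' (acromion to acromion); the facing direction is that vector rotated by
#' -90 degrees. The movement direction at each sample is the chord of the
#' COM trajectory across a 0.5 s interval around the sample, shrunk
#' one-sidedly at the trajectory edges. The rotation gamma is the signed
#' angle from the movement direction to the facing direction: 0 when the
#' shoulder line is perpendicular to the movement, positive for a left turn
#' (counter-clockwise from above), negative for a right turn.
#'
#' @param shoulder_left,shoulder_right,com [point_series()] on a common
#'   time base.
#' @param window movement-direction interval (s).
#' @param min_displacement COM displacement (m) below which gamma is
#'   undefined (`NA`) at that sample.
#' @return Numeric vector of gamma in degrees, in (-180, 180\].
#' @export
shoulder_rotation <- function(shoulder_left, shoulder_right, com,
                              window = 0.5, min_displacement = 1e-3) {
  times <- com$times
  n <- length(times)
  stopifnot(length(shoulder_left$times) == n, length(shoulder_right$times) == n)
  h <- window / 2
  t_lo <- pmax(times - h, times[1])
  t_hi <- pmin(times + h, times[n])
  px <- com$positions[, 1]; py <- com$positions[, 2]
  mx <- interp_at(times, px, t_hi) - interp_at(times, px, t_lo)
  my <- interp_at(times, py, t_hi) - interp_at(times, py, t_lo)
  disp <- sqrt(mx^2 + my^2)
  sx <- shoulder_left$positions[, 1] - shoulder_right$positions[, 1]
  sy <- shoulder_left$positions[, 2] - shoulder_right$positions[, 2]
  fx <- sy                                  # facing = shoulder line rotated -90
  fy <- -sx
  gamma <- atan2(mx * fy - my * fx, mx * fx + my * fy) * 180 / pi
  gamma[disp < min_displacement] <- NA_real_
  gamma
}

#' Onset of shoulder rotation
#'
#' The baseline rotation noise is estimated over the straight-walking phase
#' (default 3.5 m to 1.5 m before crossing): `sigma_straight` is the
#' standard deviation of gamma there, after subtracting the straight-phase
#' mean (per-run posture bias). The onset is the first sample past the
#' straight phase (d below its near edge) where |gamma - mean| exceeds
#' `n_sigma` times that baseline; if the threshold is never exceeded there
#' is no onset.
#'
#' @param gamma rotation signal (deg) from [shoulder_rotation()].
#' @param d distance-to-crossing vector.
#' @param times sample times (s).
#' @param straight_window d window (m) of straight walking.
#' @param n_sigma threshold in baseline standard deviations.
#' @param center subtract the straight-phase mean before thresholding.
#' @return A list of class `rotation_onset` with `onset_d`, `onset_t`,
#'   `onset_index`, `sigma_straight`, `straight_mean`, `detected`.
#' @export
rotation_onset <- function(gamma, d, times, straight_window = c(1.5, 3.5),
                           n_sigma = 3, center = TRUE) {
  sel <- d >= straight_window[1] & d <= straight_window[2] & !is.na(gamma)
  if (sum(sel) < 10) stop("straight-walking window has fewer than 10 samples")
  mu <- if (center) mean(gamma[sel]) else 0
  sigma <- stats::sd(gamma[sel] - mu)
  search <- which(d < straight_window[1])
  excess <- abs(gamma[search] - mu) > n_sigma * sigma
  hit <- search[which(excess)[1]]
  if (length(hit) == 0 || is.na(hit)) {
    return(structure(list(onset_d = NA_real_, onset_t = NA_real_,
                          onset_index = NA_integer_, sigma_straight = sigma,
                          straight_mean = mu, detected = FALSE),
                     class = "rotation_onset"))
  }
  structure(list(onset_d = d[hit], onset_t = times[hit],
                 onset_index = as.integer(hit), sigma_straight = sigma,
                 straight_mean = mu, detected = TRUE),
            class = "rotation_onset")
}

#' Maximum shoulder rotation after the onset
#'
#' The sample at or after the onset maximising |gamma - straight mean|
#' (earliest sample on ties). The amplitude is reported signed — positive
#' for a left turn, negative for a right turn — together with the signed
#' distance to crossing at which it occurs (negative = after crossing).
#'
#' @param gamma rotation signal (deg).
#' @param d distance-to-crossing vector.
#' @param times sample times (s).
#' @param onset a [rotation_onset()] result.
#' @return A list of class `rotation_max` with `max_amplitude` (deg,
#'   signed), `max_d`, `max_t`, `direction` (`"left"`/`"right"`), `detected`;
#'   all `NA` when the onset was not detected.
#' @export
max_rotation <- function(gamma, d, times, onset) {
  if (!isTRUE(onset$detected)) {
    return(structure(list(max_amplitude = NA_real_, max_d = NA_real_,
                          max_t = NA_real_, direction = NA_character_,
                          detected = FALSE),
                     class = "rotation_max"))
  }
  idx <- onset$onset_index:length(gamma)
  dev <- abs(gamma[idx] - onset$straight_mean)
  i <- idx[which.max(dev)]
  amp <- gamma[i] - onset$straight_mean
  structure(list(max_amplitude = amp, max_d = d[i], max_t = times[i],
                 direction = if (amp >= 0) "left" else "right",
                 detected = TRUE),
            class = "rotation_max")
}
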