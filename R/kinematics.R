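#' Locate the crossing point on the COM trajectory
#'
#' The crossing is the COM sample closest to the bottleneck line y = 0; ties
#' are broken towards the earliest sample. Its lateral position `x_cross` is
#' the crossing point reported throughout the analysis.
#'
#' @param com a [point_series()] of the centre of mass.
#' @param max_abs_y error guard: if the trajectory never comes closer to the
#'   line than this (m), there is no crossing.
#' @return A list of class `crossing_result` with `x_cross`, `t_cross`,
#'   `index` and `min_abs_y`.
#' @export
compute_crossing <- function(com, max_abs_y = 0.5) {
  y <- com$positions[, 2]
  i <- which.min(abs(y))        # which.min returns the earliest tie
  if (abs(y[i]) > max_abs_y) {
    stop(sprintf("no crossing: COM never comes within %.2f m of y = 0",
                 max_abs_y))
  }
  structure(list(x_cross = unname(com$positions[i, 1]),
                 t_cross = com$times[i],
                 index = i, min_abs_y = unname(abs(y[i]))),
            class = "crossing_result")
}

#' Signed distance to crossing along the COM path
#'
#' Cumulative chord length along the COM trajectory, measured to the crossing
#' sample: positive before the crossing, zero at it and negative after (the
#' distance already walked past the bottleneck).
#'
#' @param com a [point_series()].
#' @param crossing a [compute_crossing()] result.
#' @return Numeric vector `d` aligned with `com$times`.
#' @export
distance_to_crossing <- function(com, crossing) {
  p <- com$positions[, 1:2, drop = FALSE]
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))               # arc length from the first sample
  s[crossing$index] - s
}

# Interpolated lookup of a sampled signal; exact on affine signals.
interp_at <- function(times, values, t) {
  stats::approx(times, values, xout = t, rule = 2)$y
}

#' Unsmoothed path speed
#'
#' Central difference of the distance-to-crossing signal (one-sided at the
#' edges): the sample-rate speed before any running-mean smoothing. This is
#' the input to [smooth_acceleration()]; smoothing the speed twice would
#' smear a braking episode by a full second and make the duration
#' thresholds of the deceleration categories unidentifiable.
#'
#' @param d distance-to-crossing vector.
#' @param times sample times (s).
#' @return Speed vector (m/s).
#' @export
raw_path_speed <- function(d, times) {
  n <- length(d)
  stopifnot(length(times) == n, n >= 3)
  v <- numeric(n)
  v[2:(n - 1)] <- (d[1:(n - 2)] - d[3:n]) / (times[3:n] - times[1:(n - 2)])
  v[1] <- (d[1] - d[2]) / (times[2] - times[1])
  v[n] <- (d[n - 1] - d[n]) / (times[n] - times[n - 1])
  v
}

#' Running-mean speed along the path
#'
#' Speed estimated from the distance-to-crossing signal with a centred
#' running mean: v(t) = (d(t - h) - d(t + h)) / (2 h), where h is half the
#' window, shrunk symmetrically near the trajectory edges so the first or
#' last sample is always included. This equals the window mean of the
#' instantaneous path speed and is exact on affine d(t).
#'
#' @param d distance-to-crossing vector from [distance_to_crossing()].
#' @param times sample times (s).
#' @param window full window length (s), default 0.5 (about one step).
#' @return Numeric speed vector (m/s), aligned with `times`.
#' @export
speed_along_path <- function(d, times, window = 0.5) {
  stopifnot(length(d) == length(times), length(d) >= 2, window > 0)
  dt <- stats::median(diff(times))
  if (window <= dt) stop("window must exceed the sample spacing")
  t0 <- times[1]; t1 <- times[length(times)]
  h <- pmin(window / 2, pmax(times - t0, 0), pmax(t1 - times, 0))
  # at the extreme edges fall back to a one-sided single-step difference
  small <- h < dt / 2
  v <- numeric(length(times))
  if (any(!small)) {
    lo <- interp_at(times, d, times[!small] - h[!small])
    hi <- interp_at(times, d, times[!small] + h[!small])
    v[!small] <- (lo - hi) / (2 * h[!small])
  }
  if (any(small)) {
    idx <- which(small)
    for (i in idx) {
      j <- if (i == 1) 2 else if (i == length(times)) length(times) - 1 else
        c(i - 1, i + 1)[which.max(abs(times[c(i - 1, i + 1)] - times[i]))]
      v[i] <- (d[min(i, j)] - d[max(i, j)]) / abs(times[j] - times[i])
    }
  }
  v
}

#' Mean approach speed
#'
#' Path length divided by elapsed time from the first sample whose Euclidean
#' distance to the bottleneck centre (the origin) is at most `radius` until
#' the crossing sample. The 3 m default radius excludes the acceleration
#' phase at the start of a run.
#'
#' @param com a [point_series()].
#' @param crossing a [compute_crossing()] result.
#' @param radius start radius (m).
#' @return Mean speed (m/s).
#' @export
mean_speed <- function(com, crossing, radius = 3) {
  p <- com$positions[, 1:2, drop = FALSE]
  r <- sqrt(rowSums(p^2))
  i0 <- which(r <= radius)[1]
  if (is.na(i0)) stop("COM never enters the ", radius, " m radius")
  if (i0 >= crossing$index) stop("COM enters the radius only after crossing")
  idx <- i0:crossing$index
  seg <- sqrt(rowSums((p[idx[-1], , drop = FALSE] -
                         p[idx[-length(idx)], , drop = FALSE])^2))
  sum(seg) / (com$times[crossing$index] - com$times[i0])
}

#' Maximum and minimum speed of a run
#'
#' vmax is the maximum running-mean speed over the samples with distance to
#' crossing inside `window` (default 3.5 m to 0 m, the straight-walking
#' phase up to the crossing); vmin is the minimum speed from the time of
#' vmax until the end of the walking path. Ties resolve to the earliest
#' sample.
#'
#' @param v speed vector from [speed_along_path()].
#' @param d distance-to-crossing vector.
#' @param times sample times (s).
#' @param window distance window (m) searched for vmax.
#' @return A list with `vmax`, `d_at_vmax`, `t_at_vmax`, `vmin`.
#' @export
find_vmax_vmin <- function(v, d, times, window = c(0, 3.5)) {
  stopifnot(length(v) == length(d), length(d) == length(times))
  in_win <- d >= window[1] & d <= window[2]
  if (!any(in_win)) {
    stop(sprintf("run does not cover the d interval [%g, %g] m",
                 window[1], window[2]))
  }
  if (min(d) > window[1] + 0.2) {
    stop(sprintf("run ends before reaching d = %g m", window[1]))
  }
  iw <- which(in_win)
  imax <- iw[which.max(v[iw])]
  after <- imax:length(v)
  imin <- after[which.min(v[after])]
  list(vmax = v[imax], d_at_vmax = d[imax], t_at_vmax = times[imax],
       vmin = v[imin], d_at_vmin = d[imin])
}

#' Bin a per-run profile over distance to crossing
#'
#' First stage of the two-stage profile mean: per-run means of `values` in
#' fixed-width bins of d.
#'
#' @param values signal aligned with `d` (speed, absolute rotation, ...).
#' @param d distance-to-crossing vector.
#' @param bin bin width (m).
#' @param range d range covered (m).
#' @return A tibble of class `profile_bins` with `center`, `mean`, `count`.
#' @export
bin_profile <- function(values, d, bin = 0.1, range = c(-1, 4)) {
  if (length(values) != length(d)) stop("values and d have mismatched lengths")
  edges <- seq(range[1], range[2], by = bin)
  centers <- edges[-length(edges)] + bin / 2
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  keep <- idx >= 1 & idx <= length(centers) & !is.na(values)
  agg_mean <- tapply(values[keep], idx[keep], mean)
  agg_n <- tapply(values[keep], idx[keep], length)
  m <- rep(NA_real_, length(centers))
  n <- rep(0L, length(centers))
  at <- as.integer(names(agg_mean))
  m[at] <- as.numeric(agg_mean)
  n[at] <- as.integer(agg_n)
  structure(tibble::tibble(center = centers, mean = m, count = n),
            class = c("profile_bins", class(tibble::tibble())))
}

#' Cross-run mean profile
#'
#' Second stage of the two-stage mean: the unweighted mean over runs of the
#' per-run bin means (never a pooled single-stage mean), so runs with more
#' samples in a bin do not dominate it.
#'
#' @param profiles list of [bin_profile()] results on identical bins.
#' @return A `profile_bins` tibble; `count` is the number of runs
#'   contributing to each bin.
#' @export
mean_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  centers <- profiles[[1]]$center
  for (p in profiles) stopifnot(isTRUE(all.equal(p$center, centers)))
  mat <- vapply(profiles, function(p) p$mean, numeric(length(centers)))
  mat <- matrix(mat, nrow = length(centers))
  m <- rowMeans(mat, na.rm = TRUE)
  n <- rowSums(!is.na(mat))
  m[n == 0] <- NA_real_
  structure(tibble::tibble(center = centers, mean = m, count = as.integer(n)),
            class = c("profile_bins", class(tibble::tibble())))
}
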