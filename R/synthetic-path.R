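# Path geometry for the synthetic generator: a straight entry line from the
# starting area (on a circle of `start_radius` around the bottleneck centre)
# towards a corner point above the crossing, a circular-arc fillet, and a
# straight exit segment through the crossing point (x_cross, 0) heading -y.
# Arc-length parameterised; heading is continuous (tangent blend) and the
# walker exits straight, so the heading is tangent to the exit line at the
# crossing itself.
build_path <- function(angle_deg, x_cross, geometry) {
  th <- angle_deg * pi / 180
  p0 <- geometry$start_radius * c(sin(th), cos(th))
  # at +/-90 deg the circle touches the crossing line; keep the start on the
  # approach side (walkers round the wall edge, they do not stand on the line)
  p0[2] <- max(p0[2], 0.3)
  corner <- c(x_cross, geometry$corner_y)
  exit_dir <- c(0, -1)
  u <- corner - p0
  l_in <- sqrt(sum(u^2))
  u <- u / l_in
  cross_z <- u[1] * exit_dir[2] - u[2] * exit_dir[1]
  delta <- acos(max(-1, min(1, sum(u * exit_dir))))
  if (delta < 1e-6) {
    # effectively collinear: single straight line through the crossing
    seg1 <- l_in + geometry$corner_y
    total <- seg1 + geometry$exit_length
    point <- function(s) {
      t(vapply(s, function(si) p0 + u * si, numeric(2)))
    }
    heading <- function(s) rep(atan2(u[2], u[1]), length(s))
    return(list(point = point, heading = heading, total = total,
                s_cross = l_in + geometry$corner_y))
  }
  tl <- geometry$fillet_frac * min(l_in, geometry$corner_y)
  r_arc <- tl / tan(delta / 2)
  turn <- sign(cross_z)                      # +1 = counter-clockwise turn
  t1 <- corner - u * tl                      # arc entry
  left_u <- c(-u[2], u[1])
  center <- t1 + turn * r_arc * left_u
  a1 <- atan2(t1[2] - center[2], t1[1] - center[1])
  l1 <- l_in - tl                            # entry segment length
  l2 <- r_arc * delta                        # arc length
  l3 <- (geometry$corner_y - tl) + geometry$exit_length
  s_cross <- l1 + l2 + (geometry$corner_y - tl)
  h0 <- atan2(u[2], u[1])
  point <- function(s) {
    t(vapply(s, function(si) {
      if (si <= l1) {
        p0 + u * si
      } else if (si <= l1 + l2) {
        phi <- a1 + turn * (si - l1) / r_arc
        center + r_arc * c(cos(phi), sin(phi))
      } else {
        c(x_cross, (geometry$corner_y - tl) - (si - l1 - l2))
      }
    }, numeric(2)))
  }
  heading <- function(s) {
    vapply(s, function(si) {
      if (si <= l1) h0
      else if (si <= l1 + l2) h0 + turn * (si - l1) / r_arc
      else -pi / 2
    }, numeric(1))
  }
  list(point = point, heading = heading, total = l1 + l2 + l3,
       s_cross = s_cross)
}

# Advance the arc parameter so that the straight-line chord from point(s) to
# point(s + ds) has exactly the requested length; fixed-point iteration
# (chord <= arc, curvature is small) converging to float precision.
step_along_path <- function(path, s, chord) {
  if (chord <= 0) return(s)
  ds <- chord
  p_from <- drop(path$point(s))
  for (i in 1:6) {
    p_to <- drop(path$point(min(s + ds, path$total)))
    len <- sqrt(sum((p_to - p_from)^2))
    ds <- ds + (chord - len)
  }
  s + ds
}

# Band-limited Gaussian noise: a k-sample moving average of white noise,
# rescaled to the requested marginal standard deviation.
smooth_noise <- function(n, sd, k = 15) {
  if (sd <= 0) return(numeric(n))
  if (k <= 1) return(stats::rnorm(n, 0, sd))
  e <- stats::rnorm(n + k - 1)
  cs <- c(0, cumsum(e))
  ma <- (cs[(k + 1):(n + k)] - cs[1:n]) / k
  ma * sd * sqrt(k)
}
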