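straight_series <- function(v = 1.5, x = 0.1, y0 = 3, y1 = -2, fs = 60) {
  times <- seq(0, (y0 - y1) / v, by = 1 / fs)
  point_series(times, cbind(x, y0 - v * times))
}

test_that("the crossing is the sample closest to y = 0, earliest on ties", {
  ps <- point_series(seq(0, 0.4, 0.1) / 1,
                     cbind(0.1, c(0.5, 0.2, 0.2, -0.1, -0.6)))
  cr <- compute_crossing(ps)
  expect_equal(cr$index, 4L)
  expect_equal(cr$x_cross, 0.1)
  ps2 <- point_series(c(0, 1, 2), cbind(0, c(0.2, 0.2, 0.7)))
  expect_equal(compute_crossing(ps2)$index, 1L)   # earliest of the tie
  expect_error(compute_crossing(point_series(c(0, 1), cbind(0, c(3, 2)))),
               "no crossing")
})

test_that("crossing search matches a brute-force argmin on noisy paths", {
  set.seed(42)
  for (rep in 1:10) {
    y <- seq(2, -2, length.out = 120) + rnorm(120, 0, 0.05)
    ps <- point_series(seq_along(y) / 60, cbind(rnorm(120, 0.2, 0.02), y))
    expect_equal(compute_crossing(ps)$index, which.min(abs(y)))
  }
})

test_that("distance to crossing is the signed chord sum along the path", {
  ps <- straight_series(v = 1, y0 = 2, y1 = -2)
  cr <- compute_crossing(ps)
  d <- distance_to_crossing(ps, cr)
  i <- which.min(abs(ps$times - (cr$t_cross - 2)))
  expect_equal(d[i], 2, tolerance = 1e-9)          # 2 s earlier at 1 m/s
  expect_equal(d[cr$index], 0)
  expect_lt(max(abs(diff(d) + 1 / 60)), 1e-12)     # chord per sample

  # L-shaped path: path length, not the Euclidean shortcut
  leg <- seq(0, 1, by = 0.05)
  pos <- rbind(cbind(leg, 0), cbind(1, leg[-1]))
  psl <- point_series(seq_len(nrow(pos)) / 20, pos[nrow(pos):1, ])
  crl <- list(index = nrow(pos), t_cross = nrow(pos) / 20)
  dl <- distance_to_crossing(psl, structure(crl, class = "crossing_result"))
  corner <- nrow(pos) - length(leg) + 1
  expect_equal(dl[corner], 1.0, tolerance = 1e-12)
  expect_equal(dl[1], 2.0, tolerance = 1e-12)
})

test_that("chord sums agree with a brute-force segment-norm oracle", {
  set.seed(7)
  pos <- apply(matrix(rnorm(2 * 80, 0, 0.1), ncol = 2), 2, cumsum)
  ps <- point_series(seq_len(80) / 60, pos)
  cr <- structure(list(index = 40L), class = "crossing_result")
  d <- distance_to_crossing(ps, cr)
  oracle <- sapply(seq_len(80), function(i) {
    idx <- sort(c(i, 40))
    s <- sum(sqrt(rowSums((pos[(idx[1] + 1):idx[2], , drop = FALSE] -
                             pos[idx[1]:(idx[2] - 1), , drop = FALSE])^2)))
    if (i == 40) 0 else if (i < 40) s else -s
  })
  expect_lt(max(abs(d - oracle)), 1e-12)
})

test_that("running-mean speed is exact on constant and step profiles", {
  ps <- straight_series(v = 1.5)
  cr <- compute_crossing(ps)
  d <- distance_to_crossing(ps, cr)
  v <- speed_along_path(d, ps$times, 0.5)
  expect_equal(v, rep(1.5, length(v)), tolerance = 1e-9)  # edges included

  # speed step 1 -> 2 at t0: the centred window averages to 1.5
  fs <- 60
  t <- seq(0, 4, by = 1 / fs)
  vtrue <- ifelse(t < 2, 1, 2)
  dsig <- 5 - cumsum(c(0, vtrue[-1] / fs))
  vs <- speed_along_path(dsig, t, 0.5)
  i0 <- which(t == 2)
  expect_equal(vs[i0], 1.5, tolerance = 0.04)  # one-sample step attribution
  expect_error(speed_along_path(dsig, t, 1 / fs / 2), "window")
})

test_that("running-mean speed equals the analytic window mean (triangle)", {
  fs <- 100; window <- 0.5
  t <- seq(0, 6, by = 1 / fs)
  # triangular speed: rises 1->2 over [0,3], falls back over [3,6]
  Dfun <- function(u) ifelse(u < 3, u + u^2 / 6,
                             4.5 + 2 * (u - 3) - (u - 3)^2 / 6)
  d <- 10 - Dfun(t)
  v <- speed_along_path(d, t, window)
  h <- pmin(window / 2, t, max(t) - t)
  interior <- h >= 1 / fs
  oracle <- (Dfun(t + h) - Dfun(t - h)) / (2 * h)
  expect_lt(max(abs(v[interior] - oracle[interior])), 1e-10)
})

test_that("mean speed starts at the 3 m radius and ends at the crossing", {
  ps <- straight_series(v = 1.2, x = 0, y0 = 4, y1 = -1)
  cr <- compute_crossing(ps)
  expect_equal(mean_speed(ps, cr), 1.2, tolerance = 1e-6)

  # accelerate only outside the radius, hold 1.5 inside
  fs <- 60
  t <- seq(0, 6, by = 1 / fs)
  vtrue <- pmin(0.5 + 1 * t, 1.5)
  y <- 5 - cumsum(c(0, vtrue[-1] / fs))
  ps2 <- point_series(t, cbind(0, y))
  cr2 <- compute_crossing(ps2)
  expect_equal(mean_speed(ps2, cr2), 1.5, tolerance = 1e-3)
  expect_error(mean_speed(straight_series(y0 = 9, y1 = 5), cr), "radius")
})

test_that("vmax is searched in the 3.5-0 m window and vmin after it", {
  fs <- 60
  t <- seq(0, 8, by = 1 / fs)
  vtrue <- pmin(1.4 * t, 2.1)                    # 1.4 m/s^2 for 1.5 s
  dsig <- 6 - cumsum(c(0, vtrue[-1] / fs))
  v <- speed_along_path(dsig, t, 0.5)
  res <- find_vmax_vmin(v, dsig, t)
  expect_equal(res$vmax, 2.1, tolerance = 5e-3)
  expect_equal(res$vmin, v[length(v)], tolerance = 1e-9)

  vc <- rep(1.3, length(t))
  res2 <- find_vmax_vmin(vc, dsig, t)
  expect_equal(res2$vmax, 1.3)
  expect_equal(res2$vmin, 1.3)

  # a larger maximum outside the window must not win
  vout <- ifelse(dsig > 3.6, 2.5, ifelse(dsig > 0, 1.8, 1.0))
  res3 <- find_vmax_vmin(vout, dsig, t)
  expect_equal(res3$vmax, 1.8)
})

test_that("profiles use the two-stage (per-run, then across-run) mean", {
  d <- seq(3.95, -0.95, by = -0.1)
  p1 <- bin_profile(rep(1, length(d)), d)
  expect_true(all(abs(p1$mean[p1$count > 0] - 1) < 1e-12))
  expect_equal(nrow(p1), 50L)
  expect_equal(diff(p1$center)[1], 0.1)

  # run 2 has many more samples; the cross-run mean must stay unweighted
  d2 <- rep(d, each = 7)
  p2 <- bin_profile(rep(2, length(d2)), d2)
  mp <- mean_profile(list(p1, p2))
  expect_true(all(abs(mp$mean[mp$count == 2] - 1.5) < 1e-12))

  set.seed(3)
  vals <- rnorm(400); dr <- runif(400, -1, 4)
  pb <- bin_profile(vals, dr)
  edges <- seq(-1, 4, by = 0.1)
  oracle <- sapply(seq_len(50), function(k) {
    sel <- dr >= edges[k] & dr <= edges[k + 1] &
      (dr < edges[k + 1] | k == 50)
    if (!any(sel)) NA_real_ else mean(vals[sel])
  })
  agree <- is.na(pb$mean) == is.na(oracle)
  expect_true(all(agree))
  expect_lt(max(abs(pb$mean - oracle), na.rm = TRUE), 1e-10)
  expect_error(bin_profile(vals[-1], dr), "mismatch")
})

test_that("speed metrics are invariant under mirroring", {
  gr <- gen_one(noiseless_config(), angle = 60, seed = 21)
  r1 <- analyze_run(gr$recording)
  r2 <- analyze_run(mirror_run(gr$recording))
  expect_equal(r2$mean_speed, r1$mean_speed, tolerance = 1e-9)
  expect_equal(r2$vmax, r1$vmax, tolerance = 1e-9)
  expect_equal(r2$vmin, r1$vmin, tolerance = 1e-9)
  expect_equal(r2$x_cross, -r1$x_cross, tolerance = 1e-9)
})
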