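test_that("the amplitude fit recovers noiseless parameters exactly", {
  set.seed(1)
  R <- runif(60, 0.8, 2.6)
  pts <- data.frame(R = R, amplitude = 40 * exp(-3 * R) + 5)
  fit <- fit_max_rotation_curve(pts)
  expect_false(fit$degenerate)
  expect_equal(unname(fit$parameters["a"]), 40, tolerance = 1e-6)
  expect_equal(unname(fit$parameters["b"]), 3, tolerance = 1e-6)
  expect_equal(unname(fit$parameters["d"]), 5, tolerance = 1e-6)
  expect_equal(unname(fit$parameters["c"]), 0)
  expect_equal(length(fit$residuals), nrow(pts))
})

test_that("constant amplitude data degenerate to d = mean, a = 0", {
  set.seed(2)
  pts <- data.frame(R = runif(30, 0.8, 2.6), amplitude = 7)
  fit <- fit_max_rotation_curve(pts)
  expect_true(fit$degenerate)
  expect_equal(unname(fit$parameters["d"]), 7)
  expect_equal(unname(fit$parameters["a"]), 0)
  expect_error(fit_max_rotation_curve(pts[1:5, ]), "at least 8")
})

test_that("noisy amplitude data recover parameters within 3 SE", {
  set.seed(3)
  R <- runif(400, 0.8, 2.6)
  pts <- data.frame(R = R, amplitude = 150 * exp(-2.5 * R) + 10 + rnorm(400, 0, 3))
  fit <- fit_max_rotation_curve(pts)
  truth <- c(a = 150, b = 2.5, d = 10)
  for (p in names(truth)) {
    expect_lt(abs(fit$parameters[[p]] - truth[[p]]), 3 * fit$se[[p]] + 1e-9)
  }
})

test_that("the critical point localises a plateau edge", {
  f_pl <- function(R) ifelse(R < 1.6, 40 * (1.6 - R), 0) + 10
  cp <- critical_point(f_pl, residual_sd = 0.5, group_sizes = 10)
  expect_lte(abs(cp$rcrit - 1.6), 0.05)
  expect_s3_class(cp, "critical_point")
  expect_equal(length(cp$grid), 180L)
  expect_equal(length(cp$interval_means), 36L)
})

test_that("degenerate curves give the domain edges", {
  flat <- function(R) rep(10, length(R))
  expect_equal(critical_point(flat, residual_sd = 0.5, group_sizes = 10)$rcrit,
               0.8)
  steep <- function(R) 100 - 30 * R
  expect_gte(critical_point(steep, residual_sd = 1e-4,
                            group_sizes = 10)$rcrit, 2.5)
  expect_error(critical_point(flat, residual_sd = 0.5,
                              group_sizes = c(5, rep(0, 35))),
               "fewer than 2 intervals")
})

test_that("a steeper approach to the plateau never increases Rcrit", {
  rc <- sapply(c(0.8, 1.5, 2.5, 4, 6), function(b) {
    critical_point(function(x) 150 * exp(-b * x) + 10,
                   residual_sd = 1.5, group_sizes = 10)$rcrit
  })
  expect_true(all(diff(rc) <= 1e-9))
})

test_that("fit plus critical point recover a constructed plateau edge", {
  oracle <- critical_point(function(x) 150 * exp(-2.5 * x) + 10,
                           residual_sd = 1, group_sizes = 10)$rcrit
  for (s in 1:20) {
    set.seed(s)
    R <- runif(1000, 0.8, 2.6)
    amp <- 150 * exp(-2.5 * R) + 10 + rnorm(1000, 0, 1)
    fit <- fit_max_rotation_curve(data.frame(R = R, amplitude = amp))
    cp <- critical_point(fit, residual_sd = 1, group_sizes = 10)
    expect_lte(abs(cp$rcrit - oracle), 0.05)
  }
})

test_that("the crossing law is recovered exactly from noiseless offsets", {
  widths <- rep(c(0.4, 0.5, 0.6, 0.7, 0.8, 1.0), each = 4)
  side <- rep(c(1, -1), length.out = length(widths))
  x <- side * (0.176 * widths - 0.078)
  law <- fit_crossing_model(data.frame(width = widths, x_cross = x,
                                       side = side))
  expect_equal(law$slope, 0.176, tolerance = 1e-12)
  expect_equal(law$intercept, -0.078, tolerance = 1e-12)
  expect_equal(law$shift_per_10cm, 1.76, tolerance = 1e-10)

  zero <- fit_crossing_model(data.frame(width = widths, x_cross = 0,
                                        side = side))
  expect_equal(zero$slope, 0, tolerance = 1e-12)
  expect_equal(zero$intercept, 0, tolerance = 1e-12)
  expect_error(fit_crossing_model(data.frame(width = 0.5, x_cross = 0.1,
                                             side = 1)), "2 distinct widths")
})

test_that("the crossing law is recovered within 3 SE under noise", {
  set.seed(4)
  n <- 600
  widths <- sample(c(0.4, 0.5, 0.6, 0.7, 0.8, 1.0), n, TRUE)
  side <- sample(c(-1, 1), n, TRUE)
  x <- side * (0.176 * widths - 0.078) + rnorm(n, 0, 0.05)
  law <- fit_crossing_model(data.frame(width = widths, x_cross = x,
                                       side = side))
  expect_lt(abs(law$slope - 0.176), 3 * law$se["slope"])
  expect_lt(abs(law$intercept + 0.078), 3 * law$se["intercept"])
})

test_that("the crossing-law fit is scale consistent", {
  widths <- rep(c(0.4, 0.6, 0.8, 1.0), each = 3)
  side <- rep(1, length(widths))
  x <- 0.176 * widths - 0.078
  m_fit <- fit_crossing_model(data.frame(width = widths, x_cross = x,
                                         side = side))
  cm_fit <- fit_crossing_model(data.frame(width = widths * 100,
                                          x_cross = x * 100, side = side))
  expect_equal(cm_fit$slope, m_fit$slope, tolerance = 1e-10)
  expect_equal(cm_fit$intercept, m_fit$intercept * 100, tolerance = 1e-8)
})

test_that("tukey_hsd flags separated groups and not identical ones", {
  same <- c(rnorm(30, 0, 0) + 1, rep(1, 30))
  g <- rep(c("a", "b"), each = 30)
  res_same <- tukey_hsd(same + rep(rnorm(30, 0, 0.5), 2), g)
  expect_false(res_same$significant[1])
  set.seed(5)
  res_sep <- tukey_hsd(c(rnorm(30, 0, 1), rnorm(30, 5, 1)), g)
  expect_true(res_sep$significant[1])
  expect_error(tukey_hsd(1:3, c("a", "a", "b")), "at least 2 samples")
})

test_that("tukey_hsd decisions match a manual studentized-range oracle", {
  set.seed(6)
  vals <- c(rnorm(20, 0), rnorm(20, 0.5), rnorm(20, 3))
  g <- rep(c("a", "b", "c"), each = 20)
  res <- tukey_hsd(vals, g)
  # manual Tukey: q = |mean_i - mean_j| / sqrt(MSE / n), balanced design
  means <- tapply(vals, g, mean)
  mse <- sum((vals - ave(vals, g))^2) / (60 - 3)
  qc <- qtukey(0.95, nmeans = 3, df = 57)
  pairs <- list(c("b", "a"), c("c", "a"), c("c", "b"))
  oracle <- vapply(pairs, function(p) {
    abs(means[p[1]] - means[p[2]]) / sqrt(mse / 20) > qc
  }, logical(1))
  names(oracle) <- c("b-a", "c-a", "c-b")
  expect_equal(res$significant, unname(oracle[res$comparison]))
})

make_run_table <- function(n, couple = FALSE) {
  tibble::tibble(
    angle_deg = sample(c(-90, 0, 90), n, TRUE),
    width_w = sample(c(0.4, 0.6, 1.0), n, TRUE),
    motivation = sample(c("normal", "hurried"), n, TRUE),
    R = runif(n, 0.8, 2.6),
    max_amplitude = rnorm(n, 0, 10),
    direction = sample(c("left", "right"), n, TRUE),
    onset_d = runif(n, 0.2, 1),
    max_d = rnorm(n, -0.05, 0.1),
    foot_at_onset = sample(c("left", "right"), n, TRUE),
    foot_at_max = if (couple) NA else sample(c("left", "right"), n, TRUE),
    footedness = sample(c("left", "right"), n, TRUE)
  )
}

test_that("correlation matrices mask insignificant independent pairs", {
  set.seed(7)
  tab <- make_run_table(1000)
  cm <- correlation_matrix(tab)
  for (split in cm) {
    expect_true(all(diag(split$masked) == 1))
    off <- split$masked[upper.tri(split$masked)]
    expect_gte(mean(is.na(off)), 0.80)   # nominal 95% masking, all independent
  }
})

test_that("a deterministic foot-direction coupling shows |r| = 1", {
  set.seed(8)
  tab <- make_run_table(200, couple = TRUE)
  tab$foot_at_max <- ifelse(tab$direction == "left", "right", "left")
  cm <- correlation_matrix(tab)
  expect_equal(abs(cm$expected$r["direction", "foot_at_max"]), 1,
               tolerance = 1e-12)
  expect_false(is.na(cm$expected$masked["direction", "foot_at_max"]))
})
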