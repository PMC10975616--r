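#' Fit the maximum-rotation amplitude curve
#'
#' Nonlinear least squares of |gamma_max| against the aperture ratio
#' R = w / s with the exponential-plateau family a e^(-b R + c) + d. Since
#' a and c are jointly unidentifiable the three-parameter equivalent
#' a' e^(-b R) + d is fitted (multi-start over the decay rate) and reported
#' in the four-parameter convention with c = 0. Constant input degenerates
#' to d = mean, a' = 0 and is flagged.
#'
#' @param points data frame with columns `R` and `amplitude` (deg, absolute).
#' @param r_domain domain of R the fit is used on.
#' @return A list of class `fit_result`: `parameters` (a, b, c, d),
#'   `se`, `residuals`, `fitted`, `residual_sd`, `degenerate`, `r_domain`,
#'   `n`.
#' @export
fit_max_rotation_curve <- function(points, r_domain = c(0.8, 2.6)) {
  points <- points[stats::complete.cases(points[c("R", "amplitude")]), ]
  x <- points$R; yv <- points$amplitude
  if (length(x) < 8) stop("need at least 8 points to fit the amplitude curve")
  make_result <- function(a, b, d, se, res, degenerate) {
    structure(list(parameters = c(a = a, b = b, c = 0, d = d), se = se,
                   residuals = res, fitted = yv - res,
                   residual_sd = stats::sd(res), degenerate = degenerate,
                   r_domain = r_domain, n = length(yv)),
              class = "fit_result")
  }
  if (stats::sd(yv) < 1e-10) {
    return(make_result(0, NA_real_, mean(yv),
                       c(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_),
                       yv - mean(yv), TRUE))
  }
  best <- NULL
  for (b0 in c(0.5, 1, 2, 4, 8)) {
    d0 <- min(yv) - 0.05 * abs(min(yv)) - 1e-3
    a0 <- max(mean(yv[x <= stats::quantile(x, 0.25)]) - d0, 1e-3) /
      exp(-b0 * min(x))
    fit <- tryCatch(
      minpack.lm::nlsLM(amplitude ~ a * exp(-b * R) + d,
                        data = data.frame(R = x, amplitude = yv),
                        start = list(a = a0, b = b0, d = d0),
                        lower = c(a = 0, b = 1e-6, d = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("amplitude-curve fit failed to converge from all starts")
  }
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 3),
                                                     c("a", "b", "d")))
  make_result(cf[["a"]], cf[["b"]], cf[["d"]],
              c(a = unname(se["a"]), b = unname(se["b"]), c = NA_real_,
                d = unname(se["d"])),
              as.numeric(stats::residuals(best$fit)), FALSE)
}

#' @export
print.fit_result <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("<fit_result> a'=%.3f b=%.3f d=%.3f (n=%d, residual sd %.3f%s)\n",
              p["a"], p["b"], p["d"], x$n, x$residual_sd,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Critical aperture ratio from a fitted amplitude curve
#'
#' Evaluates the fitted curve on an evenly spaced grid of R (180 points on
#' \[0.8, 2.6\]), partitions the grid into consecutive intervals of width
#' 0.05, and compares all interval pairs with studentized-range (Tukey)
#' tests at the given level, using the fit's residual standard deviation and
#' per-interval observation counts as the error model. The critical ratio
#' Rcrit is the lower edge of the earliest interval from which onward no
#' pairwise difference is significant — the point beyond which the maximum
#' shoulder rotation no longer changes with wider bottlenecks.
#'
#' @param fit a [fit_max_rotation_curve()] result, or a plain function of R
#'   (then `residual_sd` must be given).
#' @param residual_sd error scale; defaults to the fit's residual sd.
#' @param group_sizes observations per interval: a scalar or a vector of one
#'   count per interval (zero drops the interval).
#' @param grid_n,r_range,interval,level grid and test settings.
#' @return A list of class `critical_point` with `rcrit`, `grid`, `fitted`,
#'   `intervals` and the settings.
#' @export
critical_point <- function(fit, residual_sd = NULL, group_sizes = 10,
                           grid_n = 180, r_range = c(0.8, 2.6),
                           interval = 0.05, level = 0.95) {
  grid <- seq(r_range[1], r_range[2], length.out = grid_n)
  if (is.function(fit)) {
    if (is.null(residual_sd)) stop("residual_sd is required with a bare function")
    fx <- fit(grid)
  } else {
    p <- fit$parameters
    if (is.null(residual_sd)) residual_sd <- fit$residual_sd
    fx <- if (is.na(p["b"])) rep(p["d"], grid_n) else
      p["a"] * exp(-p["b"] * grid) + p["d"]
  }
  edges <- seq(r_range[1], r_range[2], by = interval)
  iv <- pmin(findInterval(grid, edges, rightmost.closed = TRUE),
             length(edges) - 1)
  means <- as.numeric(tapply(fx, iv, mean))
  lower <- edges[sort(unique(iv))]
  k_all <- length(means)
  n_i <- if (length(group_sizes) == 1) rep(group_sizes, k_all) else group_sizes
  if (length(n_i) != k_all) stop("group_sizes must be scalar or one per interval")
  keep <- n_i > 0
  means <- means[keep]; lower <- lower[keep]; n_i <- n_i[keep]
  k <- length(means)
  if (k < 2) stop("fewer than 2 intervals populated")
  df <- max(sum(n_i) - k, 2)   # qtukey is undefined below 2 df
  qcrit <- stats::qtukey(level, nmeans = k, df = df)
  signif_pair <- function(i, j) {
    dm <- abs(means[i] - means[j])
    if (residual_sd <= 0) return(dm > 1e-12)
    q <- dm / (residual_sd * sqrt((1 / n_i[i] + 1 / n_i[j]) / 2))
    q > qcrit
  }
  rcrit <- lower[k]                       # single-interval suffix is trivial
  for (start in seq_len(k)) {
    idx <- start:k
    any_sig <- FALSE
    if (length(idx) >= 2) {
      pairs <- utils::combn(idx, 2)
      for (m in seq_len(ncol(pairs))) {
        if (signif_pair(pairs[1, m], pairs[2, m])) { any_sig <- TRUE; break }
      }
    }
    if (!any_sig) { rcrit <- lower[start]; break }
  }
  structure(list(rcrit = rcrit, grid = grid, fitted = fx,
                 interval_lower = lower, interval_means = means,
                 group_sizes = n_i, level = level, interval = interval),
            class = "critical_point")
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf("<critical_point> Rcrit = %.2f (level %.2f, %d intervals)\n",
              x$rcrit, x$level, length(x$interval_means)))
  invisible(x)
}

#' Fit the linear crossing-offset law
#'
#' Crossing offsets are folded onto the side of origin (multiplied by the
#' side sign derived from the approach angle) and regressed on the
#' bottleneck width: C(w) = slope * w + intercept. The derived
#' `shift_per_10cm` is the lateral shift in cm per 10 cm of additional
#' width.
#'
#' @param crossings data frame with columns `width`, `x_cross` and `side`
#'   (+1 start on +x, -1 start on -x, 0 straight approach).
#' @param zero_angle `"exclude"` drops side-0 runs; `"sign"` assigns their
#'   side from the sign of the offset itself.
#' @return A list of class `crossing_law` with `slope`, `intercept`, `se`,
#'   `shift_per_10cm`, `n`, `fit`.
#' @export
fit_crossing_model <- function(crossings, zero_angle = c("exclude", "sign")) {
  zero_angle <- match.arg(zero_angle)
  df <- as.data.frame(crossings)
  if (zero_angle == "sign") {
    df$side[df$side == 0] <- sign(df$x_cross[df$side == 0])
  }
  df <- df[!is.na(df$side) & df$side != 0 & !is.na(df$x_cross), ]
  if (length(unique(df$width)) < 2) {
    stop("need at least 2 distinct widths to fit the crossing law")
  }
  df$folded <- df$side * df$x_cross
  fit <- stats::lm(folded ~ width, data = df)
  cf <- stats::coef(fit)
  # noiseless input is a designed use; the "perfect fit" warning is expected
  se <- suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
  structure(list(slope = unname(cf["width"]), intercept = unname(cf["(Intercept)"]),
                 se = c(slope = unname(se["width"]),
                        intercept = unname(se["(Intercept)"])),
                 shift_per_10cm = unname(cf["width"]) * 10, n = nrow(df),
                 fit = fit),
            class = "crossing_law")
}

#' @export
print.crossing_law <- function(x, ...) {
  cat(sprintf(
    "<crossing_law> C(w) = %.3f w %+.3f (n=%d); shift %.2f cm per 10 cm width\n",
    x$slope, x$intercept, x$n, x$shift_per_10cm))
  invisible(x)
}

#' Tukey honest-significant-difference comparisons
#'
#' All-pairs studentized-range comparisons between labelled groups at the
#' given family level (Tukey-Kramer for unbalanced designs), as used for the
#' post-hoc comparisons of onset and maximum-rotation locations.
#'
#' @param values numeric observations.
#' @param groups group labels, same length.
#' @param level family confidence level.
#' @return A tibble with `comparison`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(values, groups, level = 0.95) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 samples")
  fit <- stats::aov(values ~ g, data = data.frame(values = values, g = g))
  tk <- stats::TukeyHSD(fit, conf.level = level)$g
  tibble::tibble(comparison = rownames(tk), diff = unname(tk[, "diff"]),
                 lwr = unname(tk[, "lwr"]), upr = unname(tk[, "upr"]),
                 p_adj = unname(tk[, "p adj"]),
                 significant = unname(tk[, "p adj"]) < (1 - level))
}

encode_pm1 <- function(x, pos, neg) {
  out <- rep(NA_real_, length(x))
  out[x == pos] <- 1
  out[x == neg] <- -1
  out
}

#' Correlation matrices of the rotation-related run variables
#'
#' Pearson correlations between the per-run variables tied to the rotation
#' process, split at the literature critical ratio (R <= 1.3: rotation
#' expected; R > 1.3: rotation not necessary). Binary variables are encoded
#' as +/-1 (`left`/`right` feet and turn directions, motivation); runs with
#' an unassigned foot are excluded pairwise. Entries not significant at the
#' given level are masked to `NA` in `masked`.
#'
#' @param run_table per-run result table from [analyze_run()] rows.
#' @param level significance level for the mask.
#' @param r_split split threshold on R.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with one element per split (`expected`, `free`), each
#'   holding `r`, `p`, `masked` matrices and `n` pairwise counts.
#' @export
correlation_matrix <- function(run_table, level = 0.95, r_split = 1.3,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  df <- as.data.frame(run_table)
  enc <- data.frame(
    max_abs_amplitude = abs(df$max_amplitude),
    direction = encode_pm1(df$direction, "left", "right"),
    width = df$width_w,
    motivation = encode_pm1(df$motivation, "hurried", "normal"),
    angle = df$angle_deg,
    onset_d = df$onset_d,
    max_d = df$max_d,
    foot_at_onset = encode_pm1(df$foot_at_onset, "right", "left"),
    foot_at_max = encode_pm1(df$foot_at_max, "right", "left"),
    footedness = encode_pm1(df$footedness, "right", "left")
  )
  one_split <- function(sel) {
    sub <- enc[sel, , drop = FALSE]
    if (nrow(sub) < 10) stop("fewer than 10 runs in a split")
    vars <- names(sub)
    k <- length(vars)
    r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
    for (i in seq_len(k)) for (j in i:k) {
      ok <- stats::complete.cases(sub[c(i, j)])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      xi <- sub[ok, i]; xj <- sub[ok, j]
      if (sum(ok) < 3 || stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      ct <- suppressWarnings(stats::cor.test(xi, xj, method = method))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
    masked <- r
    masked[is.na(p) | p >= (1 - level)] <- NA_real_
    diag(masked) <- 1
    list(r = r, p = p, masked = masked, n = nmat)
  }
  list(expected = one_split(df$R <= r_split),
       free = one_split(df$R > r_split))
}
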