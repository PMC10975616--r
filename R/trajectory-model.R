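#' Body-point time series
#'
#' A uniformly sampled planar (or 3D) trajectory of one tracked body point in
#' the world frame. The world frame places the origin at the bottleneck
#' centre, the crossing line at y = 0, the approach side at y > 0 and the
#' exit side at y < 0; x > 0 lies on the side of positive approach angles.
#'
#' @param times numeric vector of sample times (s), strictly increasing.
#' @param positions numeric matrix with one row per sample and 2 or 3 columns
#'   (x, y\[, z\] in metres).
#'
#' @return An object of class `point_series` with elements `times` and
#'   `positions`.
#' @export
point_series <- function(times, positions) {
  positions <- as.matrix(positions)
  if (is.null(colnames(positions))) {
    colnames(positions) <- c("x", "y", "z")[seq_len(ncol(positions))]
  }
  stopifnot(
    length(times) == nrow(positions),
    length(times) >= 2,
    ncol(positions) %in% c(2L, 3L)
  )
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (any(abs(positions[, 1:2]) > 50)) {
    stop("positions exceed plausibility bounds (|x| or |y| > 50 m); check units")
  }
  structure(list(times = as.numeric(times), positions = positions),
            class = "point_series")
}

#' @export
print.point_series <- function(x, ...) {
  cat(sprintf("<point_series> %d samples, %.2f-%.2f s, %dD\n",
              length(x$times), min(x$times), max(x$times), ncol(x$positions)))
  invisible(x)
}

#' @export
length.point_series <- function(x) length(x$times)

#' Participant description
#'
#' @param id participant label.
#' @param shoulder_width_s shoulder width s (m), > 0; the denominator of the
#'   aperture ratio R = w / s.
#' @param footedness `"right"` or `"left"`.
#' @param height body height (m), optional.
#' @return A list of class `participant`.
#' @export
participant <- function(id, shoulder_width_s, footedness = "right",
                        height = NA_real_) {
  stopifnot(shoulder_width_s > 0)
  footedness <- match.arg(footedness, c("right", "left"))
  structure(list(id = as.character(id),
                 shoulder_width_s = shoulder_width_s,
                 footedness = footedness, height = height),
            class = "participant")
}

#' Run metadata
#'
#' @param participant a [participant()].
#' @param angle_deg signed approach angle in degrees; 0 is a straight
#'   approach, positive angles start on the +x side. The study grid is
#'   `c(-90, -60, -30, 0, 30, 60, 90)` but other values are accepted for
#'   synthetic use.
#' @param width_w bottleneck width w (m), > 0.
#' @param length_l bottleneck length (m).
#' @param motivation `"normal"` or `"hurried"`.
#' @param run_id run label.
#' @return A list of class `run_meta`.
#' @export
run_meta <- function(participant, angle_deg, width_w, length_l = 1,
                     motivation = "normal", run_id = "run") {
  stopifnot(inherits(participant, "participant"), width_w > 0,
            abs(angle_deg) <= 180)
  motivation <- match.arg(motivation, c("normal", "hurried"))
  structure(list(participant = participant, angle_deg = angle_deg,
                 width_w = width_w, length_l = length_l,
                 motivation = motivation, run_id = as.character(run_id)),
            class = "run_meta")
}

#' One run's recording
#'
#' Bundles the centre-of-mass (COM), shoulder and heel trajectories of a
#' single bottleneck passage on a shared uniform time base.
#'
#' @param meta a [run_meta()].
#' @param com,shoulder_left,shoulder_right,heel_left,heel_right
#'   [point_series()] objects on the same time base.
#' @return An object of class `run_recording`.
#' @export
run_recording <- function(meta, com, shoulder_left, shoulder_right,
                          heel_left, heel_right) {
  series <- list(com = com, shoulder_left = shoulder_left,
                 shoulder_right = shoulder_right, heel_left = heel_left,
                 heel_right = heel_right)
  for (nm in names(series)) {
    if (!inherits(series[[nm]], "point_series")) {
      stop("missing series: ", nm)
    }
  }
  tb <- series$com$times
  for (nm in names(series)) {
    if (length(series[[nm]]$times) != length(tb) ||
        max(abs(series[[nm]]$times - tb)) > 1e-9) {
      stop("series ", nm, " is not on the common time base")
    }
  }
  structure(c(list(meta = meta), series), class = "run_recording")
}

#' @export
print.run_recording <- function(x, ...) {
  cat(sprintf(
    "<run_recording> %s | angle %+d deg, w = %.2f m, %s | %d samples @ %.0f Hz\n",
    x$meta$run_id, as.integer(x$meta$angle_deg), x$meta$width_w,
    x$meta$motivation, length(x$com$times),
    1 / stats::median(diff(x$com$times))))
  invisible(x)
}

series_names <- function() {
  c("com", "shoulder_left", "shoulder_right", "heel_left", "heel_right")
}

#' Mirror a run about the walking axis
#'
#' Maps x to -x on every body point, swaps the left/right shoulder and heel
#' series and negates the approach angle. Mirroring is an involution; the
#' shoulder-rotation signal of a mirrored run is the negated signal of the
#' original, which backs the left/right symmetry checks of the analysis.
#'
#' @param rec a [run_recording()].
#' @return The mirrored `run_recording`.
#' @export
mirror_run <- function(rec) {
  stopifnot(inherits(rec, "run_recording"))
  flip <- function(ps) {
    p <- ps$positions
    p[, 1] <- -p[, 1]
    point_series(ps$times, p)
  }
  meta <- rec$meta
  meta$angle_deg <- -meta$angle_deg
  run_recording(meta,
                com = flip(rec$com),
                shoulder_left = flip(rec$shoulder_right),
                shoulder_right = flip(rec$shoulder_left),
                heel_left = flip(rec$heel_right),
                heel_right = flip(rec$heel_left))
}

resample_series <- function(ps, times) {
  pos <- apply(ps$positions, 2, function(col) {
    stats::approx(ps$times, col, xout = times, rule = 2)$y
  })
  point_series(times, pos)
}

#' Read one run recording from disk
#'
#' Two dialects are supported. `long_csv` is this package's canonical format:
#' columns `run_id, point_name, t, x, y[, z]` with `point_name` in
#' `com, shoulder_left, shoulder_right, heel_left, heel_right`. `petrack_txt`
#' is the whitespace-separated tracker export `id frame x y z` where each
#' "person" id holds one body point; `point_map` names which id is which
#' point and `fps` converts frame numbers to seconds. All series are linearly
#' resampled onto a single uniform grid (default 60 Hz) covering the time
#' span common to every point.
#'
#' @param path input file.
#' @param dialect `"long_csv"` or `"petrack_txt"`.
#' @param meta a [run_meta()] attached to the recording.
#' @param fps frame rate used to convert `petrack_txt` frame numbers (Hz).
#' @param point_map named integer vector mapping series names to person ids
#'   for `petrack_txt`.
#' @param fs resampling rate of the common grid (Hz).
#' @return A [run_recording()].
#' @export
read_run_recording <- function(path, dialect = c("long_csv", "petrack_txt"),
                               meta, fps = 50,
                               point_map = c(com = 1, shoulder_left = 2,
                                             shoulder_right = 3, heel_left = 4,
                                             heel_right = 5),
                               fs = 60) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "long_csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("point_name", "t", "x", "y")
    if (!all(need %in% names(df))) {
      stop("long_csv requires columns: ", paste(need, collapse = ", "))
    }
    get_series <- function(nm) {
      sub <- df[df$point_name == nm, , drop = FALSE]
      if (nrow(sub) == 0) stop("missing series: ", nm)
      sub <- sub[order(sub$t), , drop = FALSE]
      if (any(diff(sub$t) <= 0)) stop("non-monotonic times for ", nm)
      cols <- intersect(c("x", "y", "z"), names(df))
      point_series(sub$t, as.matrix(sub[cols]))
    }
  } else {
    df <- utils::read.table(path, header = FALSE,
                            col.names = c("id", "frame", "x", "y", "z"))
    get_series <- function(nm) {
      if (!nm %in% names(point_map)) stop("missing series: ", nm)
      sub <- df[df$id == point_map[[nm]], , drop = FALSE]
      if (nrow(sub) == 0) stop("missing series: ", nm)
      sub <- sub[order(sub$frame), , drop = FALSE]
      if (any(diff(sub$frame) <= 0)) stop("non-monotonic frames for ", nm)
      point_series(sub$frame / fps, as.matrix(sub[c("x", "y", "z")]))
    }
  }
  raw <- lapply(stats::setNames(series_names(), series_names()), get_series)
  t0 <- max(vapply(raw, function(s) s$times[1], 0))
  t1 <- min(vapply(raw, function(s) s$times[length(s$times)], 0))
  if (t1 <= t0) stop("series do not overlap in time")
  grid <- seq(t0, t0 + floor((t1 - t0) * fs + 1e-9) / fs, by = 1 / fs)
  series <- lapply(raw, resample_series, times = grid)
  do.call(run_recording, c(list(meta = meta), series))
}

#' Write a run recording in the canonical long CSV dialect
#'
#' @param rec a [run_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_recording <- function(rec, path) {
  rows <- lapply(series_names(), function(nm) {
    ps <- rec[[nm]]
    data.frame(run_id = rec$meta$run_id, point_name = nm, t = ps$times,
               ps$positions)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a per-run result table
#'
#' @param results non-empty data frame of per-run results.
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  if (nrow(results) == 0) stop("refusing to write an empty result table")
  if (format == "csv") {
    utils::write.csv(format(results, digits = 10, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE, na = "NA")
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @inheritParams write_results
#' @return A tibble.
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
}
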