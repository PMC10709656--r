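# Dynamic migration analysis of nucleus tracks sampled on a regular time
# grid. Per-track operations accept a data frame with columns t_min, x_um,
# y_um (one cell, time-sorted); cohort operations accept the long trajectory
# tibble (cell_id, t_min, x_um, y_um, condition, on_pattern).

# Validate and extract one track as a list of vectors.
.as_track <- function(track, min_samples = 2L) {
  stopifnot(is.data.frame(track))
  need <- c("t_min", "x_um", "y_um")
  miss <- setdiff(need, names(track))
  if (length(miss) > 0) {
    stop(sprintf("track is missing columns: %s", paste(miss, collapse = ", ")))
  }
  ord <- order(track$t_min)
  t <- track$t_min[ord]; x <- track$x_um[ord]; y <- track$y_um[ord]
  if (length(t) < min_samples) {
    stop(sprintf("track needs at least %d samples", min_samples))
  }
  if (any(duplicated(t))) stop("track has duplicated time points")
  list(t = t, x = x, y = y, dt = if (length(t) > 1) t[2] - t[1] else NA_real_)
}

.split_tracks <- function(tracks) {
  stopifnot(is.data.frame(tracks), "cell_id" %in% names(tracks))
  split(tracks, tracks$cell_id)
}

#' Filter trajectories for dynamic analysis
#'
#' Keeps tracks that last strictly more than `min_duration_min` minutes and
#' whose nucleus stays on the topographic structures (`on_pattern`); tracks
#' on the flat control are exempt from the on-pattern requirement. Exclusion
#' counts are recorded in the `"exclusion_log"` attribute.
#'
#' @param tracks Long trajectory tibble with columns `cell_id`, `t_min`,
#'   `x_um`, `y_um`, `condition`, `on_pattern`.
#' @param min_duration_min Duration gate in minutes, strict (default 360,
#'   i.e. more than 6 h).
#' @param control_label Label of the flat control condition.
#' @return The retained subset of `tracks`, with attribute
#'   `"exclusion_log"` (tibble of `cell_id`, `reason`).
#' @export
filter_trajectories <- function(tracks, min_duration_min = 360,
                                control_label = "control") {
  need <- c("cell_id", "t_min", "x_um", "y_um", "condition", "on_pattern")
  miss <- setdiff(need, names(tracks))
  if (length(miss) > 0) {
    stop(sprintf("tracks are missing columns: %s", paste(miss, collapse = ", ")))
  }
  if (any(is.na(tracks$on_pattern))) {
    bad <- unique(tracks$cell_id[is.na(tracks$on_pattern)])
    stop(sprintf("missing on_pattern flags for cells: %s",
                 paste(bad, collapse = ", ")))
  }
  per <- lapply(.split_tracks(tracks), function(d) {
    list(cell_id = d$cell_id[1],
         duration = max(d$t_min) - min(d$t_min),
         on_pattern = all(d$on_pattern),
         is_control = d$condition[1] == control_label)
  })
  reasons <- lapply(per, function(p) {
    r <- character(0)
    if (p$duration <= min_duration_min) r <- c(r, "too_short")
    if (!p$is_control && !p$on_pattern) r <- c(r, "off_pattern")
    r
  })
  keep_ids <- names(per)[vapply(reasons, length, integer(1)) == 0]
  log <- tibble::tibble(
    cell_id = rep(names(per), times = vapply(reasons, length, integer(1))),
    reason = unlist(reasons, use.names = FALSE)
  )
  out <- tracks[tracks$cell_id %in% keep_ids, ]
  attr(out, "exclusion_log") <- log
  out
}

#' Directional orientation of a track
#'
#' Angle between the net displacement vector (final minus initial position)
#' and the groove axis (+y), folded into `[0, 90]` degrees.
#'
#' @param track One-cell data frame with `t_min`, `x_um`, `y_um`.
#' @return Orientation in degrees; errors on zero net displacement.
#' @export
#' @examples
#' tr <- data.frame(t_min = c(0, 10), x_um = c(0, 5), y_um = c(0, 5))
#' directional_orientation(tr)  # 45
directional_orientation <- function(track) {
  tr <- .as_track(track)
  dx <- tr$x[length(tr$x)] - tr$x[1]
  dy <- tr$y[length(tr$y)] - tr$y[1]
  if (dx == 0 && dy == 0) {
    stop("zero net displacement: directional orientation is undefined")
  }
  atan2(abs(dx), abs(dy)) * 180 / pi
}

#' Angular displacement series of a track
#'
#' For a time interval `delta_min`, computes the angle between the
#' displacement vector over `[t, t + delta]` and the one over
#' `[t + delta, t + 2 delta]`, for every sample time `t` on the grid for
#' which both vectors exist; values lie in `[0, 180]` degrees. Pairs in
#' which either displacement has zero magnitude are skipped and counted in
#' the `"n_skipped"` attribute (the angle is undefined, and imputing 0 would
#' bias the first bin).
#'
#' @param track One-cell data frame with `t_min`, `x_um`, `y_um` on a
#'   regular grid.
#' @param delta_min Time interval delta in minutes; must be a positive
#'   multiple of the sampling interval.
#' @return Numeric vector of angles in degrees with attribute `"n_skipped"`.
#' @export
angular_displacement <- function(track, delta_min) {
  tr <- .as_track(track)
  k <- delta_min / tr$dt
  if (delta_min <= 0 || abs(k - round(k)) > 1e-8) {
    stop(sprintf("delta_min = %g is not a positive multiple of the %g-min sampling interval",
                 delta_min, tr$dt))
  }
  k <- as.integer(round(k))
  n <- length(tr$t)
  if (n < 2 * k + 1) stop("track too short for this delta")
  i0 <- seq_len(n - 2 * k)
  v1x <- tr$x[i0 + k] - tr$x[i0];     v1y <- tr$y[i0 + k] - tr$y[i0]
  v2x <- tr$x[i0 + 2 * k] - tr$x[i0 + k]; v2y <- tr$y[i0 + 2 * k] - tr$y[i0 + k]
  m1 <- sqrt(v1x^2 + v1y^2); m2 <- sqrt(v2x^2 + v2y^2)
  ok <- m1 > 0 & m2 > 0
  cosang <- pmin(1, pmax(-1, (v1x * v2x + v1y * v2y)[ok] / (m1 * m2)[ok]))
  out <- acos(cosang) * 180 / pi
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Occurrence histogram of angular displacements
#'
#' Bins angular-displacement values over `[0, 180]` degrees into half-open
#' bins (the 180-degree edge falls into the last bin), normalised to
#' fractions summing to one.
#'
#' @param dtheta_deg Numeric vector of angles in `[0, 180]`.
#' @param bin_deg Bin width in degrees (default 15, i.e. 12 bins).
#' @return A tibble of `bin_lo`, `bin_hi`, `fraction` with attributes
#'   `n_samples` and `bin_deg`.
#' @export
occurrence_histogram <- function(dtheta_deg, bin_deg = 15) {
  .occurrence_bins(dtheta_deg, bin_deg, 180)
}

#' Average migration speed of a track
#'
#' Total travel distance (sum of consecutive step lengths) divided by total
#' travel time, in um/min.
#'
#' @inheritParams directional_orientation
#' @return Mean speed in um/min.
#' @export
average_speed <- function(track) {
  tr <- .as_track(track)
  steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  sum(steps) / (tr$t[length(tr$t)] - tr$t[1])
}

#' Groove-axis decomposition of migration speed
#'
#' Decomposes the average speed into the component along the groove
#' direction (`v_y_bar`, +y) and perpendicular to it (`v_x_bar`), each as
#' total travel distance along that axis over total travel time.
#'
#' @inheritParams directional_orientation
#' @return A list with `v_x_bar`, `v_y_bar` (um/min) and `ratio`
#'   (`v_y_bar / v_x_bar`; `Inf` with a warning-free flag when
#'   `v_x_bar = 0`).
#' @export
directional_speeds <- function(track) {
  tr <- .as_track(track)
  total_t <- tr$t[length(tr$t)] - tr$t[1]
  vx <- sum(abs(diff(tr$x))) / total_t
  vy <- sum(abs(diff(tr$y))) / total_t
  list(v_x_bar = vx, v_y_bar = vy,
       ratio = if (vx == 0) Inf else vy / vx,
       ratio_defined = vx > 0)
}

# Path length over [t0, t0 + Delta] on the sampled polyline, plus endpoint.
.path_window <- function(tr, Delta_min) {
  k <- Delta_min / tr$dt
  if (Delta_min <= 0 || abs(k - round(k)) > 1e-8) {
    stop(sprintf("Delta_min = %g is not a positive multiple of the %g-min sampling interval",
                 Delta_min, tr$dt))
  }
  k <- as.integer(round(k))
  if (k > length(tr$t) - 1) stop("Delta exceeds the track duration")
  idx <- seq_len(k + 1)
  steps <- sqrt(diff(tr$x[idx])^2 + diff(tr$y[idx])^2)
  list(k = k, D = sum(steps),
       dx = tr$x[k + 1] - tr$x[1], dy = tr$y[k + 1] - tr$y[1])
}

#' Directional displacement ratio of a track
#'
#' The groove-axis projection of the net displacement over `[0, Delta]`
#' divided by the total path length over the same window, computed on the
#' sampled polyline: `(y(Delta) - y(0)) / D(0, Delta)`. The numerator is
#' signed; values lie in `[-1, 1]` and measure how efficiently the cell
#' advances along the groove direction.
#'
#' @inheritParams directional_orientation
#' @param Delta_min Window length Delta in minutes; a positive multiple of
#'   the sampling interval, at most the track duration.
#' @return Signed ratio in `[-1, 1]`; errors if the path length is zero.
#' @export
directional_displacement_ratio <- function(track, Delta_min) {
  tr <- .as_track(track)
  w <- .path_window(tr, Delta_min)
  if (w$D == 0) stop("stationary track: zero path length over the window")
  w$dy / w$D
}

#' Directionality ratio of a track
#'
#' The classical straightness measure: straight-line distance between the
#' start point and the position at `Delta` divided by the path length over
#' `[0, Delta]`.
#'
#' @inheritParams directional_displacement_ratio
#' @return Ratio in `[0, 1]`; errors if the path length is zero.
#' @export
directionality_ratio <- function(track, Delta_min) {
  tr <- .as_track(track)
  w <- .path_window(tr, Delta_min)
  if (w$D == 0) stop("stationary track: zero path length over the window")
  sqrt(w$dx^2 + w$dy^2) / w$D
}

#' Per-cell migration summary
#'
#' Computes, for every track in a cohort, the duration, directional
#' orientation (only for tracks at least `orientation_min_duration` minutes
#' long; `NA` otherwise), mean speed and its groove-axis decomposition.
#'
#' @param tracks Long trajectory tibble (see [filter_trajectories()]).
#' @param orientation_min_duration Minimum duration (minutes, inclusive) for
#'   the directional-orientation statistic (default 600, i.e. 10 h).
#' @return A tibble with one row per cell: `cell_id`, `condition`,
#'   `duration_min`, `orientation_deg`, `mean_speed`, `v_x_bar`, `v_y_bar`,
#'   `vy_vx_ratio`.
#' @export
migration_table <- function(tracks, orientation_min_duration = 600) {
  parts <- .split_tracks(tracks)
  rows <- lapply(parts, function(d) {
    tr <- d[, c("t_min", "x_um", "y_um")]
    dur <- max(d$t_min) - min(d$t_min)
    sp <- directional_speeds(tr)
    orient <- if (dur >= orientation_min_duration) {
      tryCatch(directional_orientation(tr), error = function(e) NA_real_)
    } else NA_real_
    tibble::tibble(cell_id = d$cell_id[1], condition = d$condition[1],
                   duration_min = dur, orientation_deg = orient,
                   mean_speed = average_speed(tr),
                   v_x_bar = sp$v_x_bar, v_y_bar = sp$v_y_bar,
                   vy_vx_ratio = sp$ratio)
  })
  do.call(rbind, rows)
}

#' Cohort curve of the directional displacement ratio
#'
#' Evaluates the directional displacement ratio (or the classical
#' directionality ratio) per cell on a grid of window lengths and reports
#' the mean and standard error of the mean over cells at each window. Cells
#' shorter than a window drop out of that window (counted in `n`).
#'
#' @param tracks Long trajectory tibble.
#' @param Delta_grid_min Window lengths in minutes (default 10-600 min in
#'   10-min increments).
#' @param statistic `"directional"` (signed d_y/D, default), `"absolute"`
#'   (|d_y|/D) or `"directionality"` (d/D).
#' @return A tibble of `Delta_min`, `mean`, `sem`, `n` (SEM is 0 when
#'   `n = 1`).
#' @export
cohort_ratio_curve <- function(tracks, Delta_grid_min = seq(10, 600, by = 10),
                               statistic = c("directional", "absolute",
                                             "directionality")) {
  statistic <- match.arg(statistic)
  parts <- .split_tracks(tracks)
  if (length(parts) == 0) stop("empty cohort")
  fun <- switch(statistic,
                directional = directional_displacement_ratio,
                absolute = function(tr, D) abs(directional_displacement_ratio(tr, D)),
                directionality = directionality_ratio)
  rows <- lapply(Delta_grid_min, function(D) {
    vals <- unlist(lapply(parts, function(d) {
      tryCatch(fun(d[, c("t_min", "x_um", "y_um")], D),
               error = function(e) NULL)
    }), use.names = FALSE)
    if (length(vals) == 0) {
      return(tibble::tibble(Delta_min = D, mean = NA_real_, sem = NA_real_,
                            n = 0L))
    }
    tibble::tibble(Delta_min = D, mean = mean(vals),
                   sem = if (length(vals) > 1) {
                     stats::sd(vals) / sqrt(length(vals))
                   } else 0,
                   n = length(vals))
  })
  do.call(rbind, rows)
}

#' Mean squared displacement of a cohort
#'
#' Time-and-ensemble-averaged MSD: for each track and lag, the squared
#' displacement is averaged over all overlapping windows of that lag; the
#' per-track averages are then averaged over cells.
#'
#' @param tracks Long trajectory tibble.
#' @param lags_min Lags in minutes, multiples of the sampling interval.
#' @return A tibble of `lag_min`, `msd_um2`, `n_tracks`.
#' @export
mean_squared_displacement <- function(tracks, lags_min) {
  parts <- .split_tracks(tracks)
  rows <- lapply(lags_min, function(lag) {
    vals <- unlist(lapply(parts, function(d) {
      tr <- .as_track(d[, c("t_min", "x_um", "y_um")])
      k <- lag / tr$dt
      if (abs(k - round(k)) > 1e-8 || lag <= 0) {
        stop(sprintf("lag %g min is not on the sampling grid", lag))
      }
      k <- as.integer(round(k))
      n <- length(tr$t)
      if (k > n - 1) return(NULL)
      i0 <- seq_len(n - k)
      mean((tr$x[i0 + k] - tr$x[i0])^2 + (tr$y[i0 + k] - tr$y[i0])^2)
    }), use.names = FALSE)
    if (length(vals) == 0) {
      stop(sprintf("lag %g min exceeds every track duration", lag))
    }
    tibble::tibble(lag_min = lag, msd_um2 = mean(vals), n_tracks = length(vals))
  })
  do.call(rbind, rows)
}

#' Velocity autocorrelation of a cohort
#'
#' Normalised autocorrelation of the per-interval step vectors. With
#' `method = "dot"` (default), the lag-tau correlation is
#' `<v_t . v_(t+tau)> / <|v_t|^2>` (time-averaged per track, then averaged
#' over cells), which is 1 at lag 0 by construction. With
#' `method = "cosine"`, the mean cosine of the angle between step vectors at
#' the lag is reported instead, which removes speed-fluctuation weighting.
#'
#' @param tracks Long trajectory tibble.
#' @param lags_min Lags in minutes, multiples of the sampling interval
#'   (lag 0 allowed).
#' @param method `"dot"` or `"cosine"`.
#' @return A tibble of `lag_min`, `vacf`, `n_tracks`.
#' @export
velocity_autocorrelation <- function(tracks, lags_min,
                                     method = c("dot", "cosine")) {
  method <- match.arg(method)
  parts <- .split_tracks(tracks)
  per_track <- lapply(parts, function(d) {
    tr <- .as_track(d[, c("t_min", "x_um", "y_um")])
    list(vx = diff(tr$x), vy = diff(tr$y), dt = tr$dt)
  })
  rows <- lapply(lags_min, function(lag) {
    vals <- unlist(lapply(per_track, function(p) {
      k <- lag / p$dt
      if (abs(k - round(k)) > 1e-8 || lag < 0) {
        stop(sprintf("lag %g min is not on the sampling grid", lag))
      }
      k <- as.integer(round(k))
      n <- length(p$vx)
      if (k > n - 1) return(NULL)
      i0 <- seq_len(n - k)
      if (method == "dot") {
        num <- mean(p$vx[i0] * p$vx[i0 + k] + p$vy[i0] * p$vy[i0 + k])
        den <- mean(p$vx^2 + p$vy^2)
        if (den == 0) return(NULL)
        num / den
      } else {
        m1 <- sqrt(p$vx[i0]^2 + p$vy[i0]^2)
        m2 <- sqrt(p$vx[i0 + k]^2 + p$vy[i0 + k]^2)
        ok <- m1 > 0 & m2 > 0
        if (!any(ok)) return(NULL)
        mean(((p$vx[i0] * p$vx[i0 + k] + p$vy[i0] * p$vy[i0 + k]) /
                (m1 * m2))[ok])
      }
    }), use.names = FALSE)
    if (length(vals) == 0) {
      stop(sprintf("lag %g min exceeds every track duration", lag))
    }
    tibble::tibble(lag_min = lag, vacf = mean(vals), n_tracks = length(vals))
  })
  do.call(rbind, rows)
}
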