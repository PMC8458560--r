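# Per-track step statistics.
#
# Index conventions used throughout the package, for a track of n positions
# p_1..p_n and displacements d_s = p_{s+1} - p_s (s = 1..n-1):
#   speed[s]  : |d_s| / dt, length n-1
#   turn[j]   : angle(d_j, d_{j+1}), j = 1..n-2 -- the turn at the joint
#               *entering* step j+1
#   plane[j]  : signed dihedral between plane(d_j, d_{j+1}) and
#               plane(d_{j+1}, d_{j+2}) about d_{j+1}, j = 1..n-3 -- the
#               plane rotation entering step j+2
# Undefined entries (pauses, collinear joints) are NA in the internal
# aligned vectors; exported functions drop them.

# Default pause threshold: steps slower than 1 um/min are treated as pauses
# and angles touching them are undefined (the direction of a near-zero
# displacement is numerically meaningless).
PAUSE_SPEED <- 1

.step_speeds_mat <- function(m, dt) {
  d <- diff(m)
  sqrt(rowSums(d * d)) / dt * 60
}

.turning_angles_mat <- function(m, dt, pause_speed = PAUSE_SPEED) {
  n <- nrow(m)
  if (n < 3L) return(numeric(0))
  d <- diff(m)
  len <- sqrt(rowSums(d * d))
  ok <- len / dt * 60 >= pause_speed
  a <- d[-nrow(d), , drop = FALSE]
  b <- d[-1L, , drop = FALSE]
  la <- len[-length(len)]
  lb <- len[-1L]
  cosang <- rowSums(a * b) / (la * lb)
  ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
  ang[!(ok[-length(ok)] & ok[-1L])] <- NA_real_
  ang
}

.plane_angles_mat <- function(m, dt, pause_speed = PAUSE_SPEED,
                              collinear_tol = 1e-8) {
  n <- nrow(m)
  if (n < 4L) return(numeric(0))
  d <- diff(m)
  len <- sqrt(rowSums(d * d))
  ok <- len / dt * 60 >= pause_speed
  k <- nrow(d) - 2L
  out <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    if (!all(ok[j:(j + 2L)])) next
    n1 <- cross3(d[j, ], d[j + 1L, ])
    n2 <- cross3(d[j + 1L, ], d[j + 2L, ])
    s1 <- vec_norm(n1) / (len[j] * len[j + 1L])
    s2 <- vec_norm(n2) / (len[j + 1L] * len[j + 2L])
    if (s1 < collinear_tol || s2 < collinear_tol) next  # collinear pair
    axis <- d[j + 1L, ] / len[j + 1L]
    ang <- atan2(sum(cross3(n1, n2) * axis), sum(n1 * n2)) * 180 / pi
    if (ang <= -180) ang <- ang + 360  # range (-180, 180]
    out[j] <- ang
  }
  out
}

.one_or_many <- function(tracks, fun) {
  if (is.matrix(tracks)) return(fun(tracks))
  stopifnot(is.data.frame(tracks))
  dt <- attr(tracks, "dt")
  mats <- track_matrices(tracks)
  out <- lapply(mats, fun)
  if (length(out) == 1L) out[[1L]] else out
}

#' Step speeds, turning angles and plane angles of 3D tracks
#'
#' `step_speeds()` returns instantaneous step speeds `|p[i+1] - p[i]| / dt` in
#' um/min. `turning_angles()` returns the angle in degrees (0 = straight,
#' 180 = reversal) between consecutive displacement vectors.
#' `plane_angles()` returns the signed dihedral angle in degrees
#' (-180, 180] between the planes spanned by consecutive displacement pairs,
#' the sign given by the right-hand rule about the shared displacement.
#'
#' Steps slower than `pause_speed` are treated as pauses: angles touching a
#' pause, and plane angles at collinear joints, are undefined and dropped
#' (use `drop_na = FALSE` to keep them as `NA` in step order).
#'
#' @param tracks a `track_table` or an n-by-3 coordinate matrix of one track.
#' @param dt sampling interval in seconds; taken from the track table when
#'   available.
#' @param pause_speed pause threshold in um/min.
#' @param drop_na drop undefined angles (default) or keep them as `NA`.
#' @return for a matrix or single-track table, a numeric vector; for a
#'   multi-track table, a named list of vectors (one per track).
#' @examples
#' m <- cbind(c(0, 1, 1), c(0, 0, 1), c(0, 0, 0))
#' turning_angles(m, dt = 20)  # 90 degrees
#' @export
step_speeds <- function(tracks, dt = 20) {
  if (is.data.frame(tracks)) dt <- attr(tracks, "dt")
  .one_or_many(tracks, function(m) .step_speeds_mat(m, dt))
}

#' @rdname step_speeds
#' @export
turning_angles <- function(tracks, dt = 20, pause_speed = PAUSE_SPEED,
                           drop_na = TRUE) {
  if (is.data.frame(tracks)) dt <- attr(tracks, "dt")
  out <- .one_or_many(tracks, function(m)
    .turning_angles_mat(m, dt, pause_speed))
  if (drop_na) out <- if (is.list(out)) lapply(out, stats::na.omit) else
    as.numeric(stats::na.omit(out))
  out
}

#' @rdname step_speeds
#' @export
plane_angles <- function(tracks, dt = 20, pause_speed = PAUSE_SPEED,
                         drop_na = TRUE) {
  if (is.data.frame(tracks)) dt <- attr(tracks, "dt")
  out <- .one_or_many(tracks, function(m)
    .plane_angles_mat(m, dt, pause_speed))
  if (drop_na) out <- if (is.list(out)) lapply(out, stats::na.omit) else
    as.numeric(stats::na.omit(out))
  out
}

#' Mean displacement versus square root of time
#'
#' For each lag tau = k * dt up to `max_lag`, the mean over all tracks and
#' all start indices (overlapping windows) of the displacement
#' `|p(t + tau) - p(t)|`, paired with `sqrt(tau)`. The overlapping-window
#' estimate is standard and has lower variance than disjoint windows, at the
#' price of correlated points along the curve.
#'
#' @param tracks a `track_table` or coordinate matrix.
#' @param max_lag largest lag in seconds; defaults to the span of the longest
#'   track.
#' @param dt sampling interval in seconds.
#' @return data.frame with columns `lag_s` (seconds), `sqrt_t_min`
#'   (min^(1/2)) and `displacement_um`; the first row is (0, 0, 0).
#' @export
mean_displacement_curve <- function(tracks, max_lag = NULL, dt = 20) {
  if (is.data.frame(tracks)) dt <- attr(tracks, "dt")
  mats <- if (is.matrix(tracks)) list(tracks) else track_matrices(tracks)
  max_steps <- max(vapply(mats, nrow, 1L)) - 1L
  if (is.null(max_lag)) max_lag <- max_steps * dt
  K <- min(max_steps, floor(max_lag / dt))
  if (K < 1L) stop("max_lag admits no lag")
  sums <- numeric(K)
  cnts <- numeric(K)
  for (m in mats) {
    n <- nrow(m)
    for (k in seq_len(min(K, n - 1L))) {
      d <- m[(k + 1L):n, , drop = FALSE] - m[1L:(n - k), , drop = FALSE]
      sums[k] <- sums[k] + sum(sqrt(rowSums(d * d)))
      cnts[k] <- cnts[k] + (n - k)
    }
  }
  lag <- c(0, seq_len(K) * dt)
  data.frame(lag_s = lag,
             sqrt_t_min = sqrt(lag / 60),
             displacement_um = c(0, sums / cnts))
}

#' Motility coefficient from a displacement curve
#'
#' Fits the slope m of mean displacement versus sqrt(time) through the origin
#' by least squares over a lag window, and reports MC = m^2 / 6 in um^2/min
#' (the 3D Brownian analogy: for isotropic diffusion with diffusivity D the
#' displacement magnitude is Maxwell with mean sqrt(16 D tau / pi), so the
#' fitted slope is sqrt(16 D / pi) and MC = m^2 / 6 = 8 D / (3 pi)). The
#' default window of 2-10 minutes excludes the early ballistic regime of
#' persistent walkers.
#'
#' @param curve a displacement curve from [mean_displacement_curve()].
#' @param fit_window numeric length-2, lag window in seconds.
#' @return motility coefficient in um^2/min.
#' @export
motility_coefficient <- function(curve, fit_window = c(120, 600)) {
  stopifnot(is.data.frame(curve),
            all(c("lag_s", "sqrt_t_min", "displacement_um") %in% names(curve)))
  sel <- curve$lag_s >= fit_window[1L] & curve$lag_s <= fit_window[2L] &
    curve$lag_s > 0
  if (!any(sel)) stop("fit window [", fit_window[1L], ", ", fit_window[2L],
                      "] s contains no lag of the curve")
  s <- curve$sqrt_t_min[sel]
  d <- curve$displacement_um[sel]
  m <- sum(s * d) / sum(s * s)
  m^2 / 6
}

#' Fit cohort motility statistics
#'
#' The package's central summary of a measured (or simulated) track cohort:
#' per-track mean speeds, the cohort mean speed with its standard error
#' (track = unit of replication), the turning-angle histogram, the mean
#' displacement versus sqrt(time) curve, and the motility coefficient.
#'
#' @param tracks a `track_table` (or data.frame coercible by [track_table()]).
#' @param fit_window lag window in seconds for the motility-coefficient fit.
#' @param breaks turning-angle histogram breaks in degrees.
#' @param pause_speed pause threshold in um/min.
#' @param max_lag largest displacement-curve lag in seconds (`NULL`: full
#'   track span).
#' @return an object of class `"motility"`: a list with elements
#'   `per_track_mean_speed`, `cohort_mean_speed`, `sem`, `turning_angle_hist`
#'   (data.frame: `lower`, `upper`, `frequency`, summing to 1),
#'   `displacement_curve`, `motility_coefficient`, `n_tracks`, `dt`,
#'   `fit_window`.
#' @seealso [plot.motility()]
#' @export
motility <- function(tracks, fit_window = c(120, 600),
                     breaks = seq(0, 180, by = 15),
                     pause_speed = PAUSE_SPEED, max_lag = NULL) {
  if (!is_track_table(tracks)) tracks <- track_table(tracks)
  if (n_tracks(tracks) < 1L) stop("empty cohort")
  dt <- attr(tracks, "dt")
  mats <- track_matrices(tracks)
  per_speed <- vapply(mats, function(m) mean(.step_speeds_mat(m, dt)), 0)
  turns <- unlist(lapply(mats, function(m)
    .turning_angles_mat(m, dt, pause_speed)), use.names = FALSE)
  turns <- turns[!is.na(turns)]
  h <- graphics::hist(pmin(turns, 180 - 1e-12), breaks = breaks, plot = FALSE)
  hist_df <- data.frame(lower = h$breaks[-length(h$breaks)],
                        upper = h$breaks[-1L],
                        frequency = h$counts / sum(h$counts))
  curve <- mean_displacement_curve(tracks, max_lag = max_lag, dt = dt)
  mc <- motility_coefficient(curve, fit_window)
  out <- list(per_track_mean_speed = per_speed,
              cohort_mean_speed = mean(per_speed),
              sem = stats::sd(per_speed) / sqrt(length(per_speed)),
              turning_angle_hist = hist_df,
              displacement_curve = curve,
              motility_coefficient = mc,
              n_tracks = length(per_speed),
              n_turning_angles = length(turns),
              dt = dt,
              fit_window = fit_window)
  class(out) <- "motility"
  out
}

#' @export
print.motility <- function(x, ...) {
  cat("Cohort motility summary\n")
  cat(sprintf("  tracks               : %d (dt = %g s)\n", x$n_tracks, x$dt))
  cat(sprintf("  mean track speed     : %.2f +/- %.2f um/min (mean +/- SEM)\n",
              x$cohort_mean_speed, x$sem))
  cat(sprintf("  motility coefficient : %.1f um^2/min (fit %g-%g min)\n",
              x$motility_coefficient,
              x$fit_window[1L] / 60, x$fit_window[2L] / 60))
  invisible(x)
}

#' @export
summary.motility <- function(object, ...) {
  print(object)
  cat(sprintf("  turning angles       : n = %d, median %.1f deg\n",
              object$n_turning_angles, median_from_hist(object)))
  cat("  speed quartiles (um/min):\n")
  print(round(stats::quantile(object$per_track_mean_speed), 2))
  invisible(object)
}

# Median turning angle interpolated from the binned histogram.
median_from_hist <- function(x) {
  h <- x$turning_angle_hist
  cf <- cumsum(h$frequency)
  i <- which(cf >= 0.5)[1L]
  lo <- if (i == 1L) 0 else cf[i - 1L]
  h$lower[i] + (0.5 - lo) / h$frequency[i] * (h$upper[i] - h$lower[i])
}

#' @export
coef.motility <- function(object, ...) {
  c(mean_speed = object$cohort_mean_speed,
    sem = object$sem,
    motility_coefficient = object$motility_coefficient)
}

#' Plot a motility fit
#'
#' Two base-graphics panels: the turning-angle frequency histogram and the
#' mean displacement versus sqrt(time) curve with the origin-constrained fit
#' line over the fit window.
#'
#' @param x a `motility` object.
#' @param ... passed to [plot()].
#' @export
plot.motility <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  h <- x$turning_angle_hist
  graphics::barplot(h$frequency, names.arg = paste0(h$lower, "-", h$upper),
                    las = 2, xlab = "turning angle (deg)", ylab = "frequency",
                    ...)
  cv <- x$displacement_curve
  graphics::plot(cv$sqrt_t_min, cv$displacement_um, type = "b", pch = 16,
                 xlab = expression(sqrt(t) ~ (min^{1 / 2})),
                 ylab = "mean displacement (um)", ...)
  m <- sqrt(6 * x$motility_coefficient)
  graphics::abline(a = 0, b = m, lty = 2)
  invisible(x)
}
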