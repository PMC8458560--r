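# Fixture builders shared across test files. All tracks are built in code;
# dt defaults to the 20-s two-photon frame interval.

make_track <- function(m, dt = 20, id = "1") {
  track_table(data.frame(track_id = id,
                         t = seq(0, by = dt, length.out = nrow(m)),
                         x = m[, 1], y = m[, 2], z = m[, 3]),
              dt = dt)
}

bind_tracks <- function(...) {
  dfs <- lapply(list(...), as.data.frame)
  dt <- attr(list(...)[[1]], "dt")
  track_table(do.call(rbind, dfs), dt = dt)
}

# Straight track along +x at a given speed (um/min).
straight_track <- function(speed, n_pos = 10, dt = 20, id = "1") {
  step <- speed / 60 * dt
  make_track(cbind((seq_len(n_pos) - 1) * step, 0, 0), dt = dt, id = id)
}

# Circular helix of given radius (um) and pitch (um per turn), sampled at
# n_pos points with angular step dphi. Constant chord length, hence constant
# speed and constant turning angle.
helix_track <- function(radius = 5, pitch = 6, n_pos = 30, dphi = pi / 8,
                        dt = 20, id = "1") {
  phi <- (seq_len(n_pos) - 1) * dphi
  make_track(cbind(radius * cos(phi), radius * sin(phi),
                   pitch * phi / (2 * pi)), dt = dt, id = id)
}

helix_chord <- function(radius, pitch, dphi) {
  sqrt((2 * radius * sin(dphi / 2))^2 + (pitch * dphi / (2 * pi))^2)
}

# Isotropic 3D Brownian cohort with diffusivity D in um^2/min: per-axis
# step variance 2 * D * dt(min).
brownian_tracks <- function(n_tracks, n_steps, D, dt = 20) {
  sd_axis <- sqrt(2 * D * dt / 60)
  dfs <- lapply(seq_len(n_tracks), function(i) {
    steps <- matrix(stats::rnorm(3 * n_steps, 0, sd_axis), ncol = 3)
    pos <- rbind(0, apply(steps, 2, cumsum))
    data.frame(track_id = as.character(i),
               t = seq(0, by = dt, length.out = n_steps + 1),
               x = pos[, 1], y = pos[, 2], z = pos[, 3])
  })
  track_table(do.call(rbind, dfs), dt = dt)
}

# A random rigid motion applied to every track of a table.
apply_rigid <- function(tracks, rot = NULL, shift = NULL) {
  if (is.null(rot)) rot <- tcellscan:::random_rotation()
  if (is.null(shift)) shift <- stats::rnorm(3, 0, 100)
  m <- as.matrix(as.data.frame(tracks)[, c("x", "y", "z")]) %*% t(rot)
  out <- as.data.frame(tracks)
  out$x <- m[, 1] + shift[1]
  out$y <- m[, 2] + shift[2]
  out$z <- m[, 3] + shift[3]
  track_table(out, dt = attr(tracks, "dt"))
}
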