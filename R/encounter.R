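#' Geometry and schedule of the encounter simulation
#'
#' The model T cell zone is a sphere of `zone_diameter` um (default 1 mm)
#' containing `n_dc` static dendritic cells placed uniformly at random.
#' `n_tcells` synthetic T cell tracks are dropped in with starting positions
#' drawn from an isotropic normal of SD `start_sd` um about the centre, and
#' followed for `duration` seconds at `dt`-second steps. A cell whose
#' distance to any DC falls within `contact_radius` um is in stable contact
#' and is frozen at that position for the rest of the run. The whole
#' simulation is repeated `n_reps` times with fresh DC placement and fresh
#' track selection.
#'
#' @param zone_diameter T cell zone diameter, um.
#' @param start_sd SD of the starting-position distribution, um.
#' @param contact_radius stable-contact distance, um.
#' @param n_dc number of static DCs.
#' @param n_tcells number of simulated T cells per replicate.
#' @param duration simulated time in seconds (default 8 h).
#' @param dt step duration in seconds.
#' @param n_reps number of replicate simulations.
#' @return an object of class `"arena_config"`.
#' @export
arena_config <- function(zone_diameter = 1000, start_sd = 150,
                         contact_radius = 15, n_dc = 50, n_tcells = 100,
                         duration = 8 * 3600, dt = 20, n_reps = 50) {
  stopifnot(zone_diameter > 0, start_sd > 0, contact_radius > 0,
            contact_radius < zone_diameter / 2, n_dc >= 0, n_tcells >= 1,
            duration > 0, dt > 0, n_reps >= 1)
  out <- list(zone_diameter = zone_diameter, start_sd = start_sd,
              contact_radius = contact_radius, n_dc = n_dc,
              n_tcells = n_tcells, duration = duration, dt = dt,
              n_reps = n_reps)
  class(out) <- "arena_config"
  out
}

#' @export
print.arena_config <- function(x, ...) {
  cat("<arena_config>\n")
  cat(sprintf("  zone %g um sphere; %d DCs; contact within %g um\n",
              x$zone_diameter, x$n_dc, x$contact_radius))
  cat(sprintf("  %d T cells from Normal(0, %g um) for %g h at %g s; %d reps\n",
              x$n_tcells, x$start_sd, x$duration / 3600, x$dt, x$n_reps))
  invisible(x)
}

#' Place dendritic cells uniformly in the zone
#'
#' @param n number of DCs.
#' @param radius zone radius, um.
#' @param method `"inverse"` (radius = R * U^(1/3) times a uniform
#'   direction) or `"rejection"` (uniform in the bounding cube, keep points
#'   inside the ball); the two are distributionally equivalent.
#' @return n-by-3 matrix of positions (um, zone centre at the origin).
#' @export
place_dcs <- function(n, radius = 500, method = c("inverse", "rejection")) {
  method <- match.arg(method)
  if (n == 0L) return(matrix(numeric(0), 0L, 3L))
  if (method == "inverse") {
    dirs <- runif_sphere(n)
    r <- radius * stats::runif(n)^(1 / 3)
    dirs * r
  } else {
    out <- matrix(numeric(0), 0L, 3L)
    while (nrow(out) < n) {
      cand <- matrix(stats::runif(3L * n, -radius, radius), ncol = 3L)
      keep <- rowSums(cand * cand) <= radius^2
      out <- rbind(out, cand[keep, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  }
}

# A uniform random 3D rotation matrix (Haar measure), via QR of a Gaussian
# matrix with sign fixing.
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Place T cell tracks in the arena
#'
#' Randomly selects `n_tcells` tracks (without replacement), applies an
#' independent uniform 3D rotation to each, and translates it so its first
#' position is an isotropic Normal(centre, `start_sd`^2 I) draw. Rotation
#' and translation are rigid, so all speeds and angles are preserved.
#'
#' @param mats list of n-by-3 track coordinate matrices (see
#'   [track_matrices()]), each with at least `n_steps + 1` rows.
#' @param n_tcells number of tracks to place.
#' @param start_sd starting-position SD, um.
#' @param n_steps number of steps to keep (tracks are truncated to
#'   `n_steps + 1` positions); `NULL` keeps full tracks.
#' @return list of placed coordinate matrices.
#' @export
place_tcells <- function(mats, n_tcells, start_sd, n_steps = NULL) {
  stopifnot(n_tcells <= length(mats))
  picked <- sample.int(length(mats), n_tcells)
  lapply(mats[picked], function(m) {
    if (!is.null(n_steps)) {
      if (nrow(m) < n_steps + 1L)
        stop("track shorter than the simulation duration")
      m <- m[seq_len(n_steps + 1L), , drop = FALSE]
    }
    m <- m %*% t(random_rotation())
    start <- stats::rnorm(3L, 0, start_sd)
    sweep(m, 2L, m[1L, ] - start)
  })
}

# --- contact detection -----------------------------------------------------

# Brute force: first row of pos (n x 3) within r of any DC row, or NA.
first_contact_bruteforce <- function(pos, dcs, r) {
  if (nrow(dcs) == 0L) return(NA_integer_)
  d2 <- outer(rowSums(pos * pos), rowSums(dcs * dcs), "+") -
    2 * pos %*% t(dcs)
  hit <- which(rowSums(d2 <= r * r + 1e-9) > 0L)
  if (length(hit)) hit[1L] else NA_integer_
}

# Uniform-grid spatial hash over DC positions with cell size = contact
# radius; a query point can only contact DCs in its own or the 26
# neighbouring grid cells.
dc_grid <- function(dcs, r) {
  key <- function(ix, iy, iz) paste(ix, iy, iz, sep = ",")
  idx <- floor(dcs / r)
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(dcs))) {
    k <- key(idx[i, 1L], idx[i, 2L], idx[i, 3L])
    env[[k]] <- c(env[[k]], i)
  }
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  list(env = env, r = r, dcs = dcs, offs = offs, key = key)
}

first_contact_grid <- function(pos, grid) {
  r2 <- grid$r^2 + 1e-9
  for (i in seq_len(nrow(pos))) {
    p <- pos[i, ]
    base <- floor(p / grid$r)
    for (o in seq_len(27L)) {
      k <- grid$key(base[1L] + grid$offs[o, 1L],
                    base[2L] + grid$offs[o, 2L],
                    base[3L] + grid$offs[o, 3L])
      cand <- grid$env[[k]]
      if (is.null(cand)) next
      dc <- grid$dcs[cand, , drop = FALSE]
      dd <- sweep(dc, 2L, p)
      if (any(rowSums(dd * dd) <= r2)) return(i)
    }
  }
  NA_integer_
}

#' Run one encounter replicate
#'
#' Follows each placed track step by step: the first position within
#' `contact_radius` of any DC freezes the cell there for all later steps
#' (contact is tested on actual distance, whether or not the cell is
#' momentarily outside the zone). Residency counts every step whose
#' (possibly frozen) position lies inside the zone, including steps after
#' re-entry.
#'
#' @param placed list of placed track matrices from [place_tcells()].
#' @param dcs DC position matrix from [place_dcs()].
#' @param config an [arena_config()].
#' @param method contact detection: `"bruteforce"`, `"grid"` (spatial hash,
#'   used automatically for large DC counts) or `"auto"`.
#' @param keep_positions also return the followed (post-freeze) trajectories.
#' @return list with `contact_fraction` (% of cells with >= 1 contact),
#'   `first_contact_time` (minutes, NA if none, per cell), `residency_steps`
#'   (per cell), `in_zone_fraction` (fraction of cells inside the zone
#'   at each time point, length n_steps + 1), and with `keep_positions` the
#'   list of effective trajectories `positions`.
#' @export
run_replicate <- function(placed, dcs, config,
                          method = c("auto", "bruteforce", "grid"),
                          keep_positions = FALSE) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (nrow(dcs) > 500L) "grid" else "bruteforce"
  r <- config$contact_radius
  R <- config$zone_diameter / 2
  grid <- if (method == "grid" && nrow(dcs) > 0L) dc_grid(dcs, r) else NULL
  n_cells <- length(placed)
  n_pos <- nrow(placed[[1L]])
  contact_step <- rep(NA_integer_, n_cells)
  residency <- integer(n_cells)
  inzone <- matrix(FALSE, n_cells, n_pos)
  kept <- if (keep_positions) vector("list", n_cells) else NULL
  for (ci in seq_len(n_cells)) {
    pos <- placed[[ci]]
    hit <- if (method == "grid") {
      if (is.null(grid)) NA_integer_ else first_contact_grid(pos, grid)
    } else first_contact_bruteforce(pos, dcs, r)
    if (!is.na(hit) && hit < n_pos)  # freeze at the contact position
      pos[(hit + 1L):n_pos, ] <- rep(pos[hit, ], each = n_pos - hit)
    contact_step[ci] <- hit
    inz <- rowSums(pos * pos) <= R^2
    inzone[ci, ] <- inz
    residency[ci] <- sum(inz)
    if (keep_positions) kept[[ci]] <- pos
  }
  out <- list(contact_fraction = 100 * mean(!is.na(contact_step)),
              first_contact_time = (contact_step - 1L) * config$dt / 60,
              residency_steps = residency,
              in_zone_fraction = colMeans(inzone))
  if (keep_positions) out$positions <- kept
  out
}

#' Run the full encounter experiment
#'
#' `n_reps` independent replicates, each with fresh DC placement and a fresh
#' random choice, rotation and start position of the T cell tracks; the
#' synthesized cohort itself is fixed for the whole experiment.
#'
#' @param tracks a `track_table` of synthesized tracks (at least
#'   `config$n_tcells` tracks of at least `config$duration` seconds).
#' @param config an [arena_config()].
#' @param seed integer RNG seed, or `NULL`.
#' @param method contact-detection method, see [run_replicate()].
#' @return object of class `"encounter_result"`: list with
#'   `per_rep_contact_fraction` (%), `mean_contact_fraction`,
#'   `sd_contact_fraction`, `first_contact_times` (list per rep, minutes),
#'   `residency_steps` (list per rep), `in_zone_fraction_curve` (matrix,
#'   reps x time points), `time_h`, and `config`.
#' @export
run_experiment <- function(tracks, config, seed = NULL,
                           method = c("auto", "bruteforce", "grid")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  mats <- if (is.list(tracks) && !is.data.frame(tracks)) tracks else
    track_matrices(tracks)
  n_steps <- floor(config$duration / config$dt)
  fracs <- numeric(config$n_reps)
  fct <- res <- vector("list", config$n_reps)
  curves <- matrix(0, config$n_reps, n_steps + 1L)
  for (rep_i in seq_len(config$n_reps)) {
    dcs <- place_dcs(config$n_dc, config$zone_diameter / 2)
    placed <- place_tcells(mats, config$n_tcells, config$start_sd, n_steps)
    one <- run_replicate(placed, dcs, config, method)
    fracs[rep_i] <- one$contact_fraction
    fct[[rep_i]] <- one$first_contact_time
    res[[rep_i]] <- one$residency_steps
    curves[rep_i, ] <- one$in_zone_fraction
  }
  out <- list(per_rep_contact_fraction = fracs,
              mean_contact_fraction = mean(fracs),
              sd_contact_fraction = stats::sd(fracs),
              first_contact_times = fct,
              residency_steps = res,
              in_zone_fraction_curve = curves,
              time_h = seq(0, by = config$dt, length.out = n_steps + 1L) /
                3600,
              config = config)
  class(out) <- "encounter_result"
  out
}

#' @export
print.encounter_result <- function(x, ...) {
  cat("Encounter simulation\n")
  cat(sprintf("  %d reps x %d cells, %d DCs, %g h\n",
              x$config$n_reps, x$config$n_tcells, x$config$n_dc,
              x$config$duration / 3600))
  cat(sprintf("  contact fraction: %.1f +/- %.1f %% (mean +/- SD)\n",
              x$mean_contact_fraction, x$sd_contact_fraction))
  invisible(x)
}

#' @export
summary.encounter_result <- function(object, ...) {
  print(object)
  t1 <- unlist(object$first_contact_times)
  if (any(!is.na(t1)))
    cat(sprintf("  median first-contact time: %.1f min\n",
                stats::median(t1, na.rm = TRUE)))
  cat(sprintf("  mean residency: %.0f of %d steps\n",
              mean(unlist(object$residency_steps)),
              ncol(object$in_zone_fraction_curve)))
  invisible(object)
}

#' Residence half-life from the fraction-inside-zone curve
#'
#' Fits f(t) = f0 * exp(-lambda t) by least squares on the log of the mean
#' fraction of cells inside the zone, and reports the half-life
#' ln(2) / lambda in hours. Intended for free-migration runs (no DCs), the
#' residency-calibration counterpart of the published 11-hour wild-type
#' half-life; extrapolation beyond the simulated duration is expected. A
#' non-decaying curve gives an infinite half-life.
#'
#' @param result an `encounter_result` (or a numeric fraction-inside curve).
#' @param time_h time points in hours (required for a bare numeric curve).
#' @return half-life in hours (`Inf` when the fit does not decay).
#' @export
residence_half_life <- function(result, time_h = NULL) {
  if (inherits(result, "encounter_result")) {
    f <- colMeans(result$in_zone_fraction_curve)
    time_h <- result$time_h
  } else {
    f <- as.numeric(result)
    if (is.null(time_h)) stop("time_h required for a bare curve")
  }
  keep <- f > 0
  if (sum(keep) < 2L) stop("too few positive points to fit a decay")
  fit <- stats::lm(log(f[keep]) ~ time_h[keep])
  lambda <- -unname(stats::coef(fit)[2L])
  if (lambda <= 0) return(Inf)
  log(2) / lambda
}
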