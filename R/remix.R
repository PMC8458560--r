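#' Build the joint step-triplet pool from measured tracks
#'
#' Long in-silico tracks are synthesized by resampling measured steps as
#' joint (speed, turning angle, plane angle) triplets rather than drawing
#' the three components independently, because in vivo the components are
#' coupled: steps at higher velocities tend to have smaller turning angles.
#' A step qualifies for the pool only if all three components are defined at
#' its entry joint, which requires two prior displacements (so the third and
#' later steps of a track) and excludes pauses and collinear joints.
#'
#' @param measured a `track_table` of measured (or simulated) tracks.
#' @param pause_speed pause threshold in um/min.
#' @return data.frame of class `"step_pool"` with columns `speed` (um/min),
#'   `turn` (deg, 0-180), `plane` (deg, (-180, 180]), and provenance
#'   `track_id`, `step` (displacement index within the source track).
#'   The number of excluded steps is kept in attribute `n_excluded`.
#' @export
build_step_pool <- function(measured, pause_speed = PAUSE_SPEED) {
  if (!is_track_table(measured)) measured <- track_table(measured)
  dt <- attr(measured, "dt")
  mats <- track_matrices(measured)
  rows <- list()
  excluded <- 0L
  for (id in names(mats)) {
    m <- mats[[id]]
    n_steps <- nrow(m) - 1L
    if (n_steps < 3L) { excluded <- excluded + n_steps; next }
    sp <- .step_speeds_mat(m, dt)
    tu <- .turning_angles_mat(m, dt, pause_speed)
    pl <- .plane_angles_mat(m, dt, pause_speed)
    s <- 3L:n_steps
    ok <- !is.na(tu[s - 1L]) & !is.na(pl[s - 2L])
    excluded <- excluded + (n_steps - sum(ok))
    if (any(ok))
      rows[[id]] <- data.frame(speed = sp[s][ok], turn = tu[s - 1L][ok],
                               plane = pl[s - 2L][ok],
                               track_id = id, step = s[ok])
  }
  if (!length(rows))
    stop("empty step pool: no step has a defined turning and plane angle ",
         "(straight or pausing tracks?)")
  pool <- do.call(rbind, rows)
  rownames(pool) <- NULL
  class(pool) <- c("step_pool", "data.frame")
  attr(pool, "dt") <- dt
  attr(pool, "n_excluded") <- excluded
  pool
}

#' Roughness of the measured tracks
#'
#' The temporal smoothness targets for the exchange algorithm: the mean over
#' all within-track consecutive pairs (pooled across tracks, never across
#' track boundaries) of the squared difference of consecutive step speeds
#' and of consecutive turning angles.
#'
#' @inheritParams build_step_pool
#' @return list with `speed_roughness` ((um/min)^2) and `turn_roughness`
#'   (deg^2).
#' @export
measured_roughness <- function(measured, pause_speed = PAUSE_SPEED) {
  if (!is_track_table(measured)) measured <- track_table(measured)
  dt <- attr(measured, "dt")
  mats <- track_matrices(measured)
  ds2 <- dt2 <- numeric(0)
  for (m in mats) {
    sp <- .step_speeds_mat(m, dt)
    if (length(sp) >= 2L) ds2 <- c(ds2, diff(sp)^2)
    tu <- .turning_angles_mat(m, dt, pause_speed)
    if (length(tu) >= 2L) {
      dd <- diff(tu)^2
      keep <- !is.na(dd)          # both adjacent angles defined
      dt2 <- c(dt2, dd[keep])
    }
  }
  if (!length(ds2) || !length(dt2))
    stop("fewer than 2 consecutive defined values; cannot compute roughness")
  list(speed_roughness = mean(ds2), turn_roughness = mean(dt2))
}

#' Reorder sampled step triplets to match measured roughness
#'
#' A freshly resampled triplet sequence is temporally white: its consecutive
#' speed and turning-angle differences are larger than in real tracks.
#' `remix_exchange()` repeatedly proposes swapping two random positions and
#' keeps a swap only if it strictly decreases the summed normalised excess
#' of the sequence's speed and turning-angle roughness over the measured
#' targets, stopping as soon as both roughness values are at or below their
#' targets. A sequence that already satisfies both targets is returned
#' unchanged.
#'
#' @param sampled data.frame of step triplets (columns `speed`, `turn`,
#'   `plane`), typically rows sampled with replacement from a
#'   [build_step_pool()] pool.
#' @param targets roughness targets from [measured_roughness()].
#' @param max_proposals proposal budget before giving up.
#' @return the reordered data.frame, with attributes `n_proposals`,
#'   `n_accepted`, `speed_roughness`, `turn_roughness` and
#'   `objective_trace` (objective value after each accepted swap).
#' @export
remix_exchange <- function(sampled, targets, max_proposals = 2e5) {
  stopifnot(is.data.frame(sampled),
            all(c("speed", "turn", "plane") %in% names(sampled)))
  res <- .remix_exchange_cpp(sampled$speed, sampled$turn,
                             targets$speed_roughness,
                             targets$turn_roughness,
                             as.integer(max_proposals))
  if (!res$converged)
    stop("remix_exchange did not reach the roughness targets within ",
         max_proposals, " proposals; use a larger step pool or looser ",
         "targets")
  out <- sampled[res$order, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_proposals") <- res$n_proposals
  attr(out, "n_accepted") <- res$n_accepted
  attr(out, "speed_roughness") <- res$speed_roughness
  attr(out, "turn_roughness") <- res$turn_roughness
  attr(out, "objective_trace") <- res$objective_trace
  out
}

# R reference implementation of sequence roughness, used as the oracle for
# the C++ local-delta bookkeeping.
sequence_roughness <- function(sampled) {
  list(speed_roughness = mean(diff(sampled$speed)^2),
       turn_roughness = mean(diff(sampled$turn)^2))
}

#' Reconstruct 3D positions from a step-triplet sequence
#'
#' Rebuilds a track from (speed, turning angle, plane angle) triplets. The
#' initial direction is uniform on the sphere and the initial plane normal
#' uniform on the circle orthogonal to it (so reconstructed tracks carry no
#' orientation bias); thereafter each triplet rotates the plane normal about
#' the current direction by its plane angle, rotates the direction about the
#' new normal by its turning angle, and advances by speed * dt. Re-deriving
#' the angle sequences from the reconstructed positions reproduces the
#' input triplets (the round-trip property, up to the randomised initial
#' frame consuming the first turn and the first two plane angles).
#'
#' @param steps data.frame of triplets (columns `speed`, `turn`, `plane`).
#' @param dt step duration in seconds.
#' @param track_id identifier for the reconstructed track.
#' @return a one-track `track_table` starting at the origin.
#' @export
reconstruct_track <- function(steps, dt = 20, track_id = "1") {
  stopifnot(is.data.frame(steps), nrow(steps) >= 1L,
            all(c("speed", "turn", "plane") %in% names(steps)))
  u0 <- drop(runif_sphere(1L))
  n0 <- runif_orthogonal(u0)
  pos <- .reconstruct_track_cpp(steps$speed, steps$turn, steps$plane,
                                dt, u0, n0)
  track_table(data.frame(track_id = track_id,
                         t = seq(0, by = dt, length.out = nrow(pos)),
                         x = pos[, 1L], y = pos[, 2L], z = pos[, 3L]),
              dt = dt)
}

#' Synthesize long tracks from a measured cohort
#'
#' The full remix pipeline: build the joint triplet pool and the roughness
#' targets from the measured cohort, then for each synthetic track sample
#' `duration / dt` triplets with replacement, reorder them with
#' [remix_exchange()], and reconstruct 3D positions. Per-track RNG streams
#' are derived from `seed`, so a fixed seed gives bit-identical output.
#'
#' @param measured a `track_table` of measured (or simulated) short tracks.
#' @param n_tracks number of synthetic tracks (default 200).
#' @param duration synthetic track duration in seconds (default 8 h).
#' @param dt step duration in seconds.
#' @param seed integer RNG seed, or `NULL` for the current RNG state.
#' @param max_proposals per-track proposal budget for [remix_exchange()].
#' @param pause_speed pause threshold in um/min.
#' @param verbose print per-stage counters.
#' @return a `track_table` of `n_tracks` tracks with `duration / dt` steps
#'   each.
#' @export
synthesize_tracks <- function(measured, n_tracks = 200, duration = 8 * 3600,
                              dt = 20, seed = NULL, max_proposals = 2e5,
                              pause_speed = PAUSE_SPEED, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  pool <- build_step_pool(measured, pause_speed)
  targets <- measured_roughness(measured, pause_speed)
  n_steps <- floor(duration / dt)
  if (verbose)
    message(sprintf("step pool: %d triplets (%d steps excluded); targets: %.2f (um/min)^2, %.1f deg^2",
                    nrow(pool), attr(pool, "n_excluded"),
                    targets$speed_roughness, targets$turn_roughness))
  dfs <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    sampled <- pool[sample.int(nrow(pool), n_steps, replace = TRUE), ,
                    drop = FALSE]
    remixed <- remix_exchange(sampled, targets, max_proposals)
    if (verbose)
      message(sprintf("track %d: %d/%d proposals accepted", i,
                      attr(remixed, "n_accepted"),
                      attr(remixed, "n_proposals")))
    tt <- reconstruct_track(remixed, dt = dt, track_id = as.character(i))
    dfs[[i]] <- as.data.frame(tt)
  }
  track_table(do.call(rbind, dfs), dt = dt)
}
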