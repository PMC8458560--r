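#' Track tables
#'
#' A track table is the package's universal exchange format: a `data.frame`
#' with one row per observed cell position and columns `track_id` (identifier),
#' `t` (time in seconds, strictly increasing within a track), and `x`, `y`, `z`
#' (centroid coordinates in micrometres). `track_table()` validates a raw data
#' frame and attaches the class `"track_table"`; most other functions in the
#' package accept anything `track_table()` accepts.
#'
#' Validation enforces the container's invariants: every track has at least
#' two positions, time points are strictly increasing within a track, all
#' coordinates are finite, and (unless `dt = NULL`) sampling is uniform at the
#' stated interval within a tolerance.
#'
#' @param df data.frame with columns `track_id`, `t`, `x`, `y`, `z` (or the
#'   names given in `mapping`).
#' @param dt expected sampling interval in seconds, or `NULL` to skip the
#'   uniform-spacing check. Default 20 s, the usual two-photon frame interval.
#' @param mapping named character vector translating this package's column
#'   names to the input's, e.g. `c(track_id = "TrackID", t = "Time", x = "X",
#'   y = "Y", z = "Z")`. Useful for other tracking-export dialects.
#' @param tol relative tolerance on the sampling interval.
#' @return `df`, with canonical column names and class `"track_table"`, sorted
#'   by track and time.
#' @examples
#' tt <- track_table(data.frame(track_id = 1, t = c(0, 20, 40),
#'                              x = c(0, 4, 8), y = 0, z = 0))
#' n_tracks(tt)
#' @export
track_table <- function(df, dt = 20, mapping = NULL, tol = 1e-6) {
  stopifnot(is.data.frame(df))
  if (!is.null(mapping)) {
    want <- c("track_id", "t", "x", "y", "z")
    miss <- setdiff(want, names(mapping))
    if (length(miss))
      stop("mapping must name columns for: ", paste(miss, collapse = ", "))
    idx <- match(mapping[want], names(df))
    if (anyNA(idx))
      stop("mapped columns absent from input: ",
           paste(mapping[want][is.na(idx)], collapse = ", "))
    df <- df[idx]
    names(df) <- want
  }
  need <- c("track_id", "t", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("track table lacks columns: ", paste(miss, collapse = ", "))
  df <- df[need]
  df$track_id <- as.character(df$track_id)
  for (col in c("t", "x", "y", "z")) {
    df[[col]] <- as.numeric(df[[col]])
    if (!all(is.finite(df[[col]])))
      stop("non-finite values in column '", col, "'")
  }
  df <- df[order(df$track_id, df$t), , drop = FALSE]
  rownames(df) <- NULL
  for (id in unique(df$track_id)) {
    tt <- df$t[df$track_id == id]
    if (length(tt) < 2L)
      stop("track '", id, "' has fewer than 2 positions")
    d <- diff(tt)
    if (any(d <= 0))
      stop("time points not strictly increasing in track '", id, "'")
    if (!is.null(dt) && any(abs(d - dt) > tol * dt))
      stop("track '", id, "' is not uniformly sampled at dt = ", dt, " s")
  }
  class(df) <- c("track_table", "data.frame")
  attr(df, "dt") <- if (is.null(dt)) unname(stats::median(diff(df$t))) else dt
  df
}

#' @rdname track_table
#' @param x a track table.
#' @export
is_track_table <- function(x) inherits(x, "track_table")

#' @rdname track_table
#' @export
n_tracks <- function(x) length(unique(x$track_id))

#' Split a track table into per-track coordinate matrices
#'
#' @param tracks a track table.
#' @return named list of n-by-3 matrices of x, y, z positions, ordered by time.
#' @keywords internal
track_matrices <- function(tracks) {
  sp <- split(seq_len(nrow(tracks)), tracks$track_id)
  lapply(sp, function(i)
    cbind(x = tracks$x[i], y = tracks$y[i], z = tracks$z[i]))
}

#' Read and write track tables
#'
#' `read_tracks()` reads a delimited text file (TSV by default, CSV if the
#' file name ends in `.csv` or `sep = ","`) with a header row, applies an
#' optional column mapping, and validates the result. `write_tracks()` writes
#' the standard five-column TSV.
#'
#' @param file path to a delimited text file.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @inheritParams track_table
#' @return `read_tracks()` a validated `track_table`; `write_tracks()` the
#'   file path, invisibly.
#' @export
read_tracks <- function(file, sep = NULL, dt = 20, mapping = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  track_table(df, dt = dt, mapping = mapping)
}

#' @rdname read_tracks
#' @param tracks a track table.
#' @export
write_tracks <- function(tracks, file) {
  utils::write.table(as.data.frame(tracks), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf("<track_table> %d tracks, %d positions, dt = %g s\n",
              n_tracks(x), nrow(x), attr(x, "dt")))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
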