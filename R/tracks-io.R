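#' Build a track set
#'
#' A `track_set` is a list of single-molecule tracks sharing one frame
#' interval and one imaging regime. Each track is a list with `cell_id`,
#' `track_id` and a `points` data frame (`frame`, `x`, `y`; frames strictly
#' increasing, coordinates in um).
#'
#' @param tracks List of track records as described above.
#' @param dt Frame interval in seconds shared by all tracks.
#' @param regime `"fast"` (displacement analysis, default 0.01 s) or
#'   `"slow"` (residence-time analysis, default 0.5 s).
#' @return An object of class `track_set`.
#' @export
track_set <- function(tracks, dt, regime = c("fast", "slow")) {
  regime <- match.arg(regime)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  for (tr in tracks) {
    p <- tr$points
    if (nrow(p) < 1L) stop("each track needs >= 1 point", call. = FALSE)
    if (is.unsorted(p$frame, strictly = TRUE)) {
      stop("track ", tr$track_id, ": frames must be strictly increasing",
           call. = FALSE)
    }
  }
  structure(list(tracks = tracks, dt = dt, regime = regime),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  np <- sum(vapply(x$tracks, function(t) nrow(t$points), integer(1)))
  cat(sprintf("track_set: %d tracks, %d points, dt = %g s, regime = %s\n",
              length(x$tracks), np, x$dt, x$regime))
  cat("cells:", paste(unique(vapply(x$tracks, `[[`, "", "cell_id")),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Default column mapping for tracker CSV exports
#'
#' Maps the package's field names to the column headers of a common tracker
#' export (TrackMate-style spots table). `cell_id` is optional: if the
#' column is absent, the file name (without extension) is used as cell id.
#'
#' @param track_id,frame,x,y,cell_id Column names in the CSV.
#' @return Named list usable as the `dialect` of [read_tracks_csv()].
#' @export
tracks_dialect <- function(track_id = "TRACK_ID", frame = "FRAME",
                           x = "POSITION_X", y = "POSITION_Y",
                           cell_id = "CELL_ID") {
  list(track_id = track_id, frame = frame, x = x, y = y, cell_id = cell_id)
}

#' Read single-molecule tracks from a tracker CSV export
#'
#' Reads a track table (one row per localization), groups rows into tracks
#' by `(cell_id, track_id)` and sorts each track by frame. Rows with missing
#' coordinates are dropped with a message reporting the count. Numeric
#' parsing always uses the decimal point, independent of the locale.
#'
#' @param path CSV file path.
#' @param dt Frame interval in seconds.
#' @param regime `"fast"` or `"slow"`.
#' @param dialect Column mapping from [tracks_dialect()].
#' @param pixel_size Optional scale factor (um per coordinate unit) applied
#'   to x and y, for exports in pixel units. Default 1 (already um).
#' @return A [track_set()].
#' @export
read_tracks_csv <- function(path, dt, regime = c("fast", "slow"),
                            dialect = tracks_dialect(), pixel_size = 1) {
  regime <- match.arg(regime)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, dec = ".")
  if (nrow(df) == 0L) {
    warning("empty track table: ", path)
    return(track_set(list(), dt = dt, regime = regime))
  }
  need <- c(dialect$track_id, dialect$frame, dialect$x, dialect$y)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         "; available: ", paste(names(df), collapse = ", "), call. = FALSE)
  }
  cell <- if (dialect$cell_id %in% names(df)) {
    as.character(df[[dialect$cell_id]])
  } else {
    rep(tools::file_path_sans_ext(basename(path)), nrow(df))
  }
  x <- as.numeric(df[[dialect$x]]) * pixel_size
  y <- as.numeric(df[[dialect$y]]) * pixel_size
  frame <- as.integer(df[[dialect$frame]])
  bad <- !is.finite(x) | !is.finite(y) | is.na(frame)
  if (any(bad)) {
    message("dropped ", sum(bad), " row(s) with missing coordinates")
  }
  keep <- which(!bad)
  key <- paste(cell[keep], df[[dialect$track_id]][keep], sep = "\r")
  tracks <- lapply(split(keep, key), function(idx) {
    o <- idx[order(frame[idx])]
    list(cell_id = cell[o[1]],
         track_id = as.character(df[[dialect$track_id]][o[1]]),
         points = data.frame(frame = frame[o], x = x[o], y = y[o]))
  })
  names(tracks) <- NULL
  track_set(tracks, dt = dt, regime = regime)
}

#' Write a track set as a tracker-style CSV
#'
#' Inverse of [read_tracks_csv()] under the same dialect; round-trips a
#' `track_set` exactly (up to numeric printing precision, 15 significant
#' digits).
#'
#' @param trackset A [track_set()].
#' @param path Output CSV path.
#' @param dialect Column mapping from [tracks_dialect()].
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(trackset, path, dialect = tracks_dialect()) {
  stopifnot(inherits(trackset, "track_set"))
  rows <- lapply(trackset$tracks, function(tr) {
    data.frame(cell = tr$cell_id, track = tr$track_id,
               frame = tr$points$frame, x = tr$points$x, y = tr$points$y)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- data.frame(df$cell, df$track, df$frame,
                    format(df$x, digits = 15, scientific = FALSE, trim = TRUE),
                    format(df$y, digits = 15, scientific = FALSE, trim = TRUE))
  names(out) <- c(dialect$cell_id, dialect$track_id, dialect$frame,
                  dialect$x, dialect$y)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract consecutive-frame jump magnitudes from tracks
#'
#' Computes Euclidean displacements between localizations in *consecutive*
#' frames only: pairs whose frame numbers differ by more than 1 (gap-closed
#' links from upstream trackers) are excluded, so a gap never contributes an
#' inflated long displacement.
#'
#' @param trackset A [track_set()].
#' @param by_cell If `TRUE`, return a named list of per-cell jump vectors;
#'   otherwise one pooled numeric vector.
#' @return Numeric vector of jump magnitudes (um), or a list of them.
#' @export
extract_jumps <- function(trackset, by_cell = FALSE) {
  stopifnot(inherits(trackset, "track_set"))
  per_track <- lapply(trackset$tracks, function(tr) {
    p <- tr$points
    if (nrow(p) < 2L) return(numeric(0))
    i <- which(diff(p$frame) == 1L)
    sqrt(diff(p$x)[i]^2 + diff(p$y)[i]^2)
  })
  if (!by_cell) return(unlist(per_track, use.names = FALSE))
  cells <- vapply(trackset$tracks, `[[`, "", "cell_id")
  lapply(split(per_track, cells), function(l) unlist(l, use.names = FALSE))
}

#' Per-cell jump counts
#'
#' @param trackset A [track_set()].
#' @return Data frame with columns `cell_id`, `n_tracks`, `n_jumps`.
#' @export
jump_counts <- function(trackset) {
  jl <- extract_jumps(trackset, by_cell = TRUE)
  cells <- vapply(trackset$tracks, `[[`, "", "cell_id")
  data.frame(
    cell_id = names(jl),
    n_tracks = as.integer(table(cells)[names(jl)]),
    n_jumps = vapply(jl, length, integer(1)),
    row.names = NULL
  )
}
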