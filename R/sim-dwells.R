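#' Dwell-time set
#'
#' Durations of immobile binding events observed in the slow imaging
#' regime, as multiples of the frame interval, with a parallel censoring
#' flag (`TRUE` when the event was cut short by photobleaching, movie end
#' or track loss rather than observed unbinding).
#'
#' @param durations Numeric vector of dwell durations (s); each must be at
#'   least `min_duration` and an integer multiple of `frame_interval`.
#' @param censored Logical vector parallel to `durations`.
#' @param frame_interval Frame interval in seconds (default 0.5).
#' @param min_duration Shortest retainable dwell in seconds (default 2.5,
#'   i.e. 5 frames at 0.5 s).
#' @param movie_length Optional movie duration (s), used to sanity-check
#'   analysis windows.
#' @return An object of class `dwell_set`.
#' @export
dwell_set <- function(durations, censored = rep(FALSE, length(durations)),
                      frame_interval = 0.5, min_duration = 2.5,
                      movie_length = NULL) {
  if (length(durations) != length(censored)) {
    stop("durations and censored must have the same length", call. = FALSE)
  }
  if (any(durations < min_duration - 1e-9)) {
    stop("all durations must be >= min_duration (", min_duration, " s)",
         call. = FALSE)
  }
  k <- durations / frame_interval
  if (any(abs(k - round(k)) > 1e-6)) {
    stop("durations must be integer multiples of frame_interval",
         call. = FALSE)
  }
  structure(
    list(durations = as.numeric(durations), censored = as.logical(censored),
         frame_interval = frame_interval, min_duration = min_duration,
         movie_length = movie_length),
    class = "dwell_set"
  )
}

#' @export
print.dwell_set <- function(x, ...) {
  cat(sprintf(
    "dwell_set: %d dwells (%.1f%% censored), frame %g s, min duration %g s\n",
    length(x$durations), 100 * mean(x$censored), x$frame_interval,
    x$min_duration))
  invisible(x)
}

# draw dwell times from a mixture of exponentials; rate 0 => never unbinds
.rmixexp <- function(n, weights, rates) {
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  r <- rates[comp]
  t <- rep(Inf, n)
  pos <- r > 0
  t[pos] <- stats::rexp(sum(pos), r[pos])
  t
}

#' Simulate observed dwell times from a slow-regime movie
#'
#' Each molecule draws a true bound time from the configured exponential
#' mixture, a photobleaching time from `Exp(k_bleach)`, and a binding start
#' time uniform over the movie; the observed dwell is the minimum of the
#' three competing horizons, discretized to whole frames
#' (`duration = n_frames * frame_interval`). Molecules observed for fewer
#' than `min_frames` frames are dropped. The censoring flag is set when
#' bleaching or the movie end (not unbinding) terminated the observation.
#'
#' @param cfg A [slow_movie_config()].
#' @param n_molecules Number of molecules to attempt (>= 1); fewer are
#'   retained after the minimum-frames cut.
#' @param seed Integer seed.
#' @return A [dwell_set()] with a `ground_truth` attribute recording the
#'   configuration, seed and attempted molecule count.
#' @export
simulate_slow_movie_dwells <- function(cfg, n_molecules, seed) {
  stopifnot(inherits(cfg, "slow_movie_config"))
  n_molecules <- as.integer(n_molecules)
  if (n_molecules < 1L) stop("n_molecules must be >= 1", call. = FALSE)
  res <- withr::with_seed(as.integer(seed), {
    T_true <- .rmixexp(n_molecules, cfg$k_off_weights, cfg$k_off_rates)
    B <- if (cfg$k_bleach > 0) stats::rexp(n_molecules, cfg$k_bleach) else
      rep(Inf, n_molecules)
    start <- stats::runif(n_molecules, 0, cfg$movie_length)
    horizon <- cfg$movie_length - start
    obs <- pmin(T_true, B, horizon)
    list(obs = obs, censored = obs < T_true)
  })
  n_frames <- floor(res$obs / cfg$frame_interval)
  keep <- n_frames >= cfg$min_frames
  ds <- dwell_set(
    durations = n_frames[keep] * cfg$frame_interval,
    censored = res$censored[keep],
    frame_interval = cfg$frame_interval,
    min_duration = cfg$min_frames * cfg$frame_interval,
    movie_length = cfg$movie_length
  )
  attr(ds, "ground_truth") <- list(
    generator = "simulate_slow_movie_dwells", config = unclass(cfg),
    n_molecules = n_molecules, n_retained = sum(keep),
    seed = as.integer(seed)
  )
  ds
}

#' Render dwells as slow-regime tracks
#'
#' Builds a synthetic slow-movie track set in which each dwell becomes an
#' immobile track: one localization per frame, jittered by a small
#' localization error around a fixed position. Dwells whose unbinding was
#' observed (uncensored) are given two extra fast-diffusing frames after
#' the immobile stretch, so that [extract_dwells()] terminates the run at
#' the large jump and recovers both the duration and the censoring status.
#'
#' @param dwells A [dwell_set()].
#' @param seed Integer seed for positions and jitter.
#' @param sigma_loc Localization jitter per axis in um (default 0.02).
#' @param escape_jump Displacement (um) of the post-unbinding frames
#'   (default 1.0; must exceed the immobility radius used for extraction).
#' @param fov Field-of-view side in um (default 20).
#' @return A [track_set()] with regime `"slow"`.
#' @export
dwells_to_tracks <- function(dwells, seed, sigma_loc = 0.02,
                             escape_jump = 1.0, fov = 20) {
  stopifnot(inherits(dwells, "dwell_set"))
  n <- length(dwells$durations)
  m <- as.integer(round(dwells$durations / dwells$frame_interval))
  tracks <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(k) {
      L <- m[k]
      extra <- if (!dwells$censored[k]) 2L else 0L
      x0 <- stats::runif(1, 0, fov); y0 <- stats::runif(1, 0, fov)
      x <- x0 + stats::rnorm(L, 0, sigma_loc)
      y <- y0 + stats::rnorm(L, 0, sigma_loc)
      if (extra > 0L) {
        th <- stats::runif(extra, 0, 2 * pi)
        x <- c(x, x[L] + cumsum(escape_jump * cos(th)))
        y <- c(y, y[L] + cumsum(escape_jump * sin(th)))
      }
      list(cell_id = "sim", track_id = paste0("d", k),
           points = data.frame(frame = seq_len(L + extra) - 1L, x = x, y = y))
    })
  })
  track_set(tracks, dt = dwells$frame_interval, regime = "slow")
}
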