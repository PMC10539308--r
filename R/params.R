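#' Three-component diffusion parameter set
#'
#' Container for the parameters of the three-state displacement-distribution
#' model used throughout the fast-imaging analysis: three state fractions
#' `F1, F2, F3` (bound, slow, fast), three diffusion coefficients
#' `D1 < D2 < D3` in um^2/s, and the frame interval `dt` in seconds.
#' The same object is both the input of [simulate_jumps()] and the point
#' estimate returned by [fit_three_component()].
#'
#' @param fractions Numeric length-3 vector of state fractions. Must be
#'   non-negative and sum to 1 (tolerance 1e-9).
#' @param coeffs Numeric length-3 vector of diffusion coefficients (um^2/s),
#'   non-negative and strictly increasing.
#' @param dt Frame interval in seconds (default 0.01 s, i.e. 100 fps).
#'
#' @return An object of class `diffusion_params`.
#' @examples
#' wt <- diffusion_params(c(0.44, 0.34, 0.22), c(0.034, 0.46, 3.4), dt = 0.01)
#' wt
#' @export
diffusion_params <- function(fractions, coeffs, dt = 0.01) {
  if (length(fractions) != 3L || length(coeffs) != 3L) {
    stop("`fractions` and `coeffs` must each have length 3", call. = FALSE)
  }
  if (any(!is.finite(fractions)) || any(fractions < 0)) {
    stop("invalid diffusion_params: fractions must be finite and >= 0",
         call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("invalid diffusion_params: fractions must sum to 1 (got ",
         format(sum(fractions)), ")", call. = FALSE)
  }
  if (any(!is.finite(coeffs)) || any(coeffs < 0)) {
    stop("invalid diffusion_params: diffusion coefficients must be finite and >= 0",
         call. = FALSE)
  }
  if (is.unsorted(coeffs, strictly = TRUE)) {
    stop("invalid diffusion_params: coefficients must satisfy D1 < D2 < D3",
         call. = FALSE)
  }
  if (!is.finite(dt) || dt <= 0) {
    stop("invalid diffusion_params: dt must be > 0", call. = FALSE)
  }
  structure(
    list(fractions = as.numeric(fractions),
         coeffs = as.numeric(coeffs),
         dt = as.numeric(dt)),
    class = "diffusion_params"
  )
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat("Three-component diffusion parameters (dt =", x$dt, "s)\n")
  tab <- data.frame(
    state = c("bound", "slow", "fast"),
    fraction = round(x$fractions, 4),
    D_um2_s = x$coeffs
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Reference parameter fixtures for the fast-imaging analysis
#'
#' `wt_diffusion_fixture()` returns the wild-type MITF parameter set used as
#' simulation ground truth throughout the package: bound fraction 44% at
#' D1 = 0.034 um^2/s, slow fraction 34% at D2 = 0.46 um^2/s, and the
#' remaining 22% fast at D3 = 3.4 um^2/s, imaged at 10 ms frame intervals.
#' `halo_diffusion_fixture()` is the unconjugated-HaloTag control: a 13%
#' immobile fraction with the same diffusion coefficients (the non-bound
#' mass is assigned to the slow and fast states in the same 34:22 ratio as
#' the wild type).
#'
#' @return A [diffusion_params()] object.
#' @export
wt_diffusion_fixture <- function() {
  diffusion_params(c(0.44, 0.34, 0.22), c(0.034, 0.46, 3.4), dt = 0.01)
}

#' @rdname wt_diffusion_fixture
#' @export
halo_diffusion_fixture <- function() {
  rest <- 1 - 0.13
  diffusion_params(c(0.13, rest * 0.34 / 0.56, rest * 0.22 / 0.56),
                   c(0.034, 0.46, 3.4), dt = 0.01)
}

#' Slow-movie acquisition and kinetics configuration
#'
#' Parameters of the residence-time imaging regime: long-exposure movies at
#' 2 fps in which diffusing molecules are blurred out and only immobile ones
#' are tracked. Dwell times are drawn from a mixture of exponentials
#' (`k_off_components`), truncated by photobleaching at rate `k_bleach` and
#' by the end of the movie, and only immobile stretches of at least
#' `min_frames` frames are retained.
#'
#' @param frame_interval Frame interval in seconds (default 0.5 s, 2 fps).
#' @param movie_length Movie duration in seconds.
#' @param k_off_components List of `c(weight, rate)` pairs; weights must be
#'   non-negative and sum to 1, rates in 1/s (a rate of 0 means permanent
#'   binding).
#' @param k_bleach Photobleaching rate in 1/s.
#' @param min_frames Minimum number of frames for a dwell to be retained
#'   (default 5 frames, i.e. 2.5 s at the default frame interval).
#'
#' @return An object of class `slow_movie_config`.
#' @export
slow_movie_config <- function(frame_interval = 0.5,
                              movie_length = 600,
                              k_off_components = list(c(1, 0.02)),
                              k_bleach = 0.0316,
                              min_frames = 5L) {
  if (!is.finite(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be > 0", call. = FALSE)
  }
  w <- vapply(k_off_components, `[`, numeric(1), 1L)
  r <- vapply(k_off_components, `[`, numeric(1), 2L)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("k_off component weights must be >= 0 and sum to 1", call. = FALSE)
  }
  if (any(r < 0)) stop("k_off rates must be >= 0", call. = FALSE)
  if (!is.finite(k_bleach) || k_bleach < 0) {
    stop("k_bleach must be >= 0", call. = FALSE)
  }
  min_frames <- as.integer(min_frames)
  if (min_frames < 1L) stop("min_frames must be >= 1", call. = FALSE)
  if (movie_length < min_frames * frame_interval) {
    stop("movie_length shorter than min_frames * frame_interval",
         call. = FALSE)
  }
  structure(
    list(frame_interval = frame_interval, movie_length = movie_length,
         k_off_weights = w, k_off_rates = r, k_bleach = k_bleach,
         min_frames = min_frames),
    class = "slow_movie_config"
  )
}

#' H2B-like photobleaching control configuration
#'
#' Dwell-time configuration emulating the histone H2B control used to
#' estimate the photobleaching rate: a minority fast chromatin-exchange
#' component (weight 0.4 at 0.15 1/s) plus a majority stably incorporated
#' component whose apparent decay is photobleaching at 0.0316 1/s. The
#' bleaching rate is folded into the dwell mixture (and `k_bleach` set to 0)
#' because for stably bound H2B the observed decay *is* the bleaching.
#'
#' @param movie_length Movie duration in seconds (default 1000 s, long
#'   enough that movie-end truncation is negligible).
#' @return A [slow_movie_config()] object.
#' @export
h2b_dwell_fixture <- function(movie_length = 1000) {
  slow_movie_config(
    frame_interval = 0.5,
    movie_length = movie_length,
    k_off_components = list(c(0.4, 0.15), c(0.6, 0.0316)),
    k_bleach = 0,
    min_frames = 5L
  )
}

#' Fluorescein-labelled probe duplexes used in the anisotropy assay
#'
#' The three double-stranded DNA probes titrated in the binding assay,
#' named by the regulatory element class they carry: the palindromic
#' CLEAR-box (TCACGTGA), the TYR enhancer element (TCATGTGA) and the
#' promoter M-box (TCATGTGT). These sequences are shared with the motif
#' module, whose classifier assigns them to the TCACGTGA, TCATGTGA and
#' TCATGTGB classes respectively.
#'
#' @return Named character vector of probe top-strand sequences.
#' @export
probe_oligos <- function() {
  c(CLEAR = "GAGATCACGTGATGAC",
    TYR   = "GAGATCATGTGATGAC",
    MBOX  = "GAGATCATGTGTTGAC")
}
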