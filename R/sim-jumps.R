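#' Simulate single-frame displacement magnitudes from the three-state model
#'
#' Draws jump magnitudes from the mixture model underlying the fast-imaging
#' analysis: each jump picks a diffusive state i with probability `F_i`, then
#' a 2-D Brownian displacement with per-axis variance `2 * D_i * dt`, so the
#' magnitude is Rayleigh with scale `sqrt(2 * D_i * dt)`. An optional static
#' localization error can be added per axis for robustness studies; by
#' default none is added, matching the noise-free displacement model.
#'
#' @param params A [diffusion_params()] object (ground truth).
#' @param n_jumps Number of jumps to draw (>= 1).
#' @param seed Integer seed; the same seed gives bit-identical output.
#' @param sigma_loc Per-axis Gaussian localization error in um (default 0).
#'   When positive, each endpoint of the jump receives independent noise, so
#'   the per-axis displacement variance becomes `2 * D_i * dt + 2 * sigma_loc^2`.
#'
#' @return Numeric vector of `n_jumps` displacement magnitudes in um.
#' @seealso [jump_cdf()] for the closed-form magnitude distribution,
#'   [simulate_tracks()] for full trajectories.
#' @examples
#' r <- simulate_jumps(wt_diffusion_fixture(), 1000, seed = 1)
#' mean(r < 0.1)  # ~0.60 for the wild-type fixture
#' @export
simulate_jumps <- function(params, n_jumps, seed, sigma_loc = 0) {
  stopifnot(inherits(params, "diffusion_params"))
  n_jumps <- as.integer(n_jumps)
  if (n_jumps < 1L) stop("n_jumps must be >= 1", call. = FALSE)
  if (sigma_loc < 0) stop("sigma_loc must be >= 0", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    comp <- sample.int(3L, n_jumps, replace = TRUE, prob = params$fractions)
    s2 <- 2 * params$coeffs[comp] * params$dt + 2 * sigma_loc^2
    dx <- stats::rnorm(n_jumps, 0, sqrt(s2))
    dy <- stats::rnorm(n_jumps, 0, sqrt(s2))
    sqrt(dx^2 + dy^2)
  })
}

#' Closed-form CDF of jump magnitudes under the three-state model
#'
#' For a mixture of 2-D Brownian states the magnitude CDF is
#' `sum_i F_i * (1 - exp(-r^2 / (4 * D_i * dt)))`; a state with `D_i = 0`
#' contributes a point mass at r = 0.
#'
#' @param params A [diffusion_params()] object.
#' @param r Vector of magnitudes (um).
#' @return `P(jump <= r)` for each element of `r`.
#' @export
jump_cdf <- function(params, r) {
  stopifnot(inherits(params, "diffusion_params"))
  out <- numeric(length(r))
  for (i in 1:3) {
    v <- 4 * params$coeffs[i] * params$dt
    ci <- if (v > 0) 1 - exp(-r^2 / v) else as.numeric(r >= 0)
    out <- out + params$fractions[i] * ci
  }
  out
}

#' Simulate fast-regime single-molecule trajectories
#'
#' Generates 2-D Brownian tracks for the fast imaging regime. Each track
#' (molecule) is assigned one diffusive state for its whole lifetime, drawn
#' with probabilities `F_i`; with equal track lengths the pooled jumps then
#' follow the same mixture as [simulate_jumps()]. Track lengths are drawn
#' from a geometric survival per frame (`p_survive`), truncated to
#' `[2, max_len]` frames, emulating bleaching-limited fast tracks.
#'
#' @param params A [diffusion_params()] object.
#' @param n_tracks Number of tracks.
#' @param seed Integer seed.
#' @param p_survive Per-frame survival probability of the fluorophore
#'   (default 0.85). Set to 1 for fixed-length tracks of `max_len` frames.
#' @param max_len Maximum track length in frames (default 20).
#' @param cell_id Cell label attached to all tracks (default "cell1").
#' @param sigma_loc Per-axis localization error in um (default 0).
#' @param fov Side of the square field of view in um within which track
#'   origins are placed uniformly (default 20 um).
#'
#' @return A `track_set` (see [track_set()]) with regime `"fast"`, carrying
#'   a `ground_truth` attribute recording every generator parameter.
#' @export
simulate_tracks <- function(params, n_tracks, seed, p_survive = 0.85,
                            max_len = 20L, cell_id = "cell1",
                            sigma_loc = 0, fov = 20) {
  stopifnot(inherits(params, "diffusion_params"))
  n_tracks <- as.integer(n_tracks)
  if (n_tracks < 1L) stop("n_tracks must be >= 1", call. = FALSE)
  tracks <- withr::with_seed(as.integer(seed), {
    comp <- sample.int(3L, n_tracks, replace = TRUE, prob = params$fractions)
    lens <- if (p_survive >= 1) rep(as.integer(max_len), n_tracks) else {
      pmin(2L + stats::rgeom(n_tracks, 1 - p_survive), as.integer(max_len))
    }
    lapply(seq_len(n_tracks), function(k) {
      L <- lens[k]
      sd_step <- sqrt(2 * params$coeffs[comp[k]] * params$dt)
      x <- stats::runif(1, 0, fov) + cumsum(c(0, stats::rnorm(L - 1, 0, sd_step)))
      y <- stats::runif(1, 0, fov) + cumsum(c(0, stats::rnorm(L - 1, 0, sd_step)))
      if (sigma_loc > 0) {
        x <- x + stats::rnorm(L, 0, sigma_loc)
        y <- y + stats::rnorm(L, 0, sigma_loc)
      }
      list(cell_id = cell_id, track_id = paste0("t", k),
           points = data.frame(frame = seq_len(L) - 1L, x = x, y = y))
    })
  })
  ts <- track_set(tracks, dt = params$dt, regime = "fast")
  attr(ts, "ground_truth") <- list(
    generator = "simulate_tracks", params = unclass(params),
    n_tracks = n_tracks, seed = as.integer(seed), p_survive = p_survive,
    max_len = as.integer(max_len), sigma_loc = sigma_loc, fov = fov
  )
  ts
}
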