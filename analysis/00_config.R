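# Shared study configuration for the analysis stages (01-05).
#
# All synthetic inputs are rebuilt deterministically from the seeds below,
# so every stage can regenerate exactly what stage 01 recorded in the run
# manifest instead of passing bulky intermediates around.

library(mitfkinetics)

SEED <- 20260101L

# fast-regime conditions: per-cell track sets (ground-truth parameters)
fast_conditions <- function() {
  list(
    WT = wt_diffusion_fixture(),
    mutantQ = diffusion_params(c(0.36, 0.38, 0.26), c(0.034, 0.46, 3.4)),
    halo = halo_diffusion_fixture()
  )
}

N_CELLS <- 8L
N_TRACKS_PER_CELL <- 2500L

fast_tracksets <- function() {
  conds <- fast_conditions()
  out <- list()
  for (ci in seq_along(conds)) {
    cond <- names(conds)[ci]
    out[[cond]] <- lapply(1:N_CELLS, function(cell) {
      simulate_tracks(conds[[cond]], n_tracks = N_TRACKS_PER_CELL,
                      seed = SEED + 1000L * ci + 13L * cell,
                      cell_id = sprintf("%s_cell%02d", cond, cell))
    })
  }
  out
}

# slow-regime conditions: dwell mixtures (short-lived scanning + stable
# binding) under a common bleaching rate, plus the H2B bleaching control
slow_configs <- function() {
  list(
    WT = slow_movie_config(movie_length = 1200,
                           k_off_components = list(c(0.6, 0.1),
                                                   c(0.4, 0.005)),
                           k_bleach = 0.0316),
    mutantQ = slow_movie_config(movie_length = 1200,
                                k_off_components = list(c(0.7, 0.1),
                                                        c(0.3, 0.009)),
                                k_bleach = 0.0316),
    h2b = h2b_dwell_fixture(movie_length = 1200)
  )
}

N_MOLECULES_SLOW <- 2e4

slow_dwellsets <- function() {
  cfgs <- slow_configs()
  out <- list()
  for (ci in seq_along(cfgs)) {
    out[[names(cfgs)[ci]]] <-
      simulate_slow_movie_dwells(cfgs[[ci]], N_MOLECULES_SLOW,
                                 seed = SEED + 50L + ci)
  }
  out
}

# anisotropy: three probes at distinct ground-truth affinities (nM)
PROBE_KDS <- c(CLEAR = 20, TYR = 60, MBOX = 250)
TITRATION_GRID <- c(0, 2, 5, 10, 20, 35, 50, 75, 100, 200, 400, 800, 1600)

titrations <- function() {
  out <- list()
  for (pi in seq_along(PROBE_KDS)) {
    p <- names(PROBE_KDS)[pi]
    out[[p]] <- simulate_titration(PROBE_KDS[[p]], b0 = 0.05, bmax = 0.2,
                                   c = 1.33, x_grid = TITRATION_GRID,
                                   noise_sd = 0.002, seed = SEED + 80L + pi,
                                   probe_id = p)
  }
  out
}

# motif: three "conditions" emulating a dose-dependent shift away from the
# canonical class, plus one mutant-like set that stays canonical
PEAK_MIXES <- list(
  WT_low  = c(TCACGTGA = 0.60, TCACGTGB = 0.15, TCATGTGA = 0.10,
              TCATGTGB = 0.05, none = 0.10),
  WT_high = c(TCACGTGA = 0.40, TCACGTGB = 0.22, TCATGTGA = 0.22,
              TCATGTGB = 0.06, none = 0.10),
  mutantQ = c(TCACGTGA = 0.72, TCACGTGB = 0.10, TCATGTGA = 0.04,
              TCATGTGB = 0.04, none = 0.10)
)
N_PEAKS <- 2000L

peaksets <- function() {
  out <- list()
  for (mi in seq_along(PEAK_MIXES)) {
    out[[names(PEAK_MIXES)[mi]]] <-
      simulate_peakset(N_PEAKS, PEAK_MIXES[[mi]], seed = SEED + 90L + mi)
  }
  out
}
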