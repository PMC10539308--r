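# mitfkinetics

Quantitative analysis of transcription-factor chromatin-binding kinetics
and DNA-binding specificity, built around the MITF acetylation system.
The package is aimed at single-molecule imaging and protein–DNA binding
labs that need the full arithmetic behind four common readouts — bound
fractions, residence times, dissociation constants and motif-class
shifts — as tested, reusable functions rather than one-off notebook code.
Every analysis has a matched synthetic-data generator with recorded
ground truth, so the whole pipeline can be validated end to end on data
whose correct answer is known.

## What it computes

**Fast-regime tracking (100 fps).** Single-frame displacement magnitudes
are histogrammed (Δr = 20 nm) and fit with a three-component 2-D
diffusion mixture,

    p(r) = r Δr Σᵢ Fᵢ / (2 Dᵢ Δt) · exp(−r² / (4 Dᵢ Δt)),   i = 1..3,

giving the chromatin-bound fraction F₁ (slowest state), a slow
transiently interacting state and free diffusion, with per-cell fits
compared across conditions by Kruskal–Wallis.

**Slow-regime tracking (2 fps, long exposure).** Immobile-segment dwell
times populate a survival curve S(t) = P(duration ≥ t) starting at 2.5 s
(5 frames). The photobleaching rate k_b is the slowest component of a
two-exponential fit to an H2B control; dividing S(t) by exp(−k_b t) and
renormalizing yields the corrected residence-time distribution, which is
summarized by the restricted mean survival time ∫ S(t) dt over
[2.5, 100] s and by S(100), with errors from 1000 delete-half resamples.

**Anisotropy titrations.** Binding of a labelled probe (C = 1.33 nM) is
fit with the ligand-depletion quadratic isotherm

    y = B₀ + (Bmax − B₀) · (C + x + K_D − √((C + x + K_D)² − 4Cx)) / (2C),

per replicate, reporting mean ± sd of the replicate K_D values and
pairwise affinity ratios with t-tests.

**E-box motif classes.** Peak sequences are scanned on both strands for
CACGTG/CATGTG cores and classified into extended-E-box classes
(TCACGTGA, TCACGTGB, TCATGTGA, TCATGTGB, CACGTG_other, CATGTG_other,
none; B = C/G/T), with per-condition class ratios and score-ranked
moving-average incidence (100-peak window).

## Worked example

```r
library(mitfkinetics)

# simulate 2e5 displacement magnitudes from the wild-type fixture and
# recover its parameters from the binned displacement distribution
wt <- wt_diffusion_fixture()          # F = (0.44, 0.34, 0.22), D = (0.034, 0.46, 3.4)
jumps <- simulate_jumps(wt, 2e5, seed = 101)
fit_three_component(jump_histogram(jumps, bin_width = 0.02, dt = 0.01))
#> diffusion_fit (cell NA, 200000 jumps, sse = 5.19e-06, converged = TRUE)
#> Three-component diffusion parameters (dt = 0.01 s)
#>  state fraction    D_um2_s
#>  bound   0.4321 0.03600245
#>   slow   0.3447 0.47838936
#>   fast   0.2231 3.63382436
```

The fitted bound fraction (43.2%) and coefficients land within a few
percent of the generating values: that recovery accuracy, at this sample
size, is what the acceptance checks quantify.

```r
# photobleaching rate from an H2B-like control (truth: 0.0316 1/s)
h2b <- simulate_slow_movie_dwells(h2b_dwell_fixture(), 5e4, seed = 7)
estimate_bleach_rate(h2b)$k_b
#> [1] 0.0322

# dissociation constant from noisy triplicate titrations (truth: 50 nM)
xg <- c(0, 2, 5, 10, 20, 35, 50, 75, 100, 200, 400, 800)
tit <- simulate_titration(50, b0 = 0.05, bmax = 0.2, c = 1.33,
                          x_grid = xg, noise_sd = 0.002, seed = 11)
fit_kd(tit)
#> kd_fit: KD = 49.3 +/- 2.75 nM (3 replicate(s)), b0 = 0.04883, bmax = 0.1991

# the three assay probe duplexes classify to their named element classes
classify_ebox(probe_oligos())
#>      class position strand
#> 1 TCACGTGA        6      +
#> 2 TCATGTGA        6      +
#> 3 TCATGTGB        6      +
```

## Analysis workflow

The numbered drivers under `analysis/` run the full study-style workflow
on synthetic data and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates all inputs, writes the ground-truth run manifest |
| `02_fit_diffusion.R` | per-cell three-component fits + Kruskal–Wallis comparison |
| `03_residence.R` | bleach rate from H2B, corrected survival, RMST summaries |
| `04_anisotropy.R` | per-probe K_D fits and affinity ratios |
| `05_motif.R` | E-box class ratios and score-vs-incidence tables |

Run them from the repository root, e.g.
`Rscript analysis/01_simulate.R && Rscript analysis/02_fit_diffusion.R`.
All stages rebuild their inputs deterministically from the seeds in
`analysis/00_config.R`.

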