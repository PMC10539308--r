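---
title: "Models and methods: single-molecule kinetics, binding isotherms and E-box classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the quantitative methods it
implements: what each model assumes, which parameters matter and why their
defaults are what they are, what the synthetic-data generators do and do
not emulate, and where numerically consequential choices were made.

## The system

MITF is a bHLH-LZ transcription factor whose DNA binding is regulated by
acetylation of a lysine in its basic region. The package implements the
four quantitative analyses used to characterize that regulation: (i)
fast-framerate single-molecule tracking (100 fps) analyzed through
displacement distributions to estimate the chromatin-bound fraction and
diffusion coefficients; (ii) slow-framerate tracking (2 fps, long
exposure) analyzed through residence-time survival curves with
photobleaching correction; (iii) fluorescence-anisotropy titrations of
labelled DNA probes analyzed with a ligand-depletion (quadratic) binding
isotherm; and (iv) classification of extended E-box motif classes under
ChIP peaks. Each analysis has a matched generator with recorded ground
truth, so the full pipeline is exercised end to end on data whose correct
answer is known.

## Fast regime: three-component displacement model

Single-frame displacement magnitudes $r$ are modelled as a mixture of
three 2-D Brownian states. The probability of observing a displacement in
a histogram bin of width $\Delta r$ centered at $r$ is

$$p(r) = r\,\Delta r \sum_{i=1}^{3} \frac{F_i}{2 D_i \Delta t}
  \exp\!\left(-\frac{r^2}{4 D_i \Delta t}\right),$$

with fractions $F_i$ summing to one, diffusion coefficients
$D_1 < D_2 < D_3$ and frame interval $\Delta t$. The slowest state is
interpreted as chromatin-bound ($F_1$ = bound fraction); the middle state
as transiently interacting ("slow"); the fastest as free diffusion.
Defaults follow the experimental regime: $\Delta t = 10$ ms,
$\Delta r = 20$ nm, histogram range 1.5 um (displacements beyond it are
tallied as overflow; at the fixture parameters the truncated mass is
below $10^{-6}$).

Fitting minimizes the sum of squared differences between the empirical
bin fractions and $p(r)$ — the histogram-domain objective, matching how
such data are fit in practice. Choices that matter:

* **Parameterization.** Fractions are stick-broken onto the simplex and
  coefficients fitted on the log scale inside box bounds
  ($D_1 \in [10^{-3}, 0.1]$, $D_2 \in [0.05, 2]$,
  $D_3 \in [0.5, 20]$ um²/s), so every iterate is a valid parameter set
  and the three states cannot swap roles silently. Reported components
  are sorted by coefficient.
* **Multi-start.** L-BFGS-B is run from 8 starts on a log-spaced
  coefficient grid (plus any user initialization); the lowest residual
  wins, ties broken toward the smaller $D_1$. The fit-permutation test in
  the suite confirms the optimum does not depend on where the search
  began.
* **$D_1$ free by default.** The slowest coefficient can be pinned
  (`fix_d1 = 0.034`) for protocols that treat it as a calibrated
  constant, but the default fits it, since per-cell estimates of the
  bound-state coefficient are themselves informative.
* **Bin-center rule.** $p(r)$ is evaluated at bin centers, not
  integrated over bins. This reproduces the model as used on real data
  but carries a small convexity bias (about 0.01 of cumulative mass at
  0.1 um for the wild-type fixture); the simulator tests therefore
  compare against exact closed-form bin masses, while fit-recovery tests
  accept the bias inside their 10% bands.

Per-cell fits are primary; pooling cells is an explicit separate mode.
Cross-condition comparison uses the Kruskal-Wallis rank test per
statistic, with medians and quartiles reported per condition.

The wild-type fixture is $F = (0.44, 0.34, 0.22)$,
$D = (0.034, 0.46, 3.4)$ um²/s; the HaloTag control fixture keeps the
same coefficients with a 13% bound fraction, the remaining mass split
between slow and fast in the wild-type 34:22 ratio (only the bound
fraction of this control is ever asserted; the split is a convention).

## Slow regime: residence times and photobleaching

In long-exposure movies diffusing molecules blur out and only immobile
ones are tracked. Dwells are maximal runs of consecutive frames whose
inter-frame displacement stays below `r_immobile` (default 0.2 um);
duration is `n_frames * frame_interval`, so 5 frames at 0.5 s is 2.5 s,
the shortest retained dwell. The kymograph-based segment calling used on
real movies is not an explicit algorithm, so this displacement-threshold
criterion is the package's documented substitute; the threshold is
configurable and the generator round-trip test pins its behavior.

The survival curve is the empirical $1-\mathrm{CDF}$,
$S(t) = P(\text{duration} \ge t)$, normalized to 1 at 2.5 s. Censored
events (track or movie end) are included as observed durations by
default — the raw track-duration curve — with exclusion and Kaplan-Meier
weighting available as options.

Disappearance confounds unbinding with photobleaching. The bleaching
rate $k_b$ is estimated from an H2B control: stably incorporated histone
does not unbind on the experimental timescale, so after fitting its
survival with a two-exponential decay (non-negative weights and rates,
components with weight below $10^{-3}$ discarded as artifacts, slowest
surviving rate taken), the slow rate is bleaching. The fit is plain least
squares on the frame-grid survival so each half-second plateau
contributes one residual; a warning flags component rates separated by
less than 3-fold, where the decomposition is weakly identifiable. The
correction divides by $e^{-k_b t}$ in absolute time and renormalizes at
2.5 s (the offset form differs only by that constant).

Summary statistics are the restricted mean survival time — the
trapezoidal integral of $S$ over $[2.5, 100]$ s, hence at most 97.5 s —
and the fraction of events outliving 100 s, $S(100)$. Error bars are the
standard deviations of each statistic over 1000 delete-half replicates
(drop a random 50% of dwells, rebuild the curve, re-apply the same
$k_b$, recompute); no SEM rescaling is applied, since the delete-half
spread is itself the reported uncertainty.

The dwell generator draws true bound times from a mixture of
exponentials, bleaching times from $\mathrm{Exp}(k_b)$, uniform binding
start times, and observes the minimum of the three horizons discretized
to whole frames. A mixture of exponentials is a modelling choice for
testing — real dwell distributions need not be multi-exponential. Two
consequences the generator exposes deliberately: observed single-rate
decays have apparent rate $k_{\mathrm{off}} + k_b$ (competing risks), and
uniform start times leave a $(1 - t/L)$ movie-end deficit that the bleach
correction does not remove, which is why end-to-end recovery tests use
movies much longer than the analysis window. The H2B fixture folds
bleaching into the dwell mixture (weight 0.4 at 0.15 1/s exchange plus
weight 0.6 at 0.0316 1/s bleaching) — equivalent to bleaching acting on a
never-unbinding molecule.

## Anisotropy: quadratic binding isotherm

With probe concentration $C$ (1.33 nM in the assay) comparable to the
dissociation constant, free and total protein differ, so the hyperbolic
isotherm is replaced by the exact (ligand-depletion) solution

$$y = B_0 + (B_{\max} - B_0)\,
  \frac{C + x + K_D - \sqrt{(C + x + K_D)^2 - 4 C x}}{2C}.$$

The discriminant is mathematically non-negative and clamped at zero
against floating-point error. $K_D$, $B_0$ and $B_{\max}$ are all fitted
(bounded so $B_{\max} > B_0$); initialization takes $K_{D,0}$ as the
concentration at half-maximal signal, $B_{0,0} = \min y$,
$B_{\max,0} = \max y$. Replicates are fitted independently and the
reported $K_D$ is the replicate mean with its standard deviation —
matching an assay analyzed as independent triplicates — with a pooled
joint fit available. Baseline subtraction (free-probe anisotropy)
happens before fitting; the raw-plus-baseline input path performs it
internally. Condition comparisons use unpaired two-tailed t-tests on
replicate $K_D$s by default; a per-concentration point-level test is
provided as the alternative mode, since either reading of "significance
per measurement point" is defensible.

## E-box motif classes

Peak sequences are scanned on both strands for the CACGTG and CATGTG
6-mer cores; each occurrence is extended by its 5' and 3' flanking bases
on its own strand and assigned to one of seven classes in priority
order: `TCACGTGA` (CLEAR-box), `TCACGTGB`, `TCATGTGA` (TYR-type),
`TCATGTGB` (includes the TCATGTGT M-box), `CACGTG_other`,
`CATGTG_other`, `none` (B = C/G/T). A peak's class is the
highest-priority occurrence; ties break to the leftmost plus-strand
position (the comparison is logical, not locale-dependent character
sort). Cores at sequence edges lacking a flank fall to their `_other`
class, and `N` never matches a core or a flank. The seven-class scheme
is this package's interpretation covering every extended E-box named in
the melanocyte literature; classification is provably strand-symmetric,
which the suite checks on random sequences.

The ratio analysis reports per-condition class proportions (summing to
one); the incidence analysis sorts peaks by descending score and takes a
centered 100-peak moving average of the class-membership indicator,
truncating the window at the edges.

The peak generator plants exactly one 8-mer of the drawn class into a
GC-0.41 background guaranteed core-free on both strands (candidates with
spurious cores from the background or the planting junction are
resampled, and a read-back through the classifier is required), on a
random strand, with class-conditional Gaussian scores. Zero
planted-vs-assigned confusion is therefore a generator guarantee, which
is what makes proportion-recovery tests exact binomial checks.

## Problem sizes and determinism

Every generator takes an explicit integer seed and is bit-reproducible;
ground truths round-trip through a JSON run manifest. The test suite and
the reproduction script use the scales at which the recovery properties
were calibrated: $2\times10^5$ jumps for displacement-fit recovery
(10% relative bands), $10^5$ molecules for the bleaching-rate fit
(10% band), $2\times10^4$–$5\times10^4$ molecules for survival
round-trips, 2000 peaks for proportion recovery ($3\sigma$ binomial
bands). The analysis drivers under `analysis/` use 8 cells per condition
at ~2500 tracks each, 20 000 molecules per dwell condition and 2000
peaks per peak set.

## What passing tests do and do not show

The generators emulate the statistical structure the analyses assume:
Rayleigh-mixture displacements, exponential-mixture dwells censored by
bleaching and movie end, Gaussian-noise titrations, peaks with exactly
one planted motif. They do not emulate localization error beyond an
optional Gaussian term (off by default, as the displacement model has no
noise term), defocalization or z-escape, motion blur of the 200 ms
exposures, state switching within a track, non-exponential dwell
families, pipetting or plate-position effects in titrations, or
composition-realistic regulatory sequence. Recovery on these fixtures
therefore validates the estimators against their own model assumptions —
it does not certify accuracy on real microscopy data, where those
unmodelled effects bias $D_1$, the bound fraction and long residence
times in known directions.
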