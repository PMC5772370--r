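---
title: "Particle concentration as a structural and stability probe for colloids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle concentration as a structural and stability probe for colloids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanocount)
library(dplyr)
```

## The model

Size distribution is the conventional stability readout for pharmaceutical
colloids, but it misses an entire class of failure: a particle population can
thin out (degradation, erosion, disruption) with little or no size shift.
Nanoparticle tracking analysis (NTA) adds the missing observable — the
absolute particle concentration $C_p$ (particles/mL) — and with it two
quantities this package is built around.

**Per-particle stoichiometry.** A formulation with excipient molarity $c$
(mol/L) contains $N = c \, N_A / 1000$ molecules per mL. If NTA counts
$C_p$ particles/mL, each particle contains on average

$$ n = \frac{N}{C_p} $$

excipient molecules, and the suspension has particle molarity
$C_p \times 1000 / N_A$. Because the excipient amount is fixed, $n \cdot C_p$
must equal $N$ in every condition of a destabilisation series — the
*conservation audit* (`conservation_audit()`), which doubles as an
internal-consistency check on any reported data table.

**Geometric cross-check (vesicles).** A unilamellar vesicle of diameter $d$
carries lipid only in its shell: two monolayers of area $4\pi(d/2)^2$ each,
divided by the headgroup area $a$ (55 Å$^2$ for phosphatidylcholine) gives

$$ n_{\text{geo}}(d) = \frac{2 \cdot 4\pi (d/2)^2}{a}, $$

implemented in `theoretical_molecules_per_vesicle()`. For a 162.5 nm vesicle
this yields $3.0\times 10^5$ lipids, within 10% of the tracking-derived
value, and predicts $N / n_{\text{geo}} \approx 2.5\times10^{11}$
particles/mL for a 0.125 mM suspension — the convergence point of measured
and predicted counts for a fully extruded monodisperse preparation.

**The stability statistic.** Growth-type destabilisation (fusion,
agglutination, Ostwald ripening) produces fewer, larger particles, so size
and concentration are strongly negatively correlated across a
destabilisation series; `stability_correlation()` computes the Pearson r
over per-condition means (replicate-level values are rarely published, so
$n$ is the number of conditions; a t-based p-value is available behind
`p_value = TRUE` but warned against at these tiny $n$).
`classify_instability()` turns the two relative changes into a verdict:
concentration drop *with* size growth is `aggregation_or_fusion`;
concentration drop *without* it is `degradation` — the early-warning
signature that motivates monitoring concentration at all. Both thresholds
default to 10% (no published convention exists; they are strict
inequalities, so an exactly-threshold change stays in the milder class) and
are user-settable.

## Dispersity metrics

NTA is number-weighted; dynamic light scattering (DLS) is
intensity-weighted. The package keeps both views explicit:

* `weighted_percentiles()` / `span()`: number-weighted D10/D50/D90 and
  Span $=(D_{90}-D_{10})/D_{50}$. The Span formula is the standard one for
  number-based tracking data. Percentiles interpolate linearly between
  order statistics with midpoint plotting positions; integer count weights
  behave exactly like repeated particles, and ties keep stable order.
* `intensity_weights()`: Rayleigh $d^6$ weights. This is applied at *all*
  sizes, including micron-scale aggregates where Mie scattering would be
  correct; the $d^6$ proxy keeps the model analytic and preserves the
  qualitative large-particle bias, but absolute z-averages for
  micron-sized particles should not be over-interpreted.
* `z_average_and_pdi()`: z-average $\sum n d^6 / \sum n d^5$ and cumulant
  PDI $\mu_2/\bar\Gamma^2$, computed from moments of the decay-rate
  distribution ($\Gamma \propto 1/d$, intensity-weighted) rather than by
  fitting a simulated correlogram — deterministic, and exact in the
  no-noise limit. PDI and Span are scale-invariant; the intensity-weighted
  mean never falls below the number-weighted mean, with equality only for
  monodisperse samples.
* `classify_dispersity()`: monodisperse iff PDI < 0.2 **and** Span < 1, the
  conventional thresholds.

## The synthetic colloid generator

`make_population()` draws explicit per-particle diameter lists from
lognormal mixtures (geometric SD 1 collapses a mode to its median — handy
for exact fixtures). Explicit lists are practical up to ~10^6 particles,
which covers every scale used here; the transforms below are written
against the list representation.

The three destabilisation transforms conserve the excipient exactly
(relative drift $<10^{-6}$, verified in tests):

* **`extrude()`** (vesicles, area-conserving): a vesicle with $d$ above the
  pore fragments into $\lceil d^2/p^2 \rceil$ daughters drawn around the
  pore size with 10% geometric jitter and rescaled so daughter area sums to
  the parent's. Each oversize vesicle fragments on a given passage only
  with probability `fragmentation_prob` (default 0.5): not every vesicle
  meets a pore on each pass, which is exactly why six consecutive passages
  are used in practice, and it is this partial per-pass conversion that
  makes mean size, Span and particle count converge gradually and
  monotonically over the passage series instead of collapsing in one step.
  Setting `fragmentation_prob = 1` and `jitter_gsd = 1` recovers the
  idealised equal-daughter rule (one 300 nm vesicle, 100 nm pore, gives
  exactly nine 100 nm daughters).
* **`fuse()`** (vesicles, area-conserving): per round, a chosen fraction of
  disjoint random pairs merges with $d = \sqrt{d_1^2+d_2^2}$ — the
  solvent-type destabilisation of bilayers, where partial solubilisation of
  acyl chains drives vesicle fusion.
* **`aggregate_particles()`** (solid particles, volume-conserving):
  surfactant coverage is expressed relative to a fully stabilising level
  (for the poloxamer series, 5% maps to coverage 1.0); merge propensity is
  $p = 1 - f^\gamma$ ($\gamma = 2$ by default, penalising low coverage
  super-linearly), realised as coalescence into an expected $n(1-p)$
  random clusters with $d = (\sum d^3)^{1/3}$. Cluster coalescence rather
  than single pairwise merging is deliberate: observed agglutination
  series span factor-300 drops in particle count, far beyond what one
  pairwise round can produce. The $\gamma$ default is illustrative, not
  fitted to any particular surfactant.

Vesicle area conservation means $\sum d^2$ (lipid lives in the shell);
solid volume conservation means $\sum d^3$ (excipient fills the core). A
corollary used throughout the tests: mean molecules-per-particle times
particle count is invariant under `fuse()` and `extrude()` — the simulation
analogue of the conservation audit.

All transforms are deterministic given `seed`; different seeds give
statistically equivalent summaries (checked at 3-SE level in tests).

## Instrument forward models

**NTA (`simulate_tracks()` + `estimate_from_tracks()`).** Track-level, not
image-level: the number of particles resident in the observation volume is
Poisson with mean (diluted concentration × sampling volume); over a video
of $F$ frames, particles enter and leave so the number of distinct tracks
is Poisson with mean residents $\times F/L$, where $L$ is the mean
(geometric) track length. Each track carries per-axis Gaussian steps of
variance $2D\Delta t$ with $D = k_BT/(3\pi\eta d)$. Sizing uses the lag-1
MSD estimator $\hat D = \sum(\Delta x^2+\Delta y^2)/(4 n \Delta t)$ per
track — chosen over covariance estimators for transparency, and swappable.
No finite-track-length bias correction is applied: at the default 30-frame
mean length the $1/\hat D$ inversion bias is ~3%, inside the 5% recovery
band the tests enforce. Localisation noise is off by default (no imaging
parameters are modelled). Concentration is mean particles visible per
frame ÷ sampling volume × dilution; it is unbiased (checked over 50 seeds)
and its counting scatter corresponds to Poisson statistics on the number
of distinct tracks.

Defaults: 25 °C water ($T = 298.15$ K, $\eta = 8.9\times10^{-4}$ Pa·s),
30 fps, 30-frame mean tracks with a 10-frame filter, $10^{-7}$ mL
observation volume — so typical working concentrations at instrument-style
dilutions (200× for liposomes, larger for concentrated solid
nanoparticles) put tens to hundreds of particles in view and a 128-frame
video yields roughly the two thousand tracks a real measurement counts.

**DLS (`simulate_dls()`).** The deterministic `z_average_and_pdi()` of the
population, optionally with independent multiplicative Gaussian noise on
each reported quantity; `noise_sd = 0` is exact, which the tests use as an
oracle. For any polydisperse population the DLS z-average strictly exceeds
the NTA-style number mean — the $d^6$-weighting contrast that explains why
the two instruments disagree on heterogeneous samples and agree after full
extrusion.

## What the generator does and does not emulate

It reproduces the *structure* the analysis relies on: lognormal (possibly
multimodal) sizes, excipient-conserving fragmentation/fusion/aggregation,
number- vs intensity-weighted measurement, counting statistics, and
MSD-estimator scatter. It does not emulate multilamellarity (all vesicles
are treated as unilamellar shells; no inner-leaflet radius offset or
bilayer-thickness correction), Mie scattering, video-level tracking
artefacts (drift, blinking, mislinking), vibration or operator effects.
Passing tests therefore demonstrate the pipeline's correctness and the
qualitative instrument physics, not instrument-grade accuracy on real
formulations; measured series such as the published liposome and SLN
tables enter as data, not as simulation targets.

## Numerical choices and study conditions

* Constants: $N_A = 6.02214076\times10^{23}$,
  $k_B = 1.380649\times10^{-23}$ J/K (exact SI). Cetyl palmitate MW fixed
  at 480.85 g/mol, which reproduces the quoted 208 mmol/L for a 10% w/v
  phase.
* For mixed phospholipid:sterol vesicles the stated molarity is treated as
  the phospholipid concentration; cholesterol is excluded from
  stoichiometry (it contributes no headgroup area term).
* Stoichiometry is computed at full precision; display follows the field's
  2-significant-figure convention. `stability_report()` accepts a
  `molecules_per_ml` override so that analyses anchored to a *reported*
  rounded molecule budget (e.g. $7.5\times10^{16}$) reproduce reported
  per-particle counts digit-for-digit.
* Simulation problem sizes used by the tests and the acceptance script:
  populations of 2 000–20 000 particles, ~2 000 tracks per simulated NTA
  run, five-level destabilisation sweeps, six-passage extrusion series on
  a 4 000-particle broad start (median 150 nm, geometric SD 1.6 — Span
  ≈ 1.3, the regime of a coarse pre-extrusion preparation). These sizes
  put Monte-Carlo scatter well inside the tolerances being checked while
  keeping any run to seconds.
* Degenerate inputs: empty populations, zero particle concentrations,
  constant correlation inputs and zero divisors raise classed errors
  (`nanocount_domain_error`, `nanocount_schema_error`, …) rather than
  propagating NaN.

## Known limitations

* Rayleigh weighting overstates intensity contrast for particles beyond
  ~λ/10; DLS simulations of micron-scale aggregates are qualitative.
* The liposome destabilisation series recomputes to r = −0.95 from its
  four published condition means; the originally reported −0.92 is not
  recoverable from the printed values alone (it may reflect
  replicate-level data). The package reports what it computes.
* The CHCl₃ dose column of the liposome table is carried as an ordering
  label only; its conversion basis (v/v to molecules/mL) is not stated in
  the source and is not modelled.
* No encapsulation efficiency, drug loading, or bilayer-thickness
  corrections; no proprietary instrument file formats.
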