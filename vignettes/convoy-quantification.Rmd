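---
title: "Quantifying polymerase convoys and multi-scale promoter dynamics"
author: "ConvoyQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying polymerase convoys and multi-scale promoter dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ConvoyQuant)
```

# The measurement problem

In MS2/MCP live-cell imaging, a reporter gene carries a large array of MS2
stem loops that are bound co-transcriptionally by a fluorescent coat
protein. The transcription site (TS) appears as a diffraction-limited spot
whose intensity is proportional to the amount of MS2 repeat currently
present in nascent transcripts. Bright, short-lived TS pulses arise when
many RNA polymerase II molecules initiate in rapid succession and elongate
together — a *polymerase convoy*. ConvoyQuant implements, as reusable R
functions, the quantitative machinery needed to go from such movies (or
from synthetic stand-ins for them) to kinetic parameters:

* a deterministic forward model of convoy TS intensity and its inverse
  (cycle fitting),
* a movie-quantification scheme that converts arbitrary fluorescence units
  into absolute nascent-transcript counts via single-molecule calibration,
* threshold segmentation of long movies into active/silent periods with
  exponential and bi-exponential dwell-time inference, and
* a four-state promoter model fitted to per-cell mRNA count distributions
  by population simulation and grid search.

Because raw imaging data of this kind are typically not deposited, the
package ships first-class synthetic-data generators that emulate every
input the pipeline consumes. All generators are pure functions of their
arguments and a seed.

# The convoy model

A convoy of `nPol` polymerases with temporal spacing `tSpace` (s),
elongation rate `vEl` (kb/min) and 3'-end processing time `tProc` (s)
traverses a gene described by three segment lengths (`GeneGeometry`): the
sequence upstream of the MS2 repeat (`lPre`, invisible), the repeat itself
(`lMs2`) and the sequence from repeat end to cleavage site (`lPost`).
Polymerase $i$ (0-based) initiates at $t_0 + i\,t_\mathrm{space}$ and moves
at constant speed $v = v_\mathrm{el}\cdot 1000/60$ nt/s. Its contribution
to TS intensity is 0 before it enters the repeat, grows linearly from 0 to
1 RNA equivalent across the repeat, stays at 1 until release at
$(l_\mathrm{pre}+l_\mathrm{MS2}+l_\mathrm{post})/v + t_\mathrm{proc}$
after its initiation, and drops to 0 instantaneously. Summation over the
convoy yields the characteristic tri-phasic curve: a linear UP ramp while
polymerases enter the repeat, a plateau equal to `nPol`, and a linear DOWN
ramp as transcripts are released at regular intervals.

```{r convoy}
p <- convoyParams(nPol = 19, tSpace = 4.1, vEl = 4.1, tProc = 103)
g <- geneGeometry()          # 2000 / 2800 / 4500 nt
analyticDurations(p, g)
nucleotideSpacing(4.1, 4.1)  # ~280 nt between polymerases
```

Modelling choices worth making explicit:

* **Continuum repeat.** Per-polymerase signal grows linearly with position
  inside the repeat rather than as a 128-step staircase; the discrete
  increments are far below measurement noise.
* **Deterministic release.** Transcript release happens exactly `tProc`
  seconds after the polymerase reaches the cleavage site. This is the
  simplest model consistent with the observed linear DOWN ramps.
* **Default geometry.** `lMs2 = 2800` nt follows from 128 stem-loop units
  of roughly 22 nt with 3-nt linkers. `lPre = 2000` nt and
  `lPost = 4500` nt are plausible for the reporter but are *not* measured
  quantities; `lPost` is chosen so that the post-repeat residency
  `lPost/vEl + tProc` is about 169 s at the parameter means above. All
  fitting code takes the geometry as an argument, and every test passes
  for any geometry.
* **`t0` convention.** `t0` is the initiation time of the first
  polymerase, not its entry into the repeat; it is a free nuisance
  parameter of every fit.
* **Clamped plateau.** When `(nPol-1)*tSpace > lPost/vEl + tProc` the
  plateau phase is absent; `analyticDurations()` clamps it to zero and
  raises a `truncated` flag. The nominal up/down formulas are reported
  unchanged in that regime.

# Cycle detection and fitting

`findIsolatedCycles()` extracts maximal above-threshold segments flanked
by silence (defaults: 0.5 RNA equivalents, 3 silent frames — the notion of
"isolated" is not quantified in the field, so both are configuration
keys). Segments touching the movie boundary are flagged and excluded from
fits by default.

`fitConvoyCycle()` performs least squares of the forward model over
(`nPol`, `tSpace`, `vEl`, `tProc`, `t0`). The mixed discrete/continuous
landscape is handled in stages:

1. *Corner estimation.* The smoothed cycle is reduced to a trapezoid via
   interpolated crossings at 25% and 75% of the peak. The rise slope
   estimates $1/t_\mathrm{space}$, the fall spans
   $(n_\mathrm{pol}-1)\,t_\mathrm{space}$ when a plateau exists, and the
   extrapolated rise corners sit on the linear midline offset by half the
   repeat transit time — these relations give closed-form starting values.
2. *Integer search.* Candidate `nPol` values span ±50% around the
   peak-intensity estimate (the plateau equals `nPol` when present) plus a
   duration-based estimate that remains valid for truncated triangles;
   candidates are scored cheaply at their analytic starts and the best few
   refined. Residual ties between adjacent `nPol` break toward the
   smaller convoy.
3. *Profiled refinement.* For each retained `nPol`, `vEl` is profiled over
   a coarse grid and then optimised continuously between its best grid
   neighbours, with (`tSpace`, `tProc`, `t0`) re-optimised at each step by
   Nelder-Mead; a final polish optimises all four jointly until the
   objective stalls.

When a cycle has no plateau the envelope constrains `vEl` only from below
— on real reporters this is common: only a minimal elongation rate can be
determined for a substantial fraction of cycles. The fit flags
`vElIsLowerBound` when doubling `vEl` (re-optimising the rest) changes the
RMS residual by less than 1%, or when the fitted parameters themselves
imply a truncated plateau; the reported `vEl` is then the smallest value
whose profiled residual stays within 1% of the optimum.

Two caveats the tests make explicit. First, with instantaneous release the
DOWN ramp is a staircase of unit drops; on a coarse frame grid a parameter
shift smaller than the frame interval can leave every sampled value
unchanged, so `tProc` is identifiable only up to a fraction of `dt` — the
round-trip recovery tests therefore use 1-s sampling, at which all four
parameters are recovered to better than 1% over the tested regime
(`nPol` 3–40, `tSpace` 2–12 s, `vEl` 1–6 kb/min, `tProc` 30–200 s,
restricted to plateau-bearing combinations). Second, phase boundaries are
implied by the model fit rather than segmented independently; the corner
estimates are only initial values.

`pooledUprampRegression()` exploits the model relation
$U = (n_\mathrm{pol}-1)t_\mathrm{space} + l_\mathrm{MS2}/v_\mathrm{el}$:
OLS of UP-ramp duration on `nPol` has slope `tSpace` and intercept
`lMs2/vEl − tSpace`, giving pooled estimates independent of the per-cycle
ones. `interconvoyStats()` multiplies `nPol` by `tSpace` for convoy
durations and measures gaps from the end of one UP ramp to the start of
the next; the exponential time constant of the gaps is fitted by maximum
likelihood (the sample mean), preferred over histogram regression for its
statistical efficiency.

# Movie quantification and single-molecule calibration

The movie pipeline mirrors a standard spot-quantification workflow:

* **Bleach correction** (`bleachCorrect()`): the per-frame nuclear mean is
  fitted with a sum of three exponentials (multi-start
  Levenberg-Marquardt, falling back to fewer components with a warning
  when the fit degenerates) and every frame is rescaled so its fitted
  nuclear intensity matches frame 1.
* **Bandpass filtering** (`bandpassFilter()`): subtraction of a
  large-kernel Gaussian background followed by small-kernel smoothing.
  The kernel sds (defaults 1 and 5 px) are configuration keys, as no
  single pair suits every magnification. Kernels act per z-plane.
* **Tracking** (`trackTS()`): per frame, the brightest voxel above a
  threshold within the search region; frames without detection reuse the
  last known position; exact value ties break toward the lowest (z, y, x)
  index.
* **Two-round Gaussian fitting** (`quantifyTSTrace()`): round 1 fits an
  unconstrained 3D Gaussian (amplitude, background, position, one lateral
  sd `sigma_xy` and one axial sd `sigma_z`); round 2
  re-fits with the sigmas bounded to median ± sd over pre-detected frames
  and the background fixed at its median, stabilising dim frames. The
  fitting window is a cube of about 3σ per axis; intensity is the
  integrated Gaussian volume above background,
  $A\,(2\pi)^{3/2}\sigma_{xy}^2\sigma_z$.
* **Calibration** (`calibrateNascentCounts()`): with `iFinal` the mean TS
  intensity of the last four movie frames and `nNascFinal` the absolute
  nascent count measured on the higher-power calibration stack acquired at
  movie end, the whole trace converts as
  $N(t) = I_\mathrm{MS2}(t)\cdot N_\mathrm{nasc,final}/I_\mathrm{final}$.
  The formula is forced by the definitions of its terms. Movies whose TS
  is dark at the end cannot be calibrated and raise an error. The
  single-molecule reference (`singleMoleculeIntensity()`) averages
  3D-Gaussian integrated intensities of detected nucleoplasmic molecules;
  the per-spot background estimate performs the per-cell background
  subtraction, and supplying a cohort mean rescales the reference by the
  cell-to-cohort molecule ratio (brightness tracks the cell's available
  coat protein). Background subtraction uses the per-spot scalar
  estimate rather than a per-pixel background image.
* **FRAP normalisation** (`frapNormalize()`): spot intensities divided by
  total cell fluorescence and renormalised to the pre-bleach mean, which
  cancels acquisition bleaching exactly.

`singleMoleculeCopyEstimates()` chains these steps over validation movies
that contain only single molecules; a well-calibrated pipeline yields a
mean near 1 RNA equivalent (the packaged acceptance script reports about
1.05–1.07 with an sd near 0.3 at the default noise settings).

# ON/OFF segmentation and dwell times

`segmentOnOff()` smooths the trace with a centred moving average (window
3 frames), classifies frames against an intensity threshold ("based on the
mean single-molecule intensity"; the multiplier defaults to 1.0 and is a
configuration key), and requires at least 2 consecutive frames per state.
Shorter runs are merged into the flanking state — merging is chosen over
delete-and-gap-fill and documented as such; with binary states both
flanks agree, and ties resolve to the preceding state. The first and last periods are flagged censored and are
excluded from dwell fits by default (optionally they enter the likelihood
through survival terms).

`fitDwell()` fits dwell durations by maximum likelihood: the mono
exponential MLE is the sample mean; the two-component mixture is fitted by
EM with 10 seeded restarts. The same machinery serves the 100-s
inter-convoy gaps of short movies and the minute-to-hour non-permissive
periods of long movies (bi-exponential with time constants near 9 and
34 min and a ~77/23% split in the regime studied).

# The four-state promoter model

Promoter states ON ↔ OFF1 → {OFF2a, OFF2b} → OFF1 capture bursting on two
time scales: minute-scale convoy firing (ON/OFF1) and sub-hour
permissive/non-permissive switching (OFF1/OFF2). The deep OFF state is
split into two substates reached with probability `f1` and `1 − f1` to
account for the bi-exponential non-permissive dwell times; the total exit
rate `kOff2` with branch probabilities is an equivalent parameterisation
of separate rates (`kOff2a = f1 * kOff2`). While ON, polymerases initiate
at `kIni`; each nascent RNA matures at `kRelease` per molecule and mature
RNAs decay at `kDeg` per molecule (first-order release matches the
structure of the steady-state constraint).

Because the state graph is a tree, detailed balance gives the stationary
distribution in closed form (weights relative to OFF1: `kOn1/kOff1`,
`f1*kOff2/kOn2a`, `(1−f1)*kOff2/kOn2b`), and Little's law gives
`mean_nascent = kIni π_ON / kRelease` and
`mean_mature = kIni π_ON / kDeg`, hence the identity
`mean_mature / mean_nascent = kRelease / kDeg`. `solveConstrainedRates()` derives the `kOff2` constraint directly from
the stationary solution (it is linear in `kOff2`), and the tests validate
it against both the algebraic round trip and simulation. Parameter combinations requiring negative `kOff2` are
reported as infeasible rather than raising errors, so grid searches can
skip and log them.

`simulatePopulation()` offers two schemes. The reference `fixed_step`
scheme (compiled) uses per-step transition probabilities `rate * dt` with
the canonical protocol of 3,000 cells × 36,000 one-second steps = 10 h;
initiation is drawn as Poisson(`kIni * dt`), which is exact and lifts the
stability constraint from the (fast) initiation rate, while the switching
and per-molecule rates must satisfy `rate * dt < 0.1`. The `exact` scheme
simulates the promoter path by the Gillespie algorithm and draws
end-of-run counts from their exact conditional Poisson distributions
(thinning of the initiation process), making it both discretisation-free
and fast — it is the cross-check for the fixed-step scheme and the
work-horse for large grid searches. Initial promoter states are drawn from
the analytic stationary distribution (no burn-in); RNA counts start at
zero, which is immaterial over runs much longer than `1/kDeg` = 75 min.

`compareDistributions()` scores simulated against observed populations
with a two-sample KS test on mature counts and a chi-squared test on
nascent counts (pooled so every expected cell is at least 5 — nascent
distributions carry many ties, e.g. zeros from silent TS, which breaks
KS). `gridSearchFit()` completes each grid point via the steady-state
constraints, simulates, ranks by the product of the two p-values and
averages the 10 best-fitting parameter sets. The default grid is the
canonical 8 × 4 × 4 × 4 × 5 design over `1/kIni`, `f1`, `1/kOn2b`,
`kOff1` and `1/kOn1` with `1/kOn2a` fixed at 5 min and `kDeg` at
1/75 min⁻¹. The `kOff1` values `{1/90, …, 1/160}` are rates in s⁻¹, i.e. mean ON
durations of 90–160 s, consistent with the convoy statistics (reading them
as dwell times of ~10 ms would contradict the minute-scale ON periods).

# What the synthetic data do and do not emulate

The generators reproduce the features the estimators rely on: tri-phasic
convoy cycles with additive/multiplicative Gaussian measurement noise;
promoter switching on two time scales with Poisson initiation;
diffraction-limited 3D Gaussian spots on a fluorescent background with
global tri-exponential photobleaching and Poisson-Gaussian camera noise;
exponential-mixture dwell samples; steady-state count distributions. They
do **not** emulate nuclear texture, cell-to-cell rate variability
(extrinsic noise), molecule diffusion within a frame, spot overlap
statistics of dense nucleoplasm, or segmentation errors — so passing tests
demonstrate correctness of the estimators under the stated model, not
robustness to every artefact of real microscopy. The TS intensity noise
magnitude has no canonical value; the default additive sd of 0.5 RNA
equivalents is a realistic level for single-TS traces at moderate
illumination and is a test parameter, not a truth.

# Numerical choices and problem sizes

* Convoy fits: Nelder-Mead on a piecewise-smooth objective with analytic
  starts; `vEl` bounded to [0.1, 20] kb/min, `tSpace` ≥ 0.05 s, `tProc`
  ≥ 0. Noiseless fits terminate early once the residual reaches the
  numerical floor.
* Bleach fits fall back tri → bi → mono with a warning; a constant is the
  last resort.
* EM for dwell mixtures uses 10 restarts, 500 iterations, relative
  log-likelihood tolerance 1e-8; components are reported in increasing
  tau order.
* The chi-squared pooling scans integer bins left to right, emitting a
  pooled bin whenever the combined column total guarantees expected
  counts ≥ 5 in both rows; a trailing remainder merges into the last bin.
* Test and acceptance runs use desk-scale sizes chosen to keep the whole
  suite comfortably reproducible on a laptop: populations of a few
  hundred to 3,000 cells, 10 validation movies of 30 molecules, reduced
  3 × 2 × 2 × 2 × 2 grids for self-consistency checks, 100 seeded
  parameter sets for round-trip recovery. The full 2,560-point default
  grid with 3,000-cell populations runs in minutes with the exact scheme.

# Known limitations

* The pipeline assumes a single TS per cell and takes masks/regions as
  inputs; nuclear segmentation and multi-TS tracking are out of scope.
* No polymerase pausing, premature termination or inter-polymerase
  coupling mechanics; spacing is regular or i.i.d. exponential.
* Dwell censoring at movie boundaries is handled by exclusion or a
  survival likelihood; interval censoring from the 3-min frame interval
  of long movies is not modelled.
* `tProc` (and `tSpace` for small convoys) are identifiable only up to a
  fraction of the frame interval on coarse grids, as discussed above.
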