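---
title: "Modelling interocular suppression with dichoptic contrast-response functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling interocular suppression with dichoptic contrast-response functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dichoptics)
```

## The scientific problem

When the two eyes see different contrasts (dichoptic presentation), the
response of early visual cortex reflects not just excitation from each
eye but also suppression *between* the eyes. In impaired binocular
vision — amblyopia and related developmental disorders — this
suppression is thought to be unbalanced, but it could take two quite
different forms:

* **tonic suppression** — a fixed attenuation of the weaker eye's
  signal, present even when the other eye sees nothing;
* **dynamic suppression** — contrast-dependent inhibition, where
  stimulation of one eye actively suppresses the channel of the other.

These make different predictions for dichoptic contrast-response
functions (CRFs): neural response amplitude measured over a factorial
grid of (target contrast, mask contrast) combinations across the two
eyes. `dichoptics` implements the generative model, the experimental
designs, seedable synthetic-data generators for both EEG-like and
BOLD-like recordings, the analysis pipelines that turn raw recordings
into CRF matrices, and the group statistics and model fitting that
discriminate the two suppression regimes.

## The two-stage gain-control model

The core model is a two-stage binocular contrast gain-control cascade.
Contrasts are Michelson percentages $C_L, C_R \in [0, 100]$ — no
internal renormalisation to $[0,1]$ is performed, so the saturation
constant $S$ is in percent-contrast units. Stage 1 computes, per eye,

$$S_{1,L} = \frac{(a_L C_L)^m}{S + a_L C_L + \omega_{R \to L}\, a_R C_R},$$

and symmetrically for the right eye. Here $a_L, a_R \in (0,1]$ are the
attenuation factors, $\omega$ the directional interocular suppression
weights, and $m$ the excitatory exponent. Attenuation is applied to an
eye's contrast *before both its excitatory and its suppressive use*: an
attenuated eye responds less and also suppresses the other eye less.

The two monocular outputs are summed binocularly, $B = S_{1,L} +
S_{1,R}$, and passed through a second gain-control stage,

$$R = g\,\frac{B^{p}}{Z + B^{q}},$$

with output gain $g$ mapping the dimensionless response into measurement
units (GLM $\beta$ or SSVEP SNR). Because $\beta$ and SNR units differ,
$g$ is treated as a free scale at fitting time rather than a fixed
constant.

Defaults are the standard parameterisation of this model family:
$m = 1.28$, $S = 0.985$, $p = 7.99$, $q = 6.59$, $Z = 0.076$, unit
suppression weights, no attenuation. What is binding about these numbers
is not their exact values but the qualitative signatures they must (and
do) produce, which the test suite asserts directly:

1. zero input gives zero response, and the monocular CRF is monotonic;
2. with symmetric parameters, swapping the eyes leaves the response
   unchanged;
3. a high-contrast mask plus a weak target *reduces* the response below
   the mask-alone level (the dichoptic "dip": excitation from the weak
   target is outweighed by its suppression of the mask response);
4. the tonic variant reduces the affected eye's responses monotonically
   in $1 - a$, while the dynamic variant leaves all monocular
   predictions bit-identical and deepens the dip monotonically in the
   weight multiplier.

```{r signatures}
p <- modelParams()
c(mask_alone = modelResponse(0, 96, p), plus_weak_target = modelResponse(6, 96, p))
predictCrfMatrix(p, c(0, 6, 24, 48, 96))
```

Variants are derived with `applyVariant()`: `"tonic"` sets the affected
eye's attenuation; `"dynamic"` multiplies the suppression weight *from*
the affected eye *onto* the other. The dynamic direction follows the
empirical observation in impaired binocular vision that the weaker eye
suppresses the dominant eye more strongly, so the default deficit
simulations scale $\omega_{\text{weak}\to\text{dominant}}$.

## Experimental designs

`buildConditionMatrix()` crosses five contrast levels
$\{0, 6, 24, 48, 96\}\%$ factorially into 25 dichoptic conditions. The
6, 24 and 96% levels (plus 0) are the canonical published levels for
this design; the mid level defaults to 48% and is configurable. Three
schedule builders reproduce the acquisition arithmetic exactly:

* fMRI CRF run: 12 s lead-in blank, then each condition once (12 s
  trial + 12 s blank) in seeded random order — 612 s = 204 TRs at
  TR = 3 s; the first 4 TRs are discarded at analysis time, leaving 200;
* EEG block: each condition once (12 s trial + 3 s intertrial interval)
  — 375 s per block, with sessions of 8 independently permuted blocks;
* phase-encoded localiser: 12 s blank + 6 cycles of 4 positions × 6 s
  — 156 s = 52 TRs.

Events are half-open intervals `[onset, onset + duration)` in seconds,
0-indexed, and schedules round-trip losslessly through a TSV
representation that records the level set, modality, TR and ordering
seed. The stimulus itself flickers on/off as a raised cosine,
$c(t) = c_0 (1 - \cos 2\pi f t)/2$ at $f = 4$ Hz, chosen so that onset
is smooth at zero contrast; any static nonlinearity applied to this
waveform generates second-harmonic (8 Hz) content, which motivates the
harmonic analysis below.

## What the synthetic data emulate — and what they do not

`generateSsvepRecording()` produces multichannel EEG-like data at
1000 Hz: during each trial, channels carry a 4 Hz sinusoid plus an 8 Hz
harmonic (default amplitude ratio 0.5 — the published spectra show a
strong but unquantified second harmonic, so the ratio is configurable),
with amplitude given by the two-stage model at the trial's contrasts,
weighted by an occipital topography (exponential falloff in scalp
distance from Oz, length constant 0.35 head radii), and tapered by a
0.1 s raised-cosine ramp at trial edges. Monocular trials of the
designated weaker eye are phase-delayed by a configurable interocular
lag (112° at 4 Hz corresponds to 77.8 ms). Noise is independent per
channel: $1/f^\alpha$ (default $\alpha = 1$) plus white, each with its
own SD in signal units.

The generator is deliberately *linear*: dichoptic trials take a single
amplitude from the model rather than mixing two eye-specific carriers
through a nonlinearity. The analyses only require calibrated amplitudes
and phases, and this choice keeps the generating truth exactly
recoverable. Consequently, passing tests demonstrate that the pipelines
measure what the model injects — they do not demonstrate robustness to
real-EEG phenomena such as alpha bursts, blinks, electrode drift or
non-stationary noise, none of which are modelled (the pipelines apply no
artifact rejection, by design).

`generateBoldRun()` produces voxel × TR matrices: per-trial amplitudes
from the model scale a TR-resolution boxcar, convolved with a canonical
double-gamma HRF (positive lobe peaking at 5 s, undershoot at 15 s,
ratio 6, unit-sum kernel — the source analyses name no specific HRF, so
the conventional shape is used). Each voxel adds a linear drift and
AR(1) noise (default $\rho = 0.3$, matching common BOLD practice) and a
±10% gain scatter so voxels are not clones. `generatePrfVoxels()`
implements the standard pRF forward model: neural drive = integral of a
2D Gaussian over the drifting-bar aperture, HRF-convolved, plus white
noise. Head motion, physiological noise and spatial correlation between
voxels are not simulated.

## Analysis pipelines

**SSVEP.** `trialSpectrum()` takes a rectangular-window Fourier
transform of a 10 s window starting 1 s after trial onset (skipping the
onset transient). No taper is applied: the design places 4 Hz exactly on
a bin for both the 10 s (0.1 Hz resolution) and sliding 1 s (1 Hz)
windows, so there is no leakage to control, and tapering would blur the
adjacent-bin SNR definition. Amplitudes are scaled $2/N$ so a unit
sinusoid reads 1. `coherentAverage()` averages complex coefficients
across repetitions and across the occipital electrode set
(Oz, POz, O1, O2 by default); because complex averaging is linear, the
order of electrode vs repetition averaging is immaterial. `snrAt()`
divides the 4 Hz amplitude by the mean of the ten adjacent bins
(±0.5 Hz in 0.1 Hz steps, signal bin excluded). A denominator at
floating-point-residual level (below $\varepsilon^{3/4}$ of the signal)
marks a noiseless recording; the SNR is returned as flagged infinity
rather than an astronomically large ratio. `slidingSnr()` repeats the
analysis in 1 s windows every 10 ms with ±1 Hz noise bins and a small
denominator floor for silent windows. The same machinery applied at
`f0 = 8` analyses the harmonic. Phase differences are converted to
latencies by $\mathrm{lag_{ms}} = \mathrm{lag_{deg}}/360 \times
1000/f_0$, wrapped to $(-180°, 180°]$.

**fMRI.** `glmBetas()` fits one HRF-convolved boxcar regressor per
condition plus per-run intercept and linear drift, discarding the first
4 TRs of each run and concatenating repeated runs (shared condition
columns, per-run nuisance columns). `coherencePhase()` summarises a
voxel by the amplitude at the stimulus repetition frequency divided by
the root-sum-square over the analysis band — all bins from the drift
cutoff (2 cycles/run, configurable) to Nyquist — plus the phase at that
frequency. `fitPrf()` does a coarse grid search (0.25° position lattice,
log-spaced sigmas, ties towards the smallest sigma) followed by
Nelder-Mead refinement, with gain and offset solved analytically for
each candidate; refinements that leave the search region or fail to
improve are discarded in favour of the grid optimum. `selectRoi()`
retains voxels with coherence *strictly* above 0.3 (0.3 exactly is
excluded) and variance explained of at least 10%.

One practical subtlety: an unresponsive voxel has VE exactly 0 only for
noiseless data. With noise, the pRF search's flexibility gives a
noise-only voxel an apparent VE of roughly 0.05–0.15 at 64 TRs,
dropping below the 10% threshold only at realistic scan lengths
(132 TRs per run). The tests assert both facts; users filtering real
data should combine the VE threshold with the localiser coherence
threshold, as `selectRoi()` does.

`trialTriggeredTimecourse()` expresses ROI-mean responses as % signal
change against the mean of the 4 pre-onset TRs; when that baseline is
not positive (possible in drift-free synthetic data with no intercept),
the series mean is used as the divisor so the measure stays defined.

## Group statistics and model comparison

`assembleCrf()` handles eye roles: for control participants each cell is
averaged with its mirror (complementary left/right conditions); for
patients the grid is re-ordered so rows index the fellow or the
amblyopic eye as target — a pure transpose, applied per participant's
amblyopic eye, that never changes the numbers. `suppressionContrast()`
computes the per-participant dip difference $\Delta = R(0, \max) -
R(\text{low}, \max)$ and a paired t-test with Cohen's
$d = \bar\Delta/s_\Delta$; an all-equal nonzero $\Delta$ vector is
flagged degenerate rather than reported as an infinite t. Per-eye tests
are reported uncorrected, mirroring the source analyses; Holm-corrected
p-values can be computed from the returned per-eye p-values with
`p.adjust()` and are never silently substituted.

`crfAnova()` runs the two-way repeated-measures ANOVA (target level ×
mask level, both 5-level factors including 0%, giving the familiar
(4, 44)-type degrees of freedom for 12 participants) and reports
$\omega^2 = (SS_{\mathrm{eff}} - df_{\mathrm{eff}} MS_{\mathrm{err}}) /
(SS_{\mathrm{total}} + MS_{\mathrm{err}})$ per effect, using each
effect's own error stratum. No sphericity correction is applied —
uncorrected degrees of freedom are reported, and the output notes this.

`fitModelToCrf()` operationalises model comparison: bounded nonlinear
least squares on the 25 cells with free parameters \{gain, $Z$\}
(baseline), plus attenuation (tonic, bounded to $(0,1]$) or a weight
multiplier (dynamic, bounded to $[1, 50]$). Gain and $Z$ are fitted on
the log scale; optimisation is L-BFGS-B from a seeded multi-start grid
(8 starts, the first at the no-deficit point). Variants are ranked by
AIC with the cell count (25) as $n$; AICc is reported alongside, since
with ≤4 parameters and 25 cells the two rarely disagree. The fit is
invariant to global rescaling of the data (the gain absorbs it), so
$\beta$- and SNR-unit CRFs are handled identically.

## Numerical and design choices

* **Problem sizes.** The test suite and acceptance script use 12-person
  cohorts with 4 runs of the full 204-TR design and 8 voxels per run,
  10 cohort seeds per regime, 200 Monte-Carlo seeds for the
  coherent-averaging law, and 40–100 voxels for pRF recovery — sizes
  chosen to give stable statistics on a single core.
* **Determinism.** Every generator takes an explicit seed and restores
  the caller's RNG state; identical seeds give bit-identical output.
  Schedule ordering seeds are stored in the schedule file.
* **Degenerate inputs** fail loudly: contrasts outside [0, 100],
  non-positive saturation constants, |AR(1) ρ| ≥ 1, windows longer than
  trials, rank-deficient GLM designs, missing CRF cells, apertures that
  never stimulate, and empty ROI tables all raise informative errors or
  warnings rather than propagating NaNs.
* **Known limitations.** The generator's linearity (above); no
  psychophysical predictions (the model here predicts neural response
  amplitudes, not 2AFC thresholds); no volumetric/NIfTI handling or
  cortical geometry — ROIs are defined by the quantitative thresholds on
  synthetic truth, not by drawing boundaries on flat maps; and the
  second-stage exponents are held fixed during fitting, which is what
  makes the three-variant comparison well-posed on 25 cells.

## A compact end-to-end example

```{r end-to-end}
p  <- applyVariant(modelParams(), "tonic", 0.6, "left")
cm <- buildConditionMatrix()
sch <- buildFmriCrfSchedule(cm, seed = 1)
run <- generateBoldRun(sch, p, noise = list(ar1_rho = 0.3, sigma = 0.3,
                                            drift = 0.05),
                       nVoxels = 8, seed = 1)
crf <- betaMatrix(glmBetas(run))
fits <- fitModelToCrf(crf, seed = 1)
attr(fits, "ranking")
round(fits$tonic$magnitude, 2)
```

A single noisy run already ranks the generating (tonic) variant first
and recovers the attenuation near its true value of 0.6; the acceptance
script repeats this over full cohorts and reports the recovery rates.
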