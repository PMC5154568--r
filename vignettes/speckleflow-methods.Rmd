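---
title: "Pulse-waveform analysis of laser speckle flowgraphy scans: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse-waveform analysis of laser speckle flowgraphy scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speckleflow)
```

## The measurement

Laser speckle flowgraphy (LSFG) infers relative blood-flow velocity from the
temporal blurring of a laser speckle pattern. Its primary output, the mean
blur rate (MBR, arbitrary units), is recorded as a short movie of
two-dimensional flow maps — by convention 118 frames of 750 x 360 pixels at
30 frames/s, about 4 s, a handful of cardiac cycles. Two families of
quantities are derived at the optic nerve head (ONH):

* **Regional mean MBR.** Pixels are averaged over one cardiac cycle into a
  *composite map*; an ellipsoid region of interest (ROI) is placed at the
  ONH margin; an automatic intensity threshold splits the ROI into visible
  surface vessels and tissue. MA, MV and MT are the mean MBR of the whole
  ROI, the vessel area and the tissue area.
* **Pulse-waveform indices.** The ROI-averaged MBR time series is segmented
  into cardiac cycles, phase-normalized into a single composite cycle, and
  summarized by eight shape indices: blowout time (BOT), blowout score
  (BOS), skew, acceleration time index (ATI), rising and falling rate
  (RR/FR), flow acceleration index (FAI) and resistivity index (RI).

This package implements both paths, the repeatability and association
statistics used in test-retest LSFG studies, and a synthetic cohort
generator that emulates the data structure of such a study (80 subjects in
four age groups, both sexes, three scans before and after pupil dilation)
so that the entire pipeline is testable without any instrument data.

## The composite cycle and the indices

`detectCycles()` smooths the series with a centered moving average (default
width 3 samples) and takes successive diastolic troughs — local minima that
are followed by a rise within half a minimal cycle — as cycle boundaries.
Only boundary spacings corresponding to heart rates of 40–120 bpm are
admitted; a series in which no admissible cycle exists (e.g. a flat series)
raises a "no cardiac cycle detected" error, the analogue of a failed scan
quality check. Cycles are half-open index ranges; indices are 1-based as
usual in R.

`compositeCycle()` resamples every cycle to `phaseBins` (default 30,
roughly one bin per frame at heart rate 60 and 30 fps) equally spaced
phases by linear interpolation and averages pointwise. Averaging across
cycles reduces uncorrelated noise; the tests verify that the composite is
closer to the underlying analytic cycle than single cycles are.

On the composite cycle `v` with minimum `mn`, maximum `mx` and mean `m`:

| index | definition | units |
|---|---|---|
| BOT | `100 * mean(v > (mn + mx) / 2)` | % |
| BOS | `100 * (1 - (mx - mn) / (2 m))` | % |
| skew | scaled weighted phase skewness (below) | AU |
| ATI | `100 * (argmax - 1) / n`, first occurrence | % |
| RR | mean positive per-bin increment, trough to peak, `/ m * 100` | % |
| FR | mean per-bin decrement, peak to trough (wrapping), `/ m * 100` | % |
| FAI | max cyclically adjacent increment | AU/bin |
| RI | `(mx - mn) / mx` | — |

The algebraic identity `BOS = 100 (1 - RI * mx / (2 m))` holds to machine
precision and is asserted on random cycles.

### Design choices where the definitions are underdetermined

These conventions are fixed here and exposed through `waveformConfig()`:

* **BOT half level.** The verbal definition of the half width is
  grammatically ambiguous between `(mn + mx) / 2` and `(mn + mx) / 4`. The
  standard half-width level `(mn + mx) / 2` is the default (`botLevel =
  "half"`); the alternative reading is available as `"quarter"`.
* **Skew.** Reversing a waveform in time must negate its skew, and a
  steeper post-peak decline must increase it. A plain skewness of the
  *value* distribution satisfies neither (it is invariant under time
  reversal), so skew is computed *temporally*: the cycle is treated as a
  distribution of flow over phase, with weights `v - mn` at the phase-bin
  centres, and the standardized third moment of phase under those weights
  is returned, times a scale constant (default 10; the instrument vendor's
  scaling is unpublished, and every sign/symmetry property is scale-free).
  It is exactly zero for time-symmetric cycles, positive for early-peaked
  (arterial-type) pulses, and odd under time reversal.
* **RR/FR.** Only "steepness" of the limbs is specified. The definition
  used — mean positive per-bin increment (decrement) over the monotone limb,
  normalized by the mean MBR — is scale-invariant, equal for the two limbs
  of a symmetric trapezoid, and strictly increasing in pulsatility (FR grows
  as the diastolic decay constant shrinks). Its absolute magnitude depends
  on the phase-bin count and is *not* calibrated to the instrument's
  printed range; comparisons of RR/FR are meaningful within a fixed
  configuration only.
* **Flat cycles.** BOT of a flat cycle is 100 with a warning (the whole
  cycle sits at the level); RI and FAI are 0; BOS is 100; skew and RR/FR
  are errors, since the formulas have no defined limit there.
* **Ties.** Extremum positions use the first occurrence; the descending
  limb runs from the *last* occurrence of the maximum, so flat-topped
  cycles treat both limbs symmetrically.

## The composite map and vessel extraction

`compositeMap()` averages each pixel over the frames of the complete
detected cycles only. `roiMask()` uses a centre-of-pixel, boundary-inclusive
test against the rotated ellipse. The instrument's "digital cross-section"
vessel threshold is proprietary; `extractVessels()` uses Otsu's
between-class-variance threshold on the in-ROI intensity histogram
(normalized to the data range, hence translation- and scale-equivariant) as
the automatic method, with a percentile threshold as a pluggable
alternative. No equivalence with the vendor algorithm is claimed. The
regional means satisfy the exact decomposition
`MA = f * MV + (1 - f) * MT` with `f` the vessel pixel fraction.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
exercised; it is not a tuning dial. Its analytic core is a Windkessel-style
pulse: a raised-cosine systolic upstroke over a fraction `s` of the period
followed by an exponential diastolic decay toward the baseline with time
constant `tau`. The upstroke starts at the value the decay reached at the
end of the previous cycle, so the waveform is continuous, periodic, and
single-peaked; the baseline is approached asymptotically in long diastoles.

Age enters through linear maps with subject-level Gaussian scatter
(`generatorConfig()` defaults): `tau` falls from about 0.65 s at age 25 to
0.35 s at 75 (stiffer arteries, faster diastolic runoff), the rise fraction
narrows slightly, and the tissue MBR baseline declines. These slopes are a
calibration — the study this emulates reports no quantitative age map — and
were chosen once so that an 80-subject cohort shows age correlations of the
observed sign and rough magnitude for the MBR-level indices and for
BOT (negative) and FR (positive). Blood pressure uses DBP and pulse
pressure (both mildly increasing with age, higher in males) with
SBP = DBP + PPA; heart rate declines mildly with age; IOP is
age-independent. Scan noise has two parts: additive within-scan measurement
noise (SD 0.4 AU) and a scan-to-scan level shift (SD 0.5 AU). Scan failures
are Bernoulli per scan, 15/240 undilated and 3/240 dilated by default, and
age-independent (whether failure correlates with age through pupil size is
unreported; independence is the neutral choice). Pupil dilation is a
condition label plus small configured additive index offsets — no
pharmacological model. A random phase offset, uniform over one period, is
drawn per scan; in the fully noise-free configuration the generator
collapses to its analytic core and the phase is pinned to zero, which makes
repeated scans identical and the repeatability statistics exactly
degenerate (COV 0, ICC 1) — the property the degeneracy tests assert.

Each simulated scan is pushed through `waveformProfile()` — the cohort table
is produced by the analysis pipeline under test, never by formula shortcuts.
MT is the scan's mean MBR; MV and MA are composed through a per-subject
vessel ratio and vessel area fraction, so MV > MA > MT by construction.

What the generator does *not* emulate: eye movement and blink artifacts,
choroidal signal leakage, pigmentation effects on signal saturation,
instrument drift, and any nonlinearity between true flow and MBR. Passing
tests therefore demonstrate internal consistency of the pipeline under the
stated generative model, not instrument-level validity. The repeatability
of the *shape* indices in the synthetic cohort is lower than a real
instrument report would show, because a 4-second record holds only ~4
cycles and the per-scan phase offset leaves visible discretization variance
in a 30-bin composite; the MBR-level indices (MA/MV/MT) reach ICC ≈ 0.93
under the default noise.

## The statistics layer

* **Hemodynamics.** `MAP = DBP + (SBP - DBP) / 3`, `PPA = SBP - DBP`,
  `OPP = 2/3 MAP - IOP`, exact. A variant MAP formula
  (`mapFormula = "printed"`, adding the pulse term to SBP instead of DBP)
  is kept behind a flag because it circulates in print despite being
  inconsistent with the summary tables it accompanies; the standard formula
  is the default.
* **COV** is the mean within-subject SD of the repeats over the grand mean,
  in percent (n−1 SDs).
* **ICC** is computed from the repeated-measures ANOVA mean squares
  (`stats::aov`). The default form is ICC(3,1) — two-way mixed, consistency,
  single measurement — with ICC(2,1) and the one-way form switchable; which
  variant a given published table used is generally not recoverable from
  text, so the form is explicit in the output. Perfectly repeated
  measurements give ICC 1 by convention even when subjects coincide.
* **Associations** are Pearson correlations with the two-sided t-test on
  n−2 df plus the least-squares line and its 95% confidence band, computed
  on per-subject means of the successful mydriatic scans (the convention of
  the emulated design).
* **Comparisons** are two-sided t-tests: paired for the dilation effect,
  pooled-variance independent (Welch optional) for sex differences. Exact
  zero-variance inputs use the degenerate limits (p = 1 for no difference,
  p → 0 for a certain shift) rather than erroring.
* **Success rates** are compared with the uncorrected Pearson chi-square on
  the 2 x 2 table; uncorrected is the default because it is the variant
  consistent with the printed p-value of the emulated study's counts
  (225/240 vs 237/240 gives p = 0.004 uncorrected, ~0.008 with Yates);
  Yates' correction is a flag.
* **No multiple-testing correction** is applied anywhere, matching the
  emulated analysis; every p-value is nominal.

## Problem sizes and determinism

The default pipeline scale is the study's: 80 subjects x 2 conditions x 3
repeats of 118-frame series, which runs in seconds. The test suite uses
smaller cohorts for structural checks, 100-seed Monte-Carlo loops for
direction-of-effect and calibration properties (sign recovery at n = 80 in
at least 95% of seeds; paired-test null rejection 0.05 ± 0.02 over 2000
replicates), and 1000 random cycles for the BOS–RI identity. All
generators are pure functions of their inputs and a single seed, and they
restore the caller's RNG state; `runPipeline()` writes byte-identical CSVs
for identical seeds.

## Known limitations

* The vendor's cycle segmentation, vessel threshold, skew scaling and RR/FR
  denominators are unpublished; this implementation fixes documented,
  configurable conventions instead, and absolute values of skew, RR and FR
  are not comparable with instrument output.
* Whether indices should be computed on the composite cycle (done here) or
  per cycle and then averaged is unreported in the emulated methods; the
  composite-cycle route follows the stated order of operations.
* The generator's age maps are calibrated, not derived; effect *sizes*
  recovered from synthetic cohorts are statements about the generator only.
* With ~4 cycles per record, trough placement on the flat diastolic tail
  dominates the variance of the duration and shape estimates; expect
  single-scan cycle-duration errors up to ~5–10% at 5% noise.
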