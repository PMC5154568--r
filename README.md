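# speckleflow

Pulse-waveform analysis of laser speckle flowgraphy (LSFG) optic-nerve-head
perfusion scans, for researchers working with ocular blood-flow data or
evaluating waveform-derived perfusion biomarkers.

LSFG records the mean blur rate (MBR, arbitrary units) — a relative
blood-flow-velocity measure — as a short stack of 2-D flow maps (118 frames
of 750 x 360 px at 30 fps, ~4 s). This package implements the two analysis
paths built on that signal:

* **Waveform path.** Cardiac cycles are detected at successive diastolic
  troughs of the MBR series, resampled onto a common phase grid and averaged
  into one composite pulse cycle `v` (minimum `mn`, maximum `mx`, mean `m`),
  from which the eight standard pulse-waveform indices are computed:

  - blowout time `BOT = 100 · mean(v > (mn + mx)/2)`
  - blowout score `BOS = 100 · (1 − (mx − mn)/(2m))`
  - skew: scaled weighted third moment of phase (temporal asymmetry)
  - acceleration time index `ATI = 100 · (time to peak)/(cycle duration)`
  - rising / falling rate RR, FR: mean per-bin slope of the systolic /
    diastolic limb, normalized by `m`, in percent
  - flow acceleration index `FAI = max adjacent MBR increment`
  - resistivity index `RI = (mx − mn)/mx`

* **Map path.** Per-pixel averaging over complete cycles yields the
  composite map; an ellipsoid ONH region of interest is split into vessel
  and tissue areas by automatic (Otsu) thresholding, giving the regional
  means MA (all), MV (vessel) and MT (tissue), with the exact identity
  `MA = f·MV + (1−f)·MT`.

On top sit the statistics of a repeated-scan study: coefficient of
variation and ANOVA-based intraclass correlation (ICC(3,1) default) for
test-retest repeatability, Pearson/linear-regression associations with age
and pulse pressure amplitude, paired (pupil dilation) and independent (sex)
t-tests, the 2 x 2 chi-square for scan success rates, and the derived
hemodynamics `MAP = DBP + (SBP − DBP)/3`, `PPA = SBP − DBP`,
`OPP = 2/3·MAP − IOP`.

A synthetic cohort generator (`simulateCohort()`) emulates the structure of
an 80-subject study — four age groups, both sexes, three scans before and
after pupil dilation, age-dependent Windkessel-style pulse shapes, scan
failures — so the full pipeline runs end to end with no instrument data.
See the methods vignette (`vignettes/speckleflow-methods.Rmd`) for the
model, parameter defaults and design decisions.

## Worked example

```r
library(speckleflow)

p <- simulateSubject(age = 68, sex = "male", seed = 42)
p
#> SubjectProfile 'subject': male, 68 y, HR 71 bpm
#>   waveform: baseline 6.43 AU, amplitude 9.16 AU, rise 0.276, tau 0.461 s
#>   SBP/DBP 147/85 mmHg, IOP 12.6 mmHg

s <- generateMbrSeries(p, seed = 42)   # 118 frames at 30 fps, noisy
waveformProfile(s)
#> WaveformIndices
#>  meanMbr    BOT    BOS  Skew    ATI    RR    FR   FAI    RI
#>   11.724 43.333 71.327 5.538 26.667 8.192 2.813 1.287 0.441
```

The mean tissue MBR is 11.7 AU; the waveform stays above its half level for
43% of the cycle (BOT), peaks 27% of the way into it (ATI), and swings by
44% of its maximum (RI) — the fast-runoff pulse expected of an older
subject's stiffer vasculature.

A full study-scale run (80 subjects x 2 conditions x 3 repeats, a few
seconds) produces the cohort table and every report table:

```r
res <- runPipeline(pipelineConfig(), seed = 1)
res$successRate$counts
#>   condition success total rate
#> 1   dilated     234   240 97.5
#> 2 undilated     225   240 93.8

subset(res$repeatability, condition == "undilated" & index %in% c("MA", "MT"))
#>   index condition      cov       icc nSubjects nRepeats
#> 1    MA undilated 3.783537 0.9300017        66        3
#> 3    MT undilated 3.802790 0.9263675        66        3

subset(res$association, covariate == "age" & index %in% c("MA", "BOT", "FR"))
#>   index covariate          r            p       slope intercept  n
#> 1    MA       age -0.5970924 5.035375e-09 -0.12848679 29.014056 80
#> 4   BOT       age -0.6474975 8.541407e-11 -0.10994477 46.549619 80
#> 9    FR       age  0.7197208 5.386699e-14  0.02397747  1.794476 80
```

MBR-level indices are highly repeatable (ICC ≈ 0.93) and decline with age,
blowout time falls with age and falling rate rises — the direction pattern
the generator is calibrated to reproduce. `runPipeline(..., outDir = "out")`
additionally writes the cohort CSV, the report tables and a run log; a thin
command-line wrapper lives at `inst/scripts/run-pipeline.R`.

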