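# megadyn

Temporal dynamics of GABA+ and Glx from MEGA-PRESS edited magnetic
resonance spectroscopy.

Conventional MRS collapses an entire acquisition (typically 200–300
transients, ~10–13 min) into a single concentration estimate per subject,
discarding everything that happens *during* the scan. megadyn implements
two analyses that recover that temporal dimension for the edited signals
of GABA+ (GABA plus co-edited macromolecules, 3.0 ppm) and Glx
(glutamate + glutamine, ~3.75 ppm):

- **Low-resolution sliding-window analysis.** Per subject, overlapping
  windows (width 128 transients, step 2) are averaged per editing
  condition, the edited difference spectrum DIFF = mean(ON) − mean(OFF)
  is quantified with peak models (Lorentzian tCr/tNAA on the mean OFF
  spectrum; single-Gaussian GABA+ and double-Gaussian Glx on DIFF; areas
  are analytic: πAγ and Aσ√(2π)), and the tCr-referenced ratio is
  expressed as percent change from the first window. Group inference uses
  a cluster-based permutation test: per-window one-sample t statistics,
  maximal same-sign suprathreshold runs scored by their summed t values,
  compared with a randomisation null of maximal cluster masses.
- **High-resolution across-subject binning.** Transients from *all*
  subjects falling in the same 12 s acquisition bin are pooled (4
  transients/bin at TR 3 s; 6 at TR 2 s), producing one cohort-level
  trace per metabolite with no temporal smoothing. The GABA+ and Glx
  traces are cross-correlated at every signed lag retaining ≥ 25
  overlapping bins (negative lags: GABA+ precedes and predicts Glx), with
  per-lag t = r√((n−2)/(1−r²)), Fisher-z confidence intervals, and the
  same cluster-permutation correction over lags.

Upstream of both analyses sits a standard edited-MRS preprocessing chain
(per-transient complex-Lorentzian creatine reference fits, 3 SD outlier
rejection on frequency/phase/area/FWHM, frequency and phase alignment of
Cr to 3.0 ppm), quantification quality metrics (FWHM, fit error,
frequency drift), CSF partial-volume correction
C_corr = C_meas / (1 − f_CSF), and FWHM-based participant exclusion.

Because raw cohorts of this kind are rarely shareable, the package also
provides a synthetic MEGA-PRESS cohort generator with fully known ground
truth — linear concentration drifts, a cohort-shared latent fluctuation
with a delayed GABA+→Glx anti-coupling (120 s at the defaults),
frequency/phase jitter, and per-subject variability — so the entire
pipeline is verifiable end to end. See the methods vignette
(`vignettes/megadyn-methods.Rmd`) for the models, the calibration of the
defaults, and the statistical design choices.

## Worked example

```r
library(megadyn)

cohort <- simulateCohort(vcProfile(), defaultGroundTruth(),
                         nSubjects = 12, seed = 7)
cohort <- preprocessCohort(cohort)

plan   <- slidingWindows(nTransients(cohort), width = 128, step = 2,
                         trS = trS(cohort))
traces <- changeTraces(cohort, plan, "gaba", "tcr")
clusterPermutationTest(traces, nPerm = 2000, seed = 7,
                       timesS = plan$timesS)
#> ClusterTestResult: 65 windows, 1 cluster(s), 1 significant (nPerm 2000, alpha 0.05)
#>   start end sign      mass          p significant
#> 1     6  65   -1 -239.3407 0.00149925        TRUE

gm <- colMeans(traces, na.rm = TRUE)
sprintf("maximum group-mean GABA+:tCr change: %.1f%% at %d s",
        gm[which.max(abs(gm))], round(plan$timesS[which.max(abs(gm))]))
#> "maximum group-mean GABA+:tCr change: -5.4% at 478 s"

high <- binAcrossSubjects(cohort, binSize = 4)
cc <- crossCorrClusterTest(
  crossCorrelation(normalizeTrace(high$gaba), normalizeTrace(high$glx),
                   minOverlap = 25),
  nPerm = 2000, seed = 7)
cc
#> CrossCorrResult: 79 lags (-468 .. +468 s, >= 25 overlapping bins)
#>   2 significant cluster(s):
#>       direction lagStartS lagEndS sign       mass            p significant
#> 3  A_precedes_B      -144     -96   -1 -18.734664 0.0004997501        TRUE
#> ...
```

Reading the output: GABA+:tCr declines significantly across the scan
(one negative cluster spanning windows 6–65; the windowed maximum change
of about −5% corresponds to the injected −10% end-to-end drift smoothed
by the 128-transient window), and the cross-correlation shows a
significant negative cluster at lags −144…−96 s — GABA+ predicting the
*opposite* change in Glx about two minutes later, which is exactly the
generator's injected 120 s anti-coupling. Because both traces also carry
the opposite-signed drifts, weak negative correlation spreads across the
whole lag map (visible as the near-threshold clusters); the vignette
discusses this floor.

The full orchestration — simulation or loading, preprocessing, static
CSF-corrected estimates, all three metabolite trace analyses,
cross-correlation, low/high cross-validation, CSV outputs and a YAML run
manifest — is available as `runPipeline(defaultConfig("vc"))`.

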