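---
title: "Models and methods behind megadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind megadyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

megadyn studies how the edited-MRS signals of GABA+ (GABA plus co-edited
macromolecules, 3.0 ppm in the difference spectrum) and Glx (glutamate +
glutamine, ~3.75 ppm) evolve *during* a MEGA-PRESS acquisition, instead of
collapsing all transients into one static estimate.  It implements two
complementary analyses:

* a **low-resolution sliding-window analysis** — per subject, overlapping
  blocks of transients are averaged, quantified, and expressed as percent
  change from the first window; group inference uses a cluster-based
  permutation test over window time; and
* a **high-resolution across-subject binning analysis** — transients from
  all subjects falling in the same 12 s acquisition bin are pooled into a
  single cohort-level trace per metabolite, and the GABA+ and Glx traces
  are cross-correlated over signed lags with a cluster-corrected
  permutation test.

Because raw scanner data for this kind of study are rarely shareable, the
package ships a synthetic MEGA-PRESS cohort generator with a fully known
ground truth, so every stage — preprocessing, quantification, inference —
can be validated end to end.

# The synthetic cohort generator

## Spectral model

Each transient is a complex frequency-domain spectrum on a decreasing ppm
axis (2000 Hz sweep at 127.7 MHz, carrier at 4.7 ppm).  OFF transients
contain complex Lorentzians for total creatine (tCr, 3.0 ppm, FWHM 8.5 Hz)
and total N-acetylaspartate (tNAA, 2.0 ppm, FWHM 8.4 Hz), optionally a
broad residual-water component at 4.7 ppm, a per-subject linear baseline,
and complex Gaussian noise.  ON transients add the edited signature
directly: a positive GABA+ Gaussian at 3.0 ppm (FWHM ~25 Hz), a positive
double-Gaussian Glx complex, and a *negative* co-edited tNAA Lorentzian at
2.0 ppm.  Editing physics (J-evolution under the editing pulse) is not
simulated — the analyses only ever consume the ON−OFF difference, so the
difference-spectrum signature is injected directly and scaled by an
editing-efficiency parameter.

The Glx resonance is described in the edited-MRS literature simply as a
peak "at 3.8 ppm"; its sub-structure is modelled here as two equal-width
Gaussians at 3.71 and 3.79 ppm, a conventional choice for difference-
spectrum fitting.  Line-shape areas are analytic: `pi*A*gamma` for a
Lorentzian of amplitude `A` and half-width `gamma`, `A*sigma*sqrt(2*pi)`
for a Gaussian.

The instrument model applies, per transient, a frequency offset (Gaussian
jitter of SD 0.0088 ppm — matching the reported across-subject average
frequency drift of this kind of acquisition — plus an optional cumulative
linear scanner drift) and a zero-order phase offset (SD 5°) as a complex
rotation.

## Concentration dynamics

Per-transient metabolite amplitudes follow, for subject $s$ and transient
$t$ ($\tau = t/(N-1)$):

$$A_m(s, t) = c_s\, r_m(s)\,\bigl(1 + d_m \tau + L_m(b(t))\bigr) A_{\mathrm{tCr}}$$

where $r_m(s)$ is the subject's baseline ratio to tCr, $d_m$ the
fractional endpoint-to-endpoint linear drift, and $L_m$ a cohort-shared
latent fluctuation defined per high-resolution bin $b(t)$.  The GABA+
latent is a stationary AR(1) process; the Glx latent is a *delayed
anti-coupling*:

$$L_{\mathrm{Glx}}(b) = -\kappa\, L_{\mathrm{GABA}}(b - \delta) + \varepsilon_b$$

so a change in GABA+ predicts the opposite change in Glx $\delta$ bins
(120 s at the defaults) later.

## Calibration of the defaults

The defaults are the study conditions and were fixed by closed forms
before any end-to-end run:

* **Drifts**: a linear ramp observed through a sliding window of width
  $w$ over $N$ transients has a maximum percent change (relative to the
  first window) of
  $100\, d\, (N-w)/(N-1) \,/\, (1 + d\,(w-1)/(2(N-1)))$.
  Setting $d_{\mathrm{GABA}} = -0.100$ and $d_{\mathrm{Glx}} = +0.054$
  makes the 128/2 window analysis of a 256-transient acquisition recover
  maxima of about −5.1% and +2.7%, the magnitudes reported for visual
  cortex.
* **Coupling**: with latent SD $\sigma_g = 0.02$, AR coefficient 0.5,
  $\kappa = 0.5$, innovation SD $0.025$, and per-bin measurement noise of
  about 2%, the predicted peak lagged correlation between the group
  traces is $\approx -0.38$ (the reported value is −0.36 at the 120 s
  lag).  The drift trends alone contribute $\approx -0.29$ at *every*
  lag — an anticorrelation floor that caps how small the peak can be made
  while the drifts stay at their calibrated values, and which spreads
  weak negative correlation across the whole lag map.
* **Noise**: the per-point complex noise SD (0.01) was chosen so the
  per-bin high-resolution GABA+ *area* noise is ~2%, the value the
  coupling calibration assumes.  A subtlety worth recording: the GABA+
  fit window (2.8–3.3 ppm) barely exceeds the GABA+ linewidth, which
  makes the amplitude/width/baseline least-squares problem roughly 20×
  less efficient (in variance) than a matched-filter area estimate.
  Matching the published ~7.6% residual-over-amplitude fit error would
  therefore push the area noise to ~9% and bury the coupling; the
  area-noise calibration governs, and the simulated fit errors (~2%) are
  consequently lower than the published ones.
* **Baselines and spreads**: baseline ratios (GABA+:tCr 0.12, Glx:tCr
  0.15, tNAA:tCr 1.40) and their across-subject SDs are set from the
  qualitative spreads of published static distributions; they are tunable
  and nothing downstream depends on their exact values because all
  dynamic quantities are ratios or percent changes.
* **Null configuration**: the posterior-cingulate profile and all type-I
  studies use `nullGroundTruth()`, which zeroes the drifts, the coupling
  *and* the shared latent.  A nonzero cohort-shared latent is genuine
  common signal — the group test would correctly detect it — so it cannot
  be part of a type-I-error condition.

## What the generator does and does not emulate

It emulates alternating OFF/ON acquisition, frequency/phase jitter,
scanner drift, subject-level intensity/linewidth/baseline variability,
CSF-containing voxels, and the dynamics above.  It does not emulate
J-coupling evolution, macromolecule baselines, eddy currents,
non-Gaussian artifacts (motion spikes, lipid contamination) or
vendor-specific raw formats.  Passing tests therefore demonstrate that
the *pipeline* recovers known truth under a realistic-but-idealised
signal model, not that it is robust to every failure mode of real data.

# Preprocessing

Every transient (ON and OFF alike — creatine appears in both) is fitted
with a complex Lorentzian plus complex linear baseline over 2.4–3.6 ppm,
with free zero-order phase; first-order phase is not modelled.  The
fitted frequency, phase, area and FWHM feed the 3-SD outlier rule,
applied per subject across that subject's transients: a transient is
dropped if any of the four parameters is more than `k = 3` SDs from the
subject mean (a parameter with zero spread is skipped).  Surviving
transients are frequency-shifted so Cr lands exactly on 3.0 ppm —
implemented as a time-domain phase ramp with signed time indices, exact
for band-limited spectra — and dephased by complex rotation.  Frequency
drift is reported as the SD of the *pre-alignment* Cr position across
retained OFF transients.

Numerical notes: the nonlinear fits use a small Levenberg–Marquardt
optimiser (compiled) with forward-difference Jacobians, edge-based
baseline initialisation and extremum-based centre initialisation; widths
are kept positive by reflection; a fit that cannot improve further is at
a (local) minimum and is accepted, with sanity checks (positive
amplitude, centre inside the window, width below half the window) deciding
the retention flag.

# Quantification

From each averaged selection, tCr and tNAA are fitted on the mean OFF
spectrum (Lorentzians, 2.6–3.4 and 1.8–2.2 ppm), GABA+ (single Gaussian,
2.8–3.3 ppm) and Glx (double Gaussian, 3.45–4.10 ppm) on the difference
spectrum, and the co-edited negative tNAA lobe with an inverse Lorentzian
(1.8–2.2 ppm).  The windows are package conventions in the style of the
standard edited-MRS toolboxes; published descriptions of this kind of
analysis typically name only the peak centres.  Fit error is defined as residual SD divided by the (largest)
fitted amplitude, in percent — the numerator choice is ours, the
denominator matches the published definition.  Ratios go to tCr by
default, with tNAA available as a control reference.  CSF correction
divides by the metabolite-visible fraction, `corrected = measured /
(1 - fCsf)`.  Participants whose FWHM on any quantified peak is more than
3 SDs from the cohort mean are excluded; note that with $n$ participants
the largest attainable z-score is $(n-1)/\sqrt{n}$, so the rule only has
teeth for $n \gtrsim 11$.

For the partial-correlation table the control variable is the tCr area
itself, even though both correlated variables are tCr ratios — this
mirrors how such correlation tables are usually described; the exact
operationalisation is ambiguous in the literature and flagged as such.

# Inference

## Sliding-window cluster test

Per window, a two-sided one-sample t test of the subject percent changes
against zero; windows with $|t|$ above the two-sided point-wise critical
value form maximal same-sign runs scored by summed t values.  The null
distribution of the maximal positive and |negative| cluster mass is
built by randomisation and observed clusters must exceed the
$1-\alpha/2$ percentile of the matching null.

Two design choices here deserve justification because both deviate from a
literal reading of the usual description of this test:

* **Exchange unit.** Shuffling each subject's window labels destroys the
  window-to-window autocorrelation that 128-wide, step-2 windows induce
  (adjacent windows share 126 of 128 transients), so shuffled traces
  produce systematically smaller cluster masses than real null traces and
  the family-wise error roughly doubles (~0.11–0.14 measured at nominal
  0.05).  The default scheme therefore flips the sign of each subject's
  whole trace instead — the standard one-sample cluster-permutation
  device — which preserves autocorrelation exactly and is exact under a
  symmetric null.  The label shuffle remains available
  (`nullScheme = "shuffle"`).
* **Per-side level.** Testing positive and negative clusters separately,
  each at the 95th percentile of its own null, is a union of two
  one-sided 5% tests and yields ~10% family-wise error (measured 0.11 on
  exactly symmetric traces).  megadyn uses the $1-\alpha/2$ percentile
  per side so the two-sided family level is $\alpha$; the literal
  95th-per-side behaviour corresponds to `alpha = 0.10`.

A trace's first window is identically zero by construction; its t value
is defined as 0 and it can never seed a cluster.  A window with zero
spread but nonzero mean is a perfect deviation and gets a capped t of
$\pm 10^6$.  Missing windows (flagged fits) are excluded pairwise.

## Cross-correlation cluster test

For lag index $k \ge 0$, the Pearson correlation between `A[1:n]` and
`B[(k+1):(k+n)]` (`n = nBins - k`) is reported at signed lag $-k\,\Delta t$
— trace A (GABA+) acquired earlier, predicting trace B (Glx) — and the
mirrored computation at $+k\,\Delta t$; only lags retaining at least 25
overlapping bins are kept (40 per direction for 64 bins, 29 for 53).
Correlations are converted to t statistics, thresholded at each lag's own
two-sided point-wise critical value, clustered within a direction, and
compared with a null built by fully permuting the time order of trace B
(not circular shifts) and recomputing the entire lag map.  Cross-
correlation always runs on the raw (unsmoothed) binned trace; smoothing
is for presentation and for the low/high cross-validation only.
Confidence intervals are Fisher-z with each lag's own sample size.

Because both traces carry the deterministic drifts, the whole lag map in
*both* directions sits on a weak negative-correlation floor; the delayed
coupling adds a localised bump at −120 s.  With the calibrated peak of
$\approx -0.4$ and ~50 overlapping bins, the sampling SD of a single lag's
correlation is ~0.14, so the location of the *most negative* point
fluctuates by a few bins across realisations even though the significant
cluster reliably covers the injected −120 s lag.  The package's recovery
check is therefore phrased as cluster coverage of the injected lag, and
the lag estimate reported across seeds is modal rather than mean.

## Low/high cross-validation

A sliding window of the low-resolution width (128 transients = 32 bins),
advanced one bin at a time, is applied to the high-resolution trace and
correlated with the low-resolution group-mean trace at the matching
window starts (33 matched points for the 256-transient acquisition).  To
first order both analyses are the same linear functional of the same
spectra — averaging before fitting versus averaging fitted ratios — so
their fit noise is largely shared and the correlation on default cohorts
exceeds 0.99.

# Problem sizes used in the shipped checks

The test suite exercises full-size cohorts (57 subjects, 256 transients,
2048 points) for the headline recovery checks and scaled-down cohorts
(6–14 subjects, 64–128 transients, 1024 points) for error-control and
property checks; the acceptance script uses 57-subject cohorts for the
recovery quantities, 20 seeds for the lag mode, and 200 six-subject
null cohorts (1024-point digitisation, full 65-window plan) for the
family-wise error rate.  These sizes are the package's choices for its
own validation studies; all of them can be scaled up through the same
functions.

# Known limitations

* The generator's fit errors are below published values at the default
  noise (see the calibration note above); conversely its per-subject
  sliding-window trace variability (~3%) is below the ~12% implied by
  published group statistics, because real cohorts add biological
  drift heterogeneity that the generator deliberately omits (drifts are
  uniform across subjects).
* The drift-induced anticorrelation floor means significant negative
  lag clusters can extend well beyond the coupling bump, and weak
  negative clusters can appear in the "Glx predicts GABA+" direction on
  drifting cohorts; disabling the drifts isolates the coupling.
* `compareGroups()` gates on Shapiro–Wilk at 0.05, so ~10% of truly
  Gaussian datasets are routed to the rank-sum test by construction.
* The serialization format is R-native (RDS + YAML sidecar); no HDF5
  binding is required by the package.
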