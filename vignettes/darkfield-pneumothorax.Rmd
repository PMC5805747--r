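---
title: "Simulating and quantifying pneumothorax in x-ray dark-field radiography"
author: "dfpneumo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying pneumothorax in x-ray dark-field radiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfpneumo)
```

## The problem

Pneumothorax — free air in the pleural cavity collapsing the adjacent
lung — is easy to miss on conventional chest radiographs because inflated
lung and free gas attenuate x-rays almost equally. A grating
interferometer adds a second, independent contrast channel: the
**dark-field signal**, the reduction of fringe visibility caused by
small-angle scattering at the myriad air–tissue interfaces of the
alveolar microstructure. Inflated lung scatters strongly (low dark-field
signal $D$), free pleural gas not at all ($D \approx 1$), so the pleural
line stands out sharply.

`dfpneumo` re-creates the quantitative analysis of a large-animal
(porcine) dark-field pneumothorax experiment as a fully synthetic,
tested pipeline. Because no image data from such scanners are publicly
deposited, the package pairs a thorax phantom and an acquisition
simulator with the analysis stages, and the whole chain is validated
against the summary statistics such a study reports.

## Forward model

The scanner is a fringe-scanning (phase-stepping) grating
interferometer: a source grating G0, a reference grating G1 whose direct
shadow is analyzed by G2, and a flat-panel detector. During a scan the
intensity fringe pattern moves over each pixel, which records a
stepping curve. With sample transmission $T = e^{-\mu}$ and dark-field
signal $D = e^{-\epsilon}$ ($\mu$, $\epsilon$ the attenuation and
scatter line integrals of the phantom), frame $k$ has expectation

$$ I_k = I_0\, T\, \bigl(1 + v_0\, D \cos(\varphi_k + \varphi_{pix})\bigr), $$

with reference visibility $v_0$, step phases $\varphi_k$ and a
flat-field fringe phase $\varphi_{pix}$ oriented in horizontal lines
(orthogonal to the scan direction). Photon noise is Poisson. The model
is deliberately *effective and monochromatic*: no spectral or
beam-hardening physics, no wave-optical propagation, because every
quantity the pipeline reproduces is an ROI statistic of the retrieved
images, not an absolute signal level.

Retrieval fits $a_0 + a_1 \cos(\varphi_k + \varphi)$ per pixel by linear
least squares (for equally spaced phases this is the discrete-Fourier
estimate) and forms

$$ T = a_0^s / a_0^r, \qquad
   D = \frac{a_1^s / a_0^s}{a_1^r / a_0^r}. $$

Transmission and dark-field therefore come from the same exposure and
are registered by construction. $D$ is clipped to $[0, 1.5]$ before
analysis (photon noise can push visibility ratios above 1); the clip
never touches calibrated signal ranges.

## The phantom and what it does (not) emulate

`generatePhantom()` renders a stylized 2-D projection: elliptical body,
two lung fields clipped at the diaphragm, a dome of weakly scattering
retro-diaphragmatic lung per side, heart, nine rib bands, and an
abdominal attenuation step. The stylization is intentional — all
downstream analysis is ROI-based, so ROI statistics, not organ shapes,
must be realistic. Two correlated Gaussian random fields provide the
"anatomical noise" that dominates the ROI standard deviations in real
radiographs:

* **lung granularity** in the scatter domain — high spatial frequency
  (correlation FWHM 4.2 px), sd 0.16; the retro-diaphragmatic lung
  carries half that amplitude;
* **soft-tissue structure** in the attenuation domain — low spatial
  frequency (correlation FWHM 30 px), sd 0.26 across the body.

Pneumothorax induction is ground-truth-first: a **lateral** pneumothorax
carves a pleural gas band (zero scatter, slightly reduced attenuation)
between lung and lateral rib cage, with width growing linearly in the
instilled volume (500 ml &rarr; 12 mm; only monotonicity matters, the
true volume-to-gap relation of a living thorax is not modeled). A
**dorsal** pneumothorax shrinks the affected retro-diaphragmatic lung
mask by a drawn collapse fraction and rescales the truth area. Truth
areas are always exactly mask pixel count times squared pixel size.

What the phantom does *not* emulate: 3-D anatomy, organ motion over
time, species-accurate airways, bone texture, detector MTF, scanner
slot-scanning weights. Passing tests therefore demonstrate that the
*analysis chain* is correct and that the *calibrated statistics* are
reproduced — not that the renderer would fool a radiologist.

## Calibration `paper2018`

The study the pipeline is calibrated against prints four
lung-to-pneumothorax CNR values (filtered/unfiltered dark-field and
transmission), cohort area statistics, and the post-processing filters —
but not the system visibility, fluence, or texture spectra. Those free
parameters are collected in `calibrationPreset("paper2018")` and were
finalized by simulation so the default cohort experiment reproduces the
printed summary statistics:

* $v_0 = 0.25$, 8 equally spaced phase steps, 9000 photons/pixel/step,
  noiseless (well-averaged) reference;
* phantom signal levels: lung scatter 0.36 (plus a smooth radial
  envelope), retro-diaphragmatic scatter 0.51, lung attenuation
  contrast 0.152 over a body of 0.916;
* texture amplitudes/correlations as above;
* segmentation threshold factor 0.8, quantitative filter FWHM 3.25 px.

The interplay is worth recording: the unfiltered dark-field CNR fixes
the ratio of contrast $\Delta D \approx 0.30$ to combined photon +
granularity noise; the filtered/unfiltered ratio (3.65/2.45) pins how
much of that noise is high-frequency (strongly filtered) versus
correlated (barely filtered); the transmission CNR is dominated by
low-frequency anatomical structure, which makes it both insensitive to
fluence and intrinsically unstable from animal to animal (its printed
cohort sd is as large as its mean — the simulation reproduces that
instability).

The calibration is frozen **at the default analysis grid**: half the
prototype's effective sampling, i.e. 0.72 mm pixels, 444 × 486 px over
the 32 × 35 cm field of view. CNR statistics are governed by pixel-domain
quantities (filter FWHM in px, photons per pixel, texture correlation in
px, ROI size in px), so a calibration is only meaningful together with
its grid; the half grid keeps a 20-cohort experiment comfortably on a
single CPU. `scale = "full"` (0.36 mm) and `scale = "smoke"` (1.44 mm)
grids exist for resolution experiments and fast structural tests.

## Filters and the dose-equivalence argument

The quantitative pipeline applies one filter only: a 2-D Gaussian of
FWHM 3.25 px ($\sigma = $ FWHM$/2\sqrt{2\ln 2}$, truncated at $4\sigma$,
renormalized, reflected edges) to the dark-field image. Transmission is
analyzed unfiltered (a filtered variant exists for comparison — it
improves transmission CNR only marginally, since that modality is
anatomical-noise-limited). For uncorrelated noise the filter reduces the
pixel variance by $\sum w_i^2$; `noiseEquivalenceFactor(3.25)` returns
$1/\sum w_i^2 \approx 23.9$, the "equivalent to a ~25-fold dose
increase" argument in closed form. The display pipeline (tile-gap
replacement, 3 × 3 binomial kernel; one pass by default, the number of
successive passes is configurable) marks its output *display-grade*, and
every quantitative operation rejects display-grade images.

## Segmentation and areas

Inflated retro-diaphragmatic lung is visible only in the dark-field
channel, so `segmentInflatedLung()` thresholds the Gaussian-filtered
dark-field image inside a per-side analysis band (the padded bounding
box of the baseline truth mask, clipped at the diaphragm row), at 0.8 ×
the median of the local gas/background plateau, then closes
morphologically and keeps the largest component. The threshold factor
0.8 is the midpoint of the blurred lung/gas edge for the calibrated
retro-lung level ($D \approx 0.6$ against a plateau of 1), which makes
the segmented area unbiased to first order; lower factors would place
the boundary inside the lung and bias areas low by a perimeter rim.
Areas are pixel counts times squared pixel size; percent change is the
mean of per-animal percent changes, not the percent change of means
(the two differ, and only the former is consistent with paired
statistics on animals).

## Cohort experiment and statistics

`generateCohort()` draws a cohort mirroring the study layout — default
8 animals, the first 3 ex vivo, 6 with lateral and 2 (in vivo) with
dorsal-only pneumothoraces; anterior-posterior diameter
$\mathcal N(20.2, 2.3^2)$ cm, affected-side baseline
retro-diaphragmatic area $\mathcal N(62.8, 7.8^2)$ cm², control side
$\mathcal N(57.6, 10.3^2)$ cm², collapse fraction mean 0.205 (sd 0.035,
truncated to [0.05, 0.4]), lateral volumes uniform on 200–500 ml (the
studied range reaches down to 50 ml, but sub-200 ml gaps are thinner
than a usable ROI at the analysis grid; the two dorsal-only animals
draw 50–150 ml, where the lateral pleural line is not visible). Every
animal receives the dorsal collapse of its affected side — pleural air
accumulates dorsally in a prone animal regardless of where the pleural
line is seen — and lateral animals additionally receive the gas band.
In-vivo animals get a small step-correlated cardiac-edge perturbation
(amplitude 0.01 of the local intensity), which reproduces the
horizontal-streak motion artifact of live scans without biasing CNRs:
the ex-vivo/in-vivo CNR comparison stays non-significant, as in the
study.

Statistics are deliberately plain: Student's two-tailed paired t-test
on before/after areas, an unpaired two-tailed t-test for the
ex-vivo/in-vivo comparison, and exact two-sided power for the paired
test from the noncentral t distribution
(ncp $= (\mu_d/\sigma_d)\sqrt n$, df $= n-1$). No multiple-testing
correction is applied, matching the analysis being reproduced.

## Numerical choices and degenerate inputs

* Seeds: every stochastic stage takes an explicit integer seed; cohort
  seeds derive child seeds by fixed integer arithmetic below $2^{31}$,
  and repeated runs are bit-identical.
* Stepping-curve fit: closed-form normal equations on
  $(1, \cos\varphi_k, \sin\varphi_k)$; $a_1 \ge 0$ with the phase
  absorbing the sign; an all-zero series sets a per-pixel error flag
  that propagates to the gap mask. Fewer than 3 steps is rejected
  (three unknowns).
* Retrieval masks pixels whose reference modulation is below 5% of the
  image median (tile gaps, dead pixels); masked pixels are NA and any
  ROI touching them errors rather than silently averaging.
* Ellipse rasterization uses pixel-center ownership; truth areas are
  exact by construction, and drawn target areas are met to
  rasterization accuracy (sub-percent at the analysis grid).
* `airVolumeMl = 0` and `collapseFraction = 0` are exact identities;
  `amplitude = 0` motion artifact and an empty gap list return the
  input unchanged.

## Problem sizes

The acceptance-style experiments run 20 cohorts (seeds derived from one
base seed) at the half grid: 120 lateral animals for the CNR grand
means, 160 animals for the area statistics, a few minutes on one CPU.
Structural and property tests run on coarser grids (1.4–2 mm pixels)
where a full phantom–scan–retrieve–segment cycle takes well under a
second.

## Known limitations

* The calibration reproduces cohort-level summary statistics; per-image
  realism (rib texture, diaphragm shape, heart motion detail) is out of
  scope.
* The transmission CNR estimate is intrinsically noisy (anatomical
  noise with correlation length comparable to the ROI); even 120
  animals determine its grand mean only to a few percent. This mirrors
  the large printed spread of the real measurement.
* The linear volume-to-gap-width map is a stand-in; only monotonicity
  is anchored.
* The slot-scanning acquisition of the real prototype (30–40 s, pulsed
  tube) is collapsed into a static stepping model; its per-pixel
  weighting is not reproduced.

## A minimal session

```{r example, eval = FALSE}
co  <- generateCohort(nAnimals = 8, cohortSeed = 1)
res <- analyzeCohort(co)
res                      # show(): CNRs and area changes
cohortSummary(res)$cnr   # mean +- sd per modality/filter state

## closed-form pieces
powerPairedTTest(1.933, 0.734, n = 6, alpha = 0.05)  # 0.999
noiseEquivalenceFactor(3.25)                         # ~23.9
organDoseFromDap(0.5, 0.16)                          # 0.08 mSv
```
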