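---
title: "Methods: quantitative EEG stroke-severity indices and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative EEG stroke-severity indices and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegstroke)
```

## The problem

Prehospital stroke scales miss a substantial fraction of acute ischemic
strokes, including large-vessel occlusions that benefit most from rapid
endovascular treatment.  Cerebral ischemia slows the EEG in a graded,
lateralised way, so a few minutes of resting-state EEG from a low-cost
headband (four dry electrodes -- TP9/TP10 at the ears, AF7/AF8 frontal --
plus an on-board accelerometer and gyroscope) is a plausible triage
instrument.  This package implements the complete analysis chain for such
recordings: spectral estimation, symmetry and slowing indices, an
aperiodic-background fit, head-motion statistics, and bagged classification
trees scored out-of-bag, together with a synthetic-cohort generator so that
every stage is testable without clinical data.

## Spectral estimation

Power spectra are estimated with a complex Morlet wavelet of wavenumber 15
(cycles per Gaussian envelope) on a dense grid, by default 0.5--31 Hz in
0.1 Hz steps (306 frequencies).  At analysis frequency $f$ the envelope SD
is $\sigma_t = 15/(2\pi f)$ seconds; power is the squared magnitude of the
convolution, averaged over time.

Numerical choices:

* The convolution is evaluated in the frequency domain with the wavelet's
  analytic Gaussian transfer function (unit-energy normalization), zero
  padded so that circular wrap-around never exceeds $e^{-40}$ of the
  kernel peak at any retained sample.
* **Edge policy**: at each frequency the first and last
  $\lceil 3\sigma_t \cdot \text{rate} \rceil$ samples are dropped before
  averaging.  At 0.5 Hz this is ~14.3 s per side, which sets the minimum
  usable recording length (about 57 s for the default grid; a 3-minute
  session is comfortable).
* Absolute power units are arbitrary-but-consistent: every downstream
  index is a ratio, and the reference toolchain's internal scaling is
  unknowable, so only relative power is ever interpreted.

Band powers sum the grid bins in the *closed* intervals delta 1--3, theta
4--7, alpha 8--13, beta 14--20 Hz (21/31/51/61 bins on the default grid);
the inter-band gaps belong to no band.  Relative powers divide by the
four-band total.

## Symmetry and slowing indices

The pairwise-derived brain symmetry index compares homologous electrode
pairs frequency by frequency:

$$\mathrm{pdBSI} = \frac{1}{MN}\sum_{j=1}^{M}\sum_{i=1}^{N}
  \left|\frac{R_{ij}-L_{ij}}{R_{ij}+L_{ij}}\right|$$

with $R$, $L$ the right/left power spectral densities, $M$ pairs and $N$
in-band frequencies (1--30 Hz by default).  **Normalization** is a design
choice the source index leaves ambiguous: a raw double sum grows without
bound in $N$, while published values are well below 1, so the mean
($1/MN$) convention is the default and a raw-sum mode sits behind a flag.
Frequencies with $R+L=0$ are excluded from $N$.  The low/high split
boundary is not standardised; 10 Hz -- the crossover frequency where
stroke-related asymmetry changes sign -- is the default and is
configurable.  The posterior index uses TP9/TP10 only; the frontal index
uses AF7/AF8 only.

Slowing ratios are DAR $=\delta/\alpha$ and DTABR
$=(\delta+\theta)/(\alpha+\beta)$ on summed band powers.  A zero
denominator raises a degenerate-spectrum error rather than returning
infinity.

**Contralateral scope.**  Ischemic slowing expresses over the lesioned
hemisphere, and clinical deficits are contralateral to it.  The
"contralateral" DAR/DTABR predictors therefore use the posterior channel
over the lesioned hemisphere (left lesion $\to$ TP9).  Controls have no
lesion side; they use the mean TP9/TP10 spectrum.  This resolution makes
the severity effect recoverable end-to-end and is validated against the
generator's analytic band-power oracle.

## Aperiodic (1/f) fit

The aperiodic background $P(f) = 10^{b} f^{-\chi}$ is fit in log-log
coordinates over 0.5--30 Hz with a two-pass robust line: ordinary least
squares, then a refit using only points whose first-pass residual is
negative or at most the 40th percentile of the positive residuals.
Oscillatory peaks lie strictly above the background, so the second pass
discards them.  This deliberately replaces the reference peak-Gaussian
iteration of full spectral parameterization: acceptance is by slope
recovery on synthetic spectra (exact on pure power laws; $\le 5\%$ error
under a 10$\times$ alpha peak; beats single-pass OLS on seeded random
spectra), not numeric identity with any external implementation.

## Motion features

Per axis and sensor: RMS on the raw samples (DC retained, so accelerometer
RMS keeps the gravity component and hence posture information) and the
population SD.  The two are tied by $\mathrm{rms}^2 = \mathrm{sd}^2 +
\mathrm{mean}^2$, which doubles as a self-test.  Axis labels are passed
through, never interpreted.

## Classification

Bootstrap-aggregated CART trees (200 by default): each tree is fit on an
$n$-out-of-$n$ bootstrap resample with Gini-impurity splits, grown to
purity.  Hyperparameters the source method leaves unstated default to:
all features considered at every split (plain bagging; random-subspace
`mtry` available), minimum leaf size 1.  Evaluation is out-of-bag: each
participant is predicted by majority vote over the trees whose bootstrap
excluded them; ties break by class prevalence, then label order; samples
never out of bag (possible at very small tree counts) are flagged and
excluded from the confusion matrix.  Metrics are
$\mathrm{ACC}=(TP+TN)/(TP+TN+FP+FN)$, $\mathrm{SE}=TP/(TP+FN)$,
$\mathrm{SP}=TN/(TN+FP)$ -- the standard specificity, which reproduces the
published validation values; the variant denominator sometimes printed
($TN/(TP+FN)$) contradicts those same values and is not implemented.
The chance baseline is the majority-class relative frequency.

The three tasks map severity labels to: the 4-class severity problem;
stroke vs control; and moderate-or-large vs the rest (the triage-relevant
split).  Undefined metrics (zero denominators) are `NA`, never 0.

## The synthetic cohort: what it emulates, and what a green test means

Each channel is 1/f-filtered Gaussian noise (exponent $\chi = 1.5$, RMS
8 uV) plus narrowband oscillations (Gaussian mask, FWHM 1 Hz) at 2, 5.5,
10 and 17 Hz with RMS amplitudes 4/3/6/2 uV -- an eyes-closed,
alpha-dominant resting spectrum.  Severity scales the lesioned
hemisphere's channels: delta power $\times$ 1/1.5/2.5/4 and alpha power
$\times$ 1/0.8/0.6/0.4 across control/small/moderate/large.  Homologous
channels draw independent log-power jitters (SD 0.1) so symmetry indices
have realistic spread.  Demographics: ages uniform 19--91, genders
balanced, lesions 75% left among strokes, severity-graded clinical
scores.  Motion: accelerometer X-axis SD rises with severity
(0.020 to 0.060 g) and Z falls (0.060 to 0.020 g) around a 1 g gravity
mean on Z; Y and the gyroscope carry no group signal.  Magnitudes encode
only the reported *ordering* -- no published effect sizes exist for the
motion channels, so these are free parameters chosen once.

One numerical subtlety: shaped noise is scaled by its **expected** RMS
(analytic, from the shaping amplitudes), not the realization's RMS.
Normalizing each realization exactly would couple all frequencies to the
highly variable low-frequency draw of a $1/f^{1.5}$ process and inject a
spurious broadband asymmetry (~0.2 pdBSI) between homologous channels
that no amount of averaging removes.

What the generator does *not* emulate: eye-blink/EMG artifacts, the
headset's on-board filtering, electrode popping, inter-individual alpha
frequency variation, or any genuine neurophysiology.  A green end-to-end
test therefore establishes that the pipeline recovers effects *of the
stated form and size* from realistically noisy spectra -- not that the
classifier would attain any particular accuracy on clinical data.

## Session I/O

Delimited sessions use the MuseLSL CSV layout (per-stream files with a
timestamp column; `meta.json` for rates and condition).  Timestamp repair
is deterministic: duplicates keep the first sample; jitter and sub-50 ms
gaps are linearly interpolated onto the nominal grid; a gap of 50 ms or
more is treated as a connectivity dropout and the session is rejected
(dropout sessions are excluded from analysis; published exclusion criteria
are unstated, so the threshold is this package's own).  Vendor electrode
shorthand (A7/A8/T9/T10) is canonicalised to AF7/AF8/TP9/TP10 on input;
TP9/TP10 are mandatory, the frontal pair optional (frontal contact
commonly fails; the frontal pdBSI is then `NA` and is imputed by the
cohort median at design-matrix time, with the imputation flagged).
EDF files are written as 16-bit, one-second records; the true duration is
stored in the reserved header field so read-back trims record padding,
and the serialized physical range is reused for digitization so round
trips are exact to one quantization step.

## Time-budget scale-downs in the test suite

Monte-Carlo tests use 30--160 s recordings rather than the 180 s default:
the 1 Hz wavenumber-15 wavelet needs about 29 s of support, and the
generator's severity structure is duration-free, so shorter recordings
change only estimator variance.  The frozen full-duration bound (control
pdBSI < 0.05 at 180 s with zero asymmetry noise) is checked once.
Pipeline tests run a 10-participant cohort at 40 s on a 1--21 Hz grid.

## Known limitations

* The aperiodic fit models no peak parameters (centers/widths/heights);
  the revised-BSI variant is not provided.
* EDF support covers the subset of the format this package writes
  (16-bit, per-second records, integer rates); it is not a general EDF+
  reader.
* The published patient-level results are not reproducible (no public
  data); published confusion counts and cohort tables are reproduced
  exactly, everything else is validated by construction on synthetic
  data.
* At cohort sizes around 25, OOB estimates carry large variance; the
  pipeline reports counts alongside metrics so that is visible.
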