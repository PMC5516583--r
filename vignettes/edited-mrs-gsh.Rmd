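---
title: "Edited-MRS glutathione quantification: models, simulation conditions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edited-MRS glutathione quantification: models, simulation conditions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gshmrs implements a desk-scale version of a longitudinal edited magnetic
resonance spectroscopy (MRS) study of brain glutathione (GSH): simulated
MEGA-PRESS and PRESS acquisitions, the processing and fitting chain that
turns raw transients into per-scan GSH/Cr ratios and water-referenced
absolute GSH, and the cohort-level statistics (imputation, differences
versus baseline, repeated-measures ANOVA with Holm–Šidák comparisons).
This vignette is the package's own account of the models it uses, the
study conditions its synthetic cohort encodes, and the design decisions
taken where the underlying methods left choices open.

## The signal model

A free induction decay (FID) is modelled as a sum of damped complex
exponentials plus white complex Gaussian noise,

$$ s(t) \;=\; \sum_k a_k\, e^{i\varphi_k}\, e^{(2\pi i\,\Delta f_k - d_k)\,t} \;+\; \varepsilon(t), $$

sampled at the dwell time $1/\mathrm{SW}$ with $\mathrm{SW} = 2000$ Hz and
2048 points (repetition time 2000 ms, echo time 122 ms for the edited
protocol; 36 ms, 64 averages for short-echo PRESS). Offsets
$\Delta f_k$ are chemical shifts relative to water at 4.7 ppm on a
127.7 MHz (3 T) instrument; $d_k$ is a Lorentzian decay rate in Hz, so
the frequency-domain full width at half maximum is $d_k/\pi$ Hz. The
discrete Fourier transform is scaled by the dwell time, which makes peak
integrals independent of zero-filling and keeps Parseval's identity in
integral form; the pipelines halve the first FID sample (trapezoid-rule
first-point correction) so the discrete transform matches the continuous
lineshape without a constant baseline offset.

Spectral editing alternates acquisitions with the editing pulse on the
GSH cysteinyl α-CH resonance (ON) and applied symmetrically about water
(OFF). Edited lines appear at full amplitude $a$ in ON and at
$a(1-e)$ in OFF, so the difference retains $a\,e$ with editing
efficiency $e = 0.74$ by default (a conventional value; quantification
divides the fitted difference area by the efficiency it assumes).
Background lines — creatine (Cr) at 3.03 ppm, GABA-like 3.01 ppm,
aspartate-like 2.82 ppm, and the large common NAA/choline/myo-inositol
peaks — are identical in both sub-spectra and cancel. Four co-edited
contaminants at 2.82, 3.01, 3.10 and 3.26 ppm survive with their own
efficiencies; their default amplitudes put them at roughly a third to a
half of a typical edited GSH amplitude. The edited GSH resonance itself
is rendered as a narrowly split doublet (0.02 ppm) about 2.95 ppm — the
edited multiplet is not a clean singlet — which also makes the
single-Gaussian area convention used for GSH match the creatine singlet
convention (the noiseless round trip recovers the true ratio to about
0.1%, versus −9% for a pure Lorentzian singlet).

Simulation is deliberately lightweight: lines are phenomenological
Lorentzians, not density-matrix simulations of J-coupled spin systems,
and there is no field-inhomogeneity or eddy-current modelling.

## Processing chain

The edited pathway applies 3 Hz exponential line broadening per stored
average, frequency- and phase-aligns the individual transients, averages
per condition, zero-fills (×2), transforms, and applies a common
zero-order phase taken from the creatine peak of the OFF spectrum.
Alignment is spectral registration in the time domain against the median
transient: for each transient the optimal zero-order phase at a given
frequency shift is analytic, and a grid-plus-refine search finds the
shift. A soft Gaussian notch centred at 2.95 ppm (σ 0.12 ppm) removes
the edited region from the *registration* signals only: content that
legitimately differs between ON and OFF must not steer a correction that
is applied rigidly to the whole spectrum, because even a millihertz-scale
systematic ON–OFF offset leaks the large creatine singlet into the
difference spectrum at amplitudes comparable to the GSH peak. This is
also why the packaged difference spectra subtract cleanly without a
further pairwise micro-alignment: a rigid pairwise fit on the creatine
core proved worse, since it trades creatine cancellation against the
in-band co-edited tails (their dispersive components bias both the
shift and the phase estimate).

The PRESS pathway removes residual water by a time-domain subspace
decomposition (Hankel-SVD): poles are estimated from the leading FID
samples, and components inside 4.4–5.0 ppm are subtracted — at most
eight, only those decaying (damping capped below 60 Hz, since very
broad poles model the spectrum-wide offset rather than water) and only
those clearly above the noise, because the subspace method happily fits
pure-noise exponentials whose subtraction perturbs the metabolite
region. Then zero-fill, 1.1 Hz dampening, and zero- and first-order
phasing.

## Quantification models

The difference spectrum is fitted over 2.6–3.3 ppm with a 5-Gaussian
model (components initialised at 2.82, 2.95, 3.01, 3.10 and 3.26 ppm,
centres bounded ±0.02 ppm, widths 0.006–0.03 ppm, GSH amplitude
constrained non-negative, three fixed width starts for determinism) plus
a linear baseline, by trust-region Levenberg–Marquardt with analytic
Jacobians. GSH quantification defaults to the *simple* single-Gaussian
fit of the GSH peak computed after subtracting the resolved (≥0.1 ppm
away) co-edited components of the 5-Gaussian model; components
overlapping the GSH line would trade area with it, so they are left to
the simple fit's own baseline. Both areas (simple and 5-Gaussian GSH
component) are reported. The creatine reference is fitted from the mean
OFF sub-spectrum with a Gaussian at 3.03 ppm, a tightly bounded
companion at 3.19 ppm absorbing any choline edge, and a linear baseline;
the unresolvable 3.01 ppm signal is deliberately *not* modelled, because
an extra component there trades area degenerately with creatine.

The fit error is the standard deviation of the fit residual over the
analyte-peak region (centre ±0.1 ppm) expressed as a percentage of the
fitted peak amplitude; 0.19 residual SD on a 0.5 amplitude is a 38% fit
error. Detectability uses a linear matched-filter z-statistic: the
shape-weighted mean of the difference spectrum over the GSH core minus
the flank mean, divided by the empirical SD of the identical statistic
at ~200 signal-free centres. Because the statistic is linear in the
data, its null distribution is Gaussian and the threshold (z ≥ 4.5)
self-calibrates to whatever noise correlation the processing induced.
A rule thresholding the fitted Gaussian amplitude was rejected: a
non-negative, centre-searching fit returns 2–3 noise SDs on pure noise,
which cannot separate truly absent peaks from the smallest real ones.
GSH is undetectable when z < 4.5 or the fit error exceeds 200%.

PRESS spectra are fitted as a non-negative linear combination of a
self-consistent basis (each metabolite simulated at 1 IU and processed
identically) plus a free quadratic baseline. Concentration uncertainties
are reported as Cramér–Rao-style percent bounds from the linear-model
covariance *under the frequency-domain noise correlation induced by
zero-filling and exponential dampening* — assuming white frequency noise
would understate the variance several-fold — with the marginal noise SD
taken from a signal-free downfield region. Quality control follows the
standard gates: creatine linewidth ≤ 0.1 ppm, SNR ≥ 5, creatine CRLB
< 20%.

Water referencing scales the fitted creatine area to the unsuppressed
water peak extrapolated to zero echo time with the water T2 estimated
from two echo times ($T_2 = \Delta TE / \log(S_a/S_b)$), multiplied by a
water concentration-equivalent of 55,510 × 0.7 (tissue-water
attenuation), giving institutional units (IU) approximating mmol/l; the
whole pathway is invariant to receiver gain. Both area conventions
integrate essentially the complete line (a wide window on the isolated
creatine singlet for the unit area; 2.2–7.2 ppm for the pure water
scan), so the capture fractions cancel. The partial-volume correction is
$C_{\text{corrected}} = C_{\text{measured}} / (1 - f_{\text{CSF}})$:
CSF contributes negligible metabolite signal, so the measured
concentration is diluted by the non-tissue fraction and corrected
upward; no metabolite-T2 or further tissue-water correction is applied
beyond creatine's. Absolute GSH is the GSH/Cr ratio times the corrected
creatine concentration.

## Statistics

Undetectable *baselines* are all assigned the same value — the lowest
measured GSH/Cr ratio across all subjects and scans, divided by 2;
non-baseline undetectables are excluded, not imputed, and detectable
measurements are never altered. Scans are grouped by post-dose ordinal
index, labelled by the mean (SEM) of their midpoints, and differenced
against each subject's baseline. The omnibus test is a one-way
repeated-measures ANOVA; with unbalanced data (dropped scans, subjects
with three rather than four post-dose scans) the primary analysis is the
general-linear-model form with subject as a blocking factor on all
available data (a complete-case variant is available); on complete
balanced data this reduces exactly to the classical within-subject sums
of squares, and in the two-condition case to the squared paired t
statistic. Each post-dose bin is compared with baseline by a paired t
test on the subjects contributing both, with step-down Šidák (Holm–Šidák)
adjustment over that family of four comparisons and significance flags at
α = 0.05. The percent change from baseline to the final reported bin uses
the ratio-of-means × 100 convention (0.0457 against 0.0170 prints as a
"269% increase"); the ratio-minus-one convention is also returned, since
the wording of such percentages is genuinely ambiguous.

## The synthetic cohort

The default cohort encodes the study conditions: 15 subjects; one
baseline scan each; six subjects with three post-dose scans, eight with
four, one with five (70 edited scans); reference PRESS and two-echo
water acquisitions once per subject at baseline, which is when the
protocol acquires them; six subjects with baseline GSH below
detectability; and exactly one randomly chosen subject's second
post-dose scan corrupted with 10× noise. Scan midpoints are drawn near
7.5, 19.9, 32.0 and 44.7 min; per-bin true means are 0.0170, 0.0259,
0.0364, 0.0385 and 0.0457 (the single fifth-scan bin extrapolates to
0.050 at ~57 min and is reported only when two or more subjects
contribute). Subject covariates: CSF fraction normal (mean 0.17, SD
0.049) truncated to 7–25%, CSF-corrected creatine normal around 6.09 IU,
water T2 around 80 ms, and a per-scan receiver gain in 0.85–1.15 that
everything downstream must be invariant to.

Post-dose truth follows
$x_{it} = \mu_t + \rho_t (b_i - \mu_0) + \varepsilon_{it}$ with baseline
$b_i$ (detectable draws truncated to ≥ 0.012; undetectable draws uniform
below 0.001), persistence $\rho_t = (0.25, 0.45, 0.45, 0.3)$ and
within-subject SDs $(0.0144, 0.012, 0.011, 0.016)$, floored at 0.010.
Two calibrations deserve an honest note, both made once and frozen:

* **Within-subject spread.** Back-solving the reference per-bin SEMs of
  the levels *and* of the differences-versus-baseline yields per-scan
  SDs of roughly 0.014–0.036 with low persistence. Under those values
  the omnibus test reaches p < 0.001 in only about half of replicate
  cohorts — a single observed realisation cannot constrain both. The
  defaults above keep the first post-dose comparison non-significant
  (mean difference 0.0089 against a difference SD near 0.02) while the
  later elevations and the omnibus test come out clearly, which is the
  study's inference pattern; they under-disperse the later bins relative
  to the reference SEM columns.
* **Noise level and fit error.** The reference mean fit error of 38%
  cannot coexist with the reference bookkeeping inside this processing
  chain: 3 Hz broadening correlates frequency noise over ~6 Hz, so the
  narrow analyte-region fit absorbs nearly all noise, and any noise
  level high enough to produce 38% fit errors would push every ratio
  below ~0.02 past a 50% fit error, contradicting the reference minima
  near 0.008. The default per-average noise SD (0.01) is instead set so
  the detection boundary sits between the undetectable band (< 0.001)
  and the smallest detectable values (≥ 0.010) with > 3.5σ margins on
  both sides, making the 70-acquired / 63-analyzed bookkeeping
  deterministic in practice; cohort fit errors then run at ~4–10%. The
  38% figure survives as the arithmetic instance of the definition and
  as the elevated-noise regime of the recovery simulations.

What passing tests on this cohort do *not* show about real data: the
generator has no macromolecular background, no baseline drift or
eddy-current distortion, no frequency drift beyond rigid per-transient
jitter, phenomenological lineshapes, and co-edited contamination far
tamer than a worst-case in vivo difference spectrum. Accuracy statements
(e.g. ratio recovery within a few percent) are statements about this
model, not about in vivo accuracy.

## Problem sizes and numerics

Simulation studies use sizes chosen for a single CPU: the replicate
inference study runs the full spectral pipeline on cohorts with one
stored ON/OFF pair per scan, with the per-average noise scaled by
$\sqrt{n_\text{pairs}}$ so the per-scan effective noise is identical to
the 8-pair default, and with transient jitter off (registration has its
own recovery tests); recovery and CRLB simulations use 200 seeds.
Optimizer settings are fixed (three width starts, analytic Jacobians,
tolerances 10⁻¹¹) so identical inputs give identical fits; all cohort
randomness flows from a single integer seed. Degenerate inputs are
handled explicitly: empty peak lists simulate silence, equal echo times
or non-decaying water areas make the T2 unidentifiable (flagged),
rank-deficient bases and failed decompositions abort or pass through
with a warning flag, and a cohort with no detectable measurement
anywhere aborts imputation with a data error.
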