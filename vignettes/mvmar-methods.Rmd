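---
title: "Methods: MV-CBCT-driven metal artifact reduction and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MV-CBCT-driven metal artifact reduction and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvmar)
```

## The problem and the approach

Kilovoltage CT around metal implants suffers from beam hardening and
photon starvation: rays that traverse metal arrive at the detector with
a spectrum so hardened and a signal so weak that the log-transformed
projections become inconsistent, and filtered back-projection (FBP)
turns the inconsistency into bright/dark streaks. Those streaks corrupt
the Hounsfield units (HU) that a treatment planning system converts to
relative electron density (RED), and hence corrupt dose.

Megavoltage cone-beam CT (MV-CBCT), acquired at ~6 MV, is essentially
immune: at megavoltage energies Compton scattering dominates for every
material, so there is no spectral differentiation to harden and metal is
far less opaque. The price is heavy quantum noise, compressed
soft-tissue contrast, and a truncated HU scale (the package caps MV at
1400 HU). `mvmar` implements the resulting MAR recipe:

1. clip the MV image at 1400 HU;
2. translate it into a synthetic CT (sCT) with a cycle-consistent
   generative translator, once per intensity scaling (P1, P2, P3);
3. fuse the three candidates by HU range;
4. segment metal as the intersection CT > 2500 HU and MV > 300 HU, and
   copy the original CT values back onto those pixels.

The dual threshold matters: bright kV streaks can exceed 2500 HU, but
they have no counterpart in the MV image, so requiring MV > 300 HU
rejects them while true metal (bright in both) survives.

## Intensity scalings

Network inputs are scaled into $(-1, 1)$ by
$x = \tanh\!\big((\mathrm{HU} - s)/d\big)$ with per-modality constants:

| method | MV-CBCT $(s, d)$ | CT $(s, d)$ | emphasis |
|--------|------------------|-------------|----------|
| P1 | (0, 400) | (0, 400) | whole range |
| P2 | (0, 150) | (0, 300) | soft tissue |
| P3 | (800, 400) | (1600, 960) | bone and high HU |

The P3 constants are read as $\tanh((\mathrm{HU}-800)/400)$ and
$\tanh((\mathrm{HU}-1600)/960)$: the subtraction applies to the HU value
before division, the only dimensionally coherent reading. The inverse is
$\mathrm{HU} = s + d\,\mathrm{atanh}(x)$; inputs with $|x| \ge 1$ (a
saturated generator output) are clamped to $\pm(1-10^{-7})$ first so the
inverse stays finite, while legitimate values arbitrarily close to 1 are
left untouched — at the extreme of the clamped range (P2 on MV,
$\tanh(1400/150)$) the scaled value sits within $2\times10^{-8}$ of 1
and still round-trips to better than 0.1 HU. Candidate fusion operates
in the HU domain after inversion (the HU-banded evaluation supports this
reading), with half-open bands: P2 below 400 HU, P1 in $[400, 800)$, P3
at and above 800 HU, classified by the P3 candidate's HU (configurable;
P3 is the scaling that performs best at high HU, where the band decision
matters). The bands partition the axis, so every pixel comes from
exactly one candidate.

## The phantom simulator

No clinical images ship with the package; the simulator is the study
population. `make_phantom()` paints a head-like slice — elliptical head
outline, mandible arc, seven teeth, oral cavity, two parotids, spinal
cord — with seeded size jitter and smooth soft-tissue texture, then
applies a 3×3 binomial blur so structures have a one-pixel
partial-volume transition (ideal step edges would dominate FBP error
with aliasing). Ground-truth HU: air −1000, soft tissue ≈ 25–60, mandible
≈ 900, teeth ≈ 1500; metal inserts carry their material HU pre-clamp
(aluminium alloy 3000, titanium alloy 3600, stainless steel 4200, paired
with RED 2.43 / 3.73 / 6.83 in the packaged calibration curves).

`simulate_kvct()` is polychromatic: a four-bin spectrum (50/70/90/110
keV, versioned in `inst/extdata/kv_spectrum_v1.csv`) with per-bin
hardening multipliers for bone and metal. The metal multipliers
(100/60/45/40) make implants nearly opaque across the whole spectrum, as
real steel and titanium are at diagnostic energies; with the default
fluence of $10^6$ photons per detector bin, rays through metal starve to
the one-count detector floor. Projections are water-precorrected (the
tabulated polychromatic water response is inverted, the standard
single-material scanner calibration), so metal-free soft tissue
reconstructs with a mean absolute error well under 40 HU while bone and
metal still project inconsistently — which is exactly what produces
streaks. Reconstruction is ramp-filtered FBP over 180 parallel-beam
angles; the ramp is built from its real-space kernel, whose correct DC
term removes the few-percent bias a naive $|f|$ filter leaves. An
apodized (Hann) ramp was evaluated and rejected: it trades noise for
resolution loss whose mid-frequency bias inflates the artifact index
everywhere.

`simulate_mvcbct()` is monochromatic (no hardening, hence no streaks),
uses a lower fluence ($8\times10^5$ with a five-fold smaller attenuation
scale, giving roughly twice the kV noise standard deviation in uniform
soft tissue), and sees the kV truth through a fixed piecewise-linear HU
compression (`mv_compress_hu()`, soft-tissue slope 0.6, capped at 1400
HU) that mimics the distinct CT–ED characteristics of megavoltage
imaging. Scatter, detector response and cone-beam geometry are not
modelled; the simulator aims for the artifact phenomenology, not scanner
realism. Consequences for interpretation: passing tests demonstrate the
pipeline's correctness and the direction and rough magnitude of its
effects on data with kV-streak physics, not clinical performance on
patient images.

## The artifact index

"Streak severity" needs a number. Definition v1, used by every contract
in the package: take the error image (volume minus ground truth when
available), zero it outside the soft-tissue mask (so large bone/metal
residuals cannot bleed through the filters), band-pass it as the
difference of a 5×5 and a 21×21 box mean, and report the 5–95
inter-percentile spread over the 2-px-eroded soft-tissue pixels within
40 mm of metal (the whole soft-tissue mask when there is no metal). The
band-pass is the essential choice: raw spreads conflate FBP-correlated
noise (high frequency) and residual hardening shading (low frequency)
with streaks (mid frequency); both alternatives were measured and
rejected during design. Calibrated against 20 seeded no-metal phantoms,
the residual level is 16–19 (kV) and 13–16 (MV); the frozen no-metal
thresholds in `artifact_threshold_no_metal()` are 22 and 19. A steel
insert drives the kV index above 200 — an order of magnitude over
threshold — while the MV index stays below its no-metal threshold.

## The translator

The learned translator is a cycle-consistent adversarial pair: generators
$G_{MV\to CT}$ and $G_{CT\to MV}$ with patch discriminators on each
domain, least-squares adversarial loss plus $\lambda = 10$ times the L1
cycle loss, Adam with $\beta_1 = 0.5$. The clinical-mirror configuration
(`clinical_model_config()`) records the clinical-scale protocol — batch size
6, learning rate $2\times10^{-4}$ constant for 100 epochs then decayed
over 100 — for provenance. A stated decay of 1% per epoch is ambiguous
between geometric ×0.99 steps and a linear ramp; the default is the
canonical linear-to-zero schedule, with the geometric reading available
via `decay = "geometric"`.

The trainable default is the toy configuration: 64×64 slices, width-6
networks, batch size 1, learning rate $2\times10^{-3}$, 10 constant + 6
linear-decay epochs. Three design details matter at this scale and were
fixed after inspecting training dynamics on the synthetic benchmark:

* **He initialisation.** These small networks have no normalisation
  layers; with the common small-constant initialisation the activations
  shrink several-fold per layer and both networks freeze. He-scaled
  weights keep activation variance near 1.
* **Logit-residual generator.** The generator output is
  $\tanh(c(h) + \mathrm{atanh}(x))$ with the last convolution
  initialised near zero, so an untrained generator is the identity on
  the scaled domain and training perturbs identity instead of first
  recovering it through a saturating tanh.
* **Batch size 1.** Adam's per-step movement is bounded by the learning
  rate, so with only 100 training pairs the number of optimiser steps —
  not the gradient quality — limits what can be learned in minutes;
  batch 1 gives 16 × 100 steps, which suffices.

On the packaged benchmark (MV = fixed monotone compression of the CT
truth plus Gaussian noise, 100 pairs), training beats the identity
baseline's mean absolute HU error on held-out slices for every tested
seed. The deterministic `surrogate_translator()` ships alongside: a 3×3
median filter followed by the exact piecewise-linear inverse of the MV
compression. The median step is part of the surrogate's design because a
trained generator denoises as well as restores contrast, and the pure
inverse map would amplify MV noise by the inverse-contrast slope
(≈ 1.7). The `"identity"` surrogate passes scaled intensities through
untouched, giving a closed-form reference for the translate pipeline.

## Dosimetry

The toy dose engine deposits $\exp(-k \cdot d_\mathrm{rad})$ along each
of a configurable set of coplanar beams (default four at 0/90/180/270°),
where $d_\mathrm{rad}$ is the cumulative RED-weighted path length to the
voxel centre and $k = 0.005\,\mathrm{mm}^{-1}$ per unit RED; the summed
pattern is scaled to the prescription (6000 cGy) at a normalisation
point. No buildup, scatter or divergence — just enough physics that RED
errors move DVH metrics, and exactly verifiable against the closed form.

Gamma analysis is global: $\gamma$ at a reference point is the minimum
over test points of
$\sqrt{(\Delta r/\mathrm{DTA})^2 + (\Delta D/(p\% \cdot D_\mathrm{norm}))^2}$
with $D_\mathrm{norm}$ the reference maximum (prescription
normalisation by flag) and no low-dose cutoff by default. The search
enumerates grid offsets in order of increasing distance and stops when
the pure distance term exceeds the worst running minimum — a bound that
makes the result *exactly* equal to exhaustive search over all test
points, which the tests verify to $10^{-9}$. A fixed search radius would
not: where local dose differences are large, the true minimiser can lie
beyond any fixed multiple of the DTA. DVH metrics use interpolated order
statistics (`Dx` = dose exceeded by exactly x% of the ROI volume); slice
ROIs are assigned a 1 mm thickness for volume, and a structure smaller
than 0.1 cm³ reports `D0.1cc` as its maximum with a warning.

## Problem sizes and numerical choices

The shipped defaults are the study conditions everywhere: 128×128 slices
at 1 mm for simulation studies (256×256 is available), 180 projection
angles, 10-case MAR studies with half the cases carrying one 2.5–3.5 mm
insert, 20 no-metal seeds for the index calibration, and the toy
training setup above. Inverse-scaling clamp $\varepsilon = 10^{-7}$;
fusion bands half-open; metal-mask cleanup (morphological
small-component removal) off by default because the reference procedure
is pure thresholding; no feathering at fusion seams or the copy-back
edge. NIfTI I/O quantises to the nearest integer HU (int16), and the
minimal DICOM reader/writer covers single-frame Explicit-VR
little-endian CT slices only — no R DICOM package exists in the
dependency set, and the package's scope needs only rescale, spacing,
position and orientation handling. Deformable registration is out of
scope: synthetic pairs are intrinsically aligned, and real data must be
pre-registered.

## Known limitations

* The simulator omits scatter, cone-beam geometry and detector physics;
  its calibration curves are synthetic and labelled as such. None of the
  package's numbers are estimates of clinical performance.
* The toy translator demonstrates a learning signal, not image quality;
  its capacity is far below what slice-wise clinical translation needs.
* The surrogate translator is intensity-wise and cannot correct
  structured MV reconstruction error, which bounds the artifact-index
  reduction achievable without training.
* `D0.1cc` on single slices depends on the assumed slice thickness.
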