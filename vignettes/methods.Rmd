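---
title: "Simulating pulse waveforms with abdominal aortic aneurysm and estimating severity with an adversarially regularized CNN"
author: "PulseAAA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arterial model, cohort synthesis, features, CPAR network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

PulseAAA builds an end-to-end in-silico study of non-invasive abdominal
aortic aneurysm (AAA) screening from cuff pulse-volume-recording (PVR)
waveforms.  Four layers of machinery are involved:

1. a frequency-domain transmission-line model of the systemic arterial
   circulation, with the aneurysm inserted into the infrarenal abdominal
   aorta;
2. a synthetic-cohort generator that turns the model into labeled and
   unlabeled waveform datasets with inter-individual and sample-to-sample
   variability;
3. waveform feature extractors (carotid-femoral pulse wave velocity,
   carotid upstroke index, carotid area ratio, carotid oscillatory ratio)
   used for physiological plausibility analysis;
4. a one-dimensional CNN with continuous property-adversarial
   regularization (CPAR) that estimates the volumetric severity index
   (VSI) from brachial and tibial waveforms.

This vignette documents the models, their assumptions, the parameters that
matter, and the design decisions taken where the problem was genuinely
open.

# The arterial transmission-line model

Each of 55 arteries is a uniform, linear, lossy transmission line.  Per
unit length, the longitudinal impedance follows Womersley oscillatory-flow
theory,

$$Z'(\omega) = \frac{j\omega\rho/A}{1 - F_{10}(\alpha)},\qquad
  \alpha = r\sqrt{\omega\rho/\mu},$$

with $F_{10}$ the Womersley function built from Bessel functions
($J_1/J_0$ evaluated by a backward continued fraction for moderate
arguments and Hankel asymptotics for large ones), and the transverse
compliance is the thin-wall elastic value $C' = 3\pi r^3/(2Eh)$, implying
a local lossless wave speed $c=\sqrt{2Eh/(3\rho r)}$.  Terminal branches
carry three-element Windkessel loads $Z = R_1 + R_2/(1 + j\omega R_2 C)$.
Blood density and viscosity default to 1050 kg/m^3 and 4 mPa s.

The periodic solution is assembled per heart-rate harmonic (all harmonics
up to 40 Hz, below Nyquist of the 128 Hz output): a leaf-to-root recursion
computes every segment's input impedance (parallel combination at
bifurcations), the aortic-root pressure is $P=Z_\mathrm{in}Q$ for the
inflow harmonic $Q$, and forward/backward wave amplitudes propagate
root-to-leaf.  The mean (DC) component is solved separately on the
Poiseuille-resistance skeleton.  Because the solution is constructed in
the frequency domain it is periodic — i.e. at steady state — by
construction; records are 2 s at 128 Hz (256 samples).

Assumptions worth keeping in mind: linearity (no convective acceleration,
no pressure-dependent compliance), uniform segments, thin elastic walls
without viscoelastic damping (the only viscoelasticity in the pipeline is
the artery-tissue-cuff interface below), and idealized fusiform aneurysm
geometry (no intraluminal thrombus, no tortuosity or asymmetry).

## Anatomy and calibration

The default anatomy (`defaultArterialTree()`, also shipped as an editable
YAML table in `inst/extdata/`) follows the classic 55-artery multi-branch
layout, with aortic calibres set at modern adult-male ultrasound norms
(monotone taper from 1.45 cm at the ascending aorta to 0.90 cm at the
infrarenal segment).  The infrarenal abdominal aorta — the aneurysm host,
segment id 31 — spans the renal-to-inferior-mesenteric stretch at 9.0 cm
by 0.90 cm radius; a full-severity aneurysm therefore reaches a 4.5 cm
apex diameter, a clinically representative sac.  Terminal resistances are
sized from typical regional flow fractions so the net DC resistance gives
a mean aortic pressure near 95 mmHg at 5.25 L/min; terminal compliances
follow a distal time constant $R_2C$ of 1.4 s; the proximal Windkessel
fraction is 0.2.

Two global calibrations were fixed once, before any downstream analysis,
and are deliberate modelling choices rather than fitted values:

* `stiffnessScale = 1.7` scales all Young's moduli so that the cohort's
  carotid-femoral PWV spans roughly 5-15 m/s across the stiffness
  variability (0.7-1.6) and ages 40-80 — the physiological range the
  cohort is meant to cover;
* the age-stiffness slope (0.042/year, reference age 50) was derived from
  requiring that the age trend together with the stiffness variability
  covers that same span.

## Aneurysm insertion

The aneurysm is a raised-cosine dilation of the luminal area:
$r(x) = r_0\sqrt{1 + (A_{SL}/2)(1-\cos 2\pi(x+1/2))}$ for normalized
position $x\in[-1/2,1/2]$.  Its volumetric severity index normalizes the
volume excess by the maximum attainable value,
$\mathrm{VSI} = 100\,(l_{AAA}A_{SL}/2)/2.625$, which is exact because the
raised-cosine area integrates in closed form.  `insertAneurysm()` replaces
the host segment by a chain of healthy stubs plus 16 uniform cells whose
radii sample the profile at cell midpoints and whose wall stiffness is
scaled by $K_E$; with $A_{SL}=0$ and $K_E=1$ the chain is exactly
equivalent to the original uniform line, and halving the cell size changes
site pressures by well under 0.5%.

# Cohort synthesis

A subject is drawn as: age uniform on 40-80 y; eight inter-individual
variability (IIV) coefficients, uniform 0.8-1.2 for heart rate (nominal
75 bpm, hence 60-90), stroke volume (nominal 70 mL), lengths, radii,
thicknesses, terminal resistances and compliances, and uniform 0.7-1.6
for arterial stiffness; severity VSI uniform on 0-100% with the sac
length fraction drawn uniformly on $[\max(0.4,\mathrm{VSI}/100), 1]$ (the
lower bound keeps the area parameter within its ceiling of 5.25) and wall
stiffening $K_E$ uniform on 1.25-2.45, independent of geometry.  Age
enters through linear multipliers with the physiological directions:
lower stroke volume, longer proximal aorta, larger diameters, lower
compliance, higher resistance and stiffness with age.

Height is not an independent dial: it is defined as 170 cm times the
length-IIV coefficient, which makes it a genuine waveform-affecting
confounder (the anatomical size axis) — exactly what the adversarial
regularizer needs to be tested against.

Each recording applies sample-to-sample variability (SSV): every
circulation parameter is multiplied by an independent normal coefficient
(mean 1, SD 0.01), and the five viscoelastic cuff parameters are re-drawn
from lognormal distributions centred at the subject values with CV 0.01.
Subject-level viscoelastic parameters come from lognormal distributions
with medians $(E_{B1},E_{B2},\eta_B,E_T,\eta_T)=(1,4,0.2,1,0.1)$ in
normalized units and dispersion 0.2; the absolute PVR scale is arbitrary,
which is why the network standardizes each input row.

The ejection waveform is a half-sine of duration
$T_\mathrm{sys} = 0.34\sqrt{60/\mathrm{HR}}$ s.  The 0.34 scale puts the
left-ventricular ejection time at about 0.30 s for 75 bpm, matching
resting physiology; a shorter ejection (0.3 scale, the more common
textbook default, also available) places the systolic peak early enough
that aneurysm wave reflections frequently miss the upstroke entirely,
which we judged less realistic.

What the generator does *not* emulate: measurement noise, motion
artifacts, device transfer functions, arrhythmia, comorbidities
(diabetes, smoking, hypertension-specific remodelling), sex differences,
and non-idealized sac shapes.  Tests passing on this generator therefore
demonstrate internal consistency of the method under clean, idealized
physiology — not clinical performance.

# Waveform features

All four features are computed from a *canonical beat*: the record is
exactly periodic with known heart rate, so a least-squares harmonic fit
(`harmonicFit()`) recovers its Fourier series even though 2 s holds a
non-integer number of beats, and the folded beat is reconstructed on a
dense phase grid.  This removes beat-segmentation jitter, which otherwise
dominates within-subject feature variance on oscillatory records.
`detectBeats()` remains available for
raw records and anchors beats on the systolic upstroke, which is robust
to reflection-induced diastolic dips below the end-diastolic level.

* **cf-PWV**: intersecting-tangent feet (horizontal line through the
  diastolic minimum meets the tangent at the steepest upstroke point) of
  the carotid and femoral records; the transit time is the circular
  difference of absolute foot times, and the path length is the
  root-to-femoral minus root-to-carotid distance along the tree.
* **CUI**: the foot-to-peak upstroke is split at the index minimizing the
  pooled RMSE of two least-squares lines (ties toward the earlier index);
  the lines' intersection amplitude is bounded into the pulse range to
  guard against near-parallel fits; CUI is the peak-to-intersection
  amplitude over pulse pressure.  The systolic peak is the earliest local
  maximum within 2% of the global maximum, stabilizing beats whose early
  and late systolic shoulders nearly tie.
* **CAR**: diastolic over systolic area above the diastolic minimum,
  split at the systolic peak (no incisura detector; the split convention
  is configurable in the sense that the beat's peak index can be
  overridden).
* **COR**: ratio of harmonic energy at 3-8 times the fundamental to the
  energy below (the boundary harmonic belongs to the high band; DC is
  excluded by mean subtraction).

The age-sweep plausibility analysis (`ageSweepStatistics()`) reuses one
set of IIV combinations — five equally spaced levels per coefficient,
subsampled from the $5^8$ factorial — across every age, so age trends are
paired and direction checks are exact rather than statistical.

# The CPAR network

The estimator is a one-dimensional, AlexNet-style CNN.  Brachial and
tibial records are stacked as two rows of a (1, 2, 256) input; each row
is z-scored (PVR units are arbitrary).  Five dilated convolutions (kernel
5 then 3,3,3,3; stride 1; dilation 3; length-preserving padding) with
batch normalization and ReLU act along the width only, so the two rows
are processed independently until the latent stage.  A skip connection
joins layer 2 to layer 4, CBAM attention blocks (channel reduction 16,
spatial kernel 7) follow layers 3 and 5, and a 1x1 convolution to 32
channels plus 4-fold average pooling compress the features to a
(32, 2, 64) latent tensor.  Three parallel heads (64, 64, 1 fully
connected) map the flattened 4096-dimensional latent to the VSI estimate
and to the two adversarial targets; each head holds 266,433 parameters,
and the default channel widths (128, 256, 256, 256, 320) put the feature
extractor near 810,000.  Convolution layers carry no bias: batch
normalization directly follows, making a bias parameter exactly
redundant.

Training minimizes a joint objective: the VSI head descends the mean
squared label error on labeled batches; the height and age heads descend
their disturbance losses $\frac1N\sum\log\frac{1}{1-\tanh|e_i|}$ on
labeled and unlabeled batches (interleaved 1:1); the feature extractor
descends $L_L - \lambda(L_{D,H} + L_{D,A})$, i.e. it *ascends* the
adversaries' objectives (gradient reversal), learning representations
predictive of severity but uninformative about height and age.  Design
choices taken here, where the formulation was ambiguous:

* the adversarial sign: joint descent of all three losses by the feature
  extractor would cooperate with, not fight, the adversaries; the
  gradient-reversal form is the default and the cooperative form remains
  available (`trainingConfig(adversarial = FALSE)`);
* the disturbance error enters as an absolute value, keeping the loss
  bounded below, symmetric, and with gradients saturating at 2;
* height and age are z-scored over the training pool before entering the
  tanh (raw centimetres or years would saturate it immediately).

Each parameter set has its own Adam optimizer (batch size 16; the PVR
variant uses betas 0.95/0.95, lambda 6.5e-4 and learning rates 1.2e-3 /
1.1e-3 / 7.0e-4 for extractor / VSI head / adversaries; the arterial-BP
variant 0.989/0.970, 7.3e-4, 2.2e-4 / 3.6e-5 / 5.5e-6), with early
stopping on validation label loss (patience 25, at most 100 epochs) and
the best-validation checkpoint returned.  One master seed fans out to
initialization and data order, so runs are exactly reproducible; with
lambda = 0 the extractor/VSI-head trajectory is bit-identical to plain
supervised training.  Batch-normalization running statistics update on
labeled batches only, which keeps that equivalence exact.

The whole engine — im2col convolutions, batch-norm, CBAM, backward passes
and the in-place Adam kernel — is implemented in the package (R with two
small C++ kernels) and verified against central finite differences in the
test suite.  Numerical notes: ReLU subgradients at exactly zero are taken
as zero; channel/spatial attention argmax ties break toward the first
index; Adam updates parameter buffers in place, so all parameter arrays
are freshly allocated at initialization and deep-copied at checkpoint and
API boundaries.

# Evaluation conventions

Regression reports Pearson correlation, MAE and RMSE in %VSI, with
calibration summarized per true-severity decade bin (5-15% through
85-95%).  Detection fixes the ground truth by a labeling threshold
("positive" = reference VSI strictly above it) and, for the operating
point, sets the decision threshold equal to it; the threshold sweep walks
20-80% in 10% steps.  ROC and precision-recall curves sweep the decision
threshold over the predicted values; AUCs are trapezoidal, the PRC
baseline is the positive prevalence, and ties in the score are collapsed
to single operating points.  Ensemble summaries report mean and sample
(n-1) standard deviation over independently trained models; curves
aggregate vertically (over false-positive rate for ROC).

# Problem sizes used in the shipped analyses

The reference protocol trains on 200 patients x 100 recordings with an
equally sized unlabeled set, validates on another 20,000 records and
tests on millions.  The analyses shipped with the package use scaled
problem sizes chosen as sensible defaults for a single workstation: the
feature-severity analysis regenerates 10,000 single-recording patients;
the network demonstration trains on 150 x 4 labeled plus 100 x 2
unlabeled records with a 50 x 2 validation split and a 400-record test
set, with reduced channel widths (16, 24, 24, 24, 32) and at most 32
epochs.
Scaling down mainly costs regression accuracy (fewer subjects to span the
IIV space) and widens the spread of all reported metrics.

# Known limitations

* The transmission-line constitutive constants, the age-dependence
  slopes, and the viscoelastic parameter distributions are standard
  choices for this model family, not fits to a specific published
  dataset; with them, the feature-severity couplings reproduce the
  expected directions and ordering (CUI strongest, CAR weakest, PWV
  negative) but their absolute magnitudes depend visibly on reflection
  timing, i.e. on exactly these unpinned constants.
* The aneurysm is axisymmetric and thrombus-free; severity maps cleanly
  to volume, which real sacs violate.
* No measurement noise or device model is included, so detection metrics
  here are upper bounds on what the same pipeline could do on real cuff
  recordings.
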