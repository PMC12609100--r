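# PulseAAA

Screening for abdominal aortic aneurysm (AAA) today means imaging —
accurate, but operator-dependent and chronically under-used.  An aneurysm
also leaves a mechanical fingerprint on arterial pulse waves: the dilated,
compliant infrarenal segment slows the pulse and reflects part of each
wave back up the aorta.  PulseAAA is an in-silico laboratory for asking
whether that fingerprint is readable from signals a blood-pressure cuff
can record: it simulates arterial blood-pressure (BP) and cuff
pulse-volume-recording (PVR) waveforms across a synthetic cohort with
graded aneurysm severity, extracts the AAA-sensitive waveform features
used in the clinical literature, and trains an adversarially regularized
convolutional network to estimate severity from brachial and tibial
waveforms alone.

The package is aimed at cardiovascular modellers and biomedical-ML
researchers who need a fully reproducible, physiologically grounded
waveform generator with ground-truth severity labels, plus reference
implementations of the downstream analyses.

## What's inside

* **Hemodynamics** — a 55-segment linear transmission-line model of the
  systemic circulation: Womersley longitudinal impedance
  `Z' = (jωρ/A)/(1 − F₁₀(α))`, thin-wall compliance `C' = 3πr³/(2Eh)`,
  three-element Windkessel terminal loads, and a per-harmonic
  leaf-to-root impedance recursion with forward/backward wave
  propagation.  The anatomy ships as an editable YAML table.
* **Aneurysm geometry** — a raised-cosine luminal dilation
  `r(x) = r₀√(1 + (A_SL/2)(1 − cos 2π(x+½)))` of the infrarenal aorta,
  severity-indexed volumetrically: `VSI = 100·(l_AAA·A_SL/2)/2.625` %.
* **Cohort synthesis** — age-adjusted nominals (40–80 y), eight
  inter-individual variability coefficients (uniform 0.8–1.2; stiffness
  0.7–1.6, spanning ~5–15 m/s carotid-femoral PWV), per-recording
  perturbations (CV 1%), and viscoelastic artery–tissue–cuff transfer
  functions (standard linear solid at the arm, Voigt body at the ankle)
  turning BP into PVR.  Cohorts are `SummarizedExperiment` objects.
* **Features** — carotid-femoral PWV (intersecting tangent), carotid
  upstroke index, carotid area ratio, carotid oscillatory ratio, plus an
  age-sweep plausibility analysis and feature–severity correlation
  tables.
* **CPAR network** — a dilated 1-D CNN with CBAM attention, a skip
  connection, and three regressor heads; the feature extractor is trained
  to predict severity while *defeating* two adversarial heads that try to
  recover the subject's height and age from the latent features
  (continuous property-adversarial regularization).  The engine, from
  im2col convolutions to the in-place Adam kernel, is implemented in the
  package and gradient-checked in the tests.
* **Evaluation** — regression metrics, threshold-swept detection metrics
  (20–80% VSI), ROC/PRC construction, and ensemble aggregation.

## A worked example

Simulate a subject with a 60%-severity aneurysm and read the waveform
features:

```r
library(PulseAAA)

tree <- defaultArterialTree()
tree
#> ArterialModel with 55 transmission-line segments
#>   terminals: 24  (3-element Windkessel loads)
#>   sites: ascending_aorta, carotid, brachial, femoral, tibial, TL_31
#>   blood: density 1050 kg/m^3, viscosity 0.004 Pa s

spec <- aneurysmSpec(vsi = 60, lAaa = 0.8, kE = 1.8)
spec
#> AneurysmSpec: VSI 60.0% (lAaa = 0.800, aSl = 3.937, kE = 1.80, 16 cells)

aaa <- insertAneurysm(tree, spec)
p <- simulatePressures(aaa, aorticInflow(hr = 75, sv = 70e-6),
                       simSettings(), sites = c("carotid", "femoral"))
round(range(p$carotid), 1)
#> [1]  76.1 125.9        # diastolic/systolic carotid pressure, mmHg

path <- sitePathLength(aaa, "femoral") - sitePathLength(aaa, "carotid")
round(cfPwv(p$carotid, p$femoral, path, fs = 128, hr = 75), 2)
#> [1] 6.85               # m/s; the compliant sac slows the pulse

beat <- canonicalBeat(p$carotid, 128, 75)
round(c(cui = cui(beat), car = carRatio(beat),
        cor = corRatio(p$carotid, 75, 128)), 3)
#>   cui   car   cor
#> 0.271 3.353 0.083
```

A full study is three calls: `generateCohort()` for labeled / unlabeled /
validation / test datasets, `trainCpar()` for the network (modality
`"pvr"` or `"abp"`), and `evaluateSeverity()` for the metrics.
`extractFeatures()` + `featureSeverityCorrelations()` reproduce the
feature-level analysis.  A thin command-line wrapper with `generate`,
`features`, `train` and `evaluate` subcommands lives in
`inst/scripts/pulseaaa.R`.

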