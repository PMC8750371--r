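---
title: "Quantifying metastatic burden and treatment response on longitudinal FDG PET/CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying metastatic burden and treatment response on longitudinal FDG PET/CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petResponse)
```

## The problem

Patients with metastatic breast cancer are monitored with whole-body
^18F-FDG PET/CT over repeated acquisitions. Once the metastatic lesions
have been segmented (manually or by an automatic method), the clinical
questions become quantitative: how much metabolically active disease is
there, where is it, and did it respond to treatment between baseline and
follow-up? petResponse implements that post-segmentation pipeline: value
normalisation (SUV/SUL), four imaging biomarkers, segmentation-quality
metrics, and the longitudinal response statistics, together with a
synthetic phantom cohort that exercises every stage with exact ground
truth.

The package deliberately stops at the segmentation boundary: producing
lesion masks (deep networks, expert contours) and registering serial
acquisitions are upstream tasks. Every inter-volume operation requires
identical lattices and fails loudly otherwise; nothing is silently
resampled or registered.

## Value normalisation

PET voxels store an activity concentration $C$ (Bq/mL). The standardized
uptake value normalises it by injected activity $A$ (Bq, decay-corrected
to scan start) and body weight $W$ (g):

$$\mathrm{SUV}_{BW} = \frac{C \cdot W}{A}.$$

The PERCIST uptake quantity instead normalises by lean body mass from
the Janmahasatian anthropometric model,

$$\mathrm{LBM}_{female} = \frac{9270\,W}{8780 + 244\,\mathrm{BMI}},
\qquad
\mathrm{LBM}_{male} = \frac{9270\,W}{6680 + 216\,\mathrm{BMI}},$$

so that $\mathrm{SUL} = \mathrm{SUV}_{BW} \cdot \mathrm{LBM}/W$. The
coefficients above are the single source of lean body mass in this
package. Whether the injected activity was decay-corrected to injection
or acquisition time is a property of the input data that the package
cannot infer; the manifest contract makes it the caller's
responsibility, and no decay chain is computed.

`clipSUV()` reproduces the [0, 5] SUV window used when images are fed to
a segmentation network (an SUV of 2.5 being a common malignancy
threshold, the window preserves the contrast that matters for
delineation). It is exposed for that preprocessing role only: all
biomarkers are computed from unclipped volumes, because clipping at 5
would corrupt the SULpeak and TLG of hot lesions.

## The four biomarkers

**SULpeak** (`sulPeak()`): a 1.2-cm-diameter sphere (~1 mL) is centred
on every voxel of the segmentation; the highest sphere-mean SUL is
retained. Two discretization choices matter and are fixed here: a voxel
belongs to the sphere when its *centre* lies within 6 mm (inclusive) of
the candidate centre, measured in world millimetres (correct for
anisotropic voxels); and the sphere is *not* restricted to the
segmentation — only its centre is — so the retained VOI is legitimately
not always centred on the hottest voxel. On a 2 mm isotropic grid the
inclusive rule yields the stable 123-voxel sphere. Spheres reaching
beyond the image border are truncated to existing voxels rather than
left undefined. SULpeak is one value per acquisition, over the pooled
segmentation of all lesions.

**TLG** (`lesionStats()`): lesions are individualised by
connected-component labeling (default 26-connectivity, so diagonal voxel
chains that an expert would outline as one lesion stay one lesion; 6 and
18 are available). Per lesion, $\mathrm{MTV}$ is voxel count times voxel
volume (mL), $\mathrm{SUV}_{mean}$ the arithmetic mean over the lesion's
voxels, and $\mathrm{TLG} = \mathrm{MTV} \times \mathrm{SUV}_{mean}$,
summed over lesions for the per-patient total. Following the
conventional attribution, TLG uses the body-weight SUV while SULpeak
uses SUL — both volumes are inputs to `biomarkerPanel()`.

**PBI and PLI** (`petBoneIndex()`, `petLiverIndex()`): percent of the
bone (liver) volume occupied by bone (liver) lesions. A lesion is
assigned to an organ when strictly more than half of its voxels fall
inside the organ mask, with bone taking precedence over liver should
overlapping organ masks make both exceed the majority. A lesion
straddling an organ boundary contributes its *full* volume to the index
by default — the assignment is per lesion, keeping the numerator in
lesion-volume units — with `volumeWithin = "intramask"` as the
alternative reading. Empty organ masks make the index undefined and
raise an error rather than returning 0.

An empty segmentation yields a panel with zero volumes and an
NA-flagged SULpeak rather than an error: follow-ups with complete
response are a normal, informative outcome.

## Segmentation evaluation

`diceScore()` is the usual $2|A\cap B|/(|A|+|B|)$; when both masks are
empty it returns 1 with a `degenerate` flag (keeping cohort means
defined while letting callers exclude those cases). `diceSummary()`
reports both the per-acquisition mean (each acquisition weighs equally,
so it is most sensitive to errors on acquisitions with few or small
lesions) and the pooled global Dice (most sensitive to errors on large
lesions).

`detectionCounts()` implements the 50 %-overlap lesion detection rule:
a ground-truth component is detected (TP) when at least half of it is
covered by the pooled prediction, otherwise FN; a predicted component is
a false alarm (FP) when strictly less than half of it is explained by
the pooled ground truth. The boundary semantics differ on purpose
("greater or equal" on the truth side, "less than" on the prediction
side) and both denominators are the component's own volume — the
prediction-side denominator is left implicit in common statements of the
rule, and the component's own volume is the reading consistent with the
detection literature this rule descends from; it is configurable in
spirit by symmetry of the implementation. Overlap is always measured
against the pooled opposite mask, not a best-matching single component.

## Response assessment

Each biomarker change is
$\Delta = 100\,(\mathrm{FU} - \mathrm{BL})/\mathrm{BL}$ percent. Zero
baselines occur naturally for PBI/PLI; the declared policy is
$0 \to 0$ gives 0 % and $0 \to$ positive gives $+\infty$ (new-lesion
appearance), both flagged, with the $+\infty$ sentinel always classified
non-responder. When a follow-up segmentation is empty, the pipeline
treats the disappearance as a $-100\,\%$ SULpeak change so that complete
responders are not dropped from the ROC analysis.

PERCIST expert categories are binarized: CR and PR are responders, SD
and PD non-responders. The ROC uses every observed $\Delta$ as a
candidate threshold (no midpoint interpolation), responders as the
positive class, and the orientation *call responder when
$\Delta \le t$* — response is a decrease. On this construction the
trapezoidal AUC equals the Mann-Whitney pair-counting estimator exactly,
which the tests assert. The operating point maximises Youden's
$J = \mathrm{sens} + \mathrm{spec} - 1$ over observed thresholds, ties
broken toward the most negative $\Delta$ (the most conservative
responder call). Whether sensitivity refers to the responder or
non-responder class is a convention; here responders are the positive
class throughout.

Correlated AUCs are compared with the paired DeLong test via placement
values; the degenerate self-comparison returns $z = 0$, $p = 1$ exactly.
Agreement between two measurement routes of the same biomarker uses
Lin's concordance correlation coefficient with population (1/n) moments,
following Lin's original estimator (sample moments available), plus
Spearman rank correlation and the Wilcoxon signed-rank test.
Kolmogorov–Smirnov normality checks use the sample's own moments. All
tests are two-sided and the reporting layer applies a significance level
of 0.001; the statistics themselves never threshold.

## The synthetic phantom

`phantomSpec()` defines a stylised whole-body acquisition: a
96 × 96 × 192 grid at 3 mm isotropic spacing (a typical whole-body PET
lattice), an elliptic body at background SUV 1.0, a liver ellipsoid at
SUV 2.0, a spinal column and pelvic bar as the bone compartment, and a
Poisson(8) number of non-overlapping spherical lesions with diameters
8–40 mm and amplitudes SUV 3–15, placed in bone, liver or soft tissue
(probabilities 0.5/0.2/0.3, reflecting the bone-dominant metastatic
pattern of breast cancer). Acquisition physics is reduced to a 6-mm
FWHM Gaussian point spread function and additive Gaussian noise
(sd 0.05 SUV, clipped at 0).

Follow-ups rescale each lesion's amplitude and volume by planted
response factors from which the PERCIST label derives: CR removes all
lesions; PR multiplies SUV by U(0.3, 0.6) and volume by U(0.4, 0.8); SD
draws both near 1; PD grows lesions (SUV × U(1.1, 1.4)) and usually adds
a new one. Half the cohort responds; 20 % of responders are CR and half
of non-responders PD; 75 % of patients have a second follow-up, matching
a cohort where most patients are imaged twice after baseline. Patients
are always female with weight, height and injected activity drawn from
plausible clinical ranges (55–90 kg, 1.50–1.85 m, 200–350 MBq); phantoms
are generated directly in SUV space, with the metadata carrying the
nominal dosimetry so the activity-to-SUV conversions are exercised by
their own unit tests rather than by pretending to model scanner
calibration.

Ground truth is the *pre-PSF* lesion support: experts outline lesions,
not point-spread tails, and this choice keeps detection metrics
meaningfully below 1 under degradation. Truth biomarkers are computed
from the piecewise-constant pre-noise model, so on a noiseless, PSF-free
phantom the measured panel must reproduce them exactly (MTV to within a
voxel, TLG to relative 1e-6, PBI/PLI exactly) — an acceptance test
enforces this. Lesions are placed with a separation margin wide enough
that their discrete supports remain distinct 26-connected components
even after PD growth, which keeps the truth bookkeeping and the measured
labeling in one-to-one correspondence.

Because no segmentation network exists inside the package, the study
replica simulates an imperfect automatic segmentation
(`perturbMask()`): per-lesion one-voxel erosions/dilations, a drop
probability for small components (mimicking missed low-contrast
lesions), and occasional spurious blobs inside the body. This produces
non-trivial Dice/detection values and realistic manual-vs-automatic
concordance behaviour, but it is a *statistical* stand-in: it does not
model the spatially correlated errors, contrast dependence or
systematic biases of a trained network, so passing tests validate the
measurement and statistics machinery, not any segmentation method.

What the phantom does not emulate: anatomical realism (organs are
ellipsoids and tubes), CT Hounsfield realism (the CT channel is a coarse
density map used to exercise resampling), scanner reconstruction
artefacts, respiratory motion, or inter-observer segmentation
variability.

## Numerical choices and degenerate inputs

- Voxel indices are 1-based in R; world coordinates are
  `origin + (index − 1) · spacing`; all geometry (sphere membership,
  lesion placement, organ shapes) is evaluated in world millimetres.
- NIfTI-1 is the single supported volume format (volumes stored float64,
  masks uint8); DICOM ingestion and its SUV header arithmetic are
  non-goals. The stored value semantics (`value_kind`) are declared by
  the manifest, never guessed from the data.
- Trilinear resampling fills out-of-field voxels with the moving
  volume's minimum (air, for CT) unless told otherwise, and is exact on
  constants and at shared lattice points.
- SULpeak tie-breaks (identical sphere means) resolve to the first
  centre in storage scan order; component labels are numbered by first
  voxel in scan order — both make reruns bit-identical.
- Seeds: every stochastic routine takes an explicit seed, restores the
  caller's RNG state, and pins the RNG kind, so the same seed is
  bit-reproducible across sessions; cohort per-patient seeds are derived
  arithmetically from the master seed and stay below 2³¹.
- Empty structures have declared semantics everywhere: empty mask →
  K = 0 lesions, NA SULpeak, zero volumes; both-empty Dice → 1 flagged;
  empty organ mask → error; single-class response data → error.

## Problem sizes used by the test suite

The unit and property tests run on small lattices (up to 20³ voxels)
where brute-force oracles — exhaustive sphere search, label relaxation,
per-component overlap counting — are affordable and exact. The
phantom-truth acceptance test uses 20 patients at the full default
geometry; the end-to-end response-recovery test uses twenty 60-patient
cohorts at a 40 × 40 × 80 / 4 mm geometry, a size chosen so the whole
suite completes in minutes on one core while still spanning ~1200
synthetic patients; the acceptance script runs the full replica at the
study scale of 60 patients with one or two follow-ups each. None of the
statistical machinery depends on lattice size.

## Known limitations

- The measured-vs-planted response separation on phantoms is far cleaner
  than clinical reality: lesion response is modelled as a single
  multiplicative factor per patient, so synthetic AUCs approach 1 and
  should not be read as performance claims for real cohorts.
- PBI/PLI depend on organ masks supplied as inputs; organ-segmentation
  error propagates directly into the indices and is not modelled.
- SULpeak needs at least one 1.2-cm sphere's worth of image around a
  lesion; for lesions at the image border the truncated-sphere mean is a
  biased estimate.
- The five-category PERCIST classification (and survival endpoints) are
  out of scope; only the binarized responder/non-responder contrast is
  assessed.
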