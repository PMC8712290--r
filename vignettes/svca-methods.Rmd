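---
title: "Supervised clustering for TSPO PET: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised clustering for TSPO PET: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svcaref)
```

## The model

TSPO is expressed throughout the brain, so no anatomical region is free of
specific binding and classical reference-tissue quantification has nothing
to anchor to.  The supervised clustering approach sidesteps anatomy: it
looks for voxels whose *kinetic behaviour* matches that of low-binding
grey matter in healthy brains, and uses their average curve as a
pseudo-reference.

The machinery has two stages.

**Training.**  Dynamic scans of healthy volunteers are frame-wise
z-normalized inside a brain mask: for frame $j$, every voxel value $v$
becomes $(v - \mu_j)/\sigma_j$ with $\mu_j, \sigma_j$ the mean and
population SD over in-mask voxels.  This removes global activity scale
(injected dose, body weight, scanner calibration) and leaves curve
*shape*.  From tissue masks (grey/white probability maps thresholded at
0.9, eroded; a thalamic or pathological mask for high binding; the ~50
hottest early-frame voxels for blood) a normalized TAC is extracted per
tissue and subject, then averaged (or medianed) across subjects into four
kinetic classes $K_1 \dots K_4$: low-binding grey matter, white matter,
blood, high-binding grey matter.  For second-generation tracers the
rs6971 polymorphism changes tracer affinity, so separate HAB and MAB
class sets are built.

**Extraction.**  A new scan is normalized the same way — with the same
brain-mask definition, which the package enforces by hashing — and every
candidate voxel's normalized TAC is decomposed by non-negative least
squares:

$$\mathrm{TAC}_v = \sum_i w_i K_i, \qquad w_i \ge 0 .$$

The low-binding grey matter ratio $w_\mathrm{LBGM} / \sum_i w_i$ measures
how purely reference-like the voxel is; voxels with ratio strictly above a
threshold (default 0.9) form the reference region.  The reference TAC is
computed from the *raw* scan (the normalized space is unitless and useless
for kinetic modelling), as a simple or $w_\mathrm{LBGM}$-weighted average.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | 0.9 | tissue-probability cut for GM/WM masks (strict `>`) |
| `erode` | 1 (binary) / 0 (probabilistic) | 6-connected erosions against partial volume |
| `early_window_s` | 180 s | early frames summed for the blood-voxel search |
| `n_top_blood` | 50 | hottest early voxels kept as the blood mask |
| `aggregation` | mean | across-subject summary (median is robust to outliers) |
| `lbgm_ratio_threshold` | 0.9 | selection cut on the LBGM ratio (strict `>`) |
| `averaging` | simple | reference TAC averaging (`weighted` uses `w_LBGM`) |
| `min_voxels` | 50 | selection-size warning floor (never an error) |

The defaults mirror common practice for TSPO tracers; all are explicit
`run_config()` fields, validated before any computation, and echoed into
each run manifest.

## Numerical choices

- **Population SD** (divide by $N$) in the normalization; the convention is
  recorded in the output.  Idempotence and affine invariance of the
  transform are tested to 1e-10.
- **Out-of-mask voxels are `NA`**, never 0, so they cannot leak into any
  average.
- **NNLS** is the classical Lawson–Hanson active-set algorithm, written in
  R; at 20 frames by 4 classes it converges in a few passes and is
  deterministic.  Its optimality is tested against an exact grid-search
  oracle.
- **Degenerate weights** ($\sum w_i = 0$) define a ratio of 0: such a voxel
  can never be selected.
- **Ties in the blood-voxel search** break by ascending linear voxel index,
  making training bit-reproducible.
- **Strict inequalities** at both thresholds, so a threshold of 1.0 selects
  nothing (and extraction fails loudly rather than returning an empty
  reference).
- Schedules must match *exactly* between training and testing; the package
  never resamples in time or space, and mask/PET grid mismatches are
  errors, never silent interpolation.

## The phantom generator

Real validation of SVCA needs arterial-input cohorts.  To make every stage
testable at desk scale, `generate_phantom()` builds a 24³ voxel, 20-frame
(49-min) world with known truth:

- **Blood input**: a gamma-variate $C_p(t) = A\,t\,e^{-t/\beta}$ peaking at
  30 s.
- **Tissues**: one-tissue-compartment responses
  $C(t) = K_1 e^{-k_2 t} \ast C_p(t)$, integrated *analytically* over each
  frame interval (the analytic averages are verified against a fine-grid
  numerical convolution to 0.1%).  Default distribution volumes order
  hbgm (5.0) > lbgm (3.0) > wm (1.1), with washout rates ordered so the
  late-frame activity ordering holds to the end of the scan.
- **CSF**: an off-class compartment (~15% of the brain: ventricle plus
  sulcal layers).  This is not decoration.  If the brain were an exact
  convex mixture of the four class templates, frame-wise normalization
  would make the normalized class curves exactly linearly dependent
  (the brain-composition-weighted sum of the $K_i$ is identically zero)
  and per-voxel weights would be unidentifiable — the class matrix had
  condition number ~1e16 until the CSF compartment was added, ~170 after.
  Real brains likewise contain tissue that the four classes deliberately
  do not span; the phantom must too.
- **Partial volume** (`mixing = "dirichlet"`): tissue voxels within two
  voxels of a region boundary draw convex mixtures of the four classes
  from a Dirichlet centred on their own class (concentrations 1.2 own /
  0.6 other, i.e. heavily blended); deeper voxels are pure, as are vessels
  and CSF.  This mimics PET-PSF blending reaching deeper than the 1-voxel
  partial-volume shell of the MRI probability maps.
- **Noise**: additive Gaussian with per-frame SD
  $\texttt{noise\_level} \cdot v_j / \sqrt{\Delta t_j}$ — noise tracks
  local activity and longer frames are quieter, a desk-scale surrogate for
  count statistics (not a reconstruction model).
- **Cohorts**: per-subject log-normal jitter (default 5%) on the tissue
  $K_1, k_2$ only.  Frame-wise normalization removes global amplitude
  differences by design, so the jitter parameter represents residual
  kinetic *shape* variability, which is considerably smaller than the
  10–20% amplitude variability reported between subjects.  The population
  input function is shared, as is common in simulation studies.

What a green test does establish: the pipeline is internally consistent —
exact recovery in the noiseless world, graceful and monotone degradation
with noise, bit determinism, and correct guard rails.  What it does not:
performance on real scanners (no PSF, attenuation, scatter, motion or
reconstruction artefacts; box anatomy; one-tissue kinetics), and no claim
about clinical outcome measures.

## Design decisions where the field is genuinely open

- **Which image feeds the reference TAC**: the raw scan.  The normalized
  space is unitless; published practice computes outcome measures from
  activity concentrations.  Selection, by contrast, happens entirely in
  normalized space, which makes the selected mask scale-invariant and the
  reference TAC exactly scale-equivariant (both tested).
- **Mask-hash enforcement**: the class set records a content hash of the
  training brain mask when all training masks are identical (template
  space, and the phantom world), otherwise a policy descriptor.  At
  extraction a content mismatch is an error unless explicitly forced,
  because normalizing with a different mask definition mismatches testing
  and training data.
- **Blood class ordering**: voxel selection for the blood mask uses the
  *raw* early frames (signal ranking needs units); the class TAC is then
  extracted from the *normalized* image like every other class.
- **Blood-shape QC in normalized units**: normalized curves can be
  negative, so the washout check uses the peak-to-minimum range (final
  value below 50% of the range above minimum) rather than a naive ratio,
  which would mis-handle negative plateaus.
- **"Early" and "late" frames** in QC are the first and last thirds of the
  frame list — the qualitative published guidance quantified once,
  configurably.
- **Logan DVR**: included only as a demonstration endpoint; the
  $k_2'$ term is optional and omitted by default.  `t*` must sit in the
  pseudo-equilibrium window (the identity and DVR-recovery tests use a
  90-min schedule for exactly that reason).
- **Class count is fixed at four** (the brain-masked variant); legacy
  six-class training with skull/muscle classes is out of scope.

## Known limitations

- Masks must arrive co-registered in PET space; the package refuses to
  resample and performs no registration or segmentation.
- Decay-correction status is recorded but not verified.
- The NNLS conditioning of real class sets depends on how distinct the
  class kinetics are for a given tracer; per-voxel ratio estimates are
  noisy in any case, and the method's robustness comes from averaging
  hundreds to thousands of selected voxels, not from per-voxel accuracy.
- With noiseless, kinetically-jittered synthetic subjects the LBGM ratio
  is *constant* across a subject's pure reference voxels, so selection is
  all-or-nothing per subject — an instructive corner of the simulation
  world with no analogue in noisy real data.
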