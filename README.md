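# svcaref

Supervised clustering reference-region extraction for dynamic TSPO PET.

## The problem

Quantifying neuroinflammation with 18 kDa translocator protein (TSPO) PET
normally requires an arterial input function, because TSPO is expressed
everywhere in the brain and no true reference region exists.  A widely used
non-invasive alternative is a *supervised clustering algorithm* (SVCA): it
identifies, scan by scan, the voxels whose kinetics look like low-binding
grey matter and averages them into a *pseudo-reference* time-activity curve
(TAC) that can feed reference-tissue models (Logan DVR, SRTM, ...).

`svcaref` implements the full SVCA workflow for 4D PET data:

1. **Training** — from a cohort of healthy-volunteer scans (ideally N > 10,
   same tracer/scanner), build four *kinetic classes*: normalized TACs for
   low-binding grey matter (`lbgm`), white matter (`wm`), `blood` and
   high-binding grey matter (`hbgm`), optionally stratified by the rs6971
   binding genotype (HAB/MAB).
2. **Extraction** — normalize a new scan frame-by-frame inside the brain
   mask, decompose every candidate voxel's TAC against the classes by
   non-negative least squares,

   ```
   TAC_v = w1*K1 + ... + wn*Kn,   w_i >= 0
   ```

   compute the low-binding grey matter ratio

   ```
   LBGM ratio = w_LBGM / sum_i(w_i)
   ```

   and keep voxels with ratio above a threshold (usually 0.9).  The
   reference TAC is the (simple or `w_LBGM`-weighted) average of the
   selected voxels' raw TACs.
3. **QC** — coherence of training curves, reference-vs-anatomical TAC
   comparison, spatial spread of the selection.
4. **Validation support** — a ground-truthed compartment-model phantom
   simulator, so every stage is testable without any scanner data, plus a
   minimal Logan reference-region DVR for end-to-end demonstrations.

Everything is plain R; NIfTI-1 I/O is built in (no external imaging
package needed).

## Worked example (runs in a few seconds)

```r
library(svcaref)

## simulate a 12-subject training cohort (49-min TSPO protocol, 20 frames)
spec   <- phantom_spec(noise_level = 0.1, seed = 2026L)
cohort <- generate_cohort(12, spec)

## build kinetic classes, holding out subject s12 (leave-one-out)
cfg     <- class_config(hbgm_source = "high_binding")
classes <- build_class_sets_loo(cohort$subjects, cfg, held_out = "s12")
classes
#> <kinetic_class_set> ALL/mean: 20 frames x 4 classes (lbgm,wm,blood,hbgm), 11 subjects

## extract the pseudo-reference region for the held-out subject
s12  <- cohort$subjects[[12]]
cand <- prepare_tissue_mask(s12$masks$gm_prob, p_threshold = 0.9, erode = 0)
ref  <- extract_reference(s12$pet, s12$masks$brain, cand, classes,
                          threshold = 0.9, averaging = "simple")
ref
#> <reference_region_result> 1128 voxels selected (ratio > 0.90, simple average)

## the recovered reference TAC is within 1% of the simulated ground truth
max(abs(ref$ref_tac - cohort$truth$s12$templates[, "lbgm"])) /
  max(cohort$truth$s12$templates[, "lbgm"])
#> 0.0088

## QC: the selection spreads evenly across the candidate mask
qc_selection_distribution(ref$selected_mask, cand)
#> status "pass", 1128 voxels, 37% of candidates, max octant share 0.15

## demonstration: Logan reference-region DVR of the high-binding region
hb   <- prepare_tissue_mask(s12$masks$high_binding, 0.5, 1)
d    <- dim(s12$pet$voxels)
flat <- matrix(s12$pet$voxels, prod(d[1:3]), d[4])
tgt  <- colMeans(flat[which(hb$voxels == 1), ])
logan_ref_dvr(tgt, ref$ref_tac, s12$pet$schedule, t_star = 1500)
#> <dvr_result> DVR = 1.4086 (t* = 1500 s, R^2 = 1.0000, 5 frames)
```

The numbers above are what the code prints: 1128 of ~3000 candidate grey
matter voxels are retained at the 0.9 ratio threshold under 10% frame
noise, the reference TAC matches the generating low-binding template to
0.9% of its peak, and the Logan slope of the high-binding region versus
that reference is a DVR of 1.41.

## Command line

A launcher is installed at `inst/cli/svca`:

```sh
svca simulate      --out-dir phantom/ --n-subjects 12 --seed 7
svca build-classes --cohort phantom/manifest.csv --out classes.json
svca extract-ref   --pet pet.nii.gz --timing timing.csv --brain brain.nii.gz \
                   --candidate lbgm.nii.gz --classes classes.json \
                   --threshold 0.9 --out-dir out/
svca qc            --run-dir out/ --anat-tac cereb_tac.csv --report qc.json
```

Options can also come from a YAML config (`--config run.yaml`); precedence
is CLI flag > config file > documented defaults, and every run writes a
`run_manifest.json` with the effective configuration and input/output
hashes.

## Documentation

The methods vignette (`vignettes/svca-methods.Rmd`) describes the model,
the tunable parameters, the phantom generator's assumptions and known
limitations.
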