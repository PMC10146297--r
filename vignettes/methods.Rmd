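---
title: "Methods: adaptive-threshold coronary calcium scoring on CCTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive-threshold coronary calcium scoring on CCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the scoring model,
the pipeline and its assumptions, what the synthetic phantom does and does
not emulate, the numerical and design choices that were genuinely open, and
the known limitations. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Reference scoring model

The clinical reference is the Agatston score on non-contrast
calcium-scoring CT (CSCT; 120 kVp, 3 mm slices). `detect_lesions()`
implements the classic rule literally: per-slice 8-connected components of
voxels with attenuation **strictly** above 130 HU whose in-plane area is
**strictly** above 1 mm². Both strict inequalities matter at the boundary
(a 1.0 mm² component and a 130 HU voxel are excluded) and the tests pin
them. Components overlapping across adjacent slices are merged into one 3D
lesion for volume reporting; the Agatston sum itself is slice-wise,

\[
A \;=\; \sum_{\text{lesions}} \sum_{\text{slices}}
  \mathrm{area}\,(\mathrm{mm}^2)\times w(\text{peak HU})
  \times \frac{\Delta z}{3\,\mathrm{mm}},
\]

with \(w = 1,2,3,4\) for peak attenuation in [130, 200), [200, 300),
[300, 400), [400, ∞). Bin edges map to the upper bin. The
\(\Delta z / 3\) factor is a no-op on protocol CSCT and makes the same
scorer reusable on thinner reconstructions. Two conventions are ambiguous
in the literature and are declared here (both flag-switchable in
`agatston_params()`): the weight is evaluated per slice-component, the
convention of the established clinical software, and the > 1 mm² filter is
applied per slice-component rather than per 3D lesion. The volume score is
member-voxel count × voxel volume.

The implementation is checked against an independent brute-force per-pixel
oracle (iterative label propagation, no connected-component machinery,
slice-additive accumulation) on randomized grids; the two agree to
floating-point tolerance.

## 2. The automated CCTA pipeline

The contrast-enhanced pathway cannot use a fixed 130 HU cutoff: iodinated
blood sits at 300–700 HU depending on tube voltage and protocol. The
pipeline therefore derives a per-scan **calibration factor** from the
ascending aorta and makes both the extraction threshold and the score
weights functions of it.

Stages, in order:

1. **Mixture modelling** (`fit_gmm_em`): 1D Gaussian mixture over HU fitted
   by EM on a seeded subsample of 10⁵ voxels, k-means initialised, with a
   relative log-likelihood tolerance of 1e−6 and a monotonicity check on
   the trace. Components are mapped to tissue classes by their means
   (air < −200 < soft tissue < 150 ≤ blood pool < 800 ≤ calcium).
2. **Attenuation-window standardisation**
   (`optimize_attenuation_window`): a monotone piecewise-linear remap
   sending the blood-pool mean to a fixed 400 HU working level and
   compressing sub-soft-tissue values with slope 0.5. Downstream vesselness
   thresholds then see a comparable blood pool at any kVp. Absence of a
   blood-pool component (mean in [150, 800]) is a typed calibration error —
   the input is presumably non-contrast.
3. **Vesselness** (`vesselness`): multi-scale Frangi filter on the remapped
   volume; Gaussian scales 1.0 and 1.6 mm cover lumen radii of roughly
   0.75–3 mm; sensitivities α = β = 0.5; the structure scale is set
   per-volume to half the maximal Hessian norm; bright-tube polarity
   (λ₂, λ₃ < 0); maximum over scales.
4. **Aorta** (`segment_aorta`): per-slice threshold at the blood-pool mean
   − 2.5 sd, morphological opening (radius ≈ 1 mm) to detach coronary
   ostia, then the largest bright near-circular component with equivalent
   radius 10–25 mm and circularity ≥ 0.8 (tie-break: higher median HU);
   ≥ 3 consecutive slices required, else a typed segmentation failure. The
   central third of the aortic extent is the calibration portion.
5. **Calibration** (`calibration_factor`): an affine function
   `a · median + b` of the mid-aorta attenuation — a robust location
   estimate with a packaged correction rather than a plain mean. On the
   phantom tuning cohort the aorta median tracks the true lumen enhancement
   directly, so the packaged coefficients are (1, 0); the sanity band
   (value within 0.5–1.5 × median, > 0) is enforced as a typed error.
6. **Coronary segmentation** (`segment_coronary`): hysteresis thresholds
   (0.30 / 0.05) on vesselness, restricted to remapped HU > 150, seeded at
   voxels within 3 voxels of the aorta surface. Unseeded bright tubes are
   kept as flagged candidates so that the mislabel-removal stage can
   adjudicate them.
7. **Post-processing** (`connect_gaps`, `remove_mislabeled`): endpoint
   pairs closer than 5 mm with direction mismatch < 45° are bridged by a
   straight tube of the mean local radius (idempotent); components
   unreachable from an ostium, components with median HU below 0.5 × the
   calibration (heart tissue), and components anti-parallel (> 135°) to
   the nearest retained vessel are removed.
8. **Centerlines** (`skeletonize`): 3D topological thinning — iterative
   deletion of simple border points (Bertrand's two-component
   characterisation: one 26-connected foreground component in N₂₆, one
   6-connected background component in N₁₈ adjacent to the voxel), cycling
   the six border directions. Voxels with two or fewer foreground
   neighbours are never deleted: a curve voxel whose two neighbours are
   mutually adjacent is locally indistinguishable from the end of a
   staircase arc, and deleting such points lets a sequential sweep consume
   a thin digital rod end to end — each step topologically simple, the sum
   a collapsed skeleton. The redundant elbow voxels this protection keeps
   are resolved afterwards on the skeleton graph: a BFS spanning tree
   rooted at the ostium (skeleton point nearest the aorta) drops triangle
   chords, leaf twigs shorter than 2 mm are pruned as thinning spurs, and
   the tree decomposes into maximal chains between branch points, ordered
   outward. Finally each point is re-centred on the centroid of the nearby
   mask cross-section (the sequential direction sweep can leave the digital
   skeleton up to a voxel off-axis — an even-width tube has no centre
   voxel) and smoothed with a window-3 moving average; on a synthetic
   cylinder this brings the skeleton within 0.2 mm of the true axis. A
   distance-ordered alternative was considered; thinning was chosen because
   it needs no extra parameters on masks this small.
9. **Cross-sections** (`cross_sections`): one section every 0.5 mm; local
   tangents by central differences on the smoothed centerline; HU sampled
   by trilinear interpolation on a 3.5 mm disc at 0.3 mm spacing. A section
   is **unreliable** when the centerline attenuation exceeds 1.3 × the
   calibration (calcium on the centerline), falls below 0.85 × the
   calibration (the centerline has strayed off the contrast-filled lumen,
   so its attenuation is not a valid lumen estimate either), or the
   tangent is degenerate.
10. **Extraction and scoring** (`extract_calcium_mask`,
    `ccta_volume_score`, `adaptive_agatston`): per-section samples are
    classified calcium by HU **> 1.45 ×** calibration where the section is
    unreliable and **≥ 1.25 ×** the local centerline attenuation where it
    is reliable — the two printed multipliers, implemented with exactly
    that strict/non-strict asymmetry. Samples map back to voxels; 3D
    components smaller than 2 voxels are dropped; voxels inside the
    2-voxel-dilated aorta are excluded (aortic-wall attenuation is not
    coronary calcium, and the near-ostium sampling discs overlap the
    aortic blood pool). The volume score is voxel count × voxel volume per
    vessel. The adaptive Agatston score weights **each voxel** by the
    standard bins with edges scaled by calibration / 400 HU (the reference
    calibration), times in-plane voxel area, times Δz/3. At reference
    calibration the weight map is exactly the standard bins (identity
    limit, asserted in tests); raising the threshold multiplier can only
    shrink the extracted volume (monotonicity, asserted in tests).

Two rules here are package interpretations of under-specified behaviour,
both frozen after tuning on a phantom cohort and both config-exposed: the
0.85 reliability floor in stage 9 (without it, skeleton stubs with
soft-tissue centerline values turn the 1.25× rule into a ~200 HU threshold
and contrast blood pool scores as calcium), and the aorta exclusion in
stage 10. The 1.25× comparison uses the local section's centerline value,
not a segment average (switchable).

Every failure mode — aorta not found, no coronary seed, calibration out of
band — is a typed condition that `run_ccta_pipeline()` converts into a
failed `score_report`, never a crash; `run_validation()` excludes failed
subjects from the statistics while tallying them, the way a clinical
validation reports its failure rate.

## 3. The synthetic phantom

`phantom_spec()` / `render_pair()` generate a paired study of one simulated
heart on a 45 × 45 × 36 mm field of view: CSCT at 120 kVp with 3 mm slices
and CCTA at the spec's kVp with 0.75 mm slices, both at 0.5 mm in-plane.
The scene holds a 15 mm-radius ascending aorta, three coronary branches
(LCA main + diagonal sharing an ostium at azimuth 180°, RCA at 270°,
lumen radii 1.2–1.4 mm), a free-floating bright tube standing in for a
cardiac vein (deliberately not ostium-connected, to exercise mislabel
removal), a fat pocket, an air margin, and spherical calcified plaques on
the branches.

Attenuation model: soft tissue/blood 40 HU; contrast enhancement 400 HU at
120 kVp; a plaque of density index *d* ∈ [0, 1] has base attenuation
130 + 770 d at 120 kVp, spanning all four weight bins. Tube-voltage physics
is a two-point model linear in 1/kVp with scale(120) = 1 and
scale(80) = 1.55 for calcium, 1.70 for iodine — monotone, iodine steeper
than calcium, which is exactly the asymmetry that makes a fixed HU
threshold fail and an iodine-calibrated threshold conservative at low kVp.
No published quantitative kVp→HU mapping exists for this setting; these
scale factors are a declared model, used consistently by the renderer and
the tests.

Partial volume: plaques are rendered by 4× supersampled subvoxel counting
in their bounding boxes (≤ 0.25 mm subsamples along z), which produces the
sub-threshold rim voxels that stress the 130 HU cutoff; tubes and the
aorta use an analytic distance-based occupancy profile with z-supersampling
where slices are thick — the same rim behaviour at a fraction of the cost
of supersampling whole-volume rasterisations. Noise is additive i.i.d.
Gaussian (sd 15 HU), seeded; two renders from one spec are bit-identical.

Ground truth: calcium masks are the noise-free occupancy ≥ 0.5 per
modality; per-plaque volumes are mask voxel count × voxel volume (for a
2 mm sphere on the CCTA grid this is within one voxel volume of 4πr³/3,
asserted); reference scores come from running the standard scorer on the
noise-free CSCT rendering, so the scorer-equals-truth invariant is exact by
construction and tested.

`default_cohort()` cycles five burden strata — zero calcium, then 1, 2, 4, 8
plaques of increasing radius (0.8–2.4 mm) and density (0.70–0.90) — so
every risk category is populated from n ≥ 5. Densities are high because
clinically scored plaques are; stratum targets were placed near bin
centres on the reference side so that the known, systematic CCTA
underestimation (a factor ≈ 0.5 on this phantom) does not straddle the
0/10/100/400 category boundaries. Tube voltages are allocated
deterministically at 25 % / 69 % / 6 % for 80 / 100 / 120 kVp, the
distribution seen clinically. All cohort randomness (plaque placement and
jitter, kVp shuffling) derives from one seed.

What the phantom does **not** emulate: scanner blur/PSF and beam hardening,
respiratory or cardiac motion (the dominant real-world failure mode),
eccentric or non-calcified plaque, anatomical variation, and table/FOV
truncation. Passing the phantom validation therefore demonstrates the
internal consistency of the calibration, threshold and weighting logic
under controlled physics — not patient-level accuracy. The packaged
cross-classification matrices are the bridge to patient data: their
accuracy, kappa and reclassification statistics are recomputed by the
package's own functions.

## 4. Numerical choices

* Problem sizes: the validation study uses a 50-subject cohort on
  90 × 90 × 48 CCTA grids; unit tests use 32–40³ grids. These sizes keep a
  full run in minutes on a single core while leaving every stage
  non-trivial (the coronary tree is ~80 mm long and 2–3 voxels in radius).
* Connected components are frontier BFS on border-padded arrays; 2D
  8-connectivity is the 3D 26-connectivity of a one-slice array.
* Hessians are computed by separable sampled-Gaussian derivative kernels
  (radius 3.5 σ, replicate edges) as dense band-matrix multiplies;
  eigenvalues by the closed-form trigonometric method, sorted by |λ| with
  a three-element sorting network.
* EM degeneracies: component sd floored at 1e−3 HU; empty components keep
  weight ≈ 0; a constant volume returns a single active component; k = 1
  is the closed-form mean/sd.
* Aorta tie-break between admissible circles: larger equivalent radius,
  then higher median HU.
* Trilinear sampling outside the grid returns NA, which flags the section
  unreliable rather than inventing attenuation.
* Seeds: every stochastic step (phantom noise, EM subsample, cohort
  jitter) takes an explicit seed; derived seeds are kept below 2³¹.

## 5. Known limitations

* The three learned components of the original clinical system (coronary
  segmentation network, aorta segmentation network, calibration regressor)
  are replaced by classical operators with the same I/O and failure
  contracts. This is the package's central, deliberate substitution: the
  quantitative logic (calibration, adaptive threshold, adaptive weights,
  scoring, statistics) is the contribution being exercised, not the
  segmentation backbone.
* The histogram-optimisation preprocessing and the calibration regressor
  of the clinical system are unpublished; the remap of stage 2 and the
  affine median correction of stage 5 are declared stand-ins.
* Patient-level absolute score distributions, per-kVp subgroup results and
  the clinical failure rate are not reproducible at desk scale and are not
  asserted anywhere; the phantom bounds (rank correlation, categorical
  agreement, underestimation direction) are regression properties of this
  package under its own study conditions.
* DICOM input is out of scope (no DICOM reader among the package's
  dependencies); NIfTI is the interchange format, and the rescale
  arithmetic is exposed for callers who convert DICOM themselves.
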