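---
title: "CT ventilation imaging under quantum noise: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT ventilation imaging under quantum noise: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctviqa)
```

## The problem this package addresses

CT-based ventilation imaging (CTVI) derives a map of regional lung function
from an ordinary exhale/inhale CT pair: deformable image registration (DIR)
aligns the inhale image onto the exhale image, and the Jacobian determinant of
the recovered displacement field measures local volume change — values above 1
mean local expansion (ventilated tissue), below 1 contraction. Because the
input is plain CT, the method inherits CT's quantum (photon) noise, and the
question this package operationalizes is *how much that noise corrupts the
ventilation map, and whether noise-reduction preprocessing (a median filter or
a learned CNN denoiser) restores it*.

Answering that question requires ground truth, which patient data cannot
provide. The package therefore ships a **digital nonrigid alveoli phantom**: a
synthetic exhale/inhale pair with a known, analytic deformation field, known
ventilation map, and known landmark correspondences, so that every stage of
the pipeline can be scored against truth with no external data.

## The digital phantom

The phantom emulates a physical quality-assurance device: an acrylic cylinder
filled with polyurethane foam (lung-equivalent texture) whose caudal face is
driven by a diaphragm-like piston.

* **Geometry.** An axis-aligned grid (default 96 × 96 × 48 voxels at
  2 × 2 × 3 mm — a desk-scale analogue of the 512 × 512 × 131 at
  0.78 × 0.78 × 3 mm regime of a clinical scanner) holds a cylinder of radius
  80 mm: a 5 mm acrylic wall (+120 HU) around band-limited Gaussian foam
  texture (mean −700 HU, SD 60 HU after smoothing — the foam HU distribution
  is a free parameter with lung-like defaults) over air (−1000 HU).
* **Motion model.** The displacement field is dominantly caudal:
  `u_z = A · exp(−d/L) · (1 − (r/R)^4)`, where `d` is the axial distance
  cranial of the diaphragm face, `L` = 150 mm the decay length, and the
  quartic taper vanishes at the cylinder wall. The Jacobian of this field is
  `1 + (A/L)·exp(−d/L)·taper ≥ 1` — fold-free by construction, expansion
  concentrated near the diaphragm, exactly the qualitative pattern expected
  during inhalation. With the default amplitude `A = 22` mm the mean landmark
  displacement is ≈ 14.6 mm, matching the breathing magnitude the phantom is
  meant to emulate (≈ 14.6 ± 6.4 mm). The diaphragm face is placed far enough
  from the grid edge that the fully displaced face stays in the field of view.
* **Field convention.** All displacement fields are pull-back fields on the
  exhale (reference) grid, in physical mm: `T(x) = x + u(x)` maps reference
  positions into the moving (inhale) image, so `warp(inhale, u) ≈ exhale`.
  This is the convention a registration estimate uses, which makes the
  phantom's `true_dvf` directly comparable to registration output, makes
  landmarks map as `inhale = exhale + u(exhale)`, and feeds the Jacobian map
  without sign gymnastics. The inhale volume is synthesized by resampling the
  exhale volume through the *numerically inverted* field (fixed-point
  inversion), so the pair is exactly consistent with `true_dvf`.
* **Landmarks.** 25 landmarks are placed automatically at strict local maxima
  of the foam texture (high-contrast internal structure), eroded away from the
  wall and the axial faces, with a 12 mm minimum separation, ranked by
  intensity. Automatic placement replaces manual placement by an expert for
  the sake of reproducibility.
* **Not modelled.** Scanner physics (beam hardening, reconstruction kernels),
  motion artifact within a breathing cycle (only the two static phases are
  simulated), airflow/pressure dynamics.

## Noise and denoising

**Quantum noise** is simulated as additive, spatially white, zero-mean
Gaussian noise in HU — a deliberate simplification (no noise power spectrum
correlation), with no value clipping afterwards so the injected SD is
unbiased. The study conditions use SD ∈ {30, 80, 150} HU, each drawn
independently for the exhale and inhale image of a pair; sigmas above 200 HU
are rejected as outside the regime where registration remains stable.

**Median filter.** A strictly 2-D 3 × 3 median applied to each axial slice
independently (slices never mix), reflect padding at the borders (avoids rim
darkening on HU data), implemented as a vectorized min/max exchange network
and verified against a brute-force sort-of-9 oracle.

**U-Net denoiser.** A small 2-D U-Net: per level two 3 × 3 convolution + ReLU
blocks, 2 × 2 max pooling down, nearest-neighbour upsampling with channel
concatenation (skip connections) up, and a final 1 × 1 convolution. Depth 3.
The full-scale profile uses 32 base filters on 512 × 512 slices; the
desk-scale profile used in all tests uses 8 base filters on 96 × 96 phantom
slices. Because no deep-learning framework is available in this R stack, the
forward pass, backpropagation and the Adam optimizer are implemented in
vectorized base R (im2col + GEMM convolutions); gradients are verified against
finite differences in the test suite.

Design choices the architecture description leaves open were resolved as
follows and are deliberately conventional:

* **Global residual connection** — the network outputs
  `input + correction(input)`. The final 1 × 1 convolution is
  zero-initialized, so the untrained network is exactly the identity. This
  matters at desk scale: with raw HU inputs (no normalization is applied to
  pixel values, matching the reference training regime) and a randomly
  initialized head, the first epochs are spent unlearning a large random
  correction, and with short schedules the optimizer collapses into a dead
  identity instead. Starting *at* the identity makes every optimizer step an
  improvement over "do nothing".
* **Noise curriculum** — fresh noise every epoch at an SD drawn uniformly from
  the 14 training sigmas {10, 20, 50, …, 200}; validation uses a fixed seeded
  realization at {40, 90, 160}; the tested sigmas {30, 80, 150} are never seen
  during training or selection (the three lists are disjoint by
  construction). The checkpoint with minimum validation L1 loss is returned.
* **L1 loss** — `l(x, y) = (1/N) Σ |x_n − y_n|`, the mean absolute pixel
  difference between prediction and clean slice.
* **Desk training schedule** — 20 epochs on 48 × 48 random crops (the network
  is fully convolutional, so crop training is legitimate and quadruples the
  steps per unit time), batch 8, Adam at 1e-3, ~4 minutes on one CPU. The
  full-scale regime (500 epochs, 512 × 512, GPU) is expressible through the
  same configuration objects but is not exercised by the tests. At the desk
  schedule the denoiser reduces the RMSE of a σ = 150 HU volume by roughly
  60% and beats the median filter at every study noise level.

## Registration

The inhale image is deformed onto the exhale image with a multi-step cubic
B-spline free-form deformation (FFD):

* **Parameterization.** A cubic B-spline control grid in *physical*
  coordinates (default spacing: 8 voxels per axis), evaluated through
  separable basis matrices. Because the control grid lives in mm, the same
  coefficients act at every level of the multi-resolution pyramid — no
  coefficient refitting between levels.
* **Cost.** `−similarity + w_be · bending + w_J · mean((J − 1)²)`.
  Similarity is either normalized mutual information
  (`NMI = (H(A)+H(B))/H(A,B)`, 64 equal-width bins, the default) or SSD
  normalized by the squared reference dynamic range (appropriate and faster
  for same-modality synthetic images; the desk experiment profile uses it).
  The Jacobian term penalizes large local volume changes and discourages
  folding.
* **Optimizer.** Gradient descent with backtracking (Armijo) line search;
  analytic gradients throughout (the NMI gradient via soft-binned joint
  histograms; the similarity gradient uses the exact derivative of the
  trilinear interpolant, with clamped out-of-grid samples contributing zero
  derivative). Cost is non-increasing across accepted iterations by
  construction, which the tests assert on real traces.
* **Penalty evaluation.** Inside the optimizer the bending energy is computed
  in closed form from the spline coefficients (per-axis Gram matrices of the
  basis' second derivatives — exact for the spline field and orders of
  magnitude cheaper than dense finite differences), and the fold penalty on a
  stride-2 sub-lattice. The exported `bending_energy()` and `jacobian_map()`
  operate on dense fields with finite differences and are used for reporting
  and acceptance checks; the optimizer-internal forms are gradient-exact
  against finite differences in the test suite.
* **Cascade.** `n_steps` registrations (default 4; desk profile 2) are run,
  each starting from the moving image re-warped through the accumulated
  field; each step's field is composed (not added) onto the accumulation:
  `u(x) = u_step(x) + u_acc(x + u_step(x))`. Composition is the geometrically
  correct accumulation of pull-back fields. A step whose own field folds more
  than `overdeform_threshold` (default 0.1%) of voxels is omitted — an
  automated, reproducible stand-in for a visual over-deformation check. No
  rigid pre-alignment is performed (the phantom does not move between
  phases).
* **Default weights.** The desk profile uses bending weight 1.0 and Jacobian
  weight 0.05 against the normalized SSD; they were calibrated once on the
  phantom's two analytic recovery tasks (a known 2-voxel translation and the
  breathing field), where they give sub-half-voxel median recovery error,
  and are logged with every run.

The registration backend is a contract: anything that maps
`(reference, moving, config)` to a displacement field can stand in, and all
downstream stages depend only on the field.

## Ventilation maps and categories

The ventilation surrogate is the Jacobian determinant of the recovered field:
`J(x) = det(I + ∇u(x))`, with all nine partials taken with respect to physical
coordinates — central differences in the interior, one-sided at grid faces,
each divided by the per-axis spacing in mm. Spacing awareness matters because
clinical voxels are strongly anisotropic. `J` is computed inside an analysis
mask: the phantom's foam interior when geometry is available, otherwise the
largest connected component below −300 HU in the reference exhale image,
lightly eroded.

For the clinical-consistency analysis, the reference map's value *range*
inside the mask is divided into three equal-width intervals ("low", "middle",
"high" ventilation): with `r = max − min`, cut points `min + r/3` and
`min + 2r/3`. This is a literal range division, not tertile quantiles —
quantiles would force 33.3% occupancy in every category by construction and
make observed deviations from it meaningless. Intervals are
left-closed/right-open with the top interval closed (a value exactly at `t1`
is "middle", at `t2` "high"). The same thresholds — always derived from the
*reference* CTVI, never from the map under test — are applied to every other
map; extreme Jacobian values are not clipped, they only influence the range
through the logged min/max.

## Evaluation

* **Landmark displacement** — per-pair Euclidean distance
  `√(Δx² + Δy² + Δz²)` between exhale and inhale landmarks.
* **TRE** — each inhale-phase landmark is pulled back into reference space by
  solving `p + u(p) = target` with fixed-point iteration (≤ 20 iterations,
  tolerance 1e-3 voxel, trilinear field sampling); the TRE is the distance to
  the corresponding exhale landmark. On non-convergence (not observed in
  practice on smooth fields) the forward mapping of the reference landmark is
  used and flagged. Reports state whether all TREs sit within the 3 mm
  tolerance used for image-registration QA (TG-132).
* **Category agreement** — the 3 × 3 proportion table reference × test over
  masked voxels, and unweighted Cohen's kappa `(p_o − p_e)/(1 − p_e)` with the
  asymptotic z-test p-value (large-sample null SE); a seeded permutation test
  is available for small masks.
* **Voxel-level consistency** — Spearman rank correlation on the raw voxel
  pairs (mid-ranks for ties, p from the t-approximation). Correlating raw
  pairs rather than binned 2-D-histogram counts is intentional: binning would
  coarsen the ranks, while the histogram (default 100 × 100 equal-width bins
  over the pooled range) is retained as the visual/reporting artifact, with
  agreement showing up as mass along y = x.

## The experiment runner

`run_experiment()` reproduces the full design: one phantom realization per run
(mirroring the single physical phantom; replicates can be obtained by varying
the seed), a noiseless reference branch registered with the identical
configuration, then for each noise level and branch (raw noise / median / CNN)
independent noising of both phases, denoising, registration, Jacobian map,
classification with the reference thresholds, and the full consistency report.
Everything derives from one master seed; identical configurations produce
identical tables. Artifacts (NIfTI volumes and fields, CSV tables, a JSON
manifest recording seeds and configurations) are persisted when an output
directory is given.

## Problem sizes and what the tests show

The test suite and the acceptance checks run entirely on synthetic data at
desk scale: a 48 × 48 × 24 phantom for unit tests, the 96 × 96 × 48 default
phantom for recovery and trend checks, and a 20-epoch crop-trained denoiser.
These sizes were chosen so a full check-out completes on a single CPU in well
under half an hour while still exercising every stage at meaningful
resolution.

Passing on the phantom demonstrates internal correctness — analytic anchors
(zero-field TRE and Jacobian, closed-form determinants, exact statistics
oracles), sub-voxel recovery of known transforms, and the *directional*
result that CNN denoising preserves CTVI consistency at high noise better
than no denoising while median filtering helps at low noise. It does not
demonstrate clinical performance: real lungs have vascular/airway structure,
sliding motion at the pleura, reconstruction-kernel-correlated noise, and
intensity changes from air-content variation, none of which the phantom
contains. Numeric agreement with any particular physical-phantom study is
therefore out of scope; the package reproduces the *structure* and the
forced calibration points of such an analysis, not its measured table
entries.

## Known limitations

* The registration is a plain FFD with gradient descent — no diffeomorphic
  guarantee beyond the fold penalty and the over-deformation gate.
* The U-Net at desk scale is a small model trained on one phantom's slices;
  it denoises that phantom family well but is not a general CT denoiser.
* Kappa and Spearman p-values at realistic mask sizes are astronomically
  small and serve as sanity checks, not as interesting statistics.
* The NMI similarity is implemented with hard fixed-image bins and linear
  moving-image bins; entropy estimation bias at very small overlap is not
  corrected.
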