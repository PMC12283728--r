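# ctviqa — quality assurance for CT ventilation imaging under quantum noise

CT-based ventilation imaging (CTVI) turns an ordinary exhale/inhale CT pair
into a map of regional lung function: deformable image registration (DIR)
estimates the displacement field **u**(x) aligning the inhale image onto the
exhale image, and the local volume change

```
J(x) = det(I + ∇u(x))        J > 1: expansion, J < 1: contraction
```

serves as a voxel-wise ventilation surrogate. CT images inevitably carry
quantum (photon) noise, and noise corrupts the Jacobian map long before it
visibly degrades the CT itself. `ctviqa` is an R toolbox for quantifying that
effect and for testing whether noise-reduction preprocessing restores CTVI
consistency. It is aimed at medical-physics and image-analysis researchers
who need a fully synthetic, ground-truthed testbed rather than patient data.

The package provides:

* a **digital nonrigid alveoli phantom** — a cylinder of lung-like foam
  texture with a diaphragm-driven analytic deformation, known ventilation
  map, and auto-placed landmarks (`generate_phantom()`);
* **quantum-noise simulation** as seeded additive Gaussian noise in HU
  (`add_gaussian_noise()`);
* two denoisers: a slice-wise 3×3 **median filter** (`median_filter()`) and a
  small 2-D **U-Net** trained with an L1 loss, implemented from scratch in
  vectorized R including backpropagation and Adam (`train_denoiser()`,
  `denoise_cnn()`);
* **multi-step B-spline free-form registration** with NMI or SSD similarity,
  bending-energy and Jacobian penalties, composition-based field integration
  and an automated over-deformation gate (`register_ffd()`);
* **Jacobian ventilation maps** and even-range low/middle/high
  categorization (`jacobian_map()`, `tertile_thresholds()`,
  `classify_ventilation()`);
* **consistency metrics** — landmark displacement, target registration error
  (TRE) with a 3 mm QA tolerance flag, 3×3 category agreement, Cohen's kappa,
  2-D histograms and Spearman correlation (`target_registration_error()`,
  `consistency_report()`);
* an **experiment runner** comparing the noisy, median-filtered and
  CNN-denoised pipelines against a noiseless reference across noise levels
  (`run_experiment()`, `summarize_experiment()`).

NIfTI-1 volumes/fields and CSV landmark lists are read and written with
strict metadata round-tripping (`read_volume()`, `read_landmarks()`).

## Worked example

```r
library(ctviqa)

## phantom with known ground truth (96 x 96 x 48 @ 2 x 2 x 3 mm)
ph <- generate_phantom(phantom_spec(seed = 1))
landmark_displacement(ph$landmarks_exhale, ph$landmarks_inhale)$mean
#> [1] 13.17208          # mean breathing displacement in mm

## register the clean pair and score spatial accuracy
cfg <- reg_config(n_steps = 2, levels = 3, max_iterations = 40,
                  similarity = "ssd", bending_weight = 1,
                  jacobian_weight = 0.05)
dvf <- register_ffd(ph$exhale, ph$inhale, cfg)
tre <- target_registration_error(ph$landmarks_exhale, ph$landmarks_inhale, dvf)
c(tre$mean, tre$max)
#> [1] 0.7752547 1.6449870   # mm; well inside the 3 mm QA tolerance

## ventilation map and agreement with the ground truth
ctvi <- jacobian_map(dvf, ph$foam_mask)
spearman_correlation(ph$true_ventilation, ctvi)$rho
#> [1] 0.8103909
```

A full comparative run (noiseless reference plus noisy / median / CNN
branches at 30, 80, 150 HU, with the CNN trained on the phantom's clean
slices) and its kappa table:

```r
ex <- run_experiment(desk_experiment_config(seed = 1))
summarize_experiment(ex)$kappa
#>   method sigma_hu     kappa kappa_p agreement
#> 1  noise       30 0.7178697       0 0.8421826
#> 2 median       30 0.9060813       0 0.9448860
#> 3    cnn       30 0.7915813       0 0.8804181
#> 4  noise       80 0.3435543       0 0.6253595
#> 5 median       80 0.6260763       0 0.7875416
#> 6    cnn       80 0.5086346       0 0.7256976
#> 7  noise      150 0.1459092       0 0.4857894
#> 8 median      150 0.4271584       0 0.6746581
#> 9    cnn      150 0.2733528       0 0.5626261
```

Reading the table: added noise erodes categorical agreement with the
noiseless reference (kappa 0.72 → 0.15 as sigma grows from 30 to 150 HU),
and both denoisers recover a large part of it, with the largest relative
gains of the learned denoiser appearing at the highest noise level. The
corresponding Spearman table and a TRE table (mean ± SD, max in mm per
branch) come from the same `summarize_experiment()` call. (~16 minutes on
one CPU, dominated by the ten registrations and the short CNN training.)

## Layout

```
R/                  phantom, noise, denoise (median + U-Net), registration,
                    ventilation, evaluation, pipeline, NIfTI/CSV I/O
scripts/acceptance.R
tests/testthat/     unit, property and acceptance tests (all synthetic)
vignettes/          methods vignette: models, parameters, design choices
```
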