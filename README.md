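# petcoreg

Simulating how rigid coregistration perturbs PET metabolic volumetry.

## The problem

Quantitative FDG-PET endpoints — SUVmax, metabolic tumor volume (MTV,
ml) and total lesion glycolysis (TLG = MTV × SUVmean) — are usually read
from the PET volume *after* rigid coregistration to a CT, i.e. after
resampling the PET onto the CT voxel lattice by trilinear interpolation.
Even a purely rigid (rotation + translation) transform therefore changes
every voxel the reads are computed from:

- a translation by an exact multiple of the voxel size incurs **no
  interpolation** (the resampled volume is an index-shifted copy);
- a translation by half a voxel maximizes it (every output voxel
  averages two neighbours);
- trilinear interpolation is a convex combination, so the resampled
  maximum never exceeds the source maximum — SUVmax can only drop under
  noise-free pure resampling;
- the effect grows with grid coarseness: 5 mm CT slices are much worse
  than 1 mm slices.

`petcoreg` replicates this pipeline end to end on digital lung-lesion
phantoms with analytic ground truth, for researchers who want to
quantify (or teach) how much of a "response" or "progression" in
MTV/TLG can be pure resampling arithmetic. It provides:

- image geometry, rigid transforms (intrinsic Z-Y-X Euler angles about
  an explicit center) and trilinear resampling, with NIfTI-1 I/O;
- a synthetic-data generator: blurred (5 mm FWHM), noisy lesion
  phantoms in the printed cohort ranges (1.1–27.2 ml, SUV 1.6–30.9),
  homogeneous or with cold necrotic cores, plus matched pseudo-CT
  volumes and a thorax body model;
- mutual-information rigid registration with `fast`/`slow` sampling
  modes (the commercial fast/slow contrast);
- four threshold segmentation methods: fixed T40/T50/T60 and a
  background-adapted volume-reproducing adaptive threshold (AT) with a
  calibration routine;
- SUVmax/MTV/TLG quantification and deviation records (coregistered −
  original, %);
- paired Wilcoxon signed-rank tests (exact by enumeration up to n = 12),
  Bland–Altman limits of agreement, grouped summary tables, and ggplot
  builders for Bland–Altman and box plots;
- the orchestrating study pipeline (`run_study()`), a sub-voxel
  `shift_sweep()`, a `heterogeneity_contrast()` experiment and a
  known-truth `registration_experiment()`.

## Worked example

A necrotic lesion (true volume 6.7 ml), resampled onto the 5 mm slice
CT grid with no shift (the "original" arm, OR) and with a half-voxel
axial shift (the coregistered arm), both segmented with the adaptive
threshold:

```r
library(petcoreg)

ph <- generate_phantom(
  phantom_spec(radii_mm = c(10, 10, 16), suv_lesion = 8,
               suv_background = 0.5, necrosis_fraction = 0.5),
  geometry_preset("pet")
)

ct5 <- geometry_preset("ct5")
or <- resample_volume(ph$volume, rt_identity(), ct5)
cg <- resample_volume(ph$volume,
                      rigid_transform(translation = c(0, 0, 2.5)), ct5)

voi_or <- lesion_voi(or, ph$truth$center, max(ph$truth$radii_mm))
voi_cg <- lesion_voi(cg, ph$truth$center + c(0, 0, 2.5),
                     max(ph$truth$radii_mm))
q_or <- quantify_lesion(or, segment_lesion(or, voi_or, "AT"))
q_cg <- quantify_lesion(cg, segment_lesion(cg, voi_cg, "AT"))
q_or
#> quant_result [AT]: SUVmax 7.577 | MTV 5.802 ml | SUVmean 5.604 | TLG 32.510 ml
q_cg
#> quant_result [AT]: SUVmax 6.833 | MTV 6.154 ml | SUVmean 5.139 | TLG 31.627 ml

relative_difference(q_cg, q_or)[, c("dsuvmax_pct", "dmtv_pct", "dtlg_pct")]
#>   dsuvmax_pct dmtv_pct dtlg_pct
#> 1       -9.82     6.08    -2.72
```

Nothing about the lesion changed — a 2.5 mm shift alone depressed
SUVmax by 9.8% and inflated the measured MTV by 6.1%. Shifting instead
by 5.0 mm (a full voxel) gives exactly 0% for all three quantities.

The full study design — a seeded 28-lesion cohort, random sub-voxel
misalignments, both CT grids, all four segmentation methods, grouped
summaries with Wilcoxon p-values and limits of agreement — is one call:

```r
res <- run_study(study_config(seed = 1), out_dir = "study_out")
res$summary
plot_bland_altman(res$deviations, "mtv")
```

A thin command-line front end over the same functions ships at
`inst/cli/petcoreg` (subcommands `simulate`, `register`, `resample`,
`segment`, `quantify`, `study`, `sweep`, `hetero`).

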