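test_that("voxelized sphere volume approximates the analytic volume", {
  g <- image_geometry(c(40, 40, 40), c(1, 1, 1))
  ph <- generate_phantom(
    phantom_spec(radii_mm = 10, psf_fwhm = 0, noise_sd = 0,
                 suv_background = 0),
    g
  )
  vox_ml <- sum(ph$support) * voxel_volume_mm3(g) / 1000
  expect_equal(ph$truth$volume_ml, 4 / 3 * pi * 1000 / 1000)
  expect_lt(abs(vox_ml - 4.18879) / 4.18879, 0.02)
})

test_that("Gaussian blur conserves total background-subtracted activity", {
  g <- image_geometry(c(36, 36, 36), c(2, 2, 2))
  spec0 <- phantom_spec(radii_mm = 10, psf_fwhm = 0, noise_sd = 0,
                        suv_lesion = 8, suv_background = 1)
  spec5 <- phantom_spec(radii_mm = 10, psf_fwhm = 5, noise_sd = 0,
                        suv_lesion = 8, suv_background = 1)
  sum0 <- sum(generate_phantom(spec0, g)$volume$values - 1)
  sum5 <- sum(generate_phantom(spec5, g)$volume$values - 1)
  expect_lt(abs(sum5 - sum0) / sum0, 0.001)
})

test_that("phantom generation is bit-identical under a fixed seed", {
  g <- geometry_preset("pet")
  spec <- phantom_spec(radii_mm = 12, noise_sd = 0.3, seed = 77)
  a <- generate_phantom(spec, g)
  b <- generate_phantom(spec, g)
  expect_identical(a$volume$values, b$volume$values)
})

test_that("partial volume effect lowers small-lesion SUVmax but not large", {
  g <- image_geometry(c(60, 60, 48), c(2, 2, 2.5))
  big <- generate_phantom(
    phantom_spec(radii_mm = 20, psf_fwhm = 5, noise_sd = 0,
                 suv_lesion = 8, suv_background = 0.5), g)
  expect_lt(abs(max(big$volume$values) - 8) / 8, 0.01)
  small <- generate_phantom(
    phantom_spec(radii_mm = 4, psf_fwhm = 5, noise_sd = 0,
                 suv_lesion = 8, suv_background = 0.5), g)
  expect_lt(max(small$volume$values), 8)
})

test_that("the global maximum stays near the lesion under blur and noise", {
  g <- geometry_preset("pet")
  for (s in 1:5) {
    ph <- generate_phantom(
      phantom_spec(radii_mm = 9, noise_sd = 0.3, seed = s), g)
    peak <- arrayInd(which.max(ph$volume$values), g$shape)
    peak_world <- voxel_to_world(g, as.vector(peak) - 1)
    dist <- sqrt(sum((peak_world - ph$truth$center)^2))
    expect_lte(dist, max(ph$truth$radii_mm) + 2 * ph$spec$psf_fwhm)
  }
})

test_that("lesions that do not fit inside the grid are rejected", {
  g <- tiny_geom(c(8, 8, 8), c(2, 2, 2))
  expect_error(generate_phantom(phantom_spec(radii_mm = 12), g), "fit")
})

test_that("pseudo-CT places the lesion where the offset transform says", {
  pet_g <- geometry_preset("pet", c(130, 130, 100))
  ct_g <- geometry_preset("ct5", c(130, 130, 100))
  spec <- phantom_spec(radii_mm = 12, suv_lesion = 8, noise_sd = 0)
  ph <- generate_phantom(spec, pet_g)

  centroid <- function(v, thresh) {
    idx <- petcoreg:::grid_indices(v$geometry$shape)
    w <- as.vector(v$values) > thresh
    colMeans(voxel_to_world(v$geometry, idx[w, , drop = FALSE]))
  }
  # aligned case: PET and CT lesion centroids agree within half a voxel
  ct0 <- generate_pseudo_ct(spec, ct_g, noise_sd = 0, texture_sd = 0)
  c_pet <- centroid(ph$volume, 4)
  c_ct <- centroid(ct0, -300)
  expect_lt(max(abs(c_pet - c_ct)), max(pet_g$spacing) / 2)

  # known offset: centroid displacement equals the translation
  tr <- rigid_transform(translation = c(6.3, -4.2, 5.0))
  ct1 <- generate_pseudo_ct(spec, ct_g, offset = tr, noise_sd = 0,
                            texture_sd = 0)
  shift <- centroid(ct1, -300) - c_ct
  expect_lt(max(abs(shift - c(6.3, -4.2, 5.0))), max(ct_g$spacing))
})

test_that("PET and pseudo-CT intensities are not linearly related", {
  pet_g <- geometry_preset("pet", c(130, 130, 100))
  ct_g <- geometry_preset("ct5", c(130, 130, 100))
  spec <- phantom_spec(radii_mm = 10, suv_lesion = 8, noise_sd = 0)
  ph <- generate_phantom(spec, pet_g)
  ct <- generate_pseudo_ct(spec, ct_g)
  ct_on_pet <- resample_volume(ct, rt_identity(), pet_g,
                               fill = min(ct$values))
  r <- cor(as.vector(ph$volume$values), as.vector(ct_on_pet$values))
  expect_lt(abs(r), 0.9)
})

test_that("cohort truths fall inside the configured ranges and reproduce", {
  g <- geometry_preset("pet")
  cs <- cohort_spec(n_lesions = 28, seed = 5)
  phantoms <- generate_cohort(cs, g)
  truth <- cohort_truth(phantoms)
  expect_equal(nrow(truth), 28)
  expect_true(all(truth$volume_ml >= 1.1 & truth$volume_ml <= 27.2))
  expect_true(all(truth$suvmax >= 1.6 & truth$suvmax <= 30.9))
  # volumes span at least a decade
  expect_gte(max(truth$volume_ml) / min(truth$volume_ml), 10)
  # same master seed, same cohort
  phantoms2 <- generate_cohort(cohort_spec(n_lesions = 28, seed = 5), g)
  expect_identical(phantoms[[13]]$volume$values,
                   phantoms2[[13]]$volume$values)
})
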