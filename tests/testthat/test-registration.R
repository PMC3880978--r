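test_that("joint histogram of an image with itself is diagonal", {
  g <- tiny_geom(c(10, 10, 8), c(2, 2, 2))
  v <- random_volume(g, seed = 1)
  h <- joint_histogram(v, v, rt_identity(), mi_config(n_bins = 16))
  expect_equal(sum(h), prod(g$shape))
  expect_equal(sum(diag(h)), sum(h))
})

test_that("a constant second image collapses to a single histogram column", {
  g <- tiny_geom()
  a <- random_volume(g, seed = 2)
  b <- volume3d(array(5, g$shape), g)
  h <- joint_histogram(a, b, rt_identity(), mi_config(n_bins = 16))
  nonzero_cols <- which(colSums(h) > 0)
  expect_length(nonzero_cols, 1)
})

test_that("subsampled joint histograms are reproducible under a seed", {
  g <- tiny_geom(c(12, 12, 10), c(2, 2, 2))
  a <- random_volume(g, seed = 3)
  b <- random_volume(g, seed = 4)
  cfg <- mi_config(n_bins = 16, seed = 9)
  h1 <- joint_histogram(a, b, rt_identity(), cfg, sample_fraction = 0.3)
  h2 <- joint_histogram(a, b, rt_identity(), cfg, sample_fraction = 0.3)
  expect_identical(h1, h2)
  expect_equal(sum(h1), ceiling(0.3 * prod(g$shape)))
})

test_that("non-overlapping volumes raise an error", {
  g <- tiny_geom()
  v <- random_volume(g)
  far <- rigid_transform(translation = c(1e4, 0, 0))
  expect_error(joint_histogram(v, v, far, mi_config()), "overlap")
})

test_that("mutual information matches hand-computed values", {
  expect_equal(mutual_information(matrix(c(2, 0, 0, 2), 2, 2)), 1)
  # independent marginals carry zero information
  px <- c(0.2, 0.3, 0.5)
  py <- c(0.6, 0.4)
  h <- outer(px, py) * 1000
  expect_equal(mutual_information(h), 0, tolerance = 1e-12)
})

test_that("MI of an image with itself equals its marginal entropy", {
  g <- tiny_geom(c(10, 10, 10), c(2, 2, 2))
  v <- random_volume(g, seed = 6)
  h <- joint_histogram(v, v, rt_identity(), mi_config(n_bins = 32))
  p <- rowSums(h) / sum(h)
  p <- p[p > 0]
  entropy <- -sum(p * log2(p))
  expect_equal(mutual_information(h), entropy, tolerance = 1e-12)
  # and MI is bounded by the marginal entropies in the cross case
  b <- random_volume(g, seed = 7)
  h2 <- joint_histogram(v, b, rt_identity(), mi_config(n_bins = 32))
  pa <- rowSums(h2) / sum(h2)
  pb <- colSums(h2) / sum(h2)
  expect_lte(mutual_information(h2),
             min(-sum(pa[pa > 0] * log2(pa[pa > 0])),
                 -sum(pb[pb > 0] * log2(pb[pb > 0]))) + 1e-12)
})

test_that("self-registration recovers the identity", {
  pet_g <- geometry_preset("pet", c(120, 120, 80))
  ph <- generate_phantom(
    phantom_spec(radii_mm = c(14, 10, 9), suv_lesion = 8, noise_sd = 0),
    pet_g
  )
  reg <- register_rigid(ph$volume, ph$volume, "slow",
                        mi_config(seed = 1, n_bins = 32))
  p <- rt_parameters(reg$transform)
  expect_lt(max(abs(p$translation_mm)), 0.1)
  expect_lt(max(abs(p$rotation_deg)), 0.1)
})

test_that("a known translation is recovered within half a voxel per axis", {
  pet_g <- geometry_preset("pet", c(140, 140, 100))
  ct_g <- geometry_preset("ct5", c(140, 140, 100))
  bm <- body_model()
  spec <- phantom_spec(radii_mm = c(14, 10, 9), suv_lesion = 8,
                       noise_sd = 0)
  scene <- generate_scene(list(spec), pet_g, body = bm)
  t_true <- rigid_transform(translation = c(3.5, -2.1, 1.0),
                            center = world_center(ct_g))
  ct <- generate_pseudo_ct(spec, ct_g, offset = t_true, body = bm,
                           noise_sd = 0)
  reg <- register_rigid(scene$volume, ct, "slow", mi_config(seed = 2),
                        translation_only = TRUE)
  err <- rt_parameters(reg$transform)$translation_mm - c(3.5, -2.1, 1.0)
  expect_lt(max(abs(err)), 0.5 * min(ct_g$spacing))
})

test_that("registration is invariant to a monotone intensity remapping", {
  pet_g <- geometry_preset("pet", c(140, 140, 100))
  ct_g <- geometry_preset("ct5", c(140, 140, 100))
  bm <- body_model()
  spec <- phantom_spec(radii_mm = c(14, 10, 9), suv_lesion = 8,
                       noise_sd = 0)
  scene <- generate_scene(list(spec), pet_g, body = bm)
  t_true <- rigid_transform(translation = c(3.5, -2.1, 1.0),
                            center = world_center(ct_g))
  ct <- generate_pseudo_ct(spec, ct_g, offset = t_true, body = bm,
                           noise_sd = 0)
  remapped <- volume3d(exp(scene$volume$values / 4), pet_g)
  reg_plain <- register_rigid(scene$volume, ct, "slow",
                              mi_config(seed = 2),
                              translation_only = TRUE)
  reg_mono <- register_rigid(remapped, ct, "slow", mi_config(seed = 2),
                             translation_only = TRUE)
  delta <- rt_parameters(reg_mono$transform)$translation_mm -
    rt_parameters(reg_plain$transform)$translation_mm
  expect_lt(max(abs(delta)), 0.5 * min(ct_g$spacing))
})

test_that("MI at the true transform beats a two-voxel perturbation", {
  pet_g <- geometry_preset("pet", c(140, 140, 100))
  ct_g <- geometry_preset("ct5", c(140, 140, 100))
  bm <- body_model()
  spec <- phantom_spec(radii_mm = c(14, 10, 9), suv_lesion = 8,
                       noise_sd = 0)
  scene <- generate_scene(list(spec), pet_g, body = bm)
  t_true <- rigid_transform(translation = c(2.0, -1.0, 2.5),
                            center = world_center(ct_g))
  ct <- generate_pseudo_ct(spec, ct_g, offset = t_true, body = bm,
                           noise_sd = 0)
  obj <- petcoreg:::make_mi_objective(ct, scene$volume,
                                      mi_config(seed = 3), 0.5,
                                      world_center(ct_g), TRUE)$objective
  mi_true <- obj(c(2.0, -1.0, 2.5))
  for (axis in 1:3) {
    pert <- c(2.0, -1.0, 2.5)
    pert[axis] <- pert[axis] + 2 * ct_g$spacing[axis]
    expect_gt(mi_true, obj(pert))
  }
})
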