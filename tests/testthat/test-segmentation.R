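make_cube_volume <- function() {
  g <- tiny_geom(c(12, 12, 12), c(2, 2, 2))
  arr <- array(0, g$shape)
  arr[5:8, 5:8, 5:8] <- 10
  volume3d(arr, g)
}

test_that("fixed threshold delineates a cube in zero background exactly", {
  v <- make_cube_volume()
  voi <- lesion_voi(v, c(0, 0, 0), radius_mm = 6, margin_mm = 8)
  m <- fixed_threshold_segment(v, voi, 0.40)
  want <- array(FALSE, dim(v$values))
  want[5:8, 5:8, 5:8] <- TRUE
  expect_identical(m$mask, want)
  expect_equal(m$threshold, 4)
})

test_that("a voxel exactly at the threshold is included (at-least semantics)", {
  g <- tiny_geom(c(9, 9, 9), c(2, 2, 2))
  arr <- array(0, g$shape)
  arr[5, 5, 5] <- 10
  arr[6, 5, 5] <- 4  # exactly 40% of the maximum
  v <- volume3d(arr, g)
  voi <- lesion_voi(v, c(0, 0, 0), radius_mm = 4, margin_mm = 4)
  m <- fixed_threshold_segment(v, voi, 0.40)
  expect_true(m$mask[6, 5, 5])
})

test_that("threshold voxel counts match an exhaustive scan oracle", {
  g <- tiny_geom(c(5, 5, 5), c(2, 2, 2))
  set.seed(13)
  arr <- array(runif(125), g$shape)
  arr[3, 3, 3] <- 1  # ensure the maximum sits at the center
  v <- volume3d(arr, g)
  voi <- lesion_voi(v, c(0, 0, 0), radius_mm = 4, margin_mm = 2)
  m <- fixed_threshold_segment(v, voi, 0.50)
  # oracle: exhaustive flood fill from the seed over >= threshold voxels
  cand <- arr >= 0.5 * max(arr)
  comp <- array(FALSE, dim(cand))
  comp[3, 3, 3] <- TRUE
  repeat {
    grown <- comp
    for (i in which(comp)) {
      ijk <- arrayInd(i, dim(comp))
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        p <- ijk + c(dx, dy, dz)
        if (all(p >= 1) && all(p <= 5) && cand[p[1], p[2], p[3]])
          grown[p[1], p[2], p[3]] <- TRUE
      }
    }
    if (identical(grown, comp)) break
    comp <- grown
  }
  expect_identical(m$mask, comp)
})

test_that("fixed thresholds are nested: T60 within T50 within T40", {
  g <- geometry_preset("pet")
  for (s in 1:4) {
    ph <- generate_phantom(
      phantom_spec(radii_mm = 8 + 2 * s, suv_lesion = 6, noise_sd = 0.2,
                   seed = s), g)
    voi <- lesion_voi(ph$volume, ph$truth$center, max(ph$truth$radii_mm))
    m40 <- fixed_threshold_segment(ph$volume, voi, 0.40)$mask
    m50 <- fixed_threshold_segment(ph$volume, voi, 0.50)$mask
    m60 <- fixed_threshold_segment(ph$volume, voi, 0.60)$mask
    expect_true(all(m50[m60]))
    expect_true(all(m40[m50]))
    # every method's mask contains the seed voxel
    at <- adaptive_threshold_segment(ph$volume, voi)
    for (m in list(m40, m50, m60, at$mask)) {
      expect_true(m[voi$seed[1], voi$seed[2], voi$seed[3]])
    }
  }
})

test_that("background estimation returns a constant background exactly", {
  g <- tiny_geom(c(16, 16, 16), c(2, 2, 2))
  arr <- array(1.25, g$shape)
  arr[7:10, 7:10, 7:10] <- 9
  v <- volume3d(arr, g)
  voi <- lesion_voi(v, c(0, 0, 0), radius_mm = 6, margin_mm = 10)
  m <- fixed_threshold_segment(v, voi, 0.40)
  expect_equal(estimate_background(v, m), 1.25)
})

test_that("a mask filling its whole VOI leaves no background shell", {
  g <- tiny_geom(c(8, 8, 8), c(2, 2, 2))
  v <- volume3d(array(5, g$shape) + array(seq_len(512) * 1e-9, c(8, 8, 8)),
                g)
  voi <- lesion_voi(v, c(0, 0, 0), radius_mm = 20, margin_mm = 0)
  m <- fixed_threshold_segment(v, voi, 0.40)
  expect_error(estimate_background(v, m), "shell")
})

test_that("with zero background AT reduces to a fixed threshold at f max", {
  v <- make_cube_volume()
  voi <- lesion_voi(v, c(0, 0, 0), radius_mm = 6, margin_mm = 8)
  at <- adaptive_threshold_segment(v, voi, f = 0.55)
  expect_true(at$converged)
  expect_equal(at$background, 0)
  expect_equal(at$threshold, 0.55 * 10)
  fixed <- petcoreg:::threshold_component(v, voi, 5.5)
  expect_identical(at$mask, fixed)
})

test_that("AT is invariant under a global additive offset; fixed thresholds are not", {
  g <- geometry_preset("pet")
  ph <- generate_phantom(
    phantom_spec(radii_mm = 11, suv_lesion = 6, suv_background = 1,
                 noise_sd = 0.1, seed = 3), g)
  voi <- lesion_voi(ph$volume, ph$truth$center, max(ph$truth$radii_mm))
  shifted <- volume3d(ph$volume$values + 2.5, g)

  at0 <- adaptive_threshold_segment(ph$volume, voi)
  at1 <- adaptive_threshold_segment(shifted, voi)
  expect_identical(at0$mask, at1$mask)

  t40_0 <- fixed_threshold_segment(ph$volume, voi, 0.40)
  t40_1 <- fixed_threshold_segment(shifted, voi, 0.40)
  expect_false(identical(t40_0$mask, t40_1$mask))
})

test_that("larger volume-reproducing fractions give smaller masks", {
  g <- geometry_preset("ct5", c(110, 110, 90))
  ph <- calibration_spheres(g, volumes_ml = 6)[[1]]
  voi <- lesion_voi(ph$volume, ph$truth$center, max(ph$truth$radii_mm))
  sizes <- vapply(c(0.3, 0.45, 0.6), function(f)
    sum(adaptive_threshold_segment(ph$volume, voi, f = f)$mask),
    numeric(1))
  expect_true(all(diff(sizes) < 0))
})

test_that("calibrated AT recovers a blurred-sphere volume within 15 percent", {
  g <- geometry_preset("ct5", c(110, 110, 90))
  f <- calibrated_f()
  expect_gt(f, 0.2)
  expect_lt(f, 0.8)
  # held-out sphere, not part of the calibration set
  ph <- calibration_spheres(g, volumes_ml = 4.18879)[[1]]
  voi <- lesion_voi(ph$volume, ph$truth$center, max(ph$truth$radii_mm))
  at <- adaptive_threshold_segment(ph$volume, voi, f = f)
  mtv <- sum(at$mask) * voxel_volume_mm3(g) / 1000
  expect_lt(abs(mtv - 4.18879) / 4.18879, 0.15)
})

test_that("degenerate calibration inputs are rejected", {
  g <- geometry_preset("ct5", c(110, 110, 90))
  one <- calibration_spheres(g, volumes_ml = 6)
  expect_error(calibrate_volume_reproducing_fraction(one), "at least 3")
  narrow <- calibration_spheres(g, volumes_ml = c(4, 5, 6))
  expect_error(calibrate_volume_reproducing_fraction(narrow), "decade")
})
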