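# Independent oracles and shared fixtures, kept deliberately separate
# from the package implementation paths they check.

# Brute-force trilinear interpolation: explicit weighted sum over the 8
# surrounding corners with product weights (1 - d) / d per axis.
trilinear_oracle <- function(arr, idx0) {
  d <- dim(arr)
  if (any(idx0 < 0) || any(idx0 > d - 1)) return(NA_real_)
  i0 <- pmin(floor(idx0), d - 2)
  i0 <- pmax(i0, 0)
  fr <- idx0 - i0
  val <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) fr[1] else 1 - fr[1]) *
      (if (cy) fr[2] else 1 - fr[2]) *
      (if (cz) fr[3] else 1 - fr[3])
    val <- val + w * arr[i0[1] + cx + 1, i0[2] + cy + 1, i0[3] + cz + 1]
  }
  val
}

# Exact two-sided Wilcoxon signed-rank p-value by full enumeration over
# all 2^n sign patterns of the observed absolute-value ranks.
wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- as.vector(signs %*% r)
  eps <- 1e-9
  min(1, 2 * min(mean(sums >= w - eps), mean(sums <= w + eps)))
}

# Small test grid.
tiny_geom <- function(shape = c(8, 8, 8), spacing = c(2, 2, 2)) {
  image_geometry(shape, spacing)
}

random_volume <- function(geom, seed = 1) {
  set.seed(seed)
  volume3d(array(runif(prod(geom$shape)), geom$shape), geom)
}

# Noise-free blurred spheres spanning more than a decade of volume, for
# calibrating the adaptive threshold's volume-reproducing fraction.
calibration_spheres <- function(geom, volumes_ml = c(1.2, 4, 14),
                                suv_lesion = 8, suv_background = 1) {
  lapply(volumes_ml, function(v) {
    r <- (3 * v * 1000 / (4 * pi))^(1 / 3)
    generate_phantom(
      phantom_spec(radii_mm = r, suv_lesion = suv_lesion,
                   suv_background = suv_background, noise_sd = 0),
      geom
    )
  })
}

# The calibrated fraction is reused by several tests; cache it for the
# session.
.calib_cache <- new.env(parent = emptyenv())
calibrated_f <- function() {
  if (is.null(.calib_cache$f)) {
    geom <- geometry_preset("ct5", c(110, 110, 90))
    .calib_cache$f <-
      calibrate_volume_reproducing_fraction(calibration_spheres(geom))
  }
  .calib_cache$f
}
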