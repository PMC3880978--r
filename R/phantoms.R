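#' Specification of a single lesion phantom
#'
#' Describes an idealized solid lung lesion: a sphere or ellipsoid of
#' elevated uptake in a low, homogeneous lung background, optionally with
#' a cold necrotic core (the heterogeneous case), voxelized by
#' center-inclusion, convolved with the isotropic Gaussian reconstruction
#' point-spread function, and finally degraded with additive Gaussian
#' noise clipped at 0 SUV.
#'
#' @param center lesion center, world mm triple.
#' @param radii_mm radius (sphere) or three semi-axes (ellipsoid), mm.
#' @param suv_lesion lesion uptake, SUV; must exceed `suv_background`.
#' @param suv_background lung background uptake, SUV (>= 0).
#' @param necrosis_fraction `NULL` for a homogeneous lesion, otherwise
#'   the core radius as a fraction of the lesion radii (in (0, 1)).
#' @param suv_core core uptake for heterogeneous lesions; defaults to the
#'   background (cold necrosis). Must be below `suv_lesion`.
#' @param psf_fwhm reconstruction blur, mm FWHM (default 5).
#' @param noise_sd post-blur Gaussian noise, SUV.
#' @param seed RNG seed for the noise draw.
#' @param label free text.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(center = c(0, 0, 0), radii_mm = 10,
                         suv_lesion = 8, suv_background = 0.5,
                         necrosis_fraction = NULL, suv_core = NULL,
                         psf_fwhm = 5, noise_sd = 0, seed = 1L,
                         label = "") {
  if (length(radii_mm) == 1L) radii_mm <- rep(radii_mm, 3L)
  radii_mm <- as.numeric(radii_mm)
  if (length(radii_mm) != 3L || any(radii_mm <= 0))
    stopf("`radii_mm` must be one or three positive radii")
  if (!is.finite(suv_lesion) || !is.finite(suv_background) ||
      suv_background < 0 || suv_lesion <= suv_background)
    stopf("need suv_lesion > suv_background >= 0")
  if (!is.null(necrosis_fraction)) {
    if (necrosis_fraction <= 0 || necrosis_fraction >= 1)
      stopf("`necrosis_fraction` must be in (0, 1)")
    suv_core <- suv_core %||% suv_background
    if (suv_core < 0 || suv_core >= suv_lesion)
      stopf("need 0 <= suv_core < suv_lesion")
  }
  if (psf_fwhm < 0) stopf("`psf_fwhm` must be >= 0")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  structure(
    list(center = as.numeric(center), radii_mm = radii_mm,
         suv_lesion = suv_lesion, suv_background = suv_background,
         necrosis_fraction = necrosis_fraction, suv_core = suv_core,
         psf_fwhm = psf_fwhm, noise_sd = noise_sd,
         seed = as.integer(seed), label = label),
    class = "phantom_spec"
  )
}

# Ellipsoid membership of world points for one spec, optionally with the
# lesion displaced by a rigid transform (membership is evaluated at
# transform^-1(x)).
ellipsoid_inside <- function(pts, center, radii, shrink = 1) {
  rel <- sweep(pts, 2L, center, `-`)
  rel <- sweep(rel, 2L, radii * shrink, `/`)
  rowSums(rel^2) <= 1
}

# Ideal piecewise-constant activity for a list of specs on given world
# points; returns list(values, support).
voxelize_specs <- function(specs, pts, background) {
  values <- rep(background, nrow(pts))
  support <- rep(FALSE, nrow(pts))
  for (s in specs) {
    inside <- ellipsoid_inside(pts, s$center, s$radii_mm)
    values[inside] <- s$suv_lesion
    if (!is.null(s$necrosis_fraction)) {
      core <- ellipsoid_inside(pts, s$center, s$radii_mm,
                               shrink = s$necrosis_fraction)
      values[core] <- s$suv_core
    }
    support <- support | inside
  }
  list(values = values, support = support)
}

#' Thorax body model for two-modality scenes
#'
#' A simple torso: an elliptic cylinder of soft tissue (chest wall)
#' surrounded by air, with a lung compartment inside holding the
#' lesions. The body outline and chest wall are visible in both PET
#' (mild soft-tissue uptake) and CT (soft-tissue density), providing the
#' whole-field shared structure that anchors mutual-information
#' registration in clinical images; lesion uptake and density remain
#' non-monotonically related between the modalities (chest wall and
#' lesion share the same density while their uptake differs grossly).
#'
#' @param semi_axes_mm in-plane semi-axes of the body ellipse, mm; an
#'   eccentric cross-section makes in-plane rotation identifiable.
#' @param lung_scale lung compartment as a fraction of the body ellipse.
#' @param taper fractional narrowing of the body at `z_half_mm` (a
#'   barrel-shaped torso, so axial position and out-of-plane rotations
#'   are identifiable too).
#' @param z_half_mm axial half-length scale of the taper, mm.
#' @param suv_wall,suv_lung,suv_air PET uptake of wall, lung, air.
#' @param hu_wall,hu_lung,hu_air CT density of wall, lung, air.
#' @return A list of class `body_model`.
#' @export
body_model <- function(semi_axes_mm = c(75, 55), lung_scale = 0.8,
                       taper = 0.15, z_half_mm = 55,
                       suv_wall = 1.0, suv_lung = 0.4, suv_air = 0,
                       hu_wall = 30, hu_lung = -800, hu_air = -1000) {
  structure(
    list(semi_axes_mm = as.numeric(semi_axes_mm), lung_scale = lung_scale,
         taper = taper, z_half_mm = z_half_mm,
         suv_wall = suv_wall, suv_lung = suv_lung, suv_air = suv_air,
         hu_wall = hu_wall, hu_lung = hu_lung, hu_air = hu_air),
    class = "body_model"
  )
}

# Classify world points into air (0), chest wall (1), lung (2).
body_regions <- function(body, pts) {
  s <- 1 - body$taper * (pts[, 3] / body$z_half_mm)^2
  s <- pmax(s, 0.2)
  r2 <- (pts[, 1] / (body$semi_axes_mm[1] * s))^2 +
    (pts[, 2] / (body$semi_axes_mm[2] * s))^2
  region <- integer(nrow(pts))
  region[r2 <= 1] <- 1L
  region[r2 <= body$lung_scale^2] <- 2L
  region
}

body_background_suv <- function(body, pts) {
  region <- body_regions(body, pts)
  vals <- rep(body$suv_air, nrow(pts))
  vals[region == 1L] <- body$suv_wall
  vals[region == 2L] <- body$suv_lung
  vals
}

check_fits <- function(spec, g) {
  margin <- max(spec$radii_mm) + spec$psf_fwhm
  lo <- voxel_to_world(g, c(0, 0, 0))
  hi <- voxel_to_world(g, g$shape - 1)
  bounds <- rbind(pmin(lo, hi), pmax(lo, hi))
  if (any(spec$center - margin < bounds[1, ]) ||
      any(spec$center + margin > bounds[2, ]))
    stopf("lesion (center +/- radius + PSF margin) does not fit inside the grid")
}

#' Generate a PET lesion phantom with analytic ground truth
#'
#' The ideal activity map is voxelized by center-inclusion, blurred with
#' a Gaussian of `psf_fwhm` mm FWHM (sigma = FWHM / 2.3548; the blur is
#' applied to the background-subtracted map so a constant background is
#' preserved exactly), and seeded Gaussian noise is added and clipped at
#' 0. The true lesion volume is returned analytically as
#' `4/3 * pi * r1 * r2 * r3` (the necrotic core, when present, is part of
#' the lesion support and is not subtracted).
#'
#' @param spec a [phantom_spec()].
#' @param g an [image_geometry()]; the lesion must fit inside with at
#'   least a PSF-width margin.
#' @param body optional [body_model()]; when given, the lesion is
#'   embedded in its lung compartment instead of a uniform background.
#' @return An object of class `pet_phantom`: list with `volume` (a
#'   [volume3d()]), `support` (logical array, pre-blur lesion support),
#'   `truth` (list: `volume_ml`, `suvmax`, `center`, `radii_mm`) and
#'   `spec`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(radii_mm = 12), geometry_preset("pet"))
#' ph$truth$volume_ml
generate_phantom <- function(spec, g, body = NULL) {
  scene <- generate_scene(list(spec), g, body = body)
  structure(
    list(volume = volume3d(scene$volume$values, g, label = spec$label),
         support = scene$support, truth = scene$truth[[1]], spec = spec),
    class = "pet_phantom"
  )
}

#' Generate a multi-lesion PET scene
#'
#' Like [generate_phantom()] but places several lesions in one volume
#' (used e.g. for registration experiments, where multiple well-separated
#' lesions make rotations identifiable). Blur and noise settings are
#' taken from the first spec.
#'
#' @param specs list of [phantom_spec()] objects.
#' @param g an [image_geometry()].
#' @param body optional [body_model()]; when given, the lesions are
#'   embedded in its lung compartment instead of a uniform background.
#' @return A `pet_phantom` whose `truth` holds per-lesion lists.
#' @export
generate_scene <- function(specs, g, body = NULL) {
  for (s in specs) check_fits(s, g)
  lead <- specs[[1]]
  pts <- voxel_to_world(g, grid_indices(g$shape))
  if (is.null(body)) {
    vx <- voxelize_specs(specs, pts, lead$suv_background)
  } else {
    vx <- list(values = body_background_suv(body, pts))
    tmp <- voxelize_specs(specs, pts, 0)
    vx$values[tmp$support] <- tmp$values[tmp$support]
    vx$support <- tmp$support
  }
  arr <- array(vx$values, g$shape)
  if (lead$psf_fwhm > 0) {
    sigma_vox <- (lead$psf_fwhm / (2 * sqrt(2 * log(2)))) / g$spacing
    base <- if (is.null(body)) lead$suv_background else 0
    arr <- base + gaussian_blur(arr - base, sigma_vox)
  }
  if (lead$noise_sd > 0) {
    arr <- with_seed(lead$seed,
                     arr + array(rnorm(length(arr), 0, lead$noise_sd),
                                 dim(arr)))
    arr <- pmax(arr, 0)
  }
  structure(
    list(volume = volume3d(arr, g, label = "scene"),
         support = array(vx$support, g$shape),
         truth = lapply(specs, function(s)
           list(volume_ml = 4 / 3 * pi * prod(s$radii_mm) / 1000,
                suvmax = s$suv_lesion, center = s$center,
                radii_mm = s$radii_mm)),
         spec = specs),
    class = "pet_phantom"
  )
}

#' Generate the structural (pseudo-CT) counterpart of a phantom
#'
#' Produces an HU-like piecewise-constant volume on a CT geometry: low
#' lung background, a soft-tissue-density lesion, plus seeded smooth
#' parenchymal texture and voxel noise in the background. The intensity
#' mapping is deliberately unrelated to the PET SUV mapping (necrotic
#' core and solid rim have near-identical density while their uptake
#' differs grossly; the textured background decorrelates the rest), so
#' that registration against the PET must rely on mutual information
#' rather than on any linear intensity relationship. The anatomy may be
#' displaced by a known rigid transform to simulate PET/CT misalignment:
#' the lesion then appears at `offset(center)`.
#'
#' @param spec a [phantom_spec()] or list of specs.
#' @param g CT [image_geometry()].
#' @param offset a [rigid_transform()]; the true misalignment.
#' @param body optional [body_model()]; when given, the displaced
#'   anatomy includes the torso (air / chest wall / lung classes).
#' @param hu_background,hu_lesion,hu_core HU-like class intensities
#'   (`hu_background` is the uniform background used without a body
#'   model).
#' @param texture_sd,texture_fwhm amplitude (HU) and smoothness (mm) of
#'   the parenchymal texture added to the lung/background region.
#' @param noise_sd CT voxel noise, HU.
#' @param seed RNG seed; defaults to the (first) spec seed + 500.
#' @return A [volume3d()].
#' @export
generate_pseudo_ct <- function(spec, g, offset = rt_identity(),
                               body = NULL, hu_background = -800,
                               hu_lesion = 30, hu_core = 45,
                               texture_sd = 100, texture_fwhm = 8,
                               noise_sd = 40, seed = NULL) {
  specs <- if (inherits(spec, "phantom_spec")) list(spec) else spec
  seed <- seed %||% (specs[[1]]$seed + 500L)
  pts <- voxel_to_world(g, grid_indices(g$shape))
  back <- rt_apply(rt_invert(offset), pts)
  if (is.null(body)) {
    values <- rep(hu_background, nrow(pts))
    texture_zone <- rep(TRUE, nrow(pts))
  } else {
    region <- body_regions(body, back)
    values <- rep(body$hu_air, nrow(pts))
    values[region == 1L] <- body$hu_wall
    values[region == 2L] <- body$hu_lung
    texture_zone <- region == 2L
  }
  inside_any <- rep(FALSE, nrow(pts))
  for (s in specs) {
    inside <- ellipsoid_inside(back, s$center, s$radii_mm)
    values[inside] <- hu_lesion
    if (!is.null(s$necrosis_fraction)) {
      core <- ellipsoid_inside(back, s$center, s$radii_mm,
                               shrink = s$necrosis_fraction)
      values[core] <- hu_core
    }
    inside_any <- inside_any | inside
  }
  arr <- array(values, g$shape)
  with_seed(seed, {
    if (texture_sd > 0) {
      tex <- array(rnorm(length(arr)), dim(arr))
      sigma_vox <- (texture_fwhm / (2 * sqrt(2 * log(2)))) / g$spacing
      tex <- gaussian_blur(tex, sigma_vox)
      tex <- tex * (texture_sd / sd(tex))
      arr <- arr + tex * array(texture_zone & !inside_any, dim(arr))
    }
    if (noise_sd > 0)
      arr <- arr + array(rnorm(length(arr), 0, noise_sd), dim(arr))
  })
  volume3d(arr, g, label = "pseudo-CT")
}

#' Specification of a synthetic lesion cohort
#'
#' Emulates the lesion population of a clinical lung-lesion cohort:
#' lesion volumes drawn log-uniformly over 1.1 to 27.2 ml and lesion SUV
#' drawn uniformly over 1.6 to 30.9 (the printed cohort ranges), with a
#' configurable fraction of heterogeneous (necrotic-core) lesions. Mild
#' random ellipticity and a sub-voxel random placement of each lesion
#' center make the voxelization generic. Per-lesion seeds are derived
#' deterministically from the master seed (`seed + lesion index`).
#'
#' @param n_lesions number of lesions (>= 1).
#' @param volume_range_ml lesion true-volume range, ml.
#' @param suv_range lesion uptake range, SUV.
#' @param frac_heterogeneous fraction of lesions given a cold necrotic
#'   core (radius fraction 0.5).
#' @param suv_background lung background, SUV.
#' @param psf_fwhm reconstruction blur, mm FWHM.
#' @param noise_sd post-blur noise, SUV.
#' @param seed master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_lesions = 28L, volume_range_ml = c(1.1, 27.2),
                        suv_range = c(1.6, 30.9),
                        frac_heterogeneous = 0.25, suv_background = 0.5,
                        psf_fwhm = 5, noise_sd = 0.15, seed = 1L) {
  if (n_lesions < 1L) stopf("`n_lesions` must be >= 1")
  if (length(volume_range_ml) != 2L || diff(volume_range_ml) < 0 ||
      volume_range_ml[1] <= 0)
    stopf("invalid `volume_range_ml`")
  if (length(suv_range) != 2L || diff(suv_range) < 0 ||
      suv_range[1] <= suv_background)
    stopf("invalid `suv_range`")
  if (frac_heterogeneous < 0 || frac_heterogeneous > 1)
    stopf("`frac_heterogeneous` must be in [0, 1]")
  structure(
    list(n_lesions = as.integer(n_lesions),
         volume_range_ml = as.numeric(volume_range_ml),
         suv_range = as.numeric(suv_range),
         frac_heterogeneous = frac_heterogeneous,
         suv_background = suv_background, psf_fwhm = psf_fwhm,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a cohort of lesion phantoms
#'
#' @param cohort a [cohort_spec()].
#' @param g PET [image_geometry()].
#' @param body optional [body_model()] shared by all lesions.
#' @return List of `pet_phantom` objects (see [generate_phantom()]).
#' @export
generate_cohort <- function(cohort, g, body = NULL) {
  n <- cohort$n_lesions
  draws <- with_seed(cohort$seed, {
    vol <- exp(runif(n, log(cohort$volume_range_ml[1]),
                     log(cohort$volume_range_ml[2])))
    suv <- runif(n, cohort$suv_range[1], cohort$suv_range[2])
    het <- runif(n) < cohort$frac_heterogeneous
    ecc <- matrix(exp(runif(3 * n, -0.18, 0.18)), n, 3)
    jit <- matrix(runif(3 * n, -0.5, 0.5), n, 3)
    list(vol = vol, suv = suv, het = het, ecc = ecc, jit = jit)
  })
  lapply(seq_len(n), function(i) {
    e <- draws$ecc[i, ]
    e <- e / exp(mean(log(e)))  # unit geometric mean: volume-preserving
    r0 <- (3 * draws$vol[i] * 1000 / (4 * pi))^(1 / 3)
    spec <- phantom_spec(
      center = draws$jit[i, ] * g$spacing,
      radii_mm = r0 * e,
      suv_lesion = draws$suv[i],
      suv_background = cohort$suv_background,
      necrosis_fraction = if (draws$het[i]) 0.5 else NULL,
      psf_fwhm = cohort$psf_fwhm,
      noise_sd = cohort$noise_sd,
      seed = cohort$seed + i,
      label = sprintf("lesion%02d", i)
    )
    generate_phantom(spec, g, body = body)
  })
}

#' Truth table of a generated cohort
#'
#' @param phantoms list of `pet_phantom` objects.
#' @return Data frame with one row per lesion: true volume (ml), true
#'   SUVmax, heterogeneity flag and spec fields.
#' @export
cohort_truth <- function(phantoms) {
  do.call(rbind, lapply(seq_along(phantoms), function(i) {
    p <- phantoms[[i]]
    data.frame(
      lesion = i,
      label = p$spec$label,
      volume_ml = p$truth$volume_ml,
      suvmax = p$truth$suvmax,
      heterogeneous = !is.null(p$spec$necrosis_fraction),
      noise_sd = p$spec$noise_sd,
      psf_fwhm = p$spec$psf_fwhm,
      seed = p$spec$seed
    )
  }))
}
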