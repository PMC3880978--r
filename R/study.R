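#' Configuration of the in-silico coregistration study
#'
#' Defines the full experiment: a synthetic lesion cohort, the target CT
#' grids (1 mm and 5 mm slices), the transform modes -- `"truth"` applies
#' the known misalignment directly (isolating the pure interpolation
#' effect of the rigid transform), `"rf"` and `"rs"` estimate it by
#' mutual-information registration in fast or slow mode -- the four
#' segmentation methods, and the misalignment distribution (translations
#' uniform within +/- `shift_range_vox` PET voxels per axis, rotations
#' uniform within +/- `rot_range_deg` degrees, seeded).
#'
#' @param cohort a [cohort_spec()].
#' @param grids subset of `c("ct1", "ct5")`.
#' @param modes subset of `c("truth", "rf", "rs")`.
#' @param methods subset of `c("AT", "T40", "T50", "T60")`.
#' @param shift_range_vox half-range of per-axis translations, in PET
#'   voxel units.
#' @param rot_range_deg half-range of per-axis rotations, degrees.
#' @param f_at volume-reproducing fraction used by the AT method.
#' @param voi_margin_mm VOI margin around each lesion.
#' @param fov_mm per-lesion scene field of view, mm.
#' @param mi an [mi_config()] for the registration modes.
#' @param seed master seed for the misalignment draws.
#' @return An object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_spec(),
                         grids = c("ct1", "ct5"),
                         modes = "truth",
                         methods = c("AT", "T40", "T50", "T60"),
                         shift_range_vox = 1.5, rot_range_deg = 2,
                         f_at = 0.41, voi_margin_mm = 12,
                         fov_mm = c(131.2, 131.2, 100),
                         mi = mi_config(), seed = 1L) {
  grids <- match.arg(grids, c("ct1", "ct5"), several.ok = TRUE)
  modes <- match.arg(modes, c("truth", "rf", "rs"), several.ok = TRUE)
  methods <- match.arg(methods, c("AT", "T40", "T50", "T60"),
                       several.ok = TRUE)
  if (!is.finite(shift_range_vox) || !is.finite(rot_range_deg))
    stopf("misalignment ranges must be finite")
  structure(
    list(cohort = cohort, grids = grids, modes = modes, methods = methods,
         shift_range_vox = shift_range_vox, rot_range_deg = rot_range_deg,
         f_at = f_at, voi_margin_mm = voi_margin_mm, fov_mm = fov_mm,
         mi = mi, seed = as.integer(seed)),
    class = "study_config"
  )
}

# Draw the per-lesion true misalignments (one per lesion, shared across
# target grids: the same physical PET/CT mismatch is resampled onto both
# grids, exactly the comparison that isolates grid coarseness).
draw_misalignments <- function(cfg, pet_geom) {
  n <- cfg$cohort$n_lesions
  center <- world_center(pet_geom)
  with_seed(cfg$seed + 7919L, lapply(seq_len(n), function(i) {
    tr <- runif(3, -1, 1) * cfg$shift_range_vox * pet_geom$spacing
    rot <- runif(3, -1, 1) * cfg$rot_range_deg
    rigid_transform(rotation = rot, translation = tr, center = center)
  }))
}

#' Run the full in-silico coregistration study
#'
#' For each lesion: (1) generate the PET phantom (and, for the
#' registration modes, a pseudo-CT offset by the sampled true
#' misalignment); (2) the original (OR) arm resamples the aligned PET
#' onto the target CT geometry with the identity transform; (3) the
#' coregistered arm resamples through the true transform (`"truth"`
#' mode) or through the transform estimated by mutual-information
#' registration (`"rf"` / `"rs"`); (4) both arms are segmented
#' independently with every method; (5) SUVmax, MTV and TLG deviations
#' (coregistered minus original) are recorded; (6) group summaries are
#' computed. Fully deterministic given the seeds. Per-lesion failures
#' are tabulated and do not abort the study.
#'
#' @param cfg a [study_config()].
#' @param out_dir optional directory; when given, deviations, summary,
#'   transform and failure tables are written as CSV plus a JSON run
#'   log.
#' @param verbose print per-lesion progress.
#' @return An object of class `coreg_study`: list with `deviations`,
#'   `summary`, `transforms`, `failures`, `truth`, `config`.
#' @export
run_study <- function(cfg, out_dir = NULL, verbose = FALSE) {
  pet_geom <- geometry_preset("pet", cfg$fov_mm)
  target_geoms <- lapply(cfg$grids, geometry_preset, fov_mm = cfg$fov_mm)
  names(target_geoms) <- cfg$grids

  # thorax scaled to the scene FOV; the lung uptake matches the cohort's
  # lesion background so lesion-level quantification is unaffected
  scene_body <- body_model(semi_axes_mm = 0.45 * cfg$fov_mm[1:2],
                           z_half_mm = cfg$fov_mm[3] / 2,
                           suv_lung = cfg$cohort$suv_background)
  phantoms <- generate_cohort(cfg$cohort, pet_geom, body = scene_body)
  misalign <- draw_misalignments(cfg, pet_geom)

  deviations <- list()
  transforms <- list()
  failures <- list()

  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    t_true <- misalign[[i]]
    if (verbose) message(sprintf("lesion %d/%d", i, length(phantoms)))
    for (grid in cfg$grids) {
      tg <- target_geoms[[grid]]
      res <- tryCatch({
        or_vol <- resample_volume(ph$volume, rt_identity(), tg)
        voi_or <- lesion_voi(or_vol, ph$truth$center,
                             max(ph$truth$radii_mm), cfg$voi_margin_mm)
        or_q <- lapply(cfg$methods, function(m)
          quantify_lesion(or_vol, segment_lesion(or_vol, voi_or, m,
                                                 f = cfg$f_at)))
        names(or_q) <- cfg$methods

        rows <- list()
        trows <- list()
        for (mode in cfg$modes) {
          t_est <- if (mode == "truth") {
            t_true
          } else {
            ct <- generate_pseudo_ct(ph$spec, tg, offset = t_true,
                                     body = scene_body)
            reg <- register_rigid(ph$volume, ct,
                                  mode = if (mode == "rf") "fast" else "slow",
                                  cfg = cfg$mi)
            reg$transform
          }
          cg_vol <- resample_volume(ph$volume, t_est, tg)
          voi_cg <- lesion_voi(cg_vol, rt_apply(t_est, ph$truth$center),
                               max(ph$truth$radii_mm), cfg$voi_margin_mm)
          for (m in cfg$methods) {
            cg_q <- quantify_lesion(cg_vol,
                                    segment_lesion(cg_vol, voi_cg, m,
                                                   f = cfg$f_at))
            rows[[length(rows) + 1L]] <-
              relative_difference(cg_q, or_q[[m]], lesion = i,
                                  grid = grid, mode = mode)
          }
          pt <- rt_parameters(t_true)
          pe <- rt_parameters(t_est)
          trows[[length(trows) + 1L]] <- data.frame(
            lesion = i, grid = grid, mode = mode,
            true_tx = pt$translation_mm[1], true_ty = pt$translation_mm[2],
            true_tz = pt$translation_mm[3],
            true_rx = pt$rotation_deg[1], true_ry = pt$rotation_deg[2],
            true_rz = pt$rotation_deg[3],
            est_tx = pe$translation_mm[1], est_ty = pe$translation_mm[2],
            est_tz = pe$translation_mm[3],
            est_rx = pe$rotation_deg[1], est_ry = pe$rotation_deg[2],
            est_rz = pe$rotation_deg[3]
          )
        }
        list(rows = rows, trows = trows)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          lesion = i, grid = grid, message = conditionMessage(res))
      } else {
        deviations <- c(deviations, res$rows)
        transforms <- c(transforms, res$trows)
      }
    }
  }

  empty_dev <- data.frame()
  out <- structure(
    list(
      deviations = if (length(deviations)) do.call(rbind, deviations)
                   else empty_dev,
      transforms = if (length(transforms)) do.call(rbind, transforms)
                   else empty_dev,
      failures = if (length(failures)) do.call(rbind, failures)
                 else data.frame(lesion = integer(), grid = character(),
                                 message = character()),
      truth = cohort_truth(phantoms),
      config = cfg
    ),
    class = "coreg_study"
  )
  out$summary <- if (nrow(out$deviations))
    summarize_deviations(out$deviations) else empty_dev

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out$deviations, file.path(out_dir, "deviations.csv"),
              row.names = FALSE)
    write.csv(out$summary, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
    write.csv(out$transforms, file.path(out_dir, "transforms.csv"),
              row.names = FALSE)
    write.csv(out$failures, file.path(out_dir, "failures.csv"),
              row.names = FALSE)
    write.csv(out$truth, file.path(out_dir, "truth.csv"),
              row.names = FALSE)
    log <- list(seed = cfg$seed, cohort_seed = cfg$cohort$seed,
                grids = cfg$grids, modes = cfg$modes,
                methods = cfg$methods,
                n_lesions = cfg$cohort$n_lesions,
                package_version =
                  as.character(utils::packageVersion("petcoreg")))
    jsonlite::write_json(log, file.path(out_dir, "run_info.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' @export
print.coreg_study <- function(x, ...) {
  cat(sprintf("coreg_study: %d deviation records, %d failures\n",
              nrow(x$deviations), nrow(x$failures)))
  if (nrow(x$deviations)) {
    med <- summarize_deviations(x$deviations, by = c("grid", "mode"))
    print(med[, c("grid", "mode", "quantity", "median", "median_abs",
                  "wilcoxon_p")])
  }
  invisible(x)
}

#' Deviation versus sub-voxel shift fraction
#'
#' Translates a (noise-free) phantom along one axis of the target grid
#' by `fraction x spacing`, resamples, segments and quantifies, and
#' returns the deviation curves. Deviations vanish at fractions 0 and 1
#' (integer-voxel shifts incur no interpolation) and peak near the
#' half-voxel shift.
#'
#' @param phantom a `pet_phantom` (see [generate_phantom()]).
#' @param target target [image_geometry()].
#' @param fractions shift fractions of the voxel size to evaluate.
#' @param axis axis (1-3) along which to shift.
#' @param methods segmentation methods to evaluate.
#' @param f_at AT volume-reproducing fraction.
#' @param voi_margin_mm VOI margin.
#' @return Data frame: fraction, method, and the three deviation
#'   percentages.
#' @export
shift_sweep <- function(phantom, target, fractions = seq(0, 1, by = 0.1),
                        axis = 3, methods = c("AT", "T40", "T50", "T60"),
                        f_at = 0.41, voi_margin_mm = 12) {
  or_vol <- resample_volume(phantom$volume, rt_identity(), target)
  voi_or <- lesion_voi(or_vol, phantom$truth$center,
                       max(phantom$truth$radii_mm), voi_margin_mm)
  or_q <- lapply(methods, function(m)
    quantify_lesion(or_vol, segment_lesion(or_vol, voi_or, m, f = f_at)))
  names(or_q) <- methods

  rows <- list()
  for (fr in fractions) {
    shift <- numeric(3)
    shift[axis] <- fr * target$spacing[axis]
    tr <- rigid_transform(translation = shift)
    cg_vol <- resample_volume(phantom$volume, tr, target)
    voi_cg <- lesion_voi(cg_vol, phantom$truth$center + shift,
                         max(phantom$truth$radii_mm), voi_margin_mm)
    for (m in methods) {
      cg_q <- quantify_lesion(cg_vol, segment_lesion(cg_vol, voi_cg, m,
                                                     f = f_at))
      rec <- relative_difference(cg_q, or_q[[m]], lesion = NA,
                                 grid = target$label, mode = "shift")
      rec$fraction <- fr
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  out[, c("fraction", "method", "dsuvmax_pct", "dmtv_pct", "dtlg_pct",
          "or_suvmax", "cg_suvmax", "or_mtv_ml", "cg_mtv_ml",
          "or_tlg_ml", "cg_tlg_ml")]
}

#' Known-truth recovery experiment for the registration modes
#'
#' Repeatedly builds a thorax scene (tapered eccentric body, two lung
#' lesions, one cardiac-like organ), misaligns the pseudo-CT by a random
#' known 6-DOF transform, registers the PET to it in fast and slow mode,
#' and records the per-axis recovery errors. The slow (densely sampled)
#' mode serves as the accuracy reference.
#'
#' @param n_seeds number of repetitions.
#' @param grid target CT grid preset name.
#' @param fov_mm scene field of view, mm.
#' @param trans_range_mm,rot_range_deg half-ranges of the random true
#'   misalignment.
#' @param ct_noise_sd CT voxel noise (0 = noise-free pairs).
#' @param ct_texture_sd amplitude of the random parenchymal CT texture;
#'   the texture is a frozen random field uncorrelated with the PET, so
#'   the noise-free recovery experiment omits it too.
#' @param pet_noise_sd PET voxel noise.
#' @param seed base seed; repetition `i` uses `seed + i`.
#' @return Data frame with one row per repetition x mode: max absolute
#'   translation and rotation errors, and per-axis errors.
#' @export
registration_experiment <- function(n_seeds = 20L, grid = "ct1",
                                    fov_mm = c(160, 160, 110),
                                    trans_range_mm = 6, rot_range_deg = 2,
                                    ct_noise_sd = 0, ct_texture_sd = 0,
                                    pet_noise_sd = 0,
                                    seed = 0L) {
  pet_g <- geometry_preset("pet", fov_mm)
  ct_g <- geometry_preset(grid, fov_mm)
  bm <- body_model()
  rows <- list()
  for (i in seq_len(n_seeds)) {
    s <- seed + i
    draws <- with_seed(s, list(
      jitter1 = runif(3, -5, 5), jitter2 = runif(3, -5, 5),
      rot = runif(3, -rot_range_deg, rot_range_deg),
      trans = runif(3, -trans_range_mm, trans_range_mm)
    ))
    specs <- list(
      phantom_spec(center = c(-30, -12, -12) + draws$jitter1,
                   radii_mm = c(16, 11, 9), suv_lesion = 9,
                   noise_sd = pet_noise_sd, seed = s),
      phantom_spec(center = c(30, 14, 8) + draws$jitter2,
                   radii_mm = c(10, 14, 12), suv_lesion = 6),
      phantom_spec(center = c(18, -14, -18), radii_mm = c(24, 19, 17),
                   suv_lesion = 4)
    )
    t_true <- rigid_transform(rotation = draws$rot,
                              translation = draws$trans,
                              center = world_center(ct_g))
    scene <- generate_scene(specs, pet_g, body = bm)
    ct <- generate_pseudo_ct(specs, ct_g, offset = t_true, body = bm,
                             noise_sd = ct_noise_sd,
                             texture_sd = ct_texture_sd)
    for (mode in c("fast", "slow")) {
      reg <- register_rigid(scene$volume, ct, mode, mi_config(seed = s))
      pe <- rt_parameters(reg$transform)
      pt <- rt_parameters(t_true)
      te <- pe$translation_mm - pt$translation_mm
      re <- pe$rotation_deg - pt$rotation_deg
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, mode = mode,
        t_err_max = max(abs(te)), r_err_max = max(abs(re)),
        t_err_x = te[1], t_err_y = te[2], t_err_z = te[3],
        r_err_x = re[1], r_err_y = re[2], r_err_z = re[3],
        mi = reg$mi, converged = reg$converged
      )
    }
  }
  do.call(rbind, rows)
}

#' Interpolation sensitivity of heterogeneous versus homogeneous lesions
#'
#' Builds two volume-matched lesions -- one homogeneous, one with a cold
#' necrotic core (identical support, hence identical true volume) --
#' applies a half-voxel shift on the target grid, and returns both
#' lesions' deviations side by side. The defaults realize the regime in
#' which necrosis actually matters: a large lesion with a thin viable
#' rim, elongated along the shift axis so its maximum is point-like.
#' There the axial smoothing depresses the rim maximum, the
#' background-adapted threshold drops with it, and the mask inflates --
#' whereas the homogeneous twin's flat-topped maximum is untouched and
#' only its boundary layers move.
#'
#' @param volume_ml common true lesion volume, ml.
#' @param suv_lesion,suv_background lesion and background uptake, SUV.
#' @param necrosis_fraction core radius fraction of the heterogeneous
#'   lesion (0.65: a thin viable rim).
#' @param elongation long-axis to short-axis ratio along the shift axis.
#' @param noise_sd phantom noise (0 for the clean mechanistic contrast).
#' @param pet_geom PET [image_geometry()].
#' @param target target [image_geometry()] (5 mm slice CT by default).
#' @param axis shift axis.
#' @param methods segmentation methods.
#' @param f_at AT volume-reproducing fraction.
#' @param seed noise seed.
#' @return Data frame with one row per lesion type x method.
#' @export
heterogeneity_contrast <- function(volume_ml = 15, suv_lesion = 8,
                                   suv_background = 0.5,
                                   necrosis_fraction = 0.65,
                                   elongation = 1.4, noise_sd = 0,
                                   pet_geom = geometry_preset("pet"),
                                   target = geometry_preset("ct5"),
                                   axis = 3,
                                   methods = c("AT", "T40", "T50", "T60"),
                                   f_at = 0.41, seed = 1L) {
  a <- (3 * volume_ml * 1000 / (4 * pi) / elongation)^(1 / 3)
  radii <- rep(a, 3)
  radii[axis] <- a * elongation
  specs <- list(
    homogeneous = phantom_spec(radii_mm = radii, suv_lesion = suv_lesion,
                               suv_background = suv_background,
                               noise_sd = noise_sd, seed = seed),
    heterogeneous = phantom_spec(radii_mm = radii, suv_lesion = suv_lesion,
                                 suv_background = suv_background,
                                 necrosis_fraction = necrosis_fraction,
                                 noise_sd = noise_sd, seed = seed + 1L)
  )
  rows <- lapply(names(specs), function(type) {
    ph <- generate_phantom(specs[[type]], pet_geom)
    sw <- shift_sweep(ph, target, fractions = 0.5, axis = axis,
                      methods = methods, f_at = f_at)
    sw$lesion_type <- type
    sw$true_volume_ml <- ph$truth$volume_ml
    sw
  })
  do.call(rbind, rows)
}
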