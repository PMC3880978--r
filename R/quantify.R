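#' Quantify a segmented lesion: SUVmax, MTV, SUVmean, TLG
#'
#' `SUVmax` is the maximum over the lesion's VOI (not the mask), so it is
#' independent of the segmentation method; `MTV` is the mask voxel count
#' times the voxel volume, in ml; `SUVmean` is the mean over the mask;
#' `TLG = MTV x SUVmean`.
#'
#' @param v a [volume3d()].
#' @param mask a `lesion_mask` from the segmentation functions.
#' @return An object of class `quant_result`: `suvmax`, `mtv_ml`,
#'   `suvmean`, `tlg_ml`, `method`, `n_voxels`.
#' @export
quantify_lesion <- function(v, mask) {
  if (!inherits(mask, "lesion_mask")) stopf("`mask` must be a lesion_mask")
  if (!geometry_equal(v$geometry, mask$geometry))
    stopf("volume and mask geometries differ")
  if (!any(mask$mask)) stopf("mask is empty")
  mtv <- sum(mask$mask) * voxel_volume_mm3(v$geometry) / 1000
  suvmean <- mean(v$values[mask$mask])
  structure(
    list(suvmax = voi_max(v, mask$voi), mtv_ml = mtv, suvmean = suvmean,
         tlg_ml = mtv * suvmean, method = mask$method,
         n_voxels = sum(mask$mask)),
    class = "quant_result"
  )
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("quant_result [%s]: SUVmax %.3f | MTV %.3f ml | SUVmean %.3f | TLG %.3f ml\n",
              x$method, x$suvmax, x$mtv_ml, x$suvmean, x$tlg_ml))
  invisible(x)
}

#' Relative differences between coregistered and original quantification
#'
#' Differences are calculated as coregistered minus original:
#' `dq% = 100 (q_coreg - q_original) / q_original` for SUVmax, MTV and
#' TLG, together with the absolute differences.
#'
#' @param coreg,original `quant_result` objects for the same lesion and
#'   method.
#' @param lesion,grid,mode identifying labels carried into the record.
#' @return One-row data frame (a deviation record).
#' @export
relative_difference <- function(coreg, original, lesion = NA, grid = NA,
                                mode = NA) {
  if (!identical(coreg$method, original$method))
    stopf("method labels differ: %s vs %s", coreg$method, original$method)
  for (q in c("suvmax", "mtv_ml", "tlg_ml")) {
    if (original[[q]] == 0) stopf("original %s is zero", q)
  }
  data.frame(
    lesion = lesion, grid = grid, mode = mode, method = coreg$method,
    or_suvmax = original$suvmax, cg_suvmax = coreg$suvmax,
    or_mtv_ml = original$mtv_ml, cg_mtv_ml = coreg$mtv_ml,
    or_suvmean = original$suvmean, cg_suvmean = coreg$suvmean,
    or_tlg_ml = original$tlg_ml, cg_tlg_ml = coreg$tlg_ml,
    dsuvmax = coreg$suvmax - original$suvmax,
    dmtv_ml = coreg$mtv_ml - original$mtv_ml,
    dtlg_ml = coreg$tlg_ml - original$tlg_ml,
    dsuvmax_pct = 100 * (coreg$suvmax - original$suvmax) / original$suvmax,
    dmtv_pct = 100 * (coreg$mtv_ml - original$mtv_ml) / original$mtv_ml,
    dtlg_pct = 100 * (coreg$tlg_ml - original$tlg_ml) / original$tlg_ml
  )
}
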