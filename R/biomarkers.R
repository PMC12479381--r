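#' Intensity statistics over a region of interest
#'
#' Mean and standard deviation of the in-mask voxels, with the voxel count
#' and physical volume. The SD uses the population convention (divisor `N`);
#' the convention is recorded here so downstream tables are labelled.
#'
#' @param vol a [volume].
#' @param mask a non-empty [label_mask] on the same grid.
#' @return list with `mean`, `sd`, `voxel_count`, `volume_mm3`.
#' @export
roi_stats <- function(vol, mask) {
  check_same_grid(vol, mask)
  n <- sum(mask$data)
  if (n == 0) stop("empty mask: ROI statistics undefined", call. = FALSE)
  v <- vol$data[mask$data > 0]
  m <- mean(v)
  list(mean = m, sd = sqrt(mean((v - m)^2)), voxel_count = as.integer(n),
       volume_mm3 = n * voxel_volume(mask))
}

#' Contrast-to-noise ratio of the SN relative to the crus cerebri
#'
#' `CNR = (I_sn - I_cc) / SD_cc`, with means and the (population) SD taken
#' over the respective masks. Invariant under any positive affine intensity
#' remap `a * I + b`.
#'
#' @param vol a [volume] (conventionally the `"NM"` contrast).
#' @param sn_mask,cc_mask non-empty [label_mask]s on the volume's grid.
#' @return CNR (dimensionless).
#' @export
cnr <- function(vol, sn_mask, cc_mask) {
  sn <- roi_stats(vol, sn_mask)
  cc <- roi_stats(vol, cc_mask)
  if (cc$sd == 0) stop("reference region SD is zero: CNR undefined",
                       call. = FALSE)
  (sn$mean - cc$mean) / cc$sd
}

#' Contrast ratio of the SN relative to the crus cerebri
#'
#' `CR = (I_sn - I_cc) / I_cc`. Unlike the CNR, the CR is only invariant
#' under pure intensity scaling (an offset changes it).
#'
#' @inheritParams cnr
#' @return CR (dimensionless).
#' @export
cr <- function(vol, sn_mask, cc_mask) {
  sn <- roi_stats(vol, sn_mask)
  cc <- roi_stats(vol, cc_mask)
  if (cc$mean == 0) stop("reference region mean is zero: CR undefined",
                         call. = FALSE)
  (sn$mean - cc$mean) / cc$mean
}

#' Intensity-threshold a mask against the reference region
#'
#' Keeps only mask voxels whose intensity is at least `k` reference standard
#' deviations above the reference mean (`I >= I_cc + k * SD_cc`). The common
#' literature choice is `k = 1.5`. The result may be empty; this is allowed
#' and flagged via `attr(, "empty")`.
#'
#' @inheritParams cnr
#' @param mask the mask to threshold.
#' @param k threshold multiplier (default 1.5).
#' @return The thresholded [label_mask].
#' @export
threshold_mask <- function(vol, mask, cc_mask, k = 1.5) {
  check_same_grid(vol, mask)
  cc <- roi_stats(vol, cc_mask)
  if (cc$sd == 0) stop("reference region SD is zero", call. = FALSE)
  keep <- mask$data * (vol$data >= cc$mean + k * cc$sd)
  out <- label_mask(array(as.numeric(keep), dim(mask$data)), mask$spacing)
  attr(out, "empty") <- sum(keep) == 0
  out
}

#' Per-subject imaging biomarker table
#'
#' One row per subject with CNR, CR and raw / brain-volume-normalized /
#' intensity-thresholded SN volume, computed on the `"NM"` contrast from the
#' supplied segmentation masks (CNR and CR on the bilateral union, the
#' package-wide convention). Subjects with a missing prediction are listed in
#' `attr(, "exclusions")` rather than silently dropped; empty predictions
#' yield a flagged row with `NA` intensity biomarkers.
#'
#' @param cohort a `nm_cohort`.
#' @param predictions named list (subject_id -> [label_mask]); defaults to
#'   the truth masks.
#' @param method_label segmentation source label stored in the `method`
#'   column.
#' @param threshold_k multiplier for the thresholded volume (default 1.5).
#' @return `data.frame` with columns `subject_id`, `group`, `method`,
#'   `volume_mm3`, `normalized_volume`, `thresholded_volume_mm3`, `cnr`,
#'   `cr`, `empty_prediction`.
#' @export
biomarker_table <- function(cohort, predictions = NULL, method_label = "truth",
                            threshold_k = 1.5) {
  rows <- list(); excl <- character()
  for (s in cohort$subjects) {
    pred <- if (is.null(predictions)) sn_union(s) else predictions[[s$subject_id]]
    if (is.null(pred)) { excl <- c(excl, s$subject_id); next }
    nm <- s$images[["NM"]]
    if (sum(pred$data) == 0) {
      rows[[s$subject_id]] <- data.frame(
        subject_id = s$subject_id, group = s$group, method = method_label,
        volume_mm3 = 0, normalized_volume = 0, thresholded_volume_mm3 = 0,
        cnr = NA_real_, cr = NA_real_, empty_prediction = TRUE,
        stringsAsFactors = FALSE)
      next
    }
    thr <- threshold_mask(nm, pred, s$crus_cerebri, k = threshold_k)
    rows[[s$subject_id]] <- data.frame(
      subject_id = s$subject_id, group = s$group, method = method_label,
      volume_mm3 = mask_volume_mm3(pred),
      normalized_volume = mask_volume_mm3(pred) / s$brain_volume_mm3,
      thresholded_volume_mm3 = mask_volume_mm3(thr),
      cnr = cnr(nm, pred, s$crus_cerebri),
      cr = cr(nm, pred, s$crus_cerebri),
      empty_prediction = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  attr(out, "sd_convention") <- "population (divisor N)"
  out
}

#' Volume-CNR collinearity report
#'
#' Pearson correlation between CNR and the raw normalized volume, and between
#' CNR and the intensity-thresholded volume. Intensity thresholding couples a
#' volume estimate to the signal level, so the second correlation is
#' systematically inflated relative to the first even when volume and CNR are
#' generated independently.
#'
#' @param table a [biomarker_table()] result with >= 10 complete rows.
#' @return list with `r_raw` and `r_thresholded`.
#' @export
collinearity_report <- function(table) {
  tb <- table[!table$empty_prediction & is.finite(table$cnr), ]
  if (nrow(tb) < 10) stop("need at least 10 subjects", call. = FALSE)
  for (col in c("cnr", "normalized_volume", "thresholded_volume_mm3")) {
    if (sd(tb[[col]]) == 0) stop("constant column: ", col, call. = FALSE)
  }
  list(r_raw = stats::cor(tb$cnr, tb$normalized_volume),
       r_thresholded = stats::cor(tb$cnr, tb$thresholded_volume_mm3))
}
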