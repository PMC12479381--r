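# A deterministic reference-region adaptive-threshold segmenter. It stands in
# for a trained network so that contrast screening and the domain-shift
# experiment run end-to-end on one CPU: each requested contrast is
# z-normalized by the subject's crus cerebri statistics, the (sign-oriented)
# z-maps are averaged, thresholded at k reference SDs, restricted to a
# central search box, and cleaned by 26-connected component filtering with a
# one-component-per-hemisphere preference.

#' Segmenter model
#'
#' @param k threshold multiplier over the reference-region SD.
#' @param contrast_weights named numeric vector of per-contrast weights
#'   (signs orient hypointense contrasts; magnitudes weight the z-average).
#' @param search_box_mm half-extents (mm) of the central search box per axis
#'   (`Inf` = whole axis).
#' @param min_component_voxels,max_component_voxels size bounds for candidate
#'   components.
#' @param normalization `"reference"` (z-score against the raw crus cerebri
#'   statistics) or `"polyfit"` (classical log-domain polynomial bias-field
#'   correction - a polynomial of order `bias_fit_order` is least-squares
#'   fitted to the log-intensities with the brightest 2% of voxels excluded,
#'   and divided out - before the reference z-scoring). Calibration selects
#'   between the two; on inhomogeneity-free images they are nearly
#'   equivalent.
#' @param bias_fit_order polynomial order of the `polyfit` correction.
#' @return An object of class `segmenter_model`.
#' @export
segmenter_model <- function(k = 2, contrast_weights = c(NM = 1),
                            search_box_mm = c(14, 14, Inf),
                            min_component_voxels = 40,
                            max_component_voxels = 4000,
                            normalization = c("reference", "polyfit"),
                            bias_fit_order = 3) {
  normalization <- match.arg(normalization)
  stopifnot(is.finite(k), min_component_voxels < max_component_voxels,
            length(contrast_weights) >= 1, !is.null(names(contrast_weights)))
  structure(list(k = k, contrast_weights = contrast_weights,
                 search_box_mm = rep_len(search_box_mm, 3),
                 min_component_voxels = min_component_voxels,
                 max_component_voxels = max_component_voxels,
                 normalization = normalization,
                 bias_fit_order = bias_fit_order),
            class = "segmenter_model")
}

# central search box as a logical array
search_box <- function(shape, spacing, half_mm) {
  ctr <- (shape - 1) * spacing / 2
  co <- coord_mm(shape, spacing)
  inx <- abs(co$x - ctr[1]) <= half_mm[1]
  iny <- abs(co$y - ctr[2]) <= half_mm[2]
  inz <- abs(co$z - ctr[3]) <= half_mm[3]
  outer(outer(inx, iny), inz) > 0
}

# monomial basis (degrees 1..order) over coordinates normalized to [-1, 1]
poly_basis <- function(shape, order = 3) {
  u <- seq(-1, 1, length.out = shape[1])
  v <- seq(-1, 1, length.out = shape[2])
  w <- seq(-1, 1, length.out = shape[3])
  cols <- list()
  for (i in 0:order) for (j in 0:order) for (k in 0:order) {
    if (i + j + k < 1 || i + j + k > order) next
    cols[[length(cols) + 1]] <- as.vector(outer(outer(u^i, v^j), w^k))
  }
  do.call(cbind, cols)
}

# log-domain polynomial bias correction: fit log-intensity on the basis with
# the brightest 2% of voxels excluded (so the SN does not pull the fit), and
# divide the fitted field out
polyfit_correct <- function(arr, order = 3) {
  av <- as.vector(arr)
  off <- min(av)
  lv <- log(av - off + 0.05 * (max(av) - min(av) + 1e-12))
  B <- cbind(1, poly_basis(dim(arr), order))
  use <- lv < quantile(lv, 0.98)
  fit <- stats::lm.fit(B[use, , drop = FALSE], lv[use])
  pred <- drop(B %*% fit$coefficients)
  array(exp(lv - pred), dim(arr))
}

# combined sign-weighted z-score map of the requested contrasts
combined_zmap <- function(subject, weights, normalization = "reference",
                          bias_fit_order = 3) {
  cc <- subject$crus_cerebri
  num <- 0
  for (cn in names(weights)) {
    img <- subject$images[[cn]]
    if (is.null(img)) stop("subject ", subject$subject_id,
                           " is missing contrast ", cn, call. = FALSE)
    if (normalization == "polyfit") {
      img <- volume(polyfit_correct(img$data, bias_fit_order), img$spacing)
    }
    st <- roi_stats(img, cc)
    if (st$sd == 0) stop("zero reference SD in contrast ", cn, call. = FALSE)
    num <- num + weights[[cn]] * (img$data - st$mean) / st$sd
  }
  num / sum(abs(unlist(weights)))
}

# pick up to two components ranked by excess z-mass (sum of z - k over the
# component: compact bright structures beat large barely-supra-threshold
# noise clusters), preferring one per hemisphere
select_components <- function(lab, mass, keep_ids, shape) {
  if (length(keep_ids) == 0) return(integer())
  if (length(keep_ids) == 1) return(keep_ids)
  xmid <- (shape[1] + 1) / 2
  cent_x <- vapply(keep_ids, function(id) {
    mean(((which(lab == id) - 1) %% shape[1]) + 1)
  }, 0)
  ord <- keep_ids[order(-mass[keep_ids])]
  first <- ord[1]
  same_side <- sign(cent_x[match(ord, keep_ids)] - xmid)
  opp <- ord[same_side != same_side[1]]
  second <- if (length(opp) > 0) opp[1] else ord[2]
  unique(c(first, second))
}

#' Segment a subject with a calibrated model
#'
#' @param subject a `nm_subject`.
#' @param model a [segmenter_model].
#' @param contrasts optional character vector restricting the model's
#'   contrast weights.
#' @return A binary prediction [label_mask]; empty if no component survives
#'   (a valid prediction, mirroring total failure modes).
#' @export
segment <- function(subject, model, contrasts = NULL) {
  stopifnot(inherits(subject, "nm_subject"), inherits(model, "segmenter_model"))
  w <- model$contrast_weights
  if (!is.null(contrasts)) w <- w[contrasts]
  z <- combined_zmap(subject, w, model$normalization, model$bias_fit_order)
  shape <- dim(z); sp <- subject$crus_cerebri$spacing
  cand <- (z >= model$k) & search_box(shape, sp, model$search_box_mm)
  if (!any(cand)) return(label_mask(array(0, shape), sp))
  lab <- .label_components26(as.numeric(cand), as.integer(shape))
  sizes <- tabulate(lab[lab > 0])
  mass <- component_mass(lab, z, model$k, length(sizes))
  keep_ids <- which(sizes >= model$min_component_voxels &
                      sizes <= model$max_component_voxels)
  chosen <- select_components(lab, mass, keep_ids, shape)
  out <- array(as.numeric(lab %in% chosen & lab > 0), shape)
  label_mask(out, sp)
}

# excess z-mass per component
component_mass <- function(lab, z, k, n_comp) {
  if (n_comp == 0) return(numeric())
  pos <- lab > 0
  vapply(split(z[pos] - k, lab[pos]), sum, 0)[as.character(seq_len(n_comp))]
}

#' Subject-level fold assignment
#'
#' Splits are always at the subject level so multiple records (e.g.,
#' augmented copies) of one subject stay in one fold.
#'
#' @param cohort a `nm_cohort`.
#' @param n_folds number of folds (default 3).
#' @param seed integer seed.
#' @return Named integer vector subject_id -> fold.
#' @export
make_folds <- function(cohort, n_folds = 3, seed = 0) {
  ids <- names(cohort$subjects)
  stopifnot(length(ids) >= n_folds)
  with_seed(seed, {
    perm <- sample(ids)
    assign <- stats::setNames(rep_len(seq_len(n_folds), length(ids)), perm)
    assign[ids]
  })
}

# per-contrast weight from training subjects: the mean truth-SN z-score,
# i.e. the contrast's estimated SN signal. Signs orient hypointense
# contrasts; magnitudes weight informative contrasts up and uninformative
# (pure-noise) contrasts towards zero, so adding a signal-free contrast
# leaves the combined map essentially unchanged.
orient_weights <- function(subjects, contrasts) {
  w <- vapply(contrasts, function(cn) {
    mean(vapply(subjects, function(s) {
      z <- combined_zmap(s, stats::setNames(1, cn))
      mean(z[sn_union(s)$data > 0])
    }, 0))
  }, 0)
  if (all(w == 0)) w[] <- 1
  stats::setNames(w, contrasts)
}

# mean DSC of a k-threshold over a set of (subject, truth) records given
# precomputed z-maps
eval_k <- function(records, k, proto) {
  model <- proto; model$k <- k
  mean(vapply(records, function(r) {
    cand <- (r$z >= k) & r$box
    shape <- dim(r$z)
    if (!any(cand)) return(0)
    lab <- .label_components26(as.numeric(cand), as.integer(shape))
    sizes <- tabulate(lab[lab > 0])
    mass <- component_mass(lab, r$z, k, length(sizes))
    keep_ids <- which(sizes >= proto$min_component_voxels &
                        sizes <= proto$max_component_voxels)
    chosen <- select_components(lab, mass, keep_ids, shape)
    pred <- as.numeric(lab %in% chosen & lab > 0)
    tr <- r$truth$data
    s <- sum(pred * tr)
    if (sum(pred) + sum(tr) == 0) 1 else 2 * s / (sum(pred) + sum(tr))
  }, 0))
}

make_record <- function(subject, weights, proto, normalization) {
  z <- combined_zmap(subject, weights, normalization, proto$bias_fit_order)
  list(z = z,
       box = search_box(dim(z), subject$crus_cerebri$spacing,
                        proto$search_box_mm),
       truth = sn_union(subject))
}

#' Calibrate the segmenter by cross-validation
#'
#' Selects the threshold `k` and the normalization mode maximizing the mean
#' out-of-fold DSC over a grid, with ties broken toward the plain reference
#' normalization and then toward smaller `k`. Contrast orientation signs are
#' learned from the in-fold training subjects. The selection is deterministic
#' given the cohort, folds and grid, and invariant to subject order.
#'
#' @param training a `nm_cohort` with truth masks.
#' @param contrasts character vector of contrast names to combine.
#' @param k_grid candidate thresholds (default `seq(1, 3.5, by = 0.25)`).
#' @param folds a [make_folds()] assignment (default: 3 folds, seed 0).
#' @param proto a [segmenter_model] supplying the non-calibrated fields.
#' @param normalizations candidate normalization modes searched.
#' @param extra named list (subject_id -> list of extra `nm_subject` copies,
#'   e.g. site-augmented) joining their source subject's fold.
#' @return A [segmenter_model] with attributes `cv_dsc` (the selection
#'   criterion at the optimum) and `cv_table` (mean out-of-fold DSC per
#'   normalization x k).
#' @export
calibrate <- function(training, contrasts = "NM",
                      k_grid = seq(1, 3.5, by = 0.25), folds = NULL,
                      proto = segmenter_model(),
                      normalizations = c("reference", "polyfit"),
                      extra = NULL) {
  stopifnot(inherits(training, "nm_cohort"), length(k_grid) >= 1)
  if (length(training$subjects) == 0) stop("empty training cohort", call. = FALSE)
  if (is.null(folds)) folds <- make_folds(training, 3, seed = 0)
  ids <- sort(names(training$subjects))
  k_grid <- sort(k_grid)

  cv <- matrix(NA_real_, length(normalizations), length(k_grid),
               dimnames = list(normalizations, k_grid))
  fold_scores <- array(NA_real_, c(length(normalizations), length(k_grid),
                                   max(folds)))
  for (f in sort(unique(folds))) {
    tr_ids <- ids[folds[ids] != f]
    va_ids <- ids[folds[ids] == f]
    w <- orient_weights(training$subjects[tr_ids], contrasts)
    va_subjects <- list()
    for (id in va_ids) {
      va_subjects <- c(va_subjects, list(training$subjects[[id]]),
                       if (!is.null(extra)) extra[[id]])
    }
    for (ni in seq_along(normalizations)) {
      records <- lapply(va_subjects, make_record, weights = w, proto = proto,
                        normalization = normalizations[ni])
      fold_scores[ni, , f] <- vapply(k_grid, function(k)
        eval_k(records, k, proto), 0)
    }
  }
  cv[] <- apply(fold_scores, c(1, 2), mean, na.rm = TRUE)
  # ties resolve to the first normalization listed, then to smaller k
  best <- which(cv == max(cv), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  all_subjects <- training$subjects
  if (!is.null(extra)) all_subjects <- c(all_subjects, unlist(extra,
                                                              recursive = FALSE))
  w_final <- orient_weights(all_subjects, contrasts)
  model <- proto
  model$k <- k_grid[best[2]]
  model$normalization <- normalizations[best[1]]
  model$contrast_weights <- w_final
  attr(model, "cv_dsc") <- cv[best[1], best[2]]
  attr(model, "cv_table") <- cv
  model
}

#' Calibrate with site-effect augmentation
#'
#' Enlarges the calibration set with site-transformed copies of every
#' training subject (profiles cycled over `site_profiles`, seeds derived from
#' `seed`), so the selected threshold must also perform on artifact-corrupted
#' images. With no profiles this reduces exactly to [calibrate()].
#'
#' @inheritParams calibrate
#' @param site_profiles list of [site_profile]s used as augmentations.
#' @param n_augments copies per subject (default 2).
#' @param seed integer seed for the augmentation transforms.
#' @return A [segmenter_model], as [calibrate()].
#' @export
augmented_calibrate <- function(training, contrasts = "NM",
                                k_grid = seq(1, 3.5, by = 0.25), folds = NULL,
                                site_profiles = default_site_profiles()[c("site_b", "site_b_mild")],
                                n_augments = 2, proto = segmenter_model(),
                                seed = 0) {
  if (length(site_profiles) == 0 || n_augments == 0) {
    return(calibrate(training, contrasts, k_grid, folds, proto))
  }
  extra <- list()
  ids <- names(training$subjects)
  for (i in seq_along(ids)) {
    copies <- list()
    for (a in seq_len(n_augments)) {
      prof <- site_profiles[[(a - 1) %% length(site_profiles) + 1]]
      copies[[a]] <- apply_site(training$subjects[[ids[i]]], prof,
                                seed = derive_seed(seed, i * 100 + a))
    }
    extra[[ids[i]]] <- copies
  }
  calibrate(training, contrasts, k_grid, folds, proto, extra = extra)
}

#' Segment every subject of a cohort
#'
#' @param cohort a `nm_cohort`.
#' @param model a [segmenter_model].
#' @return Named list of prediction [label_mask]s.
#' @export
segment_cohort <- function(cohort, model) {
  lapply(cohort$subjects, segment, model = model)
}

#' Evaluate predictions against cohort truth
#'
#' @param predictions named list of [label_mask]s (subject_id -> mask).
#' @param cohort a `nm_cohort` (truth = bilateral SN union).
#' @return `data.frame` of [evaluate_pair()] rows, one per subject.
#' @export
evaluate_cohort <- function(predictions, cohort) {
  rows <- lapply(cohort$subjects, function(s) {
    evaluate_pair(predictions[[s$subject_id]], sn_union(s), id = s$subject_id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
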