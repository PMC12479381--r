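#' Phantom generation parameters
#'
#' Parameters of the synthetic midbrain phantom. The phantom places two
#' mirrored crescent-shaped substantia nigra (SN) hyperintensities (built as
#' the difference of two offset ellipsoid stacks, mildly randomized per
#' subject) spanning 5-8 contiguous axial slices, plus a crus cerebri (CC)
#' reference region anterolateral to the SN, inside a uniform background.
#' Intensities are rendered per named contrast as
#' (structure level) + (SN signal coefficient x CNR x noise SD) + noise; there
#' is no physics simulation.
#'
#' @param grid_shape integer length-3 voxel counts, minimum (16, 16, 8).
#' @param spacing voxel spacing in mm; default 0.67 x 1.0 x 1.34 as in a
#'   typical NM-sensitive GRE protocol.
#' @param sn_extent_slices integer range (lo, hi) of contiguous axial slices
#'   an SN crescent may span; default 5-8.
#' @param sn_voxels_target expected per-side SN voxel count (default 600,
#'   about 540 mm^3 at the default spacing).
#' @param cc_voxels_target total (bilateral) crus cerebri voxel count
#'   (default 2400).
#' @param base_intensity background tissue mean (arbitrary units).
#' @param noise_sd additive Gaussian noise standard deviation; the CNR
#'   definition divides by the reference-region SD, so only a well-defined SD
#'   is required of the noise family.
#' @param target_cnr generative CNR of the healthy-control NM image
#'   (mean SN minus mean CC, in units of noise SD).
#' @param sn_volume_jitter SD of the per-subject log-normal SN volume factor.
#' @param side_asym_sd SD of the additive left-right CNR asymmetry.
#' @param contrast_set named list of contrast renderings; see
#'   [default_contrast_set()]. Must contain a contrast named `"NM"`.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(64L, 64L, 24L),
                           spacing = c(0.67, 1.0, 1.34),
                           sn_extent_slices = c(5L, 8L),
                           sn_voxels_target = 600,
                           cc_voxels_target = 2400,
                           base_intensity = 100,
                           noise_sd = 4,
                           target_cnr = 3,
                           sn_volume_jitter = 0.10,
                           side_asym_sd = 0.15,
                           contrast_set = default_contrast_set()) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= c(16L, 16L, 8L)),
            length(spacing) == 3L, all(spacing > 0), noise_sd > 0,
            sn_extent_slices[1] >= 1, sn_extent_slices[2] <= grid_shape[3],
            sn_extent_slices[1] <= sn_extent_slices[2],
            length(contrast_set) >= 1)
  if (!"NM" %in% names(contrast_set)) {
    stop("contrast_set must contain a contrast named 'NM'", call. = FALSE)
  }
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 sn_extent_slices = as.integer(sn_extent_slices),
                 sn_voxels_target = sn_voxels_target,
                 cc_voxels_target = cc_voxels_target,
                 base_intensity = base_intensity, noise_sd = noise_sd,
                 target_cnr = target_cnr,
                 sn_volume_jitter = sn_volume_jitter,
                 side_asym_sd = side_asym_sd,
                 contrast_set = contrast_set),
            class = "phantom_params")
}

#' Default multi-contrast rendering set
#'
#' Each contrast is described by multipliers applied to the shared geometry:
#' `bg` and `cc` scale the background and crus cerebri levels relative to
#' `base_intensity`; `sn` scales the SN signal (in units of CNR x noise SD)
#' added on top of the CC level, so `sn = 1` reproduces the generative CNR,
#' negative values render the SN hypointense (as in susceptibility-weighted
#' images) and `0` makes it invisible (as in T1-weighted images); `noise`
#' scales the additive noise SD. In the defaults the background matches the
#' CC level within each contrast: the SN hyper-/hypointensity is the only
#' intensity-delineated structure, and non-SN anatomy exists as labelled
#' masks rather than intensity boundaries.
#'
#' @return Named list of contrast descriptors: `NM` (hyperintense SN,
#'   reference contrast), `SWI` (hypointense SN, noisier), `T2` (weakly
#'   hyperintense), `T1` (no SN signal).
#' @export
default_contrast_set <- function() {
  list(
    NM  = list(bg = 0.92, cc = 0.92, sn = 1.0,  noise = 1.0),
    SWI = list(bg = 0.85, cc = 0.85, sn = -0.9, noise = 1.2),
    T2  = list(bg = 0.95, cc = 0.95, sn = 0.5,  noise = 1.1),
    T1  = list(bg = 1.05, cc = 1.05, sn = 0.0,  noise = 1.0)
  )
}

#' Disease effect parameters
#'
#' Group-level generative effects for Parkinson's disease (PD) phantoms
#' relative to healthy controls (HC). The default CNR reduction of 0.13
#' mirrors the average signal reduction reported across a whole mixed
#' cohort; 0.22 is the typical test-set-like effect.
#'
#' @param cnr_reduction fractional CNR decrease in PD (0 <= x < 1).
#' @param volume_reduction fractional SN volume decrease in PD.
#' @param between_subject_sd SD of the per-subject CNR draw (additive, on the
#'   CNR scale).
#' @param laterality_coupling in `[0, 1]`: probability excess that the
#'   clinically dominant side is contralateral to the side with the larger
#'   CNR deficit. 0 (default) decouples imaging asymmetry from symptom
#'   laterality, the built-in null.
#' @return An object of class `disease_effect`.
#' @export
disease_effect <- function(cnr_reduction = 0.13, volume_reduction = 0.05,
                           between_subject_sd = 0.35,
                           laterality_coupling = 0) {
  stopifnot(cnr_reduction >= 0, cnr_reduction < 1,
            volume_reduction >= 0, volume_reduction < 1,
            between_subject_sd >= 0,
            laterality_coupling >= 0, laterality_coupling <= 1)
  structure(list(cnr_reduction = cnr_reduction,
                 volume_reduction = volume_reduction,
                 between_subject_sd = between_subject_sd,
                 laterality_coupling = laterality_coupling),
            class = "disease_effect")
}

# mm coordinate arrays of a grid (world coordinate = (index - 1) * spacing)
coord_mm <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 1) * spacing[1],
       y = (seq_len(shape[2]) - 1) * spacing[2],
       z = (seq_len(shape[3]) - 1) * spacing[3])
}

# Crescent-shaped SN mask for one side: per-slice difference of two offset
# ellipses, tapered towards the first and last slice. All sizes in mm.
# side = -1 (left, low x) or +1 (right).
sn_crescent <- function(shape, spacing, center_mm, slices, scale, side,
                        a = 4.0, b = 7.0, a2 = 3.6, b2 = 6.2,
                        off_y = -3.0, off_x = 2.0) {
  co <- coord_mm(shape, spacing)
  m <- array(0, shape)
  nz <- length(slices)
  zc <- mean(slices)
  for (k in seq_along(slices)) {
    z <- slices[k]
    zrel <- (z - zc) / (nz / 2 + 0.25)
    sl <- sqrt(max(0.25, 1 - 0.8 * zrel^2)) * scale
    dx <- outer(co$x - center_mm[1], rep(1, shape[2]))
    dy <- outer(rep(1, shape[1]), co$y - center_mm[2])
    inside <- (dx / (a * sl))^2 + (dy / (b * sl))^2 <= 1
    removed <- ((dx - side * off_x * sl) / (a2 * sl))^2 +
      ((dy - off_y * sl) / (b2 * sl))^2 <= 1
    m[, , z] <- as.numeric(inside & !removed)
  }
  m
}

# Ellipse-stack mask (crus cerebri).
ellipse_stack <- function(shape, spacing, center_mm, slices, scale,
                          a = 4.6, b = 6.8) {
  co <- coord_mm(shape, spacing)
  m <- array(0, shape)
  dx <- outer(co$x - center_mm[1], rep(1, shape[2]))
  dy <- outer(rep(1, shape[1]), co$y - center_mm[2])
  sl <- as.numeric((dx / (a * scale))^2 + (dy / (b * scale))^2 <= 1)
  for (z in slices) m[, , z] <- sl
  m
}

# Bisection on the in-plane scale so a structure hits its voxel-count target.
fit_scale <- function(builder, target, lo = 0.4, hi = 2.5, iters = 14) {
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (sum(builder(mid)) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate one synthetic subject
#'
#' Builds a multi-contrast midbrain phantom with known ground truth. The
#' clean `"NM"` image satisfies `mean(SN) = mean(CC) + cnr * noise_sd` per
#' side before any site effects, where the per-side CNR is drawn from the
#' group's generative distribution (HC mean `target_cnr`, PD mean reduced by
#' `effect$cnr_reduction`). Group membership enters only through the effect
#' multipliers, never through the random stream, so a zero effect makes PD
#' and HC generation identical under the same seed.
#'
#' @param params a [phantom_params] object.
#' @param effect a [disease_effect] object.
#' @param group `"PD"` or `"HC"`.
#' @param seed non-negative integer seed.
#' @param subject_id,site identifier strings stored in the record.
#' @return A `nm_subject`: a list with `subject_id`, `group`, `site`,
#'   `images` (named list of [volume]), `sn_left`, `sn_right`,
#'   `crus_cerebri` ([label_mask]), `brain_volume_mm3`, `clinical`
#'   (filled by [assign_clinical()]) and `truth` (generative per-side CNR
#'   and SN volumes).
#' @export
make_subject <- function(params, effect = disease_effect(), group = c("HC", "PD"),
                         seed = 0, subject_id = "S000", site = "A") {
  group <- match.arg(group)
  stopifnot(inherits(params, "phantom_params"), seed >= 0)
  shape <- params$grid_shape
  sp <- params$spacing
  fov <- (shape - 1) * sp
  ctr <- fov / 2

  # minimum physical room for both SN crescents plus CC (empirical bounds of
  # the default geometry at maximum scale)
  if (fov[1] < 36 || fov[2] < 42 || shape[3] < params$sn_extent_slices[2] + 4) {
    stop("grid too small to place SN and crus cerebri structures", call. = FALSE)
  }

  with_seed(seed, {
    # --- generative draws (group-independent stream) ---
    n_sl <- sample(seq(params$sn_extent_slices[1], params$sn_extent_slices[2]), 1)
    cnr_base_raw <- params$target_cnr + rnorm(1, 0, effect$between_subject_sd)
    asym <- rnorm(1, 0, params$side_asym_sd)
    volf_raw <- exp(rnorm(1, 0, params$sn_volume_jitter))
    jx <- runif(2, -0.8, 0.8); jy <- runif(2, -0.8, 0.8)
    brain_volume <- rnorm(1, 1.35e6, 8e4)
    noise_seeds <- sample.int(1e6, length(params$contrast_set))

    # --- apply group effects ---
    is_pd <- group == "PD"
    fac <- 1 - if (is_pd) effect$cnr_reduction else 0
    volf <- volf_raw * (1 - if (is_pd) effect$volume_reduction else 0)
    cnr_l <- max(0.05, (cnr_base_raw + asym / 2) * fac)
    cnr_r <- max(0.05, (cnr_base_raw - asym / 2) * fac)

    # --- geometry ---
    z0 <- max(2L, as.integer(round(shape[3] / 2 - n_sl / 2)))
    sn_slices <- z0:(z0 + n_sl - 1L)
    cc_slices <- max(1L, z0 - 1L):min(shape[3], z0 + n_sl)
    target_sn <- params$sn_voxels_target * volf

    mk_sn <- function(side, j) {
      cmm <- c(ctr[1] + side * 7.0 + jx[j], ctr[2] + 1.5 + jy[j], 0)
      function(s) sn_crescent(shape, sp, cmm, sn_slices, s, side)
    }
    b_l <- mk_sn(-1, 1); b_r <- mk_sn(+1, 2)
    sn_l <- b_l(fit_scale(function(s) b_l(s), target_sn))
    sn_r <- b_r(fit_scale(function(s) b_r(s), target_sn))
    sn_r <- sn_r * (1 - sn_l)  # defensive disjointness

    mk_cc <- function(side) {
      cmm <- c(ctr[1] + side * 11.0, ctr[2] - 9.5, 0)
      function(s) ellipse_stack(shape, sp, cmm, cc_slices, s)
    }
    c_l <- mk_cc(-1); c_r <- mk_cc(+1)
    half_cc <- params$cc_voxels_target / 2
    cc <- pmin(1, c_l(fit_scale(function(s) c_l(s), half_cc)) +
                 c_r(fit_scale(function(s) c_r(s), half_cc)))
    cc <- cc * (1 - sn_l) * (1 - sn_r)
    cc <- array(cc, shape)

    # --- render contrasts ---
    base <- params$base_intensity
    nsd <- params$noise_sd
    images <- vector("list", length(params$contrast_set))
    names(images) <- names(params$contrast_set)
    for (i in seq_along(params$contrast_set)) {
      cs <- params$contrast_set[[i]]
      img <- array(base * cs$bg, shape)
      img[cc > 0] <- base * cs$cc
      img[sn_l > 0] <- base * cs$cc + cs$sn * cnr_l * nsd
      img[sn_r > 0] <- base * cs$cc + cs$sn * cnr_r * nsd
      img <- img + with_seed(noise_seeds[i],
                             array(rnorm(prod(shape), 0, nsd * cs$noise), shape))
      images[[i]] <- volume(img, sp)
    }

    structure(list(
      subject_id = subject_id, group = group, site = site,
      images = images,
      sn_left = label_mask(sn_l, sp),
      sn_right = label_mask(sn_r, sp),
      crus_cerebri = label_mask(cc, sp),
      brain_volume_mm3 = brain_volume,
      clinical = list(updrs_left = NA_real_, updrs_right = NA_real_,
                      sbr_left = NA_real_, sbr_right = NA_real_,
                      dominant_side = NA_character_),
      truth = list(cnr_left = cnr_l, cnr_right = cnr_r,
                   sn_volume_left_mm3 = sum(sn_l) * prod(sp),
                   sn_volume_right_mm3 = sum(sn_r) * prod(sp)),
      seed = seed
    ), class = "nm_subject")
  })
}

#' Union of the left and right SN truth masks
#' @param subject a `nm_subject`.
#' @return A [label_mask].
#' @export
sn_union <- function(subject) {
  label_mask(pmin(1, subject$sn_left$data + subject$sn_right$data) |>
               array(dim(subject$sn_left$data)),
             subject$sn_left$spacing)
}

#' Generate a cohort of synthetic subjects
#'
#' Per-subject seeds are derived deterministically from the master seed with
#' a counter-based scheme, so the same seed always yields a bit-identical
#' cohort and extending a cohort never reshuffles earlier subjects. Clinical
#' scores are assigned via [assign_clinical()]. The default sizes mirror a
#' typical single-site study arm (58 PD / 22 HC).
#'
#' @inheritParams make_subject
#' @param n_pd,n_hc group sizes; `n_pd + n_hc >= 2`.
#' @param site site label stored on each subject.
#' @param seed master seed.
#' @return A `nm_cohort`: list with `subjects` (PD first, then HC) and
#'   `metadata`.
#' @export
make_cohort <- function(params, effect = disease_effect(), n_pd = 58, n_hc = 22,
                        site = "A", seed = 0) {
  stopifnot(n_pd + n_hc >= 2, n_pd >= 0, n_hc >= 0)
  groups <- c(rep("PD", n_pd), rep("HC", n_hc))
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    sid <- sprintf("%s%03d", site, i)
    s <- make_subject(params, effect, groups[i], seed = derive_seed(seed, i),
                      subject_id = sid, site = site)
    subjects[[i]] <- assign_clinical(s, effect,
                                     seed = derive_seed(seed, 100000 + i))
  }
  names(subjects) <- vapply(subjects, `[[`, "", "subject_id")
  structure(list(subjects = subjects,
                 metadata = list(params = params, effect = effect,
                                 n_pd = n_pd, n_hc = n_hc, site = site,
                                 seed = seed)),
            class = "nm_cohort")
}

#' @export
print.nm_cohort <- function(x, ...) {
  g <- table(vapply(x$subjects, `[[`, "", "group"))
  cat(sprintf("<nm_cohort> %d subjects (%s), site %s, seed %d\n",
              length(x$subjects),
              paste(names(g), g, sep = "=", collapse = ", "),
              x$metadata$site, x$metadata$seed))
  invisible(x)
}

#' Simulate an imperfect human rater
#'
#' Perturbs a mask with a smooth random boundary deformation (random
#' erosion/dilation driven by a smooth noise field added to a layered signed
#' depth map) whose magnitude is searched so the resulting Dice score against
#' the input matches `target_dsc`. The default target of about 0.70 emulates
#' typical inter-rater agreement on the SN hyperintensity.
#'
#' @param mask a [label_mask] with at least 20 foreground voxels.
#' @param target_dsc target Dice in (0, 1].
#' @param seed integer seed; the result is deterministic under a fixed seed.
#' @return A perturbed [label_mask].
#' @export
simulate_rater <- function(mask, target_dsc = 0.70, seed = 0) {
  stopifnot(is_mask(mask), target_dsc > 0, target_dsc <= 1)
  nvox <- sum(mask$data)
  if (nvox < 20) {
    stop("mask too small (< 20 voxels) to simulate a rater at a target DSC",
         call. = FALSE)
  }
  if (target_dsc == 1) return(mask)

  shape <- dim(mask$data)
  idx <- which(mask$data > 0, arr.ind = TRUE)
  pad <- 5L
  lo <- pmax(1L, apply(idx, 2, min) - pad)
  hi <- pmin(shape, apply(idx, 2, max) + pad)
  sub <- mask$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub <- array(sub, hi - lo + 1L)

  # layered signed depth: +0.5 on the inner boundary shell growing inwards,
  # -0.5 on the first outside shell growing outwards, capped at 4 layers
  depth <- array(0, dim(sub))
  cur <- sub
  for (l in 1:4) {
    er <- erode6(cur)
    shell <- cur * (1 - er)
    depth[shell > 0] <- l - 0.5
    cur <- er
    if (sum(cur) == 0) break
  }
  depth[cur > 0] <- 4.5
  cur <- sub
  for (l in 1:4) {
    di <- dilate6(cur)
    shell <- di * (1 - cur)
    depth[shell > 0] <- -(l - 0.5)
    cur <- di
  }
  depth[cur == 0 & sub == 0] <- -4.5

  with_seed(seed, {
    g <- smooth_field(dim(sub), control_spacing = 3)
    g <- g / sd(g)
    dsc_at <- function(s) {
      y <- (depth + s * g) > 0
      2 * sum(y & (sub > 0)) / (sum(y) + sum(sub))
    }
    grid <- seq(0, 8, by = 0.05)
    dscs <- vapply(grid, dsc_at, 0)
    if (min(dscs) > target_dsc + 0.02) {
      stop("target_dsc unattainable for this mask", call. = FALSE)
    }
    s <- grid[which.min(abs(dscs - target_dsc))]
    out <- array(0, shape)
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      as.numeric((depth + s * g) > 0)
    label_mask(out, mask$spacing)
  })
}

#' Assign clinical scores to a subject
#'
#' PD subjects receive per-side UPDRS-III brady-rigidity + tremor sums with
#' one strictly dominant side, and specific binding ratios (SBR) generated so
#' the left/right SBR ratio separates left- from right-dominant patients at a
#' common-language effect size of about 0.92 (log-ratio means of +/-0.179 at
#' SD 0.18). Imaging truth is coupled to laterality only through
#' `effect$laterality_coupling`: the dominant side is contralateral to the
#' larger-CNR-deficit side with probability `0.5 + coupling / 2` (so the
#' default 0 is an exact null). HC subjects get zero UPDRS sums and SBR from
#' the normal range.
#'
#' @param subject a `nm_subject` with truth CNR values.
#' @param effect a [disease_effect].
#' @param seed integer seed.
#' @return The subject with its `clinical` list filled in.
#' @export
assign_clinical <- function(subject, effect = disease_effect(), seed = 0) {
  stopifnot(inherits(subject, "nm_subject"))
  with_seed(seed, {
    if (subject$group != "PD") {
      base <- max(0.5, rnorm(1, 2.2, 0.25))
      d <- rnorm(1, 0, 0.10)
      subject$clinical <- list(updrs_left = 0, updrs_right = 0,
                               sbr_left = base * exp(d / 2),
                               sbr_right = base * exp(-d / 2),
                               dominant_side = "undetermined")
      return(subject)
    }
    # dominant side: contralateral to the weaker-CNR side with probability
    # 0.5 + coupling/2
    deficit_side <- if (subject$truth$cnr_left < subject$truth$cnr_right)
      "left" else "right"
    contra <- if (deficit_side == "left") "right" else "left"
    p_contra <- 0.5 + effect$laterality_coupling / 2
    dominant <- if (runif(1) < p_contra) contra else deficit_side

    dom_sum <- max(2, round(rnorm(1, 14, 4)))
    non_sum <- min(dom_sum - 1, max(0, round(rnorm(1, 7, 3))))
    u_l <- if (dominant == "left") dom_sum else non_sum
    u_r <- if (dominant == "right") dom_sum else non_sum

    # SBR: symptom-dominant side implies contralateral striatal deficit, so
    # the log left/right ratio is shifted +m for left-dominant, -m for
    # right-dominant; m and the SD are set so CLES = pnorm(2m/(sd*sqrt(2)))
    # is approximately 0.92.
    m <- 0.1788; s_d <- 0.18
    base <- max(0.3, rnorm(1, 1.3, 0.25))
    d <- rnorm(1, if (dominant == "left") m else -m, s_d)
    subject$clinical <- list(updrs_left = u_l, updrs_right = u_r,
                             sbr_left = base * exp(d / 2),
                             sbr_right = base * exp(-d / 2),
                             dominant_side = dominant)
    subject
  })
}

#' Write a cohort to disk
#'
#' Writes one NIfTI-1 file per contrast and per truth mask for each subject,
#' a cohort-level CSV of group, site and clinical columns, and a JSON of the
#' generative truth parameters.
#'
#' @param cohort a `nm_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  truth <- list()
  for (s in cohort$subjects) {
    for (cn in names(s$images)) {
      write_volume(s$images[[cn]],
                   file.path(dir, sprintf("%s_%s.nii.gz", s$subject_id, cn)))
    }
    write_volume(s$sn_left, file.path(dir, paste0(s$subject_id, "_sn_left.nii.gz")))
    write_volume(s$sn_right, file.path(dir, paste0(s$subject_id, "_sn_right.nii.gz")))
    write_volume(s$crus_cerebri, file.path(dir, paste0(s$subject_id, "_cc.nii.gz")))
    rows[[s$subject_id]] <- data.frame(
      subject_id = s$subject_id, group = s$group, site = s$site,
      updrs_left = s$clinical$updrs_left, updrs_right = s$clinical$updrs_right,
      sbr_left = s$clinical$sbr_left, sbr_right = s$clinical$sbr_right,
      dominant_side = s$clinical$dominant_side,
      brain_volume_mm3 = s$brain_volume_mm3, stringsAsFactors = FALSE)
    truth[[s$subject_id]] <- s$truth
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
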