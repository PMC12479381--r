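# Acquisition-artifact operators: the same family serves as training-time
# augmentation and as the source of simulated cross-site domain shift.
# Intensity operators never touch masks; geometric operators transform images
# and masks with the identical sampled transform.

#' Generate a multiplicative bias field
#'
#' A random polynomial `f` over coordinates normalized to `[-1, 1]` (monomials
#' of total degree 1..`order`, iid normal coefficients), recentred to mean
#' zero and scaled so `max|f| = amplitude`; the returned field is `exp(f)`,
#' strictly positive with geometric mean 1.
#'
#' @param shape integer length-3 grid shape.
#' @param order polynomial order, >= 1 (default 3).
#' @param amplitude peak magnitude of the log-field, >= 0.
#' @param seed integer seed.
#' @return 3D array of multiplicative field values.
#' @export
make_bias_field <- function(shape, order = 3, amplitude = 0.3, seed = 0) {
  stopifnot(order >= 1, amplitude >= 0)
  if (amplitude == 0) return(array(1, shape))
  u <- seq(-1, 1, length.out = shape[1])
  v <- seq(-1, 1, length.out = shape[2])
  w <- seq(-1, 1, length.out = shape[3])
  with_seed(seed, {
    f <- array(0, shape)
    for (i in 0:order) for (j in 0:order) for (k in 0:order) {
      deg <- i + j + k
      if (deg < 1 || deg > order) next
      cf <- rnorm(1)
      f <- f + cf * outer(outer(u^i, v^j), w^k)
    }
    f <- f - mean(f)
    f <- f * (amplitude / max(abs(f)))
    exp(f)
  })
}

#' Apply a simulated bias field to a volume
#'
#' Multiplies the image by [make_bias_field()]'s smooth positive field,
#' emulating receive-coil inhomogeneity. Masks are never altered by this
#' operator.
#'
#' @param vol a [volume].
#' @inheritParams make_bias_field
#' @return The biased [volume].
#' @export
bias_field <- function(vol, order = 3, amplitude = 0.3, seed = 0) {
  stopifnot(is_volume(vol))
  if (amplitude == 0) return(vol)
  volume(vol$data * make_bias_field(dim(vol$data), order, amplitude, seed),
         vol$spacing)
}

#' Gamma intensity transform
#'
#' Rescales the image to `[0, 1]` by its own min/max, raises to `gamma`, and
#' maps back to the original range: a monotone, range-preserving intensity
#' remap. A constant image is returned unchanged.
#'
#' @param vol a [volume].
#' @param gamma exponent > 0.
#' @return The transformed [volume].
#' @export
gamma_transform <- function(vol, gamma) {
  stopifnot(is_volume(vol), gamma > 0)
  rng <- range(vol$data)
  if (rng[1] == rng[2]) return(vol)
  t <- (vol$data - rng[1]) / (rng[2] - rng[1])
  volume(rng[1] + t^gamma * (rng[2] - rng[1]), vol$spacing)
}

#' Additive Gaussian noise
#'
#' @param vol a [volume].
#' @param sd noise standard deviation, >= 0.
#' @param seed integer seed.
#' @return The noisy [volume].
#' @export
add_noise <- function(vol, sd = 1, seed = 0) {
  stopifnot(is_volume(vol), sd >= 0)
  if (sd == 0) return(vol)
  with_seed(seed,
            volume(vol$data + array(rnorm(length(vol$data), 0, sd),
                                    dim(vol$data)),
                   vol$spacing))
}

rot_mat <- function(deg, axis) {
  th <- deg * pi / 180
  c <- cos(th); s <- sin(th)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, byrow = TRUE),
         y = matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, byrow = TRUE),
         z = matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, byrow = TRUE))
}

#' Joint affine transform of images and masks
#'
#' Samples one affine transform (rotations up to `rotation` degrees per axis,
#' translations up to `translation` mm per axis, per-axis scale factors within
#' `1 +/- scale`, optional left-right flip) and applies it to every image
#' (trilinear interpolation) and every mask (nearest neighbour) on the shared
#' grid. With all magnitudes zero and `flip_lr = FALSE` the transform is the
#' identity and masks are returned bit-identically.
#'
#' @param images list of [volume]s (may be empty).
#' @param masks list of [label_mask]s (may be empty).
#' @param rotation,translation,scale length-3 (or scalar) maximum magnitudes;
#'   the realized parameters are sampled uniformly within them.
#' @param flip_lr mirror the left-right (first) axis. Note that flipping
#'   exchanges the anatomical roles of left and right structures; callers
#'   tracking laterality must swap labels accordingly.
#' @param seed integer seed for the sampled parameters.
#' @return `list(images =, masks =)`. If the transform pushes more than half
#'   of any mask outside the grid a warning is raised and the result carries
#'   `attr(, "truncated") = TRUE`.
#' @export
affine_transform <- function(images, masks, rotation = 0, translation = 0,
                             scale = 0, flip_lr = FALSE, seed = 0) {
  rotation <- rep_len(rotation, 3); translation <- rep_len(translation, 3)
  scale <- rep_len(scale, 3)
  ref <- c(images, masks)[[1]]
  shape <- dim(ref$data); sp <- ref$spacing
  with_seed(seed, {
    rot <- runif(3, -rotation, rotation)
    tr <- runif(3, -translation, translation)
    sc <- 1 + runif(3, -scale, scale)
    A <- rot_mat(rot[3], "z") %*% rot_mat(rot[2], "y") %*%
      rot_mat(rot[1], "x") %*% diag(sc)
    if (flip_lr) A <- A %*% diag(c(-1, 1, 1))
    Ainv <- solve(A)
    ctr <- (shape - 1) * sp / 2
    co <- coord_mm(shape, sp)
    g <- expand.grid(x = co$x, y = co$y, z = co$z)
    p <- t(cbind(g$x, g$y, g$z)) - ctr
    q <- Ainv %*% (p - tr) + ctr
    xi <- q[1, ] / sp[1] + 1; yi <- q[2, ] / sp[2] + 1; zi <- q[3, ] / sp[3] + 1

    out_images <- lapply(images, function(v) {
      volume(array(interp_trilinear(v$data, xi, yi, zi), shape), sp)
    })
    truncated <- FALSE
    out_masks <- lapply(masks, function(m) {
      before <- sum(m$data)
      newd <- array(interp_nearest(m$data, xi, yi, zi), shape)
      if (before > 0 && sum(newd) < 0.5 * before) truncated <<- TRUE
      label_mask(newd, sp)
    })
    if (truncated) {
      warning("affine transform pushed > 50% of a mask outside the grid")
    }
    res <- list(images = out_images, masks = out_masks)
    attr(res, "truncated") <- truncated
    res
  })
}

#' Joint elastic deformation of images and masks
#'
#' A smooth random displacement field (per-axis components drawn on a coarse
#' control grid and trilinearly upsampled) is applied jointly to every image
#' (trilinear) and mask (nearest neighbour). Component magnitudes are bounded
#' so the field's Euclidean norm never exceeds `max_displacement_mm`; the
#' fold-free heuristic requires `max_displacement_mm < grid_spacing_mm / 2`.
#'
#' @inheritParams affine_transform
#' @param grid_spacing_mm control-grid spacing in mm (default 8).
#' @param max_displacement_mm maximum displacement norm in mm; the default
#'   of 1.5 mm keeps the volume change of SN-sized masks within about 15%.
#' @return `list(images =, masks =)`.
#' @export
elastic_deform <- function(images, masks, grid_spacing_mm = 8,
                           max_displacement_mm = 1.5, seed = 0) {
  if (max_displacement_mm >= grid_spacing_mm / 2) {
    stop("max_displacement_mm must be < grid_spacing_mm / 2 (fold risk)",
         call. = FALSE)
  }
  ref <- c(images, masks)[[1]]
  shape <- dim(ref$data); sp <- ref$spacing
  if (max_displacement_mm == 0) return(list(images = images, masks = masks))
  with_seed(seed, {
    cmax <- max_displacement_mm / sqrt(3)
    nc <- pmax(2L, ceiling(shape * sp / grid_spacing_mm) + 1L)
    disp <- lapply(1:3, function(a) {
      coarse <- array(runif(prod(nc), -cmax, cmax), nc)
      xi <- seq(1, nc[1], length.out = shape[1])
      yi <- seq(1, nc[2], length.out = shape[2])
      zi <- seq(1, nc[3], length.out = shape[3])
      g <- expand.grid(x = xi, y = yi, z = zi)
      interp_trilinear(coarse, g$x, g$y, g$z)
    })
    co <- coord_mm(shape, sp)
    g <- expand.grid(x = co$x, y = co$y, z = co$z)
    xi <- (g$x - disp[[1]]) / sp[1] + 1
    yi <- (g$y - disp[[2]]) / sp[2] + 1
    zi <- (g$z - disp[[3]]) / sp[3] + 1
    list(
      images = lapply(images, function(v)
        volume(array(interp_trilinear(v$data, xi, yi, zi), shape), sp)),
      masks = lapply(masks, function(m)
        label_mask(array(interp_nearest(m$data, xi, yi, zi), shape), sp))
    )
  })
}

#' Simulated motion artifact (k-space line replacement)
#'
#' Replaces a `severity` fraction of phase-encode lines (second axis) in the
#' image's k-space with the corresponding lines of a rigidly shifted copy
#' (computed exactly in k-space via a phase ramp), producing the ghosting
#' typical of bulk motion. The single-displaced-state model is the simplest
#' that exhibits ghosting. The output is real-valued via the magnitude of the
#' inverse transform.
#'
#' @param vol a [volume].
#' @param severity fraction of corrupted phase-encode lines in `[0, 1)`.
#' @param max_shift_mm magnitude of the simulated displacement.
#' @param seed integer seed (corrupted-line subset and shift direction).
#' @return The corrupted [volume].
#' @export
motion_artifact <- function(vol, severity = 0.15, max_shift_mm = 2, seed = 0) {
  stopifnot(is_volume(vol), severity >= 0, severity < 1)
  if (severity == 0) return(vol)
  shape <- dim(vol$data); sp <- vol$spacing
  with_seed(seed, {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    shift_vox <- dir * max_shift_mm / sp
    F <- fft(vol$data)
    k1 <- (seq_len(shape[1]) - 1) / shape[1]
    k2 <- (seq_len(shape[2]) - 1) / shape[2]
    k3 <- (seq_len(shape[3]) - 1) / shape[3]
    phase <- outer(outer(k1 * shift_vox[1], k2 * shift_vox[2], "+"),
                   k3 * shift_vox[3], "+")
    F_shift <- F * exp(-2i * pi * phase)
    n_bad <- round(severity * shape[2])
    # corrupt random phase-encode lines, sparing the DC line
    candidates <- setdiff(seq_len(shape[2]), 1L)
    bad <- sample(candidates, min(n_bad, length(candidates)))
    F[, bad, ] <- F_shift[, bad, ]
    out <- Mod(fft(F, inverse = TRUE)) / prod(shape)
    volume(out, sp)
  })
}

#' Site acquisition profile
#'
#' Bundles the intensity-artifact magnitudes that characterise a simulated
#' scanner/site. All defaults are identities; [default_site_profiles()]
#' provides calibrated non-trivial settings.
#'
#' @param name label used in reports.
#' @param intensity_scale,intensity_offset global linear remap applied first.
#' @param bias_order,bias_amplitude bias-field parameters ([bias_field()]).
#' @param gamma_range length-2 bounds (within (0.2, 5)) from which the gamma
#'   exponent is drawn per subject.
#' @param motion_severity,motion_max_shift_mm motion-artifact parameters.
#' @param extra_noise_sd additional additive noise SD.
#' @return An object of class `site_profile`.
#' @export
site_profile <- function(name = "null", intensity_scale = 1,
                         intensity_offset = 0, bias_order = 3,
                         bias_amplitude = 0, gamma_range = c(1, 1),
                         motion_severity = 0, motion_max_shift_mm = 2,
                         extra_noise_sd = 0) {
  stopifnot(bias_amplitude >= 0, motion_severity >= 0, motion_severity < 1,
            gamma_range[1] > 0.2, gamma_range[2] < 5,
            gamma_range[1] <= gamma_range[2])
  structure(list(name = name, intensity_scale = intensity_scale,
                 intensity_offset = intensity_offset, bias_order = bias_order,
                 bias_amplitude = bias_amplitude, gamma_range = gamma_range,
                 motion_severity = motion_severity,
                 motion_max_shift_mm = motion_max_shift_mm,
                 extra_noise_sd = extra_noise_sd),
            class = "site_profile")
}

#' Default site profiles
#'
#' `clean` is the identity. `site_b` emulates a second scanner with markedly
#' stronger field inhomogeneity, a compressive gamma, a global intensity
#' remap, mild motion and extra noise; its magnitudes are calibration
#' constants chosen so that a segmenter calibrated on clean data degrades
#' substantially on `site_b` images while aggressive augmentation during
#' calibration recovers most of the loss. `site_b_mild` is a weaker variant.
#'
#' @return Named list of [site_profile]s.
#' @export
default_site_profiles <- function() {
  list(
    clean = site_profile("clean"),
    site_b = site_profile("site_b", intensity_scale = 1.4,
                          intensity_offset = -20, bias_order = 3,
                          bias_amplitude = 0.5, gamma_range = c(0.65, 0.8),
                          motion_severity = 0.08, extra_noise_sd = 2.5),
    site_b_mild = site_profile("site_b_mild", intensity_scale = 1.15,
                               intensity_offset = -5, bias_amplitude = 0.25,
                               gamma_range = c(0.8, 1.25),
                               motion_severity = 0.05, extra_noise_sd = 1.5)
  )
}

#' Apply a site profile to every image of a subject
#'
#' Composes intensity remap, bias field, gamma, motion and noise on each
#' image; truth masks are untouched (the site shift is intensity-only). Each
#' image uses seeds derived deterministically from `seed`.
#'
#' @param subject a `nm_subject`.
#' @param profile a [site_profile].
#' @param seed integer seed.
#' @return The subject with transformed images and `site` set to the
#'   profile's name.
#' @export
apply_site <- function(subject, profile, seed = 0) {
  stopifnot(inherits(subject, "nm_subject"), inherits(profile, "site_profile"))
  with_seed(seed, {
    gamma <- runif(1, profile$gamma_range[1], profile$gamma_range[2])
    img_seeds <- sample.int(1e6, 2 * length(subject$images))
    for (i in seq_along(subject$images)) {
      v <- subject$images[[i]]
      v <- volume(v$data * profile$intensity_scale + profile$intensity_offset,
                  v$spacing)
      v <- bias_field(v, profile$bias_order, profile$bias_amplitude,
                      seed = img_seeds[2 * i - 1])
      v <- gamma_transform(v, gamma)
      v <- motion_artifact(v, profile$motion_severity,
                           profile$motion_max_shift_mm,
                           seed = img_seeds[2 * i])
      v <- add_noise(v, profile$extra_noise_sd, seed = img_seeds[2 * i] + 1)
      subject$images[[i]] <- v
    }
    subject$site <- profile$name
    subject
  })
}
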