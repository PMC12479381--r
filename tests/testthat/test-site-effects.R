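make_test_vol <- function(shape = c(24, 24, 12), seed = 1) {
  set.seed(seed)
  volume(array(100 + rnorm(prod(shape), 0, 4), shape), c(0.67, 1.0, 1.34))
}

test_that("null-parameter calls are identities", {
  v <- make_test_vol()
  expect_identical(bias_field(v, amplitude = 0, seed = 1), v)
  expect_equal(gamma_transform(v, 1)$data, v$data, tolerance = 1e-12)
  expect_identical(add_noise(v, sd = 0, seed = 1), v)
  expect_identical(motion_artifact(v, severity = 0, seed = 1), v)
  m <- random_mask(dim(v$data), 50)
  out <- affine_transform(list(v), list(m), seed = 3)
  expect_identical(out$masks[[1]]$data, m$data)
  out2 <- elastic_deform(list(v), list(m), max_displacement_mm = 0, seed = 3)
  expect_identical(out2$masks[[1]]$data, m$data)
  # null site profile
  p <- small_params()
  s <- make_subject(p, disease_effect(), "HC", seed = 4)
  s2 <- apply_site(s, site_profile(), seed = 9)
  expect_identical(s$images$NM$data, s2$images$NM$data)
})

test_that("bias fields are positive with near-unit geometric mean", {
  for (seed in 1:5) {
    f <- make_bias_field(c(24, 20, 10), order = 3, amplitude = 0.5, seed = seed)
    expect_true(all(f > 0))
    expect_lt(abs(max(abs(log(f))) - 0.5), 1e-9)
    gm <- exp(mean(log(f)))
    expect_gt(gm, 0.9); expect_lt(gm, 1.1)
  }
  # masks are untouched by intensity operators (apply_site contract)
  p <- small_params()
  s <- make_subject(p, disease_effect(), "HC", seed = 4)
  sb <- apply_site(s, default_site_profiles()$site_b, seed = 2)
  expect_identical(sb$sn_left$data, s$sn_left$data)
  expect_identical(sb$crus_cerebri$data, s$crus_cerebri$data)
  expect_false(identical(sb$images$NM$data, s$images$NM$data))
})

test_that("gamma transform is monotone and endpoint-preserving", {
  v <- make_test_vol()
  for (g in c(0.5, 2, 3.7)) {
    out <- gamma_transform(v, g)
    expect_equal(range(out$data), range(v$data), tolerance = 1e-9)
    o1 <- order(as.vector(v$data)); o2 <- order(as.vector(out$data))
    expect_identical(o1, o2)
  }
  const <- volume(array(5, c(8, 8, 8)), c(1, 1, 1))
  expect_identical(gamma_transform(const, 2), const)
  expect_error(gamma_transform(v, 0))
})

test_that("additive noise has the requested standard deviation", {
  v <- volume(array(0, c(48, 48, 48)), c(1, 1, 1))  # > 1e5 voxels
  out <- add_noise(v, sd = 4, seed = 2)
  d <- out$data - v$data
  expect_lt(abs(sd(d) - 4) / 4, 0.05)
  expect_lt(abs(mean(d)), 0.05)
  expect_identical(add_noise(v, 4, seed = 2)$data, out$data)
})

test_that("affine transforms act jointly and conserve rigid mask volume", {
  p <- small_params()
  s <- make_subject(p, disease_effect(), "HC", seed = 6)
  m <- s$sn_left
  expect_gt(mask_size(m), 300)
  # flip twice restores the mask exactly (nearest-neighbour involution)
  f1 <- affine_transform(list(), list(m), flip_lr = TRUE, seed = 1)
  f2 <- affine_transform(list(), list(f1$masks[[1]]), flip_lr = TRUE, seed = 1)
  expect_identical(f2$masks[[1]]$data, m$data)
  # rigid transform: voxel count conserved within 5%
  for (seed in 1:5) {
    out <- affine_transform(list(s$images$NM), list(m), rotation = 8,
                            translation = 2, scale = 0, seed = seed)
    expect_lt(abs(mask_size(out$masks[[1]]) - mask_size(m)) / mask_size(m),
              0.05)
  }
  # large translation pushes the mask out: warning + flag
  expect_warning(
    out <- affine_transform(list(), list(m), translation = c(0, 60, 0),
                            seed = 2),
    "outside the grid")
  expect_true(attr(out, "truncated"))
})

test_that("elastic deformation is bounded and keeps masks binary", {
  p <- small_params()
  s <- make_subject(p, disease_effect(), "HC", seed = 7)
  m <- s$sn_left
  expect_error(elastic_deform(list(), list(m), grid_spacing_mm = 8,
                              max_displacement_mm = 5, seed = 1),
               "fold risk")
  vols <- vapply(1:20, function(seed) {
    out <- elastic_deform(list(s$images$NM), list(m), seed = seed)
    expect_true(all(out$masks[[1]]$data %in% c(0, 1)))
    mask_size(out$masks[[1]])
  }, 0)
  expect_true(all(abs(vols - mask_size(m)) / mask_size(m) <= 0.15))
})

test_that("motion artifacts conserve energy and add ghosting monotonically", {
  v <- make_test_vol(shape = c(32, 32, 12), seed = 5)
  out <- motion_artifact(v, severity = 0.3, max_shift_mm = 2, seed = 3)
  e_in <- sum(v$data^2); e_out <- sum(out$data^2)
  expect_lt(abs(e_out - e_in) / e_in, 0.2)
  # background (uniform region) SD grows with severity
  bg <- volume(array(100, c(32, 32, 12)), c(0.67, 1, 1.34))
  bg$data[14:18, 14:18, 5:7] <- 140  # a bright blob to generate ghosts
  sds <- vapply(c(0, 0.15, 0.3), function(sv) {
    o <- motion_artifact(bg, sv, max_shift_mm = 2, seed = 11)
    sd(o$data[1:10, 1:10, 1:3])
  }, 0)
  expect_true(all(diff(sds) > 0))
})

test_that("apply_site is deterministic under a fixed seed", {
  p <- small_params()
  s <- make_subject(p, disease_effect(), "HC", seed = 8)
  prof <- default_site_profiles()$site_b
  a <- apply_site(s, prof, seed = 21)
  b <- apply_site(s, prof, seed = 21)
  expect_identical(a$images, b$images)
  expect_false(identical(a$images$NM$data,
                         apply_site(s, prof, seed = 22)$images$NM$data))
  expect_equal(a$site, "site_b")
})
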