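test_that("phantom generation is deterministic and group enters only via effects", {
  p <- small_params()
  null_eff <- disease_effect(cnr_reduction = 0, volume_reduction = 0)
  a <- make_subject(p, null_eff, "HC", seed = 5)
  b <- make_subject(p, null_eff, "HC", seed = 5)
  expect_identical(a$images$NM$data, b$images$NM$data)
  expect_identical(a$sn_left$data, b$sn_left$data)
  # zero effect: PD and HC generation coincide under the same seed
  pd <- make_subject(p, null_eff, "PD", seed = 5)
  expect_identical(a$images$NM$data, pd$images$NM$data)
  expect_identical(a$truth, pd$truth)
  # different seed changes the phantom
  expect_false(identical(a$images$NM$data,
                         make_subject(p, null_eff, "HC", seed = 6)$images$NM$data))
})

test_that("phantom geometry respects its invariants", {
  p <- small_params()
  for (seed in 1:6) {
    s <- make_subject(p, disease_effect(), if (seed %% 2) "PD" else "HC", seed)
    expect_equal(sum(s$sn_left$data * s$sn_right$data), 0)
    expect_equal(sum(s$crus_cerebri$data * (s$sn_left$data + s$sn_right$data)), 0)
    for (side in c("sn_left", "sn_right")) {
      zprof <- apply(s[[side]]$data, 3, sum)
      extent <- sum(zprof > 0)
      expect_gte(extent, p$sn_extent_slices[1])
      expect_lte(extent, p$sn_extent_slices[2])
      expect_true(all(diff(which(zprof > 0)) == 1))  # contiguous slices
    }
    expect_gt(s$brain_volume_mm3, 0)
    expect_true(all(vapply(s$images, function(v) all(is.finite(v$data)), TRUE)))
  }
})

test_that("voxel-count targets and disease effects are realized", {
  p <- phantom_params()
  eff0 <- disease_effect(cnr_reduction = 0, volume_reduction = 0,
                         between_subject_sd = 0)
  hc <- lapply(1:12, function(i) make_subject(p, eff0, "HC", seed = i))
  sizes <- vapply(hc, function(s) mask_size(s$sn_left), 0)
  expect_true(all(sizes > 300))  # near the 600 target, volume-jittered
  cc <- vapply(hc, function(s) mask_size(s$crus_cerebri), 0)
  expect_true(all(cc > 1800))
  # measured CNR on truth masks recovers the generative target
  err <- vapply(hc, function(s) {
    cnr(s$images$NM, sn_union(s), s$crus_cerebri) - p$target_cnr
  }, 0)
  expect_lt(mean(abs(err)), 0.1)
  # PD group: truth CNR reduced by the configured fraction
  eff <- disease_effect(cnr_reduction = 0.22, volume_reduction = 0,
                        between_subject_sd = 0)
  pd <- make_subject(p, eff, "PD", seed = 3)
  hc3 <- make_subject(p, disease_effect(cnr_reduction = 0, volume_reduction = 0,
                                        between_subject_sd = 0), "HC", seed = 3)
  expect_equal(pd$truth$cnr_left / hc3$truth$cnr_left, 0.78, tolerance = 1e-10)
})

test_that("a too-small grid raises a placement error", {
  expect_error(phantom_params(grid_shape = c(16, 16, 8)),
               NA)  # params themselves are legal
  expect_error(make_subject(phantom_params(grid_shape = c(16, 16, 8)),
                            disease_effect(), "HC", 1),
               "too small")
})

test_that("cohorts are reproducible, extensible and correctly composed", {
  p <- small_params()
  co <- make_cohort(p, disease_effect(), n_pd = 3, n_hc = 2, seed = 9)
  co2 <- make_cohort(p, disease_effect(), n_pd = 3, n_hc = 2, seed = 9)
  expect_identical(co, co2)
  groups <- vapply(co$subjects, `[[`, "", "group")
  expect_equal(unname(table(groups)[c("PD", "HC")]), c(3L, 2L),
               ignore_attr = TRUE)
  expect_equal(anyDuplicated(names(co$subjects)), 0)
  # HC-only cohort
  hc_only <- make_cohort(p, disease_effect(), n_pd = 0, n_hc = 5, seed = 9)
  expect_true(all(vapply(hc_only$subjects, `[[`, "", "group") == "HC"))
  # per-subject seeds are counter-derived: subject i is unchanged by n
  co3 <- make_cohort(p, disease_effect(), n_pd = 3, n_hc = 4, seed = 9)
  expect_identical(co$subjects[[1]]$images$NM$data,
                   co3$subjects[[1]]$images$NM$data)
})

test_that("the rater simulator hits its target agreement", {
  p <- small_params()
  s <- make_subject(p, disease_effect(), "HC", seed = 2)
  mask <- s$sn_left
  expect_identical(simulate_rater(mask, target_dsc = 1, seed = 1), mask)
  d <- vapply(1:10, function(i) dice(simulate_rater(mask, 0.7, seed = i), mask), 0)
  expect_lt(abs(mean(d) - 0.7), 0.05)
  expect_true(all(d > 0.55 & d < 0.85))
  # deterministic under seed
  expect_identical(simulate_rater(mask, 0.7, seed = 3),
                   simulate_rater(mask, 0.7, seed = 3))
  tiny <- label_mask(array(c(rep(1, 10), rep(0, prod(c(8, 8, 6)) - 10)),
                           c(8, 8, 6)), mask$spacing)
  expect_error(simulate_rater(tiny, 0.7, 1), "too small")
})

test_that("clinical assignment is self-consistent and null by default", {
  p <- small_params()
  co <- make_cohort(p, disease_effect(), n_pd = 25, n_hc = 5, seed = 13)
  tb <- clinical_table(co)
  pd <- tb[tb$group == "PD", ]
  # recomputed dominant side matches the generated sums in all non-ties
  expect_true(all(pd$dominant_side %in% c("left", "right")))
  expect_true(all((pd$dominant_side == "left") ==
                    (pd$updrs_left > pd$updrs_right)))
  hc <- tb[tb$group == "HC", ]
  expect_true(all(hc$updrs_left == 0 & hc$updrs_right == 0))
  expect_true(all(hc$dominant_side == "undetermined"))
  expect_true(all(tb$sbr_left > 0 & tb$sbr_right > 0))
})

test_that("writing a cohort produces NIfTI images, CSV and truth JSON", {
  dir <- withr::local_tempdir()
  p <- small_params()
  co <- make_cohort(p, disease_effect(), n_pd = 1, n_hc = 1, seed = 3)
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  id <- names(co$subjects)[1]
  nm_path <- file.path(dir, sprintf("%s_NM.nii.gz", id))
  expect_true(file.exists(nm_path))
  back <- read_volume(nm_path)
  expect_equal(back$spacing, p$spacing, tolerance = 1e-6)
  expect_equal(back$data, co$subjects[[1]]$images$NM$data, tolerance = 1e-5)
  mask_back <- read_volume(file.path(dir, sprintf("%s_sn_left.nii.gz", id)),
                           mask = TRUE)
  expect_identical(as.vector(mask_back$data),
                   as.vector(co$subjects[[1]]$sn_left$data))
})
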