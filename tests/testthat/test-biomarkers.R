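const_vol <- function(vals, shape = c(8, 8, 4)) {
  volume(array(vals, shape), c(0.67, 1.0, 1.34))
}

test_that("roi_stats uses the population SD and physical volume", {
  sp <- c(0.67, 1.0, 1.34)
  v <- const_vol(7)
  m <- random_mask(c(8, 8, 4), 20, sp)
  st <- roi_stats(v, m)
  expect_equal(st$sd, 0)
  expect_equal(st$mean, 7)
  # two voxels at 0 and 2: mean 1, population sd 1
  a <- array(0, c(8, 8, 4)); a[1, 1, 1] <- 0; a[2, 1, 1] <- 2
  mm <- array(0, c(8, 8, 4)); mm[1:2, 1, 1] <- 1
  st2 <- roi_stats(volume(a, sp), label_mask(mm, sp))
  expect_equal(st2$mean, 1); expect_equal(st2$sd, 1)
  m100 <- random_mask(c(8, 8, 4), 100, sp)
  expect_equal(roi_stats(v, m100)$volume_mm3, 100 * 0.67 * 1.0 * 1.34)
  expect_error(roi_stats(v, label_mask(array(0, c(8, 8, 4)), sp)), "empty")
})

build_cnr_fixture <- function(sn_val, cc_vals) {
  sp <- c(1, 1, 1); shape <- c(10, 10, 4)
  a <- array(0, shape)
  sn <- array(0, shape); sn[2:3, 2:3, 1] <- 1
  cc <- array(0, shape); cc[6:9, 6:9, 1:2] <- 1
  a[sn > 0] <- sn_val
  a[cc > 0] <- rep_len(cc_vals, sum(cc))
  list(vol = volume(a, sp), sn = label_mask(sn, sp), cc = label_mask(cc, sp))
}

test_that("cnr and cr compute their defining formulas", {
  # CC values alternating 95/105: mean 100, population sd 5
  f <- build_cnr_fixture(110, c(95, 105))
  expect_equal(cnr(f$vol, f$sn, f$cc), 2)
  expect_equal(cr(f$vol, f$sn, f$cc), 0.1)
  f0 <- build_cnr_fixture(100, c(95, 105))
  expect_equal(cnr(f0$vol, f0$sn, f0$cc), 0)
  expect_equal(cr(f0$vol, f0$sn, f0$cc), 0)
  fflat <- build_cnr_fixture(110, 100)
  expect_error(cnr(fflat$vol, fflat$sn, fflat$cc), "SD is zero")
})

test_that("cnr is affine-invariant; cr only scale-invariant", {
  p <- small_params()
  s <- make_subject(p, disease_effect(), "HC", seed = 3)
  nm <- s$images$NM; un <- sn_union(s); cc <- s$crus_cerebri
  base_cnr <- cnr(nm, un, cc); base_cr <- cr(nm, un, cc)
  remap <- volume(3.2 * nm$data + 17, nm$spacing)
  expect_equal(cnr(remap, un, cc), base_cnr, tolerance = 1e-12)
  scaled <- volume(3.2 * nm$data, nm$spacing)
  expect_equal(cr(scaled, un, cc), base_cr, tolerance = 1e-12)
  # an offset changes CR
  expect_false(isTRUE(all.equal(cr(remap, un, cc), base_cr)))
})

test_that("threshold_mask keeps only supra-threshold voxels within the mask", {
  f <- build_cnr_fixture(110, c(95, 105))  # cc mean 100, sd 5
  # SN uniformly at mean + 2 sd, k = 1.5: mask unchanged
  expect_identical(threshold_mask(f$vol, f$sn, f$cc, k = 1.5)$data, f$sn$data)
  # very negative k: unchanged
  expect_identical(threshold_mask(f$vol, f$sn, f$cc, k = -100)$data, f$sn$data)
  # k above the SN level: empty, flagged
  thr <- threshold_mask(f$vol, f$sn, f$cc, k = 3)
  expect_equal(sum(thr$data), 0)
  expect_true(attr(thr, "empty"))
  # thresholded volume never exceeds the raw volume on noisy phantoms
  p <- small_params()
  s <- make_subject(p, disease_effect(), "PD", seed = 5)
  tm <- threshold_mask(s$images$NM, sn_union(s), s$crus_cerebri, k = 1.5)
  expect_lte(mask_volume_mm3(tm), mask_volume_mm3(sn_union(s)))
})

test_that("biomarker_table reports one row per subject and flags problems", {
  p <- small_params()
  co <- make_cohort(p, disease_effect(), n_pd = 2, n_hc = 2, seed = 6)
  tb <- biomarker_table(co)
  expect_equal(nrow(tb), 4)
  expect_equal(attr(tb, "exclusions"), character(0))
  expect_true(all(tb$normalized_volume > 0 & tb$normalized_volume < 1))
  expect_true(all(tb$thresholded_volume_mm3 <= tb$volume_mm3))
  # truth masks recover the generative CNR
  truths <- vapply(co$subjects, function(s)
    mean(c(s$truth$cnr_left, s$truth$cnr_right)), 0)
  expect_lt(max(abs(tb$cnr - truths)), 0.35)
  # missing prediction is excluded with a report; empty prediction flagged
  preds <- lapply(co$subjects, sn_union)
  preds[[1]] <- label_mask(array(0, dim(preds[[2]]$data)), preds[[2]]$spacing)
  preds[[2]] <- NULL
  tb2 <- biomarker_table(co, preds, "seg")
  expect_equal(nrow(tb2), 3)
  expect_equal(attr(tb2, "exclusions"), names(co$subjects)[2])
  expect_true(tb2$empty_prediction[tb2$subject_id == names(co$subjects)[1]])
  expect_true(is.na(tb2$cnr[tb2$empty_prediction]))
})

test_that("collinearity_report recovers trivial and degenerate cases", {
  n <- 20
  set.seed(4)
  tb <- data.frame(cnr = rnorm(n, 3, 0.5), empty_prediction = FALSE)
  tb$normalized_volume <- tb$cnr        # duplicated column: r = 1
  tb$thresholded_volume_mm3 <- rnorm(n)
  rep1 <- collinearity_report(tb)
  expect_equal(rep1$r_raw, 1)
  tb$normalized_volume <- 1
  expect_error(collinearity_report(tb), "constant column")
  expect_error(collinearity_report(tb[1:5, ]), "at least 10")
})
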