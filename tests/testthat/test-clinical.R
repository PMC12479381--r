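test_that("mann_whitney reproduces known U statistics and exact p-values", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$u, 0)   # complete separation
  x <- c(3, 1, 4, 1, 5)
  expect_equal(mann_whitney(x, x)$u, length(x)^2 / 2) # symmetry with ties
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)                              # 2/20 rank assignments
  expect_equal(mann_whitney(rep(2, 5), rep(2, 7))$p, 1)
})

test_that("mann_whitney agrees with wilcox.test across regimes", {
  set.seed(10)
  # tie-free small samples: exact match
  for (i in 1:10) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), 0.5)
    ours <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$u, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  # large tied samples: normal approximation with tie correction
  x <- sample(1:6, 60, replace = TRUE); y <- sample(2:7, 45, replace = TRUE)
  ours <- mann_whitney(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
  expect_equal(ours$u, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-6)
})

test_that("cles satisfies its tie rule, complement and U identities", {
  expect_equal(cles(c(5, 6), c(1, 2)), 1)
  expect_equal(cles(rep(3, 4), rep(3, 5)), 0.5)
  set.seed(21)
  for (i in 1:30) {
    x <- sample(1:8, sample(2:15, 1), replace = TRUE)
    y <- sample(1:8, sample(2:15, 1), replace = TRUE)
    # brute-force double loop
    tot <- 0
    for (xi in x) for (yj in y) tot <- tot + (xi > yj) + 0.5 * (xi == yj)
    expect_equal(cles(x, y), tot / (length(x) * length(y)))
    expect_equal(cles(x, y) + cles(y, x), 1)
    expect_equal(cles(x, y),
                 mann_whitney(x, y)$u / (length(x) * length(y)))
  }
})

test_that("sbr_ratio and dominant_side follow their definitions", {
  expect_equal(sbr_ratio(2, 2), 1)
  expect_equal(sbr_ratio(1, 2), 0.5)
  expect_error(sbr_ratio(-1, 2), "positive")
  expect_error(sbr_ratio(1, 0), "positive")
  expect_equal(dominant_side(10, 4), "left")
  expect_equal(dominant_side(3, 9), "right")
  expect_equal(dominant_side(0, 0), "undetermined")
  expect_equal(dominant_side(c(1, 2), c(2, 2)), c("right", "undetermined"))
})

test_that("auc equals the rank statistic and the trapezoidal ROC area", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(auc(scores, labels), 1)
  expect_error(auc(scores, rep(TRUE, 5)), "both classes")
  set.seed(33)
  for (i in 1:10) {
    s <- rnorm(40); l <- rbinom(40, 1, 0.4)
    if (sum(l) %in% c(0, 40)) next
    ours <- auc(s, l == 1)
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
    # invariance under a strictly increasing transform
    expect_equal(auc(exp(s), l == 1), ours)
  }
  # labels independent of scores: AUC near 1/2
  set.seed(34)
  expect_lt(abs(auc(rnorm(1000), rbinom(1000, 1, 0.5) == 1) - 0.5), 0.05)
})

test_that("cv_roc_auc separates, nulls and reproduces", {
  set.seed(55)
  x <- c(rnorm(30, 0), rnorm(30, 3))         # 3-SD separated feature
  y <- rep(c(FALSE, TRUE), each = 30)
  strong <- cv_roc_auc(x, y, n_seeds = 20, master_seed = 1)
  expect_gt(strong$mean_auc, 0.95)
  null <- cv_roc_auc(x, sample(y), n_seeds = 20, master_seed = 1)
  expect_gt(null$mean_auc, 0.40); expect_lt(null$mean_auc, 0.60)
  again <- cv_roc_auc(x, y, n_seeds = 20, master_seed = 1)
  expect_identical(strong$aucs, again$aucs)
  expect_equal(strong$mean_auc, mean(strong$aucs))
  expect_error(cv_roc_auc(x[c(1, 2, 31)], y[c(1, 2, 31)], n_folds = 2),
               "at least n_folds")
})

test_that("laterality coupling drives the CNR-ratio effect size", {
  p <- small_params()
  # positive control: full coupling makes dominance contralateral to the
  # CNR deficit, so the CNR ratio separates the dominance groups
  co <- make_cohort(p, disease_effect(laterality_coupling = 1),
                    n_pd = 30, n_hc = 4, seed = 19)
  lat <- laterality_analysis(co)
  expect_gt(lat$cles[lat$measure == "cnr_ratio"], 0.8)
  expect_gt(lat$cles[lat$measure == "sbr_ratio"], 0.75)
  # too few subjects per side: skipped with a message
  co_small <- make_cohort(p, disease_effect(), n_pd = 3, n_hc = 2, seed = 3)
  expect_message(lat2 <- laterality_analysis(co_small), "skipped")
  expect_true(any(is.na(lat2$cles)))
})
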