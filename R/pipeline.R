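#' Pipeline configuration
#'
#' Bundles every stage's parameters. Unknown arguments are rejected loudly
#' (the constructor has no `...`), and split sizes must sum to the cohort
#' size.
#'
#' @param params a [phantom_params].
#' @param effect a [disease_effect].
#' @param n_pd,n_hc cohort sizes (defaults 58 / 22).
#' @param n_train training-split size (subject-level; default 56, the rest
#'   is the test split).
#' @param sites named list of [site_profile]s; `test_site` selects which one
#'   is applied to the test split (`"clean"` = none).
#' @param test_site name within `sites`.
#' @param contrasts contrasts fed to the segmenter.
#' @param k_grid calibration grid.
#' @param n_folds calibration folds.
#' @param augment logical: use [augmented_calibrate()].
#' @param clinical_n_folds,clinical_n_seeds ROC cross-validation settings.
#' @param run_screening logical: also build the contrast screening matrix.
#' @param seed master seed; every stage derives its seeds from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(params = phantom_params(),
                            effect = disease_effect(),
                            n_pd = 58, n_hc = 22, n_train = 56,
                            sites = default_site_profiles(),
                            test_site = "clean",
                            contrasts = "NM",
                            k_grid = seq(1, 3.5, by = 0.25),
                            n_folds = 3, augment = FALSE,
                            clinical_n_folds = 2, clinical_n_seeds = 100,
                            run_screening = FALSE, seed = 0) {
  stopifnot(n_train >= 2, n_train < n_pd + n_hc, seed >= 0)
  if (!test_site %in% names(sites)) {
    stop("test_site '", test_site, "' not found among site profiles",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full phantom pipeline
#'
#' Executes generate -> split -> (optional site shift of the test split) ->
#' calibrate -> segment -> evaluate -> biomarkers -> (optional screening) ->
#' clinical statistics, writing every table plus a provenance JSON (config
#' hash, seed, package version) to `out_dir`. Reruns with an identical
#' config are numerically identical.
#'
#' @param config a [pipeline_config].
#' @param out_dir output directory, created if needed; `NULL` skips writing.
#' @return Invisibly, a list with the cohort splits, model, metric and
#'   biomarker tables, clinical report and file paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  cohort <- make_cohort(config$params, config$effect, config$n_pd,
                        config$n_hc, site = "A", seed = derive_seed(seed, 1))
  ids <- names(cohort$subjects)
  train_ids <- with_seed(derive_seed(seed, 2),
                         sample(ids, config$n_train))
  test_ids <- setdiff(ids, train_ids)
  training <- cohort; training$subjects <- cohort$subjects[train_ids]
  test <- cohort; test$subjects <- cohort$subjects[test_ids]

  prof <- config$sites[[config$test_site]]
  if (prof$name != "clean" || prof$bias_amplitude > 0) {
    test$subjects <- lapply(seq_along(test$subjects), function(i) {
      apply_site(test$subjects[[i]], prof, seed = derive_seed(seed, 1000 + i))
    })
    names(test$subjects) <- test_ids
  }

  folds <- make_folds(training, config$n_folds, seed = derive_seed(seed, 3))
  model <- if (config$augment) {
    augmented_calibrate(training, config$contrasts, config$k_grid, folds,
                        seed = derive_seed(seed, 4))
  } else {
    calibrate(training, config$contrasts, config$k_grid, folds)
  }

  preds <- segment_cohort(test, model)
  metrics <- evaluate_cohort(preds, test)

  bm_truth <- biomarker_table(cohort, method_label = "truth")
  bm_pred <- biomarker_table(test, preds, method_label = "segmenter")

  screening <- if (config$run_screening) {
    A <- build_matrix(training, names(config$params$contrast_set), folds)
    list(A = A, delta_single = delta_vs_single(A),
         delta_best = delta_vs_best(A),
         potential = improvement_potential(delta_vs_single(A)),
         ranking = rank_models(A))
  }

  ct <- clinical_table(cohort)
  ok <- is.finite(bm_truth$cnr)
  mw <- mann_whitney(bm_truth$cnr[ok & bm_truth$group == "PD"],
                     bm_truth$cnr[ok & bm_truth$group == "HC"])
  roc <- cv_roc_auc(cbind(cnr = bm_truth$cnr[ok],
                          normalized_volume = bm_truth$normalized_volume[ok]),
                    bm_truth$group[ok] == "PD",
                    n_folds = config$clinical_n_folds,
                    n_seeds = config$clinical_n_seeds,
                    master_seed = derive_seed(seed, 5))
  clinical <- list(group_cnr_mw = mw, roc = roc,
                   laterality = laterality_analysis(cohort))

  result <- list(training_ids = train_ids, test_ids = test_ids,
                 model = model, metrics = metrics,
                 biomarkers_truth = bm_truth, biomarkers_pred = bm_pred,
                 screening = screening, clinical = clinical,
                 collinearity = collinearity_report(bm_truth))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(bm_truth, file.path(out_dir, "biomarkers_truth.csv"),
                     row.names = FALSE)
    utils::write.csv(bm_pred, file.path(out_dir, "biomarkers_pred.csv"),
                     row.names = FALSE)
    utils::write.csv(ct, file.path(out_dir, "clinical.csv"),
                     row.names = FALSE)
    utils::write.csv(clinical$laterality, file.path(out_dir, "laterality.csv"),
                     row.names = FALSE)
    if (!is.null(screening)) {
      utils::write.csv(as.data.frame(unclass(screening$A)),
                       file.path(out_dir, "screening_matrix.csv"))
      utils::write.csv(screening$ranking,
                       file.path(out_dir, "screening_ranking.csv"),
                       row.names = FALSE)
    }
    cfg_json <- file.path(out_dir, "config.json")
    cfg_ser <- list(n_pd = config$n_pd, n_hc = config$n_hc,
                    n_train = config$n_train, test_site = config$test_site,
                    contrasts = config$contrasts, k_grid = config$k_grid,
                    n_folds = config$n_folds, augment = config$augment,
                    seed = config$seed)
    jsonlite::write_json(cfg_ser, cfg_json, auto_unbox = TRUE, digits = NA)
    prov <- list(config_md5 = unname(tools::md5sum(cfg_json)),
                 master_seed = seed,
                 package_version = as.character(utils::packageVersion("nmbench")),
                 summary = list(mean_dsc = mean(metrics$dsc),
                                group_cnr_p = mw$p,
                                roc_mean_auc = roc$mean_auc))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    result$files <- list.files(out_dir, full.names = TRUE)
  }
  invisible(result)
}
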