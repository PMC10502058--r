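#' Run the default-conditions recovery study
#'
#' Re-runs, from scratch, the full synthetic validation of the method under
#' its default study conditions: a fresh-frozen training cohort of 10
#' tissues x 40 samples (purity 1) plus 20 normals; two-condition marker
#' selection at FDR 0.01; the beta + linear SVC model with a 4:1 split,
#' oversampling, a 50-setting search and sigmoid calibration; and an
#' FFPE-mode test cohort of 10 samples per tissue at purity 0.7. Optionally
#' adds the tumor-content trend (accuracy across a purity grid) and the
#' read-thinning trend (accuracy after binomial count thinning).
#'
#' @param seed master seed; every random draw derives from it.
#' @param learner,search_budget model coordinates (defaults: the linear
#'   support vector classifier, 50 settings).
#' @param n_test_per_tissue held-out FFPE test samples per tissue (10).
#' @param trends compute the purity and thinning trends (default TRUE).
#' @param purity_grid tumor-content grid for the trend (default
#'   0.1/0.3/0.5/0.7/1.0).
#' @param thin_grid count-thinning fractions (default 0.1/0.5/1.0).
#' @param n_trend_per_tissue samples per tissue per purity bin (5).
#' @param verbose print stage progress.
#' @return list with \code{markers} (selection + recovery statistics),
#'   \code{model}, \code{test} (a \code{too_eval} plus confidence tiers),
#'   and, when requested, \code{purity_trend} and \code{thinning_trend}
#'   accuracy tables.
#' @export
too_recovery_study <- function(seed = 1, learner = "linear_svc",
                               search_budget = 50, n_test_per_tissue = 10,
                               trends = TRUE,
                               purity_grid = c(0.1, 0.3, 0.5, 0.7, 1.0),
                               thin_grid = c(0.1, 0.5, 1.0),
                               n_trend_per_tissue = 5, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  elapsed <- function() sprintf("%.0fs", as.numeric(Sys.time() - t0, units = "secs"))

  cfg <- synth_config()
  cohort <- simulate_cohort(cfg, seed = derive_seed(seed, "train_cohort"))
  say("[%s] training cohort: %d samples", elapsed(), nrow(cohort$manifest))
  mats <- cohort_matrices(cohort, metric = "beta")
  markers <- select_markers(mats$tumor, mats$normal, alpha = 0.01)
  planted <- cohort$profiles$markers
  per_tissue_recovery <- vapply(rownames(cohort$profiles$tissues), function(t) {
    sel <- markers$table$region_id[markers$table$cancer_type == t]
    mean(planted$region_id[planted$tissue == t] %in% sel)
  }, numeric(1))
  false_regions <- setdiff(markers$features, planted$region_id)
  marker_stats <- list(
    set = markers,
    per_tissue_recovery = per_tissue_recovery,
    recovery = mean(per_tissue_recovery),
    n_selected = length(markers$features),
    false_region_frac = length(false_regions) / length(markers$features)
  )
  say("[%s] markers: %d selected, recovery %.3f, false fraction %.3f",
      elapsed(), marker_stats$n_selected, marker_stats$recovery,
      marker_stats$false_region_frac)

  model <- too_fit(mats$tumor, mats$normal, learner = learner,
                   markers = markers, search_budget = search_budget,
                   seed = derive_seed(seed, "fit"))
  say("[%s] model: CV accuracy %.3f, validation top-1 %.3f", elapsed(),
      model$fit$cv_accuracy, model$validation$topk[1])

  test_cfg <- synth_config(purity = 0.7, mode = "FFPE",
                           n_samples = n_test_per_tissue, n_normal = 0)
  test <- simulate_cohort(test_cfg, seed = derive_seed(seed, "test_cohort"),
                          profiles = cohort$profiles)
  eval_cohort <- function(co) {
    per <- cohort_metrics(co, metrics = "beta")
    labels <- stats::setNames(co$manifest$label, co$manifest$sample_id)
    mat <- build_matrix(per, "beta", labels, min_depth = 0,
                        max_missing_frac = 1)
    pred <- predict.too_model(model, mat, k = length(model$classes))
    list(pred = pred, eval = evaluate_predictions(labels, pred))
  }
  test_ec <- eval_cohort(test)
  test_eval <- test_ec$eval
  say("[%s] FFPE test at purity 0.7: top-1 %.3f, top-3 %.3f, AUC %.3f",
      elapsed(), test_eval$topk[1], test_eval$topk[3], test_eval$macro_auc)

  out <- list(config = cfg, markers = marker_stats, model = model,
              test = test_eval, test_pred = test_ec$pred, seed = seed)

  if (trends) {
    trend_acc <- vapply(purity_grid, function(p) {
      tc <- synth_config(purity = p, mode = "FFPE",
                         n_samples = n_trend_per_tissue, n_normal = 0)
      co <- simulate_cohort(tc, seed = derive_seed(seed, sprintf("purity_%g", p)),
                            profiles = cohort$profiles)
      eval_cohort(co)$eval$topk[[1]]
    }, numeric(1))
    out$purity_trend <- data.frame(purity = purity_grid, top1 = trend_acc)
    say("[%s] purity trend: %s", elapsed(),
        paste(sprintf("%.2f", trend_acc), collapse = " "))

    thin_acc <- vapply(thin_grid, function(fr) {
      co <- test
      co$samples <- lapply(seq_along(co$samples), function(i) {
        downsample_records(co$samples[[i]], fr,
                           seed = derive_seed(seed, sprintf("thin_%g_%d", fr, i)))
      })
      names(co$samples) <- test$manifest$sample_id
      eval_cohort(co)$eval$topk[[1]]
    }, numeric(1))
    out$thinning_trend <- data.frame(fraction = thin_grid, top1 = thin_acc)
    say("[%s] thinning trend: %s", elapsed(),
        paste(sprintf("%.2f", thin_acc), collapse = " "))
  }
  out
}
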