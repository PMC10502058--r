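#' Fit a tissue-of-origin methylation classifier
#'
#' End-to-end fit from a tumor and a normal feature matrix of one metric:
#' (1) select cancer-type-specific marker regions by the two-condition
#' rank-sum / FDR procedure on the full tumor cohort against the normal
#' controls; (2) split the tumor samples 4:1 into training and validation
#' strata; (3) oversample the training portion (only) to class balance;
#' (4) run the budgeted hyperparameter search and fit the learner;
#' (5) calibrate class probabilities on the held-out validation stratum.
#' The default grid coordinate — beta value metric with the linear support
#' vector classifier — is the configuration that performs best for primary
#' site prediction.
#'
#' @param tumor a \code{too_matrix} of tumor samples (labels = cancer type).
#' @param normal a \code{too_matrix} of normal-tissue controls.
#' @param learner one of [too_learners()] (default \code{"linear_svc"}).
#' @param alpha marker-selection FDR threshold (default 0.01).
#' @param validation_frac held-out validation share (default 0.2).
#' @param k_neighbors oversampling neighborhood size (default 5).
#' @param search_budget hyperparameter settings tried (default 50).
#' @param cv_folds cross-validation folds in the search (default 5).
#' @param calibration \code{"sigmoid"} (default) or \code{"isotonic"}.
#' @param markers optionally a precomputed \code{too_markers} object to
#'   reuse instead of reselecting.
#' @param seed master seed; every downstream random draw is derived from it.
#' @return object of class \code{too_model}.
#' @examples
#' \donttest{
#' cfg <- synth_config(n_tissues = 3, n_regions = 40, markers_per_tissue = 5,
#'                     n_samples = 8, n_normal = 8, lambda_reads = 120)
#' cohort <- simulate_cohort(cfg, seed = 7)
#' mats <- cohort_matrices(cohort, metric = "beta")
#' fit <- too_fit(mats$tumor, mats$normal, search_budget = 4, seed = 7)
#' print(fit)
#' }
#' @export
too_fit <- function(tumor, normal, learner = "linear_svc", alpha = 0.01,
                    validation_frac = 0.2, k_neighbors = 5,
                    search_budget = 50, cv_folds = 5,
                    calibration = c("sigmoid", "isotonic"), markers = NULL,
                    seed = 1) {
  stopifnot(inherits(tumor, "too_matrix"), inherits(normal, "too_matrix"))
  calibration <- match.arg(calibration)
  if (!identical(tumor$metric, normal$metric)) {
    stopf("tumor and normal matrices carry different metrics (%s vs %s)",
          tumor$metric, normal$metric)
  }
  if (is.null(markers)) {
    markers <- select_markers(tumor, normal, alpha = alpha)
  }
  features <- markers$features
  if (!length(features)) stopf("no marker region selected at FDR <= %g", alpha)
  impute <- tumor$impute[features]
  split <- stratified_split(tumor$labels, validation_frac, seed = seed)
  x_all <- align_to_markers(tumor, features, impute)
  bal <- oversample(x_all[split$train, , drop = FALSE],
                    tumor$labels[split$train], k_neighbors, seed = seed)
  fit <- train_learner(bal$x, bal$y, learner, search_budget = search_budget,
                       cv_folds = cv_folds, seed = seed)
  fit <- calibrate(fit, x_all[split$validation, , drop = FALSE],
                   tumor$labels[split$validation], method = calibration)
  vpred <- predict_topk(fit, x_all[split$validation, , drop = FALSE],
                        k = length(fit$classes))
  vrep <- evaluate_predictions(tumor$labels[split$validation], vpred)
  structure(list(
    metric = tumor$metric, learner = learner, classes = fit$classes,
    markers = markers, features = features, impute = impute, fit = fit,
    split = split, seed = seed,
    params = list(alpha = alpha, validation_frac = validation_frac,
                  k_neighbors = k_neighbors, search_budget = search_budget,
                  cv_folds = cv_folds, calibration = calibration),
    validation = vrep
  ), class = "too_model")
}

#' @export
print.too_model <- function(x, ...) {
  cat(sprintf("<too_model> metric=%s, learner=%s\n", x$metric, x$learner))
  cat(sprintf("  %d classes, %d marker regions (FDR <= %g)\n",
              length(x$classes), length(x$features), x$params$alpha))
  cat(sprintf("  search: %d settings, %d-fold CV accuracy %.3f; calibration: %s\n",
              x$params$search_budget, x$params$cv_folds, x$fit$cv_accuracy,
              x$params$calibration))
  cat(sprintf("  held-out validation (n=%d): top-1 %.3f, top-3 %.3f\n",
              length(x$split$validation), x$validation$topk[1],
              x$validation$topk[min(3, length(x$validation$topk))]))
  invisible(x)
}

#' @export
summary.too_model <- function(object, ...) {
  print(object)
  cat("\nChosen hyperparameters:\n")
  utils::str(object$fit$params, give.attr = FALSE)
  cat("\nMarkers per cancer type:\n")
  print(table(object$markers$table$cancer_type))
  cat("\nValidation per-class metrics:\n")
  pc <- object$validation$per_class
  num <- vapply(pc, is.numeric, logical(1))
  pc[num] <- lapply(pc[num], round, 3)
  print(pc)
  invisible(object)
}

#' @export
coef.too_model <- function(object, ...) {
  if (object$learner != "linear_svc") {
    stopf("coefficients are only defined for the linear_svc learner")
  }
  w <- vapply(object$fit$fit$fits, function(f) {
    b <- crossprod(f$m$coefs, f$m$SV)[1, ]
    if (f$flip) -b else b
  }, numeric(length(object$features)))
  rownames(w) <- object$features
  w
}

#' Predict the primary site of new samples
#'
#' @param object a fitted \code{too_model}.
#' @param newdata a \code{too_matrix} (regions x samples) or an already
#'   aligned samples x features matrix.
#' @param k number of ranked classes to report (default 3).
#' @param min_marker_frac minimum fraction of marker regions that must be
#'   present in \code{newdata} (default 0.5); absent markers are filled
#'   with the training-set imputation values.
#' @param ... unused.
#' @return a \code{too_prediction} (see [predict_topk()]).
#' @export
predict.too_model <- function(object, newdata, k = 3, min_marker_frac = 0.5,
                              ...) {
  feats <- if (!inherits(newdata, "too_matrix") && is.matrix(newdata) &&
               all(object$features %in% colnames(newdata))) {
    newdata[, object$features, drop = FALSE]   # already samples x features
  } else {
    align_to_markers(newdata, object$features, object$impute, min_marker_frac)
  }
  predict_topk(object$fit, feats, k = k)
}

#' Evaluate a fitted model on a labelled feature matrix
#'
#' @param model a \code{too_model}.
#' @param newdata a labelled \code{too_matrix}.
#' @param k ranks to include in the report (default: number of classes).
#' @return an \code{too_eval} report (see [evaluate_predictions()]).
#' @export
too_evaluate <- function(model, newdata, k = NULL) {
  stopifnot(inherits(newdata, "too_matrix"))
  if (is.null(k)) k <- length(model$classes)
  pred <- predict.too_model(model, newdata, k = k)
  evaluate_predictions(newdata$labels, pred)
}
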