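#' Compute region metrics for every sample of a cohort
#'
#' @param cohort a \code{too_cohort} (in-memory records), or a named list
#'   of haplotype record data.frames.
#' @param regions a \code{too_regions}; taken from the cohort if absent.
#' @param metrics which metrics to compute (see [region_metrics()]).
#' @return named list of per-sample [region_metrics()] data.frames.
#' @export
cohort_metrics <- function(cohort, regions = NULL,
                           metrics = c("beta", "pdr", "chalm", "mhl")) {
  samples <- if (inherits(cohort, "too_cohort")) cohort$samples else cohort
  if (is.null(regions) && inherits(cohort, "too_cohort")) {
    regions <- cohort$regions
  }
  stopifnot(inherits(regions, "too_regions"))
  lapply(samples, function(rec) {
    region_metrics(assign_to_regions(rec, regions), regions, metrics = metrics)
  })
}

#' Build tumor and normal feature matrices from a cohort
#'
#' Runs region assignment and metric computation for every sample, then
#' assembles one \code{too_matrix} for the tumor samples and one for the
#' normal controls under the depth and missingness policy of
#' [build_matrix()].
#'
#' @param cohort a \code{too_cohort}.
#' @param metric the metric to tabulate.
#' @param min_depth,max_missing_frac see [build_matrix()].
#' @param per_sample optionally precomputed [cohort_metrics()] output.
#' @return list with \code{tumor} and \code{normal} matrices (the latter
#'   \code{NULL} if the cohort has no normals) and \code{per_sample}.
#' @export
cohort_matrices <- function(cohort, metric = "beta", min_depth = 100,
                            max_missing_frac = 0.2, per_sample = NULL) {
  stopifnot(inherits(cohort, "too_cohort"))
  if (is.null(per_sample)) {
    per_sample <- cohort_metrics(cohort, metrics = metric)
  }
  man <- cohort$manifest
  labels <- stats::setNames(man$label, man$sample_id)
  tum <- man$sample_id[man$group == "tumor"]
  nor <- man$sample_id[man$group == "normal"]
  tumor <- build_matrix(per_sample[tum], metric, labels,
                        min_depth = min_depth,
                        max_missing_frac = max_missing_frac)
  normal <- if (length(nor)) {
    build_matrix(per_sample[nor], metric, labels, min_depth = min_depth,
                 max_missing_frac = max_missing_frac)
  }
  list(tumor = tumor, normal = normal, per_sample = per_sample)
}

read_cohort_dir <- function(dir) {
  regions <- read_regions(file.path(dir, "regions.bed"),
                          file.path(dir, "cpgs.bed"))
  lab <- read_labels(file.path(dir, "labels.tsv"))
  qc_path <- file.path(dir, "qc.tsv")
  qc <- if (file.exists(qc_path)) read_qc_sheet(qc_path)
  files <- file.path(dir, "mhap", paste0(lab$sample_id, ".mhap.tsv"))
  gz <- !file.exists(files) & file.exists(paste0(files, ".gz"))
  files[gz] <- paste0(files[gz], ".gz")
  missing <- !file.exists(files)
  if (any(missing)) stopf("no haplotype file for sample(s): %s",
                          paste(lab$sample_id[missing], collapse = ", "))
  samples <- lapply(files, read_mhap)
  names(samples) <- lab$sample_id
  manifest <- data.frame(sample_id = lab$sample_id, label = lab$label,
                         group = lab$group, purity = NA_real_,
                         seed = NA_integer_, stringsAsFactors = FALSE)
  structure(list(profiles = NULL, regions = regions, samples = samples,
                 manifest = manifest, qc = qc, config = NULL, dir = dir),
            class = "too_cohort")
}

#' Train a model (or the full grid) from a cohort directory
#'
#' Runs the complete training pipeline: sample QC, region assignment,
#' metric computation, matrix assembly, marker selection, stratified 4:1
#' split, minority oversampling, budgeted hyperparameter search and
#' probability calibration.
#'
#' @param input a cohort directory (regions.bed, cpgs.bed, labels.tsv,
#'   optional qc.tsv, mhap/<sample>.mhap.tsv) or a \code{too_cohort}.
#' @param output_dir optional directory for the model bundle(s), marker
#'   table and validation report.
#' @param metric,learner grid coordinates (defaults: the beta value metric
#'   with the linear support vector classifier).
#' @param grid if \code{TRUE}, train all 4 metrics x 7 learners.
#' @param alpha,min_depth,search_budget,cv_folds,calibration,seed passed to
#'   the pipeline stages.
#' @param verbose log the thresholds and sizes applied at each stage.
#' @return a \code{too_model}, or a list of 28 models when \code{grid}.
#' @export
run_train <- function(input, output_dir = NULL, metric = "beta",
                      learner = "linear_svc", grid = FALSE, alpha = 0.01,
                      min_depth = 100, search_budget = 50, cv_folds = 5,
                      calibration = "sigmoid", seed = 1, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  cohort <- if (inherits(input, "too_cohort")) input else read_cohort_dir(input)
  if (!is.null(cohort$qc)) {
    qc <- qc_filter(cohort$qc)
    say("stage qc: %d passed, %d failed (conversion >= 0.99, mapping >= 0.50, CpGs10x >= 8e5)",
        length(qc$passed), nrow(qc$failed))
    keep <- cohort$manifest$sample_id %in% qc$passed
    cohort$manifest <- cohort$manifest[keep, , drop = FALSE]
    cohort$samples <- cohort$samples[cohort$manifest$sample_id]
  }
  metrics_needed <- if (grid) c("beta", "pdr", "chalm", "mhl") else metric
  say("stage metrics: %d samples, computing %s",
      length(cohort$samples), paste(metrics_needed, collapse = "/"))
  per_sample <- cohort_metrics(cohort, metrics = metrics_needed)
  fit_one <- function(met, lrn) {
    mats <- cohort_matrices(cohort, metric = met, min_depth = min_depth,
                            per_sample = per_sample)
    if (is.null(mats$normal)) stopf("training requires normal-tissue controls")
    say("stage matrix [%s]: %d regions x %d tumors (depth > %g)",
        met, nrow(mats$tumor$values), ncol(mats$tumor$values), min_depth)
    model <- too_fit(mats$tumor, mats$normal, learner = lrn, alpha = alpha,
                     search_budget = search_budget, cv_folds = cv_folds,
                     calibration = calibration, seed = seed)
    say("stage train [%s+%s]: %d markers (FDR <= %g), validation top-1 %.3f",
        met, lrn, length(model$features), alpha, model$validation$topk[1])
    model
  }
  if (grid) {
    combos <- expand.grid(metric = c("beta", "pdr", "chalm", "mhl"),
                          learner = too_learners(), stringsAsFactors = FALSE)
    models <- Map(fit_one, combos$metric, combos$learner)
    names(models) <- paste(combos$metric, combos$learner, sep = "+")
    if (!is.null(output_dir)) {
      dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
      for (nm in names(models)) {
        save_model(models[[nm]], file.path(output_dir, paste0(nm, ".rds")))
      }
    }
    return(models)
  }
  model <- fit_one(metric, learner)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    save_model(model, file.path(output_dir, "model.rds"))
    write_markers(model$markers, file.path(output_dir, "markers.tsv"))
  }
  model
}

#' Predict cohort samples with a trained model
#'
#' @param model a \code{too_model} or path to a saved bundle.
#' @param input a cohort directory or \code{too_cohort}.
#' @param k ranks to report (default 3).
#' @param min_depth coverage filter for the prediction-time matrix. The
#'   default 0 uses every covered region: the strict >100x rule is a
#'   marker-discovery filter, and at prediction time an observed value is
#'   better evidence than the training-median fallback.
#' @param output_dir optional directory for predictions.tsv (and
#'   evaluation.txt when labels are available).
#' @return list with \code{predictions} (a \code{too_prediction}) and
#'   \code{evaluation} (a \code{too_eval}, or \code{NULL} without truth
#'   labels).
#' @export
run_predict <- function(model, input, k = 3, min_depth = 0,
                        output_dir = NULL) {
  if (is.character(model)) model <- load_model(model)
  cohort <- if (inherits(input, "too_cohort")) input else read_cohort_dir(input)
  per_sample <- cohort_metrics(cohort, metrics = model$metric)
  man <- cohort$manifest
  labels <- stats::setNames(man$label, man$sample_id)
  mat <- build_matrix(per_sample, model$metric, labels,
                      min_depth = min_depth, max_missing_frac = 1)
  pred <- predict.too_model(model, mat, k = k)
  truth_known <- !all(is.na(man$label)) && !all(man$label == "")
  ev <- if (truth_known) {
    evaluate_predictions(labels, predict.too_model(model, mat,
                                                   k = length(model$classes)))
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as.data.frame(pred),
                       file.path(output_dir, "predictions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(ev)) {
      utils::capture.output(print(ev),
                            file = file.path(output_dir, "evaluation.txt"))
    }
  }
  list(predictions = pred, evaluation = ev)
}

#' Save / load a trained model bundle
#'
#' The bundle is an RDS of the fitted object plus a JSON sidecar with the
#' human-readable coordinates (metric, learner, classes, markers, chosen
#' hyperparameters, seed).
#'
#' @param model a \code{too_model}.
#' @param path bundle path (.rds).
#' @return the path (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(metric = model$metric, learner = model$learner,
               classes = model$classes, n_markers = length(model$features),
               markers = model$features, hyperparameters = model$fit$params,
               calibration = model$params$calibration, seed = model$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
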