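#' Assemble a regions-by-samples feature matrix for one metric
#'
#' A cell is defined only where the sample's region coverage exceeds
#' \code{min_depth} (strict \code{>}) and the metric itself is defined.
#' Coverage is measured as the region's haplotype (read) count by default;
#' \code{depth_measure = "mean_depth"} switches to mean per-CpG depth.
#' Regions missing in more than \code{max_missing_frac} of samples are
#' dropped; remaining missing cells are imputed with the region's
#' cross-sample median. Imputation values are label-agnostic and recorded
#' on the object so prediction-time alignment can reuse the training
#' medians instead of peeking at test data.
#'
#' @param per_sample named list (by sample id) of [region_metrics()]
#'   data.frames.
#' @param metric one of \code{"beta"}, \code{"pdr"}, \code{"chalm"},
#'   \code{"mhl"}.
#' @param labels named character vector: cancer type (or \code{"normal"})
#'   per sample id.
#' @param group named character vector per sample id: \code{"tumor"} or
#'   \code{"normal"}; defaults to \code{"normal"} where the label is
#'   "normal", else "tumor".
#' @param min_depth region coverage a sample must exceed for the cell to
#'   count as observed (default 100, i.e. the >100x coverage rule).
#' @param max_missing_frac drop a region missing in more than this fraction
#'   of samples (default 0.2).
#' @param depth_measure \code{"n_reads"} (default) or \code{"mean_depth"}.
#' @return an object of class \code{too_matrix}: list with \code{values}
#'   (regions x samples numeric matrix, fully imputed), \code{metric},
#'   \code{labels}, \code{group}, \code{impute} (named per-region medians),
#'   \code{observed} (logical matrix marking originally defined cells).
#' @export
build_matrix <- function(per_sample, metric = c("beta", "pdr", "chalm", "mhl"),
                         labels, group = NULL, min_depth = 100,
                         max_missing_frac = 0.2,
                         depth_measure = c("n_reads", "mean_depth")) {
  metric <- match.arg(metric)
  depth_measure <- match.arg(depth_measure)
  samples <- names(per_sample)
  if (is.null(samples) || anyDuplicated(samples)) {
    stopf("per_sample must be a named list with unique sample ids")
  }
  missing_lab <- setdiff(samples, names(labels))
  if (length(missing_lab)) stopf("no label for sample(s): %s",
                                 paste(missing_lab, collapse = ", "))
  ids <- per_sample[[1]]$region_id
  vals <- vapply(per_sample, function(m) {
    stopifnot(identical(m$region_id, ids))
    ifelse(m[[depth_measure]] > min_depth, m[[metric]], NA_real_)
  }, numeric(length(ids)))
  vals <- matrix(vals, nrow = length(ids),
                 dimnames = list(ids, samples))
  finalize_matrix(vals, metric, labels[samples], group, max_missing_frac)
}

finalize_matrix <- function(vals, metric, labels, group, max_missing_frac) {
  samples <- colnames(vals)
  if (is.null(group)) {
    group <- ifelse(labels == "normal", "normal", "tumor")
  }
  group <- stats::setNames(as.character(group), samples)
  miss_frac <- rowMeans(is.na(vals))
  keep <- miss_frac <= max_missing_frac
  if (!any(keep)) stopf("no region survives the missingness filter")
  vals <- vals[keep, , drop = FALSE]
  observed <- !is.na(vals)
  med <- apply(vals, 1, stats::median, na.rm = TRUE)
  for (i in which(rowSums(!observed) > 0)) {
    vals[i, !observed[i, ]] <- med[i]
  }
  structure(list(values = vals, metric = metric,
                 labels = stats::setNames(as.character(labels), samples),
                 group = group, impute = med, observed = observed),
            class = "too_matrix")
}

#' @export
print.too_matrix <- function(x, ...) {
  cat(sprintf("<too_matrix> metric=%s: %d regions x %d samples (%d tumor, %d normal)\n",
              x$metric, nrow(x$values), ncol(x$values),
              sum(x$group == "tumor"), sum(x$group == "normal")))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a feature matrix by sample
#' @param x a \code{too_matrix}.
#' @param samples sample ids to keep.
#' @return a \code{too_matrix} restricted to those samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "too_matrix"), all(samples %in% colnames(x$values)))
  structure(list(values = x$values[, samples, drop = FALSE], metric = x$metric,
                 labels = x$labels[samples], group = x$group[samples],
                 impute = x$impute,
                 observed = x$observed[, samples, drop = FALSE]),
            class = "too_matrix")
}

#' Ingest an external region-level beta table
#'
#' Reads a TSV whose first column is the region id and whose remaining
#' columns are one sample each, with beta values in \[0, 1\] or \code{NA}
#' (the array-style validation path). The same missingness policy as
#' [build_matrix()] applies.
#'
#' @param path TSV path.
#' @param labels named character vector of per-sample labels.
#' @param group optional named group vector (tumor/normal).
#' @param max_missing_frac see [build_matrix()].
#' @return a \code{too_matrix} with metric \code{"beta"}.
#' @export
ingest_beta_table <- function(path, labels, group = NULL,
                              max_missing_frac = 0.2) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  bad <- which(!is.na(vals) & (vals < 0 | vals > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("beta value out of [0,1] at region %s, sample %s: %g",
          ids[bad[1, 1]], colnames(vals)[bad[1, 2]], vals[bad[1, , drop = FALSE]])
  }
  missing_lab <- setdiff(colnames(vals), names(labels))
  if (length(missing_lab)) stopf("no label for sample(s): %s",
                                 paste(missing_lab, collapse = ", "))
  finalize_matrix(vals, "beta", labels[colnames(vals)], group, max_missing_frac)
}

#' Align a feature matrix to a trained marker list
#'
#' Restricts (and reorders) the matrix rows to the marker regions of a
#' trained model. Markers absent from the matrix are filled with the
#' training-set imputation value — never a statistic of the new data — and
#' the fraction of markers actually observed is reported.
#'
#' @param x a \code{too_matrix} (or plain regions x samples matrix).
#' @param markers character vector of marker region ids.
#' @param impute named numeric vector of training-set imputation values
#'   (one per marker).
#' @param min_observed_frac error if fewer than this fraction of markers is
#'   present in the matrix (default 0.5).
#' @return a samples x markers numeric matrix with attribute
#'   \code{observed_frac}.
#' @export
align_to_markers <- function(x, markers, impute, min_observed_frac = 0.5) {
  vals <- if (inherits(x, "too_matrix")) x$values else as.matrix(x)
  present <- markers %in% rownames(vals)
  frac <- mean(present)
  if (frac < min_observed_frac) {
    stopf(paste0("only %.0f%% of the %d marker regions are present in the ",
                 "input (floor %.0f%%): insufficient marker coverage"),
          100 * frac, length(markers), 100 * min_observed_frac)
  }
  out <- matrix(rep(impute[markers], each = ncol(vals)),
                nrow = ncol(vals), ncol = length(markers),
                dimnames = list(colnames(vals), markers))
  out[, present] <- t(vals[markers[present], , drop = FALSE])
  # cells still undefined (e.g. a region with no coverage in any sample)
  # also fall back to the training imputation values
  if (anyNA(out)) {
    na_idx <- which(is.na(out), arr.ind = TRUE)
    out[na_idx] <- impute[markers[na_idx[, 2]]]
  }
  attr(out, "observed_frac") <- frac
  out
}

#' Write / read a feature matrix as TSV (plus a labels TSV)
#' @param x a \code{too_matrix}.
#' @param path matrix TSV path; labels are written next to it as
#'   \code{<path>.labels.tsv}.
#' @return the path (write) or a \code{too_matrix} (read).
#' @export
write_matrix <- function(x, path) {
  df <- data.frame(region_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample_id = colnames(x$values), label = x$labels,
                    group = x$group, stringsAsFactors = FALSE)
  utils::write.table(lab, paste0(path, ".labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lab <- read_labels(paste0(path, ".labels.tsv"))
  ingest_beta_table(path, stats::setNames(lab$label, lab$sample_id),
                    stats::setNames(lab$group, lab$sample_id))
}
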