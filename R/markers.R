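#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact permutation p-value (via the exact null distribution of the
#' Mann-Whitney statistic) when the smaller group has at most
#' \code{exact_max} observations and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples from the two groups (both non-empty).
#' @param exact_max largest min-group size for which the exact distribution
#'   is used (default 8).
#' @return a two-sided p-value in (0, 1\].
#' @examples
#' ranksum_p(1:3, 4:6)   # 0.1 = 2/20
#' @export
ranksum_p <- function(x, y, exact_max = 8) {
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)]) - n * (n + 1) / 2   # Mann-Whitney U of group 1
  ties <- tabulate(match(r, unique(r)))
  has_ties <- any(ties > 1)
  if (min(n, m) <= exact_max && !has_ties) {
    p <- 2 * min(stats::pwilcox(W, n, m), 1 - stats::pwilcox(W - 1, n, m))
    return(min(1, p))
  }
  mu <- n * m / 2
  N <- n + m
  sigma2 <- n * m / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- W - mu
  z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)   # continuity correction
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate control:
#' \eqn{q_i = \min_{j: p_{(j)} \ge p_{(i)}} p_{(j)} m / j}, clipped to 1 and
#' mapped back to input order.
#'
#' @param pvals vector of p-values in \[0, 1\].
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Select cancer-type-specific marker regions
#'
#' For every cancer type t and region r, two two-sided rank-sum tests are
#' run on the chosen methylation metric: (1) samples of type t against all
#' other tumor types, and (2) samples of type t against the normal-tissue
#' control group. Within each comparison family (one type, one condition)
#' the p-values are converted to Benjamini-Hochberg q-values across
#' regions, and r is selected for t iff both q-values are at most
#' \code{alpha}. Hypo- and hypermethylated markers are both admitted; the
#' direction (sign of the median difference against the other tumors) is
#' recorded but not used as a filter. The classifier feature list is the
#' union of the per-type marker lists.
#'
#' @param tumor a \code{too_matrix} of tumor samples with at least two
#'   cancer types, each with at least two samples.
#' @param normal a \code{too_matrix} of normal-tissue samples sharing the
#'   tumor matrix's region space.
#' @param alpha FDR threshold (default 0.01).
#' @return object of class \code{too_markers}: list with \code{table}
#'   (data.frame cancer_type, region_id, q1, q2, direction),
#'   \code{features} (union of selected region ids), \code{alpha},
#'   \code{test}.
#' @export
select_markers <- function(tumor, normal, alpha = 0.01) {
  stopifnot(inherits(tumor, "too_matrix"), inherits(normal, "too_matrix"))
  shared <- intersect(rownames(tumor$values), rownames(normal$values))
  if (!length(shared)) stopf("tumor and normal matrices share no region")
  tv <- tumor$values[shared, , drop = FALSE]
  nv <- normal$values[shared, , drop = FALSE]
  types <- sort(unique(tumor$labels))
  if (length(types) < 2) stopf("need at least two cancer types")
  small <- names(which(table(tumor$labels) < 2))
  if (length(small)) stopf("cancer type(s) with fewer than 2 samples: %s",
                           paste(small, collapse = ", "))
  res <- vector("list", length(types))
  for (k in seq_along(types)) {
    t <- types[k]
    in_t <- tumor$labels == t
    p1 <- p2 <- dirn <- numeric(length(shared))
    for (i in seq_along(shared)) {
      xt <- tv[i, in_t]
      xo <- tv[i, !in_t]
      p1[i] <- ranksum_p(xt, xo)
      p2[i] <- ranksum_p(xt, nv[i, ])
      dirn[i] <- sign(stats::median(xt) - stats::median(xo))
    }
    q1 <- bh_fdr(p1)
    q2 <- bh_fdr(p2)
    sel <- q1 <= alpha & q2 <= alpha
    res[[k]] <- data.frame(
      cancer_type = rep(t, sum(sel)), region_id = shared[sel],
      q1 = q1[sel], q2 = q2[sel],
      direction = ifelse(dirn[sel] >= 0, "hyper", "hypo"),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, res)
  structure(list(table = tab, features = sort(unique(tab$region_id)),
                 alpha = alpha, test = "two-sided Wilcoxon rank-sum"),
            class = "too_markers")
}

#' @export
print.too_markers <- function(x, ...) {
  cat(sprintf("<too_markers> %d markers across %d cancer types (union: %d regions; FDR <= %g, %s)\n",
              nrow(x$table), length(unique(x$table$cancer_type)),
              length(x$features), x$alpha, x$test))
  print(table(x$table$cancer_type, x$table$direction))
  invisible(x)
}

#' Write / read a marker set
#' @param x a \code{too_markers} object.
#' @param path TSV path; selection parameters go to \code{<path>.json}.
#' @return the path (write) or a \code{too_markers} (read).
#' @export
write_markers <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(alpha = x$alpha, test = x$test),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(table = tab, features = sort(unique(tab$region_id)),
                 alpha = meta$alpha, test = meta$test),
            class = "too_markers")
}
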