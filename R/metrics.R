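#' Region-level methylation statistics from clipped haplotypes
#'
#' Four read-level statistics summarize the methylation state of a region
#' from its haplotype patterns. Let each record carry a 0/1 pattern and a
#' count (a pattern with count c behaves exactly as c identical reads):
#'
#' \itemize{
#'   \item \strong{beta value} — mean methylation: methylated CpG calls over
#'     total CpG calls.
#'   \item \strong{PDR} — proportion of discordant reads: among reads with at
#'     least \code{min_cpgs} CpGs, the weighted fraction whose pattern
#'     contains both 0 and 1.
#'   \item \strong{CHALM} — cell heterogeneity-adjusted clonal methylation:
#'     the weighted fraction of reads carrying at least one methylated CpG.
#'   \item \strong{MHL} — methylated haplotype load: the length-weighted
#'     average, over stretch lengths l = 1..L, of the fraction of CpG
#'     substrings of length l that are fully methylated, with weights
#'     proportional to l.
#' }
#'
#' @param records a data.frame with at least columns \code{pattern} and
#'   \code{count} (clipped haplotypes of a single region).
#' @return a fraction in \[0, 1\], or \code{NA} when no (eligible) read is
#'   present.
#' @seealso [region_metrics()] for the vectorized all-regions engine.
#' @examples
#' r <- hap_records("chr1", c(100, 100), c(140, 140), c("110", "100"), c(3, 1))
#' beta_value(r)  # 7/12
#' chalm(r)       # 1
#' @name metrics
NULL

pattern_counts <- function(records) {
  if (is.null(records) || nrow(records) == 0) return(NULL)
  stopifnot(all(c("pattern", "count") %in% names(records)))
  list(pattern = records$pattern, count = as.numeric(records$count))
}

#' @rdname metrics
#' @export
beta_value <- function(records) {
  pc <- pattern_counts(records)
  if (is.null(pc)) return(NA_real_)
  n1 <- nchar(pc$pattern) - nchar(gsub("1", "", pc$pattern, fixed = TRUE))
  sum(pc$count * n1) / sum(pc$count * nchar(pc$pattern))
}

#' @rdname metrics
#' @param min_cpgs minimum pattern length for a read to enter the PDR
#'   denominator (default 4, the convention of read-discordance scoring).
#' @export
pdr <- function(records, min_cpgs = 4) {
  pc <- pattern_counts(records)
  if (is.null(pc)) return(NA_real_)
  keep <- nchar(pc$pattern) >= min_cpgs
  if (!any(keep)) return(NA_real_)
  disc <- grepl("0", pc$pattern[keep], fixed = TRUE) &
    grepl("1", pc$pattern[keep], fixed = TRUE)
  sum(pc$count[keep] * disc) / sum(pc$count[keep])
}

#' @rdname metrics
#' @export
chalm <- function(records) {
  pc <- pattern_counts(records)
  if (is.null(pc)) return(NA_real_)
  has1 <- grepl("1", pc$pattern, fixed = TRUE)
  sum(pc$count * has1) / sum(pc$count)
}

#' @rdname metrics
#' @param max_l cap on the longest methylated stretch length entering the
#'   MHL average; \code{L = min(longest pattern, max_l)}. Weights are
#'   renormalized over the lengths actually realized (those with at least
#'   one substring), so MHL stays in \[0, 1\].
#' @param terms if \code{TRUE}, also return the per-length counts.
#' @export
mhl <- function(records, max_l = 10, terms = FALSE) {
  pc <- pattern_counts(records)
  if (is.null(pc)) return(NA_real_)
  len <- nchar(pc$pattern)
  L <- min(max(len), max_l)
  S <- F1 <- numeric(L)
  runs <- strsplit(pc$pattern, "0+")
  runlen <- lapply(runs, function(r) nchar(r)[nchar(r) > 0])
  for (l in seq_len(L)) {
    S[l] <- sum(pc$count * pmax(len - l + 1, 0))
    F1[l] <- sum(pc$count * vapply(runlen, function(r) sum(pmax(r - l + 1, 0)), numeric(1)))
  }
  realized <- S > 0
  w <- ifelse(realized, seq_len(L), 0)
  w <- w / sum(w)
  value <- sum(w[realized] * F1[realized] / S[realized])
  if (!terms) return(value)
  list(value = value, L = L, F = F1, S = S, w = w)
}

#' @rdname metrics
#' @param n_cpgs number of CpG sites in the region.
#' @details \code{mean_depth} is the total number of CpG calls divided by
#'   the number of the region's CpG sites covered by at least one read;
#'   records must carry a \code{cpg_offset} column (see
#'   [assign_to_regions()]). Zero when no records are present.
#' @export
mean_depth <- function(records, n_cpgs) {
  if (is.null(records) || nrow(records) == 0) return(0)
  stopifnot("cpg_offset" %in% names(records))
  len <- nchar(records$pattern)
  covered <- logical(n_cpgs)
  for (i in seq_len(nrow(records))) {
    covered[records$cpg_offset[i]:(records$cpg_offset[i] + len[i] - 1L)] <- TRUE
  }
  sum(as.numeric(records$count) * len) / sum(covered)
}

#' Compute all region-level metrics for one sample
#'
#' Vectorized engine producing, for every region of a region set, the four
#' methylation statistics plus mean per-CpG depth and total read count.
#' Regions without any clipped read get \code{NA} metrics, depth 0 and
#' \code{n_reads} 0.
#'
#' @param assigned clipped records as returned by [assign_to_regions()].
#' @param regions the \code{too_regions} object the records were assigned to.
#' @param metrics which metrics to compute (any of beta, pdr, chalm, mhl);
#'   skipping unneeded metrics saves time on large cohorts.
#' @param pdr_min_cpgs,mhl_max_l see [pdr()] and [mhl()].
#' @return data.frame with one row per region: \code{region_id},
#'   \code{beta}, \code{pdr}, \code{chalm}, \code{mhl}, \code{mean_depth},
#'   \code{n_reads} (unrequested metrics are \code{NA}).
#' @export
region_metrics <- function(assigned, regions,
                           metrics = c("beta", "pdr", "chalm", "mhl"),
                           pdr_min_cpgs = 4, mhl_max_l = 10) {
  stopifnot(inherits(regions, "too_regions"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  ids <- regions$regions$region_id
  out <- data.frame(region_id = ids, beta = NA_real_, pdr = NA_real_,
                    chalm = NA_real_, mhl = NA_real_, mean_depth = 0,
                    n_reads = 0L, stringsAsFactors = FALSE)
  if (!nrow(assigned)) return(out)
  f <- factor(assigned$region_id, levels = ids)
  cnt <- as.numeric(assigned$count)
  len <- nchar(assigned$pattern)

  rs <- function(x) {
    m <- rowsum(x, f)
    res <- rep(0, length(ids))
    res[match(rownames(m), ids)] <- m[, 1]
    res
  }
  out$n_reads <- as.integer(rs(cnt))
  calls <- rs(cnt * len)

  if ("beta" %in% metrics) {
    n1 <- len - nchar(gsub("1", "", assigned$pattern, fixed = TRUE))
    out$beta <- ifelse(calls > 0, rs(cnt * n1) / calls, NA_real_)
  }
  has0 <- grepl("0", assigned$pattern, fixed = TRUE)
  has1 <- grepl("1", assigned$pattern, fixed = TRUE)
  if ("chalm" %in% metrics) {
    out$chalm <- ifelse(out$n_reads > 0, rs(cnt * has1) / rs(cnt), NA_real_)
  }
  if ("pdr" %in% metrics) {
    elig <- len >= pdr_min_cpgs
    denom <- rs(cnt * elig)
    out$pdr <- ifelse(denom > 0, rs(cnt * (elig & has0 & has1)) / denom, NA_real_)
  }
  if ("mhl" %in% metrics) {
    out$mhl <- mhl_by_region(assigned$pattern, cnt, len, f, ids, mhl_max_l)
  }

  # depth: union of covered CpG index windows per region, via bitmasks when
  # regions are narrow enough, else an interval sweep
  ncpg <- region_cpg_counts(regions)[ids]
  off <- assigned$cpg_offset
  covered <- integer(length(ids))
  if (max(ncpg, na.rm = TRUE) <= 30) {
    mask <- bitwShiftL(bitwShiftL(1L, len) - 1L, off - 1L)
    or_by <- tapply(mask, f, function(m) Reduce(bitwOr, m, 0L))
    or_by[is.na(or_by)] <- 0L
    covered <- vapply(as.integer(or_by), popcount32, integer(1))
  } else {
    for (j in which(table(f) > 0)) {
      sel <- which(as.integer(f) == j)
      cov <- logical(ncpg[j])
      for (i in sel) cov[off[i]:(off[i] + len[i] - 1L)] <- TRUE
      covered[j] <- sum(cov)
    }
  }
  out$mean_depth <- ifelse(covered > 0, calls / pmax(covered, 1L), 0)
  out
}

popcount32 <- function(x) {
  n <- 0L
  while (x != 0L) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

region_cpg_counts <- function(regions) {
  reg <- regions$regions
  n <- integer(nrow(reg))
  for (chr in unique(reg$chrom)) {
    pos <- regions$cpg[[chr]]
    sel <- reg$chrom == chr
    if (is.null(pos)) next
    n[sel] <- findInterval(reg$end[sel], pos) - findInterval(reg$start[sel], pos)
  }
  stats::setNames(n, reg$region_id)
}

# Weighted fully-methylated substring counts for all regions at once.
mhl_by_region <- function(pattern, cnt, len, f, ids, max_l) {
  L <- min(max(len), max_l)
  runs <- strsplit(pattern, "0+")
  rl <- lapply(runs, nchar)
  nrun <- lengths(rl)
  runlen <- unlist(rl, use.names = FALSE)
  keep <- runlen > 0
  run_f <- rep(f, nrun)[keep]
  run_cnt <- rep(cnt, nrun)[keep]
  runlen <- runlen[keep]
  rs <- function(x, fac) {
    m <- rowsum(x, fac)
    res <- rep(0, length(ids))
    res[match(rownames(m), ids)] <- m[, 1]
    res
  }
  num <- matrix(0, length(ids), L)
  den <- matrix(0, length(ids), L)
  for (l in seq_len(L)) {
    den[, l] <- rs(cnt * pmax(len - l + 1, 0), f)
    num[, l] <- rs(run_cnt * pmax(runlen - l + 1, 0), run_f)
  }
  w <- matrix(rep(seq_len(L), each = length(ids)), length(ids), L)
  w[den == 0] <- 0
  wsum <- rowSums(w)
  frac <- ifelse(den > 0, num / den, 0)
  val <- rowSums(w * frac) / ifelse(wsum > 0, wsum, 1)
  val[wsum == 0] <- NA_real_
  val
}

#' Write / read a per-sample region-metrics table
#' @param x data.frame from [region_metrics()].
#' @param path TSV path; missing values are encoded "NA".
#' @return the path (write) or the data.frame (read).
#' @export
write_region_metrics <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_region_metrics
#' @export
read_region_metrics <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA")
}
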