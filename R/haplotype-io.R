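#' Build a table of methylation haplotype records
#'
#' A haplotype record is the methylation pattern carried by one sequenced
#' DNA molecule (epiallele): a string over \code{0}/\code{1}, one character
#' per consecutive covered CpG site (\code{1} = methylated), anchored by the
#' genomic positions of its first and last CpG (1-based, inclusive), with a
#' positive integer multiplicity.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer positions of the first and last CpG of each
#'   pattern (1-based, inclusive).
#' @param pattern character vector of 0/1 methylation patterns.
#' @param count positive integer multiplicities (default 1).
#' @param strand strand of each record: \code{"+"}, \code{"-"} or \code{"."}.
#' @return a \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{pattern}, \code{count}, \code{strand}.
#' @examples
#' hap_records("chr1", 100, 140, "110", count = 3)
#' @export
hap_records <- function(chrom, start, end, pattern, count = 1L, strand = ".") {
  n <- length(pattern)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    pattern = as.character(pattern),
    count = as.integer(rep_len(count, n)),
    strand = as.character(rep_len(strand, n)),
    stringsAsFactors = FALSE
  )
  validate_hap_records(df)
  df
}

validate_hap_records <- function(df, lines = NULL) {
  where <- function(i) {
    if (is.null(lines)) sprintf("record %d", i) else sprintf("line %d", lines[i])
  }
  bad <- which(!grepl("^[01]+$", df$pattern))
  if (length(bad)) {
    stopf("malformed pattern '%s' at %s (only characters 0/1 allowed)",
          df$pattern[bad[1]], where(bad[1]))
  }
  bad <- which(is.na(df$count) | df$count < 1)
  if (length(bad)) stopf("non-positive count at %s", where(bad[1]))
  bad <- which(is.na(df$start) | is.na(df$end) | df$start > df$end)
  if (length(bad)) stopf("start > end (or missing coordinate) at %s", where(bad[1]))
  bad <- which(nchar(df$pattern) == 1L & df$start != df$end)
  if (length(bad)) {
    stopf("single-CpG pattern with start != end at %s", where(bad[1]))
  }
  bad <- which(!df$strand %in% c("+", "-", "."))
  if (length(bad)) stopf("invalid strand '%s' at %s", df$strand[bad[1]], where(bad[1]))
  invisible(df)
}

# Sum counts of byte-identical records, keeping first-occurrence order.
aggregate_hap_records <- function(df) {
  key <- paste(df$chrom, df$start, df$end, df$pattern, df$strand, sep = "\r")
  if (!anyDuplicated(key)) return(df)
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$count <- as.integer(rowsum(df$count, factor(key, levels = key[first]))[, 1])
  rownames(out) <- NULL
  out
}

#' Read an mHap-style haplotype file
#'
#' Parses a tab-separated file with one haplotype record per line
#' (chrom, first-CpG position, last-CpG position, 0/1 pattern, count,
#' strand). Lines starting with \code{#} are comments. Files ending in
#' \code{.gz} are decompressed transparently. Byte-identical duplicate
#' records have their counts summed on load.
#'
#' @param path path to the file (optionally gzip-compressed).
#' @return a haplotype record \code{data.frame} (see [hap_records()]).
#' @export
read_mhap <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  raw <- readLines(con)
  keep <- !startsWith(raw, "#") & nzchar(raw)
  lines <- which(keep)
  raw <- raw[keep]
  if (!length(raw)) {
    return(hap_records(character(), integer(), integer(), character()))
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    stopf("expected 6 tab-separated fields at line %d of %s",
          lines[which(nf < 6)[1]], path)
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  count <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | is.na(count))
  if (length(bad)) stopf("non-numeric coordinate or count at line %d of %s",
                         lines[bad[1]], path)
  df <- data.frame(chrom = m[, 1], start = start, end = end, pattern = m[, 4],
                   count = count, strand = m[, 6], stringsAsFactors = FALSE)
  validate_hap_records(df, lines = lines)
  aggregate_hap_records(df)
}

#' Write haplotype records to an mHap-style file
#'
#' @param records a haplotype record \code{data.frame}.
#' @param path output path; \code{.gz} suffix triggers gzip compression.
#' @return the path, invisibly.
#' @export
write_mhap <- function(records, path) {
  validate_hap_records(records)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(records)) {
    writeLines(paste(records$chrom, records$start, records$end,
                     records$pattern, records$count, records$strand,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read CpG-island regions and the CpG site index
#'
#' Regions are read from a BED3+ file (0-based half-open intervals; a 4th
#' column supplies region ids, otherwise ids \code{region_<n>} are
#' generated). The CpG index is a BED3 file with one row per CpG; the
#' 1-based position of the C is BED start + 1. The CpG index is required:
#' without it the genomic position of each character inside a haplotype
#' pattern is unknowable, so records cannot be clipped to regions.
#'
#' @param region_path BED file of regions.
#' @param cpg_path BED file of single CpG sites.
#' @return an object of class \code{too_regions}: a list with \code{regions}
#'   (data.frame chrom/start/end/region_id, 0-based half-open) and
#'   \code{cpg} (named list of sorted 1-based CpG positions per chromosome).
#' @export
read_regions <- function(region_path, cpg_path) {
  reg <- read_bed(region_path, min_cols = 3)
  ids <- if (ncol(reg) >= 4) as.character(reg[[4]]) else sprintf("region_%d", seq_len(nrow(reg)))
  if (anyDuplicated(ids)) stopf("duplicate region ids in %s", region_path)
  bad <- which(reg[[2]] >= reg[[3]])
  if (length(bad)) {
    stopf("empty or inverted region interval at row %d of %s", bad[1], region_path)
  }
  cpg <- read_bed(cpg_path, min_cols = 3)
  regionset(
    data.frame(chrom = as.character(reg[[1]]), start = reg[[2]], end = reg[[3]],
               region_id = ids, stringsAsFactors = FALSE),
    split(cpg[[2]] + 1L, as.character(cpg[[1]]))
  )
}

read_bed <- function(path, min_cols = 3) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < min_cols) stopf("%s: expected at least %d columns", path, min_cols)
  if (!is.numeric(df[[2]]) || !is.numeric(df[[3]])) {
    stopf("%s: non-numeric coordinates", path)
  }
  df[[2]] <- as.integer(df[[2]])
  df[[3]] <- as.integer(df[[3]])
  df
}

#' @rdname read_regions
#' @param regions data.frame with columns chrom, start, end, region_id
#'   (0-based half-open intervals).
#' @param cpg named list (by chromosome) of sorted 1-based CpG positions.
#' @export
regionset <- function(regions, cpg) {
  stopifnot(all(c("chrom", "start", "end", "region_id") %in% names(regions)))
  cpg <- lapply(cpg, function(p) as.integer(sort(unique(p))))
  structure(list(regions = regions, cpg = cpg), class = "too_regions")
}

#' @export
print.too_regions <- function(x, ...) {
  cat(sprintf("<too_regions> %d regions on %d chromosome(s), %d indexed CpGs\n",
              nrow(x$regions), length(unique(x$regions$chrom)),
              sum(lengths(x$cpg))))
  invisible(x)
}

#' Assign and clip haplotype records to regions
#'
#' Each record's pattern is mapped onto the CpG index (the number of index
#' CpGs spanned by \code{[start, end]} must equal the pattern length) and
#' restricted to the CpGs falling inside each overlapping region. Clipped
#' patterns of length zero are discarded; counts are preserved; a record
#' overlapping several regions contributes to each.
#'
#' @param records a haplotype record \code{data.frame}.
#' @param regions a \code{too_regions} object.
#' @return a \code{data.frame} of clipped records with columns
#'   \code{region_id}, \code{chrom}, \code{start}, \code{end},
#'   \code{pattern}, \code{count}, \code{strand} and \code{cpg_offset}
#'   (1-based index of the clipped pattern's first CpG within the region's
#'   own CpG list, needed for per-CpG depth). Split by \code{region_id} to
#'   obtain the per-region mapping.
#' @export
assign_to_regions <- function(records, regions) {
  stopifnot(inherits(regions, "too_regions"))
  out <- vector("list", length(regions$cpg))
  names(out) <- names(regions$cpg)
  for (chr in unique(records$chrom)) {
    pos <- regions$cpg[[chr]]
    rec <- records[records$chrom == chr, , drop = FALSE]
    if (is.null(pos)) {
      stopf("record on chromosome '%s' but no CpGs indexed there (e.g. %s:%d)",
            chr, chr, rec$start[1])
    }
    i1 <- findInterval(rec$start - 1L, pos) + 1L    # first index CpG >= start
    i2 <- findInterval(rec$end, pos)                # last index CpG <= end
    plen <- nchar(rec$pattern)
    bad <- which(i2 - i1 + 1L != plen)
    if (length(bad)) {
      b <- bad[1]
      stopf(paste0("record %s:%d-%d pattern '%s' is inconsistent with the CpG ",
                   "index: %d CpGs indexed in its span but pattern length %d"),
            chr, rec$start[b], rec$end[b], rec$pattern[b],
            max(i2[b] - i1[b] + 1L, 0L), plen[b])
    }
    reg <- regions$regions[regions$regions$chrom == chr, , drop = FALSE]
    if (!nrow(reg) || !nrow(rec)) next
    # region CpG index window [a, b] (1-based positions are BED start+1..end)
    a <- findInterval(reg$start, pos) + 1L
    b <- findInterval(reg$end, pos)
    ord <- order(i1)
    i1s <- i1[ord]
    maxlen <- max(plen)
    chunks <- vector("list", nrow(reg))
    for (j in seq_len(nrow(reg))) {
      if (a[j] > b[j]) next   # region holds no indexed CpG
      lo_cand <- findInterval(a[j] - maxlen, i1s) + 1L
      hi_cand <- findInterval(b[j], i1s)
      if (lo_cand > hi_cand) next
      cand <- ord[lo_cand:hi_cand]
      cand <- cand[i2[cand] >= a[j]]
      if (!length(cand)) next
      lo <- pmax(i1[cand], a[j])
      hi <- pmin(i2[cand], b[j])
      chunks[[j]] <- data.frame(
        region_id = reg$region_id[j],
        chrom = chr,
        start = pos[lo],
        end = pos[hi],
        pattern = substr(rec$pattern[cand], lo - i1[cand] + 1L, hi - i1[cand] + 1L),
        count = rec$count[cand],
        strand = rec$strand[cand],
        cpg_offset = lo - a[j] + 1L,
        stringsAsFactors = FALSE
      )
    }
    out[[chr]] <- do.call(rbind, chunks)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(), pattern = character(),
                      count = integer(), strand = character(),
                      cpg_offset = integer(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Sample-level quality-control filter
#'
#' A library passes QC iff its bisulfite conversion rate is at least 0.99,
#' its mapping ratio at least 0.50, and it covers at least 0.8 million CpGs
#' at 10x depth; the filters are strict "less than" on the failing side, so
#' samples sitting exactly on a threshold pass.
#'
#' @param qc data.frame with columns \code{sample_id},
#'   \code{conversion_rate}, \code{mapping_ratio}, \code{n_cpgs_10x}.
#' @return list with \code{passed} (character vector of sample ids) and
#'   \code{failed} (data.frame of sample_id and comma-separated reasons).
#' @export
qc_filter <- function(qc) {
  need <- c("sample_id", "conversion_rate", "mapping_ratio", "n_cpgs_10x")
  if (!all(need %in% names(qc))) {
    stopf("QC sheet must have columns: %s", paste(need, collapse = ", "))
  }
  reasons <- vapply(seq_len(nrow(qc)), function(i) {
    r <- character()
    if (qc$conversion_rate[i] < 0.99) r <- c(r, "low_bisulfite_conversion")
    if (qc$mapping_ratio[i] < 0.50) r <- c(r, "low_mapping_ratio")
    if (qc$n_cpgs_10x[i] < 8e5) r <- c(r, "insufficient_cpgs_10x")
    paste(r, collapse = ",")
  }, character(1))
  ok <- !nzchar(reasons)
  list(passed = qc$sample_id[ok],
       failed = data.frame(sample_id = qc$sample_id[!ok],
                           reasons = reasons[!ok], stringsAsFactors = FALSE))
}

#' Read a QC sheet (TSV with header sample_id, conversion_rate,
#' mapping_ratio, n_cpgs_10x)
#' @param path path to the TSV file.
#' @return a data.frame.
#' @export
read_qc_sheet <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a sample sheet (TSV with header sample_id, label, group)
#' @param path path to the TSV file.
#' @return a data.frame.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label", "group") %in% names(df))) {
    stopf("label sheet must have columns sample_id, label, group")
  }
  df
}
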