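#' Configuration for the synthetic methylome simulator
#'
#' The simulator emulates the features of a reduced-representation
#' bisulfite cohort that the pipeline actually consumes: tissue-specific
#' CpG-island methylation architecture with planted marker islands, tumor
#' purity mixing against a shared normal background, Poisson read depth,
#' within-read epiallele discordance, and the short haplotype patterns
#' characteristic of formalin-fixed (FFPE) libraries.
#'
#' @param n_tissues number of tumor tissue types (default 10).
#' @param n_regions number of CpG-island regions (default 300).
#' @param cpgs_per_region CpGs per region (default 10, spaced
#'   \code{cpg_spacing} bp apart).
#' @param cpg_spacing distance between consecutive CpGs, bp (default 20).
#' @param markers_per_tissue planted marker regions per tissue, disjoint
#'   across tissues (default 25).
#' @param m0 background methylation level of unmarked islands (default 0.15,
#'   CpG islands are largely unmethylated).
#' @param m1 methylation level of a hypermethylated marker in its tissue
#'   (default 0.85); a hypomethylated marker drops to \code{1 - m1} against
#'   an \code{m1} regional baseline carried by all other tissues and the
#'   normal profile.
#' @param kappa Beta concentration of between-profile and between-sample
#'   biological variability (default 50; larger = tighter).
#' @param epsilon per-CpG epiallele discordance: each CpG flips from its
#'   read's epiallele state with this probability (default 0.05).
#' @param purity tumor cell content of simulated tumor samples in \[0, 1\]
#'   (default 1); each read is drawn from the tumor profile with this
#'   probability, else from the normal profile.
#' @param lambda_reads mean Poisson reads per region (default 150).
#' @param mode \code{"FF"} (fresh-frozen, patterns of 4-10 CpGs) or
#'   \code{"FFPE"} (fragmented DNA, 2-6 CpGs).
#' @param pattern_len_ff,pattern_len_ffpe inclusive pattern-length ranges
#'   for the two modes.
#' @param n_samples tumor samples per tissue (default 40).
#' @param n_normal normal-tissue samples (default 20).
#' @return object of class \code{too_config}.
#' @export
synth_config <- function(n_tissues = 10, n_regions = 300,
                         cpgs_per_region = 10, cpg_spacing = 20,
                         markers_per_tissue = 25, m0 = 0.15, m1 = 0.85,
                         kappa = 50, epsilon = 0.05, purity = 1,
                         lambda_reads = 150, mode = c("FF", "FFPE"),
                         pattern_len_ff = c(4, 10),
                         pattern_len_ffpe = c(2, 6),
                         n_samples = 40, n_normal = 20) {
  mode <- match.arg(mode)
  cfg <- list(n_tissues = n_tissues, n_regions = n_regions,
              cpgs_per_region = cpgs_per_region, cpg_spacing = cpg_spacing,
              markers_per_tissue = markers_per_tissue, m0 = m0, m1 = m1,
              kappa = kappa, epsilon = epsilon, purity = purity,
              lambda_reads = lambda_reads, mode = mode,
              pattern_len_ff = pattern_len_ff,
              pattern_len_ffpe = pattern_len_ffpe,
              n_samples = n_samples, n_normal = n_normal)
  if (markers_per_tissue * n_tissues > n_regions) {
    stopf("marker demand (%d x %d) exceeds the %d available regions",
          markers_per_tissue, n_tissues, n_regions)
  }
  probs <- c(m0 = m0, m1 = m1, epsilon = epsilon, purity = purity)
  if (any(probs < 0 | probs > 1)) stopf("m0, m1, epsilon, purity must lie in [0, 1]")
  if (lambda_reads <= 0) stopf("lambda_reads must be positive")
  if (cpgs_per_region > 12) stopf("cpgs_per_region is capped at 12")
  structure(cfg, class = "too_config")
}

#' @export
print.too_config <- function(x, ...) {
  cat(sprintf(paste0("<too_config> %d tissues x %d samples + %d normals; ",
                     "%d regions (%d CpGs each), %d markers/tissue\n",
                     "  m0=%.2f m1=%.2f kappa=%g epsilon=%.2f purity=%.2f ",
                     "lambda=%g mode=%s\n"),
              x$n_tissues, x$n_samples, x$n_normal, x$n_regions,
              x$cpgs_per_region, x$markers_per_tissue, x$m0, x$m1, x$kappa,
              x$epsilon, x$purity, x$lambda_reads, x$mode))
  invisible(x)
}

# 1-based genomic position of CpG j (1..cpgs) of region r on chr1.
synth_cpg_pos <- function(cfg, r, j) {
  as.integer(101 + (r - 1) * 1000 + (j - 1) * cfg$cpg_spacing)
}

synth_regionset <- function(cfg) {
  r <- seq_len(cfg$n_regions)
  first <- synth_cpg_pos(cfg, r, 1)
  last <- synth_cpg_pos(cfg, r, cfg$cpgs_per_region)
  regionset(
    data.frame(chrom = "chr1", start = first - 51L, end = last + 50L,
               region_id = sprintf("CGI_%04d", r), stringsAsFactors = FALSE),
    list(chr1 = as.integer(outer(seq_len(cfg$cpgs_per_region) - 1L,
                                 r, function(j, rr) synth_cpg_pos(cfg, rr, j + 1L))))
  )
}

#' Generate tissue-specific methylation profiles
#'
#' Plants \code{markers_per_tissue} disjoint marker regions per tissue,
#' each hyper- or hypomethylated with equal probability. Every region gets
#' one shared baseline level — a Beta draw of concentration \code{kappa}
#' around \code{m0} (around \code{m1} for hypo-marker regions) — carried by
#' all tissues and by the normal profile; only a tissue's own marker
#' regions get a tissue-specific draw around the marker level. Regions are
#' therefore tissue-discriminative exactly where markers are planted.
#' Deterministic given the seed.
#'
#' @param cfg a \code{too_config}.
#' @param seed integer seed.
#' @return list with \code{tissues} (tissues x regions level matrix),
#'   \code{normal} (region level vector), \code{markers} (data.frame
#'   tissue/region_id/direction), \code{regions} (a \code{too_regions}),
#'   \code{config}.
#' @export
make_profiles <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "too_config"))
  regions <- synth_regionset(cfg)
  ids <- regions$regions$region_id
  tissues <- sprintf("tissue_%02d", seq_len(cfg$n_tissues))
  with_seed(derive_seed(seed, "profiles"), {
    perm <- sample(cfg$n_regions)
    marker_idx <- matrix(perm[seq_len(cfg$markers_per_tissue * cfg$n_tissues)],
                         nrow = cfg$n_tissues, byrow = TRUE)
    direction <- matrix(sample(c("hyper", "hypo"),
                               length(marker_idx), replace = TRUE),
                        nrow = cfg$n_tissues)
    base_target <- rep(cfg$m0, cfg$n_regions)
    base_target[marker_idx[direction == "hypo"]] <- cfg$m1
    draw <- function(m) stats::rbeta(length(m), cfg$kappa * m,
                                     cfg$kappa * (1 - m))
    baseline <- draw(base_target)   # one draw per region, shared
    prof <- matrix(rep(baseline, each = cfg$n_tissues),
                   nrow = cfg$n_tissues, dimnames = list(tissues, ids))
    for (t in seq_len(cfg$n_tissues)) {
      m_marker <- ifelse(direction[t, ] == "hyper", cfg$m1, 1 - cfg$m1)
      prof[t, marker_idx[t, ]] <- draw(m_marker)
    }
    normal <- stats::setNames(baseline, ids)
    markers <- data.frame(
      tissue = rep(tissues, each = cfg$markers_per_tissue),
      region_id = ids[as.vector(t(marker_idx))],
      direction = as.vector(t(direction)), stringsAsFactors = FALSE
    )
    list(tissues = prof, normal = normal, markers = markers,
         regions = regions, config = cfg)
  })
}

# Lookup table: integer pattern value -> 0/1 string, per length.
pattern_lut <- local({
  cache <- list()
  function(L) {
    key <- as.character(L)
    if (is.null(cache[[key]])) {
      v <- 0:(2^L - 1)
      bits <- vapply(seq_len(L) - 1L,
                     function(b) bitwAnd(bitwShiftR(v, L - 1L - b), 1L),
                     integer(length(v)))
      bits <- matrix(bits, ncol = L)
      cache[[key]] <<- apply(bits, 1, paste, collapse = "")
    }
    cache[[key]]
  }
})

#' Simulate one sample's haplotype records
#'
#' Per region the read count is Poisson(\code{lambda_reads}); each read
#' comes from the tumor profile with probability \code{purity}, else from
#' the normal profile; the read's epiallele state is methylated with
#' probability equal to that profile's sample-level methylation (a Beta
#' draw of concentration \code{kappa} around the profile level); each CpG
#' then flips from the epiallele state with probability \code{epsilon}.
#' Pattern length follows the mode's law and is placed uniformly within
#' the region's CpGs. Deterministic given the seed.
#'
#' @param profiles output of [make_profiles()].
#' @param tissue a tissue name of the profiles, or \code{"normal"} for a
#'   pure normal-tissue sample.
#' @param purity tumor cell content in \[0, 1\] (ignored for normals).
#' @param seed integer seed.
#' @param mode overrides the config's pattern-length mode if given.
#' @return list with \code{records} (haplotype data.frame, duplicate
#'   patterns aggregated) and \code{truth} (tissue, purity, seed).
#' @export
simulate_sample <- function(profiles, tissue, purity = NULL, seed = 1,
                            mode = NULL) {
  cfg <- profiles$config
  if (is.null(mode)) mode <- cfg$mode
  if (is.null(purity)) purity <- cfg$purity
  if (!is.numeric(purity) || purity < 0 || purity > 1) {
    stopf("purity must lie in [0, 1]")
  }
  is_normal <- identical(tissue, "normal")
  if (!is_normal && !tissue %in% rownames(profiles$tissues)) {
    stopf("unknown tissue '%s'", tissue)
  }
  lrange <- if (mode == "FFPE") cfg$pattern_len_ffpe else cfg$pattern_len_ff
  lrange <- pmin(lrange, cfg$cpgs_per_region)
  R <- cfg$n_regions
  C <- cfg$cpgs_per_region
  recs <- with_seed(seed, {
    n_r <- stats::rpois(R, cfg$lambda_reads)
    region <- rep.int(seq_len(R), n_r)
    N <- length(region)
    prof_n <- profiles$normal
    m_n <- stats::rbeta(R, cfg$kappa * prof_n, cfg$kappa * (1 - prof_n))
    if (is_normal || purity == 0) {
      p_meth <- m_n[region]
    } else {
      prof_t <- profiles$tissues[tissue, ]
      m_t <- stats::rbeta(R, cfg$kappa * prof_t, cfg$kappa * (1 - prof_t))
      from_tumor <- stats::runif(N) < purity
      p_meth <- ifelse(from_tumor, m_t[region], m_n[region])
    }
    state <- stats::runif(N) < p_meth
    len <- sample(seq(lrange[1], lrange[2]), N, replace = TRUE)
    off <- floor(stats::runif(N) * (C - len + 1))   # 0-based first CpG
    value <- integer(N)
    for (L in unique(len)) {
      sel <- which(len == L)
      flips <- matrix(stats::runif(length(sel) * L) < cfg$epsilon,
                      ncol = L)
      bits <- xor(matrix(state[sel], length(sel), L), flips)
      value[sel] <- as.integer(bits %*% 2^((L - 1):0))
    }
    key <- ((region * (C + 1) + off) * (C + 1) + len) * 2^C + value
    grp <- match(key, unique(key))
    first <- !duplicated(grp)
    cnt <- as.integer(rowsum(rep(1L, N), grp)[, 1])
    region <- region[first]
    off <- off[first]
    len <- len[first]
    value <- value[first]
    pat <- character(length(value))
    for (L in unique(len)) {
      sel <- len == L
      pat[sel] <- pattern_lut(L)[value[sel] + 1L]
    }
    o <- order(region, off, len, value)
    data.frame(
      chrom = "chr1",
      start = synth_cpg_pos(cfg, region, off + 1L),
      end = synth_cpg_pos(cfg, region, off + len),
      pattern = pat, count = cnt, strand = ".",
      stringsAsFactors = FALSE
    )[o, ]
  })
  rownames(recs) <- NULL
  list(records = recs,
       truth = list(tissue = tissue,
                    purity = if (is_normal) 0 else purity, seed = seed))
}

#' Simulate a labelled cohort
#'
#' Generates \code{n_samples} tumor samples per tissue at the configured
#' purity plus \code{n_normal} normal-tissue samples, together with the
#' region BED, CpG index, labels and a QC sheet. With \code{dir} set, all
#' files are written in the formats the loaders read (mHap-style TSV,
#' BED3/4, TSV sheets); regenerating with the same seed is byte-identical.
#'
#' @param cfg a \code{too_config}.
#' @param seed integer seed.
#' @param dir optional output directory.
#' @param profiles optionally reuse an existing [make_profiles()] result
#'   (e.g. to simulate a test cohort from the same tissue architecture as
#'   the training cohort); region layout fields of \code{cfg} must match.
#' @return object of class \code{too_cohort}: list with \code{profiles},
#'   \code{regions}, \code{samples} (named list of record data.frames),
#'   \code{manifest} (sample_id, label, group, purity, seed),
#'   \code{qc}, \code{config}, and \code{dir}/file paths when written.
#' @export
simulate_cohort <- function(cfg, seed = 1, dir = NULL, profiles = NULL) {
  stopifnot(inherits(cfg, "too_config"))
  if (is.null(profiles)) {
    profiles <- make_profiles(cfg, seed = seed)
  } else {
    pcfg <- profiles$config
    same <- c("n_tissues", "n_regions", "cpgs_per_region", "cpg_spacing")
    if (!identical(pcfg[same], unclass(cfg)[same])) {
      stopf("supplied profiles were built for a different region layout")
    }
  }
  profiles$config <- cfg   # sampling parameters (purity, mode, depth) apply
  tissues <- rownames(profiles$tissues)
  manifest <- rbind(
    data.frame(sample_id = sprintf("%s_s%02d", rep(tissues, each = cfg$n_samples),
                                   rep(seq_len(cfg$n_samples), length(tissues))),
               label = rep(tissues, each = cfg$n_samples), group = "tumor",
               purity = cfg$purity, stringsAsFactors = FALSE),
    if (cfg$n_normal > 0) {
      data.frame(sample_id = sprintf("normal_s%02d", seq_len(cfg$n_normal)),
                 label = "normal", group = "normal", purity = 0,
                 stringsAsFactors = FALSE)
    }
  )
  manifest$seed <- vapply(manifest$sample_id, function(s) derive_seed(seed, s),
                          integer(1))
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    tissue <- if (manifest$group[i] == "normal") "normal" else manifest$label[i]
    simulate_sample(profiles, tissue, manifest$purity[i],
                    seed = manifest$seed[i])$records
  })
  names(samples) <- manifest$sample_id
  qc <- with_seed(derive_seed(seed, "qc"), {
    n <- nrow(manifest)
    data.frame(sample_id = manifest$sample_id,
               conversion_rate = round(stats::runif(n, 0.991, 0.999), 4),
               mapping_ratio = round(stats::runif(n, 0.55, 0.80), 3),
               n_cpgs_10x = round(stats::runif(n, 9e5, 1.4e6)),
               stringsAsFactors = FALSE)
  })
  out <- structure(list(profiles = profiles, regions = profiles$regions,
                        samples = samples, manifest = manifest, qc = qc,
                        config = cfg, dir = dir),
                   class = "too_cohort")
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "mhap"), recursive = TRUE, showWarnings = FALSE)
  reg <- cohort$regions$regions
  utils::write.table(reg, file.path(dir, "regions.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  cpg <- cohort$regions$cpg$chr1
  utils::write.table(data.frame("chr1", cpg - 1L, cpg),
                     file.path(dir, "cpgs.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  for (s in names(cohort$samples)) {
    write_mhap(cohort$samples[[s]],
               file.path(dir, "mhap", paste0(s, ".mhap.tsv")))
  }
  utils::write.table(
    data.frame(sample_id = cohort$manifest$sample_id,
               label = cohort$manifest$label, group = cohort$manifest$group),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$qc, file.path(dir, "qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.too_cohort <- function(x, ...) {
  cat(sprintf("<too_cohort> %d samples (%d tumor, %d normal), %d regions\n",
              nrow(x$manifest), sum(x$manifest$group == "tumor"),
              sum(x$manifest$group == "normal"), x$config$n_regions))
  invisible(x)
}
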