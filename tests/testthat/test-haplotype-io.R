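test_that("mHap parsing handles records, comments, gzip and duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tstart\tend\tpattern\tcount\tstrand",
               "chr1\t100\t140\t110\t3\t+",
               "chr2\t50\t50\t1\t2\t.",
               "chr1\t100\t140\t110\t2\t+"), path)
  rec <- read_mhap(path)
  expect_equal(nrow(rec), 2)                 # duplicates merged
  expect_equal(rec$count, c(5L, 2L))
  expect_equal(rec$pattern[1], "110")
  expect_equal(rec$start[1], 100L)

  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_mhap(rec, gz)
  expect_equal(read_mhap(gz), rec)           # round-trip, field-exact

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# only a header", empty)
  expect_equal(nrow(read_mhap(empty)), 0)
})

test_that("malformed records are rejected with the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t140\t110\t3\t+",
               "chr1\t200\t240\t1102\t1\t+"), path)
  expect_error(read_mhap(path), "line 2")
  writeLines("chr1\t100\t140\t110\t0\t+", path)
  expect_error(read_mhap(path), "count")
  writeLines("chr1\t140\t100\t110\t1\t+", path)
  expect_error(read_mhap(path), "start > end")
  expect_error(hap_records("chr1", 10, 20, "1"), "start != end")
})

test_that("BED regions and CpG index use their native conventions", {
  reg <- withr::local_tempfile(fileext = ".bed")
  cpg <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t200\tCGI_1", "chr1\t300\t500\tCGI_2"), reg)
  writeLines(c("chr1\t109\t110", "chr1\t89\t90", "chr1\t129\t130"), cpg)
  rs <- read_regions(reg, cpg)
  expect_equal(rs$regions$region_id, c("CGI_1", "CGI_2"))
  expect_equal(rs$regions$start[1], 0L)      # 0-based half-open kept
  expect_equal(rs$cpg$chr1, c(90L, 110L, 130L))  # BED start + 1, sorted

  writeLines("chr1\t50\t50\tbad", reg)
  expect_error(read_regions(reg, cpg), "empty or inverted")
})

test_that("records are clipped to region CpGs with counts preserved", {
  rs <- regionset(
    data.frame(chrom = "chr1", start = 100L, end = 200L, region_id = "R1"),
    list(chr1 = c(90L, 110L, 130L))
  )
  rec <- hap_records("chr1", 90, 130, "101", count = 1)
  clipped <- assign_to_regions(rec, rs)
  # region is 1-based 101..200, so CpGs 110 and 130 remain
  expect_equal(clipped$pattern, "01")
  expect_equal(clipped$start, 110L)
  expect_equal(clipped$end, 130L)
  expect_equal(clipped$cpg_offset, 1L)

  inside <- hap_records("chr1", 110, 130, "11", count = 4)
  expect_equal(assign_to_regions(inside, rs)$pattern, "11")
  expect_equal(assign_to_regions(inside, rs)$count, 4L)

  outside <- hap_records("chr1", 90, 90, "1")
  expect_equal(nrow(assign_to_regions(outside, rs)), 0)

  bad <- hap_records("chr1", 90, 130, "1011")  # 4 CpGs claimed, 3 indexed
  expect_error(assign_to_regions(bad, rs), "inconsistent")
})

test_that("region assignment is order-independent and multi-region capable", {
  rs <- regionset(
    data.frame(chrom = "chr1", start = c(0L, 100L), end = c(120L, 200L),
               region_id = c("A", "B")),
    list(chr1 = c(50L, 110L, 150L))
  )
  rec <- hap_records("chr1", c(50, 110, 50), c(150, 150, 50),
                     c("111", "10", "0"), count = c(1, 2, 3))
  a <- assign_to_regions(rec, rs)
  b <- assign_to_regions(rec[c(3, 1, 2), ], rs)
  key <- function(d) {
    d <- d[order(d$region_id, d$start, d$pattern), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(key(a), key(b))
  # the spanning read contributes its restriction to both regions
  expect_setequal(a$region_id[a$count == 1], c("A", "B"))
})

test_that("QC filter applies the strict thresholds with reasons", {
  qc <- data.frame(
    sample_id = c("pass", "conv", "boundary", "multi"),
    conversion_rate = c(0.995, 0.989, 0.99, 0.98),
    mapping_ratio = c(0.60, 0.60, 0.50, 0.40),
    n_cpgs_10x = c(1e6, 1e6, 8e5, 7e5)
  )
  res <- qc_filter(qc)
  expect_setequal(res$passed, c("pass", "boundary"))  # thresholds inclusive
  expect_equal(res$failed$reasons[res$failed$sample_id == "conv"],
               "low_bisulfite_conversion")
  expect_equal(res$failed$reasons[res$failed$sample_id == "multi"],
               "low_bisulfite_conversion,low_mapping_ratio,insufficient_cpgs_10x")
})
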