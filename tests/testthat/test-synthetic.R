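small_cfg <- function(...) {
  args <- list(n_tissues = 3, n_regions = 30, markers_per_tissue = 5,
               n_samples = 4, n_normal = 3, lambda_reads = 60)
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

test_that("profiles plant disjoint, well-separated markers deterministically", {
  cfg <- small_cfg()
  p1 <- make_profiles(cfg, seed = 21)
  p2 <- make_profiles(cfg, seed = 21)
  expect_identical(p1, p2)
  expect_false(identical(make_profiles(cfg, seed = 22)$markers, p1$markers))

  mk <- p1$markers
  expect_equal(nrow(mk), 15)
  expect_equal(anyDuplicated(mk$region_id), 0L)   # disjoint across tissues
  expect_equal(as.vector(table(mk$tissue)), rep(5L, 3))
  # each marker separates its tissue from the shared baseline by >= 0.5
  for (i in seq_len(nrow(mk))) {
    sep <- abs(p1$tissues[mk$tissue[i], mk$region_id[i]] -
                 p1$normal[mk$region_id[i]])
    expect_gte(sep, 0.5)
  }
  # non-marker regions carry the shared baseline in every tissue
  null_regions <- setdiff(colnames(p1$tissues), mk$region_id)
  for (t in rownames(p1$tissues)) {
    expect_equal(p1$tissues[t, null_regions], p1$normal[null_regions])
  }
  expect_error(synth_config(n_tissues = 5, n_regions = 20,
                            markers_per_tissue = 5), "marker demand")
})

test_that("pure noiseless tumors produce saturated marker patterns", {
  cfg <- synth_config(n_tissues = 2, n_regions = 10, markers_per_tissue = 2,
                      m1 = 1, m0 = 0, epsilon = 0, kappa = 50,
                      n_samples = 1, lambda_reads = 80)
  prof <- make_profiles(cfg, seed = 2)
  for (tissue in rownames(prof$tissues)) {
    s <- simulate_sample(prof, tissue, purity = 1, seed = 3)
    met <- region_metrics(assign_to_regions(s$records, prof$regions),
                          prof$regions)
    mk <- prof$markers[prof$markers$tissue == tissue, ]
    for (i in seq_len(nrow(mk))) {
      row <- met[met$region_id == mk$region_id[i], ]
      sat <- as.numeric(mk$direction[i] == "hyper")  # hyper -> all-'1' reads
      expect_equal(row$beta, sat)
      expect_equal(row$chalm, sat)
      expect_equal(row$mhl, sat)
    }
  }
})

test_that("read depth follows the Poisson law and seeds reproduce", {
  cfg <- small_cfg(lambda_reads = 150)
  prof <- make_profiles(cfg, seed = 5)
  s1 <- simulate_sample(prof, "tissue_02", seed = 17)
  s2 <- simulate_sample(prof, "tissue_02", seed = 17)
  expect_identical(s1, s2)
  mean_reads <- sum(s1$records$count) / cfg$n_regions
  sigma <- sqrt(cfg$lambda_reads / cfg$n_regions)
  expect_lt(abs(mean_reads - cfg$lambda_reads), 3 * sigma)
  expect_error(simulate_sample(prof, "tissue_02", purity = 1.4), "purity")
  expect_error(simulate_sample(prof, "nope"), "unknown tissue")
})

test_that("FFPE mode shortens patterns without losing depth", {
  cfg <- small_cfg()
  prof <- make_profiles(cfg, seed = 9)
  ff <- simulate_sample(prof, "tissue_01", seed = 4, mode = "FF")$records
  ffpe <- simulate_sample(prof, "tissue_01", seed = 4, mode = "FFPE")$records
  len_w <- function(r) stats::weighted.mean(nchar(r$pattern), r$count)
  expect_gte(min(nchar(ff$pattern)), 4)
  expect_lte(max(nchar(ffpe$pattern)), 6)
  expect_lt(len_w(ffpe), len_w(ff))
  expect_lt(abs(sum(ffpe$count) - sum(ff$count)) / sum(ff$count), 0.2)
})

test_that("zero purity makes marker regions match the normal background", {
  cfg <- synth_config(n_tissues = 2, n_regions = 12, markers_per_tissue = 3,
                      n_samples = 1, lambda_reads = 100)
  prof <- make_profiles(cfg, seed = 30)
  markers <- prof$markers$region_id
  beta_vec <- function(tissue, seed) {
    s <- simulate_sample(prof, tissue,
                         purity = if (tissue == "normal") NULL else 0,
                         seed = seed)
    m <- region_metrics(assign_to_regions(s$records, prof$regions),
                        prof$regions, metrics = "beta")
    m$beta[match(markers, m$region_id)]
  }
  n_sig <- 0
  n_test <- 0
  for (r in 1:4) {
    # 8 purity-0 tumor samples vs 8 normals, tested per marker region
    x <- vapply(1:8, function(i) beta_vec("tissue_01", 1000 * r + i),
                numeric(length(markers)))
    y <- vapply(1:8, function(i) beta_vec("normal", 5000 * r + i),
                numeric(length(markers)))
    for (j in seq_along(markers)) {
      n_test <- n_test + 1
      if (ranksum_p(x[j, ], y[j, ]) <= 0.01) n_sig <- n_sig + 1
    }
  }
  expect_lte(n_sig / n_test, 0.05)   # indistinguishable from normal tissue
})

test_that("cohorts round-trip through the on-disk formats byte-identically", {
  cfg <- small_cfg()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  co1 <- simulate_cohort(cfg, seed = 77, dir = dir1)
  co2 <- simulate_cohort(cfg, seed = 77, dir = dir2)
  expect_equal(nrow(co1$manifest), 3 * 4 + 3)
  files <- list.files(dir1, recursive = TRUE)
  expect_identical(files, list.files(dir2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
  back <- methorigin:::read_cohort_dir(dir1)
  expect_equal(back$manifest$sample_id, co1$manifest$sample_id)
  for (s in names(co1$samples)) {
    expect_equal(back$samples[[s]], co1$samples[[s]], label = s)
  }
  expect_equal(back$regions$regions, co1$regions$regions)
})
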