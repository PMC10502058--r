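test_that("rank-sum p matches the stated small-sample cases", {
  expect_equal(ranksum_p(1:3, 4:6), 0.1)          # 2 of C(6,3)=20 extremes
  expect_equal(ranksum_p(1, 2), 1)
  expect_equal(ranksum_p(1:4, 5:8), 2 / 70)
})

test_that("rank-sum p equals full permutation enumeration for n+m <= 10", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(1:5, 1)
    m <- sample(seq_len(10 - n), 1)
    v <- sample(stats::rnorm(50), n + m)   # distinct values, no ties
    x <- v[seq_len(n)]
    y <- v[-seq_len(n)]
    expect_equal(ranksum_p(x, y), oracle_ranksum(x, y), tolerance = 1e-12)
  }
})

test_that("tied or large samples use the corrected normal approximation", {
  x <- c(rep(0.9, 6))
  y <- c(rep(0.1, 12))
  p <- ranksum_p(x, y)
  expect_lt(p, 1e-3)         # complete separation
  expect_gt(p, 0)
  expect_equal(ranksum_p(x, x), 1)
  expect_error(ranksum_p(numeric(), 1:3), "non-empty")
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03, 0.002)), c(0.02, 0.04, 0.04, 0.008))
  set.seed(5)
  for (i in 1:25) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(bh_fdr(sort(p))) >= -1e-12))   # monotone in p
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

# A three-type toy cohort where one region separates type A from everything,
# one separates A from tumors but not normals, and one is null.
toy_matrices <- function(jitter_seed = 1) {
  set.seed(jitter_seed)
  # 6 tumors/type and 6 normals: the smallest exact two-sided p for 6 vs 6
  # is 2/C(12,6) ~ 0.0022, which still clears FDR 0.01 in a 3-region family
  n_a <- 6; n_b <- 6; n_c <- 6; n_n <- 6
  eps <- function(n) stats::runif(n, -0.01, 0.01)
  vals <- rbind(
    marker_a  = c(0.9 + eps(n_a), 0.1 + eps(n_b + n_c)),
    cond2_fail = c(0.9 + eps(n_a), 0.1 + eps(n_b + n_c)),
    null_reg  = 0.5 + eps(n_a + n_b + n_c)
  )
  colnames(vals) <- sprintf("s%02d", seq_len(n_a + n_b + n_c))
  labels <- stats::setNames(rep(c("A", "B", "C"), c(n_a, n_b, n_c)),
                            colnames(vals))
  nvals <- rbind(
    marker_a  = 0.1 + eps(n_n),
    cond2_fail = 0.9 + eps(n_n),   # same as A in normals
    null_reg  = 0.5 + eps(n_n)
  )
  colnames(nvals) <- sprintf("n%02d", seq_len(n_n))
  tumor <- methorigin:::finalize_matrix(vals, "beta", labels, NULL, 0.2)
  normal <- methorigin:::finalize_matrix(
    nvals, "beta",
    stats::setNames(rep("normal", n_n), colnames(nvals)), NULL, 0.2)
  list(tumor = tumor, normal = normal, labels = labels)
}

test_that("marker selection enforces both differential conditions", {
  m <- toy_matrices()
  ms <- select_markers(m$tumor, m$normal, alpha = 0.01)
  sel_a <- ms$table[ms$table$cancer_type == "A", ]
  expect_true("marker_a" %in% sel_a$region_id)
  expect_false("cond2_fail" %in% sel_a$region_id)  # rejected by condition 2
  expect_false("null_reg" %in% ms$features)
  expect_equal(sel_a$direction[sel_a$region_id == "marker_a"], "hyper")
  expect_true(all(ms$table$q1 <= 0.01 & ms$table$q2 <= 0.01))
})

test_that("marker selection is sample-order invariant and alpha-monotone", {
  m <- toy_matrices()
  ms1 <- select_markers(m$tumor, m$normal, alpha = 0.01)
  perm <- sample(colnames(m$tumor$values))
  ms2 <- select_markers(subset_samples(m$tumor, perm), m$normal, alpha = 0.01)
  expect_equal(ms1$features, ms2$features)
  ms_wide <- select_markers(m$tumor, m$normal, alpha = 0.1)
  expect_true(all(ms1$features %in% ms_wide$features))
  # per-type marker sets only grow with alpha
  for (t in unique(ms1$table$cancer_type)) {
    expect_true(all(ms1$table$region_id[ms1$table$cancer_type == t] %in%
                      ms_wide$table$region_id[ms_wide$table$cancer_type == t]))
  }
})

test_that("marker selection validates its inputs", {
  m <- toy_matrices()
  one_type <- subset_samples(m$tumor, names(m$labels)[m$labels == "A"])
  expect_error(select_markers(one_type, m$normal), "two cancer types")
  singleton <- subset_samples(m$tumor,
                              c(names(m$labels)[m$labels == "A"][1],
                                names(m$labels)[m$labels == "B"]))
  expect_error(select_markers(singleton, m$normal), "fewer than 2")
})

test_that("marker sets round-trip through the TSV serialization", {
  m <- toy_matrices()
  ms <- select_markers(m$tumor, m$normal, alpha = 0.05)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_markers(ms, path)
  back <- read_markers(path)
  expect_equal(back$features, ms$features)
  expect_equal(back$alpha, ms$alpha)
  expect_equal(back$table$q1, ms$table$q1, tolerance = 1e-12)
})
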