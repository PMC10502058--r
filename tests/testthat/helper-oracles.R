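# Independent brute-force oracles: these deliberately re-derive every
# statistic from first principles (explicit enumeration), never through the
# package's own code paths.

expand_reads <- function(records) {
  rep(records$pattern, records$count)   # count c -> c literal reads
}

oracle_beta <- function(records) {
  reads <- expand_reads(records)
  if (!length(reads)) return(NA_real_)
  bits <- unlist(strsplit(reads, ""))
  mean(bits == "1")
}

oracle_pdr <- function(records, min_cpgs = 4) {
  reads <- expand_reads(records)
  reads <- reads[nchar(reads) >= min_cpgs]
  if (!length(reads)) return(NA_real_)
  mean(vapply(strsplit(reads, ""), function(b) any(b == "0") && any(b == "1"),
              logical(1)))
}

oracle_chalm <- function(records) {
  reads <- expand_reads(records)
  if (!length(reads)) return(NA_real_)
  mean(grepl("1", reads, fixed = TRUE))
}

# MHL by explicit enumeration of every substring of every read.
oracle_mhl <- function(records, max_l = 10) {
  reads <- expand_reads(records)
  if (!length(reads)) return(NA_real_)
  L <- min(max(nchar(reads)), max_l)
  S <- F1 <- numeric(L)
  for (r in reads) {
    n <- nchar(r)
    for (l in seq_len(min(n, L))) {
      for (s in seq_len(n - l + 1)) {
        S[l] <- S[l] + 1
        if (substr(r, s, s + l - 1) == strrep("1", l)) F1[l] <- F1[l] + 1
      }
    }
  }
  w <- ifelse(S > 0, seq_len(L), 0)
  w <- w / sum(w)
  sum(w[S > 0] * F1[S > 0] / S[S > 0])
}

# Exact two-sided rank-sum p by full enumeration of group-1 assignments.
oracle_ranksum <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  W <- apply(combos, 2, function(idx) sum(r[idx])) - n * (n + 1) / 2
  min(1, 2 * min(mean(W <= w_obs), mean(W >= w_obs)))
}

# Naive O(m^2) Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    o <- order(p)
    rank_i <- which(o == i)
    cand <- vapply(rank_i:m, function(j) p[o[j]] * m / j, numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

random_records <- function(n_reads, max_len = 6, p1 = NULL) {
  if (is.null(p1)) p1 <- stats::runif(1)
  pats <- vapply(seq_len(n_reads), function(i) {
    paste(rbinom(sample(max_len, 1), 1, p1), collapse = "")
  }, character(1))
  data.frame(pattern = pats, count = sample(1:3, n_reads, replace = TRUE),
             stringsAsFactors = FALSE)
}
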