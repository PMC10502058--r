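# The default-conditions recovery study is expensive (a full cohort
# simulation plus model fit), so it is computed once and shared by every
# assertion that needs it.
.study_cache <- new.env(parent = emptyenv())

get_recovery_study <- function() {
  if (is.null(.study_cache$study)) {
    .study_cache$study <- too_recovery_study(seed = 1, verbose = FALSE)
  }
  .study_cache$study
}

# Published 68-patient accuracy table of the FFPE evaluation cohort,
# encoded as per-type tallies: patients, correct at rank 1, correct within
# rank 3.
cup_tallies <- data.frame(
  type = c("lung", "head_and_neck", "stomach", "colorectum", "ovary",
           "liver_and_bile_duct", "cervix", "thyroid", "esophagus"),
  n    = c(19, 17, 8, 7, 5, 6, 2, 3, 1),
  top1 = c(18, 12, 8, 4, 4, 6, 1, 1, 1),
  top3 = c(18, 16, 8, 6, 4, 6, 2, 2, 1),
  stringsAsFactors = FALSE
)

# Expand tallies into truth labels, top-1 calls and a rank matrix: correct
# top-1 hits carry the true label first; top-3-only hits at rank 2; misses
# never show the true label in the first three ranks.
tallies_to_predictions <- function(tab) {
  truth <- character()
  top1 <- character()
  ranked <- NULL
  for (i in seq_len(nrow(tab))) {
    t <- tab$type[i]
    other <- setdiff(tab$type, t)[1:3]
    n1 <- tab$top1[i]
    n3 <- tab$top3[i] - tab$top1[i]
    n0 <- tab$n[i] - tab$top3[i]
    truth <- c(truth, rep(t, tab$n[i]))
    top1 <- c(top1, rep(t, n1), rep(other[1], n3 + n0))
    rows <- rbind(
      if (n1) matrix(rep(c(t, other[1:2]), n1), n1, 3, byrow = TRUE),
      if (n3) matrix(rep(c(other[1], t, other[2]), n3), n3, 3, byrow = TRUE),
      if (n0) matrix(rep(other[1:3], n0), n0, 3, byrow = TRUE)
    )
    ranked <- rbind(ranked, rows)
  }
  list(truth = truth, top1 = top1, ranked = ranked)
}
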