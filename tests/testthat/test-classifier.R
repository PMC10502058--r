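# Small separable training problem shared across classifier tests.
sep_data <- function(n_per = 12, noise = 0.02, seed = 4) {
  set.seed(seed)
  classes <- c("A", "B", "C")
  x <- do.call(rbind, lapply(seq_along(classes), function(i) {
    centers <- diag(3)[i, ]
    matrix(rep(centers, each = n_per), n_per) +
      matrix(stats::rnorm(n_per * 3, sd = noise), n_per)
  }))
  colnames(x) <- c("f1", "f2", "f3")
  rownames(x) <- sprintf("s%02d", seq_len(nrow(x)))
  y <- stats::setNames(rep(classes, each = n_per), rownames(x))
  list(x = x, y = y)
}

test_that("stratified split follows the 4:1 rule and is deterministic", {
  labels <- stats::setNames(rep(c("A", "B", "C"), c(10, 4, 7)),
                            sprintf("s%02d", 1:21))
  sp <- stratified_split(labels, seed = 3)
  val_lab <- labels[sp$validation]
  expect_equal(sum(val_lab == "A"), 2)   # floor(10/5)
  expect_equal(sum(val_lab == "B"), 1)   # floor(4/5) but >= 1... floor = 0 -> 1
  expect_equal(sum(val_lab == "C"), 1)
  expect_setequal(c(sp$train, sp$validation), names(labels))
  expect_equal(stratified_split(labels, seed = 3), sp)
  expect_false(identical(stratified_split(labels, seed = 4), sp))
  expect_error(stratified_split(c(a = "A", b = "B", c = "B")), "single sample")
})

test_that("oversampling balances classes with convex combinations", {
  set.seed(8)
  x <- rbind(matrix(stats::rnorm(20), 10), matrix(stats::rnorm(8) + 5, 4))
  rownames(x) <- sprintf("s%d", 1:14)
  y <- rep(c("A", "B"), c(10, 4))
  bal <- oversample(x, y, seed = 2)
  expect_equal(as.vector(table(bal$y)), c(10, 10))
  syn <- bal$x[15:20, , drop = FALSE]
  orig_b <- x[11:14, , drop = FALSE]
  for (i in seq_len(nrow(syn))) {
    expect_true(all(syn[i, ] >= apply(orig_b, 2, min) - 1e-12))
    expect_true(all(syn[i, ] <= apply(orig_b, 2, max) + 1e-12))
  }
  expect_equal(oversample(x, y, seed = 2), bal)   # deterministic

  # two-point minority: every synthetic sample sits on the segment
  x2 <- rbind(x[1:10, ], x[11:12, ])
  y2 <- rep(c("A", "B"), c(10, 2))
  bal2 <- oversample(x2, y2, seed = 5)
  syn2 <- bal2$x[13:20, , drop = FALSE]
  d <- x2[12, ] - x2[11, ]
  for (i in seq_len(nrow(syn2))) {
    u <- (syn2[i, ] - x2[11, ]) / ifelse(d == 0, 1, d)
    expect_lt(max(u) - min(u[d != 0]), 1e-8)   # consistent interpolation factor
    expect_true(all(u[d != 0] >= -1e-12 & u[d != 0] <= 1 + 1e-12))
  }

  # singleton minority falls back to duplication
  x1 <- rbind(x[1:10, ], x[11, , drop = FALSE])
  bal1 <- oversample(x1, rep(c("A", "B"), c(10, 1)), seed = 1)
  expect_true(all(apply(bal1$x[bal1$y == "B", ], 1, identical, x1[11, ])))
})

test_that("training is deterministic and rejects unknown learners", {
  d <- sep_data()
  f1 <- train_learner(d$x, d$y, "linear_svc", search_budget = 4, seed = 9)
  f2 <- train_learner(d$x, d$y, "linear_svc", search_budget = 4, seed = 9)
  expect_identical(f1$params, f2$params)
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))
  expect_equal(f1$cv_accuracy, 1)            # margin-separated classes
  expect_error(train_learner(d$x, d$y, "xgboost"), "unknown learner")
})

test_that("every learner of the grid trains and emits probability vectors", {
  d <- sep_data(n_per = 8)
  sp <- stratified_split(d$y, seed = 1)
  for (lrn in too_learners()) {
    fit <- train_learner(d$x[sp$train, ], d$y[sp$train], lrn,
                         search_budget = 2, cv_folds = 3, seed = 5)
    fit <- calibrate(fit, d$x[sp$validation, ], d$y[sp$validation])
    pred <- predict_topk(fit, d$x, k = 3)
    prob <- attr(pred, "prob")
    expect_equal(rowSums(prob), rep(1, nrow(d$x)), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(prob >= 0 & prob <= 1))
    top1 <- pred$class[pred$rank == 1]
    expect_gte(mean(top1 == d$y), 0.9)   # trivially separable data
  }
})

test_that("calibration preserves ranking on a separating model and validates input", {
  d <- sep_data()
  sp <- stratified_split(d$y, seed = 2)
  fit <- train_learner(d$x[sp$train, ], d$y[sp$train], "linear_svc",
                       search_budget = 3, seed = 2)
  raw <- methorigin:::score_learner(fit, d$x[sp$validation, ])
  fit <- calibrate(fit, d$x[sp$validation, ], d$y[sp$validation])
  cal <- methorigin:::apply_calibration(fit, raw)
  expect_equal(max.col(raw), max.col(cal))   # argmax unchanged
  expect_error(calibrate(fit, d$x[0, , drop = FALSE], character()), "empty")
  only_a <- d$y[sp$validation][d$y[sp$validation] == "A"]
  expect_error(calibrate(fit, d$x[names(only_a), , drop = FALSE], only_a),
               "lacks class")
})

# Hand-built calibrated model whose probabilities are fully controlled.
fixed_prob_model <- function(probs) {
  classes <- names(probs)
  maps <- lapply(classes, function(cl) {
    list(type = "sigmoid", a = stats::qlogis(probs[[cl]]), b = 0)
  })
  names(maps) <- classes
  structure(list(learner = "knn", params = list(k = 1, weights = "uniform"),
                 classes = classes,
                 fit = list(x = matrix(0, 1, 1), y = factor(classes[1], classes),
                            k = 1, weights = "uniform", classes = classes),
                 calibration = list(method = "sigmoid", maps = maps)),
            class = "too_learner_fit")
}

test_that("top-k ranking, tie-breaks, tiers and k handling are exact", {
  m <- fixed_prob_model(c(A = 0.7, B = 0.2, C = 0.1))
  p <- predict_topk(m, matrix(0, 1, 1), k = 2)
  expect_equal(p$class, c("A", "B"))
  expect_equal(p$probability, c(0.7, 0.2), tolerance = 1e-12)
  expect_equal(unique(p$tier), "medium")    # 0.7 is not > 0.75

  tie <- fixed_prob_model(c(B = 0.5, A = 0.5))
  pt <- predict_topk(tie, matrix(0, 1, 1), k = 1)
  expect_equal(pt$class, "A")               # lexicographic tie-break
  expect_equal(pt$tier, "low")              # 0.5 is not > 0.5

  bd <- fixed_prob_model(c(A = 0.75, B = 0.25))
  expect_equal(predict_topk(bd, matrix(0, 1, 1), k = 1)$tier, "medium")
  hi <- fixed_prob_model(c(A = 0.9, B = 0.1))
  expect_equal(predict_topk(hi, matrix(0, 1, 1), k = 1)$tier, "high")

  expect_error(predict_topk(m, matrix(0, 1, 1), k = 0), "positive integer")
  clamped <- predict_topk(m, matrix(0, 1, 1), k = 10)
  expect_equal(nrow(clamped), 3)            # clamped to #classes
})
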