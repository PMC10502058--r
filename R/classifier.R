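#' The seven supported learners
#'
#' @return character vector of learner names: adaboost, knn, logistic,
#'   linear_svc, naive_bayes, random_forest, svm_rbf.
#' @export
too_learners <- function() {
  c("adaboost", "knn", "logistic", "linear_svc", "naive_bayes",
    "random_forest", "svm_rbf")
}

#' Stratified train/validation split
#'
#' Per class, \code{floor(n * validation_frac)} samples — but at least one —
#' go to validation; the rest train. Deterministic given the seed.
#'
#' @param labels named character vector (names are sample ids).
#' @param validation_frac validation share (default 0.2, i.e. a 4:1 split).
#' @param seed integer seed.
#' @return list with \code{train} and \code{validation} id vectors.
#' @export
stratified_split <- function(labels, validation_frac = 0.2, seed = 1) {
  stopifnot(!is.null(names(labels)))
  counts <- table(labels)
  if (any(counts < 2)) {
    stopf("class(es) with a single sample cannot be split: %s",
          paste(names(counts)[counts < 2], collapse = ", "))
  }
  val <- with_seed(derive_seed(seed, "split"), {
    unlist(lapply(sort(unique(labels)), function(cl) {
      ids <- names(labels)[labels == cl]
      n_val <- max(1L, floor(length(ids) * validation_frac))
      sample(ids, n_val)
    }), use.names = FALSE)
  })
  list(train = setdiff(names(labels), val), validation = val)
}

# Stratified K folds as an integer fold assignment per sample.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Interpolation-based minority oversampling
#'
#' Brings every class up to the majority-class count by adding synthetic
#' samples: each is the convex combination \eqn{x + u (x' - x)},
#' \eqn{u \sim U(0,1)}, of a random minority sample x and one of its
#' \code{k_neighbors} nearest same-class neighbors x' (Euclidean). A class
#' of size one falls back to duplication.
#'
#' @param x samples x features numeric matrix (fully imputed).
#' @param y factor of class labels, one per row of x.
#' @param k_neighbors neighborhood size (default 5), capped at class size
#'   minus one.
#' @param seed integer seed.
#' @return list with the augmented \code{x} and \code{y}.
#' @export
oversample <- function(x, y, k_neighbors = 5, seed = 1) {
  stopifnot(is.matrix(x), nrow(x) == length(y), !anyNA(x))
  y <- factor(y)
  counts <- table(y)
  target <- max(counts)
  add_x <- list()
  add_y <- character()
  with_seed(derive_seed(seed, "oversample"), {
    for (cl in levels(y)) {
      need <- target - counts[[cl]]
      if (need == 0) next
      xi <- x[y == cl, , drop = FALSE]
      n <- nrow(xi)
      if (n == 1) {
        syn <- xi[rep(1, need), , drop = FALSE]
      } else {
        k <- min(k_neighbors, n - 1)
        d2 <- as.matrix(stats::dist(xi))^2
        diag(d2) <- Inf
        nn <- apply(d2, 1, function(dd) order(dd)[seq_len(k)])
        nbr <- if (k == 1) matrix(nn, ncol = 1) else t(nn)
        base <- sample(n, need, replace = TRUE)
        pick <- nbr[cbind(base, sample(k, need, replace = TRUE))]
        u <- stats::runif(need)
        syn <- xi[base, , drop = FALSE] +
          u * (xi[pick, , drop = FALSE] - xi[base, , drop = FALSE])
      }
      rownames(syn) <- sprintf("synth_%s_%d", cl, seq_len(need))
      add_x[[cl]] <- syn
      add_y <- c(add_y, rep(cl, need))
    }
  })
  if (length(add_x)) {
    x <- rbind(x, do.call(rbind, add_x))
    y <- factor(c(as.character(y), add_y), levels = levels(y))
  }
  list(x = x, y = y)
}

# ---- learner backends ------------------------------------------------------
# Each learner exposes: sample_params(n) (draws n hyperparameter settings
# under the caller's RNG), fit(x, y, params, seed), and score(fit, newx)
# returning a samples x classes score matrix (probabilities where the
# backend has them, one-vs-rest decision values for the SVMs). Calibration
# maps either kind of score to probabilities.

lunif <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

fit_ovr_svm <- function(x, y, kernel, cost, gamma = NULL, tolerance = 1e-3) {
  fits <- lapply(levels(y), function(cl) {
    yy <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    args <- list(x = x, y = yy, type = "C-classification", kernel = kernel,
                 cost = cost, tolerance = tolerance, scale = FALSE)
    if (!is.null(gamma)) args$gamma <- gamma
    m <- do.call(e1071::svm, args)
    dv <- attr(stats::predict(m, x, decision.values = TRUE),
               "decision.values")[, 1]
    list(m = m, flip = mean(dv[yy == "pos"]) < mean(dv[yy == "neg"]))
  })
  names(fits) <- levels(y)
  fits
}

score_ovr_svm <- function(fits, newx) {
  out <- vapply(fits, function(f) {
    dv <- attr(stats::predict(f$m, newx, decision.values = TRUE),
               "decision.values")[, 1]
    if (f$flip) -dv else dv
  }, numeric(nrow(newx)))
  matrix(out, nrow = nrow(newx), dimnames = list(rownames(newx), names(fits)))
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

too_learner_backend <- function(learner) {
  switch(learner,
    adaboost = list(
      sample_params = function(n) {
        data.frame(n_rounds = sample(c(20L, 50L, 100L, 150L), n, replace = TRUE),
                   learning_rate = lunif(n, 0.05, 1))
      },
      fit = function(x, y, p, seed) {
        K <- nlevels(y)
        n <- nrow(x)
        w <- rep(1 / n, n)
        df <- data.frame(x, check.names = FALSE)
        df$.y <- y
        ctrl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                                     xval = 0, maxcompete = 0, maxsurrogate = 0)
        stumps <- list()
        alphas <- numeric()
        for (m in seq_len(p$n_rounds)) {
          wts <- w * n   # rpart dislikes tiny weights
          st <- rpart::rpart(.y ~ ., data = df, weights = wts,
                             method = "class", control = ctrl)
          pred <- stats::predict(st, df, type = "class")
          mis <- pred != y
          err <- sum(w[mis])
          if (err < 1e-10) {
            stumps <- c(stumps, list(st))
            alphas <- c(alphas, p$learning_rate * (log(1e10) + log(K - 1)))
            break
          }
          if (err >= 1 - 1 / K) break
          a <- p$learning_rate * (log((1 - err) / err) + log(K - 1))
          stumps <- c(stumps, list(st))
          alphas <- c(alphas, a)
          w <- w * exp(a * mis)
          w <- w / sum(w)
        }
        if (!length(stumps)) {   # degenerate: fall back to class priors
          return(list(stumps = NULL, prior = prop.table(table(y)),
                      classes = levels(y)))
        }
        list(stumps = stumps, alphas = alphas, classes = levels(y))
      },
      score = function(fit, newx) {
        cls <- fit$classes
        if (is.null(fit$stumps)) {
          return(matrix(rep(as.numeric(fit$prior[cls]), each = nrow(newx)),
                        nrow(newx), dimnames = list(rownames(newx), cls)))
        }
        df <- data.frame(newx, check.names = FALSE)
        votes <- matrix(0, nrow(newx), length(cls),
                        dimnames = list(rownames(newx), cls))
        for (i in seq_along(fit$stumps)) {
          pred <- as.character(stats::predict(fit$stumps[[i]], df, type = "class"))
          votes[cbind(seq_len(nrow(newx)), match(pred, cls))] <-
            votes[cbind(seq_len(nrow(newx)), match(pred, cls))] + fit$alphas[i]
        }
        votes / pmax(rowSums(votes), .Machine$double.eps)
      }
    ),
    knn = list(
      sample_params = function(n) {
        data.frame(k = sample(c(3L, 5L, 7L, 9L, 11L, 15L), n, replace = TRUE),
                   weights = sample(c("uniform", "distance"), n, replace = TRUE),
                   algorithm = "brute", stringsAsFactors = FALSE)
      },
      fit = function(x, y, p, seed) list(x = x, y = y, k = p$k,
                                         weights = p$weights,
                                         classes = levels(y)),
      score = function(fit, newx) {
        cls <- fit$classes
        k <- min(fit$k, nrow(fit$x))
        d2 <- outer(rowSums(newx^2), rep(1, nrow(fit$x))) +
          outer(rep(1, nrow(newx)), rowSums(fit$x^2)) -
          2 * newx %*% t(fit$x)
        out <- matrix(0, nrow(newx), length(cls),
                      dimnames = list(rownames(newx), cls))
        for (i in seq_len(nrow(newx))) {
          nn <- order(d2[i, ])[seq_len(k)]
          wt <- if (fit$weights == "distance") {
            1 / (sqrt(pmax(d2[i, nn], 0)) + 1e-8)
          } else rep(1, k)
          s <- rowsum(wt, factor(as.character(fit$y[nn]), levels = cls))
          out[i, rownames(s)] <- s[, 1]
        }
        out / rowSums(out)
      }
    ),
    logistic = list(
      sample_params = function(n) {
        data.frame(alpha = sample(c(0, 0.5, 1), n, replace = TRUE),
                   lambda = lunif(n, 1e-4, 1),
                   solver = "coordinate-descent", stringsAsFactors = FALSE)
      },
      fit = function(x, y, p, seed) {
        fit <- suppressWarnings(
          glmnet::glmnet(x, y, family = "multinomial", alpha = p$alpha,
                         lambda = c(p$lambda * 5, p$lambda))
        )
        list(fit = fit, lambda = p$lambda, classes = levels(y))
      },
      score = function(fit, newx) {
        pr <- stats::predict(fit$fit, newx, type = "response", s = fit$lambda)[, , 1]
        if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
        pr[, fit$classes, drop = FALSE]
      }
    ),
    linear_svc = list(
      sample_params = function(n) {
        data.frame(cost = lunif(n, 0.01, 100),
                   tolerance = sample(c(1e-4, 1e-3, 1e-2), n, replace = TRUE),
                   penalty = "l2", loss = "hinge", multiclass = "ovr",
                   stringsAsFactors = FALSE)
      },
      fit = function(x, y, p, seed) {
        list(fits = fit_ovr_svm(x, y, "linear", p$cost, tolerance = p$tolerance),
             classes = levels(y))
      },
      score = function(fit, newx) score_ovr_svm(fit$fits, newx)
    ),
    naive_bayes = list(
      sample_params = function(n) data.frame(alpha_sm = lunif(n, 0.01, 10)),
      fit = function(x, y, p, seed) {
        cls <- levels(y)
        prior <- log(as.numeric(table(y)[cls]) / length(y))
        fc <- rowsum(x, y)[cls, , drop = FALSE] + p$alpha_sm
        list(prior = prior, logp = log(fc / rowSums(fc)), classes = cls)
      },
      score = function(fit, newx) {
        z <- newx %*% t(fit$logp) +
          matrix(fit$prior, nrow(newx), length(fit$prior), byrow = TRUE)
        colnames(z) <- fit$classes
        softmax(z)
      }
    ),
    random_forest = list(
      sample_params = function(n) {
        data.frame(num_trees = sample(c(100L, 200L, 300L, 500L), n, replace = TRUE),
                   max_depth = sample(c(0L, 5L, 10L, 20L), n, replace = TRUE),
                   mtry_frac = sample(c(NA, 0.1, 0.3), n, replace = TRUE),
                   splitrule = sample(c("gini", "extratrees"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
      },
      fit = function(x, y, p, seed) {
        mtry <- if (is.na(p$mtry_frac)) floor(sqrt(ncol(x))) else
          max(1L, round(p$mtry_frac * ncol(x)))
        fit <- ranger::ranger(x = x, y = y, num.trees = p$num_trees,
                              mtry = mtry, max.depth = p$max_depth,
                              splitrule = p$splitrule, probability = TRUE,
                              seed = seed, num.threads = 1)
        list(fit = fit, classes = levels(y))
      },
      score = function(fit, newx) {
        stats::predict(fit$fit, data = newx,
                       num.threads = 1)$predictions[, fit$classes, drop = FALSE]
      }
    ),
    svm_rbf = list(
      sample_params = function(n) {
        data.frame(cost = lunif(n, 0.01, 100), gamma = lunif(n, 1e-4, 1),
                   kernel = "radial", stringsAsFactors = FALSE)
      },
      fit = function(x, y, p, seed) {
        list(fits = fit_ovr_svm(x, y, "radial", p$cost, gamma = p$gamma),
             classes = levels(y))
      },
      score = function(fit, newx) score_ovr_svm(fit$fits, newx)
    ),
    stopf("unknown learner '%s'; supported: %s", learner,
          paste(too_learners(), collapse = ", "))
  )
}

#' Train one learner with budgeted hyperparameter search
#'
#' Hyperparameters are chosen by random search over the learner's declared
#' space: \code{search_budget} settings are drawn, each scored by
#' stratified \code{cv_folds}-fold cross-validation accuracy on the
#' training matrix, and the best (first on ties) is refit on all of x.
#' Deterministic given the seed.
#'
#' @param x samples x features numeric matrix (fully imputed).
#' @param y class labels (coerced to a factor with sorted levels).
#' @param learner one of [too_learners()].
#' @param search_budget number of hyperparameter settings tried (default 50).
#' @param cv_folds cross-validation folds (default 5).
#' @param seed integer seed.
#' @return object of class \code{too_learner_fit}: learner name, chosen
#'   \code{params}, \code{classes}, fitted backend, \code{cv_accuracy}, and
#'   the full \code{search} table.
#' @export
train_learner <- function(x, y, learner, search_budget = 50, cv_folds = 5,
                          seed = 1) {
  backend <- too_learner_backend(learner)
  y <- factor(as.character(y))
  if (nlevels(y) < 2) stopf("need at least two classes")
  stopifnot(is.matrix(x), nrow(x) == length(y), !anyNA(x))
  grid <- with_seed(derive_seed(seed, "search"),
                    backend$sample_params(search_budget))
  k <- min(cv_folds, min(table(y)))
  fold <- stratified_folds(y, k, derive_seed(seed, "folds"))
  acc <- numeric(nrow(grid))
  for (tr in seq_len(nrow(grid))) {
    p <- grid[tr, , drop = FALSE]
    correct <- 0
    for (f in seq_len(k)) {
      in_tr <- fold != f
      fit <- backend$fit(x[in_tr, , drop = FALSE], droplevels(y[in_tr]), p,
                         derive_seed(seed, sprintf("cv_%d_%d", tr, f)))
      sc <- backend$score(fit, x[!in_tr, , drop = FALSE])
      pred <- colnames(sc)[max.col(sc, ties.method = "first")]
      correct <- correct + sum(pred == as.character(y[!in_tr]))
    }
    acc[tr] <- correct / length(y)
  }
  best <- which.max(acc)
  fit <- backend$fit(x, y, grid[best, , drop = FALSE],
                     derive_seed(seed, "final"))
  structure(list(learner = learner, params = as.list(grid[best, , drop = FALSE]),
                 classes = levels(y), fit = fit, cv_accuracy = acc[best],
                 search = cbind(grid, cv_accuracy = acc), seed = seed),
            class = "too_learner_fit")
}

score_learner <- function(model, newx) {
  backend <- too_learner_backend(model$learner)
  sc <- backend$score(model$fit, newx)
  sc[, model$classes, drop = FALSE]
}

#' Calibrate a trained learner on a held-out validation set
#'
#' Fits one sigmoid (Platt) map per class on the one-vs-rest scores over
#' the validation samples, with the usual smoothed targets
#' \eqn{(n_+ + 1)/(n_+ + 2)} and \eqn{1/(n_- + 2)}; calibrated per-class
#' probabilities are renormalized to sum to one. An isotonic option
#' (monotone step function with linear interpolation) is available.
#'
#' @param model a \code{too_learner_fit}.
#' @param vx validation samples x features matrix.
#' @param vy validation labels; every model class must be represented.
#' @param method \code{"sigmoid"} (default) or \code{"isotonic"}.
#' @return the model with a \code{calibration} element attached.
#' @export
calibrate <- function(model, vx, vy, method = c("sigmoid", "isotonic")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "too_learner_fit"))
  if (is.null(vx) || nrow(vx) == 0) stopf("validation set is empty")
  vy <- as.character(vy)
  absent <- setdiff(model$classes, vy)
  if (length(absent)) {
    stopf("validation set lacks class(es): %s", paste(absent, collapse = ", "))
  }
  sc <- score_learner(model, vx)
  maps <- lapply(model$classes, function(cl) {
    s <- sc[, cl]
    pos <- vy == cl
    if (method == "sigmoid") {
      np <- sum(pos)
      nn <- sum(!pos)
      t <- ifelse(pos, (np + 1) / (np + 2), 1 / (nn + 2))
      co <- tryCatch(
        stats::coef(suppressWarnings(
          stats::glm(t ~ s, family = stats::binomial())
        )),
        error = function(e) c(0, 1)
      )
      if (anyNA(co)) co[is.na(co)] <- 0
      list(type = "sigmoid", a = unname(co[1]), b = unname(co[2]))
    } else {
      o <- order(s)
      iso <- stats::isoreg(s[o], as.numeric(pos[o]))
      xs <- iso$x
      ys <- iso$yf
      keep <- !duplicated(xs)
      list(type = "isotonic", x = xs[keep], y = ys[keep])
    }
  })
  names(maps) <- model$classes
  model$calibration <- list(method = method, maps = maps)
  model
}

apply_calibration <- function(model, sc) {
  if (is.null(model$calibration)) {
    stopf("model is not calibrated; run calibrate() first")
  }
  p <- sc
  for (cl in model$classes) {
    m <- model$calibration$maps[[cl]]
    p[, cl] <- if (m$type == "sigmoid") {
      stats::plogis(m$a + m$b * sc[, cl])
    } else {
      stats::approx(m$x, m$y, xout = sc[, cl], rule = 2, ties = "ordered")$y
    }
  }
  p <- pmax(p, 1e-12)
  p / rowSums(p)
}

#' Ranked top-k prediction from a calibrated model
#'
#' @param model a calibrated \code{too_learner_fit}.
#' @param features samples x features matrix aligned to the model's feature
#'   space (a single sample may be given as a named vector).
#' @param k number of ranks to report (clamped to the number of classes).
#' @return object of class \code{too_prediction}: a data.frame with
#'   \code{sample_id}, \code{rank}, \code{class}, \code{probability},
#'   \code{tier} (high if max probability > 0.75, medium if > 0.5, else
#'   low; ties broken lexicographically by class name); the full
#'   probability matrix is kept in \code{attr(, "prob")}.
#' @export
predict_topk <- function(model, features, k = 3) {
  if (!is_count(k)) stopf("k must be a positive integer")
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1,
                       dimnames = list("sample_1", names(features)))
  }
  k <- min(k, length(model$classes))
  prob <- apply_calibration(model, score_learner(model, features))
  ids <- rownames(features)
  if (is.null(ids)) ids <- sprintf("sample_%d", seq_len(nrow(features)))
  rows <- lapply(seq_len(nrow(features)), function(i) {
    o <- order(-prob[i, ], colnames(prob), method = "radix")
    top <- prob[i, o[1]]
    tier <- if (top > 0.75) "high" else if (top > 0.5) "medium" else "low"
    data.frame(sample_id = ids[i], rank = seq_len(k),
               class = colnames(prob)[o[seq_len(k)]],
               probability = unname(prob[i, o[seq_len(k)]]),
               tier = tier, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, prob = prob, k = k, class = c("too_prediction", "data.frame"))
}

#' @export
print.too_prediction <- function(x, ...) {
  cat(sprintf("<too_prediction> %d sample(s), top-%d ranks\n",
              length(unique(x$sample_id)), attr(x, "k")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

# Full probability matrix and per-sample top-1 calls from a prediction.
prediction_prob <- function(pred) attr(pred, "prob")

top1_calls <- function(pred) {
  with(pred[pred$rank == 1, ], stats::setNames(class, sample_id))
}
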