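.FEATURE_COLS <- c("trt_s", "roa_deg", "symmetry")
.ALGOS <- c("KNN", "LDA", "NB", "SVM", "RF")

# group as a factor with TD first, ASD second (ASD = positive class)
.group_factor <- function(g) factor(as.character(g), levels = c("TD", "ASD"))

#' Stratified train/test split
#'
#' Random split stratified by group, deterministic given `seed`. Each class
#' contributes `round(n_class * test_frac)` (at least 1) test rows.
#'
#' @param features Cohort feature data.frame (needs a `group` column).
#' @param test_frac Test fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` data.frames.
#' @export
split_train_test <- function(features, test_frac = 0.1, seed = 1) {
  if (test_frac <= 0 || test_frac >= 1)
    stop("test_frac must lie strictly between 0 and 1")
  g <- .group_factor(features$group)
  if (any(table(g) < 2))
    stop("stratification error: need >= 2 participants per class")
  test_idx <- with_seed(seed, {
    unlist(lapply(levels(g), function(lv) {
      idx <- which(g == lv)
      sample(idx, max(1L, round(length(idx) * test_frac)))
    }))
  })
  list(train = features[-test_idx, , drop = FALSE],
       test = features[test_idx, , drop = FALSE])
}

#' Default hyperparameter grids
#'
#' Small standard grids for a three-feature problem: KNN k in {1,3,5,7,9};
#' SVM (RBF) cost in {0.1,1,10,100} and gamma = 1/3 x {0.1,1,10} (the scale
#' heuristic for standardized features); RF trees in {100,300} and max nodes
#' in {unbounded, 8, 32}; Gaussian NB variance smoothing in {1e-9, 1e-6};
#' LDA has no tunable parameter.
#'
#' @param algorithm One of `"KNN"`, `"LDA"`, `"NB"`, `"SVM"`, `"RF"`.
#' @return data.frame with one row per grid point.
#' @export
default_grid <- function(algorithm) {
  switch(match.arg(algorithm, .ALGOS),
         KNN = data.frame(k = c(1, 3, 5, 7, 9)),
         LDA = data.frame(dummy = 0),
         NB = data.frame(eps = c(1e-9, 1e-6)),
         SVM = expand.grid(cost = c(0.1, 1, 10, 100),
                           gamma = (1 / 3) * c(0.1, 1, 10)),
         RF = expand.grid(ntree = c(100, 300), maxnodes = c(NA, 8, 32)))
}

.scale_fit <- function(X) list(center = colMeans(X),
                               scale = pmax(apply(X, 2, stats::sd), 1e-12))
.scale_apply <- function(X, sc) scale(X, center = sc$center, scale = sc$scale)

.fit_one <- function(algorithm, X, y, par, probability = FALSE) {
  switch(algorithm,
         KNN = list(X = X, y = y, k = min(par$k, nrow(X))),
         LDA = MASS::lda(X, grouping = y),
         NB = {
           m <- e1071::naiveBayes(X, y)
           # variance smoothing: add eps * largest feature variance to every
           # class variance so zero-variance features stay usable
           vmax <- max(vapply(m$tables, function(tb) max(tb[, 2]^2),
                              numeric(1)))
           m$tables <- lapply(m$tables, function(tb) {
             tb[, 2] <- sqrt(tb[, 2]^2 + par$eps * max(vmax, 1e-12))
             tb
           })
           list(model = m, eps = par$eps)
         },
         SVM = e1071::svm(X, y, kernel = "radial", cost = par$cost,
                          gamma = par$gamma, probability = probability),
         RF = if (is.na(par$maxnodes))
           randomForest::randomForest(X, y, ntree = par$ntree)
         else randomForest::randomForest(X, y, ntree = par$ntree,
                                         maxnodes = min(par$maxnodes, nrow(X))))
}

# returns list(class = factor, score = P(ASD) or decision value)
.predict_one <- function(algorithm, fit, X) {
  switch(algorithm,
    KNN = {
      pr <- class::knn(fit$X, X, fit$y, k = fit$k, prob = TRUE)
      pwin <- attr(pr, "prob")
      list(class = pr, score = ifelse(pr == "ASD", pwin, 1 - pwin))
    },
    LDA = {
      p <- stats::predict(fit, X)
      list(class = p$class, score = p$posterior[, "ASD"])
    },
    NB = {
      raw <- stats::predict(fit$model, X, type = "raw")
      cls <- factor(colnames(raw)[max.col(raw, ties.method = "first")],
                    levels = names(fit$model$apriori))
      list(class = cls, score = raw[, "ASD"])
    },
    SVM = {
      p <- stats::predict(fit, X, probability = isTRUE(fit$compprob),
                          decision.values = TRUE)
      probs <- attr(p, "probabilities")
      if (!is.null(probs)) {
        list(class = p, score = probs[, "ASD"])
      } else {
        dv <- attr(p, "decision.values")[, 1]
        # orient decision values so larger = more ASD
        sgn <- if (grepl("^ASD", colnames(attr(p, "decision.values"))[1])) 1 else -1
        list(class = p, score = sgn * dv, decision_values = TRUE)
      }
    },
    RF = {
      pr <- stats::predict(fit, X, type = "prob")
      list(class = stats::predict(fit, X), score = pr[, "ASD"])
    })
}

# stratified fold assignment: within each class, shuffled indices dealt
# round-robin into k folds
.make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Grid search by repeated stratified cross-validation, then refit
#'
#' For every grid point, runs `repeats` rounds of stratified `folds`-fold
#' cross-validation on the training set, standardizing features inside each
#' fold (fit on the fold-train portion only), and selects the grid point with
#' the highest mean CV accuracy (first on ties). The winner is refitted on
#' the full training set.
#'
#' @param train Training data.frame (feature columns + `group`).
#' @param algorithm One of `"KNN"`, `"LDA"`, `"NB"`, `"SVM"`, `"RF"`.
#' @param grid Hyperparameter grid; default [default_grid()].
#' @param seed Integer seed for fold assignment.
#' @param folds,repeats Cross-validation design (default 10 x 10).
#' @return Object of class `wri_classifier`: list with `algorithm`, `fit`,
#'   `scaler`, `chosen_hyperparams`, `cv_accuracy`, `cv_table`, `seed`.
#' @export
tune_and_fit <- function(train, algorithm, grid = default_grid(algorithm),
                         seed = 1, folds = 10, repeats = 10) {
  algorithm <- match.arg(algorithm, .ALGOS)
  if (!nrow(grid)) stop("empty hyperparameter grid")
  X <- as.matrix(train[.FEATURE_COLS])
  y <- .group_factor(train$group)
  if (nlevels(droplevels(y)) < 2) stop("training set must contain both classes")
  k <- min(folds, min(table(y)))
  if (k < 2) stop("fold error: too few observations per class")
  cv_acc <- with_seed(seed, {
    fold_sets <- replicate(repeats, .make_folds(y, k), simplify = FALSE)
    vapply(seq_len(nrow(grid)), function(gi) {
      par <- grid[gi, , drop = FALSE]
      accs <- unlist(lapply(fold_sets, function(fold) {
        vapply(seq_len(k), function(f) {
          tr <- fold != f; te <- !tr
          sc <- .scale_fit(X[tr, , drop = FALSE])
          fit <- .fit_one(algorithm, .scale_apply(X[tr, , drop = FALSE], sc),
                          y[tr], par)
          pred <- .predict_one(algorithm, fit,
                               .scale_apply(X[te, , drop = FALSE], sc))
          mean(pred$class == y[te])
        }, numeric(1))
      }))
      mean(accs)
    }, numeric(1))
  })
  best <- which.max(cv_acc)
  par <- grid[best, , drop = FALSE]
  sc <- .scale_fit(X)
  fit <- with_seed(seed + 1L,
                   .fit_one(algorithm, .scale_apply(X, sc), y, par,
                            probability = TRUE))
  structure(list(algorithm = algorithm, fit = fit, scaler = sc,
                 chosen_hyperparams = as.list(par[setdiff(names(par), "dummy")]),
                 cv_accuracy = cv_acc[best],
                 cv_table = cbind(grid, cv_accuracy = cv_acc), seed = seed),
            class = "wri_classifier")
}

#' @export
print.wri_classifier <- function(x, ...) {
  hp <- paste(names(x$chosen_hyperparams), unlist(x$chosen_hyperparams),
              sep = "=", collapse = ", ")
  cat(sprintf("<wri_classifier> %s (CV accuracy %.3f)%s\n", x$algorithm,
              x$cv_accuracy, if (nzchar(hp)) paste0(" [", hp, "]") else ""))
  invisible(x)
}

#' AUC by the rank (Mann-Whitney) formulation
#'
#' Equals the probability that a random positive outranks a random negative,
#' counting ties as 1/2; identical to brute-force comparison of all
#' positive/negative pairs.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels Logical or factor; TRUE / `"ASD"` marks the positive class.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "ASD"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("need both classes to compute AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted classifier on a held-out test set
#'
#' ASD is the positive class: sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), accuracy = (TP+TN)/n, AUC by the rank formulation on the
#' class-probability scores (decision values, with a warning, for models
#' without probabilities).
#'
#' @param model A `wri_classifier`.
#' @param test Test data.frame (feature columns + `group`).
#' @return Object of class `classifier_report`: list with `algorithm`,
#'   `sensitivity`, `specificity`, `accuracy`, `auc`, `chosen_hyperparams`,
#'   `seed`, `n_test`.
#' @export
evaluate_classifier <- function(model, test) {
  stopifnot(inherits(model, "wri_classifier"))
  if (!nrow(test)) stop("test set is empty")
  y <- .group_factor(test$group)
  if (nlevels(droplevels(y)) < 2) stop("test set must contain both classes")
  X <- .scale_apply(as.matrix(test[.FEATURE_COLS]), model$scaler)
  pred <- .predict_one(model$algorithm, model$fit, X)
  if (isTRUE(pred$decision_values))
    warning("model lacks probability scores; AUC computed from decision values")
  tp <- sum(pred$class == "ASD" & y == "ASD")
  fn <- sum(pred$class == "TD" & y == "ASD")
  tn <- sum(pred$class == "TD" & y == "TD")
  fp <- sum(pred$class == "ASD" & y == "TD")
  structure(list(algorithm = model$algorithm,
                 sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / length(y),
                 auc = auc_rank(pred$score, y),
                 chosen_hyperparams = model$chosen_hyperparams,
                 seed = model$seed, n_test = length(y)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s: acc %.2f, sens %.2f, spec %.2f, AUC %.3f (n=%d)\n",
              x$algorithm, x$accuracy, x$sensitivity, x$specificity, x$auc,
              x$n_test))
  invisible(x)
}

#' Run the five-algorithm classification benchmark
#'
#' Shared stratified 90/10 split, per-algorithm grid search by repeated
#' stratified 10-fold cross-validation, evaluation on the held-out test set,
#' and (because a single 10% split is high-variance) an additional
#' repeated-split accuracy averaged over `eval_repeats` fresh splits reusing
#' the chosen hyperparameters. Algorithms are ranked by test accuracy, ties
#' broken by AUC.
#'
#' @param features Cohort feature data.frame.
#' @param seed Integer master seed.
#' @param test_frac Held-out fraction (default 0.1).
#' @param algorithms Subset of the five algorithms.
#' @param folds,repeats CV design passed to [tune_and_fit()].
#' @param eval_repeats Number of repeated splits for the averaged accuracy
#'   (0 to skip).
#' @return data.frame of class `wri_benchmark`, one row per algorithm, ranked.
#' @export
run_benchmark <- function(features, seed = 1, test_frac = 0.1,
                          algorithms = .ALGOS, folds = 10, repeats = 10,
                          eval_repeats = 20) {
  if (nrow(features) < 20)
    warning("small sample: ", nrow(features),
            " participants; held-out estimates will be unstable")
  split <- split_train_test(features, test_frac, seed)
  rows <- lapply(seq_along(algorithms), function(i) {
    alg <- algorithms[i]
    model <- tune_and_fit(split$train, alg, seed = seed + 131L * i,
                          folds = folds, repeats = repeats)
    rep <- evaluate_classifier(model, split$test)
    acc_rep <- NA_real_
    if (eval_repeats > 0) {
      accs <- vapply(seq_len(eval_repeats), function(j) {
        sp <- split_train_test(features, test_frac, seed + 977L * j + i)
        X <- as.matrix(sp$train[.FEATURE_COLS])
        y <- .group_factor(sp$train$group)
        sc <- .scale_fit(X)
        fit <- with_seed(seed + j,
                         .fit_one(alg, .scale_apply(X, sc), y,
                                  as.data.frame(model$chosen_hyperparams)))
        pred <- .predict_one(alg, fit,
                             .scale_apply(as.matrix(sp$test[.FEATURE_COLS]), sc))
        mean(pred$class == .group_factor(sp$test$group))
      }, numeric(1))
      acc_rep <- mean(accs)
    }
    data.frame(algorithm = alg, specificity = rep$specificity,
               sensitivity = rep$sensitivity, accuracy = rep$accuracy,
               auc = rep$auc, cv_accuracy = model$cv_accuracy,
               repeated_split_accuracy = acc_rep,
               hyperparams = paste(names(model$chosen_hyperparams),
                                   unlist(model$chosen_hyperparams),
                                   sep = "=", collapse = ";"),
               seed = seed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$accuracy, -out$auc), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("wri_benchmark", "data.frame"))
}
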