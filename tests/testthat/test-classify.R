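test_that("stratified splits have the right sizes and are reproducible", {
  set.seed(20)
  ft <- separable_features(54)   # 108 rows
  s1 <- split_train_test(ft, 0.1, seed = 3)
  s2 <- split_train_test(ft, 0.1, seed = 3)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$test), 10)
  expect_setequal(unique(s1$test$group), c("ASD", "TD"))
  expect_equal(nrow(s1$train) + nrow(s1$test), 108)
  expect_error(split_train_test(ft, 0), "between 0 and 1")
  expect_error(split_train_test(ft[1:2, ], 0.5), "2 participants per class")
})

test_that("rank AUC equals brute-force pairwise AUC", {
  brute <- function(scores, pos) {
    ps <- scores[pos]; ns <- scores[!pos]
    mean(outer(ps, ns, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(auc_rank(c(0.9, 0.8, 0.3, 0.7, 0.2, 0.1),
                        c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)), 8 / 9)
  expect_equal(auc_rank(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc_rank(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)), 0.5)
  set.seed(21)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # force ties
    expect_identical(auc_rank(scores, pos), brute(scores, pos))
  }
})

test_that("separable features give perfect cross-validated accuracy", {
  set.seed(22)
  ft <- separable_features(15)
  for (alg in c("KNN", "LDA", "NB", "SVM", "RF")) {
    m <- tune_and_fit(ft, alg, seed = 5, repeats = 2)
    expect_equal(m$cv_accuracy, 1, tolerance = 1e-9)
  }
})

test_that("permuted labels give chance-level cross-validated accuracy", {
  set.seed(23)
  ft <- separable_features(20)
  accs <- vapply(1:5, function(i) {
    ft$group <- sample(ft$group)
    tune_and_fit(ft, "LDA", seed = i, repeats = 2)$cv_accuracy
  }, numeric(1))
  # 3 sigma of a 40-sample binomial mean around 0.5
  expect_lt(abs(mean(accs) - 0.5), 3 * sqrt(0.25 / 40))
})

test_that("a single-point grid is chosen as-is", {
  set.seed(24)
  ft <- separable_features(10)
  m <- tune_and_fit(ft, "KNN", grid = data.frame(k = 7), seed = 1, repeats = 1)
  expect_equal(m$chosen_hyperparams$k, 7)
})

test_that("reports satisfy the accuracy decomposition and reproduce under a seed", {
  set.seed(25)
  ft <- separable_features(20)
  ft$trt_s <- ft$trt_s + rnorm(40, 0, 6)     # blur to avoid all-1 metrics
  ft$roa_deg <- ft$roa_deg + rnorm(40, 0, 40)
  ft$symmetry <- pmin(pmax(ft$symmetry + rnorm(40, 0, 0.3), 0), 1)
  sp <- split_train_test(ft, 0.25, seed = 2)
  m <- tune_and_fit(sp$train, "NB", seed = 2, repeats = 2)
  r <- evaluate_classifier(m, sp$test)
  prev <- mean(sp$test$group == "ASD")
  expect_equal(r$accuracy,
               r$sensitivity * prev + r$specificity * (1 - prev),
               tolerance = 1e-12)
  b1 <- run_benchmark(ft, seed = 9, repeats = 2, eval_repeats = 2)
  b2 <- run_benchmark(ft, seed = 9, repeats = 2, eval_repeats = 2)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  expect_true(all(b1$auc >= 0 & b1$auc <= 1))
  expect_setequal(b1$algorithm, c("KNN", "LDA", "NB", "SVM", "RF"))
})

test_that("tiny cohorts run with a small-sample warning", {
  set.seed(26)
  ft <- separable_features(4)
  expect_warning(run_benchmark(ft, seed = 1, repeats = 1, eval_repeats = 0),
                 "small sample")
})
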