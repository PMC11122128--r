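separable_table <- function(n = 60, seed = 2) {
  set.seed(seed)
  label <- rep(c(0, 1), each = n / 2)
  list(features = data.frame(a = label * 4 + rnorm(n, sd = 0.2),
                             b = -2 * label + rnorm(n, sd = 0.2)),
       label = label)
}

test_that("stratified folds partition rows and balance classes", {
  labels <- c(rep(1, 50), rep(0, 10))
  fold <- stratified_folds(labels, 5, seed = 3)
  expect_setequal(unique(fold), 1:5)
  for (f in 1:5) {
    expect_equal(sum(fold == f & labels == 1), 10)
    expect_equal(sum(fold == f & labels == 0), 2)
  }
  expect_identical(fold, stratified_folds(labels, 5, seed = 3))
  expect_false(identical(fold, stratified_folds(labels, 5, seed = 4)))
  expect_error(stratified_folds(c(1, 1, 1, 0), 5), "at least n_folds")
})

test_that("undersampling balances classes without touching the minority", {
  labels <- c(rep(1, 40), rep(0, 8))
  keep <- undersample_majority(labels, seed = 1)
  expect_equal(sum(labels[keep] == 1), 8)
  expect_equal(sum(labels[keep] == 0), 8)
  expect_true(all(which(labels == 0) %in% keep))
  expect_identical(keep, undersample_majority(labels, seed = 1))
  balanced <- rep(c(0, 1), 10)
  expect_identical(undersample_majority(balanced, seed = 1), 1:20)
})

test_that("both model kinds separate a linearly separable table", {
  tb <- separable_table()
  fold <- stratified_folds(tb$label, 5, seed = 1)
  te <- which(fold == 1); tr <- which(fold != 1)
  for (kind in c("xgboost", "mlp")) {
    sc <- fit_predict(tb$features[tr, ], tb$label[tr], tb$features[te, ],
                      model = kind, seed = 1, nrounds = 50,
                      xgb_params = list(min_child_weight = 0))
    expect_equal(rank_auroc(tb$label[te], sc), 1.0)
  }
})

test_that("constant features give chance-level AUROC", {
  set.seed(5)
  label <- rep(c(0, 1), each = 20)
  X <- data.frame(c1 = rep(1, 40))
  sc <- fit_predict(X, label, X, model = "xgboost", seed = 1, nrounds = 20)
  expect_equal(rank_auroc(label, sc), 0.5)
})

test_that("feature-column mismatch is rejected", {
  tb <- separable_table()
  expect_error(fit_predict(tb$features, tb$label,
                           setNames(tb$features, c("a", "zz")), "xgboost"),
               "columns differ")
})

test_that("evaluation metrics match direct confusion arithmetic", {
  # scores engineered to yield TP=8 FN=2 FP=3 TN=7 in a single fold
  y <- c(rep(1, 10), rep(0, 10))
  sc <- c(rep(0.9, 8), rep(0.1, 2), rep(0.8, 3), rep(0.2, 7))
  yhat <- as.integer(sc >= 0.5)
  tp <- sum(y == 1 & yhat == 1); fn <- sum(y == 1 & yhat == 0)
  fp <- sum(y == 0 & yhat == 1); tn <- sum(y == 0 & yhat == 0)
  expect_equal(2 * tp / (2 * tp + fn + fp), 0.762, tolerance = 1e-3)
  expect_equal(tp / (tp + fn), 0.8)
  expect_equal(tn / (tn + fp), 0.7)
})

test_that("cross-validated report is reproducible and leakage-free", {
  tb <- separable_table(n = 40)
  frozen <- data.frame(tb$features)
  r1 <- evaluate_cv(tb$features, tb$label, model = "xgboost", seed = 7,
                    nrounds = 30, xgb_params = list(min_child_weight = 0))
  r2 <- evaluate_cv(tb$features, tb$label, model = "xgboost", seed = 7,
                    nrounds = 30, xgb_params = list(min_child_weight = 0))
  expect_identical(r1$summary, r2$summary)
  expect_identical(tb$features, frozen)      # inputs untouched
  expect_true(all(r1$summary$mean >= 0 & r1$summary$mean <= 1))
  expect_gte(r1$summary$mean[r1$summary$metric == "auroc"], 0.9)
  # confusion matrices cover every test row exactly once
  expect_equal(sum(vapply(r1$confusion, sum, numeric(1))), 40)
})

test_that("AUROC is invariant under monotone score transforms", {
  set.seed(9)
  y <- rep(c(0, 1), 25)
  sc <- runif(50)
  expect_equal(rank_auroc(y, sc), rank_auroc(y, qlogis(sc * 0.98 + 0.01)))
})

test_that("comparison grid is deterministic across duplicated datasets", {
  tb <- separable_table(n = 40)
  grid <- compare_datasets(list(one = tb, two = tb), models = "xgboost",
                           seed = 3, nrounds = 30,
                           xgb_params = list(min_child_weight = 0))
  expect_equal(nrow(grid), 2)
  expect_equal(grid$auroc_mean[1], grid$auroc_mean[2])
  expect_equal(grid[1, -1], grid[2, -1], ignore_attr = TRUE)
})
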