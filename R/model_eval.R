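#' Stratified fold assignment
#'
#' Assigns each row to one of `n_folds` test folds so that per-fold class
#' counts differ from proportional allocation by less than one.
#'
#' @param labels binary 0/1 vector.
#' @param n_folds number of folds (default 5).
#' @param seed RNG seed.
#' @return integer vector of fold ids in `1:n_folds`.
#' @export
stratified_folds <- function(labels, n_folds = 5, seed = 1L) {
  stopifnot(n_folds >= 2)
  tab <- table(labels)
  if (any(tab < n_folds))
    stop("each class must have at least n_folds members")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Random undersampling of the majority class
#'
#' Subsamples the majority class without replacement down to the minority
#' count. Applied to training folds only; test folds are never resampled.
#'
#' @param labels binary 0/1 vector (both classes present).
#' @param seed RNG seed.
#' @return integer vector of retained row indices (sorted).
#' @export
undersample_majority <- function(labels, seed = 1L) {
  tab <- table(labels)
  if (length(tab) < 2) stop("both classes must be present")
  if (min(tab) == max(tab)) return(seq_along(labels))  # already balanced
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  keep_min <- which(labels == minority)
  maj <- which(labels == majority)
  keep_maj <- with_seed(seed, sample(maj, min(tab)))
  sort(c(keep_min, keep_maj))
}

#' Fit a classifier and score a test set
#'
#' XGBoost is trained for `nrounds` boosting rounds (default 1000) with the
#' AUC evaluation metric computed on a 20% stratified slice of the training
#' data held out as a validation set (no early stopping); the MLP is a
#' two-layer perceptron (12 ReLU hidden nodes, sigmoid output) trained with
#' binary cross-entropy and Adam. Scores are class-1 probabilities.
#'
#' @param train_x,test_x feature data.frames with identical columns.
#' @param train_y binary 0/1 training labels.
#' @param model `"xgboost"` or `"mlp"`.
#' @param seed RNG seed (validation split, boosting, weight init).
#' @param nrounds boosting rounds for XGBoost.
#' @param epochs,batch MLP training schedule.
#' @param xgb_params named list merged over the default XGBoost parameters
#'   (e.g. `list(min_child_weight = 0)` for very small training sets, where
#'   the default hessian floor blocks all splits).
#' @return numeric vector of test scores in `[0, 1]`.
#' @export
fit_predict <- function(train_x, train_y, test_x, model = c("xgboost", "mlp"),
                        seed = 1L, nrounds = 1000, epochs = 100, batch = 16,
                        xgb_params = list()) {
  model <- match.arg(model)
  if (!identical(colnames(train_x), colnames(test_x)))
    stop("train and test feature columns differ")
  xtr <- as.matrix(train_x)
  xte <- as.matrix(test_x)
  if (model == "mlp") {
    fit <- mlp_fit(xtr, train_y, epochs = epochs, batch = batch, seed = seed)
    return(mlp_predict(fit, xte))
  }
  # stratified 80/20 split of the training fold for the AUC eval set
  val <- with_seed(seed + 1L, unlist(lapply(unique(train_y), function(cl) {
    idx <- which(train_y == cl)
    sample(idx, max(1, round(0.2 * length(idx))))
  })))
  tr <- setdiff(seq_along(train_y), val)
  if (length(unique(train_y[tr])) < 2) tr <- seq_along(train_y)
  dtrain <- xgboost::xgb.DMatrix(xtr[tr, , drop = FALSE],
                                 label = train_y[tr], nthread = 1)
  dval <- xgboost::xgb.DMatrix(xtr[val, , drop = FALSE],
                               label = train_y[val], nthread = 1)
  params <- utils::modifyList(
    list(objective = "binary:logistic", eval_metric = "auc",
         nthread = 1, seed = seed),
    xgb_params)
  booster <- with_seed(seed, xgboost::xgb.train(
    params = params, data = dtrain, nrounds = nrounds,
    evals = list(validation = dval), verbose = 0))
  predict(booster, xgboost::xgb.DMatrix(xte, nthread = 1))
}

# Threshold-free AUROC of class-1 scores against 0/1 labels.
auroc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Cross-validated evaluation of an attentional-state classifier
#'
#' Stratified k-fold cross-validation with optional random undersampling of
#' the training folds. Reports, per class, accuracy (the recall of that
#' class, i.e. the row-normalised diagonal of the confusion matrix at a 0.5
#' decision threshold) and F1 treating that class as positive, plus the
#' threshold-free AUROC, each as mean and SD across folds. Folds whose test
#' set contains a single class are skipped with a warning.
#'
#' @param features feature data.frame.
#' @param label binary 0/1 vector (Focus = 1).
#' @param model `"xgboost"` or `"mlp"`.
#' @param n_folds folds (default 5).
#' @param undersample logical; undersample training folds (default TRUE).
#' @param seed RNG seed for folds, undersampling and model fitting.
#' @param ... passed to [fit_predict()].
#' @return list of class `eval_report`: `summary` (data.frame of mean/sd per
#'   metric), `per_fold`, `confusion` (list of 2x2 matrices), `model`,
#'   `n_folds`, `seed`.
#' @export
evaluate_cv <- function(features, label, model = c("xgboost", "mlp"),
                        n_folds = 5, undersample = TRUE, seed = 1L, ...) {
  model <- match.arg(model)
  stopifnot(nrow(features) == length(label))
  fold <- stratified_folds(label, n_folds, seed = seed)
  rows <- list()
  confusion <- list()
  for (f in seq_len(n_folds)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    if (length(unique(label[te])) < 2) {
      warning(sprintf("fold %d test set has a single class; skipped", f))
      next
    }
    if (undersample) tr <- tr[undersample_majority(label[tr],
                                                   seed = seed + f)]
    sc <- fit_predict(features[tr, , drop = FALSE], label[tr],
                      features[te, , drop = FALSE], model = model,
                      seed = seed + f, ...)
    yhat <- as.integer(sc >= 0.5)
    y <- label[te]
    tp <- sum(y == 1 & yhat == 1); fn <- sum(y == 1 & yhat == 0)
    fp <- sum(y == 0 & yhat == 1); tn <- sum(y == 0 & yhat == 0)
    f1_pos <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    f1_neg <- if (2 * tn + fp + fn > 0) 2 * tn / (2 * tn + fp + fn) else 0
    rows[[length(rows) + 1]] <- data.frame(
      fold = f,
      acc_focus = tp / (tp + fn), f1_focus = f1_pos,
      acc_notfocus = tn / (tn + fp), f1_notfocus = f1_neg,
      auroc = auroc(y, sc))
    confusion[[length(confusion) + 1]] <-
      matrix(c(tp, fn, fp, tn), 2, 2,
             dimnames = list(truth = c("Focus", "notFocus"),
                             pred = c("Focus", "notFocus")))
  }
  if (length(rows) == 0) stop("no evaluable folds")
  per_fold <- do.call(rbind, rows)
  metrics <- setdiff(names(per_fold), "fold")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_fold[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) sd(per_fold[[m]]), numeric(1)),
    row.names = NULL)
  structure(list(summary = summary, per_fold = per_fold,
                 confusion = confusion, model = model, n_folds = n_folds,
                 seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %d-fold stratified CV (seed %d)\n",
              x$model, x$n_folds, x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-13s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Compare feature datasets under identical cross-validation
#'
#' Evaluates each named feature table with each model under the same fold
#' seed and returns a grid of metrics (mean and SD across folds), one row
#' per dataset x model.
#'
#' @param tables named list; each element a list with `features`
#'   (data.frame) and `label` (0/1 vector).
#' @param models character vector of model kinds.
#' @inheritParams evaluate_cv
#' @return data.frame with columns `dataset`, `model`, and
#'   `<metric>_mean` / `<metric>_sd` for the five report metrics.
#' @export
compare_datasets <- function(tables, models = c("xgboost", "mlp"),
                             n_folds = 5, undersample = TRUE, seed = 1L, ...) {
  stopifnot(length(tables) >= 1, !is.null(names(tables)))
  out <- list()
  for (nm in names(tables)) {
    for (md in models) {
      rep <- evaluate_cv(tables[[nm]]$features, tables[[nm]]$label,
                         model = md, n_folds = n_folds,
                         undersample = undersample, seed = seed, ...)
      row <- data.frame(dataset = nm, model = md)
      for (i in seq_len(nrow(rep$summary))) {
        row[[paste0(rep$summary$metric[i], "_mean")]] <- rep$summary$mean[i]
        row[[paste0(rep$summary$metric[i], "_sd")]] <- rep$summary$sd[i]
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}
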