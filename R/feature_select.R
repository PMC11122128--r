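#' OLS coefficient p-values for feature relevance
#'
#' Fits the binary label (0/1) on all features jointly by ordinary least
#' squares with an intercept (a linear probability model) and returns the
#' two-sided p-value of each coefficient's t-statistic with n - q degrees of
#' freedom. Collinear columns (including duplicates) are dropped with a
#' warning and reported as `NA`. With `mode = "univariate"` each feature is
#' tested in its own simple regression instead, for tables with more
#' features than rows.
#'
#' @param features data.frame or matrix of numeric features (rows =
#'   sequences).
#' @param label binary 0/1 vector, one per row.
#' @param mode `"multivariate"` (joint fit, default) or `"univariate"`.
#' @return named numeric vector of p-values (NA for dropped columns).
#' @export
ols_pvalues <- function(features, label,
                        mode = c("multivariate", "univariate")) {
  mode <- match.arg(mode)
  X <- as.matrix(features)
  stopifnot(nrow(X) == length(label), all(label %in% c(0, 1)))
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.numeric(label)
  if (mode == "univariate") {
    return(vapply(seq_len(ncol(X)), function(j) {
      if (var(X[, j]) == 0) return(NA_real_)
      summary(lm(y ~ X[, j]))$coefficients[2, 4]
    }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(X)))
  }
  if (nrow(X) < ncol(X) + 2)
    stop("fewer rows than features + intercept; use mode = \"univariate\"")
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- lm(y ~ ., data = df)
  cf <- coef(fit)[-1]
  if (anyNA(cf))
    warning(sprintf("dropped collinear feature(s): %s",
                    paste(names(cf)[is.na(cf)], collapse = ", ")))
  sm <- summary(fit)$coefficients
  p <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  keep <- intersect(rownames(sm), paste0("`", colnames(X), "`"))
  plain <- intersect(rownames(sm), colnames(X))
  for (nm in plain) p[nm] <- sm[nm, 4]
  for (nm in keep) p[gsub("`", "", nm)] <- sm[nm, 4]
  p
}

#' Eliminate features by OLS p-value threshold
#'
#' Retains exactly the features whose OLS p-value is at most `alpha`
#' (default 0.05) and attaches a significance report with per-class means
#' and standard deviations, the p-value, and significance stars.
#'
#' @inheritParams ols_pvalues
#' @param alpha retention threshold on the p-value.
#' @return list with `features` (reduced data.frame), `label`, `pvalues`,
#'   and `report` (data.frame: feature, mean_focus, sd_focus, mean_notfocus,
#'   sd_notfocus, p_value, stars).
#' @export
eliminate_features <- function(features, label, alpha = 0.05,
                               mode = c("multivariate", "univariate")) {
  p <- ols_pvalues(features, label, mode = match.arg(mode))
  X <- as.data.frame(features)
  report <- data.frame(
    feature = names(p),
    mean_focus = vapply(X, function(v) mean(v[label == 1]), numeric(1)),
    sd_focus = vapply(X, function(v) sd(v[label == 1]), numeric(1)),
    mean_notfocus = vapply(X, function(v) mean(v[label == 0]), numeric(1)),
    sd_notfocus = vapply(X, function(v) sd(v[label == 0]), numeric(1)),
    p_value = unname(p),
    stars = significance_stars(p),
    row.names = NULL)
  keep <- !is.na(p) & p <= alpha
  if (!any(keep)) {
    cond <- simpleError("no feature passed the p-value threshold")
    cond$report <- report
    stop(cond)
  }
  list(features = X[, keep, drop = FALSE], label = label,
       pvalues = p, report = report)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p <= 0.05, "*", ""))))
}
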