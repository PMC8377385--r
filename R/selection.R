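#' Two-sample Student's t prefilter
#'
#' Classic pooled-variance two-sided t-test per feature between the two
#' classes; features with unadjusted p < `alpha` are retained (no
#' multiplicity correction at this stage). Features with zero pooled
#' variance have an undefined statistic and are dropped with a message.
#'
#' @param features A `ks_features` object, or a numeric features x samples
#'   matrix (then `class` is required).
#' @param class Two-level factor of per-sample labels (taken from
#'   `features` when it is a `ks_features`).
#' @param alpha Significance cut-off in (0, 1].
#' @return Character vector of retained feature IDs, with the per-feature
#'   p-values in attribute `"p"`.
#' @export
ttest_prefilter <- function(features, class = NULL, alpha = 0.05) {
  x <- feature_values(features)
  class <- feature_class(features, class)
  if (!(alpha > 0 && alpha <= 1)) stop("`alpha` must be in (0, 1]")
  lv <- levels(class)
  if (length(lv) != 2) stop("exactly two classes required")
  i1 <- class == lv[1]; i2 <- class == lv[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("each class needs >= 2 samples")
  x1 <- x[, i1, drop = FALSE]; x2 <- x[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
  degenerate <- sp2 == 0
  if (any(degenerate))
    message(sum(degenerate),
            " feature(s) with zero pooled variance dropped from prefilter")
  keep <- !degenerate & !is.na(p) & (p < alpha | alpha >= 1)
  ids <- rownames(x)[keep]
  attr(ids, "p") <- p[keep]
  ids
}

#' Pooled pairwise AUC
#'
#' Area under the ROC curve computed as the probability that a positive
#' sample scores above a negative one, with ties counted one half:
#' `AUC = P(s_pos > s_neg) + P(s_pos = s_neg) / 2`. Equivalent to the
#' Mann-Whitney statistic via mid-ranks. Used to score the pooled
#' out-of-fold predictions of [lasso_cv_select()].
#'
#' @param scores Numeric prediction scores (any strictly monotone transform
#'   gives the same AUC).
#' @param labels Two-level factor, or 0/1 vector; the lexically second
#'   level (or 1) is the positive class.
#' @return AUC in \[0, 1\].
#' @export
pooled_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("`scores` and `labels` lengths differ")
  pos <- as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  u <- sort(unique(as.character(labels)))
  if (length(u) != 2) stop("labels must have exactly two levels")
  as.character(labels) == u[2]
}

#' L1-penalized logistic feature selection with cross-validated penalty
#'
#' Fits a binomial LASSO path with stratified k-fold cross-validation, picks
#' the penalty by minimum cross-validated deviance (or the one-standard-error
#' rule), pools the out-of-fold linear predictors across folds into a single
#' ROC to report an honest classification AUC, then refits on all samples at
#' the chosen penalty and returns the features with non-zero coefficients.
#'
#' @param features A `ks_features` object or features x samples matrix,
#'   typically already restricted to prefilter survivors.
#' @param class Two-level factor (taken from `features` when possible).
#' @param n_folds Number of cross-validation folds (>= 2), stratified by
#'   class so every fold contains both classes.
#' @param seed Integer seed controlling the fold assignment.
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @return List with `selected` (data frame: feature_id, coefficient on the
#'   original feature scale), `oof_auc`, `lambda`, `foldid`, `seed`.
#' @export
lasso_cv_select <- function(features, class = NULL, n_folds = 5, seed = 1,
                            lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  x <- feature_values(features)
  class <- feature_class(features, class)
  if (nrow(x) < 1) stop("no features to select from")
  if (n_folds < 2) stop("`n_folds` must be >= 2")
  y <- factor(class)
  if (nlevels(y) != 2) stop("exactly two classes required")
  foldid <- stratified_folds(y, n_folds, seed)
  xt <- t(x)
  cvfit <- glmnet::cv.glmnet(xt, y, family = "binomial",
                             type.measure = "deviance",
                             foldid = foldid, keep = TRUE,
                             standardize = TRUE)
  lambda <- if (lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  li <- which.min(abs(cvfit$lambda - lambda))
  oof <- cvfit$fit.preval[, li]
  oof_auc <- pooled_auc(oof, y)
  cf <- as.matrix(stats::coef(cvfit, s = lambda))
  cf <- cf[rownames(cf) != "(Intercept)", 1]
  nz <- cf[cf != 0]
  list(selected = data.frame(feature_id = names(nz), coefficient = unname(nz),
                             stringsAsFactors = FALSE),
       oof_auc = oof_auc, lambda = lambda, foldid = foldid, seed = seed)
}

#' Differential feature selection: t prefilter then LASSO
#'
#' The full selection stage: [ttest_prefilter()] on all features, then
#' [lasso_cv_select()] on the survivors. The prefilter is applied once on
#' the full cohort before cross-validation (which optimistically biases the
#' out-of-fold AUC; see the methods vignette).
#'
#' @inheritParams lasso_cv_select
#' @param alpha Prefilter cut-off.
#' @return An object of class `ks_selection`: list with
#'   `prefilter_survivors`, `selected` (feature_id, type, kinase, substrate,
#'   coefficient, prefilter_p), `oof_auc`, `lambda`, `foldid`, `seed`.
#' @export
select_features <- function(features, class = NULL, alpha = 0.05,
                            n_folds = 5, seed = 1,
                            lambda_rule = c("min", "1se")) {
  x <- feature_values(features)
  class <- feature_class(features, class)
  survivors <- ttest_prefilter(x, class, alpha = alpha)
  if (!length(survivors))
    stop("no feature passed the t-test prefilter at alpha = ", alpha)
  p <- stats::setNames(attr(survivors, "p"), survivors)
  fit <- lasso_cv_select(x[survivors, , drop = FALSE], class,
                         n_folds = n_folds, seed = seed,
                         lambda_rule = match.arg(lambda_rule))
  sel <- fit$selected
  sel$prefilter_p <- unname(p[sel$feature_id])
  if (inherits(features, "ks_features")) {
    idx <- match(sel$feature_id, features$info$feature_id)
    sel$type <- features$info$type[idx]
    sel$kinase <- features$info$kinase[idx]
    sel$substrate <- features$info$substrate[idx]
  } else {
    sel$type <- ifelse(grepl("-", sel$feature_id, fixed = TRUE),
                       "edge", "node")
    sel$kinase <- NA_character_
    sel$substrate <- NA_character_
  }
  sel <- sel[, c("feature_id", "type", "kinase", "substrate",
                 "coefficient", "prefilter_p")]
  structure(list(prefilter_survivors = as.character(survivors),
                 selected = sel, oof_auc = fit$oof_auc,
                 lambda = fit$lambda, foldid = fit$foldid, seed = seed),
            class = "ks_selection")
}

#' @export
print.ks_selection <- function(x, ...) {
  cat(sprintf(
    "ks_selection: %d prefilter survivor(s), %d selected (%d node, %d edge)\n",
    length(x$prefilter_survivors), nrow(x$selected),
    sum(x$selected$type == "node"), sum(x$selected$type == "edge")))
  cat(sprintf("pooled out-of-fold AUC = %.3f at lambda = %.4g\n",
              x$oof_auc, x$lambda))
  invisible(x)
}

# Seeded class-stratified fold assignment: within each class, samples are
# permuted and dealt round-robin into folds, so every fold holds both
# classes whenever n_k >= n_folds.
stratified_folds <- function(y, n_folds, seed) {
  foldid <- integer(length(y))
  withr::with_seed(seed, {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  if (any(tabulate(foldid, n_folds) == 0))
    stop("empty fold; reduce `n_folds`")
  foldid
}

# Accept either a ks_features or a plain matrix.
feature_values <- function(features) {
  if (inherits(features, "ks_features")) features$values
  else if (is.matrix(features) && is.numeric(features)) features
  else stop("`features` must be a ks_features or numeric matrix")
}

feature_class <- function(features, class) {
  if (is.null(class)) {
    if (!inherits(features, "ks_features"))
      stop("`class` is required when `features` is a plain matrix")
    class <- features$class
  }
  cls <- factor(as.character(class), levels = sort(unique(as.character(class))))
  cls
}
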