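#' Harrell's concordance index
#'
#' Fraction of comparable sample pairs in which the sample with the higher
#' risk score fails first; a pair is comparable when the earlier observed
#' time is an event, and risk-score ties count one half.
#'
#' @param risk Numeric risk scores (higher = predicted earlier failure).
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @return C-index in \[0, 1\]; 0.5 is chance level.
#' @export
harrell_cindex <- function(risk, time, event) {
  if (!any(event == 1)) stop("no events: C-index undefined")
  fit <- survival::concordance(
    survival::Surv(time, event) ~ risk, reverse = TRUE)
  unname(fit$concordance)
}

#' Repeated random-split survival-forest concordance
#'
#' Monte-Carlo cross-validation of prognostic model variants: for each of
#' `n_iter` seeded random train/test splits, a random survival forest is
#' fitted per variant on the training partition and Harrell's C-index of its
#' predicted risk (ensemble cumulative hazard) is computed on the test
#' partition. All variants are evaluated on the identical split sequence, so
#' their C-index distributions are directly comparable.
#'
#' In `mode = "cv-safe"` (requires `expression` and `network`) the node
#' scaling and the class-conditional edge parameters are recomputed from the
#' training samples of every split and applied to the test samples of the
#' same class, so no test information leaks into feature construction.
#' `mode = "paper"` uses the feature matrix as given (full-cohort
#' parameters).
#'
#' @param clinical Data frame with `sample_id`, `time`, `event`, and any
#'   covariate columns named by the variants.
#' @param variants Named list; each element is a list with character fields
#'   `features` (feature IDs, possibly empty) and `covariates` (clinical
#'   column names, possibly empty).
#' @param features `ks_features` or features x samples matrix (required for
#'   `mode = "paper"`, and used for feature IDs in both modes).
#' @param expression A [ks_expr()] on the analysis scale (cv-safe mode).
#' @param network A [ks_network()] (cv-safe mode).
#' @param mode `"paper"` or `"cv-safe"`.
#' @param n_iter Number of random splits.
#' @param train_fraction Fraction of samples used for training, in (0, 1).
#' @param seed Integer; every split and forest is seeded from it.
#' @param num_trees,min_node_size Random survival forest size controls
#'   (log-rank splitting).
#' @return An `n_iter` x `length(variants)` matrix of C-indexes (class
#'   `ks_cindex`) with attributes `train_fraction` and `split_seeds`.
#' @export
mc_cv_cindex <- function(clinical, variants, features = NULL,
                         expression = NULL, network = NULL,
                         mode = c("paper", "cv-safe"),
                         n_iter = 100, train_fraction = 0.8, seed = 1,
                         num_trees = 1000, min_node_size = 15) {
  mode <- match.arg(mode)
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("`train_fraction` must be in (0, 1)")
  need <- setdiff(c("sample_id", "time", "event"), names(clinical))
  if (length(need))
    stop("clinical table lacks column(s): ", paste(need, collapse = ", "))
  if (anyDuplicated(clinical$sample_id))
    stop("duplicate sample IDs in clinical table")
  if (any(clinical$time <= 0) || !all(clinical$event %in% c(0, 1)))
    stop("times must be positive and events 0/1")
  if (!any(clinical$event == 1)) stop("cohort contains no events")
  if (mode == "cv-safe" && (is.null(expression) || is.null(network)))
    stop("cv-safe mode requires `expression` and `network`")
  if (mode == "paper" && is.null(features))
    stop("paper mode requires `features`")
  fmat <- if (!is.null(features)) feature_values(features) else NULL
  if (!is.null(fmat)) {
    miss <- setdiff(clinical$sample_id, colnames(fmat))
    if (length(miss)) stop("feature matrix lacks sample(s): ",
                           paste(miss, collapse = ", "))
    fmat <- fmat[, clinical$sample_id, drop = FALSE]
  }
  if (!is.null(expression))
    expression <- ks_expr(expression$values[, clinical$sample_id,
                                            drop = FALSE],
                          expression$class[clinical$sample_id])
  for (vn in names(variants)) {
    v <- variants[[vn]]
    bad_cov <- setdiff(v$covariates, names(clinical))
    if (length(bad_cov))
      stop("variant `", vn, "` references unknown covariate(s): ",
           paste(bad_cov, collapse = ", "))
    if (length(v$features) && mode == "paper") {
      bad_f <- setdiff(v$features, rownames(fmat))
      if (length(bad_f))
        stop("variant `", vn, "` references unknown feature(s): ",
             paste(bad_f, collapse = ", "))
    }
    if (!length(v$features) && !length(v$covariates))
      stop("variant `", vn, "` is empty")
  }

  n <- nrow(clinical)
  n_train <- max(2L, round(train_fraction * n))
  if (n_train >= n) stop("train fraction leaves no test samples")
  split_seeds <- withr::with_seed(seed,
                                  sample.int(.Machine$integer.max - 1L,
                                             n_iter))
  res <- matrix(NA_real_, n_iter, length(variants),
                dimnames = list(NULL, names(variants)))

  for (it in seq_len(n_iter)) {
    tr <- withr::with_seed(split_seeds[it], {
      repeat {
        idx <- sample.int(n, n_train)
        if (any(clinical$event[idx] == 1) &&
            any(clinical$event[-idx] == 1)) break
        message("split ", it, " resampled: a partition had no events")
      }
      idx
    })
    fmat_it <- if (mode == "cv-safe")
      split_features(expression, network, tr)
    else fmat
    for (vi in seq_along(variants)) {
      v <- variants[[vi]]
      df <- variant_frame(clinical, fmat_it, v)
      fit <- ranger::ranger(
        data = df[tr, , drop = FALSE],
        dependent.variable.name = "time",
        status.variable.name = "event",
        num.trees = num_trees, min.node.size = min_node_size,
        splitrule = "logrank", seed = split_seeds[it], num.threads = 1)
      pred <- stats::predict(fit, data = df[-tr, , drop = FALSE],
                             num.threads = 1)
      risk <- rowSums(pred$chf)
      res[it, vi] <- harrell_cindex(risk, clinical$time[-tr],
                                    clinical$event[-tr])
    }
  }
  structure(res, train_fraction = train_fraction,
            split_seeds = split_seeds, class = c("ks_cindex", "matrix"))
}

# Assemble the model frame for one variant: time, event, requested feature
# rows (transposed; syntactic column names) and clinical covariates.
variant_frame <- function(clinical, fmat, v) {
  df <- data.frame(time = clinical$time, event = clinical$event)
  if (length(v$features)) {
    bad <- setdiff(v$features, rownames(fmat))
    if (length(bad))
      stop("feature(s) unavailable in this split: ",
           paste(bad, collapse = ", "))
    x <- t(fmat[v$features, , drop = FALSE])
    colnames(x) <- make.names(colnames(x))
    df <- cbind(df, as.data.frame(x))
  }
  for (cv in v$covariates) {
    col <- clinical[[cv]]
    if (is.character(col)) col <- factor(col)
    df[[make.names(cv)]] <- col
  }
  df
}

# Train-only feature construction for one split: pooled z-scaling and
# class-conditional edge parameters from training samples, applied to all.
split_features <- function(expression, network, train_idx) {
  tr_expr <- ks_expr(expression$values[, train_idx, drop = FALSE],
                     droplevels(expression$class[train_idx]))
  mu <- rowMeans(tr_expr$values)
  sdv <- sqrt(rowSums((tr_expr$values - mu)^2) / ncol(tr_expr$values))
  keep <- sdv > 0
  scaled <- ks_expr((expression$values[keep, , drop = FALSE] - mu[keep]) /
                      sdv[keep], expression$class)
  params <- class_params(ks_expr(tr_expr$values[keep, , drop = FALSE],
                                 tr_expr$class))
  net <- network[network$kinase %in% rownames(scaled$values) &
                   network$substrate %in% rownames(scaled$values), ,
                 drop = FALSE]
  class(net) <- c("ks_network", "data.frame")
  suppressMessages(edge_transform(scaled, net, params = params))$values
}

#' Pairwise rank-sum comparison of C-index distributions
#'
#' Two-sided Wilcoxon rank-sum test for every pair of model variants
#' evaluated by [mc_cv_cindex()]. The exact distribution is used for small
#' samples without ties; otherwise the normal approximation with tie
#' correction (and no continuity correction, so identical distributions give
#' p = 1) is applied — the switch follows [stats::wilcox.test()] at n = 50.
#'
#' @param cindex Matrix of C-indexes (iterations x variants) or
#'   `ks_cindex`.
#' @return Symmetric matrix of two-sided p-values (diagonal NA).
#' @export
compare_variants <- function(cindex) {
  m <- as.matrix(cindex)
  if (is.null(colnames(m)) || ncol(m) < 2)
    stop("need >= 2 named variants")
  if (nrow(m) == 0) stop("empty C-index lists")
  k <- ncol(m)
  p <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    pv <- suppressWarnings(
      stats::wilcox.test(m[, i], m[, j], alternative = "two.sided",
                         correct = FALSE)$p.value)
    p[i, j] <- p[j, i] <- pv
  }
  p
}

#' Cox proportional-hazards fits with hazard ratios
#'
#' Univariate (one model per column) or multivariate (single joint model)
#' Cox regression via the partial likelihood with Efron tie handling.
#' Reports HR = exp(beta), Wald 95% CI and two-sided Wald p per term.
#' Character covariates are coded as factors with the most frequent level
#' as reference. Monotone-likelihood non-convergence is flagged, not
#' silently returned.
#'
#' @param covariates Data frame (samples x variables) or single numeric
#'   vector.
#' @param time,event Survival outcome.
#' @param multivariate Fit one joint model (`TRUE`) or one model per
#'   variable (`FALSE`, default).
#' @return Data frame: term, beta, se, hr, ci_low, ci_high, p, model,
#'   converged.
#' @export
cox_fit <- function(covariates, time, event, multivariate = FALSE) {
  if (is.atomic(covariates))
    covariates <- data.frame(x = covariates)
  if (!any(event == 1)) stop("no events: Cox model undefined")
  for (nm in names(covariates)) {
    col <- covariates[[nm]]
    if (length(unique(col)) < 2)
      stop("constant covariate: ", nm)
    if (is.character(col) || is.factor(col)) {
      col <- factor(col)
      ref <- names(which.max(table(col)))
      covariates[[nm]] <- stats::relevel(col, ref = ref)
    }
  }
  fit_one <- function(df, label) {
    df2 <- cbind(data.frame(.time = time, .event = event), df)
    converged <- TRUE
    fit <- withCallingHandlers(
      survival::coxph(survival::Surv(.time, .event) ~ ., data = df2),
      warning = function(w) {
        if (grepl("infinite|converge|beta may be infinite", conditionMessage(w)))
          converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), beta = s[, "coef"],
               se = s[, "se(coef)"], hr = exp(s[, "coef"]),
               ci_low = exp(s[, "coef"] - 1.96 * s[, "se(coef)"]),
               ci_high = exp(s[, "coef"] + 1.96 * s[, "se(coef)"]),
               p = s[, "Pr(>|z|)"], model = label,
               converged = converged, row.names = NULL,
               stringsAsFactors = FALSE)
  }
  if (multivariate) {
    fit_one(covariates, "multivariate")
  } else {
    do.call(rbind, lapply(names(covariates), function(nm)
      fit_one(covariates[, nm, drop = FALSE], "univariate")))
  }
}

#' Median-split Kaplan-Meier stratification with log-rank test
#'
#' Dichotomizes a continuous feature at its cohort median (values <= median
#' are "low", the rest "high"; the median of an even cohort is the usual
#' interpolated midpoint), builds the product-limit survival curve per
#' group, and tests the difference with the two-sided log-rank test.
#'
#' @param values Numeric per-sample feature values (node expression or edge
#'   values).
#' @param time,event Survival outcome, aligned with `values`.
#' @return An object of class `ks_km`: list with `median`, `groups`
#'   (factor low/high), `chisq`, `p`, and `curves` (data frame: group,
#'   time, n_risk, n_event, surv).
#' @export
km_median_split <- function(values, time, event) {
  if (length(unique(values)) < 2)
    stop("all feature values identical: median split is degenerate")
  med <- stats::median(values)
  groups <- factor(ifelse(values <= med, "low", "high"),
                   levels = c("low", "high"))
  if (any(table(groups) < 2))
    stop("median split leaves a group with < 2 samples")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ groups)
  chisq <- unname(sd_$chisq)
  p <- stats::pchisq(chisq, df = length(sd_$n) - 1, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ groups)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(group = sub("^groups=", "", strata),
                       time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, surv = sf$surv,
                       stringsAsFactors = FALSE)
  structure(list(median = med, groups = groups, chisq = chisq, p = p,
                 curves = curves),
            class = "ks_km")
}

#' @export
print.ks_km <- function(x, ...) {
  cat(sprintf("ks_km: median split at %.4g (low n=%d, high n=%d)\n",
              x$median, sum(x$groups == "low"), sum(x$groups == "high")))
  cat(sprintf("log-rank chi-squared = %.3f, p = %.4g\n", x$chisq, x$p))
  invisible(x)
}

#' Pearson chi-squared test on a contingency table
#'
#' Without continuity correction, as used for clinicopathological
#' count tables. A zero row or column marginal makes expected counts
#' degenerate and is rejected.
#'
#' @param counts 2-D matrix or table of non-negative counts.
#' @return List with `statistic`, `df`, `p`.
#' @export
chisq_table <- function(counts) {
  counts <- as.matrix(counts)
  if (length(dim(counts)) != 2 || nrow(counts) < 2 || ncol(counts) < 2)
    stop("`counts` must be a 2-D table with >= 2 rows and columns")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column marginal")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
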