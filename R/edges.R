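#' Log2-transform and gene-level z-scoring
#'
#' Per gene, across all samples pooled (both classes together):
#' `x -> (log2(x + pseudocount) - mean) / sd`, with the uncorrected
#' (divide-by-n) standard deviation, the same convention the edge transform
#' uses within classes. Genes with zero pooled variance carry no information
#' and are dropped with a message. The log step can be disabled for input
#' that is already on a continuous scale.
#'
#' @param expr A [ks_expr()] or numeric matrix (genes x samples).
#' @param pseudocount Added before the log to guard zeros; ignored when
#'   `log2 = FALSE`.
#' @param log2 Apply the log2 step (requires non-negative input).
#' @return Same type as the input, rows restricted to non-constant genes,
#'   each row with pooled mean 0 and unit uncorrected sd.
#' @export
log2_zscore <- function(expr, pseudocount = 1, log2 = TRUE) {
  is_ks <- inherits(expr, "ks_expr")
  values <- if (is_ks) expr$values else expr
  if (!is.matrix(values) || !is.numeric(values))
    stop("`expr` must be a numeric matrix or ks_expr")
  if (log2) {
    if (any(values < 0))
      stop("negative values are incompatible with the log2 step; ",
           "use log2 = FALSE for pre-transformed input")
    values <- base::log2(values + pseudocount)
  }
  mu <- rowMeans(values)
  sdv <- sqrt(rowSums((values - mu)^2) / ncol(values))
  keep <- sdv > 0
  if (any(!keep))
    message(sum(!keep), " zero-variance gene(s) dropped during z-scoring")
  values <- (values[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  if (is_ks) ks_expr(values, expr$class) else values
}

#' Within-class mean and uncorrected standard deviation per gene
#'
#' For each gene and each class k, computes the plain arithmetic mean
#' `mu = (1/n_k) * sum(x)` and the uncorrected (divide-by-n) standard
#' deviation `sigma = sqrt((1/n_k) * sum((x - mu)^2))`. These are the
#' class-conditional standardization parameters used by [edge_transform()].
#'
#' @param expr A [ks_expr()]. Every class must contain at least two samples.
#' @return An object of class `ks_class_params`: list with `mu` and `sigma`
#'   (genes x classes matrices), `n` (named class sizes), and `levels`.
#'   Convert with [as.data.frame()] for a long (gene, class, mu, sigma, n)
#'   table.
#' @export
class_params <- function(expr) {
  stopifnot(inherits(expr, "ks_expr"))
  lv <- levels(expr$class)
  n_k <- table(expr$class)
  if (any(n_k < 2))
    stop("class(es) with < 2 samples: ",
         paste(names(n_k)[n_k < 2], collapse = ", "))
  dn <- list(rownames(expr$values), lv)
  mu <- matrix(unlist(lapply(lv, function(k)
    rowMeans(expr$values[, expr$class == k, drop = FALSE]))),
    nrow = nrow(expr$values), dimnames = dn)
  sigma <- matrix(unlist(lapply(lv, function(k) {
    x <- expr$values[, expr$class == k, drop = FALSE]
    sqrt(rowSums((x - mu[, k])^2) / ncol(x))
  })), nrow = nrow(expr$values), dimnames = dn)
  structure(list(mu = mu, sigma = sigma,
                 n = stats::setNames(as.integer(n_k), names(n_k)),
                 levels = lv),
            class = "ks_class_params")
}

#' @export
as.data.frame.ks_class_params <- function(x, ...) {
  do.call(rbind, lapply(x$levels, function(k)
    data.frame(gene = rownames(x$mu), class = k, mu = x$mu[, k],
               sigma = x$sigma[, k], n = x$n[[k]], row.names = NULL)))
}

#' @export
print.ks_class_params <- function(x, ...) {
  cat(sprintf("ks_class_params: %d genes, classes %s\n", nrow(x$mu),
              paste(sprintf("%s (n=%d)", x$levels, x$n), collapse = ", ")))
  invisible(x)
}

#' Kinase-substrate edge feature construction
#'
#' The central transform: for kinase u, substrate v, sample j of class k,
#' `edge<u-v> = ((x_u - mu_{u,k}) / sigma_{u,k}) * ((x_v - mu_{v,k}) / sigma_{v,k})`,
#' i.e. the product of the two class-conditionally standardized values.
#' Averaging an edge feature over the samples of one class recovers exactly
#' the within-class Pearson correlation (uncorrected-sigma form) of the
#' pair.
#'
#' The returned feature table stacks node features (the expression rows of
#' `expr`, typically pooled gene-level z-scores) on top of one edge row per
#' network pair. Pairs involving a gene with zero within-class variance in
#' either class are excluded with a message, since their z-scores are
#' undefined.
#'
#' @param expr A [ks_expr()] on the analysis scale (see [log2_zscore()]).
#' @param net A [ks_network()]; both genes of every retained pair must be
#'   rows of `expr`.
#' @param params Class-conditional standardization parameters. Defaults to
#'   [class_params()] of `expr` itself; pass parameters computed on training
#'   samples only to avoid train/test leakage inside cross-validation.
#' @return An object of class `ks_features`: list with `values` (features x
#'   samples matrix; node rows then edge rows named `"KINASE-SUBSTRATE"`),
#'   `class` (the sample class factor), `info` (data frame: feature_id,
#'   type node/edge, kinase, substrate), and `provenance` (`"full"` or
#'   `"train"` depending on whether `params` was supplied).
#' @export
edge_transform <- function(expr, net, params = NULL) {
  stopifnot(inherits(expr, "ks_expr"))
  genes <- unique(c(net$kinase, net$substrate))
  absent <- setdiff(genes, rownames(expr$values))
  if (length(absent))
    stop("network gene(s) absent from expression: ",
         paste(absent, collapse = ", "))
  provenance <- if (is.null(params)) "full" else "train"
  if (is.null(params)) params <- class_params(expr)
  absent_p <- setdiff(genes, rownames(params$mu))
  if (length(absent_p))
    stop("class parameters missing for gene(s): ",
         paste(absent_p, collapse = ", "))
  if (!identical(params$levels, levels(expr$class)))
    stop("class parameter levels do not match expression classes")

  zero_sd <- rownames(params$sigma)[apply(params$sigma == 0, 1, any)]
  keep <- !(net$kinase %in% zero_sd) & !(net$substrate %in% zero_sd)
  if (any(!keep))
    message(sum(!keep),
            " pair(s) excluded (zero within-class variance in a gene)")
  net_kept <- net[keep, , drop = FALSE]
  if (!nrow(net_kept)) stop("no network pairs usable for edge construction")

  z <- expr$values
  for (k in params$levels) {
    idx <- expr$class == k
    z[, idx] <- (expr$values[, idx, drop = FALSE] -
                   params$mu[rownames(z), k]) /
      params$sigma[rownames(z), k]
  }

  edge_vals <- z[net_kept$kinase, , drop = FALSE] *
    z[net_kept$substrate, , drop = FALSE]
  rownames(edge_vals) <- paste(net_kept$kinase, net_kept$substrate,
                               sep = "-")
  values <- rbind(expr$values, edge_vals)
  if (anyDuplicated(rownames(values)))
    stop("feature ID collision between node and edge features: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  info <- data.frame(
    feature_id = rownames(values),
    type = c(rep("node", nrow(expr$values)), rep("edge", nrow(edge_vals))),
    kinase = c(rep(NA_character_, nrow(expr$values)), net_kept$kinase),
    substrate = c(rep(NA_character_, nrow(expr$values)), net_kept$substrate),
    stringsAsFactors = FALSE)
  structure(list(values = values, class = expr$class, info = info,
                 provenance = provenance),
            class = "ks_features")
}

#' @export
print.ks_features <- function(x, ...) {
  cat(sprintf("ks_features: %d node + %d edge features x %d samples (%s params)\n",
              sum(x$info$type == "node"), sum(x$info$type == "edge"),
              ncol(x$values), x$provenance))
  invisible(x)
}

#' Write an edge/node feature table as TSV
#' @param features A `ks_features` object from [edge_transform()].
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  write_expression(features$values, path, id_col = "feature_id")
}
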