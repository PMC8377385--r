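#' Expression matrix with per-sample class labels
#'
#' Lightweight container for a genes x samples expression matrix together
#' with a two-level (or, transiently, one-level) class factor indexed by
#' sample. Class levels are ordered lexically; the first level plays the role
#' of class 1 and the second of class 2 throughout the package.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames). All values must be finite.
#' @param class Factor or character vector of per-sample class labels, either
#'   unnamed and in column order or named by sample ID.
#' @return An object of class `ks_expr`: a list with elements `values`
#'   (the matrix) and `class` (a factor named by sample ID, lexically ordered
#'   levels).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' e <- ks_expr(m, rep(c("neg", "pos"), each = 2))
#' e
#' @export
ks_expr <- function(values, class) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!all(is.finite(values)))
    stop("`values` contains non-finite entries")
  cls <- as.character(class)
  if (!is.null(names(cls))) {
    missing <- setdiff(colnames(values), names(cls))
    if (length(missing))
      stop("class labels missing for samples: ",
           paste(missing, collapse = ", "))
    cls <- cls[colnames(values)]
  } else if (length(cls) != ncol(values)) {
    stop("`class` must have one label per sample")
  }
  if (anyNA(cls)) stop("class labels contain NA")
  cls <- factor(cls, levels = sort(unique(cls)))
  names(cls) <- colnames(values)
  structure(list(values = values, class = cls), class = "ks_expr")
}

#' @export
print.ks_expr <- function(x, ...) {
  cat(sprintf("ks_expr: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$class)
  cat("classes:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ks_expr <- function(x) dim(x$values)

#' Kinase-substrate interaction network
#'
#' Ordered list of directed kinase -> substrate gene-symbol pairs. Duplicate
#' pairs are removed (with a message); self-pairs (kinase == substrate) are
#' retained but flagged, since the edge transform is well defined for them.
#'
#' @param kinase,substrate Character vectors of equal length with non-empty
#'   gene symbols. Matching is by exact, case-sensitive symbol.
#' @return A data frame of class `ks_network` with columns `kinase` and
#'   `substrate`.
#' @examples
#' ks_network(c("SRC", "BUB1"), c("OCLN", "CDC20"))
#' @export
ks_network <- function(kinase, substrate) {
  kinase <- as.character(kinase)
  substrate <- as.character(substrate)
  if (length(kinase) != length(substrate))
    stop("`kinase` and `substrate` must have equal length")
  if (length(kinase) && (anyNA(kinase) || anyNA(substrate) ||
                         any(!nzchar(kinase)) || any(!nzchar(substrate))))
    stop("gene symbols must be non-empty and non-NA")
  key <- paste(kinase, substrate, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    message(sum(dup), " duplicate pair(s) dropped from network")
  net <- data.frame(kinase = kinase[!dup], substrate = substrate[!dup],
                    stringsAsFactors = FALSE)
  n_self <- sum(net$kinase == net$substrate)
  if (n_self) message(n_self, " self-pair(s) (kinase == substrate) retained")
  class(net) <- c("ks_network", "data.frame")
  net
}

#' Genes covered by a network
#'
#' @param net A [ks_network()].
#' @return Character vector of unique gene symbols (kinases then substrates,
#'   first-appearance order).
#' @export
network_genes <- function(net) {
  unique(c(net$kinase, net$substrate))
}

#' Edge feature identifiers of a network
#'
#' Edge features are identified as `"KINASE-SUBSTRATE"` with an ASCII hyphen.
#'
#' @param net A [ks_network()].
#' @return Character vector, one ID per pair, in network order.
#' @export
edge_ids <- function(net) {
  paste(net$kinase, net$substrate, sep = "-")
}

# Validate a clinical table: unique sample IDs, positive times, binary
# events, a class column with (by default) exactly two levels.
validate_clinical <- function(clinical, class_col = "class",
                              require_survival = TRUE) {
  if (!is.data.frame(clinical)) stop("clinical table must be a data frame")
  need <- c("sample_id", class_col, if (require_survival) c("time", "event"))
  missing <- setdiff(need, names(clinical))
  if (length(missing))
    stop("clinical table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(clinical$sample_id))
    stop("duplicate sample IDs in clinical table")
  if (require_survival) {
    if (anyNA(clinical$time) || any(clinical$time <= 0))
      stop("survival times must be positive and non-missing")
    if (!all(clinical$event %in% c(0, 1)))
      stop("event indicator must be 0/1")
  }
  lv <- sort(unique(as.character(clinical[[class_col]])))
  if (length(lv) != 2)
    stop("class column `", class_col, "` must have exactly two levels, got ",
         length(lv))
  invisible(clinical)
}
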