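#' Gene symbols covered by a feature selection
#'
#' Node features contribute their own gene; edge features contribute both
#' endpoint genes. The union is deduplicated.
#'
#' @param selection A `ks_selection` from [select_features()], its
#'   `selected` data frame, or a character vector of feature IDs (edge IDs
#'   are then split on the ASCII hyphen).
#' @return Character vector of unique gene symbols (may be empty).
#' @export
feature_genes <- function(selection) {
  if (inherits(selection, "ks_selection")) selection <- selection$selected
  if (is.data.frame(selection)) {
    node <- selection$feature_id[selection$type == "node"]
    kin <- selection$kinase[selection$type == "edge"]
    sub <- selection$substrate[selection$type == "edge"]
    if (anyNA(c(kin, sub))) {
      ids <- selection$feature_id[selection$type == "edge"]
      parts <- strsplit(ids, "-", fixed = TRUE)
      kin <- vapply(parts, `[[`, "", 1L)
      sub <- vapply(parts, function(p) paste(p[-1], collapse = "-"), "")
    }
    return(unique(c(node, kin, sub)))
  }
  ids <- as.character(selection)
  if (!length(ids)) return(character())
  parts <- strsplit(ids, "-", fixed = TRUE)
  unique(unlist(parts))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values, capped at 1, returned in
#' the original order. Thin validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' For every gene set, tests whether the selected genes overlap it more than
#' expected by chance: upper-tail p = P(X >= k) with
#' X ~ Hypergeometric(N, K, n), where N is the universe size, K the set size
#' within the universe, n the number of selected genes, and k the overlap.
#' P-values are Benjamini-Hochberg adjusted across all tested sets.
#'
#' @param selected Character vector of selected gene symbols (must be a
#'   subset of `universe`; symbols outside it are dropped with a message).
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#'   Each set is intersected with the universe before testing.
#' @param universe Character vector defining the background, e.g. all
#'   network genes present in the expression matrix.
#' @param alpha Significance threshold applied to the adjusted p-values
#'   (`use_adjusted = FALSE` applies it to raw p instead).
#' @param use_adjusted Flag significance on adjusted (default) or raw p.
#' @return Data frame sorted by adjusted p: set, k (overlap), K (set size),
#'   n (selected size), N (universe size), p, p_adjusted, significant,
#'   overlap (semicolon-joined symbols).
#' @export
hypergeom_enrich <- function(selected, gene_sets, universe,
                             alpha = 0.05, use_adjusted = TRUE) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  if (!length(gene_sets)) stop("no gene sets supplied")
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets))))
    stop("gene sets must be named")
  selected <- unique(as.character(selected))
  outside <- setdiff(selected, universe)
  if (length(outside)) {
    message(length(outside), " selected gene(s) outside the universe dropped")
    selected <- intersect(selected, universe)
  }
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    hits <- intersect(selected, set)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               overlap = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- bh_adjust(res$p)
  res$significant <- (if (use_adjusted) res$p_adjusted else res$p) < alpha
  res <- res[order(res$p_adjusted, res$p, res$set),
             c("set", "k", "K", "n", "N", "p", "p_adjusted",
               "significant", "overlap")]
  rownames(res) <- NULL
  res
}
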