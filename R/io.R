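#' Read a gene x sample expression table
#'
#' Expects a tab-separated file with a header row of sample IDs and gene
#' symbols in the first column. Missing or non-numeric cells are rejected
#' with the offending file line.
#'
#' @param path Path to a TSV file.
#' @param dedupe How to handle duplicated gene symbols: `"error"` (default)
#'   or `"mean"` (collapse duplicate rows by their mean).
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, dedupe = c("error", "mean")) {
  dedupe <- match.arg(dedupe)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("expression table needs >= 2 columns: ", path)
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample IDs in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  genes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  nas <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) || nrow(nas)) {
    row1 <- if (nrow(bad)) bad[1, 1] else nas[1, 1]
    stop("non-numeric or missing cell at line ", row1 + 1L,
         " (gene ", genes[row1], ") in ", path)
  }
  dimnames(num) <- list(genes, samples)
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    if (dedupe == "error")
      stop("duplicated gene symbol(s): ", paste(dups, collapse = ", "),
           " (use dedupe = \"mean\" to collapse)")
    message("collapsing ", length(dups), " duplicated gene symbol(s) by mean")
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
  }
  num
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]; round-trips values at full double
#' precision.
#'
#' @param values Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the first (gene ID) column.
#' @export
write_expression <- function(values, path, id_col = "gene") {
  chr <- matrix(sprintf("%.17g", values), nrow = nrow(values),
                dimnames = dimnames(values))
  out <- data.frame(rownames(values), chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c(id_col, colnames(values))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a kinase -> substrate pair table
#'
#' Two-column TSV with a header (`kinase`, `substrate`). Duplicate pairs are
#' dropped with a message; self-pairs are retained and flagged.
#'
#' @param path Path to a TSV file.
#' @return A [ks_network()].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first)) return(ks_network(character(), character()))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("network table needs >= 2 columns: ", path)
  ks_network(df[[1]], df[[2]])
}

#' Write a network as TSV
#' @param net A [ks_network()].
#' @param path Output path.
#' @export
write_network <- function(net, path) {
  utils::write.table(as.data.frame(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' TSV with columns `sample_id`, a class column (default `class`), `time`,
#' `event`, and arbitrary further covariates. Samples with missing survival
#' time are dropped with a message (they can never enter a survival model);
#' class values must form exactly two levels.
#'
#' @param path Path to a TSV file.
#' @param class_col Name of the two-level class column.
#' @return Data frame, validated.
#' @export
read_clinical <- function(path, class_col = "class") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("clinical table lacks `sample_id`")
  df$sample_id <- as.character(df$sample_id)
  if ("time" %in% names(df) && anyNA(df$time)) {
    n_drop <- sum(is.na(df$time))
    message(n_drop, " sample(s) with missing survival time dropped")
    df <- df[!is.na(df$time), , drop = FALSE]
  }
  validate_clinical(df, class_col = class_col,
                    require_survival = all(c("time", "event") %in% names(df)))
  df
}

#' Write a clinical table as TSV
#' @param clinical Data frame with a `sample_id` column.
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then member symbols, all
#' tab-separated.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' Align expression, clinical table, and network
#'
#' Restricts samples to the intersection of expression and clinical sample
#' IDs and restricts the network to pairs whose genes are both present in
#' the expression matrix; dropped counts are reported via [message()].
#' Alignment is idempotent.
#'
#' @param values Numeric genes x samples matrix.
#' @param clinical Clinical data frame with `sample_id` and a class column.
#' @param net A [ks_network()] (optional).
#' @param class_col Name of the class column in `clinical`.
#' @return List with elements `expr` (a [ks_expr()] over the common
#'   samples), `clinical` (reordered to match), and `network` (filtered).
#' @export
align_cohort <- function(values, clinical, net = NULL, class_col = "class") {
  validate_clinical(clinical, class_col = class_col,
                    require_survival = all(c("time", "event") %in%
                                             names(clinical)))
  common <- intersect(colnames(values), clinical$sample_id)
  if (!length(common)) stop("no samples shared between expression and clinical")
  n_e <- ncol(values) - length(common)
  n_c <- nrow(clinical) - length(common)
  if (n_e) message(n_e, " expression sample(s) without clinical record dropped")
  if (n_c) message(n_c, " clinical sample(s) without expression dropped")
  values <- values[, common, drop = FALSE]
  clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  if (!is.null(net) && nrow(net)) {
    keep <- net$kinase %in% rownames(values) &
      net$substrate %in% rownames(values)
    if (any(!keep))
      message(sum(!keep), " network pair(s) with absent gene(s) dropped")
    net <- net[keep, , drop = FALSE]
    class(net) <- c("ks_network", "data.frame")
  }
  cls <- as.character(clinical[[class_col]])
  names(cls) <- clinical$sample_id
  list(expr = ks_expr(values, cls), clinical = clinical, network = net)
}
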