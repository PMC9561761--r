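#' Enumerate all candidate gene pairs
#'
#' All unordered pairs of the gene universe in canonical orientation
#' (`gene_a` < `gene_b` in C-locale lexicographic order), listed
#' lexicographically by (`gene_a`, `gene_b`). For `n` genes this yields
#' `n(n-1)/2` pairs.
#'
#' @param genes Character vector of >= 2 unique gene ids.
#' @return A `data.frame` with columns `gene_a`, `gene_b` and row names set
#'   to the canonical pair id `"geneA|geneB"`.
#' @export
build_pairs <- function(genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) input_error("gene list contains duplicates")
  if (length(genes) < 2L) input_error("need at least 2 genes to form pairs")
  g <- sort_c(genes)
  n <- length(g)
  # column-index enumeration keeps (a, b) lexicographic without combn overhead
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  pairs <- data.frame(gene_a = g[i], gene_b = g[j], stringsAsFactors = FALSE)
  rownames(pairs) <- pair_id(pairs$gene_a, pairs$gene_b)
  pairs
}

#' Score one expression profile against a pair list
#'
#' The single-sample pair indicator: entry i is 1 when
#' `expr_values[gene_a_i] > expr_values[gene_b_i]`, else 0 (ties score 0).
#' Only the within-profile ordering matters, so any strictly increasing
#' rescaling of the profile leaves the result unchanged.
#'
#' @param expr_values Named nonnegative numeric vector (gene id -> value).
#' @param pairs Pair `data.frame` from [build_pairs()].
#' @return Integer 0/1 vector, one entry per pair, named by pair id.
#' @export
score_sample <- function(expr_values, pairs) {
  need <- unique(c(pairs$gene_a, pairs$gene_b))
  missing <- setdiff(need, names(expr_values))
  if (length(missing)) {
    input_error("expression profile misses gene(s): ", paste(missing, collapse = ", "))
  }
  out <- as.integer(expr_values[pairs$gene_a] > expr_values[pairs$gene_b])
  names(out) <- rownames(pairs)
  out
}

#' Transform an expression matrix into the binary pair-indicator matrix
#'
#' Applies [score_sample()] columnwise: cell (i, s) is 1 when, within sample
#' s, the expression of `gene_a_i` strictly exceeds that of `gene_b_i`.
#' The output is exactly invariant to strictly increasing per-sample
#' distortions of `expr`, which is the batch-robustness property of the
#' method.
#'
#' @param expr Genes x samples nonnegative matrix.
#' @param pairs Pair `data.frame` from [build_pairs()].
#' @return Integer 0/1 matrix, pairs x samples; row names are pair ids,
#'   column order matches `expr`.
#' @export
pair_transform <- function(expr, pairs) {
  expr <- validate_expression(expr)
  need <- unique(c(pairs$gene_a, pairs$gene_b))
  missing <- setdiff(need, rownames(expr))
  if (length(missing)) {
    input_error("expression matrix misses gene(s): ", paste(missing, collapse = ", "))
  }
  pm <- (expr[pairs$gene_a, , drop = FALSE] > expr[pairs$gene_b, , drop = FALSE]) + 0L
  storage.mode(pm) <- "integer"
  rownames(pm) <- rownames(pairs)
  pm
}

#' Filter pairs by indicator prevalence
#'
#' Keeps pairs whose mean indicator across samples lies within
#' `[f_low, f_high]` (inclusive). Near-constant pairs carry no contrast
#' between samples and are uninformative for survival screening; the default
#' band used elsewhere in the package is `[0.2, 0.8]`, the common convention
#' for rank-pair signatures.
#'
#' @param pm Pair x sample 0/1 matrix from [pair_transform()].
#' @param f_low,f_high Prevalence bounds, `0 <= f_low < f_high <= 1`.
#' @return The subset of rows of `pm`, original order preserved.
#' @export
filter_pairs <- function(pm, f_low = 0.2, f_high = 0.8) {
  if (!is.numeric(f_low) || !is.numeric(f_high) ||
      f_low < 0 || f_high > 1 || f_low >= f_high) {
    input_error("need 0 <= f_low < f_high <= 1")
  }
  prev <- rowMeans(pm)
  pm[prev >= f_low & prev <= f_high, , drop = FALSE]
}

#' Assess batch mixing of samples in pair space
#'
#' Projects samples onto the first two principal components of the pair
#' matrix and computes the mean silhouette width of the batch labels in that
#' plane. Well-mixed batches give silhouettes near 0 (or negative); strong
#' batch structure gives silhouettes toward 1. Running this on the raw
#' expression matrix (genes x samples also accepted) versus the pair matrix
#' shows how much batch signal the rank-pair transform removes.
#'
#' @param pm Features x samples numeric matrix (pair indicators or raw
#'   expression).
#' @param batch_labels Vector of batch labels, one per sample (or a named
#'   vector keyed by sample id).
#' @return `list(coords, silhouette, widths, batch)`: PC1/PC2 coordinates per
#'   sample, mean silhouette width, per-sample widths and the label factor.
#' @export
evaluate_batch_mixing <- function(pm, batch_labels) {
  if (!is.null(names(batch_labels)) && !is.null(colnames(pm))) {
    missing <- setdiff(colnames(pm), names(batch_labels))
    if (length(missing)) {
      input_error("batch labels missing for sample(s): ",
                  paste(head(missing, 5L), collapse = ", "))
    }
    batch_labels <- batch_labels[colnames(pm)]
  }
  if (length(batch_labels) != ncol(pm)) {
    input_error("one batch label per sample required")
  }
  batch <- factor(batch_labels)
  if (nlevels(batch) < 2L) input_error("need at least 2 batches")
  if (any(table(batch) < 3L)) input_error("need at least 3 samples per batch")
  pca <- prcomp(t(pm), center = TRUE, scale. = FALSE, rank. = 2L)
  coords <- pca$x[, seq_len(min(2L, ncol(pca$x))), drop = FALSE]
  sil <- cluster::silhouette(as.integer(batch), stats::dist(coords))
  widths <- sil[, "sil_width"]
  list(
    coords = coords,
    silhouette = mean(widths),
    widths = widths,
    batch = batch
  )
}

#' Write / read a pair-indicator matrix as TSV
#'
#' Rows are pair ids (`"geneA|geneB"`), columns samples, cells 0/1.
#'
#' @param pm Pair x sample 0/1 matrix.
#' @param path File path.
#' @return `write_pair_matrix()`: the path, invisibly. `read_pair_matrix()`:
#'   the integer matrix.
#' @export
write_pair_matrix <- function(pm, path) {
  df <- data.frame(pair_id = rownames(pm), pm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_matrix
#' @export
read_pair_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  pm <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(pm) <- "integer"
  rownames(pm) <- df[[1L]]
  if (!all(pm %in% c(0L, 1L))) input_error("pair matrix cells must be 0/1")
  split_pair_id(rownames(pm))  # validates id format
  pm
}
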