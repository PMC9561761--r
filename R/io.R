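#' Read a gene expression matrix from TSV/CSV
#'
#' Expects genes in rows (first column = gene identifier) and samples in
#' columns (header row = sample identifiers). Values may be on any
#' nonnegative, within-sample-comparable scale (FPKM, TPM, microarray
#' intensity, qPCR relative expression); the downstream pair transform uses
#' only within-sample orderings, so no normalization is applied or needed.
#'
#' Cleaning rules applied on load:
#' * duplicated gene ids are collapsed to the single row with the highest
#'   mean expression (the usual microarray probe-collapse convention);
#' * genes with any missing value are dropped;
#' * both actions are reported via `message()` with counts.
#'
#' @param path Path to a delimited text file.
#' @param format `"tsv"` or `"csv"`. Defaults from the file extension.
#' @return A numeric matrix (genes x samples) with unique row and column
#'   names and no missing or negative values.
#' @seealso [write_expression()], [read_clinical()], [align_cohort()]
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (format == "csv") "," else "\t"
  raw <- tryCatch(
    read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) input_error("cannot parse expression file '", path, "': ",
                                    conditionMessage(e))
  )
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    input_error("expression file '", path, "' contains no data")
  }
  genes <- as.character(raw[[1L]])
  values <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  if (anyDuplicated(colnames(values))) {
    input_error("duplicated sample ids in '", path, "'")
  }

  # collapse duplicated gene ids: keep the highest-mean row
  if (anyDuplicated(genes)) {
    means <- rowMeans(values, na.rm = TRUE)
    ord <- order(genes, -means)
    keep <- ord[!duplicated(genes[ord])]
    n_dropped <- nrow(values) - length(keep)
    values <- values[sort(keep), , drop = FALSE]
    msg("read_expression: collapsed ", n_dropped,
        " duplicated gene row(s), keeping highest-mean rows")
  }

  incomplete <- rowSums(is.na(values)) > 0L
  if (any(incomplete)) {
    msg("read_expression: dropped ", sum(incomplete), " gene(s) with missing values")
    values <- values[!incomplete, , drop = FALSE]
  }
  if (nrow(values) == 0L) input_error("no complete gene rows left in '", path, "'")
  if (any(values < 0)) input_error("negative expression values in '", path, "'")
  validate_expression(values)
}

#' Write an expression matrix as TSV/CSV
#'
#' Full-precision text serialization; `read_expression()` round-trips it.
#'
#' @param expr Numeric genes x samples matrix.
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @export
write_expression <- function(expr, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  expr <- validate_expression(expr)
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Validate the ExpressionMatrix contract: unique ids, nonnegative, complete.
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    input_error("expression must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    input_error("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(expr))) input_error("duplicated gene ids")
  if (anyDuplicated(colnames(expr))) input_error("duplicated sample ids")
  if (anyNA(expr)) input_error("expression matrix contains missing values")
  if (any(expr < 0)) input_error("expression matrix contains negative values")
  expr
}

#' Read a clinical table
#'
#' Requires columns `sample_id`, `os_time` (overall survival, months,
#' strictly positive) and `os_event` (0 = censored, 1 = death). Optional
#' covariates are recoded to the conventional numeric coding used throughout
#' the package: `gender` female = 0 / male = 1, `mgmt_status` methylated = 0 /
#' unmethylated = 1. Missing covariates are kept as `NA`; samples with
#' incomplete covariates stay in the table (Kaplan-Meier analyses use them)
#' and are dropped per-model by [cox_model()] (complete-case).
#'
#' @param path Path to a TSV/CSV file.
#' @param format `"tsv"`, `"csv"` or `"auto"` (extension-based).
#' @param time_unit `"months"` (default) or `"days"`; day-scaled inputs are
#'   converted to months (divide by 30.4375) so the 1-year ROC horizon is
#'   unambiguous.
#' @return A `data.frame` with at least `sample_id`, `os_time`, `os_event`.
#' @export
read_clinical <- function(path, format = c("auto", "tsv", "csv"),
                          time_unit = c("months", "days")) {
  format <- match.arg(format)
  time_unit <- match.arg(time_unit)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (format == "csv") "," else "\t"
  df <- tryCatch(
    read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE),
    error = function(e) input_error("cannot parse clinical file '", path, "': ",
                                    conditionMessage(e))
  )
  required <- c("sample_id", "os_time", "os_event")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    input_error("clinical file misses column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$os_time <- as.numeric(df$os_time)
  if (time_unit == "days") df$os_time <- df$os_time / 30.4375
  df$os_event <- as.numeric(df$os_event)
  validate_clinical(recode_clinical(df))
}

# Map textual covariate levels onto the numeric coding.
recode_clinical <- function(df) {
  map01 <- function(x, zero, one) {
    if (is.numeric(x)) return(x)
    x <- tolower(trimws(as.character(x)))
    out <- rep(NA_real_, length(x))
    out[x %in% zero] <- 0
    out[x %in% one] <- 1
    out[x %in% c("0", "1")] <- as.numeric(x[x %in% c("0", "1")])
    out
  }
  if (!is.null(df$gender)) {
    df$gender <- map01(df$gender, zero = c("female", "f"), one = c("male", "m"))
  }
  if (!is.null(df$mgmt_status)) {
    df$mgmt_status <- map01(df$mgmt_status, zero = c("methylated", "met"),
                            one = c("unmethylated", "unmet", "non-methylated"))
  }
  for (flag in c("chemo", "radio")) {
    if (!is.null(df[[flag]])) {
      df[[flag]] <- map01(df[[flag]], zero = c("no", "false"), one = c("yes", "true"))
    }
  }
  df
}

validate_clinical <- function(df) {
  if (anyDuplicated(df$sample_id)) input_error("duplicated sample ids in clinical table")
  bad_time <- which(!is.finite(df$os_time) | df$os_time <= 0)
  if (length(bad_time)) {
    input_error("os_time must be > 0; offending row(s): ",
                paste(head(bad_time, 5L), collapse = ", "))
  }
  bad_event <- which(!df$os_event %in% c(0, 1))
  if (length(bad_event)) {
    input_error("os_event must be 0 or 1; offending row(s): ",
                paste(head(bad_event, 5L), collapse = ", "))
  }
  df
}

#' Write a clinical table as TSV
#' @param clin Clinical `data.frame`.
#' @param path Output path.
#' @export
write_clinical <- function(clin, path) {
  write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one id per line, '#' comments allowed)
#' @param path Path to a text file.
#' @return Character vector of unique gene ids, input order preserved.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  genes <- unique(lines[nzchar(lines)])
  if (!length(genes)) input_error("gene list '", path, "' is empty")
  genes
}

#' Restrict an expression matrix and clinical table to shared samples
#'
#' Both objects are subset to the intersection of their sample ids, in the
#' order the intersection appears in the expression matrix. Idempotent.
#'
#' @param expr Genes x samples matrix.
#' @param clin Clinical `data.frame` with `sample_id`.
#' @return `list(expr = , clin = )`, aligned sample-for-sample.
#' @export
align_cohort <- function(expr, clin) {
  expr <- validate_expression(expr)
  shared <- intersect(colnames(expr), clin$sample_id)
  if (!length(shared)) input_error("expression and clinical tables share no samples")
  n_drop_expr <- ncol(expr) - length(shared)
  n_drop_clin <- nrow(clin) - length(shared)
  if (n_drop_expr + n_drop_clin > 0L) {
    msg("align_cohort: dropped ", n_drop_expr, " expression sample(s) and ",
        n_drop_clin, " clinical row(s) outside the intersection")
  }
  expr <- expr[, shared, drop = FALSE]
  clin <- clin[match(shared, clin$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  list(expr = expr, clin = clin)
}

#' Intersect a gene universe with one or more expression matrices
#'
#' Returns the genes of `gene_set` present in every matrix, preserving
#' `gene_set` order (so the result is stable and commutative in the matrix
#' list). This is the step that reduces a curated metabolic gene universe to
#' the genes measured on all platforms.
#'
#' @param matrices A single matrix or a list of genes x samples matrices.
#' @param gene_set Character vector of gene ids.
#' @return Character vector (subset of `gene_set`, same order).
#' @export
intersect_gene_universe <- function(matrices, gene_set) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (!length(matrices)) input_error("need at least one expression matrix")
  if (!length(gene_set)) input_error("gene_set is empty")
  if (anyDuplicated(gene_set)) input_error("gene_set contains duplicates")
  keep <- gene_set
  for (m in matrices) keep <- keep[keep %in% rownames(m)]
  if (!length(keep)) input_error("no genes shared by the gene set and all matrices")
  keep
}
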