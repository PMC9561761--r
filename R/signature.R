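#' Construct a gene-pair signature
#'
#' A signature is an ordered list of gene pairs with nonzero Cox
#' coefficients, plus the risk cutoff and the ROC horizon it was chosen at.
#' The risk score of a profile is `sum(coefficient_i * value_i)` over the
#' signature's pair indicators, and a sample is called high-risk when its
#' score strictly exceeds `cutoff`.
#'
#' @param pairs `data.frame` with columns `gene_a`, `gene_b`, `coefficient`
#'   (all coefficients nonzero, no duplicate pairs).
#' @param cutoff Risk-score threshold (`NA` until chosen).
#' @param horizon ROC horizon in months used to choose the cutoff.
#' @param metadata Named list of training provenance (n, seed, lambda,
#'   folds, ...).
#' @return An object of class `pair_signature`.
#' @export
pair_signature <- function(pairs, cutoff = NA_real_, horizon = NA_real_,
                           metadata = list()) {
  required <- c("gene_a", "gene_b", "coefficient")
  if (!is.data.frame(pairs) || !all(required %in% names(pairs))) {
    input_error("`pairs` needs columns gene_a, gene_b, coefficient")
  }
  if (nrow(pairs) == 0L) input_error("a signature needs at least one pair")
  pairs$gene_a <- as.character(pairs$gene_a)
  pairs$gene_b <- as.character(pairs$gene_b)
  pairs$coefficient <- as.numeric(pairs$coefficient)
  if (any(pairs$gene_a == pairs$gene_b)) input_error("a pair cannot repeat a gene")
  if (any(pairs$coefficient == 0 | !is.finite(pairs$coefficient))) {
    input_error("all signature coefficients must be nonzero and finite")
  }
  ids <- pair_id(pairs$gene_a, pairs$gene_b)
  if (anyDuplicated(ids)) input_error("duplicate pairs in signature")
  rownames(pairs) <- ids
  structure(
    list(pairs = pairs[required], cutoff = as.numeric(cutoff),
         horizon = as.numeric(horizon), metadata = metadata),
    class = "pair_signature"
  )
}

#' @export
print.pair_signature <- function(x, ...) {
  cat("Gene-pair signature:", nrow(x$pairs), "pair(s),",
      length(signature_genes(x)), "unique gene(s)\n")
  cat("  cutoff:", ifelse(is.na(x$cutoff), "unset", format(x$cutoff)),
      " horizon:", ifelse(is.na(x$horizon), "unset",
                          paste(format(x$horizon), "months")), "\n")
  print(head(x$pairs, 10L))
  if (nrow(x$pairs) > 10L) cat("  ... and", nrow(x$pairs) - 10L, "more\n")
  invisible(x)
}

#' Unique genes used by a signature
#' @param sig A `pair_signature`.
#' @return Character vector of unique gene ids.
#' @export
signature_genes <- function(sig) {
  unique(c(sig$pairs$gene_a, sig$pairs$gene_b))
}

#' Write / read a signature file
#'
#' The canonical serialization is JSON with fields `pairs` (gene_a, gene_b,
#' coefficient), `cutoff`, `horizon_months`, `tie_rule` (always
#' `"gt_zero_ties"`: indicator 1 iff gene_a > gene_b, ties 0) and `metadata`.
#' A flat TSV (columns `gene_a`, `gene_b`, `coefficient`, with cutoff/horizon
#' in `#` header comments) is also supported for spreadsheet use.
#'
#' @param sig A `pair_signature`.
#' @param path Output path; format chosen by extension unless given.
#' @param format `"json"` or `"tsv"`.
#' @return `write_signature()`: the path, invisibly; `read_signature()`: a
#'   `pair_signature`.
#' @export
write_signature <- function(sig, path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "json"
  }
  stopifnot(inherits(sig, "pair_signature"))
  if (format == "json") {
    payload <- list(
      pairs = sig$pairs,
      cutoff = sig$cutoff,
      horizon_months = sig$horizon,
      tie_rule = "gt_zero_ties",
      metadata = sig$metadata
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null", na = "null")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      paste0("# cutoff=", format(sig$cutoff, digits = 17)),
      paste0("# horizon_months=", format(sig$horizon, digits = 17)),
      "# tie_rule=gt_zero_ties"
    ), con)
    write.table(sig$pairs, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "json"
  }
  if (format == "json") {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    pairs <- as.data.frame(payload$pairs, stringsAsFactors = FALSE)
    pair_signature(pairs,
                   cutoff = payload$cutoff %||% NA_real_,
                   horizon = payload$horizon_months %||% NA_real_,
                   metadata = as.list(payload$metadata %||% list()))
  } else {
    lines <- readLines(path, warn = FALSE)
    header <- grep("^#", lines, value = TRUE)
    get_num <- function(key) {
      hit <- grep(paste0("^#\\s*", key, "="), header, value = TRUE)
      if (!length(hit)) return(NA_real_)
      suppressWarnings(as.numeric(sub(paste0("^#\\s*", key, "="), "", hit[1L])))
    }
    pairs <- read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
    pair_signature(pairs, cutoff = get_num("cutoff"),
                   horizon = get_num("horizon_months"))
  }
}
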