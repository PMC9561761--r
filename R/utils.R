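# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Locale-independent lexicographic sort (C collation), so pair identity and
# ordering are reproducible across systems.
sort_c <- function(x) sort(x, method = "radix")

pair_id <- function(gene_a, gene_b) paste(gene_a, gene_b, sep = "|")

split_pair_id <- function(id) {
  parts <- strsplit(id, "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed pair id(s): ", paste(id[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(
    gene_a = vapply(parts, `[`, character(1), 1L),
    gene_b = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

input_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("pairsig_input_error", "pairsig_error")))
}

model_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("pairsig_model_error", "pairsig_error")))
}

msg <- function(..., verbose = getOption("pairsig.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
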