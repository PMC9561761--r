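#' Configuration for the end-to-end signature pipeline
#'
#' Collects every tunable of the train/validation workflow. Inputs may be
#' file paths (read with the io functions) or in-memory objects.
#'
#' @param expression Genes x samples matrix, or path to a TSV/CSV.
#' @param clinical Clinical `data.frame`, or path.
#' @param gene_list Optional gene universe (character vector or path); when
#'   `NULL`, all genes of the expression matrix are used.
#' @param out_dir Output directory (created if needed); `NULL` disables file
#'   output.
#' @param train_fraction Fraction of samples assigned to training (default
#'   204/377, the conventional roughly-54% split; sizes use `round()`).
#' @param seed Integer seed driving the split, CV folds and any resampling.
#' @param filter_low,filter_high Pair-prevalence band (default \[0.2, 0.8\]).
#' @param filter_on_training When `TRUE`, prevalence filtering uses training
#'   samples only (avoids any leakage); default `FALSE` filters on the full
#'   cohort before splitting, matching the usual order of operations for
#'   this family of methods.
#' @param screen_alpha Univariate Cox screen level (default 0.001).
#' @param cv_folds LASSO CV folds (default 10).
#' @param lambda_rule `"min"` or `"1se"`.
#' @param horizon ROC horizon in months (default 12).
#' @param n_randomizations Robustness permutations (0 = skip, the default).
#' @param covariates Clinical covariates for the multivariate Cox model.
#' @param stratify_split_by_dataset Stratify the random split by the
#'   `dataset` column when present.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(expression, clinical, gene_list = NULL,
                            out_dir = NULL, train_fraction = 204 / 377,
                            seed = 1, filter_low = 0.2, filter_high = 0.8,
                            filter_on_training = FALSE, screen_alpha = 0.001,
                            cv_folds = 10, lambda_rule = c("min", "1se"),
                            horizon = 12, n_randomizations = 0,
                            covariates = c("age", "gender", "mgmt_status"),
                            stratify_split_by_dataset = FALSE) {
  lambda_rule <- match.arg(lambda_rule)
  if (train_fraction <= 0 || train_fraction >= 1) {
    input_error("train_fraction must be in (0, 1)")
  }
  structure(
    list(expression = expression, clinical = clinical, gene_list = gene_list,
         out_dir = out_dir, train_fraction = train_fraction, seed = seed,
         filter_low = filter_low, filter_high = filter_high,
         filter_on_training = filter_on_training, screen_alpha = screen_alpha,
         cv_folds = cv_folds, lambda_rule = lambda_rule, horizon = horizon,
         n_randomizations = n_randomizations, covariates = covariates,
         stratify_split_by_dataset = stratify_split_by_dataset),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' File fields mirror the arguments of [pipeline_config()]; `expression`,
#' `clinical` and `gene_list` are interpreted as paths.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw)
}

log_line <- function(con, stage, ...) {
  if (is.null(con)) return(invisible())
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
}

#' Run the full signature pipeline
#'
#' Executes, in order: cohort alignment, gene-universe intersection, pair
#' enumeration, rank-pair transform, prevalence filtering, seeded
#' train/validation split, univariate Cox screen (training only), LASSO-Cox
#' fit, ROC-derived cutoff (training only), risk scoring and evaluation of
#' both halves (log-rank, C-index, horizon AUC, uni-/multivariate Cox when
#' covariates are available), and optionally the permutation robustness
#' test. Identical config + seed reproduce identical outputs.
#'
#' When `cfg$out_dir` is set, writes `signature.json`, `signature.tsv`,
#' `risk_train.tsv`, `risk_validation.tsv`, `evaluation.json` and a
#' JSON-lines `log.jsonl` there.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the signature, per-half risk tables and
#'   evaluation reports, the split, and stage counts.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  con <- NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    con <- file(file.path(cfg$out_dir, "log.jsonl"), "w")
    on.exit(close(con), add = TRUE)
  }

  expr <- if (is.character(cfg$expression)) read_expression(cfg$expression) else cfg$expression
  clin <- if (is.character(cfg$clinical)) read_clinical(cfg$clinical) else validate_clinical(recode_clinical(cfg$clinical))
  genes <- cfg$gene_list
  if (is.character(genes) && length(genes) == 1L && file.exists(genes)) {
    genes <- read_gene_list(genes)
  }

  aligned <- align_cohort(expr, clin)
  expr <- aligned$expr
  clin <- aligned$clin
  log_line(con, "align", n_samples = ncol(expr), n_genes = nrow(expr))

  universe <- if (is.null(genes)) rownames(expr) else
    intersect_gene_universe(list(expr), genes)
  log_line(con, "gene_universe", n_genes = length(universe))

  pairs <- build_pairs(universe)
  log_line(con, "build_pairs", n_pairs = nrow(pairs))

  pm <- pair_transform(expr[universe, , drop = FALSE], pairs)

  # seeded split (before or after filtering depending on filter_on_training)
  n <- ncol(pm)
  train_idx <- with_seed(cfg$seed, {
    n_train <- round(cfg$train_fraction * n)
    if (cfg$stratify_split_by_dataset && !is.null(clin$dataset)) {
      idx <- unlist(lapply(split(seq_len(n), clin$dataset), function(rows) {
        sample(rows, round(cfg$train_fraction * length(rows)))
      }), use.names = FALSE)
      sort(idx)
    } else {
      sort(sample(n, n_train))
    }
  })
  val_idx <- setdiff(seq_len(n), train_idx)
  log_line(con, "split", n_train = length(train_idx), n_validation = length(val_idx),
           seed = cfg$seed)

  filter_cols <- if (cfg$filter_on_training) train_idx else seq_len(n)
  prev <- rowMeans(pm[, filter_cols, drop = FALSE])
  pm_f <- pm[prev >= cfg$filter_low & prev <= cfg$filter_high, , drop = FALSE]
  log_line(con, "filter_pairs", n_kept = nrow(pm_f), n_candidates = nrow(pm),
           band = c(cfg$filter_low, cfg$filter_high),
           on_training = cfg$filter_on_training)

  pm_train <- pm_f[, train_idx, drop = FALSE]
  clin_train <- clin[train_idx, , drop = FALSE]
  pm_val <- pm_f[, val_idx, drop = FALSE]
  clin_val <- clin[val_idx, , drop = FALSE]

  screened <- cox_screen(pm_train, clin_train, alpha = cfg$screen_alpha)
  log_line(con, "cox_screen", n_screened = nrow(screened),
           n_tested = attr(screened, "n_tested"), alpha = cfg$screen_alpha)
  if (nrow(screened) == 0L) {
    model_error("pipeline: no pairs passed the Cox screen at alpha = ",
                cfg$screen_alpha)
  }

  sig <- fit_lasso_cox(pm_train[rownames(screened), , drop = FALSE], clin_train,
                       n_folds = cfg$cv_folds, seed = cfg$seed,
                       lambda_rule = cfg$lambda_rule)
  log_line(con, "fit_lasso_cox", n_selected = nrow(sig$pairs),
           lambda = sig$metadata$lambda)

  scores_train <- risk_score(pm_train, sig)
  cut <- choose_cutoff(scores_train, clin_train, horizon = cfg$horizon)
  sig$cutoff <- cut$cutoff
  sig$horizon <- cfg$horizon
  sig$metadata$train_auc <- cut$auc
  sig$metadata$split <- list(n_train = length(train_idx),
                             n_validation = length(val_idx))
  log_line(con, "choose_cutoff", cutoff = cut$cutoff, auc = cut$auc,
           horizon = cfg$horizon)

  evaluate_half <- function(pm_half, clin_half) {
    scores <- risk_score(pm_half, sig)
    groups <- assign_group(scores, sig$cutoff)
    eval <- list(
      n = length(scores),
      auc = tryCatch(td_roc(scores, clin_half$os_time, clin_half$os_event,
                            cfg$horizon)$auc, error = function(e) NA_real_),
      c_index = tryCatch(c_index(scores, clin_half), error = function(e) NA_real_)
    )
    if (nlevels(droplevels(groups)) == 2L) {
      lr <- km_logrank(clin_half, groups)
      eval$logrank_chi2 <- lr$logrank_chi2
      eval$logrank_p <- lr$logrank_p
      cox_uni <- tryCatch({
        dfc <- clin_half
        dfc$risk_group <- as.character(groups)
        cox_model(dfc, "risk_group")
      }, error = function(e) NULL)
      if (!is.null(cox_uni)) eval$cox_univariate <- cox_uni
      covs <- intersect(cfg$covariates, names(clin_half))
      if (length(covs)) {
        cox_multi <- tryCatch({
          dfc <- clin_half
          dfc$risk_group <- as.character(groups)
          suppressMessages(cox_model(dfc, c("risk_group", covs)))
        }, error = function(e) NULL)
        if (!is.null(cox_multi)) eval$cox_multivariate <- cox_multi
      }
    }
    list(scores = scores, groups = groups, evaluation = eval)
  }

  train_res <- evaluate_half(pm_train, clin_train)
  val_res <- evaluate_half(pm_val, clin_val)
  log_line(con, "evaluate", train_c = train_res$evaluation$c_index,
           validation_c = val_res$evaluation$c_index,
           validation_logrank_p = val_res$evaluation$logrank_p)

  robustness <- NULL
  if (cfg$n_randomizations > 0L) {
    robustness <- robustness_test(
      pm_train, clin_train,
      config = list(screen_alpha = cfg$screen_alpha, n_folds = min(cfg$cv_folds, 5L),
                    lambda_rule = cfg$lambda_rule),
      n_randomizations = cfg$n_randomizations, seed = cfg$seed
    )
    log_line(con, "robustness", observed = robustness$observed_frequency,
             empirical_p = robustness$empirical_p)
  }

  risk_table <- function(res, clin_half) {
    data.frame(sample_id = clin_half$sample_id,
               score = unname(res$scores),
               group = as.character(res$groups),
               stringsAsFactors = FALSE)
  }
  out <- list(
    signature = sig,
    screened = screened,
    train = c(train_res["evaluation"], list(risk = risk_table(train_res, clin_train))),
    validation = c(val_res["evaluation"], list(risk = risk_table(val_res, clin_val))),
    split = list(train = clin_train$sample_id, validation = clin_val$sample_id),
    robustness = robustness,
    n_pairs = c(candidates = nrow(pm), filtered = nrow(pm_f),
                screened = nrow(screened), signature = nrow(sig$pairs))
  )

  if (!is.null(cfg$out_dir)) {
    write_signature(sig, file.path(cfg$out_dir, "signature.json"))
    write_signature(sig, file.path(cfg$out_dir, "signature.tsv"))
    write.table(out$train$risk, file.path(cfg$out_dir, "risk_train.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(out$validation$risk, file.path(cfg$out_dir, "risk_validation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report <- list(train = out$train$evaluation,
                   validation = out$validation$evaluation,
                   n_pairs = as.list(out$n_pairs),
                   seed = cfg$seed)
    if (!is.null(robustness)) {
      report$robustness <- robustness[c("observed_frequency", "empirical_p")]
    }
    jsonlite::write_json(report, file.path(cfg$out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
    log_line(con, "done", out_dir = cfg$out_dir)
  }
  invisible(out)
}
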