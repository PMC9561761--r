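#' Risk scores from pair indicators and a signature
#'
#' The risk score is the exact weighted sum
#' `sum_i coefficient_i * value_i` over the signature's pairs, where
#' `value_i` is the sample's binary indicator for pair i.
#'
#' @param values Either a pair x sample 0/1 matrix with pair-id rownames
#'   (e.g. from [pair_transform()]) or a named 0/1 vector for one sample.
#' @param sig A [pair_signature()].
#' @return Named numeric vector of scores (one per sample).
#' @export
risk_score <- function(values, sig) {
  stopifnot(inherits(sig, "pair_signature"))
  ids <- rownames(sig$pairs)
  if (is.matrix(values)) {
    missing <- setdiff(ids, rownames(values))
    if (length(missing)) {
      input_error("pair matrix misses signature pair(s): ",
                  paste(missing, collapse = ", "))
    }
    drop(crossprod(values[ids, , drop = FALSE], sig$pairs$coefficient))
  } else {
    missing <- setdiff(ids, names(values))
    if (length(missing)) {
      input_error("indicator vector misses signature pair(s): ",
                  paste(missing, collapse = ", "))
    }
    sum(sig$pairs$coefficient * values[ids])
  }
}

#' Assign high/low risk groups at a cutoff
#'
#' A sample is `"high"` risk iff its score strictly exceeds the cutoff
#' (scores exactly at the cutoff are `"low"`).
#'
#' @param scores Numeric scores.
#' @param cutoff Risk threshold.
#' @return Factor with levels `c("low", "high")`, names preserved.
#' @export
assign_group <- function(scores, cutoff) {
  if (!is.numeric(cutoff) || is.na(cutoff)) input_error("cutoff must be a number")
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier curves and log-rank comparison of groups
#'
#' Product-limit survival estimates per group and the k-group log-rank test.
#'
#' @param clin Clinical `data.frame` with `os_time`, `os_event`.
#' @param groups Group label per sample (2 or more non-empty groups).
#' @return `list(logrank_chi2, logrank_p, df, km, n)`; `km` is the
#'   `survival::survfit` object carrying the stepwise curves and at-risk
#'   counts.
#' @export
km_logrank <- function(clin, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (length(groups) != nrow(clin)) input_error("one group label per sample required")
  if (nlevels(groups) < 2L) input_error("need at least 2 non-empty groups")
  df <- data.frame(time = clin$os_time, event = clin$os_event, group = groups)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chi2 <- unname(sd$chisq)
  k <- nlevels(groups)
  p <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  list(logrank_chi2 = chi2, logrank_p = p, df = k - 1, km = km,
       n = as.vector(table(groups)))
}

#' Cox proportional-hazards model over clinical covariates
#'
#' Fits a univariate (one covariate) or multivariate Cox model and reports
#' per-covariate hazard ratios with Wald 95% confidence intervals and
#' p-values. Covariates are used with the package's numeric coding (gender
#' female = 0 / male = 1; MGMT-promoter methylated = 0 / unmethylated = 1;
#' age in years); a two-level `"high"/"low"` risk-group column is coded
#' low = 0 / high = 1. Rows with missing values in any included covariate
#' are dropped (complete-case) with a message, and covariates constant
#' across the retained rows are excluded with a warning.
#'
#' @param clin Clinical `data.frame` containing `os_time`, `os_event` and
#'   the covariate columns.
#' @param covariates Character vector of column names to include.
#' @return `data.frame` with columns `term`, `coefficient`, `hazard_ratio`,
#'   `ci95_low`, `ci95_high`, `wald_p`; attributes `model_type`
#'   (`"univariate"`/`"multivariate"`) and `n_used`.
#' @export
cox_model <- function(clin, covariates) {
  missing_cols <- setdiff(covariates, names(clin))
  if (length(missing_cols)) {
    input_error("clinical table misses covariate(s): ",
                paste(missing_cols, collapse = ", "))
  }
  df <- clin[c("os_time", "os_event", covariates)]
  for (v in covariates) {
    col <- df[[v]]
    if (is.factor(col)) col <- as.character(col)
    if (is.character(col)) {
      lv <- setdiff(unique(col), NA)
      if (all(lv %in% c("high", "low"))) {
        col <- as.numeric(col == "high")
      } else if (length(lv) == 2L) {
        col <- as.numeric(col == sort_c(lv)[2L])
      } else {
        input_error("covariate '", v, "' is non-numeric with ", length(lv),
                    " levels; recode it numerically first")
      }
    }
    df[[v]] <- as.numeric(col)
  }
  cc <- complete.cases(df)
  if (sum(!cc)) {
    msg("cox_model: dropped ", sum(!cc), " incomplete row(s) (complete-case)")
  }
  df <- df[cc, , drop = FALSE]
  if (sum(df$os_event) < 1) input_error("no events among complete cases")
  keep <- covariates[vapply(covariates, function(v) stats::var(df[[v]]) > 0, logical(1))]
  dropped <- setdiff(covariates, keep)
  if (length(dropped)) {
    warning("cox_model: excluded constant covariate(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (!length(keep)) input_error("no non-constant covariates left")
  fml <- stats::as.formula(paste(
    "survival::Surv(os_time, os_event) ~",
    paste(sprintf("`%s`", keep), collapse = " + ")
  ))
  fit <- tryCatch(
    survival::coxph(fml, data = df),
    error = function(e) model_error("Cox model failed: ", conditionMessage(e)),
    warning = function(w) {
      if (grepl("converge|infinite", conditionMessage(w))) {
        model_error("Cox model did not converge: ", conditionMessage(w))
      }
      suppressWarnings(survival::coxph(fml, data = df))
    }
  )
  b <- fit$coefficients
  se <- sqrt(diag(fit$var))
  out <- data.frame(
    term = keep,
    coefficient = unname(b),
    hazard_ratio = exp(unname(b)),
    ci95_low = exp(unname(b) - 1.96 * se),
    ci95_high = exp(unname(b) + 1.96 * se),
    wald_p = 2 * stats::pnorm(-abs(unname(b) / se)),
    stringsAsFactors = FALSE
  )
  attr(out, "model_type") <- if (length(keep) == 1L) "univariate" else "multivariate"
  attr(out, "n_used") <- nrow(df)
  out
}

#' Harrell's concordance index
#'
#' Fraction of comparable subject pairs in which the higher risk score
#' belongs to the subject with the shorter survival; tied scores contribute
#' 1/2, censored-censored and incomparable pairs are excluded (Harrell's
#' estimator).
#'
#' @param scores Numeric risk scores.
#' @param clin Clinical `data.frame` with `os_time`, `os_event` aligned with
#'   `scores`.
#' @return Concordance in \[0, 1\].
#' @export
c_index <- function(scores, clin) {
  if (length(scores) != nrow(clin)) input_error("scores and clin differ in length")
  cf <- survival::concordance(
    survival::Surv(clin$os_time, clin$os_event) ~ scores, reverse = TRUE
  )
  counts <- cf$count
  if (sum(counts[c("concordant", "discordant", "tied.x")]) == 0) {
    input_error("no comparable pairs under censoring; C-index undefined")
  }
  unname(cf$concordance)
}

#' Compare two risk-score vectors by C-index
#'
#' Computes Harrell's C for both score vectors on the same samples, their
#' difference, and a seeded bootstrap percentile confidence interval of the
#' difference (resampling samples with replacement).
#'
#' @param scores_a,scores_b Numeric score vectors over identical samples.
#' @param clin Aligned clinical `data.frame`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return `list(c_a, c_b, difference, ci, n_boot)`.
#' @export
compare_signatures <- function(scores_a, scores_b, clin, n_boot = 1000,
                               seed = 1, conf = 0.95) {
  if (length(scores_a) != length(scores_b) || length(scores_a) != nrow(clin)) {
    input_error("both score vectors must cover the same samples as clin")
  }
  c_a <- c_index(scores_a, clin)
  c_b <- c_index(scores_b, clin)
  n <- nrow(clin)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, replace = TRUE)
      cl <- clin[idx, , drop = FALSE]
      tryCatch(
        c_index(scores_a[idx], cl) - c_index(scores_b[idx], cl),
        error = function(e) NA_real_
      )
    }, numeric(1))
  })
  boots <- boots[!is.na(boots)]
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boots, c(alpha, 1 - alpha)))
  list(c_a = c_a, c_b = c_b, difference = c_a - c_b, ci = ci,
       n_boot = length(boots))
}

#' Extreme-quartile survival contrast
#'
#' Ranks samples by risk score and compares the top quartile (ranks above
#' `ceiling(0.75 n)`) against the bottom quartile (ranks up to
#' `floor(0.25 n)`) with a Kaplan-Meier / log-rank analysis. Rank ties are
#' resolved deterministically in input order, keeping boundary ties on the
#' side of their rank.
#'
#' @param scores Numeric risk scores.
#' @param clin Aligned clinical `data.frame`.
#' @return As [km_logrank()], plus `groups` (factor `"bottom"`/`"top"` over
#'   the retained samples) and `idx` (their positions).
#' @export
quartile_analysis <- function(scores, clin) {
  n <- length(scores)
  if (n < 8L) input_error("need at least 8 samples for a quartile contrast")
  if (length(unique(scores)) == 1L) {
    input_error("all scores identical; quartiles are ill-defined")
  }
  r <- rank(scores, ties.method = "first")
  bottom <- which(r <= floor(0.25 * n))
  top <- which(r > ceiling(0.75 * n))
  idx <- c(bottom, top)
  groups <- factor(rep(c("bottom", "top"), c(length(bottom), length(top))),
                   levels = c("bottom", "top"))
  res <- km_logrank(clin[idx, , drop = FALSE], groups)
  res$groups <- groups
  res$idx <- idx
  res
}

#' Score a single external expression profile
#'
#' The defining property of a single-sample signature: one profile (on any
#' monotone scale - TPM, microarray intensity, qPCR relative expression)
#' is enough to compute the risk score and group; no cohort context is
#' needed, and any strictly increasing rescaling of the profile gives the
#' identical result.
#'
#' @param expr_values Named nonnegative numeric vector covering all
#'   signature genes.
#' @param sig A [pair_signature()] with a set cutoff.
#' @param sample_id Optional label for the returned row.
#' @return One-row `data.frame` with `sample_id`, `score`, `group`.
#' @export
score_external_profile <- function(expr_values, sig, sample_id = "profile") {
  stopifnot(inherits(sig, "pair_signature"))
  if (is.na(sig$cutoff)) input_error("signature has no cutoff set")
  missing <- setdiff(signature_genes(sig), names(expr_values))
  if (length(missing)) {
    input_error("profile misses signature gene(s): ",
                paste(missing, collapse = ", "))
  }
  ind <- score_sample(expr_values, sig$pairs)
  score <- sum(sig$pairs$coefficient * ind)
  data.frame(sample_id = sample_id, score = score,
             group = as.character(assign_group(score, sig$cutoff)),
             stringsAsFactors = FALSE)
}
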