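# Independent oracle: maximize the Cox partial likelihood for a single
# binary covariate directly (no ties in simulated continuous times).
cox_loglik_1d <- function(beta, x, time, event) {
  ord <- order(time)
  x <- x[ord]; event <- event[ord]; time <- time[ord]
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

test_that("cox_screen recovers a planted pair and matches a direct partial-likelihood fit", {
  cfg <- simulation_config(n_samples = 300, n_genes = 10, n_true_pairs = 1,
                           true_coefficients = 1.0, censoring_rate_target = 0.3,
                           seed = 1)
  co <- simulate_cohort(cfg)
  pm <- pair_transform(co$expr, build_pairs(rownames(co$expr)))
  res <- suppressMessages(cox_screen(pm, co$clin, alpha = 0.001))
  planted <- rownames(co$truth$planted_pairs)
  expect_true(planted %in% rownames(res))

  # oracle: 1-D partial-likelihood maximization for the planted pair
  beta_hat <- optimize(cox_loglik_1d, c(-4, 4), x = pm[planted, ],
                       time = co$clin$os_time, event = co$clin$os_event,
                       maximum = TRUE)$maximum
  expect_equal(res[planted, "coefficient"], beta_hat, tolerance = 1e-4)
  expect_equal(res[planted, "hazard_ratio"], exp(beta_hat), tolerance = 1e-4)

  # large-sample Wald: z^2 for the planted log-HR ~ n/4 * beta^2 scale,
  # so p must be far below the screen threshold at n = 300
  expect_lt(res[planted, "p_value"], 1e-6)
})

test_that("cox_screen skips constant pairs, returns sorted p, and nests in alpha", {
  co <- signal_cohort(seed = 1)
  pm <- co$pm[1:40, , drop = FALSE]
  pm[1, ] <- 1L  # constant indicator
  res <- suppressMessages(cox_screen(pm, co$clin, alpha = 0.05))
  expect_false(rownames(pm)[1] %in% rownames(res))
  expect_gte(attr(res, "n_constant"), 1L)
  expect_true(all(diff(res$p_value) >= 0))
  expect_true(all(res$p_value < 0.05))

  loose <- suppressMessages(cox_screen(pm, co$clin, alpha = 0.2))
  expect_true(all(rownames(res) %in% rownames(loose)))  # superset at larger alpha

  no_events <- co$clin
  no_events$os_event <- 0
  expect_error(cox_screen(pm, no_events), class = "pairsig_input_error")
})

test_that("fit_lasso_cox selects planted pairs and is seed-deterministic", {
  co <- signal_cohort(seed = 4, n = 250, genes = 20)
  scr <- suppressMessages(cox_screen(co$pm, co$clin, alpha = 0.01))
  sig1 <- fit_lasso_cox(co$pm[rownames(scr), , drop = FALSE], co$clin,
                        n_folds = 5, seed = 7)
  sig2 <- fit_lasso_cox(co$pm[rownames(scr), , drop = FALSE], co$clin,
                        n_folds = 5, seed = 7)
  expect_identical(sig1$pairs, sig2$pairs)          # bit-for-bit reproducible
  expect_identical(sig1$metadata$lambda, sig2$metadata$lambda)
  expect_true(all(rownames(sig1$pairs) %in% rownames(scr)))  # nesting

  planted <- rownames(co$truth$planted_pairs)
  expect_gte(sum(planted %in% rownames(sig1$pairs)), 2)
})

test_that("single-pair input degenerates to an unpenalized fit with the right sign", {
  co <- signal_cohort(seed = 4, n = 250, genes = 20)
  planted <- rownames(co$truth$planted_pairs)[1]
  pm1 <- co$pm[planted, , drop = FALSE]
  sig <- fit_lasso_cox(pm1, co$clin, n_folds = 5, seed = 1)
  expect_equal(nrow(sig$pairs), 1L)
  expect_gt(sig$pairs$coefficient * co$truth$planted_pairs$coefficient[1], 0)
})

test_that("the penalized fit approaches the unpenalized Cox fit as lambda -> 0", {
  co <- signal_cohort(seed = 3, n = 50, genes = 8)
  pm3 <- co$pm[1:3, , drop = FALSE]
  sig <- fit_lasso_cox(pm3, co$clin, lambda = 1e-8)
  y <- survival::Surv(co$clin$os_time, co$clin$os_event)
  ref <- survival::coxph(y ~ t(pm3))
  expect_equal(sig$pairs$coefficient, unname(ref$coefficients), tolerance = 1e-3)
})

test_that("choose_cutoff: perfect separation gives AUC 1 and a separating cutoff", {
  # deaths before the horizon all score above everyone else; no censoring
  time <- c(rep(6, 10), rep(30, 10))
  event <- c(rep(1, 10), rep(0, 10))
  scores <- c(rnorm(10, 5, 0.1), rnorm(10, -5, 0.1))
  set.seed(1)
  cl <- clin_table(time, event)
  res <- choose_cutoff(scores, cl, horizon = 12)
  expect_equal(res$auc, 1.0)
  expect_gt(res$cutoff, max(scores[11:20]))
  expect_lt(res$cutoff, min(scores[1:10]))
})

test_that("outcome-independent scores give AUC near 0.5", {
  cfg <- simulation_config(n_samples = 500, n_genes = 10, n_true_pairs = 0,
                           true_coefficients = numeric(0),
                           censoring_rate_target = 0.3, seed = 3)
  co <- simulate_cohort(cfg)
  set.seed(3)
  scores <- rnorm(500)
  r <- td_roc(scores, co$clin$os_time, co$clin$os_event, horizon = 12)
  expect_lt(abs(r$auc - 0.5), 0.05)
})

test_that("the Youden cutoff equals brute-force midpoint search (censored data)", {
  for (seed in c(2, 5)) {
    cfg <- simulation_config(n_samples = 120, n_genes = 10, n_true_pairs = 2,
                             true_coefficients = c(1.5, -1), seed = seed)
    co <- simulate_cohort(cfg)
    scores <- round(co$truth$eta + rnorm(120, 0, 0.3), 2)  # some tied scores
    res <- choose_cutoff(scores, co$clin, horizon = 12)

    u <- sort(unique(scores))
    mids <- (u[-1] + u[-length(u)]) / 2
    youd <- vapply(mids, function(m) {
      pt <- tdroc_point_survfit(scores, co$clin$os_time, co$clin$os_event, 12, m)
      pt["tpr"] - pt["fpr"]
    }, numeric(1))
    best <- mids[which(youd == max(youd))[1]]  # ties toward lower threshold
    expect_equal(res$cutoff, best)
    expect_equal(res$youden, max(youd), tolerance = 1e-12)
  }
})

test_that("td_roc sensitivity/specificity match the survfit-based oracle pointwise", {
  co <- signal_cohort(seed = 1)
  scores <- co$truth$eta + rnorm(length(co$truth$eta), 0, 0.5)
  set.seed(8)
  r <- td_roc(scores, co$clin$os_time, co$clin$os_event, horizon = 12)
  for (k in sample(nrow(r$roc), 10)) {
    pt <- tdroc_point_survfit(scores, co$clin$os_time, co$clin$os_event, 12,
                              r$roc$threshold[k])
    expect_equal(r$roc$tpr[k], unname(pt["tpr"]), tolerance = 1e-10)
    expect_equal(r$roc$fpr[k], unname(pt["fpr"]), tolerance = 1e-10)
  }
  expect_error(td_roc(scores, co$clin$os_time + 100, co$clin$os_event, 12),
               class = "pairsig_input_error")  # no events before horizon
})

test_that("robustness_test separates planted signal from permutation nulls", {
  ps <- vapply(1:5, function(s) {
    co <- signal_cohort(seed = s)
    robustness_test(co$pm, co$clin, config = list(screen_alpha = 0.01),
                    n_randomizations = 30, seed = 10 + s)$empirical_p
  }, numeric(1))
  expect_true(all(ps <= 0.05))
})

test_that("robustness empirical p respects its bounds and add-one form", {
  co <- signal_cohort(seed = 1)
  r <- robustness_test(co$pm, co$clin, config = list(screen_alpha = 0.01),
                       n_randomizations = 10, seed = 99)
  n_valid <- length(r$null_frequencies)
  expect_gte(r$empirical_p, 1 / (n_valid + 1))
  expect_lte(r$empirical_p, 1)
  expect_equal(r$empirical_p,
               (1 + sum(r$null_frequencies >= r$observed_frequency)) / (1 + n_valid))
})
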