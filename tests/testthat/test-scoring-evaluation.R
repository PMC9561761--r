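two_pair_sig <- function(cutoff = 0) {
  pair_signature(
    data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"),
               coefficient = c(0.5, -0.25)),
    cutoff = cutoff, horizon = 12
  )
}

test_that("risk_score is the exact weighted sum and checks pair presence", {
  sig <- two_pair_sig()
  v <- c("A|B" = 1, "C|D" = 1)
  expect_equal(risk_score(v, sig), 0.25)
  expect_equal(risk_score(c("A|B" = 0, "C|D" = 0), sig), 0)
  expect_error(risk_score(c("A|B" = 1), sig), "C\\|D",
               class = "pairsig_input_error")

  pm <- rbind("A|B" = c(1L, 0L), "C|D" = c(1L, 1L))
  colnames(pm) <- c("S1", "S2")
  expect_equal(risk_score(pm, sig), c(S1 = 0.25, S2 = -0.25))

  # linearity: scaling all coefficients scales every score
  sig3 <- two_pair_sig()
  sig3$pairs$coefficient <- 3 * sig3$pairs$coefficient
  expect_equal(risk_score(pm, sig3), 3 * risk_score(pm, sig))
})

test_that("zero coefficients are rejected at signature construction", {
  expect_error(
    pair_signature(data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"),
                              coefficient = c(0.5, 0))),
    class = "pairsig_input_error"
  )
})

test_that("assign_group uses a strict cutoff and ignores sample order", {
  expect_equal(as.character(assign_group(0.284, -0.211)), "high")
  expect_equal(as.character(assign_group(-0.211, -0.211)), "low")  # boundary
  expect_equal(as.character(assign_group(c(-1, -2), -0.211)), c("low", "low"))
  s <- c(a = 0.3, b = -0.5, c = 0.1)
  g1 <- assign_group(s, 0)
  g2 <- assign_group(s[c(3, 1, 2)], 0)
  expect_equal(g1[names(g2)], g2)
})

test_that("km_logrank: identical groups give chi-square 0 and p 1", {
  cl <- clin_table(rep(c(3, 8, 15), 2), rep(c(1, 0, 1), 2))
  res <- km_logrank(cl, rep(c("g1", "g2"), each = 3))
  expect_lt(res$logrank_chi2, 1e-10)
  expect_equal(res$logrank_p, 1, tolerance = 1e-8)
  expect_error(km_logrank(cl, rep("g1", 6)), class = "pairsig_input_error")
})

test_that("km_logrank matches the hand-computed 6-subject log-rank table", {
  # subjects die at t = 1..6, groups alternate A B A B A B
  cl <- clin_table(1:6, rep(1, 6))
  grp <- rep(c("A", "B"), 3)
  # standard observed-minus-expected computation, done from scratch
  o_a <- e_a <- v_a <- 0
  for (t in 1:6) {
    at_risk <- which(1:6 >= t)
    n <- length(at_risk)
    n_a <- sum(grp[at_risk] == "A")
    d <- 1
    o_a <- o_a + (grp[t] == "A")
    e_a <- e_a + d * n_a / n
    if (n > 1) v_a <- v_a + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  chi2_hand <- (o_a - e_a)^2 / v_a
  res <- km_logrank(cl, grp)
  expect_equal(res$logrank_chi2, chi2_hand, tolerance = 1e-10)
  # KM curves are valid survival curves
  s <- summary(res$km)$surv
  expect_true(all(s <= 1 & s >= 0))
})

test_that("a planted two-arm hazard ratio of 3 is detected with high power", {
  hits <- vapply(1:20, function(s) {
    set.seed(300 + s)
    grp <- rep(c(0, 1), each = 100)
    time <- rexp(200, 0.05 * 3^grp)
    cens <- rexp(200, 0.02)
    cl <- clin_table(pmin(time, cens), as.numeric(time <= cens))
    km_logrank(cl, ifelse(grp == 1, "high", "low"))$logrank_p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("KM curves are non-increasing and start at 1", {
  co <- signal_cohort(seed = 1)
  grp <- assign_group(co$truth$eta, median(co$truth$eta))
  res <- km_logrank(co$clin, grp)
  for (stratum in seq_along(res$km$strata)) {
    idx <- rep(seq_along(res$km$strata), res$km$strata) == stratum
    s <- res$km$surv[idx]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(s[1], 1)
  }
  expect_gte(res$logrank_p, 0)
  expect_lte(res$logrank_p, 1)
})

test_that("cox_model recovers a known hazard ratio and handles degenerate covariates", {
  set.seed(5)
  grp <- rep(c(0, 1), each = 250)
  time <- rexp(500, 0.05 * 2^grp)  # true HR 2 for the risk group
  cens <- rexp(500, 0.02)
  cl <- clin_table(pmin(time, cens), as.numeric(time <= cens))
  cl$risk_group <- ifelse(grp == 1, "high", "low")
  res <- cox_model(cl, "risk_group")
  expect_equal(attr(res, "model_type"), "univariate")
  expect_gt(res$hazard_ratio, 1.6)
  expect_lt(res$hazard_ratio, 2.5)
  expect_true(res$ci95_low <= res$hazard_ratio &
                res$hazard_ratio <= res$ci95_high)

  cl$flat <- 1
  expect_warning(res2 <- cox_model(cl, c("risk_group", "flat")), "constant")
  expect_false("flat" %in% res2$term)

  # complete-case behavior for the multivariate model
  cl$age <- rnorm(500, 60, 10)
  cl$age[1:30] <- NA
  expect_message(res3 <- cox_model(cl, c("risk_group", "age")), "30 incomplete")
  expect_equal(attr(res3, "n_used"), 470)
  expect_equal(attr(res3, "model_type"), "multivariate")
})

test_that("c_index matches exhaustive comparable-pair enumeration", {
  # spec'd small cases
  cl <- clin_table(c(5, 4, 3, 2), rep(1, 4))
  expect_equal(c_index(1:4, cl), 1.0)           # perfectly anti-ranked
  expect_equal(c_index(rep(2, 4), cl), 0.5)     # all ties

  # 5-subject mixed censoring
  cl5 <- clin_table(c(2, 4, 4.5, 7, 9), c(1, 0, 1, 1, 0))
  sc5 <- c(5, 1, 4, 2, 3)
  expect_equal(c_index(sc5, cl5),
               c_index_bruteforce(sc5, cl5$os_time, cl5$os_event))

  # random censored instances, n <= 30
  for (s in 1:5) {
    set.seed(s)
    n <- sample(10:30, 1)
    cl <- clin_table(round(rexp(n, 0.1), 3), rbinom(n, 1, 0.7))
    sc <- sample(1:10, n, replace = TRUE)  # ties in scores
    expect_equal(c_index(sc, cl),
                 c_index_bruteforce(sc, cl$os_time, cl$os_event))
  }
})

test_that("C-index reversal identity holds on tie-free data", {
  set.seed(9)
  cl <- clin_table(rexp(40, 0.1), rbinom(40, 1, 0.7))
  sc <- rnorm(40)
  expect_equal(c_index(-sc, cl), 1 - c_index(sc, cl))
})

test_that("compare_signatures separates informative from noise scores", {
  co <- signal_cohort(seed = 9, n = 300, genes = 20)
  set.seed(9)
  noise <- rnorm(300)
  cmp <- compare_signatures(co$truth$eta, noise, co$clin, n_boot = 200, seed = 2)
  expect_gt(cmp$difference, 0)
  expect_gt(cmp$ci[1], 0)  # bootstrap CI excludes 0

  same <- compare_signatures(noise, noise, co$clin, n_boot = 50, seed = 2)
  expect_equal(same$difference, 0)

  rev <- compare_signatures(-co$truth$eta, co$truth$eta, co$clin,
                            n_boot = 50, seed = 2)
  expect_equal(rev$c_a, 1 - rev$c_b)
})

test_that("quartile_analysis forms correct extreme groups", {
  cl <- clin_table(c(1, 2, 3, 4, 5, 6, 7, 8), rep(1, 8))
  res <- quartile_analysis(8:1, cl)
  expect_equal(as.vector(table(res$groups)), c(2, 2))
  expect_error(quartile_analysis(rep(1, 8), cl), class = "pairsig_input_error")
  expect_error(quartile_analysis(1:4, cl[1:4, ]), class = "pairsig_input_error")
})

test_that("the extreme-quartile contrast is at least as sharp as the median split", {
  hits <- vapply(1:10, function(s) {
    set.seed(400 + s)
    n <- 200
    score <- rnorm(n)
    time <- rexp(n, 0.05 * exp(0.8 * score))
    cens <- rexp(n, 0.02)
    cl <- clin_table(pmin(time, cens), as.numeric(time <= cens))
    p_q <- quartile_analysis(score, cl)$logrank_p
    p_all <- km_logrank(cl, assign_group(score, median(score)))$logrank_p
    p_q <= p_all
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("score_external_profile works from a single profile and is monotone-invariant", {
  sig <- pair_signature(
    data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"),
               coefficient = c(1, 0.5)),
    cutoff = 0.2, horizon = 12
  )
  prof <- c(A = 10, B = 2, C = 8, D = 1)  # every gene_a > gene_b
  res <- score_external_profile(prof, sig, sample_id = "cell1")
  expect_equal(res$score, sum(sig$pairs$coefficient))  # saturation
  expect_equal(res$group, "high")

  for (f in monotone_maps) {
    expect_equal(score_external_profile(f(prof), sig)$score, res$score)
  }

  toy <- pair_signature(data.frame(gene_a = "A", gene_b = "B", coefficient = 1),
                        cutoff = 0, horizon = 12)
  r2 <- score_external_profile(c(A = 2, B = 1), toy)
  expect_equal(r2$score, 1)
  expect_equal(r2$group, "high")

  expect_error(score_external_profile(c(A = 1, B = 2), sig), "C",
               class = "pairsig_input_error")
})
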