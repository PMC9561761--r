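# Shared fixtures, built in code. Cohorts are cached per test run so several
# test files can reuse the same simulated data without re-simulating.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small planted-signal cohort plus its filtered pair matrix.
signal_cohort <- function(seed = 1, n = 150, genes = 20) {
  cached(sprintf("signal_%d_%d_%d", seed, n, genes), {
    cfg <- simulation_config(
      n_samples = n, n_genes = genes, n_true_pairs = 3,
      true_coefficients = c(1.2, 1.0, -1.0), censoring_rate_target = 0.3,
      seed = seed
    )
    co <- simulate_cohort(cfg)
    pm <- filter_pairs(pair_transform(co$expr, build_pairs(rownames(co$expr))))
    c(co, list(pm = pm, cfg = cfg))
  })
}

# Outcome-independent cohort (no planted pairs).
noise_cohort <- function(seed = 1, n = 150, genes = 20) {
  cached(sprintf("noise_%d_%d_%d", seed, n, genes), {
    cfg <- simulation_config(
      n_samples = n, n_genes = genes, n_true_pairs = 0,
      true_coefficients = numeric(0), censoring_rate_target = 0.3, seed = seed
    )
    co <- simulate_cohort(cfg)
    pm <- filter_pairs(pair_transform(co$expr, build_pairs(rownames(co$expr))))
    c(co, list(pm = pm, cfg = cfg))
  })
}

# Minimal clinical table from parallel vectors.
clin_table <- function(time, event, ...) {
  data.frame(sample_id = sprintf("S%03d", seq_along(time)),
             os_time = time, os_event = event, ...,
             stringsAsFactors = FALSE)
}

# Independent oracle: Harrell's C by exhaustive enumeration of comparable
# pairs (events vs later survivors; censored-censored pairs excluded).
c_index_bruteforce <- function(scores, time, event) {
  num <- den <- 0
  n <- length(scores)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # comparable iff the smaller observed time belongs to an event
      if (time[i] == time[j] && event[i] == event[j]) next
      first <- if (time[i] < time[j]) i else j
      second <- if (time[i] < time[j]) j else i
      if (time[i] == time[j]) { first <- if (event[i] == 1) i else j
                                second <- if (event[i] == 1) j else i }
      if (event[first] != 1) next
      den <- den + 1
      if (scores[first] > scores[second]) num <- num + 1
      else if (scores[first] == scores[second]) num <- num + 0.5
    }
  }
  num / den
}

# Independent oracle: KM-based time-dependent sensitivity/specificity at one
# threshold, using survival::survfit for all product-limit estimates.
tdroc_point_survfit <- function(scores, time, event, horizon, threshold) {
  km_surv <- function(idx) {
    if (!length(idx)) return(NA_real_)
    sf <- survival::survfit(survival::Surv(time[idx], event[idx]) ~ 1)
    s <- summary(sf, times = horizon, extend = TRUE)$surv
    if (!length(s)) 1 else s
  }
  s_all <- km_surv(seq_along(scores))
  pos <- which(scores > threshold)
  neg <- which(scores <= threshold)
  p_pos <- length(pos) / length(scores)
  sens <- (1 - km_surv(pos)) * p_pos / (1 - s_all)
  spec <- km_surv(neg) * (1 - p_pos) / s_all
  c(tpr = min(max(sens, 0), 1), fpr = min(max(1 - spec, 0), 1))
}

# Strictly increasing distortion families used by the invariance tests.
monotone_maps <- list(
  log1p = function(x) log1p(x),
  sqrt = function(x) sqrt(x),
  affine = function(x) 3.7 * x + 11,
  power = function(x) x^1.8,
  expit_rank = function(x) 1 / (1 + exp(-0.01 * x))
)
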