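# Shared fixtures and independent oracles, built in code.

# journal lists with one journal shared between two subfields
make_journal_lists <- function() {
  data.frame(
    subfield = c("anesthesiology", "anesthesiology", "neurology", "neurology"),
    journal = c("Pain", "Anesthesia & Analgesia", "Pain", "Brain, The"),
    stringsAsFactors = FALSE)
}

# a small random two-arm dataset for likelihood/BF checks
small_trial <- function(seed, n_per_arm = 15, beta = NULL) {
  set.seed(seed)
  if (is.null(beta)) beta <- stats::runif(1, -1, 1)
  gen_survival(n_per_arm, true_beta = beta, baseline_rate = 0.2,
               censor_rate = 0.05, seed = seed)
}

# Monte-Carlo oracle for BF10: prior-average of the partial likelihood
# ratio, independent of the quadrature path.
mc_bf10 <- function(data, sigma, side = "two_sided", draws = 1e5,
                    seed = 1, chunk = 1e5) {
  set.seed(seed)
  pl0 <- cox_partial_loglik(data, 0)
  tot <- 0; totsq <- 0; m <- 0
  while (m < draws) {
    k <- min(chunk, draws - m)
    b <- stats::rnorm(k, 0, sigma)
    if (side == "positive") b <- abs(b)
    if (side == "negative") b <- -abs(b)
    w <- exp(cox_partial_loglik(data, b) - pl0)
    tot <- tot + sum(w)
    totsq <- totsq + sum(w^2)
    m <- m + k
  }
  est <- tot / m
  list(bf = est, se = sqrt(max(totsq / m - est^2, 0) / m))
}

# closed-form pooled sigma from summary statistics (N, mean b^2, mean SE^2)
sigma_from_summaries <- function(N, mean_b2, mean_se2, n = 200) {
  sqrt(((n - 1) * N * mean_se2 + n * N * mean_b2) / (N * n - 1))
}

# constant corpus reproducing given summary statistics exactly
corpus_from_summaries <- function(N, mean_b2, mean_se2) {
  data.frame(b = rep(sqrt(mean_b2), N), se = rep(sqrt(mean_se2), N))
}
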