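test_that("standard errors are recovered from confidence bounds", {
  expect_equal(se_from_ci(1.5, 3.4, 95), 0.20876, tolerance = 1e-4)
  z <- qnorm(0.975)
  expect_equal(se_from_ci(exp(-z), exp(z), 95), 1.0, tolerance = 1e-12)
  expect_equal(se_from_ci(2.0, 2.0, 95), 0.0)
  expect_error(se_from_ci(1.5, 3.4, 150), "between 0 and 100")
  expect_error(se_from_ci(-1, 3.4, 95), "positive")
  expect_error(se_from_ci(3.4, 1.5, 95), "exceed")
})

test_that("the pooled prior mean is exactly zero for any corpus", {
  set.seed(41)
  for (i in 1:20) {
    N <- sample(1:50, 1)
    corpus <- data.frame(b = rnorm(N, 2, 3), se = runif(N, 0, 1))
    expect_identical(pooled_mu(corpus), 0)
  }
  expect_identical(pooled_mu(data.frame(b = 0.5, se = 0.1)), 0)
  expect_identical(pooled_mu(data.frame(b = c(0, 0), se = c(0, 0))), 0)
  expect_error(pooled_mu(data.frame(b = numeric(0), se = numeric(0))), "empty")
})

test_that("pooled sigma matches hand-evaluated cases", {
  expect_equal(pooled_sigma(data.frame(b = 1, se = 1), n = 200),
               sqrt(399 / 199), tolerance = 1e-12)
  expect_equal(pooled_sigma(data.frame(b = 1, se = 1), n = 200),
               1.41599, tolerance = 1e-5)
  expect_equal(pooled_sigma(data.frame(b = c(0, 0), se = c(0, 0))), 0)
  expect_error(pooled_sigma(data.frame(b = 1, se = 1), n = 1), ">= 2")
})

test_that("study-specific sizes generalize the constant-n pool", {
  # hand arithmetic: N=2, (b,se) = (1,0) and (0,1), n = (10,10)
  corpus <- data.frame(b = c(1, 0), se = c(0, 1))
  expect_equal(pooled_sigma_varying(corpus, c(10, 10)),
               sqrt((9 * 1 + 10 * 1) / 19), tolerance = 1e-12)
  set.seed(42)
  corpus2 <- data.frame(b = rnorm(40), se = runif(40, 0, 0.5))
  expect_equal(pooled_sigma_varying(corpus2, rep(200, 40)),
               pooled_sigma(corpus2, 200), tolerance = 1e-12)
  expect_error(pooled_sigma_varying(corpus2, rep(200, 39)), "one entry per study")
  expect_error(pooled_sigma_varying(corpus2, rep(1, 40)), ">= 2")
  # all SE = 0, all b = c: sigma -> |c| as total n grows
  c0 <- 0.7
  corpus3 <- data.frame(b = rep(c0, 10), se = rep(0, 10))
  expect_equal(pooled_sigma_varying(corpus3, rep(5000, 10)), c0, tolerance = 1e-4)
})

test_that("pooled sigma is scale-equivariant and monotone", {
  set.seed(43)
  corpus <- data.frame(b = rnorm(30), se = runif(30, 0, 0.5))
  for (k in c(0.5, 2, 7)) {
    scaled <- data.frame(b = k * corpus$b, se = k * corpus$se)
    expect_equal(pooled_sigma(scaled), k * pooled_sigma(corpus),
                 tolerance = 1e-12)
  }
  base <- pooled_sigma(corpus)
  bump_b <- corpus; bump_b$b[5] <- bump_b$b[5] + sign(bump_b$b[5] + 1e-12) * 0.5
  bump_se <- corpus; bump_se$se[5] <- bump_se$se[5] + 0.5
  expect_gt(pooled_sigma(bump_b), base)
  expect_gt(pooled_sigma(bump_se), base)
})

test_that("large-n limit approaches the closed form", {
  set.seed(44)
  corpus <- data.frame(b = rnorm(25), se = runif(25, 0, 0.4))
  limit <- sqrt((sum(corpus$se^2) + sum(corpus$b^2)) / nrow(corpus))
  expect_equal(pooled_sigma(corpus, n = 1e8), limit, tolerance = 1e-6)
})

test_that("surrogate corpora reproduce summary-statistic evaluation for all nine subfields", {
  # (N considered, mean b^2, mean SE^2) per subfield descriptive table
  tabs <- list(
    anesthesiology = c(211, 0.804, 0.089),
    cardiology     = c(6504, 0.824, 0.099),
    gastro         = c(1300, 1.027, 0.137),
    hematology     = c(849, 1.029, 0.123),
    immunology     = c(833, 0.937, 0.110),
    neurology      = c(1640, 0.978, 0.115),
    oncology       = c(7684, 0.830, 0.107),
    psychiatry     = c(1029, 0.768, 0.070),
    pulmonary      = c(1548, 0.886, 0.112))
  for (tb in tabs) {
    direct <- sigma_from_summaries(tb[1], tb[2], tb[3])
    via_corpus <- pooled_sigma(corpus_from_summaries(tb[1], tb[2], tb[3]))
    expect_equal(via_corpus, direct, tolerance = 1e-12)
  }
})

test_that("size-sensitivity draws are seeded and concentrate as ranges shrink", {
  set.seed(45)
  corpus <- data.frame(b = rnorm(40, 0, 0.9), se = runif(40, 0.05, 0.4))
  s1 <- sensitivity_sigma(corpus, reps = 200, seed = 7)
  s2 <- sensitivity_sigma(corpus, reps = 200, seed = 7)
  expect_identical(s1$sigmas, s2$sigmas)
  wide <- sensitivity_sigma(corpus, reps = 300, n_low = 10, n_high = 10000, seed = 8)
  narrow <- sensitivity_sigma(corpus, reps = 300, n_low = 190, n_high = 210, seed = 8)
  expect_lt(IQR(narrow$sigmas), IQR(wide$sigmas))
  degen <- sensitivity_sigma(corpus, reps = 50, n_low = 200, n_high = 200, seed = 9)
  expect_equal(max(degen$sigmas) - min(degen$sigmas), 0)
  expect_equal(degen$sigmas[1], pooled_sigma(corpus, 200), tolerance = 1e-12)
})

test_that("priors are zero-centered Normals; degenerate corpora are refused", {
  corpus <- data.frame(b = c(0.4, -0.8, 1.1), se = c(0.2, 0.3, 0.25))
  pr <- prior_from_corpus(corpus)
  expect_s3_class(pr, "cox_prior")
  expect_identical(pr$mu, 0)
  expect_equal(pr$sigma, pooled_sigma(corpus))
  expect_identical(pr$truncation, "none")
  expect_error(prior_from_corpus(data.frame(b = c(0, 0), se = c(0, 0))),
               "sigma")
})

test_that("screened effects convert to a (b, se) corpus via the log transform", {
  effects <- data.frame(
    subfield = c("a", "a", "b"),
    hr = c(2.3, 0.6, 1.1), level = c(95, 90, 95),
    hr_lower = c(1.5, 0.4, 1.0), hr_upper = c(3.4, 0.9, 1.2),
    passed = c(TRUE, TRUE, FALSE))
  corpus <- effects_to_corpus(effects, subfield = "a")
  expect_equal(nrow(corpus), 2)
  expect_equal(corpus$b, log(c(2.3, 0.6)))
  expect_equal(corpus$se[1], se_from_ci(1.5, 3.4, 95))
  expect_equal(corpus$se[2], se_from_ci(0.4, 0.9, 90))
})
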