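test_that("all reporting variants of a complete tuple are extracted", {
  variants <- c(
    "Cox model: HR: 2.3 (95% CI: 1.5-3.4), p<0.01.",
    "Outcome worsened, HR=2.3 (95% CI 1.5-3.4).",
    "Outcome worsened, HR = 2.3 ( 95 % CI 1.5 - 3.4 ).",
    "hazard ratio=2.3; 95% CI, 1.5-3.4",
    "hazards ratio = 2.3 (95% CI 1.5 to 3.4)",
    "hazard ratios: 2.3 [95% CI 1.5-3.4]",
    "hazard ratio (HR) = 2.3 (95% CI: 1.5–3.4)",
    "hazards ratio[HR]=2.3; 95% CI 1.5-3.4",
    "H.R.:2.3 (95% confidence interval: 1.5, 3.4)",
    "HR:2.3 (CI 95%: 1.5-3.4)")
  for (v in variants) {
    e <- extract_first_effect(v)
    expect_false(is.null(e), info = v)
    expect_equal(c(e$hr, e$level, e$hr_lower, e$hr_upper), c(2.3, 95, 1.5, 3.4),
                 info = v)
  }
})

test_that("printed decimal places are recorded at parse time", {
  e <- extract_first_effect("HR=2.30 (95% CI: 1.5-3.400)")
  expect_identical(c(e$decimals_hr, e$decimals_lower, e$decimals_upper),
                   c(2L, 1L, 3L))
  e2 <- extract_first_effect("HR=2 (95% CI: 1-4)")
  expect_identical(c(e2$decimals_hr, e2$decimals_lower, e2$decimals_upper),
                   c(0L, 0L, 0L))
})

test_that("incomplete reports and decoys yield no extraction", {
  decoys <- c(
    "hazard ratio = 2.3, p = 0.01",
    "HR = 1.8, p = 0.03, z = 2.01.",
    "Mean heart rate (HR) was 72 beats per minute.",
    "The HR was elevated in both arms.",
    "95% CI: 1.5-3.4 without a hazard ratio.",
    "")
  for (d in decoys) expect_null(extract_first_effect(d), info = d)
})

test_that("only the first complete tuple is kept", {
  txt <- paste("Primary: HR=1.2 (95% CI: 1.1-1.3).",
               "Secondary: HR=9.9 (95% CI: 5.0-19.6).")
  e <- extract_first_effect(txt)
  expect_equal(e$hr, 1.2)
  # a leading incomplete HR mention must not veto the later complete tuple
  txt2 <- "Unadjusted HR = 1.5, p = 0.2; adjusted HR = 2.0 (95% CI: 1.0-4.0)."
  expect_equal(extract_first_effect(txt2)$hr, 2.0)
})

test_that("screening applies the four validity checks", {
  expect_true(screen_effect(2.0, 95, 1.0, 4.0)$passed)   # exact log midpoint
  expect_true(screen_effect(2.3, 95, 1.5, 3.4)$passed)   # within rounding slack
  expect_identical(screen_effect(2.3, 150, 1.5, 3.4)$reason_codes, "LEVEL_RANGE")
  expect_true("NONPOSITIVE" %in% screen_effect(2.3, 95, -1.5, 3.4)$reason_codes)
  expect_true("BOUND_COLLISION" %in% screen_effect(2.3, 95, 2.3, 3.4)$reason_codes)
  r <- screen_effect(2.3, 95, 1.5, 3.4)
  expect_identical(r$passed, length(r$reason_codes) == 0L)
})

test_that("midpoint tolerance is the half-ULP propagation of printed rounding", {
  # at one decimal place: tol = 0.05/2.3 + 0.025*(0.1/1.5 + 0.1/3.4) = 0.0458,
  # and the observed log-midpoint deviation is 0.0183
  dev <- abs(log(2.3) - 0.5 * (log(1.5) + log(3.4)))
  tol <- 0.5 * 0.1 / 2.3 + 0.25 * (0.1 / 1.5 + 0.1 / 3.4)
  expect_equal(dev, 0.0183, tolerance = 1e-2)
  expect_equal(tol, 0.0458, tolerance = 1e-3)
  expect_true(screen_effect(2.3, 95, 1.5, 3.4,
                            decimals_hr = 1, decimals_lower = 1,
                            decimals_upper = 1)$passed)
  # perturbing the upper bound beyond the tolerance flips MIDPOINT to fail
  set.seed(21)
  for (i in 1:25) {
    b <- stats::rnorm(1, 0, 0.5)
    se <- stats::runif(1, 0.1, 0.3)
    hr <- round(exp(b), 2)
    lo <- round(exp(b - 1.96 * se), 2)
    up <- round(exp(b + 1.96 * se), 2)
    ok <- screen_effect(hr, 95, lo, up, 2, 2, 2)
    if (!ok$passed) next  # rare collision; rounding consistency not at issue
    tol_i <- 0.5 * 0.01 / hr + 0.25 * (0.01 / lo + 0.01 / up)
    bad <- screen_effect(hr, 95, lo, up * exp(4 * tol_i), 2, 2, 2)
    expect_true("MIDPOINT" %in% bad$reason_codes)
  }
})

test_that("bound collision compares values as printed, not reparsed floats", {
  # "2.30" and "2.3" denote the same float but different printed strings
  r <- screen_effect(2.3, 95, 2.3, 2.3,
                     decimals_hr = 2, decimals_lower = 1, decimals_upper = 1)
  expect_false("BOUND_COLLISION" %in% r$reason_codes)
  r2 <- screen_effect(2.3, 95, 2.3, 2.3,
                      decimals_hr = 1, decimals_lower = 1, decimals_upper = 1)
  expect_true("BOUND_COLLISION" %in% r2$reason_codes)
})

test_that("reversed confidence bounds cannot pass screening", {
  expect_false(screen_effect(2.0, 95, 4.0, 1.0)$passed)
})

test_that("retention proportions drop zero-denominator rows", {
  counts <- data.frame(
    subfield = c("a", "a", "b"), journal = c("J1", "J2", "J3"),
    allocated = c(10, 0, 13163), matched = c(5, 0, 7741),
    considered = c(5, 0, 7684))
  rt <- retention_table(counts)
  expect_equal(nrow(rt), 2)
  expect_equal(rt$S1, c(0.5, 7741 / 13163))
  expect_equal(rt$S2, c(1.0, 7684 / 7741))
  expect_equal(rt$S1[2], 0.5881, tolerance = 1e-4)
  expect_equal(rt$S2[2], 0.9926, tolerance = 1e-4)
  expect_error(retention_table(transform(counts, allocated = c(-1, 0, 1))),
               "non-negative")
})

test_that("mining counts are monotone: considered <= matched <= allocated", {
  sim <- gen_abstracts(120, p_complete = 0.6, p_decoy = 0.4,
                       journals = c("Pain", "The Brain", "Elsewhere"),
                       seed = 31)
  mined <- mine_abstracts(sim$articles, make_journal_lists())
  expect_true(all(mined$counts$matched <= mined$counts$allocated))
  expect_true(all(mined$counts$considered <= mined$counts$matched))
  # shared journal: the same article appears in both subfields' corpora
  pain_ids <- split(mined$effects$article_id, mined$effects$subfield)
  shared <- intersect(pain_ids$anesthesiology, pain_ids$neurology)
  expect_true(length(shared) > 0)
})
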