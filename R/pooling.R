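#' Standard error of a log hazard ratio from its confidence interval
#'
#' Recovers `SE(b)` for the log hazard ratio `b = log(HR)` from the reported
#' confidence bounds on the HR scale:
#' `SE(b) = (log(hr_upper) - log(hr_lower)) / (2 * z)`, where `z` is the
#' standard-Normal quantile at `1 - (1 - level/100)/2` (1.96 for a 95%
#' interval). Natural logarithms throughout.
#'
#' @param hr_lower,hr_upper Positive confidence bounds on the hazard-ratio
#'   scale, `hr_lower <= hr_upper`. Vectorized.
#' @param level Confidence level in percent, strictly between 0 and 100.
#' @return Non-negative standard error(s) on the log-HR scale.
#' @examples
#' se_from_ci(1.5, 3.4, 95)  # 0.2088
#' @export
se_from_ci <- function(hr_lower, hr_upper, level) {
  if (any(!(level > 0 & level < 100)))
    stop("confidence level must lie strictly between 0 and 100")
  if (any(hr_lower <= 0) || any(hr_upper <= 0))
    stop("confidence bounds must be strictly positive")
  if (any(hr_lower > hr_upper))
    stop("hr_lower must not exceed hr_upper")
  z <- stats::qnorm(1 - (1 - level / 100) / 2)
  (log(hr_upper) - log(hr_lower)) / (2 * z)
}

.check_corpus <- function(corpus) {
  stopifnot(is.data.frame(corpus), all(c("b", "se") %in% names(corpus)))
  if (nrow(corpus) < 1L) stop("corpus is empty (N = 0); nothing to pool")
  if (any(!is.finite(corpus$b))) stop("all log hazard ratios must be finite")
  if (any(corpus$se < 0)) stop("standard errors must be non-negative")
  invisible(corpus)
}

#' Convert screened mined effects to a (b, SE) corpus
#'
#' Log-transforms the hazard ratios of the effects that passed screening and
#' recovers the standard errors from the confidence bounds via
#' [se_from_ci()].
#'
#' @param effects Effects table, e.g. the `effects` element of
#'   [mine_abstracts()]; only rows with `passed == TRUE` are used.
#' @param subfield Optional subfield name to restrict to.
#' @return Data frame with columns `subfield` (if present in the input),
#'   `b`, and `se`, one row per screened effect.
#' @export
effects_to_corpus <- function(effects, subfield = NULL) {
  stopifnot(is.data.frame(effects))
  if ("passed" %in% names(effects))
    effects <- effects[effects$passed %in% TRUE, , drop = FALSE]
  if (!is.null(subfield) && "subfield" %in% names(effects))
    effects <- effects[effects$subfield == subfield, , drop = FALSE]
  out <- data.frame(b = log(effects$hr),
                    se = se_from_ci(effects$hr_lower, effects$hr_upper,
                                    effects$level))
  if ("subfield" %in% names(effects)) out <- cbind(subfield = effects$subfield, out)
  rownames(out) <- NULL
  out
}

#' Pooled prior mean (identically zero)
#'
#' The sign of a published log hazard ratio is an artifact of how the two
#' arms were dummy-coded, so each study enters the pooled sample twice, once
#' as `+b` and once as `-b`. The mean of the sign-symmetrized pooled sample
#' is therefore exactly 0, whatever the corpus.
#'
#' @param corpus Data frame with columns `b` and `se`, one row per study.
#' @return `0`, exactly.
#' @export
pooled_mu <- function(corpus) {
  .check_corpus(corpus)
  0
}

#' Pooled prior standard deviation at a common per-study sample size
#'
#' Treats the `N` study-level estimates `b_i` with standard errors `SE_i` as
#' `N` samples of a common size `n` that are merged into one pooled sample;
#' the pooled standard deviation
#' `sqrt(((n-1) * sum(SE^2) + n * sum(b^2)) / (N*n - 1))`
#' becomes the prior's standard deviation. Both the between-study spread of
#' the `b_i` and the within-study uncertainty `SE_i` widen the prior, which
#' distinguishes this pooling from inverse-variance meta-analytic weighting
#' (deliberately not used: it would shrink the prior as the corpus grows and
#' down-weight uncertain studies).
#'
#' The per-study size is not recoverable from an abstract; `n = 200` is the
#' conventional working value, and [sensitivity_sigma()] probes how much the
#' result depends on it.
#'
#' @param corpus Data frame with columns `b` and `se`.
#' @param n Assumed common per-study sample size, at least 2.
#' @return Pooled standard deviation on the log-HR scale (non-negative; 0
#'   only for the degenerate all-zero corpus).
#' @export
pooled_sigma <- function(corpus, n = 200) {
  .check_corpus(corpus)
  if (!(is.numeric(n) && length(n) == 1L && n >= 2))
    stop("n must be a single sample size >= 2")
  N <- nrow(corpus)
  sqrt(((n - 1) * sum(corpus$se^2) + n * sum(corpus$b^2)) / (N * n - 1))
}

#' Pooled prior standard deviation with study-specific sample sizes
#'
#' Generalization of [pooled_sigma()] in which study `i` contributes with
#' its own size `n_i`:
#' `sqrt((sum((n_i-1) * SE_i^2) + sum(n_i * b_i^2)) / (sum(n_i) - 1))`.
#' Reduces to [pooled_sigma()] when all sizes are equal.
#'
#' @param corpus Data frame with columns `b` and `se`.
#' @param sizes Integer vector of per-study sample sizes, one per row of
#'   `corpus`, each at least 2.
#' @return Pooled standard deviation on the log-HR scale.
#' @export
pooled_sigma_varying <- function(corpus, sizes) {
  .check_corpus(corpus)
  if (length(sizes) != nrow(corpus))
    stop("sizes must have one entry per study")
  if (any(sizes < 2)) stop("every per-study size must be >= 2")
  sqrt((sum((sizes - 1) * corpus$se^2) + sum(sizes * corpus$b^2)) /
         (sum(sizes) - 1))
}

#' Sensitivity of the pooled standard deviation to per-study sample sizes
#'
#' Repeatedly redraws every study's sample size from the discrete uniform
#' distribution on `[n_low, n_high]` and recomputes the pooled standard
#' deviation, quantifying how strongly the prior depends on the arbitrary
#' common-size assumption of [pooled_sigma()].
#'
#' @param corpus Data frame with columns `b` and `se`.
#' @param reps Number of Monte-Carlo repetitions (the reference analysis
#'   uses 100,000; smaller values are fine for exploration).
#' @param n_low,n_high Bounds of the size distribution (integers,
#'   `2 <= n_low <= n_high`).
#' @param seed Optional integer seed; fixing it makes the draws reproducible.
#' @return An object of class `"sigma_sensitivity"`: list with `sigmas`
#'   (length-`reps` numeric), `reps`, `n_low`, `n_high`, `seed`.
#' @export
sensitivity_sigma <- function(corpus, reps = 100000, n_low = 10,
                              n_high = 10000, seed = NULL) {
  .check_corpus(corpus)
  stopifnot(reps >= 1, n_low >= 2, n_low <= n_high)
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(corpus)
  sigmas <- vapply(seq_len(reps), function(r) {
    sizes <- sample.int(n_high - n_low + 1L, N, replace = TRUE) + n_low - 1L
    pooled_sigma_varying(corpus, sizes)
  }, numeric(1))
  structure(list(sigmas = sigmas, reps = reps, n_low = n_low,
                 n_high = n_high, seed = seed),
            class = "sigma_sensitivity")
}

#' @export
print.sigma_sensitivity <- function(x, ...) {
  q <- stats::quantile(x$sigmas, c(0.25, 0.5, 0.75))
  cat(sprintf(
    "Pooled-sigma sensitivity: %d reps, per-study n ~ U(%d, %d)\n",
    x$reps, x$n_low, x$n_high))
  cat(sprintf("  median %.4f, IQR [%.4f, %.4f]\n", q[2], q[1], q[3]))
  invisible(x)
}

#' Construct a Normal prior on the log hazard ratio
#'
#' @param mu Prior mean on the log-HR scale (0 for elicited priors).
#' @param sigma Prior standard deviation, strictly positive.
#' @param truncation `"none"` for a two-sided prior, `"positive"` or
#'   `"negative"` for a half-Normal prior truncated at 0 (directional
#'   hypotheses).
#' @param n_assumed,n_studies Optional bookkeeping fields recorded by
#'   [prior_from_corpus()].
#' @return An object of class `"cox_prior"`.
#' @export
cox_prior <- function(mu = 0, sigma, truncation = c("none", "positive", "negative"),
                      n_assumed = NA, n_studies = NA) {
  truncation <- match.arg(truncation)
  if (!(is.numeric(sigma) && length(sigma) == 1L && is.finite(sigma) && sigma > 0))
    stop("a Normal prior needs a strictly positive sigma; ",
         "degenerate (sigma = 0) corpora cannot define a prior")
  structure(list(mu = mu, sigma = sigma, family = "normal",
                 truncation = truncation, n_assumed = n_assumed,
                 n_studies = n_studies),
            class = "cox_prior")
}

#' @export
print.cox_prior <- function(x, ...) {
  trunc_txt <- switch(x$truncation,
                      none = "two-sided",
                      positive = "truncated at 0 (positive effects)",
                      negative = "truncated at 0 (negative effects)")
  cat(sprintf("Normal prior on the log hazard ratio: N(%g, %.4g), %s\n",
              x$mu, x$sigma, trunc_txt))
  if (!is.na(x$n_studies))
    cat(sprintf("  elicited from %d studies (assumed per-study n = %g)\n",
                x$n_studies, x$n_assumed))
  invisible(x)
}

#' Elicit a zero-centered Normal prior from a study corpus
#'
#' Combines [pooled_mu()] and [pooled_sigma()]: the mean and standard
#' deviation of the sign-symmetrized pooled sample become the mean (always
#' 0) and standard deviation of a Normal prior on the log hazard ratio.
#'
#' @inheritParams pooled_sigma
#' @return A `"cox_prior"` object with `mu = 0`, untruncated. Truncate with
#'   [cox_prior()] for directional alternatives.
#' @examples
#' corpus <- data.frame(b = c(0.4, -0.8, 1.1), se = c(0.2, 0.3, 0.25))
#' prior_from_corpus(corpus)
#' @export
prior_from_corpus <- function(corpus, n = 200) {
  mu <- pooled_mu(corpus)
  sigma <- pooled_sigma(corpus, n)
  cox_prior(mu = mu, sigma = sigma, truncation = "none",
            n_assumed = n, n_studies = nrow(corpus))
}
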