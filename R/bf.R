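# prior log-density on beta under the (possibly truncated) Normal prior,
# together with the integration window [lo, hi] covering mu +/- 12 sigma
# intersected with the side restriction
.prior_geometry <- function(prior, side) {
  mu <- prior$mu; s <- prior$sigma
  lo <- mu - 12 * s
  hi <- mu + 12 * s
  if (side == "positive") {
    lo <- max(lo, 0)
    logZ <- stats::pnorm(0, mu, s, lower.tail = FALSE, log.p = TRUE)
  } else if (side == "negative") {
    hi <- min(hi, 0)
    logZ <- stats::pnorm(0, mu, s, lower.tail = TRUE, log.p = TRUE)
  } else {
    logZ <- 0
  }
  if (lo >= hi) stop("prior mass is entirely outside the tested side")
  list(lo = lo, hi = hi,
       logdens = function(b) stats::dnorm(b, mu, s, log = TRUE) - logZ)
}

.bf10_terms <- function(terms, prior, side) {
  if (terms$n_events == 0L) return(1)  # likelihood constant in beta
  geo <- .prior_geometry(prior, side)
  pl0 <- .pl_from_terms(terms, 0)
  g <- function(b) .pl_from_terms(terms, b) - pl0 + geo$logdens(b)
  # center the integrand at its (grid-located) maximum to avoid under/overflow
  grid <- seq(geo$lo, geo$hi, length.out = 201L)
  M <- max(g(grid))
  quad <- stats::integrate(function(b) exp(g(b) - M), geo$lo, geo$hi,
                           rel.tol = 1e-8, abs.tol = 0,
                           subdivisions = 500L, stop.on.error = FALSE)
  if (quad$message != "OK")
    stop("quadrature for the marginal likelihood failed: ", quad$message,
         sprintf(" (window [%.3g, %.3g], value %.3g, abs.error %.3g)",
                 geo$lo, geo$hi, quad$value, quad$abs.error))
  exp(M + log(quad$value))
}

#' Bayes factor for a one-predictor Cox regression
#'
#' Computes `BF10 = P(D | H1) / P(D | H0)` for the hypotheses `H0: beta = 0`
#' versus `H1: beta ~ Normal(mu, sigma)` (optionally truncated at 0 for a
#' directional alternative). The likelihood is the Cox partial likelihood
#' ([cox_partial_loglik()]); the marginal likelihood under `H1` is a
#' one-dimensional adaptive quadrature of the partial likelihood weighted by
#' the (renormalized) prior density over `mu +/- 12 sigma`, accumulated in
#' log space so that large samples cannot overflow.
#'
#' `BF10 > 1` is evidence for an arm effect, `BF10 < 1` evidence for its
#' absence. A dataset with no observed events returns exactly 1: the partial
#' likelihood is then constant in `beta` and the data carry no information
#' about the hazard ratio.
#'
#' @param data Data frame with columns `time`, `event`, `arm`.
#' @param prior A `"cox_prior"` object (or list with `mu` and `sigma`).
#' @param side `"two_sided"` (default), `"positive"` (H1 restricted to
#'   `beta > 0`, half-Normal prior), or `"negative"`. Defaults to the
#'   prior's own truncation when one is set.
#' @return A single positive number, the Bayes factor `BF10`.
#' @examples
#' d <- gen_survival(n_per_arm = 60, true_beta = 0.8, seed = 1)
#' bf10(d, cox_prior(0, 1), side = "positive")
#' @export
bf10 <- function(data, prior, side = c("two_sided", "positive", "negative")) {
  if (missing(side) && !is.null(prior$truncation) && prior$truncation != "none")
    side <- prior$truncation
  side <- match.arg(side)
  if (!(is.numeric(prior$sigma) && prior$sigma > 0))
    stop("prior sigma must be strictly positive")
  .bf10_terms(.cox_pl_terms(data), prior, side)
}

#' First index at which a Bayes factor sequence exits a decision interval
#'
#' @param bf Numeric vector of Bayes factors at successive interim looks.
#' @param lower,upper Decision thresholds, `0 < lower < 1 < upper`. The
#'   sequence exits at the first index with `bf <= lower` or `bf >= upper`.
#' @return The exit index, or `NA_integer_` if the sequence never exits.
#' @export
stopping_index <- function(bf, lower = 1 / 20, upper = 20) {
  stopifnot(lower > 0, lower < 1, upper > 1)
  hit <- which(bf <= lower | bf >= upper)
  if (length(hit)) hit[1L] else NA_integer_
}

#' Sequential Bayes factor monitoring with optional stopping
#'
#' Emulates a study in progress: subjects are taken in a (seeded) random
#' entry order, the Bayes factor is recomputed each time `step` further
#' subjects have accrued, and data collection stops the first time `BF10`
#' leaves the decision interval `(lower, upper)` -- by default `(1/20, 20)`,
#' i.e. 20-fold evidence either way. A prefix without any events yields
#' `BF10 = 1` (no stop), not an error.
#'
#' @inheritParams bf10
#' @param thresholds Length-2 numeric `c(lower, upper)` with
#'   `0 < lower < 1 < upper`. The appropriate width is study-specific: wider
#'   intervals buy certainty at the price of more cases.
#' @param step Number of additional subjects between interim looks.
#' @param order_seed Integer seed for the random entry order. When `NULL`,
#'   the `entry_order` column of `data` is honored if present, otherwise
#'   rows are taken as given.
#' @return An object of class `"bf_trajectory"`: list with `steps` (data
#'   frame of `cases_included`, `bf10`), `stopped_at` (interim index, or
#'   `NA` when the sample is exhausted without a decision), `thresholds`,
#'   `prior`, `side`.
#' @examples
#' d <- gen_survival(n_per_arm = 150, true_beta = 0.7, seed = 2)
#' sequential_bf(d, cox_prior(0, 1), side = "positive", order_seed = 2)
#' @export
sequential_bf <- function(data, prior,
                          side = c("two_sided", "positive", "negative"),
                          thresholds = c(1 / 20, 20), step = 10,
                          order_seed = NULL) {
  side <- match.arg(side)
  .check_survival(data)
  stopifnot(length(thresholds) == 2L,
            thresholds[1] > 0, thresholds[1] < 1, thresholds[2] > 1,
            step >= 1)
  n <- nrow(data)
  if (!is.null(order_seed)) {
    set.seed(order_seed)
    perm <- sample.int(n)
  } else if ("entry_order" %in% names(data)) {
    perm <- order(data$entry_order)
  } else {
    perm <- seq_len(n)
  }
  looks <- seq(min(step, n), n, by = step)
  if (looks[length(looks)] != n) looks <- c(looks, n)

  cases <- integer(0); bfs <- numeric(0); stopped_at <- NA_integer_
  for (i in seq_along(looks)) {
    m <- looks[i]
    terms <- .cox_pl_terms(data[perm[seq_len(m)], , drop = FALSE])
    bf <- .bf10_terms(terms, prior, side)
    cases <- c(cases, m); bfs <- c(bfs, bf)
    if (bf <= thresholds[1] || bf >= thresholds[2]) {
      stopped_at <- i
      break
    }
  }
  structure(list(steps = data.frame(cases_included = cases, bf10 = bfs),
                 stopped_at = stopped_at, thresholds = thresholds,
                 prior = prior, side = side),
            class = "bf_trajectory")
}

#' @export
print.bf_trajectory <- function(x, ...) {
  k <- nrow(x$steps)
  last <- x$steps[k, ]
  cat(sprintf("Sequential Bayes factor trajectory (%d interim looks)\n", k))
  if (is.na(x$stopped_at)) {
    cat(sprintf("  sample exhausted at %d cases, final BF10 = %.4g (no decision)\n",
                last$cases_included, last$bf10))
  } else {
    cat(sprintf("  stopped at %d cases with BF10 = %.4g (thresholds %.3g / %.3g)\n",
                last$cases_included, last$bf10,
                x$thresholds[1], x$thresholds[2]))
  }
  invisible(x)
}

#' @export
plot.bf_trajectory <- function(x, log = "y", ...) {
  plot(x$steps$cases_included, x$steps$bf10, type = "b", log = log,
       xlab = "cases included", ylab = expression(BF[10]), ...)
  graphics::abline(h = x$thresholds, lty = 2, col = "grey40")
  invisible(x)
}

#' Sensitivity of a sequential Bayes factor analysis to the prior scale
#'
#' Re-runs [sequential_bf()] for a grid of prior standard deviations (the
#' reference grid is 0.3 to 1.7 in steps of 0.1), holding the entry order
#' fixed across grid members so that trajectories are comparable.
#'
#' @inheritParams sequential_bf
#' @param sigmas Positive numeric vector of prior standard deviations.
#' @param mu Common prior mean (0 for elicited priors).
#' @return A named list of `"bf_trajectory"` objects, one per sigma.
#' @export
sensitivity_grid <- function(data, sigmas = seq(0.3, 1.7, by = 0.1), mu = 0,
                             side = c("two_sided", "positive", "negative"),
                             thresholds = c(1 / 20, 20), step = 10,
                             order_seed = NULL) {
  side <- match.arg(side)
  stopifnot(length(sigmas) >= 1, all(sigmas > 0))
  .check_survival(data)
  # freeze one entry order for the whole grid
  n <- nrow(data)
  if (!is.null(order_seed)) {
    set.seed(order_seed)
    perm <- sample.int(n)
  } else if ("entry_order" %in% names(data)) {
    perm <- order(data$entry_order)
  } else {
    perm <- seq_len(n)
  }
  frozen <- data[perm, , drop = FALSE]
  frozen$entry_order <- seq_len(n)
  out <- lapply(sigmas, function(s) {
    sequential_bf(frozen, cox_prior(mu, s), side = side,
                  thresholds = thresholds, step = step, order_seed = NULL)
  })
  names(out) <- formatC(sigmas, format = "g")
  out
}
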