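.check_survival <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("time", "event", "arm") %in% names(data)))
  if (any(data$time <= 0)) stop("survival times must be positive")
  if (!all(data$event %in% c(0, 1))) stop("event must be coded 0/1")
  if (!all(data$arm %in% c(0, 1))) stop("arm must be dummy-coded 0/1")
  invisible(data)
}

# Precompute the Efron risk-set terms of the partial log-likelihood for a
# two-arm dataset. With a binary covariate every risk-set sum is a linear
# function of exp(beta), so the whole log-likelihood collapses to
#   pl(beta) = Sx * beta - sum_k log(a_k + c_k * exp(beta)),
# with one (a_k, c_k) pair per event within each tied event time (Efron's
# within-tie downweighting of the death set), and Sx the number of events in
# arm 1. This makes evaluation over a whole beta grid a single matrix op.
.cox_pl_terms <- function(data) {
  .check_survival(data)
  t <- data$time; e <- data$event; x <- data$arm
  if (sum(e) == 0) {
    return(list(Sx = 0, a = numeric(0), c = numeric(0), n_events = 0L))
  }
  ord <- order(t)
  ts <- t[ord]; es <- e[ord]; xs <- x[ord]
  n <- length(ts)
  cum1 <- cumsum(xs)
  cum0 <- cumsum(1 - xs)
  tot1 <- cum1[n]; tot0 <- cum0[n]

  ev_t <- ts[es == 1]
  ev_x <- xs[es == 1]
  ut <- unique(ev_t)
  d1 <- as.numeric(tapply(ev_x, match(ev_t, ut), sum))
  dd <- as.numeric(tapply(ev_x, match(ev_t, ut), length))
  d0 <- dd - d1
  nbefore <- findInterval(ut, ts, left.open = TRUE)  # count of times < ut
  r1 <- tot1 - ifelse(nbefore > 0, cum1[pmax(nbefore, 1L)], 0)
  r0 <- tot0 - ifelse(nbefore > 0, cum0[pmax(nbefore, 1L)], 0)

  a <- numeric(sum(dd)); cc <- numeric(sum(dd)); k <- 0L
  for (j in seq_along(ut)) {
    for (l in seq_len(dd[j]) - 1L) {
      k <- k + 1L
      a[k] <- r0[j] - (l / dd[j]) * d0[j]
      cc[k] <- r1[j] - (l / dd[j]) * d1[j]
    }
  }
  list(Sx = sum(ev_x), a = a, c = cc, n_events = as.integer(sum(dd)))
}

.pl_from_terms <- function(terms, beta) {
  if (terms$n_events == 0L) return(rep(0, length(beta)))
  eb <- exp(beta)
  # guard the far tails: with a binary covariate the risk-set sum
  # a + c*exp(beta) stays finite for |beta| < ~700, far beyond any prior mass
  terms$Sx * beta - colSums(log(outer(terms$c, eb) + terms$a))
}

#' Cox partial log-likelihood for a two-arm dataset
#'
#' Evaluates the log partial likelihood of the one-predictor Cox model
#' `lambda(t | x) = lambda0(t) * exp(x * beta)` with a dummy-coded arm
#' indicator, using Efron's correction for tied event times. The baseline
#' hazard is eliminated by the risk-set construction, so `beta` is the only
#' parameter. A dataset with no observed events has a constant (zero) log
#' partial likelihood.
#'
#' @param data Data frame with columns `time` (positive), `event` (0/1),
#'   `arm` (0/1).
#' @param beta Numeric vector of log-hazard-ratio values at which to
#'   evaluate.
#' @return Numeric vector, one log partial likelihood per element of `beta`.
#' @examples
#' d <- data.frame(time = c(1, 2), event = c(1, 0), arm = c(1, 0))
#' cox_partial_loglik(d, 0)  # log(1/2): one risk set of two subjects
#' @export
cox_partial_loglik <- function(data, beta) {
  stopifnot(is.numeric(beta), all(is.finite(beta)))
  .pl_from_terms(.cox_pl_terms(data), beta)
}

#' Maximum partial-likelihood estimate of the log hazard ratio
#'
#' Maximizes [cox_partial_loglik()] over `beta` and reports the
#' observed-information standard error (numerical second derivative at the
#' maximum). When the partial likelihood is monotone -- e.g. all events fall
#' in one arm while the other is censored -- no finite maximizer exists and
#' an error is raised.
#'
#' @inheritParams cox_partial_loglik
#' @return List with `beta` (estimate), `se` (standard error), and `loglik`
#'   (maximized log partial likelihood).
#' @export
cox_mle <- function(data) {
  terms <- .cox_pl_terms(data)
  if (terms$n_events == 0L)
    stop("no events observed; the log hazard ratio is not identified")
  bound <- 30
  opt <- stats::optimize(function(b) .pl_from_terms(terms, b),
                         interval = c(-bound, bound), maximum = TRUE,
                         tol = 1e-9)
  if (abs(opt$maximum) > bound - 0.5)
    stop("monotone partial likelihood: no finite maximum ",
         "(needs at least one event in each arm)")
  b <- opt$maximum
  h <- 1e-4 * max(1, abs(b))
  d2 <- (.pl_from_terms(terms, b + h) - 2 * .pl_from_terms(terms, b) +
           .pl_from_terms(terms, b - h)) / h^2
  if (!is.finite(d2) || d2 >= 0)
    stop("observed information is not positive at the maximum")
  list(beta = b, se = 1 / sqrt(-d2), loglik = opt$objective)
}
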