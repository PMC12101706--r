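# Sentence templates for synthetic abstracts. `%s` slots: hr, level, lower,
# upper (as printed strings). The variants span the reporting styles the
# extraction grammar must cover: =/: separators, spacing, head-token
# spellings, bracketed abbreviation, bound separators (hyphen, en-dash,
# "to", comma), and both "95% CI" and "CI 95%" orderings.
.abstract_templates <- c(
  "Treatment was associated with the outcome (HR=%s, %s%% CI: %s-%s).",
  "The adjusted hazard ratio was notable (HR = %s; %s%% CI %s to %s).",
  "Cox regression gave a hazard ratio: %s (%s%% CI, %s–%s).",
  "We observed an effect, hazards ratio = %s [%s%% CI %s-%s].",
  "H.R.: %s (%s%% confidence interval: %s, %s) in the Cox model.",
  "The hazard ratio (HR) = %s (CI %s%%: %s-%s) favored treatment.",
  "Multivariable analysis: HR:%s (%s%% CI:%s-%s).",
  "Risk was elevated (hazard ratio=%s, %s%% CI %s-%s)."
)

.decoy_sentences <- c(
  "Mean heart rate (HR) was 72 beats per minute at baseline.",
  "The hazard ratio = 1.8, p = 0.03 in the univariable model.",
  "HR = 1.2, p = 0.045, z = 2.01 for the secondary endpoint.",
  "Resting HR increased to 88 bpm after infusion."
)

.filler_sentences <- c(
  "We conducted a multicenter cohort study of adults with the condition.",
  "Participants were followed for a median of 4.2 years.",
  "Outcomes were adjudicated by a blinded committee.",
  "Analyses used Cox proportional hazards regression.",
  "Baseline characteristics were balanced between groups."
)

#' Generate synthetic abstracts with known embedded hazard-ratio tuples
#'
#' Builds an article table whose abstracts emulate the reporting styles the
#' mining grammar targets. With probability `p_complete` an abstract embeds
#' one complete HR + CI tuple, rendered in a randomly chosen format variant
#' with the numbers rounded to 1-2 decimal places; the printed tuple is
#' regenerated until it passes [screen_effect()], so every embedded tuple is
#' recoverable by construction. With probability `p_decoy` a decoy sentence
#' is added (a hazard ratio coupled only with a p-value, or "heart rate
#' (HR)"), which must never be extracted. The returned truth ledger records
#' both the printed tuple and the underlying exact effect.
#'
#' @param n_articles Number of articles.
#' @param p_complete Probability an abstract carries a complete tuple.
#' @param p_decoy Probability an abstract carries a decoy sentence.
#' @param journals Character vector of journal names to sample from.
#' @param level_probs Named numeric vector of CI-level weights (names are
#'   levels in percent); most mass on 95 by default.
#' @param seed Optional integer seed; fixed seeds give identical corpora.
#' @return List with `articles` (data frame `article_id`, `journal`,
#'   `abstract`) and `truth` (one row per embedded tuple: printed values
#'   and decimals, plus the exact `b_true` and `se_true` on the log-HR
#'   scale).
#' @export
gen_abstracts <- function(n_articles, p_complete = 0.7, p_decoy = 0.3,
                          journals = c("Journal of Synthetic Oncology",
                                       "Annals of Simulated Cardiology"),
                          level_probs = c("95" = 0.9, "90" = 0.05, "99" = 0.05),
                          seed = NULL) {
  stopifnot(n_articles >= 0, p_complete >= 0, p_complete <= 1,
            p_decoy >= 0, p_decoy <= 1, all(level_probs >= 0))
  if (!is.null(seed)) set.seed(seed)
  level_probs <- level_probs / sum(level_probs)

  arts <- vector("list", n_articles)
  truths <- vector("list", n_articles)
  for (i in seq_len(n_articles)) {
    complete <- stats::runif(1) < p_complete
    decoy <- stats::runif(1) < p_decoy
    sentences <- sample(.filler_sentences, 2)
    if (decoy) sentences <- append(sentences, sample(.decoy_sentences, 1), after = 1)
    if (complete) {
      repeat {
        b <- stats::rnorm(1, 0, 0.6)
        se <- stats::runif(1, 0.08, 0.35)
        level <- as.numeric(sample(names(level_probs), 1, prob = level_probs))
        z <- stats::qnorm(1 - (1 - level / 100) / 2)
        d <- sample(1:2, 1)
        hr_p <- round(exp(b), d)
        lo_p <- round(exp(b - z * se), d)
        up_p <- round(exp(b + z * se), d)
        ok <- hr_p > 0 && lo_p > 0 && up_p > 0 &&
          screen_effect(hr_p, level, lo_p, up_p,
                        decimals_hr = d, decimals_lower = d,
                        decimals_upper = d)$passed
        if (ok) break
      }
      tmpl <- sample(.abstract_templates, 1)
      hr_s <- .printed(hr_p, d); lo_s <- .printed(lo_p, d); up_s <- .printed(up_p, d)
      lvl_s <- formatC(level, format = "g")
      sentences <- append(sentences, sprintf(tmpl, hr_s, lvl_s, lo_s, up_s),
                          after = sample(0:length(sentences), 1))
      truths[[i]] <- data.frame(
        article_id = sprintf("A%05d", i),
        hr = hr_p, level = level, hr_lower = lo_p, hr_upper = up_p,
        decimals = d, b_true = b, se_true = se,
        stringsAsFactors = FALSE)
    }
    arts[[i]] <- data.frame(
      article_id = sprintf("A%05d", i),
      journal = sample(journals, 1),
      abstract = paste(sentences, collapse = " "),
      stringsAsFactors = FALSE)
  }
  articles <- do.call(rbind, arts)
  if (is.null(articles))
    articles <- data.frame(article_id = character(0), journal = character(0),
                           abstract = character(0), stringsAsFactors = FALSE)
  truth <- do.call(rbind, truths[!vapply(truths, is.null, logical(1))])
  if (is.null(truth))
    truth <- data.frame(article_id = character(0), hr = numeric(0),
                        level = numeric(0), hr_lower = numeric(0),
                        hr_upper = numeric(0), decimals = integer(0),
                        b_true = numeric(0), se_true = numeric(0),
                        stringsAsFactors = FALSE)
  rownames(articles) <- rownames(truth) <- NULL
  list(articles = articles, truth = truth)
}

#' Generate a synthetic corpus of study-level log hazard ratios
#'
#' Statistical stand-in for a mined effect corpus: true log hazard ratios
#' are folded-Normal magnitudes `|z| * tau` with random signs (heavy mass
#' near zero, occasional large effects, sign irrelevance), and standard
#' errors scale as `c / sqrt(n_i)` with per-study sizes drawn uniformly
#' from `size_range`, linking uncertainty to study size. The defaults are
#' calibrated so that the per-study means of `b^2` (~0.89) and `SE^2`
#' (~0.11) match a typical biomedical subfield corpus.
#'
#' @param N Number of studies.
#' @param tau Scale of the true log-HR magnitudes (`E[b^2] = tau^2`).
#' @param size_range Integer bounds of the per-study sample sizes.
#' @param se_const Constant `c` in `SE_i = c / sqrt(n_i)`.
#' @param seed Optional integer seed.
#' @return Data frame with columns `b`, `se`, and `n` (the drawn sizes).
#' @export
gen_effect_corpus <- function(N, tau = 0.94, size_range = c(50, 1000),
                              se_const = 6, seed = NULL) {
  stopifnot(N >= 1, tau > 0, se_const > 0,
            length(size_range) == 2L, size_range[1] >= 2,
            size_range[1] <= size_range[2])
  if (!is.null(seed)) set.seed(seed)
  signs <- sample(c(-1, 1), N, replace = TRUE)
  b <- signs * abs(stats::rnorm(N)) * tau
  n_i <- sample.int(size_range[2] - size_range[1] + 1L, N, replace = TRUE) +
    size_range[1] - 1L
  data.frame(b = b, se = se_const / sqrt(n_i), n = n_i)
}

#' Simulate a two-arm trial with exponential event times
#'
#' Generates time-to-event data from the proportional-hazards model with a
#' constant baseline hazard: event times are exponential with rate
#' `baseline_rate * exp(true_beta * arm)`, censoring is independent
#' exponential (rate `censor_rate`; 0 disables it) with an optional
#' administrative cutoff, and a random entry order is recorded for
#' sequential analyses.
#'
#' @param n_per_arm Subjects per arm (arm 0 = control, arm 1 = treatment).
#' @param true_beta True log hazard ratio.
#' @param baseline_rate Baseline exponential event rate (events per unit
#'   time in the control arm).
#' @param censor_rate Rate of the independent exponential censoring process.
#' @param admin_cutoff Optional administrative censoring time.
#' @param seed Optional integer seed.
#' @return Data frame with columns `time`, `event`, `arm`, `entry_order`.
#' @examples
#' d <- gen_survival(100, true_beta = 0.7, seed = 1)
#' mean(d$event[d$arm == 1]) / mean(d$event[d$arm == 0])
#' @export
gen_survival <- function(n_per_arm, true_beta, baseline_rate = 0.1,
                         censor_rate = 0.02, admin_cutoff = NULL,
                         seed = NULL) {
  stopifnot(n_per_arm >= 1, baseline_rate > 0, censor_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  arm <- rep(c(0, 1), each = n_per_arm)
  n <- length(arm)
  t_event <- stats::rexp(n, rate = baseline_rate * exp(true_beta * arm))
  t_cens <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate) else rep(Inf, n)
  if (!is.null(admin_cutoff)) t_cens <- pmin(t_cens, admin_cutoff)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  data.frame(time = time, event = event, arm = arm,
             entry_order = sample.int(n))
}
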