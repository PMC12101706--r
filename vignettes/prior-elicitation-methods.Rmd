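---
title: "Eliciting Cox-regression priors from published hazard ratios: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eliciting Cox-regression priors from published hazard ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxprior)
```

## The model and the test

For a two-arm time-to-event comparison we work with the one-predictor Cox
model $\lambda(t \mid x) = \lambda_0(t)\,e^{x\beta}$, $x \in \{0, 1\}$
dummy-coded, so the hazard ratio is $HR = e^\beta$ and $\beta = 0$ is "no
arm effect". The hypotheses are the point null $H_0:\beta = 0$ against
$H_1:\beta \sim N(\mu_p, \sigma_p)$, optionally truncated at 0 when the
direction is hypothesized in advance. The Bayes factor is

$$
BF_{10} \;=\; \frac{\int_{\Omega_1} f(D \mid \beta)\, f(\beta)\, d\beta}
                   {f(D \mid \beta = 0)},
$$

a prior-weighted average of the likelihood against its value at the null.
`f(D | beta)` is instantiated as the **Cox partial likelihood** with
Efron's correction for ties: it eliminates the baseline hazard, so no prior
on $\lambda_0$ is needed, and it is the same objective every applied Cox
analysis already maximizes. A full parametric likelihood would demand
baseline assumptions the elicited prior says nothing about. The partial
likelihood is implemented in the package (rather than delegated) because
the quadrature needs it evaluated on whole grids of $\beta$ at once; with a
binary covariate every Efron risk-set sum is linear in $e^\beta$, so one
precomputed set of coefficients serves all grid points. The test suite
cross-checks it against `survival::coxph` at many $\beta$ values,
including tied data.

## Mining abstracts

**Journal canonicalization.** Bibliographic sources disagree on
punctuation, ampersands, case, and "..., The". The cleaning order matters
and is fixed: ampersand replacement first (a punctuation strip would
destroy `&` before it can become `AND`), then the strip, then repositioning
of the trailing article, then whitespace collapse and upper-casing. The
function is idempotent, which the suite checks on random strings.

**Extraction grammar.** Published abstracts report the same fact in many
surface forms. The grammar accepts the head tokens `hazard ratio(s)`,
`hazards ratio(s)`, `HR`, `H.R.`, and a bracketed abbreviation after the
spelled-out form; `=` or `:` with optional spaces; both `95% CI` and
`CI 95%` orderings of the level; and bounds separated by hyphen, en/em
dash, `to`, or comma. Decimal points only — decimal-comma locales are out
of scope. A tuple is used **only when all four numbers are present**; an HR
coupled with a p-value alone is discarded (p-values do not map back onto an
interval without knowing how they were computed), and "heart rate (HR)"
phrasings cannot complete the grammar. When an abstract contains several
complete tuples only the **first in reading order** is kept, on the
assumption that primary findings are reported first; a leading *incomplete*
HR mention does not veto a later complete tuple.

**Screening.** Four checks, each with its own reason code, guard against
both extraction mistakes and flawed reporting: the level must lie in
(0, 100); HR and both bounds must be positive; $\log HR$ must sit at the
midpoint of the log bounds **up to printed rounding**; and the HR must not
equal a bound as printed. The midpoint tolerance is made operational as the
first-order propagation of half-ULP rounding through the log:

$$
\left|\log hr - \tfrac12(\log l + \log u)\right| \;\le\;
\frac{0.5 \cdot 10^{-d_{hr}}}{hr} +
0.25\left(\frac{10^{-d_l}}{l} + \frac{10^{-d_u}}{u}\right),
$$

with $d_\ast$ the decimal places recorded at parse time. This is
scale-aware: "2.3 (1.5–3.4)" is allowed a larger absolute log deviation
than "0.23 (0.15–0.34)" printed to three decimals. The bound-collision
check compares values *as printed* at their own decimal places, because
the exclusion targets display rounding ("2.3" collides with "2.3" but not
with "2.30"). Reversed bounds are flagged under the midpoint code: a
reversed interval cannot bracket the HR as reported.

## Pooling into a prior

Each surviving tuple gives $b_i = \log HR_i$ and
$SE(b_i) = (\log u_i - \log l_i)/(2 z^*_i)$ (natural logs throughout, so
$z^*$ calibration and the prior scale agree). Because arm coding is
arbitrary, each study enters sign-symmetrized, forcing $\mu_p = 0$
identically — `pooled_mu()` returns the exact constant rather than a
floating-point sum. The spread is the pooled standard deviation

$$
\sigma_p = \sqrt{\frac{(n-1)\sum_i SE(b_i)^2 + n \sum_i b_i^2}{Nn - 1}},
$$

treating the $N$ studies as merged samples of a common size $n$. Two
properties motivated this over inverse-variance meta-analytic weighting:
the prior should *not* shrink towards a point as the corpus grows (the
corpus informs plausible effect spread, not one common effect), and
uncertain studies should *widen* rather than lose influence. The formula
is implemented with sums over the $N$ studies and denominator $Nn-1$, as
printed in the reference treatment; at corpus sizes in the hundreds the
$2N$ sign-symmetrized variant agrees to well past three decimals.

Abstracts do not reveal per-study sample sizes, so a conventional
$n = 200$ is assumed. `pooled_sigma_varying()` generalizes to
study-specific $n_i$ (and reduces exactly to the constant-$n$ form when
all sizes agree), and `sensitivity_sigma()` redraws every $n_i$ from the
discrete uniform on $\{10, \dots, 10000\}$ — integers, since sizes are
counts — to show how little $\sigma_p$ moves. The reference analysis uses
100,000 repetitions; the default is the same, and the package's own checks
run 1,000 (the Monte-Carlo spread of quartiles is already stable there).
Degenerate corpora (all $b$ and all $SE$ zero) produce $\sigma_p = 0$ and
are refused at prior construction: a Normal prior needs $\sigma > 0$.

## Computing the Bayes factor

The marginal likelihood is a one-dimensional integral, so quadrature beats
sampling: `stats::integrate` (adaptive Gauss–Kronrod) is applied to
$\exp\{\ell(\beta) - \ell(0) + \log f(\beta) - M\}$ over
$\mu_p \pm 12\sigma_p$ (intersected with the half-line for one-sided
tests, where the truncated prior density is renormalized). The offset $M$,
the maximum of the log integrand on a 201-point grid, keeps the integrand
in floating range whatever the sample size; the relative tolerance is
1e-8. At $12\sigma$ the Normal prior mass is $\sim 10^{-33}$ and the
likelihood ratio is bounded by its maximum, so the tail truncation is
negligible against that tolerance. Two analytic anchors guard the
implementation: a dataset with no events gives $BF_{10} = 1$ exactly (the
partial likelihood is constant), and the single-event two-subject dataset
has partial likelihood $\sigma(\beta) = e^\beta/(e^\beta+1)$, whose mean
under any symmetric prior is $\tfrac12 = \sigma(0)$, so $BF_{10} = 1$.
Beyond these, an independent Monte-Carlo oracle (prior draws, averaged
likelihood ratios) must agree within three Monte-Carlo standard errors.

**Sequential monitoring.** `sequential_bf()` recomputes $BF_{10}$ each
time `step` further subjects (default 10) have accrued in a seeded random
entry order, and stops at the first interim with
$BF_{10} \le 1/20$ or $\ge 20$. Both granularity and thresholds are
configurable: the 20-fold default expresses a strong-evidence convention,
but the right interval is a certainty-versus-cost decision for the study
at hand. An event-free prefix yields $BF_{10} = 1$ and no stop.
`sensitivity_grid()` repeats the monitoring for
$\sigma_p \in \{0.3, 0.4, \dots, 1.7\}$ with the entry order frozen across
the grid, so differences between trajectories reflect the prior alone.

## What the synthetic generators emulate — and what they do not

`gen_abstracts()` renders known tuples into the grammar's surface variants
with 1–2 printed decimals, regenerating until the printed tuple passes
screening, so round-trip recovery is exact **by construction**; decoy
sentences (p-value-only HRs, heart-rate phrasings) are planted to prove
they are never extracted. This validates the mining machinery, not its
recall on real prose: abstracts in the wild contain journal-specific
formats, line-break artifacts, and unit oddities the templates do not
imitate, so passing tests bound the false-positive behavior much more
tightly than the false-negative behavior.

`gen_effect_corpus()` draws $b_i = s_i |z_i| \tau$ (folded Normal with
random sign: heavy mass near zero, occasional large effects, no
sign information) and $SE_i = c/\sqrt{n_i}$, tying uncertainty to study
size. Defaults $\tau = 0.94$, $c = 6$, $n_i \sim U(50, 1000)$ give
per-study means $E[b^2] \approx 0.89$ and $E[SE^2] \approx 0.11$, the
scale of a typical mined subfield corpus. A lognormal magnitude model was
rejected because it has no mass at zero, unlike observed corpora.

`gen_survival()` uses an exponential baseline with rate multiplied by
$e^{\beta x}$, independent exponential censoring, and an optional
administrative cutoff — the simplest generative model consistent with
proportional hazards. Real trials add staggered entry, covariates, and
non-constant baselines; none affect the validity of the partial-likelihood
checks, which condition the baseline away.

## Problem sizes and numerical conventions in the checks

The package's own verification uses sizes chosen to make Monte-Carlo error
negligible relative to the assertion: 500 abstracts for the mining
round-trip; corpora of 200–20,000 studies for pooling moments; 100 seeded
replicates of a 1,000-subject trial (true $\beta = 0.7$, half-Normal
$N(0,1)^+$ prior) for the stopping study, where the upper threshold is
crossed before sample exhaustion in at least 95% of replicates and the
median final $BF_{10}$ under $\beta = 0$ sits below 1; and $10^6$ prior
draws for the Monte-Carlo Bayes-factor oracle. Sensitivity summaries are
checked at 1,000 repetitions. Ties are broken nowhere by randomness:
stopping uses the *first* exit, level/bound parsing keeps the *first*
complete tuple, and all generators take explicit seeds.

## Known limitations

- The extraction grammar is a reconstruction of the reporting variants it
  targets, not a character-level copy of any particular production regex;
  recall on real abstracts is untested here.
- Allocation by journal is a heuristic; multi-subfield journals contribute
  the same effect to each subfield corpus, and misallocated articles blur
  subfield differences.
- Only the one-predictor, two-arm Cox Bayes factor is provided: no
  covariate adjustment, stratification, interval nulls, or posterior
  sampling (the parameter is scalar; quadrature suffices).
- The elicited priors describe whole subfields. Where better
  problem-specific information exists, it should replace them, and any
  prior choice deserves a sensitivity analysis — which is why the grid
  tooling ships with the package.
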