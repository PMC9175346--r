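---
title: "Weighted cumulative exposure screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted cumulative exposure screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

wcescreen implements an agnostic drug-safety screening pipeline for
longitudinal claims data. Starting from a case-only cohort of new users of a
drug of interest, it tests *every* health event observed after drug
initiation — other drug initiations, diagnoses, procedures — for association
with the patient's weighted cumulative exposure to the drug, and contrasts
the results with a case-crossover comparator. This vignette describes the
models, the generative model behind the synthetic-data module, and the
numerical and design choices a user or reviewer should know about.

## The weighted cumulative exposure model

For a candidate event code, follow-up is discretised into months from the
index month (the first dispensing of the drug of interest; relative month
$t = 1$). With $x(u) \in \{0,1\}$ indicating at least one dispensing in
month $u$, the hazard in month $t$ is modelled as

$$
\lambda(t) = \lambda_0(t)\,
  \exp\Big(\sum_{v=1}^{T} w(v)\, x(t - v + 1) + \gamma' C\Big),
$$

where $w(v)$ is the *weight function*: the log hazard ratio contributed by
one dose taken $v$ months ago, supported on a window of $T$ months
(default 24), and $C$ are baseline covariates (age at index, sex, a binary
disease-severity flag). The weight function is a cubic regression spline,
$w(v) = \sum_k \theta_k B_k(v)$, with `nknots` interior knots (default 1)
equally spaced over $[1, T]$ — knot placement is not canonical, so it is
configurable. Because $w$ is linear in $\theta$, the weighted exposure
history collapses into $K$ artificial time-dependent covariates

$$
Z_k(t) = \sum_{u \le t,\; t-u+1 \le T} B_k(t-u+1)\, x(u),
$$

and $(\theta, \gamma)$ are estimated by an ordinary time-dependent Cox
partial likelihood on the person-period (counting-process) table: one row
per patient-month, right-closed intervals $(t-1, t]$, the event indicator
equal to 1 only in a patient's final row. The *window hazard ratio*
$\exp\big(\sum_{v=1}^T w(v)\big)$ compares a patient exposed throughout the
window with one unexposed throughout; it is the per-code effect size the
screen reports.

Two spline variants are available: the unconstrained basis
($K = \texttt{nknots} + 4$, the default for screening, which presumes
nothing about the shape) and the right-constrained basis
($K = \texttt{nknots} + 2$), which pins $w(T) = w'(T) = 0$ and is the
natural estimator when the effect is expected to wash out within the
window; it has substantially lower variance and is what the package's own
recovery experiments use.

### Lag and timing conventions

* A dose in the current month has lag $v = 1$ (the weight-function axis
  starts adjacent to the event month).
* Time zero is the index month, because the exposure window is anchored to
  drug initiation. Row $t$ covers $(t-1, t]$; the index month is row 1.
* Events recorded in the index month itself are discarded for that code:
  month granularity cannot order within-month occurrences, so such events
  cannot be established as post-exposure. Patients whose first occurrence
  of the code *predates* the index are excluded for that code
  (incident-event design).
* Follow-up ends at the earlier of death and the end of the study period.
  Follow-up deliberately continues after the last dispensing (exposure
  becomes 0): stopping at the last claim would delete exactly the
  unexposed person-months the model needs. An opt-in
  `censor_at_last_activity` rule is available for databases where the last
  record genuinely marks scheme exit.

### Estimation

The partial likelihood is maximised by a Newton algorithm (compiled, Efron
tie correction by default — month granularity makes ties pervasive;
Breslow available) with step-halving, started at $\theta = \gamma = 0$,
gradient tolerance $10^{-8}$, at most 100 iterations, plus a secondary
stop when the likelihood improvement falls below $10^{-10}$ in relative
terms with a negligible gradient (near-collinear pseudo-covariates
otherwise crawl). Monotone likelihoods (e.g. every event among the
exposed) are flagged as non-converged and excluded downstream with a
recorded reason, as are codes with fewer than `min_events` (default 10)
events. The variance is the inverse observed information.

## The bootstrap association test

The WCE model characterises a known association; it was not built to
*test* one. The screen therefore tests each code with a nonparametric
patient-level bootstrap of the log window hazard ratio: patients are
resampled with replacement (all rows of a patient move together), the
model is refitted on each of $B$ replicates (default 1,000), and the
confidence interval is read off the sorted replicates at the order
statistics

$$
j = \lfloor \alpha/2 \cdot B \rfloor, \qquad
k = \lfloor (1 - \alpha/2) \cdot B \rfloor,
$$

with $\alpha = 0.05$ by default. A code is significant when the interval
for the log window hazard ratio excludes 0. The reported p-value is the
two-sided bootstrap tail proportion
$2 \min(\#\{r \le 0\}, \#\{r \ge 0\})/B$, floored at $1/B$ — the tail
count is the only definition consistent with percentile-interval
decisions, and the floor reflects the resolution of $B$ replicates.
Replicates that fail to converge are counted and excluded (silent
imputation would bias the tails); results with more than 20% failures are
reported as *not evaluated*. No multiple-testing correction is applied by
default — the screen is exploratory — but a Benjamini–Hochberg option
exists, and a BH-adjusted `q` column is always emitted.

Seeding: one master seed; each candidate code receives a seed derived
deterministically from the code's rank in the sorted catalog, so a screen
is byte-identical whatever the order (or parallel grouping) in which codes
are processed.

## The case-crossover comparator

For each case (first occurrence of the code after the index month) the
design takes one risk period of $L$ months ending at the event month and
three control periods of the same length earlier in time, each pair of
periods separated by a one-month washout; with half-open month ranges the
risk period is $(e-L, e]$ and control $i$ is
$(e-(i{+}1)L-i,\; e-iL-i]$, a total span of $4L+3$ months. Cases without
$4L+3$ fully observed pre-event months are excluded (and counted);
periods may extend before the index month, where exposure is legitimately
zero. Exposure in a period is the dichotomy "at least one dispensing month
inside the range". The odds ratio is estimated by conditional logistic
maximum likelihood on the 1:3 matched sets (one-parameter Newton; Wald
intervals); concordant sets are uninformative, and one-directional
discordance (separation) is reported as *non-estimable* rather than as a
number. Sensitivity analyses repeat the estimate at $L = 3, 6, 9$ months.
Because each patient is their own control, time-invariant confounding —
including the disease-severity structure described next — cancels by
design; the price is sensitivity only to recent, intermittent exposure
patterns.

## The synthetic claims generator

Real claims from the national database the pipeline targets cannot be
redistributed, so the package ships a seeded generator that reproduces the
statistical structure the pipeline assumes, with known ground truth:

* **Cohort.** Every patient initiates the drug inside the study period
  (case-only), with at least 12 months of prior observation (so new-user
  selection retains everyone) and at least one post-index month. Age, sex
  and a binary severity flag are drawn first; defaults (mean age 54.8,
  sd 16.2; 78% women; 35% severe) mirror a published cohort of
  hydroxychloroquine new users.
* **Exposure.** A single run of exposed months: initiation via a
  truncated-geometric month, then monthly persistence with probability
  `p_persist` *shifted on the log-odds scale for severe patients*. That
  shift is what makes severity a confounder: severe patients accumulate
  more exposure *and* (for severity-linked codes) have higher event
  hazards. Once exposure stops it does not restart; re-initiation cycles,
  dose strengths and stockpiling are deliberately out of scope.
* **Events.** For each code, the first event month is drawn from the
  discrete-time hazard
  $p(t) = 1 - \exp\big(-\lambda_0 m \exp(\sum_v w(v) x(t-v+1) + \gamma'C)\big)$
  — a complementary log-log link to the same linear predictor the WCE
  model fits, so the fitted model is correctly specified and parameter
  recovery is a clean end-to-end check. Events start at $t = 2$ (strictly
  after the index month) and stop follow-up for that code.
* **Truth catalog.** The default spans the effect types the screen claims
  to distinguish: one acute code (exponentially decaying weight, half-life
  2 months), one delayed/cumulative code (weight ramping up with lag), one
  severity-confounded null (zero weight, severity log hazard ratio
  $\log 3$) and 20 pure nulls across drug/diagnosis/procedure systems.
  Non-null weights are scaled so the window hazard ratio is 3.

What the generator does *not* emulate: real coding dialects, visit-driven
observation (events are observed exactly, not only when care is sought),
competing risks other than death-as-censoring, seasonal or calendar
trends, and dose quantities. Passing tests therefore demonstrate that the
estimator, test and comparator behave as designed *under the model's own
assumptions* — not that those assumptions hold in any particular claims
database.

## Validation studies shipped with the package

The test suite runs four seeded simulation studies; their problem sizes
are the package's own trade-off between Monte-Carlo error and runtime.

* **Recovery.** 2,000 patients, $T = 12$, exponential-decay truth with
  $\sum w = \log 3$, persistence 0.8, baseline hazard 0.02/month (a
  common co-prescription; roughly 1,000 events), right-constrained basis,
  10 repeats. The *mean* window hazard ratio across repeats must fall in
  $[2.4, 3.75]$ and the mean fitted curve must correlate above 0.9 with
  truth. Aggregates are asserted because single-repeat dispersion is
  irreducible: with ~1,000 events the standard error of the log window
  hazard ratio is ~0.13, so individual repeats scatter well beyond any
  reasonably tight band by sampling noise alone.
* **Calibration.** 200 null codes over a 500-patient cohort, $B = 200$:
  the significant-call proportion must lie inside the exact central 95%
  binomial region around the nominal 5%.
* **Denoising.** A severity-confounded null code (severity log hazard
  ratio $\log 3$, persistence log-odds shift +2), 100 repeats: screening
  with the severity covariate must yield strictly fewer false positives
  than screening without it. This is the pipeline's rationale for the
  severity flag: without it, everything correlated with disease severity
  lights up.
* **Comparator.** The conditional-logistic optimum is checked against
  brute-force grid maximisation and an exact conditional likelihood from
  the survival package; permuting exposures within matched sets centres
  the estimate at zero.

Deterministic machinery (pseudo-covariates, person-period construction,
percentile ranks, period layouts) is checked against brute-force oracles
exactly, and the Cox solver against `survival::coxph` to $10^{-7}$ on tied
counting-process data.

## Known limitations

* Monthly binary dose only: no dose quantities, no day/week granularity
  (the table format would support them; only month is exercised).
* First events only; death is treated as censoring, not a competing risk.
* The bootstrap refits the full model per replicate; screens over
  thousands of codes at $B = 1{,}000$ are embarrassingly parallel per
  code but sequential within a code.
* Percentile intervals only — no BCa or studentised variants.
* The number of interior knots is fixed by configuration, not selected by
  information criteria.
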