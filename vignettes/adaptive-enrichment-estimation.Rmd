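---
title: "Estimation after adaptive enrichment: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimation after adaptive enrichment: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrichest)
```

## The design and its timeline

`enrichest` analyzes two-stage adaptive enrichment trials with survival
endpoints. The full population is partitioned into $K$ biomarker strata
with known prevalences $p_1,\dots,p_K$. All calendar times are days since
the start of recruitment ($t_0 = 0$):

* $t_1$ — interim analysis, the day the `interim_events`-th event occurs
  among enrolled patients. Stage-1 patients are those with
  `entry_day <= t1`.
* $\tilde t_1 = t_1 + {}$`tilde_offset_days` — the prespecified day stage-1
  follow-up ends. Fixing this *offset* in advance (rather than reacting to
  the accumulating data) is what keeps the post-interim increment
  approximately independent of the interim data.
* $t_2$ — the day the `stage2_events`-th event occurs among stage-2
  patients (recruited after $t_1$, from the selected partitions only).

A subject recruited after an analysis day is excluded from that snapshot
entirely — they are not "censored at time zero". Survival time at analysis
day $a$ is $\min(\text{event day}, \text{last follow-up}, a) -
\text{entry day}$.

## Score statistics and the independent increment

All estimation is built on the two-sample log-rank score $S$ and its
hypergeometric information $V$, with $\hat\theta = S/V$ the log hazard
ratio estimate and $\hat\theta \sim N(\theta, 1/V)$ asymptotically. The
sign convention is that $S > 0$ means excess events under the experimental
treatment, so negative $\hat\theta$ favors it. With ties, the variance term
carries the $(n-d)/(n-1)$ correction and risk sets are right-continuous
(a subject censored on an event day is still at risk), the convention of
standard log-rank software; the test suite checks $S$ and $V$ against
`survival::survdiff` to $10^{-10}$.

For a selected partition the *combined* statistic $S_N, V_N$ pools stage-1
patients censored at $\tilde t_1$ with stage-2 patients censored at $t_2$.
The *increment* is formed by subtraction, $S_N - S_1$ and $V_N - V_1$ — not
by running a log-rank on "incremental data" — and
$\hat\theta_2 = (S_N-S_1)/(V_N-V_1)$ is taken as (approximately)
independent of the interim estimate with variance $1/(V_N-V_1)$. The
combined estimate always satisfies the inverse-variance identity
$\hat\theta_N = (\sigma_2^2\hat\theta_1 + \sigma_1^2\hat\theta_2)/
(\sigma_1^2+\sigma_2^2)$ exactly, which the tests assert per replicate.

The independence of the increment is an *approximation* when
$\tilde t_1 > t_1$: stage-1 patients contribute to both pieces. The
package treats it as exact in the estimators (as the estimators' derivation
does) and quantifies the consequences by simulation; a property test checks
that the empirical correlation between $\hat\theta_1$ and $\hat\theta_2$
under the null is within Monte-Carlo noise of zero.

## Selection rules and truncation bounds

Both rules act on the stage-1 estimates at $t_1$:

* **adaptive threshold** — the largest prefix $\{1..s\}$ with
  $\sum_{j\le s}p_j\hat\theta_{1,j} / \sum_{j\le s}p_j \le b$; appropriate
  when a threshold-ordered biomarker makes $\theta_1 \le \dots \le
  \theta_K$ plausible;
* **independent** — every partition with $\hat\theta_{1,j}\le b$.

Boundary ties select: the inequalities are non-strict, a measure-zero event
for continuous data. A stop is an empty selection, and downstream
estimation refuses it.

Each rule induces, for each selected partition $j$, the interval
$(l_j, w_j]$ of stage-1 estimates consistent with the observed selection
given the other partitions' estimates. For the independent rule this is
$(-\infty, b]$; for the adaptive threshold rule $w_j$ solves the prefix-$s$
inequality for coordinate $j$ and $l_j$ is the largest value at which some
longer prefix would have been selected ($-\infty$ when $s = K$). A
property test verifies by grid search that substituting any value inside
the interval reproduces the selection and any value outside changes it.

## The conditionally unbiased point estimate

Conditional on the selection, $\hat\theta_2$ is unbiased but noisy; the
naive $\hat\theta_N$ is efficient but selection-biased. The Rao–Blackwell
estimate

$$\hat\theta_U = \hat\theta_N - \frac{\sigma_2^2}{\sqrt{\sigma_1^2+\sigma_2^2}}
\frac{\phi(g(l)) - \phi(g(w))}{\Phi(g(l)) - \Phi(g(w))},\qquad
g(x) = \frac{\sqrt{\sigma_1^2+\sigma_2^2}}{\sigma_1^2}(\hat\theta_N - x)$$

is the expectation of $\hat\theta_2$ given $\hat\theta_N$ and
$l < \hat\theta_1 \le w$: conditional on $\hat\theta_N$, the stage-1
estimate is normal with mean $\hat\theta_N$ and standard deviation
$\sigma_1^2/\sqrt{\sigma_1^2+\sigma_2^2}$, and the truncated-normal mean
propagates linearly to $\hat\theta_2$. In the frozen regime
$\tilde t_1 = t_1$ this is an exact (asymptotic) UMVCUE; with extra stage-1
follow-up it is approximate. Properties verified in the tests: equality
with an independent quadrature oracle to $10^{-8}$ over a grid including
one- and two-sided truncations; exact-normal conditional unbiasedness at
100{,}000 replicates under the independent rule (and 40{,}000 under the
adaptive rule); and the limit $\hat\theta_U \to \hat\theta_N$ as the
bounds recede.

One property worth stating precisely because it is easy to get backwards:
$\hat\theta_U$ is monotone **decreasing** in each truncation bound.
Relaxing the truncation (raising $w$ or $l$) raises the conditional mean of
$\hat\theta_1$, hence lowers the implied $\hat\theta_2$, and the estimate
falls back toward the naive value — which is also why an upper-only
truncation always gives a positive correction.

### Numerical safety

$g$ values beyond about $\pm 6$ standard deviations are evaluated on the
log scale ($\exp(\log\phi - \log\Phi)$, a Mills-ratio form), so corrections
of order $10^{-13}$ — e.g. a truncation bound 7.6 conditional SDs away —
come out as exactly that rather than 0/0. A two-sided truncation whose
probability underflows entirely falls back to the Mills asymptote
$\hat\theta_N + \text{prefactor}\cdot g(\text{nearer bound})$, and if even
that is unavailable the naive estimate is returned with a `degenerate`
attribute and a warning.

## Interval estimation

The naive interval $\hat\theta_N \pm z_{\alpha/(2|S|)}\sigma_N$ splits
$\alpha$ over the selected partitions but ignores selection; simulations
(Table-style summaries from `operating_characteristics()`) show its
simultaneous coverage can fall below the nominal level and its upper-tail
error can exceed $\alpha/2$.

The duality intervals invert the trial's closed test. For each direction
(concluding $\theta_j > 0$, or $< 0$ after negating all estimates), each
nonempty $I \subseteq \{1..K\}$ gets a stage-1 Šidak p-value over $I$
(from stage-1 patients at $\tilde t_1$; dropped partitions at $t_1$ unless
the design follows them) and a stage-2 Šidak p-value over $I \cap S$ (1 if
empty), combined by the weighted inverse normal. $H_j$ is rejected when
every intersection containing $j$ is, i.e. when the adjusted p-value
$\max_{I \ni j} C \le \alpha/2$.

Bounds come from the generalized (shifted-null) tests:

* if every selected partition is rejected, partition $j$'s bound is
  $\max[0, \sup\{v: C(\max\{p_M, 1-(1-p_{1,j}(v))^K\},
  1-(1-p_{2,j}(v))^{|S|}) \le \alpha/2\}]$, where $p_M$ is the largest
  stage-1 Šidak p-value over subsets of dropped partitions;
* otherwise, a rejected partition's bound is fixed at 0 and flagged
  **non-informative** (the known drawback of test-inversion intervals in
  mixed-conclusion cases), and a non-rejected partition gets the minimum
  over $I \ni j$ of the per-intersection bounds, skipping intersections the
  observed data already reject.

The stage-2 Šidak exponent for a general intersection is $|I \cap S|$ —
the stage-2 test is the test of $H_{I\cap S}$ — while the elementary
all-rejected bound pins the exponents at $K$ and $|S|$ as written above.
Upper bounds are computed by negating every estimate, finding lower bounds
for $\delta = -\theta$, and negating back; the tests assert this
anti-symmetry is exact.

### Root finding and p-value clamping

Every bound is the root of a combined p-value that is nondecreasing in the
shift $v$ (both generalized p-values rise with $v$). The solver brackets at
$\tilde\theta_{1,j} \pm 10\tilde\sigma_{1,j}$, widens once to $\pm 20$ SDs,
and bisects to an absolute tolerance of $10^{-6}$; an unbracketable bound
is an error (in the simulator such a replicate is recorded as an `error`
outcome rather than silently imputed). P-values are clamped to
$[10^{-15}, 1-10^{-15}]$ before $\Phi^{-1}$; when both stagewise p-values
sit at the same extreme the combination is defined as that extreme. Subset
enumeration is exact and guarded at $K \le 15$.

Weights default to $\omega_1 = \omega_2 = 1/\sqrt2$ and should be the
square roots of the prespecified stagewise event shares. Configurations
sometimes state the *shares* themselves (e.g. 0.75/0.25, which do not
satisfy $\omega_1^2+\omega_2^2=1$); `trial_design(weights_are_squared =
TRUE)` accepts that convention explicitly rather than guessing.

## What the simulator emulates — and what it does not

`simulation_scenario()` encodes a predictive, non-prognostic biomarker:
Weibull event times with shared shape $\gamma$, control scale $\lambda_C$
in every partition, and experimental scale $\lambda_C e^{\theta_j}$ —
proportional hazards with constant log HR $\theta_j$ within partition.
Defaults mirror an oncology-scale reference design: four equal-prevalence
partitions, $\gamma = 0.5$, $\lambda_C = \ln 2/20$ (median 400 days),
2{,}200 patients accrued uniformly over two years, 1:1 allocation by
independent assignment, interim at 300 deaths, stage 2 until 300 stage-2
deaths, $\tilde t_1 = t_1 + 250$ days, futility threshold $b = 0$ at
$\alpha = 0.05$.

Two modelling choices were genuinely open:

* **Stage-2 accrual.** Post-interim entrants keep the overall accrual rate
  and are all drawn from the selected partitions (prevalences renormalized
  within $S$). With prevalence-proportional accrual instead, 300 stage-2
  deaths can be unreachable when a single quartile continues; enrichment
  with maintained rate is also what the design intends. Entrants after the
  end of stage-2 follow-up are not recruited at all.
* **Dropped partitions' follow-up.** By default stage-1 patients in dropped
  partitions are censored at $t_1$ for the stage-1 p-values
  (`dropped_followed_to_tilde = FALSE`); following them to $\tilde t_1$ is
  a design option that only makes sense when they stay on protocol.

Replicate $r$ is seeded as `seed + r`, so runs are bit-reproducible and any
single replicate can be regenerated in isolation. Replicates that stop at
the interim contribute to selection probabilities only; replicates whose
stage-2 event target is unreachable are flagged and excluded from
estimates.

The simulator does **not** emulate: non-proportional hazards within a
partition, prognostic biomarker effects (a shift of all control hazards
leaves the within-partition contrasts untouched), dropout other than
administrative censoring, staggered or non-uniform accrual, or endpoint
changes between stages. Passing simulation tests therefore demonstrate the
estimators' behavior under clean proportional-hazards sampling with
event-count-driven analyses — not robustness to informative censoring or
model misspecification. A separate caveat inherited from the score
statistic: its normal approximation is centered near $\theta = 0$, so with
very large effects (hazard ratios below about 0.4) all score-based
estimates shade the effect slightly toward zero.

## Problem sizes used in the checks

The packaged tests run the worked example instantly and size the
simulations to keep the suite fast while leaving Monte-Carlo error well
below the effects being checked: 20{,}000 stage-1-only replicates for
selection probabilities, 5{,}000 full replicates for conditional bias,
2{,}000 full replicates per configuration for simultaneous coverage,
100{,}000 exact-normal replicates for conditional unbiasedness, and 4{,}000
exact-normal replicates for duality coverage. Stochastic assertions use
3-Monte-Carlo-SE tolerances at those sizes. `scripts/acceptance.R` uses the
same sizes.

## Known limitations

* Duality bounds can be non-informative (fixed at 0) in mixed-conclusion
  cases; the report flags them, and a practical analysis would fall back to
  the naive bound there.
* The UMVCUE with $\tilde t_1 > t_1$ is only approximately conditionally
  unbiased, by the increment approximation above.
* Summary-level input carries enough for selection, truncation bounds,
  point estimates and naive intervals; duality intervals additionally need
  the stage-1-at-$\tilde t_1$ and stage-2-only summaries and are skipped
  (with a note in the report) when those are absent.
* Estimates are per-partition (a stratified model); the package does not
  pool partitions into a single overall effect, and covariate adjustment
  (Cox regression) is out of scope.
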