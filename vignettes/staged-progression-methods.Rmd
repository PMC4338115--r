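---
title: "Methods: Cox time-varying covariates and Markov multi-state estimation for staged progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Cox time-varying covariates and Markov multi-state estimation for staged progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagecif)
```

## The scientific setting

Clinical staging models posit that a severe disorder — here the motivating
case is bipolar disorder in offspring of affected parents — emerges through
a forward sequence of diagnostic stages: well, non-mood disorder, minor
mood disorder, major mood disorder, bipolar disorder. Diagnostic
convention makes the sequence monotone: once a stage is reached, a subject
is never re-classified to a less severe stage, so a subject's state at age
$t$ is the *most severe diagnosis at or before* $t$. Not every subject
passes through every stage, so stage skipping must be allowed; backward
transitions must not. `stagecif` encodes this as a severity-ordered
directed acyclic graph (`stage_structure()`), with the forward-complete
DAG as default and the terminal diagnosis the unique absorbing state.

Two standard frameworks answer related but different questions on such
data, and this package implements both so they can be compared on equal
terms.

## Framework 1: Cox regression with internal time-varying covariates

With the terminal diagnosis as the outcome, earlier stages enter as 0/1
time-varying covariates ($x_i(t) = 1$ from the age of first diagnosis).
The hazard is

$$\alpha(t \mid x_i(t)) = \alpha_0(t)\, e^{\beta' x_i(t)},$$

fit by maximum partial likelihood on counting-process $(start, stop]$ risk
intervals (`to_counting_process()`, `fit_cox()`). These covariates are
*internal*: they are generated by the subject's own disease process. The
regression coefficient keeps its interpretation — a prior stage multiplies
the terminal hazard by $e^{\beta}$ — but the usual unconditional survival
prediction is not valid, because the covariate's future path is random.
What remains well defined is the cumulative incidence along a *fixed*
covariate path $x^*(s)$, built from the Breslow increments

$$\Delta\hat A(s) = \frac{\delta(s)\, e^{\hat\beta' x^*(s)}}
 {\sum_i Y_i(s)\, e^{\hat\beta' x_i(s)}},
 \qquad
 \widehat{CIF}(t) = 1 - \exp\Big\{-\sum_{s \le t} \Delta\hat A(s)\Big\}.$$

`cif_cox()` implements this with an arbitrary conditioning age: increments
at or before the origin age are discarded, so the curve is the cumulative
incidence given event-free survival to that age under path $x^*$. The
increments always come from the model fit to the full data, not to the
conditioned subset.

### Numerical choices

* Newton–Raphson from $\beta = 0$, convergence when the absolute
  partial-log-likelihood change falls below $10^{-9}$ *and* the score norm
  below $10^{-8}$; at most 50 iterations with step-halving (budget 20
  halvings). These are conventional, reproducible settings.
* Monotone likelihood (perfect separation in risk sets) is reported as an
  estimation error rather than a huge finite estimate; it is detected by
  the step-halving budget or by $|\beta|$ exceeding 20 (a hazard ratio
  beyond $e^{20}$ has no epidemiological meaning).
* Ties are handled by the Breslow approximation by default, because the
  CIF machinery above *is* the Breslow form — using the same convention in
  the regression step keeps estimator and baseline internally consistent.
  The Efron approximation is available for the regression coefficients via
  `ties = "efron"`; the baseline table is always stored in Breslow form at
  the final estimate.
* Risk intervals are half-open $(start, stop]$ with events at $stop$, the
  standard predictable (left-continuous) covariate convention: the
  covariate value used at an event time is the value *just before* it.
* Within-subject ties (two stages dated at the same age) are collapsed to
  a single direct transition to the most severe stage. The model forbids
  zero-length sojourns and the structure permits skipping, so this is the
  only consistent reading; it also means a covariate stage dated at the
  outcome age contributes no covariate-on time.

## Framework 2: nonparametric Markov multi-state estimation

Stages become explicit states. For each allowed transition $(h, j)$ the
cumulative transition hazard is the Nelson–Aalen estimator
$\hat\Lambda_{hj}(t) = \sum_{s\le t} \delta_{hj}(s) / Y_h(s)$
(`nelson_aalen_transitions()`), and the transition probability matrix is
the Aalen–Johansen product integral

$$\hat P(s, t) = \prod_{u \in (s, t]} \big(I + \Delta\hat\Lambda(u)\big)$$

(`aalen_johansen()`), which is row-stochastic by construction, satisfies
Chapman–Kolmogorov exactly, and reduces to $1 -$ Kaplan–Meier in the
two-state case. State occupation curves are rows of $\hat P(0, t)$;
the cumulative incidence of the absorbing state from any conditioning
state and age is a single matrix entry (`cif_absorbing()`).

The Markov assumption — transition rates depend on the current state and
age only, not on sojourn time or path — is *assumed, not tested*. It is
what makes the conditional curve depend only on the state occupied at the
conditioning age.

### Variance estimation

Pointwise variances of $\hat P$ come from recursive delta-method
propagation through the product integral: at each transition time the
covariance of $\mathrm{vec}(\hat P)$ is updated by the linearization of
$P \mapsto P(I + \Delta\hat\Lambda)$, with increment covariances of the
Greenwood (multinomial) type,

$$\widehat{\mathrm{Cov}}\big(\Delta\hat\Lambda_{hj}(u),
  \Delta\hat\Lambda_{hl}(u)\big)
  = \frac{\delta_{hj}(u)\,\{\mathbf 1[j = l]\, Y_h(u) - \delta_{hl}(u)\}}
         {Y_h(u)^3},$$

rows independent across $h$. Only "the delta method" is standard
terminology; the Greenwood-type variant was chosen because it collapses
*exactly* to the Greenwood formula for the Kaplan–Meier estimator in the
two-state case, which gives the test suite a closed-form oracle. A
nonparametric bootstrap (`cif_bootstrap_band()`) is provided as a
cross-check utility, not as the primary method.

Confidence bands use the complementary log-log transform
$g(p) = \log(-\log(1 - p))$, back-transformed so bands respect $[0, 1]$;
no band is emitted where the estimate is 0 or 1, where the transform is
undefined.

### Conventions and degenerate inputs

* A subject leaving (or censored in) state $h$ at time $u$ is still in the
  risk set $Y_h(u)$; sojourn intervals are half-open $(enter, exit]$.
* Simultaneous transitions in different $(h,j)$ pairs at the same age are
  composed within a single product factor.
* Conditioning at age $s$ means accumulating strictly after $s$:
  $u \in (s, t]$. Events exactly at the conditioning age belong to the
  past. The Cox conditional curve uses the same convention.
* The absorbing-target restriction in `cif_absorbing()` is deliberate:
  for a non-absorbing target the matrix entry is not monotone and is not a
  cumulative incidence.
* Delayed entry is supported (`entry_age`, default 0): subjects enter the
  risk set of their current state from their entry age, and stages dated
  before entry are accepted only when flagged prevalent. Cohort studies of
  this kind recruit over an age window, but the default is age-0 entry;
  whether to left-truncate at recruitment is a design decision the data
  owner must make, so it is a switch, not a silent behavior.

## Why the two conditional CIFs differ, and by how much

Both frameworks yield the conditional cumulative incidence of the
absorbing diagnosis given occupation of an earlier stage at a conditioning
age (`conditional_cif_pair()`). Structurally they differ: the Cox curve
jumps at *every* terminal event after the conditioning age (all events
enter $\delta(s)$), while the multi-state curve jumps only at terminal
events reachable from the conditioning state's pathway — so the Cox curve
always has at least as many jump points. This asymmetry is a property of
the estimators, not of the data, and is tested as such.

Even in the two-state degenerate case the curves are not identical at
finite $n$: the null-model Cox curve is the exponential form
$1 - e^{-\hat\Lambda}$, the Aalen–Johansen curve the product-limit form
$1 - \prod(1 - \Delta\hat\Lambda)$. Since $e^{-x} \ge 1 - x$ factorwise,
the Cox curve lies below the multi-state curve pointwise, with a gap that
is second order in the increments and vanishes as $n \to \infty$. The test
suite asserts exactly this ordering and smallness rather than a spurious
identity.

The sup-norm distance between the two curves is computed exactly: both are
step functions, so the supremum is attained on the union of their jump
times plus the window endpoints.

## The cohort simulator

`simulate_cohort()` draws, from each occupied state, competing exponential
waiting times for every allowed outgoing transition (intensity multiplied
by $e^{\text{loghr}}$ for transitions whose trigger state has been
entered), advances to the minimum, and stops at absorption or censoring.
This is the classical competing-exponentials construction of a
time-homogeneous Markov chain, chosen over the equivalent embedded-chain
formulation because per-transition covariate effects inject naturally.
Per-subject random streams are split from the master seed, so the first
$k$ subjects of a larger cohort coincide with a smaller one.

The default staging configuration (`default_sim_config()`) uses the
5-stage forward-complete DAG, administrative censoring uniform on ages
15–30 (a recruitment-to-last-follow-up window typical of high-risk
offspring cohorts), and baseline intensities per year of

| from \\ to | NonMood | MinorMood | MajorMood | Bipolar |
|---|---|---|---|---|
| Well      | 0.045 | 0.010 | 0.010 | 0.002 |
| NonMood   |   —   | 0.060 | 0.025 | 0.004 |
| MinorMood |   —   |   —   | 0.080 | 0.008 |
| MajorMood |   —   |   —   |   —   | 0.025 |

chosen once so that the simulated spread of lifetime diagnoses
qualitatively echoes a high-risk cohort: roughly a fifth of subjects never
diagnosed, about half ever developing a non-mood disorder, a sizeable
minority reaching major mood, and on the order of a tenth reaching bipolar
disorder by end of follow-up. These are *shape* calibrations, not claims
to reproduce any particular cohort's counts.

What the simulator emulates: forward-progressive stage structure with
skipping, exponential (Markov) sojourns, proportional covariate effects,
independent right censoring. What it deliberately does not: familial
clustering (a `family_id` is carried through the data model and a seeded
one-per-family selector is provided, but the estimators treat subjects as
independent), semi-Markov sojourn dependence, diagnostic misclassification,
and interval censoring from annual assessment. Passing tests therefore
certify estimator correctness under the Markov ideal, not robustness to
those real-data features.

For time-homogeneous configurations the exact transition law is
$P(s,t) = e^{Q(t-s)}$ with $Q$ the intensity matrix; `analytic_cif()`
exposes it via the matrix exponential as ground truth for simulation
studies (cross-checked in the tests against an independent ODE solve of
the Kolmogorov forward equations).

## Study sizes used by the experiment suites

The replication studies in the test suite and `scripts/acceptance.R` use
problem sizes chosen to make Monte-Carlo error small relative to the
properties being checked while staying desk-scale: two-state reduction at
$n = 500$; Cox recovery at $n = 2000$ with true log hazard ratio 1.6 and
200 replicates for CI coverage; band coverage at $n = 200$ with 500
replicates, evaluated at the per-replicate median event age against the
analytic CIF; convergence of the two conditional CIFs over
$n \in \{100, 400, 1600\}$ with 50 replicates each; and simulator-vs-truth
agreement at $n = 5000$ in sup norm over ages 0–25. The age-25 cap is
fixed a priori because uniform 15–30 administrative censoring thins the
risk sets in the last years of the window, where any nonparametric curve
is dominated by noise.

## Known limitations

* No covariates on multi-state transition intensities; the multi-state
  side is purely nonparametric.
* No stratified Cox, frailties, or time-dependent coefficients.
* Family clustering is carried but ignored by estimators; analyses of
  multi-offspring cohorts should select one subject per family
  (`select_one_per_family()`) or accept conservative independence.
* The Markov assumption is untested; with strong sojourn-time dependence
  the two conditional CIFs estimate different quantities and need not
  converge to each other.
* Stage ages are treated as exactly observed; prospectively assessed
  cohorts observe them up to the assessment interval.
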