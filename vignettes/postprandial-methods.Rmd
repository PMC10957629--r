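---
title: "Methods: curve-based analysis of postprandial amino acid responses"
author: "postprandial package"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postprandial)
```

## The problem

Crossover digestibility trials feed healthy volunteers different protein
meals (interventions) in successive periods and follow blood amino acid
concentrations for a few hours after each meal.  The scientific question
is comparative: how does uptake after a test protein compare with uptake
after an easily digestible reference protein, summarized per amino acid
by three parameters of interest (PoIs) — the area under the response
curve (AUC), the peak height, and the time to the peak maximum?

Raw-data summaries (max minus min, trapezoid AUC) are fragile against
single outlying samples.  This package instead fits a parametric curve
to every participant x intervention x analyte series and computes the
PoIs analytically from the fitted parameters, which smooths over noise,
tolerates missing and non-equidistant samples, and gives a natural
quality-control layer (implausible curve parameters flag bad fits).

## The response model

Each series is modelled by a baseline-extended Wood curve,

$$y(t) = d + a\,t^{b}e^{-ct}, \qquad b = mc,$$

with four free parameters: baseline concentration $d \ge 0$ (the
fasting level), amplitude $a > 0$, peak time $m > 0$ (minutes), and
decay rate $c > 0$ (1/min).  The shape exponent $b = mc$ is always
derived, never free: $m$ is then directly the time-to-maximum, and the
parameterization keeps every parameter interpretable.  The curve rises
from $d$, peaks at $t = m$, and returns to the baseline as $t \to
\infty$.

The PoIs follow in closed form:

* `Time2Max` $= m$;
* `Height` $= a(b/c)^b e^{-b}$, the curve maximum above baseline,
  identical to $y(m) - d$;
* `AUC`$(t_f) = \int_0^{t_f} a t^b e^{-ct}\,dt
  = a\,\gamma(b+1, c t_f)/c^{b+1}$, where
  $\gamma(q, x) = \int_0^x z^{q-1}e^{-z}dz$ is the lower incomplete
  gamma function with shape $q$ and limit $x$.  AUC is measured above
  the baseline $d$, so it reflects the meal response, not the fasting
  level.

Two numerical points matter.  First, the AUC is evaluated through the
regularized gamma CDF (`pgamma`) on the log scale, which is stable for
any shape exponent; the implementation is verified against adaptive
quadrature of the integrand over random parameter draws (relative
agreement better than $10^{-6}$ is asserted in the test suite).
Second, the curve itself is evaluated in the peak-normalized form
$d + A\,(t/m)^b e^{-c(t-m)}$ with $A$ the peak height, because the
conventional $a\,t^b$ overflows double precision for large $b$.

The default integration limit $t_f$ is the last observed time of each
series — the AUC is then never an extrapolation beyond the data.  A
global $t_f$ (for instance 4 h) can be set when comparability across
series with different sampling matters more.

## Fitting

Because every participant has their own non-zero fasting baseline, the
model cannot be linearized by logarithms, so it is fitted by bounded
nonlinear least squares on the concentration scale (ordinary,
unweighted).  The objective is multimodal — narrow-spike local optima
exist in noisy data — so the fit is multi-start: by default 500 random
starts (configurable; clean synthetic data are fitted equally well with
25–50), each refined by a local optimizer, keeping the converged result
with the smallest residual sum of squares (ties broken by start order).
One deterministic data-driven start — peak time at the argmax of the
observed values, $b = 2$ — is always tried first, which keeps small
start counts reliable.

Internally each local search profiles the linear parameters: for fixed
$(m, c)$ the model is linear in $(A, d)$, which are solved from the
2x2 normal equations (clamped to $A \ge 0$, $0 \le d \le \max y$), so
the search runs over $(m, c)$ only with analytic gradients; a final
polish optimizes all four parameters jointly under the box constraints.
The convergence tolerance is $10^{-8}$ on the relative objective
change.

The start/bound box is deliberately liberal, because narrow boxes cause
convergence failures and the curation step is the real guard:
$d \in [0, \max y]$, $m \in [5, 1.5\,t_{\max}]$ minutes,
$c \in [10^{-4}, 1]$ per minute, and the implied peak height
log-uniform over $(0.01, 10) \times$ the observed data range.  A start
that finishes on a bound still counts as converged.  The lower bound of
0 for $d$ (rather than the minimum observed value) was chosen so that
series that never return towards baseline are not forced into an
artificially high baseline; implausible results are removed later.

At least five non-missing points are required (four parameters plus
one); eight or more are recommended.  Missing values are dropped
pairwise at fit time, never imputed at the data layer.  Duplicate
measurements at the same time within a series are rejected as a
validation error rather than averaged: technical replicates need an
explicit pre-processing decision, not a silent one.

Reproducibility: one study-level seed; per-series seeds are derived by
hashing (participant, intervention, analyte) with it, so refitting a
single series reproduces the pipeline result exactly.

## Curation

Fitted parameters and PoIs outside plausible ranges are replaced by
`NA` and logged.  Package defaults mirror common practice for
individual amino acids: AUC strictly positive, height in (0, 1000)
concentration units, peak time in (15, 200) minutes; curve parameters
are only required to be positive by default.  All intervals are open —
a value exactly on a bound is removed.  A PoI violation removes only
that PoI; a curve-parameter violation removes all three PoIs of the
series, since the whole fit is then suspect.  Curation is idempotent
and never modifies in-range values.  For aggregated amino-acid totals,
much larger heights and AUCs are expected; no automatic rescaling of
the ranges is applied — users supply rules per analyte group.

## Non-responder imputation

A missing PoI often means genuine non-response (no measurable uptake)
rather than bad data, and for AUC and Height a low estimate is then
more truthful than a missing value.  The predictor is the 0.2/0.8
quantile spread of the raw series (quantiles by linear interpolation of
order statistics, R type 7, fixed package-wide), a robust measure of
how much the time course moves.  Per analyte and target PoI, a simple
least-squares line of observed PoI on spread is trained on responders
(at least 3 required) and used to predict missing values classified as
non-response — classified, by default, when the series' spread is below
half the median responder spread for that analyte; missingness with a
large spread looks like data trouble, not non-response, and is left
missing.  Predictions are floored at 0.  Time-to-maximum is never
imputed: without a peak there is no maximum to locate.  The regressions
are fitted per analyte (not pooled): spread-to-AUC slopes differ by an
order of magnitude between amino acids, so pooling would bias low-level
analytes.  The pipeline reports both analyses — responders-only and
with imputation — side by side; diverging conclusions between the two
are themselves a finding that warrants inspection.

## Intervention comparison

Each PoI of each analyte is analysed with the linear mixed model

```
PoI ~ Intervention + Period + (1 | Participant)
```

with Participant a random intercept (participants differ in level;
their identity is a nuisance) and Period a categorical fixed effect,
included by default to catch time trends even though carryover is
unlikely with adequate washout.  Mixed models rather than
repeated-measures ANOVA because balance is not required: curation and
fit failures routinely remove individual cells.

Contrasts compare each test intervention with the reference.  AUC is
compared as a ratio: the response is log-transformed before fitting and
the contrast back-transformed (estimate and CI exponentiated), which is
exactly the estimated-marginal-means convention and keeps the CI exact
on the ratio scale.  Height and Time2Max are compared as differences on
the response scale.  Non-positive values under a log transform are
dropped with a warning rather than offset-shifted — curation guarantees
positive AUCs, and silent offsets distort ratios.

Degrees of freedom use the Kenward–Roger approximation (the package
default, via pbkrtest), with Satterthwaite (via lmerTest) as a faster
alternative; the result table records which was used per row.  On
balanced complete designs the two coincide with the classical df, which
the test suite asserts.  If a degenerate fit defeats both (zero
variance components), the classical residual df is used so that exact
data still produce a confidence interval.  Multiplicity is corrected by
Holm within each PoI family across analytes and contrasts (Holm
dominates Bonferroni without independence assumptions); the family
boundary is a documented package default, configurable to Bonferroni or
none.

## The synthetic-study generator

Every statistical property of the pipeline is validated on simulated
crossover studies with known ground truth.  The default design mirrors
a typical protein-digestibility trial: 12 participants, 3 interventions
(one reference) in 3 periods under a balanced Latin-square rotation
(Period orthogonal to Intervention), 10 sampling times within 180
minutes, and the 9 essential amino acids with realistic fasting
baselines (25–230 µmol/L) and reference peak heights (15–120 µmol/L)
peaking at 35 minutes; test interventions peak later (45/55 min) at
70–85 % of the reference amplitude.  Participant heterogeneity enters
as an additive Gaussian baseline shift (sd 8 µmol/L) and a
multiplicative log-normal amplitude shift (sd 0.15 on the log scale) per
participant x analyte — mirroring the mixed model's random intercept —
and measurement noise is additive Gaussian (sd 5 µmol/L).  These values
were chosen once as representative of published postprandial EAA data
and are not tuned.  Non-response is emulated by multiplying a series'
amplitude by 0.02 with a configurable probability.  Effect scenarios
scale the test amplitude so the true AUC ratio is exact (AUC is linear
in $a$); when an AUC ratio and a height difference are both requested
they conflict (Height is also linear in $a$ with the shape fixed), the
AUC constraint wins, and the realized height difference is recorded.

What the generator does not emulate: physiological absorption kinetics
(it is a statistical twin of the analysis model, not a compartmental
model), heteroscedastic or correlated measurement error, carryover
between periods, and curve shapes outside the Wood family.  Passing
tests therefore demonstrate correctness of the estimation machinery
under the stated model, not robustness to arbitrary real-data
pathologies — the visual curation tools exist precisely because real
data deviate.

## Validation problem sizes

The statistical test suite runs at sizes chosen to give informative
error bands at interactive runtimes: oracle agreement over 100 random
parameter draws; noiseless recovery over 100 series with 50 starts
(relative error below $10^{-3}$ required in at least 99); noisy-recovery
bias over 200 series at 5 % noise; type-I error and CI coverage of the
full pipeline over 200 replicate null studies with a 3-analyte roster
and 8 starts per fit, pooling all contrasts (rejection between 2 % and
9 %, coverage between 91 % and 98 %); effect recovery of a true AUC
ratio of 0.7 over 100 single-analyte replicate studies.  Satterthwaite
df is used inside the replicated simulations; the balanced designs make
it equivalent to Kenward–Roger there, which a dedicated test asserts.

## Known limitations

* The Wood curve cannot represent responses that dip below baseline or
  have multiple peaks; such series end as poor fits to be curated.
* Imputed values enter the mixed model as if observed: no multiple
  imputation or uncertainty propagation is attempted.  With many
  non-responders the model assumptions should be checked.
* Heterogeneous variances between interventions are not modelled; the
  comparison model is the simplest defensible default, not the only
  possible one.
* The behaviour of the Height formula in the $b \to 0$ limit is
  asserted only through the identity Height $= y(m) - d$.
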