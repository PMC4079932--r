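---
title: "Healthy life expectancy by the Sullivan method: models, variances, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Healthy life expectancy by the Sullivan method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthexp)
```

## The problem

In aging populations women typically outlive men, yet cross-sectional
surveys often show women reporting more functional limitation — the
male–female health–survival paradox. Comparing the *quantity* of
remaining life (life expectancy, from a mortality registry) with its
*quality* (prevalence of unhealthy states, from a household survey)
requires a single measure that combines both. `healthexp` implements
the prevalence-based (Sullivan) decomposition of period life
expectancy into healthy and unhealthy years, with delta-method
variances on both the mortality and the morbidity side, for
populations aged 60 and over on the abridged grid
60–64, 65–69, 70–74, 75–79, 80+.

## The life-table stage (Chiang)

Deaths $D_i$ and mid-period population $P_i$ per sex and 5-year age
group give central rates $m_i = D_i/P_i$. With $a_i$ the average years
lived within the interval by those who die in it, the interval death
probability is

$$q_i = \frac{n_i m_i}{1 + (n_i - a_i)\,m_i},$$

capped at 1 (the raw ratio exceeds 1 once $a_i m_i > 1$). The open
final interval has $q = 1$ and person-years $L = l/m$. Survivorship
$l$, person-years $L_i = n_i l_{i+1} + a_i d_i$, cumulated $T_i$ and
expectancy $e_i = T_i / l_i$ follow in the usual way.

Sampling variances use Chiang's binomial form
$\mathrm{var}(q_i) = q_i^2(1-q_i)/D_i$ and the backward cumulation

$$\mathrm{var}(e_x) = \frac{1}{l_x^2}\sum_{j \ge x}
  l_j^2\big[(n_j-a_j) + e_{j+1}\big]^2 \mathrm{var}(q_j)
  \;+\; \frac{l_w^2 e_w^2}{l_x^2 D_w},$$

where the last term treats the open-interval expectancy $e_w = 1/m_w$
as a ratio of Poisson death counts (delta method). It can be switched
off with `terminal_variance = FALSE` for strict comparability with
implementations that ignore the open interval.

Three choices deserve comment.

* **$a_i = n_i/2$.** At ages 60+ deaths are close to uniform within a
  5-year band, and the decomposition is insensitive to $a$ there; the
  midpoint rule is the standard adult-ages assumption. `a` is
  configurable per interval.
* **Variance denominators under period averaging.** Rates for an index
  year are commonly built from deaths averaged over a triennium with
  the mid-period population. The *estimator* of $q$ then rests on all
  deaths registered in the period, so `registry_life_table()` passes
  the period *total* (average × number of years) to the variance
  denominators via `life_table(var_deaths = )`. Using the averaged
  count instead would overstate $\mathrm{var}(e_x)$ by the number of
  years (threefold for a triennium); simulation with the package's
  generator confirms the total-count variance gives 95% intervals with
  ~95% coverage while the averaged-count variance gives ~99.9%.
* **Zero-death cells** get $q = 0$, $\mathrm{var}(q) = 0$ and a
  warning; a terminal interval with survivors but no deaths is refused
  as degenerate (its person-years are undefined).

Radix 100,000 by default; every reported identity is radix-invariant.
All 95% limits use $z = 1.96$. With 50 survey PSUs a $t_{49}$ quantile
(2.01) would widen survey-side intervals by ~2.5% and reclaim about
one point of coverage; the fixed-$z$ convention is kept because the
package's outputs mirror published tables that use normal limits.

## The prevalence stage

Respondents are classified into four dichotomous indicators:

* `poor_srh`: self-rated health "fair" or "poor" (of five levels);
* `severe`: limited in walking one hundred yards and/or bathing or
  dressing;
* `mild_moderate`: limited in walking more than a mile and/or several
  hundred yards, *and not limited in either severe item* — this makes
  mild/moderate and severe mutually exclusive, which is the reading
  that makes the global indicator exactly additive
  ($\pi_{global} = \pi_{mild} + \pi_{severe}$, a property the package
  asserts on every synthetic survey);
* `global`: any of the four limitations.

Items may arrive as yes/no or as the 3-level "limited a lot / a little
/ not limited" coding ("a lot"/"a little" collapse to limited).
Missing responses drop a record from the affected indicator only
(complete case); no imputation.

Weighted prevalence per sex × age cell is the ratio
$\hat\pi = \sum w y / \sum w$ with a Taylor-linearized variance under
the with-replacement first-stage approximation,
$\frac{a}{a-1}\sum_c Z_c^2 / W^2$ with $Z_c$ the PSU totals of
$w(y - \hat\pi)$. With equal weights and every record its own PSU this
reduces to $\hat\pi(1-\hat\pi)/(n-1)$ — the binomial variance up to
the with-replacement factor $n/(n-1)$. A cell with a single PSU falls
back, with a warning, to a design-effect-inflated binomial
$\mathrm{deff}_0\,\hat\pi(1-\hat\pi)/n$ (default
$\mathrm{deff}_0 = 2$, the planning value of the emulated survey);
`method = "deff"` forces this mode throughout. Confidence limits are
Wald truncated to $[0,1]$, with a logit-scale option.

`prevalence_table()` additionally stores the full covariance matrix of
*all* sex × age cells (domain linearization over the common PSU
frame). PSUs span several age groups and both sexes, so cell estimates
are positively correlated; ignoring that correlation is consequential
downstream (below).

Between-group tests: the default `prevalence_chisq()` is a Rao–Scott
second-order (Satterthwaite) corrected chi-square — the Pearson
statistic from weighted proportions referred to
$\chi^2_{d/(1+a^2)}/\bar\lambda(1+a^2)$, with $\lambda$ the
eigenvalues of the generalized design-effects matrix estimated by the
same PSU linearization. Under a self-PSU multinomial null it
reproduces classical Pearson exactly (asserted in the tests); under a
clustered null its size simulates at ~0.06, the mild anti-conservatism
expected from a $\chi^2$ rather than $F$ reference with 50 PSUs.
`method = "pearson"` gives the classical unweighted test.

## The Sullivan stage

With prevalence $\pi_i$ step-constant on the life-table grid,

$$HLE_x = \frac{1}{l_x}\sum_{i \ge x} (1-\pi_i) L_i,\qquad
  UHLE_x = \frac{1}{l_x}\sum_{i \ge x} \pi_i L_i,$$

so $HLE_x + UHLE_x = e_x$ identically, and the proportion of remaining
life in the unhealthy state is $100\,UHLE_x/e_x$. Two consequences are
useful as desk checks and are enforced as invariants: uniform
prevalence factorizes ($HLE_x = (1-\pi)e_x$), and at the open terminal
age the proportion unhealthy equals the terminal prevalence exactly,
for *any* life table, because $L_w/l_w = e_w$ there. The survey's 80+
prevalence is applied unchanged to the whole open interval.

Uncertainty follows the delta-method approach of Jagger and
colleagues. The default mode (`"prevalence_only"`) propagates only the
survey component,

$$\mathrm{var}(HLE_x) = \frac{1}{l_x^2}\, \mathbf{L}_x' \,V_\pi\,
\mathbf{L}_x,$$

with $\mathbf{L}_x$ the person-years of the tail and $V_\pi$ the full
covariance matrix of the cell prevalences when available (diagonal
otherwise). The off-diagonal terms matter: with the generator's
50-PSU design, diagonal-only propagation loses enough variance to drop
95% interval coverage to ~90%. `variance = "plus_mortality"` adds the
life-table component — the Chiang cumulation applied with
health-weighted occupancy,
$l_j^2[(n_j-a_j)(1-\pi_j) + HLE_{j+1}]^2\mathrm{var}(q_j)$ plus the
terminal Poisson term scaled by the healthy share. Prevalence-only is
the default because registry death counts dwarf survey cell sizes in
the intended setting (the mortality share of $\mathrm{var}(HLE_{60})$
is ~1% under the default scenario), and because published intervals of
this kind are typically prevalence-driven; the combined mode exists
behind the flag since the convention varies across studies.

Group comparisons are Wald intervals on the difference.
`compare_health_expectancy()` sums the two variances (appropriate for
independent surveys). When both sexes come from *one* survey their
prevalence estimates share PSUs and are positively correlated;
summing variances then overstates $\mathrm{var}(\Delta)$ by ~40% under
the default scenario and pushes interval coverage to ~97.5%.
`compare_sullivan()` therefore uses the joint covariance across the
sex × age cells (cross-sex blocks included) and is the recommended
route for within-survey contrasts; its coverage simulates at ~94%.
Mortality components, being independent registries, are always summed.

## The synthetic-data generator

The generator exists so every stage can be tested against known
truth; its defaults emulate the study conditions the package targets.

* **Mortality.** Gompertz hazards from age 60,
  $m(x) = \alpha e^{\beta(x-60)}$, with $\beta = 0.095$ per year and
  $\alpha$ = 0.01212 (men) / 0.00711 (women), chosen so remaining life
  expectancy at 60 is 19.2 / 23.7 years — a realistic female
  advantage for an urban Latin-American population around 2008.
  Registry deaths are Poisson with mean $m_i P_i$ per calendar year,
  with the closed-interval rate taken at the interval midpoint and the
  open-interval rate as the occupancy-weighted $1/e_{80}$ (exact for a
  stationary population). Populations default to a declining age
  profile of roughly 135,000 persons 60+.
* **Survey.** Two-stage cluster sample: 50 PSUs × 30 respondents
  (≈1,500 aged 60+), sex and age-group frequencies matching the
  emulated survey's cell sizes, ages uniform within groups (80+
  truncated at 90). Limitation severity is a latent ordered-logistic
  model on the cluster-specific logit scale,
  $P(\ge \text{mild}) = \mathrm{logis}(\eta + u)$,
  $P(\text{severe}) = \mathrm{logis}(\eta + u - \delta)$, with
  $\eta = b_0 + b_1(\mathrm{age}-62.5)$ per sex, $\delta = 1.9$, and
  PSU effects $u \sim N(0, \sigma^2)$. Generating both binary levels
  from one latent scale guarantees the mild/severe hierarchy the
  classification rules assume. Defaults
  ($b_0$ = −1.03 men / −0.72 women; $b_1$ = 0.055 / 0.080) put global
  limitations near 26%/33% at 60–64 rising to 55%/74% at 80+, and
  severe near 5%/6% rising to 15%/31% — the ranges a survey of this
  design reports. Poor self-rated health is a separate age-flat
  logistic (both sexes ≈12%), because that indicator shows no age
  trend in the emulated setting. $\sigma$ is solved from the target
  design effect via $\mathrm{deff} = 1 + (\bar m - 1)\rho_y$ with the
  outcome ICC computed exactly from the logistic-normal model
  (`sigma_for_deff()`; default target 2 gives $\sigma \approx 0.39$).
  Weights are constant by default with a lognormal option.
* **Ground truth.** `true_values()` integrates the Gompertz survival
  (adaptive quadrature, relative tolerance 1e-10) for $e_x$, averages
  the cluster-conditional logistic over the uniform within-group age
  distribution (analytic in age) and the normal PSU effect (numeric)
  for true cell prevalences, and integrates the step-prevalence-
  weighted survival for true $HLE_x$ — the same estimands the pipeline
  targets, without sampling noise.

What the generator does *not* emulate: probability-proportional-
to-size household selection, non-response and proxy reporting,
post-stratification weighting, institutionalized populations, and any
correlation between an individual's health state and mortality beyond
what the period framework implies. Passing calibration tests therefore
says the estimators are correct for a clean two-stage design, not that
design-specific biases of a real survey are absent.

## Numerical and testing choices

* Interval-midpoint Gompertz rates discretize the hazard; the
  resulting bias in $e_{60}$ is about −0.02 years on the default grid
  and is covered by the 0.05-year tolerance against the fine-grid
  (0.1-year) integration oracle.
* Conservation ($HLE + UHLE = e$) is asserted to 1e-9 relative over
  1,000 random life-table/prevalence pairs; render-time code
  re-asserts it before writing reports.
* Interval calibration is checked by simulation at the default
  scenario scale: 10,000 replicates for the coverage of the 95%
  intervals for prevalence, $e_{60}$, $HLE_{60}$ and the sex gap in
  $HLE_{60}$ (asserted band 93–97%), and 3,000 replicates for the
  size of the design-adjusted chi-square under a clustered null
  (band 0.03–0.07). These sizes keep the Monte-Carlo standard error
  of a coverage estimate near a quarter of a point, small against the
  two-point calibration band. Measured values sit near 94–96% for the
  intervals and 0.06 for the test size.
* Rounding to one decimal happens only at render time
  (round-half-even); all internal computation is unrounded, which is
  what makes the printed proportion-unhealthy rows consistent with
  unrounded inputs.

## Worked example

```{r example}
set.seed(2008)
sc <- hle_scenario()
registry <- generate_mortality(sc, years = 3)
survey <- generate_survey(sc)

lt_m <- registry_life_table(registry, "men")
lt_w <- registry_life_table(registry, "women")
round(le_difference(lt_m, lt_w), 2)

pt <- prevalence_table(survey, "global")
het_w <- sullivan(lt_w, pt, sex = "women")
round(het_w[, c("age", "ex", "prev", "hle", "uhle", "prop_uhle")], 2)

cmp <- compare_sullivan(lt_m, lt_w, pt, quantity = "uhle")
round(cmp, 2)
```

Published prevalence tables can stand in for survey microdata: the
packaged 2008 Campinas estimates reproduce, for instance, the
analytic terminal identity — at exact age 80 the proportion of
remaining life with global limitations equals the 80+ prevalence,
74.1% for women — for any life table on the same grid.

```{r terminal}
h80 <- sullivan(lt_w, campinas_prevalence("global", "women"))
round(h80$prop_uhle[5], 1)
```

## Known limitations

* Period, prevalence-based decomposition: no incidence/multistate
  modelling, so $HLE$ reflects current prevalence, not transitions;
  decomposition of sex gaps into mortality vs. morbidity
  contributions is out of scope.
* Variances treat the life table's $q_i$ as independent binomials and
  the survey by a with-replacement first stage; finite-population
  corrections and stratification are not modelled.
* The Wald intervals use $z = 1.96$; with few PSUs they run ~1 point
  below nominal coverage.
* Single-year-of-age tables, rate smoothing and cause-deleted tables
  are deliberately absent.
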