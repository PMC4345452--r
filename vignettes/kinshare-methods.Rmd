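---
title: "Kin-directed food transfers: model, simulator and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kin-directed food transfers: model, simulator and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinshare)
```

## The scientific problem

In subsistence societies, children consume far more than they produce for
roughly their first two decades, while adults from their late 20s through
their 60s produce large caloric surpluses. Inclusive-fitness theory predicts
how those surpluses move: a donor should transfer calories while the benefit
to the recipient, devalued by the coefficient of relatedness, exceeds the
cost to the donor — Hamilton's rule, $br > c$. Because the marginal benefit
and cost of a calorie are set by each party's production and consumption
schedule, relatedness and *need* should interact: transfers flow
predominantly from less needy to more needy households, and more strongly
the closer the kinship.

`kinshare` turns this into a testable pipeline with four predictions:

* **P1/P2** — parents and grandparents make significant net downward
  transfers to offspring and grandoffspring, with receipts peaking in
  juvenility;
* **P3** — relatedness interacts *negatively* with the donor household's net
  need in determining net transfers;
* **P4** — relatedness interacts *positively* with the recipient household's
  net need.

Field data of the required resolution (dyadic caloric flows with full
genealogies) are not publicly available, so the package pairs the analysis
chain with a synthetic-society generator whose outputs have the same
statistical structure, and validates the chain by parameter recovery: the
fitted models must recover the signatures above when the generative policy
is kin- and need-directed, and must *not* find them under a kin-blind null.

## Pedigree relatedness

Relatedness is computed from the genealogy by the standard recursive kinship
algorithm, processing individuals in generation order:
$\varphi_{ij} = (\varphi_{mj} + \varphi_{fj})/2$ for $i$ with parents $m, f$,
$\varphi_{ii} = (1 + \varphi_{mf})/2$, founders mutually unrelated and
non-inbred, and $r = 2\varphi$. The implementation is validated against an
independent gene-dropping oracle (`gene_drop_relatedness()`): founder
alleles are labelled uniquely and transmitted by Mendelian sampling 200,000
times, and the allele-sharing frequency is compared with the recursion over
a battery of random pedigrees — pair-by-pair against a three-standard-error
band, and in aggregate against the binomial exceedance envelope that
Monte-Carlo error itself implies (with thousands of pairs, a handful of
>3 s.e. pairs is expected even for an exact implementation). The oracle was
written first and is retained as an exported function.

Family dyads are classified from the genealogical links between the two
households' core adults ("heads": members who are parents of other members,
plus their spouses, or the resident adults for childless households), with
precedence parent--offspring > sibling > other-kin; a dyad is non-kin iff
its member-mean relatedness is exactly zero. Affinal links carry no genetic
relatedness; in-law relations are tracked as relationship labels only.

## The synthetic society

`simulate_pedigree()` builds communities from unrelated patrilineages: a
founder couple (ages ~63–75), their children — women marrying out of the
natal household around 18, men around 21, spouses marrying in from outside
the pedigree — and grandchildren, some of them old enough to head young
families of their own. Completed fertility averages six surviving children,
born uniformly over the mother's ages 19–45 with Poisson variation; this
between-household variance in dependent load is what creates donor and
recipient heterogeneity within kindreds. Mortality is not simulated: the
age structure is generated directly, everyone in the roster is alive during
the study window, and the pedigree invariant that every linked parent is
present holds by construction.

Daily gross production and the consumption requirement follow tabulated
age–sex schedules (kcal/day, linearly interpolated). The default knots make
individual net production negative before ~18, positive from the late 20s
through the 60s (male peak near +1800 kcal/day in the 40s), and negative
again in the 70s; at the household level, young families run deficits and
older, empty-nest families run surpluses. Production noise has a
family-level component (persistent productivity differences, default 400
kcal/day per reference adult) and a day-level component (default 600
kcal/day), both scaled by the person's productive capacity.

### Transfer allocation

Within nuclear families, production is pooled. Between co-resident
families, gifts follow Hamilton's margin under isoelastic utility: a donor
family $i$ gives to recipient $j$ while

$$ w_{ij} \cdot u'(c_j / R_j) > u'(c_i / R_i), \qquad u'(x) = x^{-\eta}, $$

where $c$ is the day's available calories, $R$ the summed consumption
requirement (so marginal utility is evaluated on consumption relative to
requirement), and $\eta$ the curvature. Three substantive choices deserve
comment:

* **Curvature** defaults to $\eta = 3$ rather than logarithmic utility.
  With the weight $w$ near 0.25–0.5, log utility requires a 2–4-fold
  consumption asymmetry before any gift flows, which would make
  between-household sharing essentially absent; $\eta = 3$ produces flows
  at ~1.3–1.6-fold asymmetries, matching the prevalence of inter-household
  sharing such economies actually show. The curvature is a policy parameter
  and $\eta = 1$ recovers the textbook logarithmic case (used by the
  two-agent closed-form benchmark).
* **The weight** $w_{ij}$ is the maximum relatedness between the two
  households' heads, multiplied by a life-history benefit bias
  $\exp\{\delta \,(a_i - a_j)\}$ (head ages $a$, default $\delta = 0.03$,
  saturating after one generation of age difference). Heads decide gifts,
  so the rule runs on the deciders' own $r$ — household-mean relatedness
  would dilute two sibling heads ($r = 0.5$) to ~0.15 through their spouses
  and children and suppress sibling-household flows entirely. The age bias
  implements the life-history half of the theory: a calorie consumed by a
  young, growing household carries a higher fitness return than the same
  calorie consumed late in life, so downward flows persist even between
  households of equal current need. Setting $\delta = 0$ recovers a pure
  current-need allocator. The *analysis* modules always use member-mean
  relatedness, which is the construct the dyadic models regress on.
* **Gift events** move the currently highest-gain pair to its
  first-order-condition optimum, which for isoelastic utility has the
  closed form $t = (c_i - K c_j)/(1 + K)$ with
  $K = w^{-1/\eta} R_i / R_j$; gifts smaller than the policy granularity
  (default 1 kcal) are not made, and the granularity doubles as the
  stopping tolerance. Fixed-size stepping was rejected because it cannot
  reach the analytic optimum to sub-kcal accuracy at any practical step
  size; the event rule is exact and conserves calories identically.

Families eat at most `satiation_ratio` (default 1.2) times their summed
requirement per day; the remainder is carried surplus (storage, processing,
waste, feasts) and is attributed to no eater. Without satiation, measured
need (consumption minus production) degenerates into net gift inflow — a
pure transfer echo rather than the production–consumption imbalance the
construct is meant to measure.

Two alternative policies support falsification: `need_only` replaces the
kin weight with a constant (need-directed but kin-blind "charity", which
must produce need main effects but no interactions with relatedness), and
`need_blind` makes random fixed-scale gifts (the null, under which every
model coefficient must be centred at zero with nominal type-I error).

### Interview recording

Families are interviewed about twice a week; each interview's recall covers
the preceding two days, so roughly half of all family-days are covered and
the final day(s) of the study can never be. Three record types are emitted
for covered days: `production` rows (each producer's gross product total),
`meal-portion` rows (the eaten share of the family's retained production,
attributed to members in proportion to their consumption requirements) and
`raw-gift` rows (between-family gifts, attributed to producers in
proportion to that day's output and to recipients in proportion to
requirement). A gift record requires *both* households' recall windows to
cover the day, and dyadic rates divide by jointly observed days; this makes
the per-dyad kcal/day estimator exactly unbiased under the sampling design
(verified by simulation in the test suite). Recorded amounts optionally
carry mean-one lognormal reporting noise (default cv 0.1). One
simplification: a gift is logged at transaction value even in the rare case
the receiving family is itself beyond satiation that day, so recorded
consumption can slightly overcount then.

## Need indices

Measured need is observed consumption minus gross production per observed
day (positive = needy). Because consumption contains received transfers,
measured donor need is mechanically entangled with the outcome — precisely
the endogeneity that motivates the instrumental variant. Estimated
(instrumental) need predicts each household's need from its age–sex
composition alone: production and consumption means are computed for every
5-year × sex cell over the whole sample *excluding the focal family*
(leave-one-family-out), and the household's need is the sum of predicted
consumption minus predicted production over its members. It is invariant to
the family's own realized output by construction; cells emptied by the
exclusion borrow from the nearest age cell of the same sex, logged in an
attribute. In finite samples two households with identical rosters can
receive minutely different predictions (each excludes its own records);
the exclusion is retained because exogeneity, not exact roster symmetry, is
the property the models rely on.

## Dyadic models

The family-level model set regresses the standardized net transfer from the
older household $i$ to the younger $j$ (orientation by age of the oldest
head; ties break to the smaller family id, with a message) on member-mean
relatedness, both households' standardized needs, and the two
need-by-relatedness interactions, with crossed random intercepts for donor
family, recipient family and community, fitted by maximum likelihood with
Wald p-values. Both need variants are fitted; significance statements use
the instrumental variant, and the measured variant enters as a sign
robustness check. Degenerate fits (e.g. a single community) fall back to
OLS with cluster-robust standard errors and are loudly flagged. The
per-category models report each relationship class's mean net transfer
(intercept-only mixed model) and the standardized need slopes within class.
Age–sex profiles of net transfers between focal individuals and a named kin
category (children, grandchildren, spouse, in-laws, and their reverses) use
one mixed model per sex with age-bin fixed effects and a community random
intercept; single-focal bins are reported without p-values and flagged.

Estimator calibration runs the fitted model against data generated from its
own assumptions (3000 dyads, Gaussian crossed random intercepts): biases
must stay below 0.05 standardized units with ~95% confidence-interval
coverage.

## Problem sizes and reproducibility

The default study conditions are two communities of ~40 families (~450
persons) observed for 120 days; recovery studies use 100 replicate seeds
for the kin-directed policy and 100 for the null, and the oracle battery
uses 20 pedigrees at 200,000 drops. These sizes keep a full replication run
in the tens of minutes on a single core while leaving all recovery rates
far from their decision thresholds. Every stage draws from a named
generator hierarchy (demography / production / interview) derived from one
seed, so identical configurations are byte-identical and stages can be
varied independently.

## What passing tests do and do not show

The generator reproduces the qualitative structure the analysis assumes:
life-course production schedules, household pooling, kin- and need-directed
gifts, interview subsampling with recall, and reporting noise. It does not
attempt realistic calibration of any particular population's vital rates,
seasonality, market foods, food processing, or breastfeeding energetics;
polygyny, short-timescale reciprocity and storage/debt are out of scope
(allocation is myopic and daily). Parameter recovery under these conditions
shows that the estimators detect the kin-by-need signature when it is
present and not when it is absent — it cannot show that any real
population's sharing follows the model, and effect magnitudes are specific
to the generator's units and defaults.

## Worked example

```{r example, eval = FALSE}
cfg <- society_config(seed = 1)
sim <- simulate_society(cfg)
nt <- individual_net_matrix(sim$ledger)
dyads <- family_dyad_table(sim$ledger, sim$pedigree)
fit <- fit_family_interaction_model(dyads, need_variant = "estimated")
fit
fit_by_relationship(dyads)
fit_age_profiles(nt, sim$pedigree, "children", direction = "from_focal")
```
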