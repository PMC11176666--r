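---
title: "Methods: dominance ranking and chronic-stress statistics in small colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominance ranking and chronic-stress statistics in small colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressrank)
```

## The problem this package addresses

In small, stable primate colonies, an animal's position in the dominance
hierarchy shapes how it experiences chronic stress: who gets groomed, who
is attacked, and how hormones such as cortisol, oxytocin (OT) and
vasopressin (AVP) move when the whole group is stressed and later allowed
to recover. The data such studies produce are (a) directed, counted
behavior logs — who initiated which behavior toward whom, summed over
six-day observation windows before and after the stressor — and (b) short
longitudinal physiology panels: three sample points for hair cortisol,
plasma neuropeptides and weight (end of baseline, end of stress, end of
recovery) and five weekly fecal immunoglobulin samples during the stress
phase.

`stressrank` implements the complete analysis chain for this design:
dominance ranking from agonistic interactions, split-plot repeated-measures
inference on the longitudinal panels, dyad-level analyses of who changed
behavior toward whom, and a synthetic-colony generator that makes the
whole chain testable without animal data.

## Dominance ranking

Rank is inferred from aggression and submission only. A "win" of animal
$i$ over $j$ is either an aggressive act $i \to j$ or a submissive act
$j \to i$; both classes carry the same weight because the field records
them as two views of the same decided encounter. From the win matrix $W$,
each dyad gets a directed index. The raw variant is the win proportion
$P_{ij} = W_{ij} / n_{ij}$ with $n_{ij} = W_{ij} + W_{ji}$; the default,
chance-corrected variant shrinks sparse dyads toward chance,

$$D_{ij} = P_{ij} - \frac{P_{ij} - 0.5}{n_{ij} + 1},$$

so a 1–0 dyad is not treated as decisively as a 10–0 dyad. David's score
is then

$$\mathrm{DS}_i = w_i + w^{(2)}_i - l_i - l^{(2)}_i,$$

with $w_i = \sum_j D_{ij}$, $l_i = \sum_j D_{ji}$ and the opponent-weighted
second-order terms $w^{(2)}_i = \sum_j D_{ij} w_j$,
$l^{(2)}_i = \sum_j D_{ji} l_j$. Scores sum to zero within each group.

Because colonies differ in size, scores are normalized per group in two
steps: shift by the absolute minimum, $\mathrm{DS}'_i = \mathrm{DS}_i +
|\mathrm{DS}_{\min}|$, then divide by the shifted maximum. The top animal
gets 1, the bottom 0. Note that this construction is ordinary min–max
scaling only while $\mathrm{DS}_{\min} \le 0$; genuine David's scores
always satisfy that (they sum to zero), and `normalize_ds()` refuses
degenerate all-equal inputs rather than returning arbitrary values.

Animals above a normalized score of 0.5 are classed high-ranking (HR),
below 0.5 low-ranking (LR). The inequalities are strict: a score of
exactly 0.5 — which arises structurally, e.g. in odd-sized perfectly
linear hierarchies — is flagged `BOUNDARY`, warned about, and excluded
from HR/LR contrasts rather than silently assigned to a side.

### Choices that were genuinely open

* **Which dyadic index the field's rank computations use** is rarely
  printed. Both variants are implemented; `chance_corrected` is the
  default because it is the convention of the dominance-index literature
  for sparse data. The two variants provably agree only where the
  hierarchy is strict: with equal $n_{ij} = n$ the corrected index is
  affine in $P_{ij}$, which re-weights the first- and second-order terms
  of DS differently from the raw index, so near-tied animals can swap.
  Do not expect identical mid-table orders between variants on noisy
  data; top and bottom of clear hierarchies are stable.
* **Dyads that never interact** contribute zero in both directions by
  default (no dominance relation is invented); a `0.5/0.5` convention is
  available (`zero_dyad = "half"`).
* **Ties in normalized scores** are broken by roster order with a
  warning; with count data and the chance correction, exact ties are
  rare but possible in tiny groups.

## Longitudinal statistics

**Change scores.** Change between sample points is the signed proportion
$(x_i - x_j)/x_j$ relative to the earlier (reference) point, so `0.10`
means a 10% rise. A zero reference makes the score undefined; callers
choose between a hard error and `NA`-with-warning (`na_undefined`), and
downstream analyses drop such units pairwise (correlations) or listwise
(ANOVA), never silently substituting 0.

**Split-plot ANOVA.** `mixed_anova()` is the classical two-way mixed
(repeated-measures) analysis: one within factor (time), one between
factor (HR/LR class, dyad type, or appearance stratum), every unit
observed at every time. Sums of squares are computed directly from cell
means; with a single between factor the time and group effects are
orthogonal, so the decomposition agrees with sequential linear-model
fits (the test suite pins this against base R's multivariate
linear-model route to 1e-8). Sphericity of the within-subject covariance
is tested with Mauchly's W using Box's second-order chi-square
approximation — note that published references differ from one another in
the third-order term of this approximation, which caps meaningful
agreement between implementations at about 1e-3 in the p-value. When the
within factor has more than two levels and Mauchly's p falls below 0.05
(the `gg_alpha` default; the trigger is configurable because "when
required" conventions differ across labs), the Greenhouse–Geisser
$\varepsilon$ scales both degrees of freedom of the within-subject tests.
With two levels, sphericity is vacuous and $\varepsilon \equiv 1$.
Effect size is partial $\eta^2 = SS_\text{effect} / (SS_\text{effect} +
SS_\text{error})$ against the matching error stratum.

**Post hocs.** Time contrasts are two-tailed paired t-tests over all
level pairs (labeled `2vs1`, `3vs1`, `3vs2` by level position), Holm-
adjusted within the family. Estimated-marginal-means contrasts would be a
defensible alternative; paired t is implemented because it is what the
small-n repeated designs in this literature report, and the choice is
visible in the output (`t`, `df` columns).

**Rank-collapsed correlation.** Colonies differ in size and in assay
level, so pooling raw values across groups confounds group effects with
individual ones. The package's non-parametric procedure ranks each
variable *within* its group (average ranks on ties), pools the ranks, and
computes a two-tailed Pearson correlation on the pooled ranks, with the
p-value from the t-transform on $n-2$ degrees of freedom. With a single
group and no ties this is exactly Spearman's $\rho$. "Social rank" as a
correlate is the within-group rank of the baseline normalized score,
oriented so that larger = higher status; the orientation is stated here
and in output headers because the sign of every rank correlation flips
with it.

**Partial correlation.** First-order partial correlation uses the
closed form $r_{xy \cdot z} = (r_{xy} - r_{xz} r_{yz}) /
\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}$ with $n-3$ degrees of freedom. A
control variable collinear with either argument makes the coefficient an
indeterminate 0/0; the package raises a degenerate-control error there
instead of returning 0.

## Dyad-level analyses

All dyads are ordered: behavior initiated by one animal and received by
another, so each partnership contributes two records. Dyad types follow
the members' baseline HR/LR classes — LL, HL, LH, HH — and a group with
$h$ HR and $l$ LR animals contributes $l(l-1)$ LL, $h(h-1)$ HH and $hl$
each of HL/LH ordered dyads; with class splits of 3/3 and 4/3 in two
colonies, the pooled LL count is 12.

Appearance strata capture how much a dyad showed a behavior at baseline:
`ZERO` (never observed), `LOW` ($0 <$ freq $< t$), `HIGH` (freq $\ge t$).
The intervals are half-open exactly as the field prints them. The
threshold $t$ can be fixed per behavior or chosen automatically: the
`auto` rule exhaustively searches integer cut points and picks the one
minimizing the size imbalance between LOW and HIGH among nonzero dyads,
ties resolved toward the smaller threshold — the "similar sample size"
rule stated explicitly. Appearance is assigned per behavior
independently: a dyad can be HIGH for grooming and ZERO for aggression.

Baseline-vs-change analyses exclude non-existing pairs (baseline 0)
before computing change scores — the proportional change is undefined at
zero, and pairs that never showed the behavior cannot shrink it — then
correlate baseline frequency with the change among the remaining pairs.

## The synthetic colony generator

The generator emulates the two-colony design end to end so every stage of
the pipeline is exercisable and parameter recovery is measurable. Its
defaults are the study conditions, not tuning knobs:

* two colonies of 7 and 6 adult females with a planted strict linear
  hierarchy; planted classes split each colony at the middle (4/3 and
  3/3);
* three observation periods of six days; a mean of 20 decided agonistic
  encounters per dyad per observation, the higher-planted animal winning
  with probability 0.9; every decided encounter emits one aggressive
  event (winner → loser) and one matching submissive event on the same
  day;
* grooming and proximity as Poisson counts per ordered dyad (means 15 and
  12 per observation) with a gamma-distributed per-dyad rate multiplier
  (`dyad_dispersion = 1`, i.e. exponential heterogeneity, drawn once per
  dyad and reused across observations). The heterogeneity is what makes
  baseline appearance strata non-trivial — some pairs never groom, some
  groom constantly — and it is also why a handful of dyads contribute
  few agonistic observations;
* post-stress behavioral shifts from the first post-stress observation
  on: LL aggression multiplied by 0.4, LL grooming by 1.8, proximity by
  1.5 across all dyad types;
* physiology proportional to baseline with Gaussian assay noise: hair
  cortisol rises at S2 by 30% plus 60% times the planted normalized rank
  and recovers halfway at S3; OT starts 30% higher at the top of the
  hierarchy, rises 30% globally at S2 and keeps rising at S3 the more the
  lower the rank; AVP rises 40% globally and declines at S3 in proportion
  to rank; immunoglobulins ramp up from week 2 (more for lower-ranked
  animals) and retain half the elevation at week 4; weight drifts up 5%
  only at S3.

Aggression and submission have no separate base rates: their counts are
fully determined by the encounter rate and the win probability, because
each decided encounter produces exactly one event of each class.

Effect sizes are deliberately larger than a 13-animal study could
reliably detect; with realistic effect sizes, n = 13 is underpowered and
recovery frequencies would say more about noise than about the pipeline.
The generator is therefore a correctness instrument, not a power
calculator: passing recovery tests shows the pipeline finds what was
planted at a detectable size, not that the emulated study design could.
Other features of real data the generator does not emulate: observation
effort differences between days, coalition structure (wins are
independent across dyads), seasonal drift, and assay-specific error
distributions (noise is Gaussian, truncated at zero).

A single global seed expands into independent behavioral and
physiological substreams, so regenerating one half of a study never
perturbs the other.

## Problem sizes and numerical conventions

The test suite and the acceptance checks run at the scale the generator
emulates: colonies of 4–9 animals, 100 seeded studies for hierarchy
recovery (median group-wise Spearman against the planted order), and 200
replicates for the rank–cortisol and LL-grooming recovery rates. The
zero-sum identity of David's scores is enforced to 1e-9 over 1,000
random matrices; ANOVA F statistics match the independent linear-model
oracle to 1e-8; partial correlations match the residual-regression oracle
to 1e-10. Degenerate inputs (all-equal scores, all-zero baselines,
constant vectors, zero references) raise typed errors rather than
returning conventional values, so silent propagation of undefined
quantities is impossible by construction.

## Limitations

* Ranking is cross-sectional per observation period; sequential
  (Elo-type) ratings and hierarchy linearity/steepness tests are out of
  scope.
* The ANOVA is the classical univariate split-plot; linear mixed-effects
  models with unit-level random slopes are out of scope, as are effect
  size confidence intervals beyond partial $\eta^2$.
* Network analyses beyond ordered dyads (centrality, community
  structure, permutation tests on network structure) are out of scope.
* With heterogeneous dyad rates, some dyads go unobserved; under the
  default zero-dyad convention they contribute no dominance information,
  which is the conservative choice but slightly widens the spread of
  recovered mid-table ranks in sparse data.
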