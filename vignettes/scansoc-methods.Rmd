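---
title: "Methods: spatial position, dominance and affiliative structure from scan sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial position, dominance and affiliative structure from scan sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scansoc)
```

## The problem

In group-living primates, access to a monopolisable food patch is contested.
Two aspects of social organisation can shape who sits where while waiting
for such a patch to open: the dominance hierarchy (contest competition
favours high-ranking animals at the resource) and affiliative relationships
(tolerated proximity within subgroups of preferentially associating
animals). `scansoc` implements a complete analysis chain for
instantaneous scan-sampling data collected in front of a feeding zone: a
square observation area (30 × 30 m by default) with a door that is the
single access point to food, scanned at 15-minute intervals over a morning
(09:00–12:00) and an afternoon (15:00–18:00) block — 13 + 13 = 26 scans
per observation day. Because the food is released after the afternoon
block, attendance and competition are concentrated in the afternoon, and
all food-patch-relative spatial measures use afternoon scans only.

Three tabular inputs drive everything: per-scan individual positions
(metres on the grid, or an explicit out-of-sight record), an ad libitum log
of agonistic interactions, and individual metadata (sex, age, matriline).

## Spatial frequencies

For each individual, positions are reduced to two numbers relative to the
door centroid (default `(5.5, 3.5)`, the centre of the door cell):

* `F10M`: the proportion of afternoon scans within 10 m of the door, out
  of the afternoon scans in which the individual was observed anywhere in
  the area. A relative frequency, because individuals differ widely in how
  often they are in view.
* `F20M`: the count of afternoon scans beyond 20 m **plus** the afternoon
  scans in which the individual was out of sight — an animal in the
  surrounding forest is by construction far from the patch. This measure is
  deliberately an absolute count, asymmetric with `F10M`.

Observations between 10 and 20 m contribute to neither: the design
contrasts proximity with distance. Boundary conventions are ours and are
fixed in code: the near radius is inclusive (`d <= 10` is "within 10 m"),
the far radius exclusive (`d > 20` is "over 20 m"), and the noon scan
belongs to the morning block. `SRF10M = sqrt(F10M)` is used in all
downstream models; the square-root transform reduces the skew of a
proportion concentrated near zero and is applied unconditionally, with
Bartlett and Breusch–Pagan diagnostics reported (never used as a gate) by
`homoscedasticity_report()`.

An open choice is whether the `F10M` denominator should count only
afternoon scans or all scans in which the individual was ever observed; we
use afternoon-only for internal consistency (numerator and denominator
refer to the same sampling frame), and the `period` argument exposes the
alternative.

## Dominance

Only strictly dyadic agonistic events with a clear outcome enter the
hierarchy; polyadic events and undecided interactions are discarded (and
counted, so the filtering is auditable). From the win matrix `s`:

* dyadic dominance indices
  `D_ij = P_ij − (P_ij − 0.5) / (n_ij + 1)` with `P_ij = s_ij / n_ij`,
  which shrink small samples toward chance (a 1–0 record is weaker
  evidence than a 10–0 record); non-interacting dyads get `D_ij = 0`;
* modified David's scores `DS_i = w_i + w2_i − l_i − l2_i` with
  `w_i = Σ_j D_ij`, `w2_i = Σ_j D_ij w_j` and the mirror-image loss terms.
  Scores sum to zero by construction; this conservation is tested on
  thousands of random win matrices.
* linearity: Landau's
  `h = 12/(N³−N) · Σ_i (V_i − (N−1)/2)²`, with tied and unknown dyads each
  contributing 0.5 to both members' `V`, plus the correction
  `h' = h + 6u/(N³−N)` for the `u` unknown dyads. Significance comes from
  randomisation: the direction of every known (including tied) dyad is
  resolved by a fair coin while unknown dyads stay unknown, and the
  right-tailed proportion of null `h'` values at least as large as the
  observed one (observed arrangement included) is reported. With all
  relationships unknown, `h'` equals its null expectation `3/(N+1)` and
  the test is never significant — the correct degenerate behaviour.

Individuals with no decided interaction have no meaningful score and are
dropped from score-based models rather than assigned zero.

## Association networks

Two animals are associated in a scan when their pairwise distance is at
most 1 m (inclusive; roughly a body length, the smallest distance the
mapping protocol resolves). Association is strictly dyadic — no chaining
through intermediates. Dyadic counts are converted to the half-weight
index

`HWI = x / (x + y_AB + (y_A + y_B)/2)`

where `x` counts scans with both observed and associated, `y_AB` both
observed but apart, and `y_A`/`y_B` scans with only one of the pair in
view. The half-weight denominator corrects for the fact that not all
animals are visible in every scan. Both observation blocks feed the
affiliative network (associations are informative all day); only the
spatial frequencies are afternoon-restricted.

**Nonrandom association.** The null "no preferred or avoided dyads" is
tested by permuting associations within each scan: a long sequential chain
of double-edge swaps rewires each scan's association graph among the
animals observed in that scan, preserving each individual's within-scan
number of associates and the scan's association count. Presence is
untouched, so each dyad's HWI denominator is constant and only the joint
counts vary. The test statistic is the coefficient of variation of the
HWI over dyads with a defined index; consistent preferences inflate the
observed CV relative to the rewired null (right-tailed p). The chain
records one replicate every `100 × (number of associations)` attempted
swaps after an equal burn-in; this swap-chain scheme approximates the
classical "permute associations within samples" null, and its type-I
behaviour is checked by simulation in the test suite (rejection rate at
the nominal 5% over hundreds of null datasets). The inner loop is
implemented in C++ because a permutation consumes hundreds of thousands
of swap attempts.

**Subgroups.** The group is partitioned by Newman's leading-eigenvector
method on the weighted modularity matrix `B = W − k kᵀ/2m`: recursive
bisection along the sign pattern of the leading eigenvector of the
generalised modularity matrix, followed by Kernighan–Lin fine-tuning
(each pass moves every member once and keeps the best intermediate
state), stopping when no split increases `Q`. On small graphs the test
suite compares the result against exhaustive search over all partitions
into up to three groups. `Q > 0.3` is flagged as a useful subdivision.
The absolute leading-eigenvector loading at an individual's final split
is reported as assignment certainty; the choice of loadings as the
certainty measure is ours (the magnitude of an individual's contribution
to the split is the natural spectral analogue of assignment confidence).

**Co-occurrence at the patch.** A second network links all pairs observed
within 5 m of the door in the same afternoon scan (the complete graph on
the co-present set), again HWI-weighted. A companion affiliative network
excludes exactly those associations whose two members are both within 5 m
of the door in that scan, so the two can be compared without shared
records.

## Hypothesis-level inference

The study group is a complete enumeration, not a sample, so every p-value
is computed by permutation (10,000 permutations by default) with the
observed arrangement counted in the null — p can never be exactly zero
and is bounded below by `1/(n_perm + 1)`.

* `perm_pearson()` / `perm_ttest()`: ordinary Pearson r and Welch t with
  label shuffling; one-tailed where the hypothesis is directional (males
  above females; age positively related to rank; `SRF10M` positively and
  `F20M` negatively related to dominance score).
* `mantel_perm()`: matrix correlation over off-diagonal dyads with
  simultaneous row/column permutation.
* `mrqap_dsp()`: multiple matrix regression with double-semi-partialing —
  for each predictor, the residual matrix given the other predictors is
  QAP-permuted and refit, building a per-predictor null of t statistics
  that is robust to predictor intercorrelation and network
  autocorrelation. Because "partial r" has no single convention, both the
  partial correlation `t/sqrt(t² + df)` and the standardised coefficient
  are reported. With one predictor the procedure reduces exactly to plain
  QAP regression (asserted in the tests on a shared seed stream).
* `variance_partition()`: per-individual response regressed on a
  continuous block (dominance score, Df 1) and a categorical block
  (subgroups, dummy-coded, Df = levels − 1); each block's unique
  contribution is the semipartial `r² = R²(full) − R²(reduced)`. The
  permutation default shuffles the response (matching the
  permutation-of-observations framing); Freedman–Lane residual
  permutation is available via `permute = "residuals"` as a sensitivity
  mode, since which of the two produced published tables of this kind is
  usually not stated.

Attribute matrices use Euclidean (absolute) differences for age and
dominance score, a binary same-sex indicator and binary matrilineal
kinship; individuals with unknown matriline become singleton matrilines
(kin to nobody) with a warning.

`run_pipeline()` chains everything and reports three blocks: H1
(one-tailed permutation correlations of `SRF10M` and `F20M` with the
dominance score), H2 (variance partitions of both outcomes on score +
subgroups), H3 (MRQAP of the 5-m co-occurrence HWI on score distance,
kinship, age distance and sex similarity; a Mantel test of co-occurrence
against the zone-excluded affiliative network; and the percentage of
co-occurrence dyads that also associate elsewhere).

## The synthetic-data generator

No field data are distributed with the package, so `simulate_study()`
generates studies with the statistical structure the analysis assumes,
and the test suite demonstrates parameter recovery on them. Defaults
describe the emulated design: 39 adults (21 males, 18 females, ages
uniform on 5–26 y), 8 matrilines, 24 observation days of 26 scans,
attendance probability 0.35 per morning scan and 0.60 per afternoon scan
(afternoon attendance is higher because that is when food release
follows), and 100 agonistic events per day with 5% polyadic and 5%
unclear records injected to exercise the filters.

The latent state is a dominance scale
`z = 2·(male) + 0.15·age + N(0, 1)` — males outrank females on average
and rank increases with age — plus planted subgroup labels aligned with
matrilines (each matriline maps to a subgroup; an individual follows its
matriline's subgroup with probability 0.75). Positions mix two
behaviours: with probability `1 − 1/subgroup_cohesion` (default 2/3) an
attendee clusters around its subgroup's anchor (spread 0.45 m, tight
enough for 1-m associations; co-present matriline mates are drawn closer
still with probability `1 − 1/kin_association_boost`), otherwise it takes
a solo position at a door distance drawn from
`N(16 − 3·z_std, 4)` metres (floored at 0.3 m, clipped to the square) on
a random bearing. Subgroup home anchors are themselves spread over 6–24 m
from the door in order of subgroup mean latent dominance: dominant
subgroups rest nearer the feeding zone, emulating the observed
confounding of subgroup composition with rank (a peripheral subgroup of
low-ranking males is a documented feature of the emulated system).
Agonistic winners follow `plogis(1.5 · (z_i − z_j))`; interaction volume
(~2,400 records per study) gives every dyad a few interactions, enough
for stable David's scores at N = 39.

What the generator does **not** emulate: movement (scans are independent
draws given the latent state), visibility gradients (out-of-sight is a
period-specific Bernoulli for everyone), within-day temporal
autocorrelation of positions, demographic change, and behavioural
responses to the door actually opening. Passing recovery tests therefore
show that the estimators recover the structure they target under the
assumed data-generating process, not that real mandrill data would be this
clean.

Null configurations used for calibration set `door_attraction_slope = 0`
and both cohesion multipliers to 1, which makes positions exchangeable
across individuals; with a positive slope the dyad structure is genuinely
non-exchangeable (dominants co-occur near the door), so such data are not
a null for the association test.

## Numerical conventions and problem sizes

* Permutation p-values: `(1 + #{null ≥ observed}) / (n_perm + 1)`.
* Ties at the 10/20 m radii and the 1 m association threshold are
  resolved as inclusive-near, exclusive-far, inclusive-association.
* Eigen-decompositions use base R's symmetric solver; a split is accepted
  only if it increases `Q` by more than `1e-10`.
* Collinear MRQAP predictor sets raise an error naming the offending
  matrix (dropping one silently would change the partialing).
* The test suite uses exhaustive enumeration oracles at `n ≤ 6`
  individuals (all `n!` relabelings), closed-form oracles at `≤ 4` nodes,
  type-I calibration at 500–1,000 null replicates with 199 permutations
  each, and 50 end-to-end synthetic replicates for the qualitative
  pattern check; `scripts/acceptance.R` runs one full default study
  (624 scans, 39 individuals) with 10,000 permutations per hypothesis
  test and 1,000 within-scan permutation replicates. These sizes are the
  package's chosen trade-off between Monte Carlo error and runtime.

## Known limitations

* The within-scan permutation is a swap-chain approximation to uniform
  sampling of degree-constrained graphs; successive replicates are
  (weakly) dependent. The swap budget per replicate is configurable.
* `h'` handles unknown relationships by the published correction; very
  sparse win matrices (most dyads unknown) have little power and the
  index is dominated by the correction term.
* The leading-eigenvector partition is a heuristic; optimality is only
  verified exhaustively on small graphs.
* Variance partitions assume the subgroup labels are fixed covariates,
  ignoring the uncertainty of the community detection that produced them
  — the same simplification the emulated analysis makes.
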