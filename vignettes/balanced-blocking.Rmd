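---
title: "Covariate-balanced block randomization: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-balanced block randomization: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockbal)
```

## The problem

Animal experiments (and many other designs with small cohorts) gain power
and credibility when experimental units are first grouped into *blocks*
that are balanced for baseline covariates — body weight, plasma lipids,
tumour volume at enrolment — and the blocks are then assigned to the
intervention groups at random. With a handful of covariates there is no
single obvious "best" division, but divisions can be *ranked*: blockbal
draws random divisions, scores each one, and keeps a leaderboard of the
best-balanced candidates for the experimenter to choose from. Choosing
among the top candidates (rather than taking the single optimum) lets
secondary concerns — such as how many animals would need a new ear mark
after re-housing — enter the decision without compromising balance.

## The balance score

A *block set* divides (a subset of) the cohort into blocks of predefined
sizes $b_1, \dots, b_k$; units in no block form an explicit *leftover
pool*. For covariate $i$ the score uses the block means
$\bar{x}_{ij}$, the block coefficients of variation
$\mathrm{CV}_{ij} = s_{ij} / \bar{x}_{ij}$, and the standard deviation
$\mathrm{SD}_{set,i}$ of the covariate over all blocked units:

$$
R \;=\; \sum_{i=1}^{p} \left(
  \frac{\Delta \mathrm{Mean}_{max,i}}{\mathrm{SD}_{set,i}}
  + \Delta \mathrm{CV}_{max,i} \right) w_i ,
$$

where $\Delta \mathrm{Mean}_{max,i}$ and $\Delta \mathrm{CV}_{max,i}$ are
the max-minus-min of the block means and block CVs, and $w_i \ge 0$ is the
covariate's weight. Lower is better; $R = 0$ exactly when every covariate
has identical block means *and* identical block CVs. Normalizing the mean
spread by the whole-set SD makes the first term scale-free, and the CV is
itself dimensionless, so the score is invariant under positive rescaling
of any covariate (this is property-tested).

Several conventions are open in this formula; blockbal fixes them as
follows and exposes the consequential ones as arguments:

* **Sample vs population SD.** Default is the sample SD ($n-1$), the
  convention of the spreadsheet tools whose output users paste in;
  `block_design(sd_type = "population")` switches every SD in the score.
  The choice moves individual scores but barely moves the induced ranking.
* **CV as a proportion, not a percentage.** The score *adds* the CV spread
  to a normalized mean spread that is typically $O(1)$; a percentage CV
  would dominate the sum roughly 100-fold and reduce the mean term to a
  tie-breaker, contradicting the evident intent that the two terms weigh
  comparably.
* **Signed means.** The CV keeps the sign of the block mean; covariates
  with negative means are allowed but flagged with a warning, because CVs
  of sign-changing data are hard to interpret. A block mean of exactly
  zero leaves the CV undefined and is a hard error rather than a silent
  `Inf`.
* **Constant covariates.** If a covariate is constant over the blocked
  units, $\mathrm{SD}_{set,i} = 0$ and no division can be distinguished by
  it; its mean term contributes 0 (and all CV spreads are 0), so the
  covariate simply drops out.
* **Singleton blocks** have CV 0 by convention (no dispersion to compare).
* **The leftover pool is excluded** from $\mathrm{SD}_{set,i}$: it is not
  part of the block set, and including it would let unblocked units
  influence the ranking of blocked ones.
* **Display rounding** (`decimals`) affects reports only; every
  computation runs at full double precision.

## The search space and its exact size

Blocks of equal size are interchangeable — swapping the two blocks of an
8+8 design produces the same division — so blockbal counts and samples
*unlabeled* block sets. The exact count is

$$
N \;=\; \frac{n!}{b_1! \cdots b_k! \; r!}\; \Big/ \; \prod_s m_s! ,
$$

with $r$ the leftover count and $m_s$ the number of blocks sharing size
$s$. The leftover pool is *never* interchangeable with a block of equal
size: only this convention gives $\binom{16}{8}/2 = 6435$ for 16 units in
two blocks of 8 while keeping leftover semantics distinct (for 6 units in
2+2 blocks it gives 45, not 15). `count_unique_block_sets()` evaluates
the formula in exact arbitrary-precision integer arithmetic (digits in
base $10^7$, built from Legendre prime-factorization exponents), because
realistic designs overflow doubles: 64 units in four blocks of 16 give
exactly 27,588,448,683,790,477,691,829,516,810,909,225 $\approx$
2.8·10^34 unique sets. The figure of 1.8·10^36 sometimes quoted for this
design is not reproducible under any convention consistent with the 6435
count above (it matches a 65-unit off-by-one almost exactly:
$65!/(16!^4\,1!\,4!) \approx 1.79\cdot10^{36}$); blockbal reports the
exact value. Scientific rendering uses round-half-to-even at the
requested number of significant digits.

## Uniform random search with duplicate rejection

`run_blocking()` draws a uniform permutation of the unit ids
(Fisher-Yates, via R's `sample.int`), fills the blocks in declared order
and sends the remainder to the leftover pool. Every unlabeled block set
corresponds to exactly $b_1! \cdots b_k! \, r! \prod_s m_s!$ permutations
— a constant — so the induced distribution over unlabeled sets is exactly
uniform. This is checked empirically by a $\chi^2$ test over the three
outcomes of a 4-unit 2+2 design and, at scale, by the allocation-count
experiment below.

Each draw is reduced to a canonical key — the block-membership vector with
equal-size block labels canonicalized by order of first appearance — and
checked against a registry, so each unique block set is scored once.
Duplicates count as attempts and are redrawn. The registry stores full
canonical serializations (not hashes), so key collisions are impossible
by construction. Stopping rules: a target number of unique sets, a target
fraction of the design's total, exhaustion, or a safety cap on attempts
(default 50 times the target: near exhaustion the search behaves like a
coupon collector and the expected attempts to find all $N$ sets grow like
$N \ln N$). Hitting the cap is a warning, not an error, and is reported
in `glance()`.

The leaderboard keeps the `leaderboard_capacity` (default 100) lowest
ranking values, sorted ascending; among equal values the
earlier-discovered set ranks first, which makes runs bit-for-bit
reproducible under a fixed seed even in the all-ties limit of a constant
cohort. The seed is stored in the result and written into every report.

## How much of the space must be searched?

If `sampled` distinct sets are drawn uniformly from `total`, the chance
that none of a designated best $k$ is found is hypergeometric:

$$
P_{miss} = \binom{total-k}{sampled} \Big/ \binom{total}{sampled}
 = \prod_{i=0}^{k-1} \frac{total - sampled - i}{total - i}.
$$

For the 16-unit 8+8 design, searching half of the 6435 sets leaves a
$9.7\cdot10^{-4}$ chance of missing all of the ten best — under 0.1%.
`miss_rate_experiment()` verifies the closed form by simulation, and a
test on a fully enumerable design checks that *actual* `run_blocking()`
searches obey the same law.

`coverage_experiment()` maps the whole trade-off: it enumerates and
scores a design exhaustively once (the oracle for the global minimum
$R_{min}$ and the *fully random baseline* $\bar{R}$, defined as the mean
ranking value over all unique sets — the expected score of a single
random draw), then simulates repeated searches at each coverage fraction
and reports the lowest value found, the attempts spent, and the
fractional reduction $(\bar{R} - R_{best})/(\bar{R} - R_{min})$, which is
100% at exhaustive coverage by construction. The baseline had to be
chosen here; the mean of one random draw is the canonical "no search"
reference. Replicated searches are simulated by drawing uniform set
indices with duplicate rejection, which is distribution-identical to the
engine's sample-and-reject loop (both are uniform over canonical sets;
see the fiber-size argument above) while avoiding thousands of redundant
re-scorings; the engine-law test above validates the equivalence.
`attempts_vs_systematic()` compares the attempts with the
$\lceil f \cdot N \rceil$ steps a systematic enumeration would need:
excess stays within a few percent up to moderate coverage and only
becomes material (>5%) near exhaustion.

## Physical markers and housing subgroups

When blocks are split into housing subgroups (cages), identity markers
(ear clips, toe cuts) must stay unique within a cage, and re-marking
causes discomfort. For a block with given marker labels and subgroup
sizes, `minimal_remarking()` maximizes the number of units that keep
their marker, subject to subgroup sizes and within-subgroup distinctness
of kept markers. Units are interchangeable within a label, so the optimum
is a maximum flow on a small network — source → label (capacity: label
count), label → subgroup (capacity 1), subgroup → sink (capacity:
subgroup size) — solved exactly with igraph; integral capacities
guarantee an integral optimal flow, which is realized into an explicit
division. The count of modifications is reported *beside* the ranking
value and never enters it; which replacement marker a modified unit
should receive is left to the experimenter. A brute-force enumerator over
all divisions serves as an independent oracle in the tests (10,000 random
blocks of size ≤ 8). Note one subtlety the tests encode: the intuitive
bound $\sum_\ell \max(0, c_\ell - G)$ (label counts $c_\ell$, $G$
subgroups) is a *lower* bound on modifications, not an upper one —
subgroup capacities can force more (markers AABBC with cages of 4+1 need
one modification even though no label count exceeds 2).

Without markers, `random_subgroups()` divides blocks uniformly at random
and reports no modification count.

## The validation experiments

`randomness_experiment()` generates two independent batches of unique
block sets for a full-coverage equal-block design (default: 32 units,
4 blocks of 8, 10,000 sets per batch) and tallies a unit-by-block
allocation count matrix. Conservation forces the mean count to
$S \cdot b / n$ exactly (2,500 at the defaults); across units the counts
should scatter with roughly binomial dispersion
$\sqrt{S p (1-p)} \approx 43$, and the two batches' per-unit counts
should be uncorrelated (per-block Pearson tests). A 24-unit variant with
four blocks of 6 has the same 1/4 allocation probability and is available
through the arguments; the 32-unit default is used because it matches
"blocks of 8" designs exactly.

## Synthetic cohorts

`generate_cohort()` draws covariates as independent normals — normality
is also the score's working assumption — with defaults emulating a
16-mouse baseline table: three covariates at 4.4 ± 1.7, 14.6 ± 2.1 and
1.2 ± 0.35 (think body weight–scale, lipid-scale and ratio-scale
measurements) and two ear-mark labels 8 units each. A `correlation`
argument (default 0) adds an equicorrelated structure. What the
generator does *not* emulate: skewed or heavy-tailed covariates,
discrete/binary covariates, missing values (a hard error throughout), or
marker alphabets richer than the labels supplied. Tests passing on these
cohorts therefore demonstrate the machinery — exact counting, uniform
sampling, exact optimization, score correctness — not robustness to
non-normal data, which the score does not claim. One practical
consequence of the two-label default: with cages of 4, at most one "L"
and one "R" can be kept per cage, so marker-based subgroup divisions of
an 8-block always report 4 modifications; richer marker alphabets (pass
e.g. `markers = c("N","L","R","B")`) are needed for re-marking-free
divisions to exist.

## Numerical choices and test scales

Variances use centered two-pass sums, keeping the implementation within
$10^{-12}$ of an independently coded scorer over a full 6435-set
enumeration (asserted in the tests). Exact integer work never touches
doubles; conversions to `numeric` happen only for user-facing arithmetic.
All randomness flows through R's RNG; every simulation takes a `seed` and
restores the caller's RNG state (`withr`).

The test suite runs its heavy checks at deliberately chosen scales: the
16-unit 8+8 design (6435 sets) for exhaustive-search fidelity and scorer
equivalence; an 8-unit 4+4 design (35 sets) for replicated
distributional checks (400 real engine runs against the hypergeometric
law); 10,000 random blocks for marker-optimality; 256 replicates per
coverage fraction; and 2 × 10,000 sets for the allocation-count
experiment. These sizes make every claim checkable in a coffee break
while keeping the statistical assertions at 3-sigma strength.

## Known limitations

* Continuous, roughly normal covariates only; categorical or stratified
  covariates are out of scope, and missing values are rejected rather
  than imputed.
* The score compares blocks marginally per covariate; it is not a joint
  (e.g. Mahalanobis-type) balance distance.
* Systematic enumeration is available as an oracle
  (`enumerate_block_sets()`) but deliberately not as a user-facing search
  mode: enumerating a fixed prefix of a systematic order would bias which
  sets are ever seen, while uniform sampling treats all sets evenly at
  any coverage.
* Marker handling counts modifications; it does not propose replacement
  markers or model re-housing stress.
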