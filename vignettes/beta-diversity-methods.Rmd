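---
title: "Incidence-based beta-diversity partitioning and null-model inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incidence-based beta-diversity partitioning and null-model inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventbeta)
```

## The problem

Insular habitat systems — deep-sea hydrothermal vents being the motivating
case — consist of a handful of small, widely separated sites, each holding
a few dozen species recorded as presence/absence. Conservation planning
for such systems turns on *how* diversity is distributed among sites: do
poorer sites hold subsets of richer ones (nestedness, arguing for
protecting the richest sites), or do sites substitute species for one
another (replacement, arguing for protecting many representative sites)?
`ventbeta` implements the pairwise, incidence-based toolkit for answering
that question: beta-diversity decomposition, a richness-controlled null
model, per-site leverage (LCBD), richness estimation, permutation
comparisons between systems, and minimum-set coverage.

## Pairwise pattern components

For a site pair with $a$ shared species, $b$ unique to the first and $c$
unique to the second ($n = a + b + c$), the Jaccard-family components are

$$O = \frac{a}{n}, \qquad R = \frac{2\min(b,c)}{n}, \qquad
  D = \frac{|b-c|}{n}, \qquad O + R + D = 1.$$

$O$ is species overlap, $R$ balanced replacement, and $D$ relativized
richness difference; each pair is a point on the $O$–$R$–$D$ simplex
(`ternary_coordinates()`). Beta diversity and relativized nestedness are

$$\beta_J = 1 - O = R + D, \qquad N_J = 1 - R = O + D
  \ \text{(when } a > 0\text{, else } N_J = 0\text{)}.$$

Because $D$ enters both $\beta_J$ and $N_J$, their intersection is
$I_J = D$ (again only when the pair shares at least one species,
otherwise $I_J = 0$) with relative complement $RC_J = \beta_J - I_J$, so
that $I_J + RC_J = \beta_J$ always — including the disjoint-pair corner
case where $I_J = 0$ and $RC_J = \beta_J = 1$. The ratio
$\beta_{ratio} = I_J / \beta_J$ locates the dominant driver: below 0.5,
replacement; above 0.5, richness difference. For identical sites
$\beta_J = 0$ and the ratio is reported as missing and excluded from
summaries — averaging an arbitrary fill value would bias comparisons
between systems.

Setting $N_J = 0$ (rather than $1 - R$) for pairs sharing no species
follows the simplex convention that nestedness requires at least one
shared species; summaries always report both the mean and the median of
every component, since small pair sets (21–28 pairs for 7–8 sites) make
the two diverge noticeably.

```{r}
decompose_pair(paste0("sp", 1:5), paste0("sp", c(1:3, 6)))
```

## The Raup–Crick null model

Observed $\beta_J$ confounds richness differences with true compositional
divergence. The Raup–Crick approach asks, for each pair, how often
random assembly would produce at least as much sharing as observed. Each
null replicate rebuilds the whole matrix: every site draws exactly its
observed richness, without replacement, with species selection weights
proportional to occupancy frequency (sequential draws with
renormalization; species recorded nowhere are never drawn). With
$S^{obs}$ the observed shared count and $S^{null}$ its null counterpart,

$$\mathrm{rc} = \frac{\#\{S^{null} > S^{obs}\}
  + \tfrac12\,\#\{S^{null} = S^{obs}\}}{n_{sim}}, \qquad
  \beta_{RC} = 2\,\mathrm{rc} - 1 \in [-1, 1].$$

Ties are half-weighted (the "split ties" convention); with whole-number
shared counts ties are common, and alternative conventions visibly shift
borderline pairs. Significance at confidence level $c$ (default 0.95, on
9,999 replicates by default) is operationalised as $|\beta_{RC}| \ge c$,
i.e. tail mass at most $(1-c)/2$ per side: pairs at $\beta_{RC} \le -c$
are more similar than random essentially ever produces ("similar"),
pairs at $\beta_{RC} \ge c$ "dissimilar". Whole-matrix replicates (all
pairs scored per replicate) reuse draws efficiently and match the
behaviour of the widely used implementations.

Two calibration facts matter when reading results:

* When the tested null *is* the generating process (the check
  `calibration_suite()` performs, passing the generator's true weights
  through), the significant fraction sits near — in practice slightly
  below — the nominal 5%, the shortfall coming from the discreteness of
  shared counts under the mid-p convention.
* On field data the weights must be estimated from the observed matrix.
  With few sites the realized frequency profile is flatter than the
  underlying law, null assemblages share fewer species than the process
  that actually built the data, and pairs drift toward the "similar"
  tail. The package makes no hidden correction for this; it is inherent
  to the method, shared by the standard implementations, and worth
  remembering when a system shows many significantly similar pairs.

The weights are always computed from whatever matrix is passed in; a
combined-region analysis therefore uses combined-region frequencies.

## Local contributions to beta diversity

LCBD apportions total community variance among sites. With
$d_{ij} = \sqrt{\beta_J(i,j)}$ (the square root makes the Jaccard
dissimilarity Euclidean-embeddable, hence all contributions
non-negative), the matrix $A = [-\tfrac12 d_{ij}^2]$ is Gower-centred to
$G$; $SS_{total} = \mathrm{tr}(G) = \sum_{i<j} d_{ij}^2 / n$ and
$\mathrm{LCBD}_i = G_{ii}/SS_{total}$, a partition of unity. Identical
sites everywhere give $SS_{total} = 0$ and an error rather than an
arbitrary division.

Significance uses a null that permutes each species column independently
across sites — preserving every species' occupancy frequency while
destroying site identity — with the add-one correction
$p_i = (1 + \#\{\mathrm{LCBD}^{null}_i \ge \mathrm{LCBD}^{obs}_i\}) /
(1 + n_{perm})$ so no p-value is exactly zero at finite replicates. The
permutation scheme is a package design choice (the statistic's standard
test); 9,999 permutations by default, configurable.

## Richness estimation

`chao1()` implements the classic estimator
$S_{obs} + F_1^2 / (2 F_2)$ and its bias-corrected form
$S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))$; by default the classic form
is used unless there are no doubletons ($F_2 = 0$), where it is
undefined and the bias-corrected form substitutes. `rarefied_richness()`
gives the exact expected species count of an individual-based subsample
via the hypergeometric formulation, with binomial ratios on the
log-gamma scale so totals up to $10^5$ individuals pose no overflow
risk.

## Group comparisons and environmental screening

`perm_anova()` and `perm_t_test()` compare groups of pairwise values
(e.g. $\beta_J$ across vent systems) using the observed one-way $F$ and
pooled-variance $t$ with label-permutation nulls and add-one p-values.
Pairwise dissimilarities within a system are not independent — each site
enters several pairs — so these p-values should be read as descriptive
strength-of-separation measures; the functions compute the conventional
analysis while the documentation carries the caveat. The permutation
statistic is $F$ itself (equivalent monotone alternatives exist; $F$ is
used and documented). `kendall_tau()` wraps the tie-corrected tau-b of
`stats::cor.test` for screening environmental correlates of site
richness.

## Minimum-set coverage and group overlap

`minimum_set()` finds the smallest combination of sites containing every
species, by exhaustive search over subset sizes in ascending order (all
minimal solutions are reported — conservation planners need the
alternatives, so ties are never broken arbitrarily). The exact search is
bounded at 25 sites; beyond it a greedy complement heuristic runs and is
flagged non-exact. Coverage targets below 100% are deliberately not a
default: partial targets change the character of the answer and should
be an explicit analysis choice. `group_overlap()` and `subset_pairs()`
support combined-region analyses: per-group richness, shared species,
and within/between pair splits.

## Site clustering and field merging

`upgma()` performs average-linkage (UPGMA) clustering of the $\beta_J$
matrix via `stats::hclust`, whose deterministic lowest-index tie-break
the package inherits; `dendrogram_newick()` exports the ultrametric tree
with ape. `merge_nearby_fields()` implements the convention that vent
fields within 3 km (great-circle, haversine on a 6371 km sphere —
unstated metrics differ only trivially at this scale) belong to one
site, by transitive closure with union occupancy. Because the rule is
really about fields sharing a heat source, nearby sites on distinct
sources are legitimate exceptions: the `fields` argument restricts the
merge candidates so the rule is applied deliberately rather than
automatically.

## The synthetic generator

`generate_community()` produces matrices whose assembly structure is
known, so every analytical stage can be validated without field data.
Defaults mirror the scale of the motivating systems: 8 sites, 40
species, per-site richness 20, and a geometric occupancy-frequency law
with ratio $q = 0.8$ reproducing the skew of real vent matrices (a few
ubiquitous species, 21–47% single-site species). Regimes:

* **random** — the Raup–Crick null model itself (fixed richness,
  frequency-weighted draws);
* **nested** — ranked pool, site $i$ takes the top $r_i$ species: every
  pair strictly nested, $R = 0$, and $\beta_{ratio} = 1$ for unequal
  pairs;
* **turnover** — equal-richness windows sliding along the pool at the
  maximal whole-number offset: pure replacement, $D = 0$,
  $\beta_{ratio} = 0$;
* **mixed** — a shared nested core (`mix_weight`, default 0.5, of each
  site's richness) plus densely overlapping tail windows (offset 1).
  The dense tail keeps mean replacement strictly between the nested and
  turnover extremes; at the maximal tail offset the mixed and turnover
  regimes would coincide in their replacement component, which defeats
  the purpose of an intermediate regime.

What the generator does *not* emulate: spatial/environmental gradients,
abundance dynamics, detection failure, or taxonomic ambiguity. Passing
tests on synthetic regimes therefore demonstrates the correctness of the
computations and the statistical calibration of the nulls — not that any
field system is nested or turnover-driven.

## Numerical and reproducibility choices

Every stochastic function takes an integer seed and restores the
caller's RNG state afterwards; pipeline outputs are a pure function of
(inputs, configuration, seed), and the seed is mandatory in
`pipeline_config()`. Comparisons against observed statistics use a
`1e-12` slack so ties are never lost to floating-point noise. LCBD
non-negativity is asserted in the test suite at `1e-10` against the
positive-semidefiniteness of the centred matrix. Default problem sizes
in the shipped tests — e.g. null-model calibration on 12 datasets of
499 replicates (24 × 999 in the acceptance script), permutation
calibration on 150 null datasets of 199 permutations — were chosen as
the smallest sizes at which the Monte-Carlo error is comfortably inside
the asserted bands.

The package is function-first: analyses are driven from R via
`run_pipeline()` (which writes the full CSV/JSON/Newick report bundle)
rather than a shell executable, which suits how this kind of analysis is
actually embedded in scripted workflows.

## Known limitations

* Pairwise values are interdependent; between-system tests are
  descriptive (see above).
* The Raup–Crick weight-conditioning effect inflates the "similar" tail
  on small matrices (see above).
* `minimum_set()` is exponential beyond ~25 sites by design; the greedy
  fallback guarantees coverage, not minimality.
* Incidence input is strictly binary; abundance information only enters
  through the estimators module.
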