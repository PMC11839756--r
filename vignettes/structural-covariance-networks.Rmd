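---
title: "Structural covariance networks of thalamic nuclei and cortex: methods"
author: "thalnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks of thalamic nuclei and cortex: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalnet)
```

## The model

A structural covariance network treats the across-subject correlation of
regional brain volumes as a proxy for the coordination of those regions.
`thalnet` builds one such network per subject group over 22 nodes: six
thalamic nuclear groups per hemisphere (ventral, anteroventral, medial,
lateral, pulvinar, geniculate — the lateral and medial geniculate nuclei
are merged into one node, since they form one anatomical group, even
though volumetric tables usually report them separately) and five
cortical lobes per hemisphere (frontal, parietal, temporal, occipital,
cingulate). Fine parcels — 25 thalamic nuclei per hemisphere from a
probabilistic atlas, 34 Desikan–Killiany cortical regions per
hemisphere — are aggregated into these nodes by summation
(`aggregate_parcels()`); the insula belongs to none of the five classical
lobes and is excluded by default, with an option to merge it into the
frontal or temporal lobe.

Before network construction, every node volume is residualized on age,
sex and intracranial volume by ordinary least squares
(`fit_adjustment()`, `residualize()`), fitted on the pooled sample.
Pooled fitting is the default because fitting per group would regress out
part of any group difference asymmetrically and would break the
exchangeability that the permutation test relies on; a per-group mode
exists for sensitivity analyses. Because the correlation of two residual
vectors equals the partial correlation of the raw volumes given the
covariates, the resulting edges can equivalently be described as partial
correlations — one mechanism, two names.

Edges are Pearson correlations of the adjusted volumes across the
group's subjects, with negative correlations set to zero
(`build_group_network()`). No further thresholding or density matching
is applied: the weights are used as estimated. A constant column yields
zero-weight edges and a warning rather than an error, so that a
degenerate permutation replication cannot abort a run.

### Assumptions

* Volumes are approximately linear in the covariates; nonlinear age
  effects are out of scope.
* Subjects are exchangeable under the null hypothesis of no group
  difference, which the pooled adjustment preserves.
* The correlation structure is meaningfully summarized by nonnegative
  weights; anticorrelations are treated as absent connections, following
  the standard convention for covariance networks.

## Graph measures

All measures use the standard weighted-network conventions for
correlation-based brain graphs (the Rubinov–Sporns definitions, which
are also what the common graph-analysis toolboxes implement):

* **Distances.** Edge length is the reciprocal weight, `l = 1/w`;
  shortest path lengths `d_ij` come from Dijkstra's algorithm (via
  igraph). Unreachable pairs have `d = Inf`; they are excluded from
  path-length and eccentricity averages (with a log note) and contribute
  zero to efficiency, which handles disconnection natively.
* **Nodal measures** (`nodal_measures()`): degree; strength; Onnela
  triangle intensity `t_i = 1/2 * sum_{jh} (w'_ij w'_ih w'_jh)^(1/3)`
  with weights normalized by the network maximum; clustering
  `C_i = 2 t_i / (k_i (k_i - 1))`; path length `L_i` (mean finite
  distance); eccentricity (max finite distance); closeness centrality
  defined as `1 / L_i`, so closeness times path length is identically 1;
  nodal global efficiency (mean reciprocal distance); local efficiency
  (global efficiency of the neighbor-induced subgraph with original
  weights); betweenness centrality (fraction of shortest paths through
  the node, normalized by `(N-1)(N-2)` so the values are comparable
  across node counts); participation coefficient and within-module
  degree z-score against the Louvain partition.
* **Global measures** (`global_measures()`): averages of the nodal
  quantities, plus radius/diameter (min/max eccentricity), transitivity
  (ratio of total triangle intensity to total connected triples),
  weighted assortativity (correlation of endpoint strengths over edges,
  each edge weighted by its weight), modularity, and small-worldness.
  The global "eccentricity" is reported as the **mean** of nodal
  eccentricities: published tables print it as a scalar alongside both
  radius and diameter, so it is neither the min nor the max; a switch to
  the max is available.
* **Modularity** (`detect_modules()`): weighted Newman modularity
  optimized by Louvain, best of 10 seeded restarts; the winning
  partition is the single source of community labels for modularity,
  participation and within-module z-score on that network, and the seed
  is recorded.
* **Small-worldness** (`small_worldness()`):
  `sigma = (C / <C_rand>) / (L / <L_rand>)` against an ensemble of
  Maslov–Sneppen degree-preserving rewirings of the binary topology
  (10x|E| attempted swaps) with the original weight multiset reassigned
  uniformly at random. Defaults: 100 realizations for observed networks,
  20 inside permutation replications (the statistic stays comparable
  because the identical generator is used for observed and permuted
  networks). Dense correlation networks are often complete; a complete
  topology cannot be rewired, in which case the realizations reshuffle
  weights only and a warning is emitted.

The exact clustering variant (Onnela) and the betweenness normalization
are conventions rather than published choices; both are documented here
and checked in the test suite against brute-force oracles (Floyd–
Warshall distances, exhaustive path enumeration, triple enumeration,
exhaustive partition search for modularity on small graphs).

## Group inference

`permutation_test()` compares every requested global and nodal measure
between the two groups. Group labels are permuted over the pooled
subjects preserving group sizes ("randomly reassigned" label
permutation, not sign-flipping); both networks are rebuilt and all
measures recomputed per replication (default R = 1000). The adjustment
is performed once on the full sample and the residuals are permuted —
under the null, the covariate–volume relation does not depend on the
labels — with per-replication refitting available as a sensitivity
option.

The default p-value is two-tailed, `p = #{|d_r| >= |d_obs|} / R`:
published comparison tables reject in both directions, so a two-sided
rule is required even though the procedure is often described with the
literal one-sided exceedance wording. That literal one-sided rule and
the `(k+1)/(R+1)` small-sample correction are available by flag. The
reported 95% interval is the 2.5th/97.5th percentile of the *null*
difference distribution (not a CI of the observed difference): published
intervals straddle zero while the observed differences fall outside
them, which identifies them as null-distribution intervals.

FDR control uses the Benjamini–Hochberg step-up (`bh_fdr()`, q = 0.05).
Families: the 12 global measures as one family; all nodal tests (22
nodes x 12 measures) as one pooled family, because the published nodal
table applies a single FDR statement without per-measure qualification.
Per-measure families are available by flag. Note the nodal measure list
in the methods of such studies sometimes omits nodal global efficiency
while the results tables include it; this package computes 12 nodal
measures so the tables can be reproduced.

## Quality control

`iqr_outliers()` flags volumes below `Q1 - 1.5 IQR` or above
`Q3 + 1.5 IQR` per ROI, with quartiles by linear interpolation of order
statistics (type 7) — the quartile convention is unspecified in most
study descriptions, so the most widespread default is pinned and written
into the QC report header for reproducibility.
`thalamus_consistency()` compares the whole-thalamus volume of the
primary segmentation with the summed nucleus volumes
(`ratio = |whole - sum| / whole`); the default flag threshold of 0.10 is
a package default, not a published value. QC never mutates the cohort:
`apply_qc_exclusions()` is a separate, logged step and by default
reports without dropping, because in the original workflow statistical
flags fed a human visual review that a pipeline cannot replicate.

## The synthetic cohort generator

`simulate_cohort()` draws, per subject, covariates (age ~ N(64.7, 11),
sex ~ Bernoulli(0.5), ICV ~ N(1.45e6, 1.4e5 mm^3)), standard-normal
latent factors shared within subject, and volumes
`mu_r + beta_r (c - E[c]) + Lambda[r,] f + eps`, with `eps ~ N(0,
sigma_r^2)`. Covariates are centered in generation so `mu_r` is the
group mean; with a single factor and loading `lambda` relative to unit
noise, the implied inter-ROI correlation is `lambda^2/(lambda^2+1)`,
which gives closed-form expectations for recovery tests. The
latent-factor construction was chosen over direct covariance draws
precisely for those closed forms and for natural group contrasts via
loading scaling.

`preset_et_hc()` instantiates the study conditions: 109 patient-like and
81 control-like subjects, node means and SDs on the published volumetric
scale (e.g. left ventral 2571 ± 358 mm^3, left frontal 55288 ± 5561
mm^3), covariate slopes of realistic sign and size (age -0.2% of the
node mean per year, sex dimorphism 2%, allometric ICV scaling with
exponent-like factor 0.7).

Its covariance structure has two layers, and the second is a deliberate
design choice. A first draft of the preset used only two domain factors
(thalamic, cortical, bridged by the ventral and pulvinar nodes) and
scaled all patient-group loadings uniformly. That reproduces the weaker
strength, efficiency, clustering and longer path lengths of the
patient-like network, but it leaves modularity and small-worldness near
coin-flip: uniformly scaled correlations preserve the *relative* module
structure, so the patient network is weaker but not more fragmented.
Real patient networks in this disorder are described differently — both
groups keep strong correlations between bilaterally homologous regions
while the patients lose cortico-thalamic integration. The preset
therefore adds one bilateral homolog factor per left/right node pair
(loading 0.8 of the node SD) that is *never* scaled by the contrast,
plus mild cross-domain loadings (0.4) that integrate the two blocks in
the control group. Under a contrast of 0.5 the patient-like network then
retains its homolog backbone but fragments around it: higher modularity,
higher eccentricity and characteristic path length, lower
small-worldness — the full qualitative direction pattern, stable across
seeds. Frozen defaults: base loading 0.9, bridge 0.5, cross 0.4, homolog
pair 0.8, idiosyncratic noise 0.4, all as fractions of each node's scale
SD.

What the generator does **not** emulate: segmentation error and its
spatial correlation, non-Gaussian volume distributions (Gaussian tails
can even produce rare negative volumes for the smallest nuclei, which
the simulator permits and real data cannot show), site or scanner
effects, age-by-group interactions, and any true localization of effects
to specific nuclei. Passing tests therefore demonstrate that the
*pipeline* is correct and well-calibrated under a plausible generative
model — not that the biological findings would replicate.

## Numerical choices and degenerate inputs

* Quartiles: type 7; recorded in QC output.
* Constant columns: zero edges plus a warning, never an error.
* Correlations are clamped to `[0, 1]` after zeroing negatives (floating
  point can nudge a duplicate column's correlation above 1).
* Distance ties: betweenness aggregates over all co-minimal paths, so
  tie-breaking does not affect any reported measure.
* Isolated nodes: path length and eccentricity are missing sentinels
  (`NA`) with a warning; efficiency treats them as zero contribution.
* Within-module z-score is 0 where a module's strength SD is 0 (including
  singleton modules); participation is 0 for isolated nodes.
* Null replications that produce a degenerate measure are excluded from
  that measure's null distribution, with a logged count.
* All randomness (permutations, Louvain restarts, rewiring ensembles) is
  seeded and recorded; identical inputs and seeds give bit-identical
  outputs.

## Problem sizes used in the test suite

The suite exercises the statistical guarantees at sizes chosen to keep a
full run in a few minutes on one core while leaving comfortable Monte
Carlo margins: 200 random graphs (4-8 nodes) for the measure oracles,
500 null simulations (40 + 40 subjects, R = 200, average strength) for
the type-I error and p-uniformity checks, 50 seeded repeats of the full
preset (109 + 81) for the direction pattern, and n = 4000-6000 for
correlation-convergence smoke tests, where the entrywise maximum over
hundreds of near-zero edges needs large n for a tight bound.

## Known limitations

* The 22-node networks here are near-complete, so measures that depend
  on sparse topology (betweenness, radius/diameter) carry limited
  information; they are computed for completeness of the reported
  tables.
* Small-worldness against weight-reshuffled references is weakly
  identified on complete topologies (no rewiring is possible); the
  warning makes this visible.
* The permutation engine rebuilds networks per replication, which is
  exact but means R = 1000 with full nodal measures and small-world
  references takes a few minutes; measure subsets
  (`measures_global =`, `measures_nodal =`) make targeted runs cheap.
* Exact p-values for Spearman associations are only computed for n <= 9
  without ties; elsewhere the t approximation is used.
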