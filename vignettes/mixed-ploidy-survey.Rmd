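---
title: "Analysing mixed-ploidy microsatellite surveys with msatmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing mixed-ploidy microsatellite surveys with msatmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Large strain collections of clonal yeasts such as *Brettanomyces
bruxellensis* mix diploid isolates with allotriploids — strains carrying a
core diploid genome plus a third haploid chromosome set acquired from a
divergent lineage. Microsatellite genotyping of such a collection yields,
per isolate and locus, a *set* of one to five distinct allele sizes, and
almost every classical population-genetic method breaks on that input:
distances assume equal ploidy, F-statistics assume diploid genotypes,
admixture models assume allele dosages. `msatmix` implements the analysis
chain that works around this: a ploidy-aware genotype distance validated by
five independent clustering views, inference of ploidy classes from allele
counts, statistical extraction of the shared "core diploid" genotype, the
structure statistics (AMOVA, Mantel, pairwise F~ST~), ancestry estimation
with held-out model choice, and growth-curve classification of sulfite
tolerance — the phenotype that separates the triploid wine lineages from
the rest.

Everything is exercisable end to end on a bundled synthetic generator with
known truth; the numbered drivers under `analysis/` run the whole chain and
write their tables under `results/`.

# Genotype representation and ploidy

A call is the set of distinct repeat counts at a locus (fragment sizes are
converted by `round((size - offset) / repeat_unit)`; deviations above 0.34
repeat units warn, because real fragment calls drift by a base pair but a
larger deviation usually means a mis-specified locus definition). Missing
calls are per locus, not per isolate.

Ploidy classes follow the maximum allele count over loci: ≤2 alleles
everywhere is diploid (2n), a maximum of 3 is triploid (3n), 4–5 is noted
4n/5n. The count of loci with ≥3 alleles is kept alongside, since isolates
with a single such locus are weaker triploid candidates than isolates with
many. This is an observational lower bound on ploidy: a triploid
homozygous (or identical-by-descent) at every third allele looks diploid.
The synthetic generator's truth records let you measure exactly how often
that happens under given heterozygosity.

Clone collapse treats two isolates as the same multilocus genotype only if
every locus matches exactly, including missing status — conservative, so
clonal multiplicities are never inflated by incomplete profiles.

# Bruvo's distance with genome addition and loss

The single-allele distance under the stepwise mutation model is
$d_a(x, y) = 1 - 2^{-|x-y|}$: one repeat step costs 0.5, and the cost
saturates at 1 as alleles diverge. For two allele sets of equal size the
locus distance is the minimum over perfect matchings of the mean allele
distance. For unequal sizes (diploid vs triploid) the smaller set is
padded: under *genome addition* with copies of its own alleles, under
*genome loss* with alleles of the larger set, in both cases averaging over
all unordered padding combinations; the default model averages the two
branches, and an *infinity* fallback (unmatched alleles cost 1) is
available. All matchings are enumerated exactly — at ≤5 alleles that is at
most 120 permutations, so no heuristic assignment is ever used.

Pairwise distances average the locus distance over loci called in both
isolates; loci missing on either side are dropped from that pair's mean
rather than scored or globally deleted. Computation runs over unique
allele sets per locus and unique multilocus genotypes, so heavily clonal
collections cost far less than their isolate count suggests. Analyses
that need a complete matrix (classical MDS) first impute each missing call
from the nearest isolate (Bruvo distance over shared loci) that is called
there, with ties broken by dataset order.

# Five views of the same structure

The clustering module deliberately reuses standard machinery: `ape`'s
neighbour joining (negative branches clamped to zero with the deficit
moved to the adjacent branch), average-linkage UPGMA via `hclust`,
Torgerson MDS via `cmdscale`, and `kmeans` for the successive-K-means
step. What `msatmix` adds is the glue and the two non-standard pieces:

* **Cluster number.** K-means runs for k = 1..kmax on MDS coordinates
  retaining 95% of the positive-eigenvalue variance, and k\* is the
  smallest k whose relative WSS drop `(WSS(k) − WSS(k+1)) / WSS(1)` falls
  below τ = 0.05. τ is exposed because the "sharp decrease" criterion it
  approximates has no canonical numeric form. Two caveats are worth
  knowing: on a *single* Gaussian cloud the rule does not return k = 1
  (splitting any blob keeps buying WSS for a while — no WSS-only rule
  returns 1 there), and near the threshold the chosen k can move by one
  with the K-means restarts; 25 restarts per k are the default to keep
  the WSS curve stable.
* **Partition-based node reliability.** For each internal clade C the
  observed mean pairwise distance is compared against R = 1000 random
  leaf subsets of size |C|; reliability is the fraction of subsets with
  strictly greater mean distance, and nodes above 0.90 are flagged. Null
  distributions are cached per clade size. This is a reconstruction from
  a verbal description of the published partition method, and one bias is
  inherent: the tree is built from the same distances the statistic uses,
  so even unstructured data yields many "tight" clades (we measured
  roughly 40% of nodes above 0.90 on i.i.d. points). Reliabilities are
  therefore useful for ranking clades and confirming strong groups, not
  as calibrated p-values.

# Core diploid genotype

To run diploid machinery on a mixed collection, alleles specific to the
polyploid class are removed. Every isolate with ≥3 distinct alleles at ≥1
locus forms the polyploid class; each observed (locus, allele) is tested
in a 2×2 carrier-by-class table with Pearson's χ² (1 df, no continuity
correction, α = 0.01). An allele is excluded only when the test is
significant *and* its carrier frequency is higher among polyploids — the
screen targets alleles specific to the triploids, and a two-sided rule
would also strip diploid-private core alleles, defeating the purpose.
Expected counts below 5 are logged but do not switch the test to an exact
variant. After removal, calls left empty or still holding more than two
alleles become missing; everything else is kept verbatim, which is why
most isolates survive with an intact pseudo-diploid profile.

# Structure statistics

**AMOVA** is distance-based and single-factor, run separately per factor
(country, substrate, ploidy) to mirror a row-per-factor report:
$SS_{total} = \sum_{i<j} d_{ij}^2 / N$, within-group sums analogous per
group, variance components via the usual
$n_0 = (N - \sum n_g^2/N)/(G-1)$ correction, and significance from
permuting labels with the add-one rule. Negative among-group components
truncate to zero for the percentage. Groups of one isolate are dropped
with a warning; a single remaining group reports 0% among-group variance
by convention.

**Mantel** correlates the upper triangles of the genetic and geographic
matrices, permuting rows/columns of the second (one-sided, greater,
add-one). Geography resolves isolates to country centroids from a small
editable table (`country_centroids()`), with haversine distances on a
6371 km sphere; same-country pairs get distance 0.

**Pairwise F~ST~** uses the Weir–Cockerham (1984) θ estimator on the core
dataset, per pair of populations: per locus and allele the among-
population (a), among-individual (b) and within-individual (c)
components are accumulated and θ = Σa / Σ(a+b+c) (ratio of sums across
alleles and loci). Single-allele calls count as homozygotes — for a
conservatively called microsatellite panel that is the only defensible
reading. Monomorphic loci carry no information and are skipped; negative
estimates truncate to 0. The 2-deme estimator is noisy per locus (the
among-deme component has essentially one degree of freedom), which is
why the validation suite uses hundreds of loci to pin its expectation.

# Ancestry by simplex-constrained factorization

The core genotypes are encoded as allele dosages (heterozygote 0.5/0.5,
homozygote 1, missing masked) so each isolate-locus block lies on the
simplex. The model $X \approx QG$ — Q rows are ancestry proportions, G's
per-locus blocks are ancestral allele frequencies — is fitted by EM for
the multinomial likelihood, which coincides with KL-NMF multiplicative
updates plus renormalization and is monotone in the training likelihood.
A Dirichlet pseudocount (`g_prior = 1e-3`) keeps rare alleles off the
boundary of G; without it a single held-out allele unseen by a component
sends the held-out log loss to infinity and the model-choice criterion
becomes meaningless.

Model choice holds out 5% of the called isolate-locus *calls* — whole
blocks, never single allele cells, because the visible half of a
heterozygote call leaks the masked half and makes larger K look better
indefinitely. For each K the fit is repeated (fresh seeds, masks and
initialisations) and K\* is the smallest K within one standard error of
the minimal mean held-out cross-entropy; entropy curves plateau, so the
tie rule resolves toward parsimony. Components are identified only up to
permutation; `match_ancestry()` aligns fits by exhaustive column matching
before any comparison. Note one structural property: even on noiseless
rank-K data the held-out cross-entropy sits slightly above the data
entropy (training shifts block mass off held-out cells), so the criterion
is comparative across K, never an absolute goodness-of-fit.

This implementation is a methodological stand-in for the sparse-NMF
ancestry tools used in survey practice: it agrees with them on
well-separated structure but is not bit-compatible, and it applies no
sparsity penalty (none is needed at the problem sizes exercised here).

# Sulfite tolerance from growth curves

Per OD~600~ curve three direct statistics are taken, with no parametric
growth model: the plateau `max(od)`; the lag as the linearly interpolated
time of a 5% rise of the total OD increase over the inoculation value;
and the maximal rate as the largest per-interval slope of log2(OD), in
divisions per hour. A curve counts as grown only if it rises by
`delta_grow = 0.2` OD units (the growth-absence criterion is not numeric
in survey practice; 0.2 is far above plate-reader noise and far below any
real plateau). With 24 h sampling the interval slope underestimates fast
growth — a 0.10 div/h strain with a 20-fold OD range spans barely two
intervals of exponential phase, and the recoverable maximum is 12–18%
low. The generator truth therefore treats rate recovery as approximate
(tested within 20%) while lag recovery is exact to one sampling interval.

Classification runs one omnibus Kruskal–Wallis test per parameter
(`r_max`, `od_max`) across doses. A strain is **sensitive** if growth is
absent in all replicates at some non-zero dose, or if a parameter is
significant at α = 0.05 *and* its mean at some dose lies more than 5%
below the dose-0 mean. The 5% practical-significance floor exists because
highly reproducible replicates let the rank test reach significance on
sub-percent wobble — in particular the grid-phasing artifact above, where
a pure lag shift changes the measured rate by a percent or two. A strain
whose only response is lag prolongation is **tolerant**: that is exactly
the phenotype of the SO₂-tolerant triploid wine lineages. A secondary
`s_effect_size` flag marks monotone ≥50% rate declines regardless of the
rank test, as a power-limited triplicate design misses real declines; it
is reported in its own column and never changes the primary call.

# The synthetic generator

`sim_config()` defaults encode the study conditions of a 6-group
diploid-triploid complex at roughly one-eighth of the real collection's
size (188 isolates, 81 genotypes, 12 loci), chosen so the full validation
chain runs in seconds to minutes on one CPU:

* All core pools draw from one shared window of 10 allele states; each
  pool's frequencies mix a species-wide Dirichlet draw (weight 0.2) with
  a pool-specific draw (α = 0.15). Groups therefore share a core genome —
  so the χ² screen strips roughly a third of alleles while most diploid
  calls survive — yet remain strongly diverged (pairwise θ ≈ 0.2–0.5,
  cluster recovery ARI > 0.95).
* Each triploid group has its own donor pool 40+ repeats away: the
  triploid lineages arose from distinct hybridisation events, and the
  foreign third allele is what makes them identifiable.
* Clonal multiplicities are geometric, calibrated to the observed
  isolate/genotype ratios (e.g. 548/197 for the dominant wine group);
  clonal copies mutate ±1 repeat at rate 0.002 per allele and lose a call
  at rate 0.03.
* Wine groups share one global country distribution; niche substrates are
  regional. Geographic signal comes from two mechanisms: each group's
  country profile is a Dirichlet perturbation (concentration 8) of its
  substrate base, and clones stay in their genotype's home country with
  probability 0.9. Together these reproduce the expected pattern —
  geography explains far more variance among non-wine isolates than
  overall, and the Mantel test is significant but weak.
* Growth archetypes: tolerant groups keep rate and plateau at every dose
  and only lengthen lag; sensitive groups scale rate/plateau down with
  dose and fail entirely at 0.6 mg/L molecular SO₂. OD noise is Gaussian
  (σ = 0.02 by default, 0.03 in the validation panel).

What the generator does **not** emulate: allele-size homoplasy and
binning artifacts, linkage between loci, partial aneuploidy (whole extra
chromosome sets only), within-group admixture gradients, country-level
sampling bias, non-logistic growth (diauxie, death phase) and
plate-reader drift. Passing the validation suite therefore shows the
estimators are correct under the model's assumptions — not that those
assumptions hold for any particular real survey.

# Numerical and design choices

* Bruvo distances are computed on repeat counts, never base pairs; the
  conversion's 0.34-repeat warning threshold flags off-grid calls.
* Exhaustive matching is capped at 5 alleles (120 permutations); larger
  sets are rejected rather than approximated.
* NJ negative branches: clamp to zero, transfer the deficit to the
  adjacent branch; logged invariants are exact additivity round-trips.
* MDS drops negative eigenvalues with a warning; K-means retains
  components covering 95% of the positive spectrum.
* Permutation p-values all use the add-one rule; defaults are 10⁴
  permutations in the drivers and smaller counts in unit tests.
* χ² screen: α = 0.01 fixed; the polyploid-class boundary (≥3 alleles) is
  exposed as `min_alleles` because a phrase like "more than 3 alleles" in
  survey prose is ambiguous between ≥3 and >3 — class arithmetic in such
  reports usually implies ≥3, which is the default here.
* EM ancestry: `max_iter = 500`, `tol = 1e-8` on training cross-entropy,
  `mask_fraction = 0.05`, 10 repetitions by default (full-scale surveys
  commonly use 100; scaled down here and configurable).
* All stochastic operations take explicit seeds and are reproducible to
  the byte.

# Known limitations

Partition reliability inherits tree-selection bias (see above). The
WSS-drop cluster rule cannot return k = 1 on unimodal data. θ between
populations that are monomorphic at shared loci is undefined and flagged
rather than forced. The growth-rate estimator is bounded by the sampling
interval. And because raw genotype tables of real collections are rarely
redistributable, the validation suite exercises the identical pipeline on
the synthetic complex rather than on real data; with such tables in hand,
`reproduce_survey("<dir>")` runs the same chain unchanged.
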