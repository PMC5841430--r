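# msatmix

Population genetics for mixed-ploidy microsatellite surveys of clonal
microbes — built for collections like the wine-spoilage yeast
*Brettanomyces bruxellensis*, where diploid isolates coexist with
allotriploids (a core diploid genome plus a third haploid set from a
divergent lineage) and standard diploid machinery breaks.

## What it does

For a table of allele calls (isolate × locus → set of fragment sizes),
`msatmix` provides the full analysis chain:

* **Bruvo's distance** for mixed ploidy: allele distance
  d(x, y) = 1 − 2^(−|x−y|) under the stepwise mutation model, optimal
  allele matching per locus, and genome **addition/loss** models for
  unequal allele counts (exact enumeration, no heuristics).
* **Ploidy inference** from maximum allele counts (2n / 3n / 4n–5n) and
  **clone collapse** to unique multilocus genotypes.
* **Cluster validation five ways**: neighbour joining, UPGMA, classical
  MDS (`cmdscale`), successive K-means with a WSS-drop rule for the
  number of clusters, and partition-method node reliability against
  random leaf subsets.
* **Core diploid genotype** extraction: χ² screen (2×2, 1 df, α = 0.01)
  removing alleles specific to the polyploid class; calls left with >2
  alleles become missing.
* **Structure statistics**: distance-based AMOVA with permutation
  p-values, Mantel test against country-centroid geography (haversine,
  R = 6371 km), and pairwise Weir–Cockerham θ (F_ST) between
  populations.
* **Ancestry**: simplex-constrained matrix factorization X ≈ QG fitted
  by EM (monotone multinomial likelihood), with whole-call hold-out
  cross-entropy and a 1-SE rule to choose the number of ancestral
  populations K.
* **Sulfite (SO₂) tolerance** from OD₆₀₀ growth curves: lag (5% rise,
  interpolated), maximal rate (log2 interval slope, divisions/h),
  plateau; Kruskal–Wallis across doses classifies strains sensitive (S)
  vs tolerant (T), with lag prolongation alone never forcing S.
* A **seeded synthetic generator** of diploid–triploid complexes
  (ancestral pools, allotriploid donors, clonal expansion, stepwise
  mutation, missing data, geography) and dose-response growth curves,
  with full truth records — every estimator above is validated against
  it.

## Worked example

The numbered drivers under `analysis/` run the whole chain on the bundled
synthetic complex (188 isolates × 12 loci, 6 groups, with truth):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_population_structure.R
Rscript analysis/03_core_popgen.R
Rscript analysis/04_ancestry.R
Rscript analysis/05_sulfite_tolerance.R
```

Output from a run at the default seed:

```
Ploidy census: 188 isolates | 86 diploid (2n), 102 triploid (3n), 0 4n/5n
Clone collapse: 188 isolates -> 124 multilocus genotypes
Successive K-means selected k = 4 clusters (tau = 0.05)
Cluster labels vs generator groups: adjusted Rand index 0.983
Allele screen: 73 of 235 alleles associated with the polyploid class
  (chi-square, p < 0.01) and excluded
AMOVA:  country 34.7% | substrate 43.1% | ploidy 33.8% |
        country (non-wine isolates) 54.4%   (all p = 1e-04)
Mantel genetic vs geographic distance: r = 0.050, p = 0.0240
Pairwise FST (Weir-Cockerham theta): 0.17 - 0.55 between groups
Tolerance calls: 39 strains | 24 sensitive (S), 15 tolerant (T)
Agreement with archetype truth: 39/39
```

Read: the collection splits into well-separated groups recovered almost
perfectly from the Bruvo distances (ARI 0.983); ploidy is a major
structuring factor; geography matters far more once the globally traded
wine isolates are set aside (54.4% vs 34.7%); removing the 73
polyploid-associated alleles yields a core dataset on which the groups
remain strongly differentiated (θ up to 0.55); and the growth classifier
recovers every strain's tolerance archetype.

Each driver writes its tables (distance matrices, Newick trees with
reliability labels, cluster assignments, the χ² association report, the
AMOVA/Mantel/FST tables, ancestry Q matrices and entropy curve, growth
parameters and S/T calls) under `results/`.

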