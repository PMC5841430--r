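#' Run the full mixed-ploidy survey analysis on one dataset
#'
#' Chains the whole workflow: ploidy census, clone collapse, Bruvo distance,
#' NJ/UPGMA/MDS/K-means/partition-reliability clustering, core-genotype
#' extraction, AMOVA per factor, Mantel test against country-centroid
#' geography, pairwise FST between groups, and entropy-selected ancestry.
#' Every stage's output is returned in one bundle; drivers under
#' `analysis/` write the pieces to disk.
#'
#' @param ds an [msat_dataset()]; metadata should carry `country`,
#'   `substrate` and (for FST/AMOVA by group) `group`.
#' @param nperm permutations for AMOVA and Mantel.
#' @param k_range,repetitions ancestry model-choice grid.
#' @param kmax,tau successive K-means parameters.
#' @param reliability_R partition-method null replicates.
#' @param seed integer master seed for all stochastic stages.
#' @param run_ancestry set `FALSE` to skip the (slower) ancestry stage.
#' @return A list bundle; see the individual functions for the pieces.
#' @export
run_survey <- function(ds, nperm = 1000L, k_range = 1:8, repetitions = 5L,
                       kmax = 10L, tau = 0.05, reliability_R = 200L,
                       seed = 1L, run_ancestry = TRUE) {
  stopifnot(inherits(ds, "msat_dataset"))
  ploidy <- infer_ploidy(ds)
  genotypes <- collapse_clones(ds)
  D <- bruvo_dist(ds)
  ds_full <- impute_nearest(ds)
  D_full <- bruvo_dist(ds_full)
  nj <- nj_tree(D)
  nj_rel <- partition_reliability(nj, D, R = reliability_R, seed = seed)
  up <- upgma_tree(D)
  mds <- mds_retain(D_full, 0.95)
  clusters <- find_clusters(mds$coords, kmax = kmax, tau = tau, seed = seed)

  assoc <- triploid_associated_alleles(ds, ploidy)
  core <- build_core_dataset(ds, assoc)

  amova <- list()
  for (fac in c("country", "substrate")) {
    if (!is.null(ds$meta[[fac]])) {
      amova[[fac]] <- amova_dist(D, stats::setNames(ds$meta[[fac]],
                                                    ds$meta$isolate_id),
                                 nperm = nperm, seed = seed)
    }
  }
  amova$ploidy <- amova_dist(D, stats::setNames(as.character(ploidy$klass),
                                                ploidy$isolate_id),
                             nperm = nperm, seed = seed)
  nonwine <- ds$meta$substrate != "wine"
  if (sum(nonwine) >= 4 &&
      length(unique(ds$meta$country[nonwine])) >= 2) {
    amova$country_nonwine <- tryCatch(
      amova_dist(D[nonwine, nonwine],
                 stats::setNames(ds$meta$country[nonwine],
                                 ds$meta$isolate_id[nonwine]),
                 nperm = nperm, seed = seed),
      error = function(e) NULL)
  }

  geo <- haversine_matrix(ds$meta, centroids = country_centroids())
  mantel <- mantel_test(D_full, geo[rownames(D_full), rownames(D_full)],
                        nperm = nperm, seed = seed)

  fst <- if (!is.null(ds$meta$group)) {
    tryCatch(pairwise_fst(core, stats::setNames(ds$meta$group,
                                                ds$meta$isolate_id)),
             warning = function(w) suppressWarnings(
               pairwise_fst(core, stats::setNames(ds$meta$group,
                                                  ds$meta$isolate_id))))
  } else NULL

  anc <- NULL
  if (run_ancestry) {
    enc <- encode_genotypes(core)
    anc <- select_k(enc, k_range = k_range, repetitions = repetitions,
                    seed = seed)
  }

  list(ploidy = ploidy, genotypes = genotypes,
       dist = D, dist_complete = D_full,
       nj = nj_rel, upgma = up, mds = mds, clusters = clusters,
       association = assoc, core = core,
       amova = amova, mantel = mantel, fst = fst, ancestry = anc,
       seed = seed)
}

#' Ploidy census in the shape the survey reports it
#'
#' @param ploidy output of [infer_ploidy()].
#' @return list of counts: `n`, `n_2n`, `n_3n`, `n_4n5n`, `n_max3`,
#'   `n_max4`, `n_max5`.
#' @export
ploidy_census <- function(ploidy) {
  list(n = nrow(ploidy),
       n_2n = sum(ploidy$klass == "2n", na.rm = TRUE),
       n_3n = sum(ploidy$klass == "3n", na.rm = TRUE),
       n_4n5n = sum(ploidy$klass == "4n/5n", na.rm = TRUE),
       n_max3 = sum(ploidy$max_alleles == 3L, na.rm = TRUE),
       n_max4 = sum(ploidy$max_alleles == 4L, na.rm = TRUE),
       n_max5 = sum(ploidy$max_alleles >= 5L, na.rm = TRUE))
}

#' Reproduce the survey from user-supplied genotype tables
#'
#' Convenience entry point for re-running the analysis on a real
#' collection: point it at a directory holding `alleles.csv`, `loci.csv`
#' and `meta.csv` in the dialect [read_genotypes()] documents, and the
#' full [run_survey()] bundle is computed.
#'
#' @param fixtures_dir directory with the three tables.
#' @param ... passed to [run_survey()].
#' @return As [run_survey()].
#' @export
reproduce_survey <- function(fixtures_dir, ...) {
  ds <- read_genotypes(file.path(fixtures_dir, "alleles.csv"),
                       file.path(fixtures_dir, "loci.csv"),
                       file.path(fixtures_dir, "meta.csv"))
  run_survey(ds, ...)
}

#' Adjusted Rand index between two partitions
#'
#' Standard chance-corrected agreement between cluster labelings,
#' used to score recovery of generator truth.
#'
#' @param a,b label vectors of equal length.
#' @return Numeric in `[-1, 1]`; 1 for identical partitions.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
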