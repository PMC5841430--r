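#!/usr/bin/env Rscript
# Core diploid genotype extraction and classical population genetics:
# chi-square screen of polyploid-associated alleles, AMOVA per factor,
# Mantel test against country-centroid geography, pairwise Weir-Cockerham
# FST between groups. Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(msatmix))

seed <- as.integer(Sys.getenv("MSATMIX_SEED", "1"))
dat <- "results/data"
out <- "results/popgen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ds <- read_genotypes(file.path(dat, "alleles.csv"),
                     file.path(dat, "loci.csv"),
                     file.path(dat, "meta.csv"))
pl <- infer_ploidy(ds)

assoc <- triploid_associated_alleles(ds, pl)
write.csv(assoc, file.path(out, "allele_association.csv"), row.names = FALSE)
cat(sprintf("Allele screen: %d of %d alleles associated with the polyploid class (chi-square, p < 0.01) and excluded\n",
            sum(assoc$excluded), nrow(assoc)))

core <- build_core_dataset(ds, assoc)
write_genotypes(core, file.path(out, "core_alleles.csv"),
                file.path(out, "core_loci.csv"),
                file.path(out, "core_meta.csv"))
n_miss <- mean(vapply(core$calls, is.null, logical(1)))
cat(sprintf("Core diploid dataset: %.1f%% of calls masked\n", 100 * n_miss))

D <- suppressWarnings(bruvo_dist(ds))
rows <- list()
factors <- list(country = ds$meta$country,
                substrate = ds$meta$substrate,
                ploidy = as.character(pl$klass))
for (f in names(factors)) {
  a <- suppressWarnings(amova_dist(D, setNames(factors[[f]], ds$meta$isolate_id),
                                   nperm = 9999, seed = seed))
  rows[[f]] <- data.frame(factor = f, pct_variance = a$pct_variance, p = a$p)
}
nw <- ds$meta$substrate != "wine"
a_nw <- suppressWarnings(
  amova_dist(D[nw, nw], setNames(ds$meta$country[nw], ds$meta$isolate_id[nw]),
             nperm = 9999, seed = seed))
rows$country_nonwine <- data.frame(factor = "country (non-wine isolates)",
                                   pct_variance = a_nw$pct_variance,
                                   p = a_nw$p)
amova_tab <- do.call(rbind, rows)
write.csv(amova_tab, file.path(out, "amova.csv"), row.names = FALSE)
cat("AMOVA:\n")
print(amova_tab, row.names = FALSE)

D_full <- bruvo_dist(impute_nearest(ds))
geo <- haversine_matrix(ds$meta, centroids = country_centroids())
mt <- mantel_test(D_full, geo[rownames(D_full), rownames(D_full)],
                  nperm = 9999, seed = seed)
cat(sprintf("Mantel genetic vs geographic distance: r = %.3f, p = %.4f (%d permutations)\n",
            mt$r, mt$p, mt$nperm))
write.csv(data.frame(r = mt$r, p = mt$p, nperm = mt$nperm),
          file.path(out, "mantel.csv"), row.names = FALSE)

fst <- suppressWarnings(
  pairwise_fst(core, setNames(ds$meta$group, ds$meta$isolate_id)))
write.csv(as.data.frame(fst), file.path(out, "pairwise_fst.csv"))
cat("Pairwise FST (Weir-Cockerham theta) between groups:\n")
print(round(fst, 2))
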