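#!/usr/bin/env Rscript
# Generate the synthetic diploid-triploid complex and the sulfite growth
# panel that every downstream analysis step consumes. Writes the same CSV
# dialects a real microsatellite survey would provide, plus the generator
# truth for validation.

suppressPackageStartupMessages(library(msatmix))

seed <- as.integer(Sys.getenv("MSATMIX_SEED", "1"))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- simulate_complex(cfg)
write_genotypes(sim$dataset,
                file.path(out, "alleles.csv"),
                file.path(out, "loci.csv"),
                file.path(out, "meta.csv"))
write.csv(sim$truth, file.path(out, "truth.csv"), row.names = FALSE)
write.csv(sim$extra_alleles, file.path(out, "triploid_extra_alleles.csv"),
          row.names = FALSE)

panel <- data.frame(
  strain = sprintf("st%02d", 1:39),
  archetype = rep(c("tolerant", "sensitive", "sensitive", "tolerant",
                    "sensitive", "sensitive"),
                  times = c(12, 8, 10, 3, 2, 4)),
  stringsAsFactors = FALSE)
gw <- simulate_growth(sim_config(seed = seed + 6L, od_noise_sd = 0.03), panel)
write.csv(gw$curves, file.path(out, "growth_curves.csv"), row.names = FALSE)
write.csv(merge(panel, gw$truth, by = "strain"),
          file.path(out, "growth_truth.csv"), row.names = FALSE)

cat("Simulated", nrow(sim$dataset$calls), "isolates x",
    ncol(sim$dataset$calls), "loci in", length(unique(sim$truth$group)),
    "groups;", nrow(panel), "strains x 4 doses x 3 replicates of growth.\n")
cat("Wrote inputs to", out, "\n")
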