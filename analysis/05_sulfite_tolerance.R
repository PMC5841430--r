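#!/usr/bin/env Rscript
# Sulfite (SO2) tolerance phenotyping: growth parameters per curve and
# sensitive/tolerant classification per strain, scored against the
# generator's archetype truth. Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(msatmix))

dat <- "results/data"
out <- "results/growth"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

curves <- read.csv(file.path(dat, "growth_curves.csv"))
params <- growth_param_table(curves)
write.csv(params, file.path(out, "growth_params.csv"), row.names = FALSE)

# per-strain, per-dose means in the usual supplementary-table layout
agg <- aggregate(cbind(lag_h, r_max, od_max) ~ strain + dose, params,
                 mean, na.action = na.pass)
write.csv(agg[order(agg$strain, agg$dose), ],
          file.path(out, "growth_param_means.csv"), row.names = FALSE)

calls <- tolerance_table(curves)
write.csv(calls, file.path(out, "tolerance_calls.csv"), row.names = FALSE)

truth <- read.csv(file.path(dat, "growth_truth.csv"))
arche <- unique(truth[, c("strain", "archetype")])
want <- ifelse(arche$archetype == "tolerant", "T", "S")
got <- calls$klass[match(arche$strain, calls$strain)]
cat(sprintf("Tolerance calls: %d strains | %d sensitive (S), %d tolerant (T)\n",
            nrow(calls), sum(calls$klass == "S"), sum(calls$klass == "T")))
cat(sprintf("Agreement with archetype truth: %d/%d\n",
            sum(got == want), length(want)))
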