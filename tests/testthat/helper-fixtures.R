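# Small in-code fixtures shared by the unit tests.

# build an msat_dataset straight from a list of per-isolate call lists
make_ds <- function(rows, n_loci = length(rows[[1]]),
                    ids = sprintf("i%02d", seq_along(rows)),
                    meta_extra = NULL) {
  n <- length(rows)
  calls <- matrix(vector("list", n * n_loci), n, n_loci)
  for (i in seq_len(n)) {
    for (j in seq_len(n_loci)) calls[i, j] <- rows[[i]][j]
  }
  loci <- data.frame(name = sprintf("L%02d", seq_len(n_loci)),
                     repeat_unit_bp = 3L, offset_bp = 90L,
                     stringsAsFactors = FALSE)
  meta <- data.frame(isolate_id = ids, stringsAsFactors = FALSE)
  if (!is.null(meta_extra)) meta <- cbind(meta, meta_extra)
  msat_dataset(calls, loci, meta)
}

# write the three CSV tables for read_genotypes into a temp dir
write_fixture_tables <- function(allele_rows,
                                 dir = tempfile("fixtures")) {
  if (!dir.exists(dir)) dir.create(dir)
  writeLines(allele_rows$alleles, file.path(dir, "alleles.csv"))
  writeLines(allele_rows$loci, file.path(dir, "loci.csv"))
  writeLines(allele_rows$meta, file.path(dir, "meta.csv"))
  dir
}

# replicate growth-parameter table from per-dose means, jittered
# symmetrically so the replicate means equal the printed means exactly
params_from_means <- function(doses, r, od, lag, grew = NULL,
                              dr = 0.005, dod = 0.05, dlag = 2) {
  if (is.null(grew)) grew <- !is.na(r)
  rows <- list()
  for (d in seq_along(doses)) {
    for (k in 1:3) {
      off <- c(-1, 0, 1)[k]
      rows[[length(rows) + 1L]] <- data.frame(
        strain = "X", dose = doses[d], replicate = k,
        lag_h = if (grew[d]) lag[d] + off * dlag else NA_real_,
        r_max = if (grew[d]) r[d] + off * dr else 0,
        od_max = if (grew[d]) od[d] + off * dod else 0.1,
        grew = grew[d], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
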