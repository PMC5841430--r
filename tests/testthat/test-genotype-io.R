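test_that("fragment sizes convert to repeat counts, deduplicate, and blank cells are missing", {
  dir <- write_fixture_tables(list(
    alleles = c("isolate_id,L1,L2",
                "s1,128;131,200",
                "s2,128;128,",
                "s3,,203;207"),
    loci = c("name,repeat_unit_bp,offset_bp",
             "L1,3,98", "L2,4,180"),
    meta = c("isolate_id,country,substrate",
             "s1,France,wine", "s2,Italy,wine", "s3,USA,beer")))
  ds <- read_genotypes(file.path(dir, "alleles.csv"),
                       file.path(dir, "loci.csv"),
                       file.path(dir, "meta.csv"))
  expect_equal(ds$calls[["s1", "L1"]], c(10L, 11L))
  expect_equal(ds$calls[["s1", "L2"]], 5L)
  expect_equal(ds$calls[["s2", "L1"]], 10L)        # deduplicated
  expect_null(ds$calls[["s2", "L2"]])              # blank -> missing
  expect_null(ds$calls[["s3", "L1"]])
  expect_equal(ds$calls[["s3", "L2"]], c(6L, 7L))  # 5.75 and 6.75 round up
})

test_that("reading rejects unknown ids and negative repeats, warns off-grid", {
  base <- list(
    alleles = c("isolate_id,L1", "s1,104"),
    loci = c("name,repeat_unit_bp,offset_bp", "L1,3,98"),
    meta = c("isolate_id,country,substrate", "s1,France,wine"))
  dir <- write_fixture_tables(base)
  # 104 is 2 repeats exactly on the grid
  expect_silent(ds <- read_genotypes(file.path(dir, "alleles.csv"),
                                     file.path(dir, "loci.csv"),
                                     file.path(dir, "meta.csv")))
  expect_equal(ds$calls[["s1", "L1"]], 2L)

  bad <- base; bad$alleles <- c("isolate_id,LX", "s1,104")
  dir <- write_fixture_tables(bad)
  expect_error(read_genotypes(file.path(dir, "alleles.csv"),
                              file.path(dir, "loci.csv"),
                              file.path(dir, "meta.csv")), "LX")

  bad <- base; bad$meta <- c("isolate_id,country,substrate", "sZ,France,wine")
  dir <- write_fixture_tables(bad)
  expect_error(read_genotypes(file.path(dir, "alleles.csv"),
                              file.path(dir, "loci.csv"),
                              file.path(dir, "meta.csv")), "s1")

  bad <- base; bad$alleles <- c("isolate_id,L1", "s1,80")  # below offset
  dir <- write_fixture_tables(bad)
  expect_error(suppressWarnings(
    read_genotypes(file.path(dir, "alleles.csv"),
                   file.path(dir, "loci.csv"),
                   file.path(dir, "meta.csv"))), "negative")

  offg <- base; offg$alleles <- c("isolate_id,L1", "s1,105.5")  # 2.5 repeats
  dir <- write_fixture_tables(offg)
  expect_warning(read_genotypes(file.path(dir, "alleles.csv"),
                                file.path(dir, "loci.csv"),
                                file.path(dir, "meta.csv")), "0.34")
})

test_that("write_genotypes/read_genotypes round-trips a dataset on the motif grid", {
  ds <- make_ds(list(list(c(10L, 12L), 5L),
                     list(NULL, c(5L, 7L)),
                     list(11L, NULL)))
  dir <- withr::local_tempdir()
  write_genotypes(ds, file.path(dir, "alleles.csv"),
                  file.path(dir, "loci.csv"), file.path(dir, "meta.csv"))
  back <- read_genotypes(file.path(dir, "alleles.csv"),
                         file.path(dir, "loci.csv"),
                         file.path(dir, "meta.csv"))
  expect_identical(back$calls, ds$calls)
})

test_that("ploidy classes follow the maximum allele count per isolate", {
  # per-locus allele-count patterns [2,2,1,2], [2,3,3,1], [2,4,3]
  ds <- make_ds(list(
    list(c(1L, 2L), c(3L, 4L), 5L, c(6L, 7L)),
    list(c(1L, 2L), c(3L, 4L, 5L), c(6L, 7L, 8L), 9L),
    list(c(1L, 2L), c(3L, 4L, 5L, 6L), c(7L, 8L, 9L), NULL)))
  pl <- infer_ploidy(ds)
  expect_equal(as.character(pl$klass), c("2n", "3n", "4n/5n"))
  expect_equal(pl$n_loci_ge3, c(0L, 2L, 2L))
  expect_equal(pl$max_alleles, c(2L, 3L, 4L))
})

test_that("ploidy inference ignores locus and isolate order and flags empty isolates", {
  rows <- list(list(c(1L, 2L), c(3L, 4L, 5L), NULL),
               list(6L, NULL, c(7L, 8L)),
               list(NULL, NULL, NULL))
  ds <- make_ds(rows)
  expect_warning(pl <- infer_ploidy(ds), "missing at every locus")
  expect_true(pl$all_missing[3])
  expect_true(is.na(pl$klass[3]))

  ds_shuf <- subset_dataset(ds, isolates = c(2L, 1L, 3L), loci = c(3L, 1L, 2L))
  pl2 <- suppressWarnings(infer_ploidy(ds_shuf))
  expect_equal(pl2[match(pl$isolate_id, pl2$isolate_id), "klass"], pl$klass)
})

test_that("clone collapse partitions isolates by exact multilocus identity", {
  rows <- list(a = list(c(1L, 2L), 5L),
               b = list(c(1L, 2L), 5L),
               c = list(c(1L, 2L), 6L),
               d = list(NULL, 5L),
               e = list(c(1L, 2L), 5L))
  ds <- make_ds(unname(rows))
  tab <- collapse_clones(ds)
  expect_equal(nrow(tab), 3L)
  expect_equal(sum(tab$multiplicity), 5L)
  # every isolate in exactly one class
  members <- unlist(strsplit(tab$isolates, ";"))
  expect_setequal(members, rownames(ds$calls))
  expect_equal(anyDuplicated(members), 0L)
  # missing status participates in identity: d is its own genotype
  expect_true(any(tab$multiplicity == 1L & tab$representative == "i04"))

  same <- make_ds(list(list(1L, 2L), list(1L, 2L), list(1L, 2L)))
  expect_equal(collapse_clones(same)$multiplicity, 3L)
})

test_that("clone collapse recovers the generator's genotype count exactly without mutation or holes", {
  cfg <- sim_config(seed = 5, smm_rate = 0, missing_rate = 0)
  sim <- simulate_complex(cfg)
  tab <- collapse_clones(sim$dataset)
  expect_equal(nrow(tab), length(unique(sim$truth$genotype_id)))
  expect_equal(sum(tab$multiplicity), nrow(sim$truth))
})
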