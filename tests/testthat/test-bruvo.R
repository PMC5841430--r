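test_that("single-allele distance follows the stepwise closed form", {
  expect_equal(bruvo_allele_dist(20, 20), 0)
  expect_equal(bruvo_allele_dist(20, 21), 0.5)
  expect_equal(bruvo_allele_dist(20, 24), 0.9375)
  expect_equal(bruvo_allele_dist(21, 20), bruvo_allele_dist(20, 21))
  expect_error(bruvo_allele_dist(20.5, 21), "integer")
  expect_error(bruvo_allele_dist(-1, 2), "integer")
})

test_that("locus distance handles equal-size genotypes by optimal matching", {
  expect_equal(bruvo_locus_dist(c(20L, 23L), c(20L, 23L)), 0)
  # best matching pairs 20-21 and 24-24: (0.5 + 0)/2
  expect_equal(bruvo_locus_dist(c(20L, 24L), c(21L, 24L)), 0.25)
  expect_equal(bruvo_locus_dist(20L, 30L), bruvo_allele_dist(20, 30))
})

test_that("genome addition and loss branches average over paddings", {
  # {20} vs {20,30}: addition pads with 20 -> (0 + 1-2^-10)/2;
  # loss pads with 20 or 30 -> mean(0.49951, 0); frozen from the
  # exhaustive oracle (and hand arithmetic)
  add <- (1 - 2^-10) / 2
  expect_equal(bruvo_locus_dist(20L, c(20L, 30L),
                                bruvo_model(addition = TRUE, loss = FALSE)),
               add)
  expect_equal(bruvo_locus_dist(20L, c(20L, 30L),
                                bruvo_model(addition = FALSE, loss = TRUE)),
               add / 2)
  expect_equal(bruvo_locus_dist(20L, c(20L, 30L)), 0.3746337890625)
  expect_error(bruvo_locus_dist(1:6, 1L), "larger than 5")
})

test_that("locus distance agrees with the exhaustive oracle on random mixed-ploidy pairs", {
  set.seed(101)
  models <- list(bruvo_model(TRUE, TRUE, FALSE),
                 bruvo_model(TRUE, FALSE, FALSE),
                 bruvo_model(FALSE, TRUE, FALSE),
                 bruvo_model(FALSE, FALSE, TRUE),
                 bruvo_model(TRUE, TRUE, TRUE))
  for (r in 1:200) {
    a <- random_allele_set(); b <- random_allele_set()
    m <- models[[sample.int(length(models), 1)]]
    got <- bruvo_locus_dist(a, b, m)
    want <- oracle_locus(a, b, m$addition, m$loss, m$infinity)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(got, bruvo_locus_dist(b, a, m))       # symmetry
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("diploid pairs match the two-permutation computation exactly", {
  set.seed(7)
  for (r in 1:50) {
    a <- sort(sample(5:40, 2)); b <- sort(sample(5:40, 2))
    two_perm <- min((oracle_allele(a[1], b[1]) + oracle_allele(a[2], b[2])) / 2,
                    (oracle_allele(a[1], b[2]) + oracle_allele(a[2], b[1])) / 2)
    expect_equal(bruvo_locus_dist(a, b), two_perm)
  }
})

test_that("distance matrices average over shared loci and respect invariants", {
  dup <- make_ds(list(list(c(10L, 12L), 5L), list(c(10L, 12L), 5L)))
  expect_equal(unname(bruvo_dist(dup)), matrix(0, 2, 2))

  ds3 <- make_ds(list(list(10L), list(11L), list(13L)), n_loci = 1)
  D <- bruvo_dist(ds3)
  expect_equal(unname(D),
               matrix(c(0, .5, .875, .5, 0, .75, .875, .75, 0), 3))

  # locus-order invariance and [0,1] range on a simulated complex
  cfg <- sim_config(seed = 3, groups = sim_config()$groups[c(1, 3), ])
  sim <- simulate_complex(cfg)
  D1 <- bruvo_dist(sim$dataset)
  perm <- sample(ncol(sim$dataset$calls))
  D2 <- bruvo_dist(subset_dataset(sim$dataset, loci = perm))
  expect_equal(D1, D2)
  expect_true(all(D1 >= 0 & D1 <= 1))
  expect_equal(D1, t(D1))
})

test_that("matrix entries equal direct per-pair locus averaging", {
  cfg <- sim_config(seed = 9, groups = sim_config()$groups[c(2, 6), ])
  sim <- simulate_complex(cfg)
  ds <- sim$dataset
  D <- bruvo_dist(ds)
  set.seed(2)
  for (r in 1:20) {
    ij <- sample(nrow(ds$calls), 2)
    vals <- c()
    for (j in seq_len(ncol(ds$calls))) {
      a <- ds$calls[[ij[1], j]]; b <- ds$calls[[ij[2], j]]
      if (!is.null(a) && !is.null(b)) vals <- c(vals, oracle_locus(a, b))
    }
    expect_equal(D[ij[1], ij[2]], mean(vals))
  }
})

test_that("pairs sharing no called locus are rejected by name", {
  ds <- make_ds(list(list(10L, NULL), list(NULL, 5L)))
  expect_error(bruvo_dist(ds), "share no called locus")
})

test_that("nearest-neighbour imputation fills holes from the closest called isolate", {
  ds <- make_ds(list(list(c(10L, 12L), 5L, 7L),
                     list(c(10L, 12L), NULL, 7L),
                     list(c(30L, 32L), c(12L, 14L), 25L)))
  imp <- impute_nearest(ds)
  expect_equal(imp$calls[["i02", "L02"]], 5L)   # i01 is far closer than i03
  # already-complete datasets come back unchanged
  expect_identical(impute_nearest(imp)$calls, imp$calls)
  # original untouched
  expect_null(ds$calls[["i02", "L02"]])
})

test_that("imputation recovers punched-out calls in a highly clonal complex", {
  groups <- sim_config()$groups[c(1, 3), ]
  groups$n_genotypes <- c(6L, 6L)
  groups$n_isolates <- c(60L, 60L)
  cfg <- sim_config(seed = 13, smm_rate = 0, missing_rate = 0,
                    groups = groups)
  sim <- simulate_complex(cfg)
  ds <- sim$dataset
  set.seed(14)
  holes <- which(matrix(runif(length(ds$calls)), nrow(ds$calls)) < 0.05)
  punched <- ds$calls
  for (h in holes) punched[h] <- list(NULL)
  ds_p <- msat_dataset(punched, ds$loci, ds$meta)
  imp <- impute_nearest(ds_p)
  ok <- vapply(holes, function(h) identical(imp$calls[[h]], ds$calls[[h]]),
               logical(1))
  expect_gte(mean(ok), 0.95)
})
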