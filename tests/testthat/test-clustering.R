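additive_4taxon <- function() {
  # tree: (A:1, B:2):5 joined to (C:3, D:4); distances are path lengths
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["A", "C"] <- 9; D["A", "D"] <- 10
  D["B", "C"] <- 10; D["B", "D"] <- 11; D["C", "D"] <- 7
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

test_that("NJ reproduces additive distances exactly", {
  D <- additive_4taxon()
  tr <- nj_tree(D)
  cd <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_lt(max(abs(cd - D)), 1e-10)
  expect_true(all(tr$edge.length >= 0))
  # internal edge of length 5 present
  expect_true(any(abs(tr$edge.length - 5) < 1e-10))
})

test_that("three taxa resolve by the three-point formulas", {
  D <- matrix(c(0, .3, .7, .3, 0, .6, .7, .6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  cd <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_lt(max(abs(cd - D)), 1e-10)
  # branch to A = (dAB + dAC - dBC)/2
  a_edge <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "A")]
  expect_equal(a_edge, (.3 + .7 - .6) / 2)
})

test_that("UPGMA joins by average linkage and is ultrametric", {
  D2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- upgma_tree(D2)
  expect_equal(sort(tr2$edge.length), c(0.2, 0.2))

  D3 <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- upgma_tree(D3)
  cd <- ape::cophenetic.phylo(tr3)
  expect_equal(cd["A", "B"], 0.2)
  expect_equal(cd["A", "C"], 0.6)
  expect_true(ape::is.ultrametric(tr3, tol = 1e-8))

  # heights are monotone: cophenetic distances >= input join heights order
  set.seed(31)
  X <- matrix(rnorm(30), 10)
  D <- as.matrix(dist(X)); dimnames(D) <- list(paste0("t", 1:10), paste0("t", 1:10))
  tr <- upgma_tree(D)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
})

test_that("NJ and UPGMA induce the same partitions on ultrametric input", {
  set.seed(5)
  for (r in 1:5) {
    # random ultrametric matrix from a random UPGMA tree over noise points
    base <- as.matrix(dist(matrix(rnorm(16), 8)))
    dimnames(base) <- list(paste0("t", 1:8), paste0("t", 1:8))
    U <- ape::cophenetic.phylo(upgma_tree(base))    # ultrametric by construction
    U <- U[paste0("t", 1:8), paste0("t", 1:8)]
    pn <- ape::prop.part(nj_tree(U))
    pu <- ape::prop.part(upgma_tree(U))
    canon <- function(pp, n) {
      sp <- lapply(pp, function(cl) {
        side <- sort(attr(pp, "labels")[cl])
        other <- sort(setdiff(paste0("t", 1:8), side))
        paste(min(paste(side, collapse = ","), paste(other, collapse = ",")))
      })
      setdiff(unlist(sp), paste(paste0("t", 1:8)[-1], collapse = ","))
    }
    expect_true(all(canon(pn) %in% canon(pu)))
  }
})

test_that("classical MDS round-trips Euclidean distances", {
  # collinear points
  D <- as.matrix(dist(matrix(c(0, 1, 2), 3)))
  dimnames(D) <- list(c("a", "b", "c"), c("a", "b", "c"))
  m <- suppressWarnings(classical_mds(D, 1))
  expect_equal(as.matrix(dist(m$coords)), D, ignore_attr = TRUE,
               tolerance = 1e-10)

  set.seed(8)
  X <- matrix(rnorm(20), 10)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("p", 1:10), paste0("p", 1:10))
  m2 <- suppressWarnings(classical_mds(D, 2))
  expect_lt(max(abs(as.matrix(dist(m2$coords)) - D)), 1e-8)

  # duplicated point -> identical embedding coordinates
  Dd <- as.matrix(dist(rbind(X, X[1, ])))
  dimnames(Dd) <- list(paste0("p", 1:11), paste0("p", 1:11))
  m3 <- suppressWarnings(classical_mds(Dd, 2))
  expect_equal(m3$coords[11, ], m3$coords[1, ], ignore_attr = TRUE,
               tolerance = 1e-8)

  # k beyond the positive spectrum shrinks with a warning
  expect_warning(classical_mds(D, 9), "positive eigenvalues")
})

test_that("successive K-means recovers separated blobs and flags degenerate input", {
  set.seed(21)
  centers <- rbind(c(0, 0), c(14, 0), c(7, 12))
  X <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(100, sd = 1), 50, 2), 2, centers[k, ], "+")
  }))
  rownames(X) <- sprintf("p%03d", 1:150)
  fc <- find_clusters(X, kmax = 8, seed = 4)
  expect_equal(fc$k, 3L)
  truth <- rep(1:3, each = 50)
  expect_equal(adjusted_rand(fc$labels, truth), 1)
  # WSS at the true k drops by >90% vs k-1
  expect_gt((fc$wss[2] - fc$wss[3]) / fc$wss[2], 0.9)
  expect_true(all(diff(fc$wss) <= 1e-8))

  same <- matrix(1, 20, 2, dimnames = list(paste0("q", 1:20), NULL))
  expect_equal(find_clusters(same, kmax = 5)$k, 1L)
})

test_that("partition reliability scores tight clades near 1 and skips the root", {
  # 12 tips: {a,b,c} identical, the rest diffuse and far
  set.seed(2)
  n <- 12
  D <- matrix(runif(n * n, 0.5, 0.9), n)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D[1:3, 1:3] <- 0
  ids <- letters[1:n]
  dimnames(D) <- list(ids, ids)
  tr <- upgma_tree(D)
  rel <- partition_reliability(tr, D, R = 200, seed = 2)
  tab <- attr(rel, "reliability")
  expect_true(is.na(tab$reliability[tab$size == n]))    # root skipped
  tight <- tab$reliability[tab$size == 3 & abs(tab$observed) < 1e-12]
  # the only null subsets not beating a zero-distance clade are re-draws of
  # the clade itself, so reliability sits at (or within a tie of) 1
  expect_gte(tight, 0.95)
  expect_true(all(tab$reliability >= 0 & tab$reliability <= 1, na.rm = TRUE))
})

test_that("reliability separates true groups from tree-artefact clades", {
  # NJ on unstructured points still nests tips by proximity, so some
  # apparent clades score high; genuine groups must score higher still
  groups <- sim_config()$groups[c(1, 2, 3), ]
  cfg <- sim_config(seed = 19, groups = groups)
  sim <- simulate_complex(cfg)
  D <- bruvo_dist(impute_nearest(sim$dataset))
  tr <- partition_reliability(nj_tree(D), D, R = 200, seed = 3)
  tab <- attr(tr, "reliability")
  # the clades corresponding to whole groups exist and are near-certain
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  all_ids <- sort(labs)
  for (g in groups$name) {
    members <- sort(sim$truth$isolate_id[sim$truth$group == g])
    comp <- setdiff(all_ids, members)
    hit <- which(vapply(seq_along(pp), function(i) {
      side <- sort(labs[pp[[i]]])
      identical(side, members) || identical(side, comp)
    }, logical(1)))
    # the group shows up as a bipartition side; identical-genotype clones
    # can make it appear under the clade or its complement
    expect_gte(length(hit), 1)
    expect_gt(max(tab$reliability[hit], na.rm = TRUE), 0.9)
  }
})
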