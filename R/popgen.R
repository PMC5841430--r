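#' Distance-based analysis of molecular variance (AMOVA)
#'
#' Partitions the total squared pairwise distance into among-group and
#' within-group components for one grouping factor. Sums of squares follow
#' the standard distance formulation: `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`, `SS_among` by
#' difference. Variance components use `sigma2_w = SS_within / (N - G)` and
#' `sigma2_a = (SS_among/(G-1) - sigma2_w) / n0` with
#' `n0 = (N - sum n_g^2 / N) / (G - 1)`. Significance comes from random
#' permutations of the group labels, with the add-one rule
#' `p = (1 + #[sigma2_a_perm >= sigma2_a]) / (1 + nperm)`.
#'
#' Groups of size 1 are dropped with a warning; negative variance
#' components are truncated to zero for the percentage.
#'
#' @param D complete symmetric distance matrix (ids as dimnames).
#' @param labels group label per isolate, in matrix order (or named by id).
#' @param nperm number of permutations.
#' @param seed integer seed.
#' @return list: `SS_among`, `SS_within`, `df_among`, `df_within`,
#'   `sigma2_among`, `sigma2_within`, `pct_variance`, `p`, `nperm`,
#'   `n_groups`, `n`.
#' @export
amova_dist <- function(D, labels, nperm = 1000L, seed = 1L) {
  .check_dist(D, min_n = 2L)
  if (!is.null(names(labels)) && !is.null(rownames(D))) {
    labels <- labels[rownames(D)]
  }
  if (length(labels) != nrow(D)) stop("one label per isolate required")
  keep <- !is.na(labels)
  labels <- as.character(labels[keep])
  D2 <- D[keep, keep, drop = FALSE]^2
  tab <- table(labels)
  singles <- names(tab)[tab < 2L]
  if (length(singles)) {
    warning("dropping group(s) of size 1: ", paste(singles, collapse = ", "))
    keep2 <- !(labels %in% singles)
    labels <- labels[keep2]
    D2 <- D2[keep2, keep2, drop = FALSE]
    tab <- table(labels)
  }
  G <- length(tab)
  if (G == 1L && length(unique(labels)) == 1L) {
    # a single group carries no among-group variance by convention
    N <- length(labels)
    return(list(SS_among = 0, SS_within = sum(D2) / (2 * N),
                df_among = 0L, df_within = N - 1L,
                sigma2_among = 0, sigma2_within = sum(D2) / (2 * N) / (N - 1L),
                pct_variance = 0, p = NA_real_, nperm = 0L,
                n_groups = 1L, n = N))
  }
  if (G < 2L) stop("need at least 2 usable groups")
  N <- length(labels)
  ss_total <- sum(D2) / (2 * N)
  comp <- function(lab) {
    M <- stats::model.matrix(~ lab - 1)
    within_sums <- diag(t(M) %*% D2 %*% M) / 2
    n_g <- colSums(M)
    ss_w <- sum(within_sums / n_g)
    ss_a <- ss_total - ss_w
    s2w <- ss_w / (N - G)
    n0 <- (N - sum(n_g^2) / N) / (G - 1)
    s2a <- (ss_a / (G - 1) - s2w) / n0
    c(ss_a = ss_a, ss_w = ss_w, s2a = s2a, s2w = s2w)
  }
  obs <- comp(factor(labels))
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(nperm)) {
    perm <- comp(factor(sample(labels)))
    if (perm["s2a"] >= obs["s2a"]) exceed <- exceed + 1L
  }
  s2a_pos <- max(obs[["s2a"]], 0)
  list(SS_among = obs[["ss_a"]], SS_within = obs[["ss_w"]],
       df_among = G - 1L, df_within = N - G,
       sigma2_among = obs[["s2a"]], sigma2_within = obs[["s2w"]],
       pct_variance = 100 * s2a_pos / (s2a_pos + obs[["s2w"]]),
       p = (1 + exceed) / (1 + nperm), nperm = nperm,
       n_groups = G, n = N)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the upper-triangle entries, with significance
#' from simultaneous row/column permutations of the second matrix
#' (one-sided, greater; add-one rule).
#'
#' @param D1,D2 complete symmetric matrices over the same ids in the same
#'   order.
#' @param nperm number of permutations.
#' @param seed integer seed.
#' @return list: `r`, `p`, `nperm`.
#' @export
mantel_test <- function(D1, D2, nperm = 10000L, seed = 1L) {
  .check_dist(D1); .check_dist(D2)
  if (!identical(dim(D1), dim(D2))) stop("matrices differ in size")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2))) {
    stop("matrices must share ids in the same order")
  }
  ut <- upper.tri(D1)
  x <- D1[ut]
  if (stats::sd(x) == 0 || stats::sd(D2[ut]) == 0) {
    stop("zero variance in a distance triangle; r undefined")
  }
  r_obs <- stats::cor(x, D2[ut])
  set.seed(seed)
  n <- nrow(D1)
  exceed <- 0L
  for (b in seq_len(nperm)) {
    o <- sample.int(n)
    if (stats::cor(x, D2[o, o][ut]) >= r_obs) exceed <- exceed + 1L
  }
  list(r = r_obs, p = (1 + exceed) / (1 + nperm), nperm = nperm)
}

#' Great-circle distance matrix from isolate coordinates
#'
#' Haversine distances on a sphere of radius 6371 km. Isolates resolved to
#' the same coordinates (e.g. the same country centroid) get distance 0.
#'
#' @param meta data.frame with `isolate_id`, `lat`, `lon`; or with
#'   `isolate_id`, `country` plus a `centroids` lookup.
#' @param centroids optional data.frame `country`, `lat`, `lon` used when
#'   `meta` lacks coordinates.
#' @return Symmetric matrix of distances in km, ids as dimnames.
#' @export
haversine_matrix <- function(meta, centroids = NULL) {
  stopifnot("isolate_id" %in% names(meta))
  if (!all(c("lat", "lon") %in% names(meta)) || anyNA(meta$lat) ||
      anyNA(meta$lon)) {
    if (is.null(centroids)) stop("coordinates missing and no centroid table")
    hit <- match(meta$country, centroids$country)
    if (anyNA(hit)) {
      stop("countries without centroid: ",
           paste(unique(meta$country[is.na(hit)]), collapse = ", "))
    }
    meta$lat <- centroids$lat[hit]
    meta$lon <- centroids$lon[hit]
  }
  if (any(abs(meta$lat) > 90) || any(abs(meta$lon) > 180)) {
    stop("coordinates out of range")
  }
  pts <- cbind(meta$lon, meta$lat)
  D <- geosphere::distm(pts, fun = function(p, q)
    geosphere::distHaversine(p, q, r = 6371000)) / 1000
  dimnames(D) <- list(meta$isolate_id, meta$isolate_id)
  D
}

#' Bundled country-centroid table
#'
#' A small editable lookup of approximate country centroids used to turn
#' country labels into geographic distances.
#'
#' @return data.frame with `country`, `lat`, `lon`.
#' @export
country_centroids <- function() {
  path <- system.file("extdata", "country_centroids.csv", package = "msatmix")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Weir-Cockerham variance components for one pair of populations.
# calls_by_pop: list of two list-columns of allele sets at one locus.
.wc_components <- function(sets1, sets2) {
  gt <- function(s) {
    # single-allele calls are homozygotes; two alleles a heterozygote
    if (length(s) == 1L) c(s, s) else s
  }
  sets1 <- Filter(Negate(is.null), sets1)
  sets2 <- Filter(Negate(is.null), sets2)
  n1 <- length(sets1); n2 <- length(sets2)
  if (n1 < 2L || n2 < 2L) return(NULL)
  alleles <- sort(unique(c(unlist(sets1), unlist(sets2))))
  if (length(alleles) < 2L) return(NULL)     # monomorphic locus: no information
  g1 <- lapply(sets1, gt); g2 <- lapply(sets2, gt)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  out <- matrix(0, length(alleles), 3,
                dimnames = list(alleles, c("a", "b", "c")))
  for (al in seq_along(alleles)) {
    A <- alleles[al]
    p1 <- mean(vapply(g1, function(g) sum(g == A), numeric(1))) / 2
    p2 <- mean(vapply(g2, function(g) sum(g == A), numeric(1))) / 2
    h1 <- mean(vapply(g1, function(g) sum(g == A) == 1L, numeric(1)))
    h2 <- mean(vapply(g2, function(g) sum(g == A) == 1L, numeric(1)))
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    out[al, ] <- c(a, b, cc)
  }
  out
}

#' Pairwise Weir-Cockerham FST between populations
#'
#' Computes the 1984 theta estimator on a core (<= 2 alleles per call)
#' dataset: per locus and allele the among-population (a),
#' among-individual (b) and within-individual (c) variance components are
#' accumulated and theta is the ratio of sums `sum a / sum (a+b+c)` across
#' alleles and loci. Single-allele calls count as homozygotes. Negative
#' estimates truncate to 0; a pair with no polymorphic shared locus is
#' returned as `NA` with a warning.
#'
#' @param core an `msat_dataset` whose calls have at most 2 alleles.
#' @param pops population label per isolate (named by id, or in dataset
#'   order). `NA`-labelled isolates are ignored.
#' @return Symmetric matrix of theta values (diagonal `NA`), population
#'   labels as dimnames.
#' @export
pairwise_fst <- function(core, pops) {
  stopifnot(inherits(core, "msat_dataset"))
  if (!is.null(names(pops))) pops <- pops[rownames(core$calls)]
  if (length(pops) != nrow(core$calls)) stop("one population label per isolate")
  sizes <- vapply(core$calls, function(s) if (is.null(s)) 0L else length(s),
                  integer(1))
  if (any(sizes > 2L)) stop("core dataset must have <= 2 alleles per call")
  keep <- !is.na(pops)
  pops <- as.character(pops[keep])
  calls <- core$calls[keep, , drop = FALSE]
  labs <- sort(unique(pops))
  if (any(table(pops) < 2L)) stop("each population needs >= 2 isolates")
  K <- length(labs)
  Th <- matrix(NA_real_, K, K, dimnames = list(labs, labs))
  for (p in seq_len(K - 1L)) {
    for (q in (p + 1L):K) {
      i1 <- which(pops == labs[p]); i2 <- which(pops == labs[q])
      num <- 0; den <- 0; informative <- FALSE
      for (j in seq_len(ncol(calls))) {
        comp <- .wc_components(calls[i1, j], calls[i2, j])
        if (is.null(comp) || !all(is.finite(comp))) next
        informative <- TRUE
        num <- num + sum(comp[, "a"])
        den <- den + sum(comp)
      }
      if (!informative || den == 0) {
        warning("no polymorphic shared locus for pair ", labs[p], " / ",
                labs[q], "; theta undefined")
        next
      }
      Th[p, q] <- Th[q, p] <- max(0, num / den)
    }
  }
  Th
}
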