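#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomerative NJ (via \pkg{ape}). NJ can produce
#' negative branch lengths on non-additive input; these are clamped to zero
#' and the deficit transferred to the adjacent branch at the same node so
#' that path lengths through the pair are preserved as far as possible.
#' On additive matrices the tree reproduces the input distances exactly.
#'
#' @param D complete symmetric distance matrix with ids as dimnames.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  .check_dist(D, min_n = 3L)
  tr <- ape::nj(stats::as.dist(D))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    len <- tr$edge.length[e]
    child <- tr$edge[e, 2]
    # adjacent branch: first other edge incident to the child node,
    # falling back to the sibling edge at the parent
    adj <- setdiff(which(tr$edge[, 1] == child), e)
    if (!length(adj)) adj <- setdiff(which(tr$edge[, 1] == tr$edge[e, 1]), e)
    tr$edge.length[e] <- 0
    if (length(adj)) {
      tr$edge.length[adj[1]] <- max(0, tr$edge.length[adj[1]] + len)
    }
  }
  tr
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomeration; the result is rooted and ultrametric
#' (equal root-to-leaf path lengths).
#'
#' @param D complete symmetric distance matrix with ids as dimnames.
#' @return A rooted ultrametric `phylo` tree.
#' @export
upgma_tree <- function(D) {
  .check_dist(D, min_n = 2L)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ape::as.phylo(hc)
}

.check_dist <- function(D, min_n = 2L) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (nrow(D) < min_n) stop("need at least ", min_n, " taxa")
  if (anyNA(D)) stop("distance matrix is incomplete")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  invisible(TRUE)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distances and eigendecomposes (via
#' `stats::cmdscale`, as the original workflow). Coordinates come from the
#' top-k non-negative eigenvalues scaled by their square roots; negative
#' eigenvalues (non-Euclidean input) are dropped with a warning, and `k`
#' is reduced with a warning when fewer positive eigenvalues exist.
#'
#' @param D complete symmetric distance matrix.
#' @param k number of dimensions requested.
#' @return list with `coords` (N x k' matrix, ids as rownames), `eig`
#'   (all eigenvalues) and `k` (dimensions actually returned).
#' @export
classical_mds <- function(D, k = 2L) {
  .check_dist(D, min_n = 2L)
  stopifnot(k >= 1L)
  # cmdscale warns on its own about dropped eigenvalues; we re-derive the
  # diagnostics below with more context
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(D),
                                          k = min(k, nrow(D) - 1L),
                                          eig = TRUE))
  eig <- fit$eig
  npos <- sum(eig > 1e-9)
  if (any(eig < -1e-9)) {
    warning("negative eigenvalues dropped (non-Euclidean distances)")
  }
  if (npos < k) {
    warning("only ", npos, " positive eigenvalues; returning k = ", npos)
  }
  kk <- max(1L, min(k, npos))
  coords <- fit$points[, seq_len(min(kk, ncol(fit$points))), drop = FALSE]
  rownames(coords) <- rownames(D)
  list(coords = coords, eig = eig, k = ncol(coords))
}

#' MDS coordinates retaining a share of the positive-eigenvalue variance
#'
#' Convenience wrapper around [classical_mds()] keeping the smallest number
#' of components whose eigenvalues cover `var_explained` of the positive
#' eigenvalue mass -- the usual dimension reduction before successive
#' K-means.
#'
#' @param D complete symmetric distance matrix.
#' @param var_explained fraction of positive-eigenvalue variance to retain.
#' @return As [classical_mds()].
#' @export
mds_retain <- function(D, var_explained = 0.95) {
  full <- suppressWarnings(classical_mds(D, k = nrow(D) - 1L))
  pos <- full$eig[full$eig > 1e-9]
  kk <- which(cumsum(pos) / sum(pos) >= var_explained)[1]
  list(coords = full$coords[, seq_len(kk), drop = FALSE],
       eig = full$eig, k = kk)
}

#' Select clusters by successive K-means on ordination coordinates
#'
#' Runs K-means for k = 1..kmax (multiple restarts, best within-group sum
#' of squares kept) and selects k by a diffNgroup-style rule: the smallest
#' k at which the relative WSS drop `(WSS(k) - WSS(k+1)) / WSS(1)` falls
#' below the threshold `tau` -- i.e. adding a further cluster stops buying
#' a meaningful share of the total variance. Degenerate coordinates (all
#' points identical) give k = 1.
#'
#' @param coords numeric matrix (points x dimensions), e.g. from
#'   [classical_mds()].
#' @param kmax largest k examined (>= 2).
#' @param restarts K-means restarts per k.
#' @param tau relative-drop threshold (default 0.05).
#' @param seed integer seed for the K-means restarts.
#' @return list with `k`, `labels` (integer vector named by rownames),
#'   `wss` (WSS for k = 1..kmax) and `tau`.
#' @export
find_clusters <- function(coords, kmax = 10L, restarts = 25L, tau = 0.05,
                          seed = 1L) {
  stopifnot(is.matrix(coords) || is.data.frame(coords), kmax >= 2L)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  kmax <- min(kmax, n - 1L)
  if (all(apply(coords, 2, stats::sd) < 1e-12)) {
    return(list(k = 1L,
                labels = stats::setNames(rep(1L, n), rownames(coords)),
                wss = stats::setNames(0, "1"), tau = tau))
  }
  set.seed(seed)
  wss <- numeric(kmax)
  labs <- vector("list", kmax)
  center <- colMeans(coords)
  wss[1] <- sum(sweep(coords, 2, center)^2)
  labs[[1]] <- rep(1L, n)
  for (k in 2:kmax) {
    km <- stats::kmeans(coords, centers = k, nstart = restarts,
                        iter.max = 100L)
    wss[k] <- km$tot.withinss
    labs[[k]] <- km$cluster
  }
  drops <- (wss[-kmax] - wss[-1]) / wss[1]
  below <- which(drops < tau)
  k_star <- if (length(below)) min(below) else kmax
  list(k = k_star,
       labels = stats::setNames(as.integer(labs[[k_star]]), rownames(coords)),
       wss = stats::setNames(wss, seq_len(kmax)),
       tau = tau)
}

#' Node reliability by the partition method
#'
#' For every internal clade C (2 <= |C| < N) the observed mean pairwise
#' distance within C is compared against `R` random leaf subsets of the
#' same size: reliability is the fraction of random subsets whose mean
#' pairwise distance is strictly greater than the observed one. Clades of
#' isolates more closely related than random draws score near 1; the
#' conventional display cutoff is 0.90. Null distributions are computed
#' once per clade size and reused.
#'
#' @param tree a `phylo` tree whose tip labels appear in `D`.
#' @param D distance matrix (ids as dimnames).
#' @param R number of random subsets per clade size (>= 100).
#' @param seed integer seed.
#' @return The tree with `node.label` set to the reliability (root `NA`),
#'   plus attribute `"reliability"`: data.frame of node, clade size,
#'   observed mean distance and reliability.
#' @export
partition_reliability <- function(tree, D, R = 1000L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), R >= 100L)
  if (!all(tree$tip.label %in% rownames(D))) {
    stop("tree tips missing from distance matrix")
  }
  set.seed(seed)
  n <- length(tree$tip.label)
  Dm <- D[tree$tip.label, tree$tip.label]
  clades <- ape::prop.part(tree)
  # prop.part: one entry per internal node, first = root (all tips)
  node_ids <- seq_len(tree$Nnode) + n
  sizes <- lengths(clades)
  null_means <- new.env(parent = emptyenv())
  mean_pair <- function(idx) {
    m <- length(idx)
    (sum(Dm[idx, idx])) / (m * (m - 1L))
  }
  rel <- rep(NA_real_, length(clades))
  obs <- rep(NA_real_, length(clades))
  for (c in seq_along(clades)) {
    m <- sizes[c]
    if (m < 2L || m >= n) next
    obs[c] <- mean_pair(clades[[c]])
    key <- as.character(m)
    if (is.null(null_means[[key]])) {
      null_means[[key]] <- vapply(seq_len(R), function(r) {
        mean_pair(sample.int(n, m))
      }, numeric(1))
    }
    rel[c] <- mean(null_means[[key]] > obs[c])
  }
  tree$node.label <- ifelse(is.na(rel), "", sprintf("%.3f", rel))
  attr(tree, "reliability") <- data.frame(
    node = node_ids, size = sizes, observed = obs, reliability = rel)
  tree
}
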