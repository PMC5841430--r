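#' Encode a core dataset as an allele-dosage matrix
#'
#' One column per surviving (locus, allele) pair. A two-allele call puts
#' dosage 0.5 on each allele, a single-allele call (homozygote) dosage 1;
#' missing calls leave the locus block zero and masked. Per called locus
#' the block of an isolate sums to 1, so rows behave like per-locus
#' allele-frequency profiles.
#'
#' @param core an `msat_dataset` with at most 2 alleles per call.
#' @return list: `X` (N x A dosage matrix), `mask` (logical N x A, `TRUE`
#'   where the locus is called), `columns` (data.frame `locus`, `allele`),
#'   `locus_of` (integer locus index per column).
#' @export
encode_genotypes <- function(core) {
  stopifnot(inherits(core, "msat_dataset"))
  cols <- list()
  for (j in seq_len(ncol(core$calls))) {
    alleles <- sort(unique(unlist(core$calls[, j])))
    if (length(alleles)) {
      cols[[length(cols) + 1L]] <- data.frame(
        locus = colnames(core$calls)[j], locus_idx = j,
        allele = alleles, stringsAsFactors = FALSE)
    }
  }
  columns <- do.call(rbind, cols)
  A <- nrow(columns)
  n <- nrow(core$calls)
  X <- matrix(0, n, A, dimnames = list(rownames(core$calls),
                                       paste(columns$locus, columns$allele,
                                             sep = ".")))
  mask <- matrix(FALSE, n, A, dimnames = dimnames(X))
  for (j in unique(columns$locus_idx)) {
    block <- which(columns$locus_idx == j)
    al <- columns$allele[block]
    for (i in seq_len(n)) {
      s <- core$calls[[i, j]]
      if (is.null(s)) next
      if (length(s) > 2L) stop("call with more than 2 alleles; build the core dataset first")
      mask[i, block] <- TRUE
      X[i, block[match(s, al)]] <- 1 / length(s)
    }
  }
  list(X = X, mask = mask, columns = columns,
       locus_of = columns$locus_idx)
}

# one EM pass for the admixture model P(allele) = sum_k q_ik g_kla,
# restricted to weighted (training) entries. g_prior is a per-cell
# Dirichlet pseudocount keeping ancestral frequencies off the boundary
# (a rare allele absent from a component's training cells would otherwise
# receive probability 0 and blow up the held-out log loss).
.admix_em_step <- function(X, W, Q, G, locus_of, g_prior = 0) {
  eps <- 1e-12
  Xw <- X * W
  P <- Q %*% G
  R <- Xw / pmax(P, eps)
  Q2 <- Q * (R %*% t(G))
  rs <- rowSums(Xw)
  Q2 <- Q2 / pmax(rowSums(Q2), eps)
  Q2[rs == 0, ] <- 1 / ncol(Q)          # isolates with no training data
  G2 <- G * (t(Q) %*% R) + g_prior
  for (l in unique(locus_of)) {
    block <- which(locus_of == l)
    bs <- rowSums(G2[, block, drop = FALSE])
    G2[, block] <- G2[, block, drop = FALSE] / pmax(bs, eps)
  }
  list(Q = Q2, G = G2)
}

.masked_ce <- function(X, P, cells) {
  eps <- 1e-12
  x <- X[cells]
  p <- pmax(P[cells], eps)
  keep <- x > 0
  if (!any(keep)) return(0)
  -sum(x[keep] * log(p[keep])) / sum(keep)
}

#' Fit admixture proportions by simplex-constrained factorization
#'
#' Models each isolate's per-locus allele profile as a mixture of K
#' ancestral allele-frequency profiles: `X ~ Q G` with Q rows on the
#' simplex (ancestry proportions) and G's per-locus blocks on the simplex
#' per ancestral population. Fitting maximizes the multinomial
#' log-likelihood of the observed dosages by EM (equivalently, KL-NMF
#' multiplicative updates with renormalization), which is monotone. A
#' random `mask_fraction` of the called isolate-locus genotype calls is
#' held out -- whole per-locus blocks, so no allele of a masked call leaks
#' into training -- and the cross-entropy of the fitted probabilities on
#' that hold-out is reported as the model-choice criterion.
#'
#' @param enc output of [encode_genotypes()].
#' @param K number of ancestral populations (>= 1).
#' @param seed integer seed (initialisation and hold-out mask).
#' @param mask_fraction fraction of called genotype calls held out
#'   (default 0.05).
#' @param max_iter maximum EM iterations (default 500).
#' @param tol stop when the training cross-entropy improves by less.
#' @param g_prior Dirichlet pseudocount smoothing the ancestral frequency
#'   blocks (default 1e-3); keeps rare alleles off the boundary so the
#'   held-out cross-entropy stays finite and comparable across K.
#' @return list of class `ancestry_fit`: `K`, `Q`, `G`, `ce_heldout`,
#'   `ce_train`, `iterations`, `converged`, `seed`.
#' @export
fit_ancestry <- function(enc, K, seed = 1L, mask_fraction = 0.05,
                         max_iter = 500L, tol = 1e-8, g_prior = 1e-3) {
  stopifnot(K >= 1L)
  X <- enc$X; mask <- enc$mask; locus_of <- enc$locus_of
  n <- nrow(X); A <- ncol(X)
  set.seed(seed)
  # hold out whole isolate-locus calls (blocks), never single allele cells
  loci_ids <- unique(locus_of)
  block_called <- mask[, match(loci_ids, locus_of), drop = FALSE]
  called_blocks <- which(block_called)
  held_blocks <- if (mask_fraction > 0 && length(called_blocks) > 1L) {
    sample(called_blocks,
           max(1L, floor(mask_fraction * length(called_blocks))))
  } else integer(0)
  hb <- arrayInd(held_blocks, dim(block_called))
  W <- matrix(0, n, A)
  W[mask] <- 1
  heldout <- integer(0)
  for (r in seq_len(nrow(hb))) {
    cols <- which(locus_of == loci_ids[hb[r, 2]])
    W[hb[r, 1], cols] <- 0
    heldout <- c(heldout, (cols - 1L) * n + hb[r, 1])
  }
  if (K == 1L) {
    G <- matrix(colSums(X * W) + g_prior, 1, A)
    for (l in unique(locus_of)) {
      block <- which(locus_of == l)
      G[, block] <- G[, block, drop = FALSE] / max(sum(G[, block]), 1e-12)
    }
    Q <- matrix(1, n, 1, dimnames = list(rownames(X), NULL))
    P <- Q %*% G
    return(structure(list(K = 1L, Q = Q, G = G,
                          ce_heldout = .masked_ce(X, P, heldout),
                          ce_train = .masked_ce(X, P, which(W == 1)),
                          iterations = 0L, converged = TRUE, seed = seed),
                     class = "ancestry_fit"))
  }
  Q <- matrix(stats::rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  G <- matrix(stats::rgamma(K * A, 1), K, A)
  for (l in unique(locus_of)) {
    block <- which(locus_of == l)
    G[, block] <- G[, block, drop = FALSE] /
      rowSums(G[, block, drop = FALSE])
  }
  train <- which(W == 1)
  ce_prev <- .masked_ce(X, Q %*% G, train)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    st <- .admix_em_step(X, W, Q, G, locus_of, g_prior)
    Q <- st$Q; G <- st$G
    ce <- .masked_ce(X, Q %*% G, train)
    if (ce_prev - ce < tol && it > 1L) { converged <- TRUE; ce_prev <- ce; break }
    ce_prev <- ce
  }
  P <- Q %*% G
  rownames(Q) <- rownames(X)
  structure(list(K = as.integer(K), Q = Q, G = G,
                 ce_heldout = .masked_ce(X, P, heldout),
                 ce_train = ce_prev,
                 iterations = it, converged = converged, seed = seed),
            class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat("ancestry_fit: K =", x$K, "|", nrow(x$Q), "isolates |",
      x$iterations, "EM iterations",
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  cat("  held-out cross-entropy:", format(x$ce_heldout, digits = 5), "\n")
  invisible(x)
}

#' Choose the number of ancestral populations by held-out cross-entropy
#'
#' For each K in `k_range`, `repetitions` fits are run with fresh seeds
#' (hence fresh hold-out masks and initialisations) and the mean held-out
#' cross-entropy is recorded. The selected K* is the smallest K whose mean
#' lies within one standard error of the minimum (entropy curves plateau,
#' so ties resolve toward parsimony).
#'
#' @param enc output of [encode_genotypes()].
#' @param k_range integer vector of K values.
#' @param repetitions fits per K.
#' @param seed integer base seed.
#' @param ... passed to [fit_ancestry()].
#' @return list: `k` (K*), `curve` (data.frame K, mean/sd/se of the
#'   held-out cross-entropy), `fits` (best fit per K).
#' @export
select_k <- function(enc, k_range = 1:8, repetitions = 10L, seed = 1L, ...) {
  stopifnot(length(k_range) >= 1L, repetitions >= 1L)
  rows <- list(); best_fits <- list()
  for (K in k_range) {
    ces <- numeric(repetitions)
    best <- NULL
    for (r in seq_len(repetitions)) {
      f <- fit_ancestry(enc, K, seed = seed + 1000L * K + r, ...)
      ces[r] <- f$ce_heldout
      if (is.null(best) || f$ce_heldout < best$ce_heldout) best <- f
    }
    best_fits[[as.character(K)]] <- best
    rows[[length(rows) + 1L]] <- data.frame(
      K = K, ce_mean = mean(ces),
      ce_sd = stats::sd(ces),
      ce_se = stats::sd(ces) / sqrt(repetitions))
  }
  curve <- do.call(rbind, rows)
  i_min <- which.min(curve$ce_mean)
  thr <- curve$ce_mean[i_min] +
    (if (is.finite(curve$ce_se[i_min])) curve$ce_se[i_min] else 0)
  k_star <- curve$K[which(curve$ce_mean <= thr)[1]]
  list(k = k_star, curve = curve, fits = best_fits)
}

#' Align two ancestry fits over the label-switching symmetry
#'
#' Admixture components are identified only up to permutation. Finds the
#' column permutation of `Q2` best matching `Q1` (maximal trace of
#' `t(Q1) %*% Q2[, perm]`, by exhaustive search; K <= 8).
#'
#' @param Q1,Q2 N x K ancestry matrices.
#' @return list: `perm` (permutation to apply to `Q2`'s columns), `Q2`
#'   (permuted matrix).
#' @export
match_ancestry <- function(Q1, Q2) {
  K <- ncol(Q1)
  stopifnot(ncol(Q2) == K, K <= 8L)
  S <- t(Q1) %*% Q2
  P <- .perms(K)
  best <- -Inf; bp <- seq_len(K)
  for (r in seq_len(nrow(P))) {
    v <- sum(S[cbind(seq_len(K), P[r, ])])
    if (v > best) { best <- v; bp <- P[r, ] }
  }
  list(perm = bp, Q2 = Q2[, bp, drop = FALSE])
}
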