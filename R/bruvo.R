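#' Bruvo model for unequal allele counts
#'
#' Bruvo's genotype distance needs a rule for comparing allele sets of
#' unequal size (e.g. a diploid against a triploid). Under *genome addition*
#' the smaller set is padded with copies of its own alleles (the missing
#' genome is assumed to duplicate what is there); under *genome loss* it is
#' padded with alleles from the larger set (the missing alleles are assumed
#' lost copies of the partner's); the *infinity* fallback scores every
#' unmatched allele at the maximal distance 1. Enabled models are averaged.
#'
#' @param addition,loss,infinity logicals; at least one must be `TRUE`.
#' @return A `bruvo_model` list.
#' @export
bruvo_model <- function(addition = TRUE, loss = TRUE, infinity = FALSE) {
  if (!addition && !loss && !infinity) {
    stop("at least one of addition/loss/infinity must be enabled")
  }
  structure(list(addition = addition, loss = loss, infinity = infinity),
            class = "bruvo_model")
}

#' Bruvo's single-allele distance
#'
#' Under the stepwise mutation model the chance of mutating between two
#' alleles decays geometrically in their repeat-count difference, giving the
#' distance `1 - 2^(-|x - y|)`: 0 for identical alleles, 0.5 for one step,
#' approaching 1 as alleles diverge.
#'
#' @param x,y non-negative integer repeat counts (vectorized).
#' @return Numeric in `[0, 1)`.
#' @export
bruvo_allele_dist <- function(x, y) {
  if (any(x != round(x)) || any(y != round(y)) || any(x < 0) || any(y < 0)) {
    stop("repeat counts must be non-negative integers")
  }
  1 - 2^(-abs(x - y))
}

# permutations of 1..n as an (n!) x n matrix; n <= 5 so at most 120 rows
.perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

# minimum over perfect matchings of the mean allele distance (equal sizes)
.match_min <- function(a, b) {
  k <- length(a)
  if (k == 1L) return(bruvo_allele_dist(a, b))
  D <- 1 - 2^(-abs(outer(a, b, "-")))
  P <- .perms(k)
  best <- Inf
  for (r in seq_len(nrow(P))) {
    v <- sum(D[cbind(seq_len(k), P[r, ])])
    if (v < best) best <- v
  }
  best / k
}

# unordered selections of `m` elements from `pool` with repetition
.pad_combos <- function(pool, m) {
  idx <- seq_along(pool)
  grid <- do.call(expand.grid, rep(list(idx), m))
  keep <- rep(TRUE, nrow(grid))
  if (m > 1L) {
    for (c in 2:m) keep <- keep & (grid[[c]] >= grid[[c - 1L]])
  }
  grid <- grid[keep, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(r) pool[as.integer(grid[r, ])])
}

#' Bruvo's distance between two allele sets at one locus
#'
#' For equal-sized sets the distance is the minimum over all perfect
#' matchings of the mean single-allele distance. For unequal sizes the
#' smaller set is padded up under each enabled model of [bruvo_model()]
#' (all unordered padding combinations, each scored as an equal-size
#' comparison and averaged) and enabled models are averaged.
#'
#' @param a,b integer vectors of distinct repeat counts (1-5 alleles).
#' @param model a [bruvo_model()].
#' @return Numeric in `[0, 1]`.
#' @export
bruvo_locus_dist <- function(a, b, model = bruvo_model()) {
  if (is.null(a) || is.null(b)) stop("allele sets must not be missing")
  if (length(a) > 5L || length(b) > 5L) stop("allele sets larger than 5")
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) == length(b)) return(.match_min(a, b))
  m <- length(b) - length(a)
  vals <- numeric(0)
  if (model$addition) {
    pads <- .pad_combos(a, m)
    vals <- c(vals, mean(vapply(pads, function(p) .match_min(c(a, p), b),
                                numeric(1))))
  }
  if (model$loss) {
    pads <- .pad_combos(b, m)
    vals <- c(vals, mean(vapply(pads, function(p) .match_min(c(a, p), b),
                                numeric(1))))
  }
  if (model$infinity) {
    # unmatched alleles at distance 1: best injective matching of a into b
    k <- length(b)
    D <- 1 - 2^(-abs(outer(a, b, "-")))
    P <- .perms(k)
    best <- Inf
    for (r in seq_len(nrow(P))) {
      sel <- P[r, seq_along(a)]
      v <- sum(D[cbind(seq_along(a), sel)]) + m
      if (v < best) best <- v
    }
    vals <- c(vals, best / k)
  }
  mean(vals)
}

# per-locus cache: distance matrix among the unique allele sets at locus j
# idx[i] = row of M for isolate i (NA when missing)
.locus_cache <- function(calls, j, model) {
  n <- nrow(calls)
  keys <- vapply(seq_len(n), function(i) .set_key(calls[[i, j]]), character(1))
  called <- keys != "."
  uk <- unique(keys[called])
  sets <- lapply(strsplit(uk, ","), as.integer)
  m <- length(uk)
  M <- matrix(0, m, m)
  if (m > 1L) {
    for (p in seq_len(m - 1L)) {
      for (q in (p + 1L):m) {
        M[p, q] <- M[q, p] <- bruvo_locus_dist(sets[[p]], sets[[q]], model)
      }
    }
  }
  idx <- rep(NA_integer_, n)
  idx[called] <- match(keys[called], uk)
  list(M = M, idx = idx)
}

#' Pairwise Bruvo distance matrix
#'
#' Per pair of isolates the distance is the mean of [bruvo_locus_dist()]
#' over loci where both are called; loci missing on either side are dropped
#' from that pair's mean. A pair sharing no called locus is an error
#' (impute first, see [impute_nearest()]). Computation is done on the
#' unique allele sets per locus and the unique multilocus genotypes, so
#' clonal collections cost far less than their isolate count suggests.
#'
#' @param ds an `msat_dataset`.
#' @param model a [bruvo_model()].
#' @return Symmetric numeric matrix with isolate ids as dimnames, zero
#'   diagonal, entries in `[0, 1]`.
#' @export
bruvo_dist <- function(ds, model = bruvo_model()) {
  stopifnot(inherits(ds, "msat_dataset"))
  n <- nrow(ds$calls)
  L <- ncol(ds$calls)
  caches <- lapply(seq_len(L), function(j) .locus_cache(ds$calls, j, model))
  IDX <- vapply(caches, `[[`, integer(n), "idx")
  if (n == 1L) {
    D <- matrix(0, 1, 1, dimnames = list(rownames(ds$calls), rownames(ds$calls)))
    return(D)
  }
  IDX <- matrix(IDX, nrow = n)
  gkey <- apply(IDX, 1, paste, collapse = "|")
  ug <- unique(gkey)
  gmap <- match(gkey, ug)
  reps <- match(ug, gkey)           # one representative isolate per genotype
  G <- length(ug)
  S <- matrix(0, G, G)
  C <- matrix(0L, G, G)
  for (j in seq_len(L)) {
    idj <- IDX[reps, j]
    ok <- !is.na(idj)
    if (!any(ok)) stop("locus ", colnames(ds$calls)[j], " missing in all isolates")
    Dj <- matrix(NA_real_, G, G)
    Dj[ok, ok] <- caches[[j]]$M[idj[ok], idj[ok], drop = FALSE]
    hit <- !is.na(Dj)
    S[hit] <- S[hit] + Dj[hit]
    C <- C + hit
  }
  if (any(C == 0 & upper.tri(C))) {
    bad <- which(C == 0 & upper.tri(C), arr.ind = TRUE)[1, ]
    stop("isolates ", rownames(ds$calls)[reps[bad[1]]], " and ",
         rownames(ds$calls)[reps[bad[2]]], " share no called locus; impute first")
  }
  Dg <- S / C
  diag(Dg) <- 0
  D <- Dg[gmap, gmap, drop = FALSE]
  dimnames(D) <- list(rownames(ds$calls), rownames(ds$calls))
  D
}

#' Impute missing loci from the nearest neighbour
#'
#' Each missing allele set is replaced by the allele set of the closest
#' isolate (Bruvo distance over mutually called loci) that is called at that
#' locus; ties break by dataset order. The input is not modified. Needed
#' before analyses that require a complete matrix, e.g. classical MDS.
#'
#' @param ds an `msat_dataset`.
#' @param model a [bruvo_model()].
#' @return A new `msat_dataset` with no missing calls.
#' @export
impute_nearest <- function(ds, model = bruvo_model()) {
  stopifnot(inherits(ds, "msat_dataset"))
  miss <- which(vapply(ds$calls, is.null, logical(1)))
  if (!length(miss)) return(ds)
  D <- bruvo_dist(ds, model)
  n <- nrow(ds$calls)
  calls <- ds$calls
  for (j in seq_len(ncol(calls))) {
    holes <- which(vapply(seq_len(n), function(i) is.null(ds$calls[[i, j]]),
                          logical(1)))
    if (!length(holes)) next
    donors <- setdiff(seq_len(n), which(vapply(
      seq_len(n), function(i) is.null(ds$calls[[i, j]]), logical(1))))
    if (!length(donors)) {
      stop("locus ", colnames(calls)[j], " is missing in every isolate")
    }
    for (i in holes) {
      d <- D[i, donors]
      best <- donors[which.min(d)]    # which.min keeps the first = dataset order
      calls[[i, j]] <- ds$calls[[best, j]]
    }
  }
  msat_dataset(calls, ds$loci, ds$meta)
}

#' Write a distance matrix as square CSV or PHYLIP
#'
#' @param D symmetric matrix with ids as dimnames.
#' @param path output file.
#' @param format `"csv"` (header row/column of ids) or `"phylip"` (square).
#' @return Invisibly, `path`.
#' @export
write_dist <- function(D, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(D), path, row.names = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(D)), con)
    for (i in seq_len(nrow(D))) {
      writeLines(paste(formatC(rownames(D)[i], width = -10),
                       paste(sprintf("%.6f", D[i, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}
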