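# Independent oracles, written as literal transcriptions of the
# definitions (plain recursion and loops), deliberately sharing no code
# with the package implementations they check.

oracle_allele <- function(x, y) 1 - 2^(-abs(x - y))

# minimum total allele distance over all perfect matchings (equal sizes)
oracle_assign <- function(a, b) {
  if (length(a) == 0L) return(0)
  best <- Inf
  for (i in seq_along(b)) {
    v <- oracle_allele(a[1], b[i]) + oracle_assign(a[-1], b[-i])
    if (v < best) best <- v
  }
  best
}

# all unordered selections of m elements from pool, with repetition
oracle_selections <- function(pool, m) {
  if (m == 0L) return(list(integer(0)))
  out <- list()
  for (i in seq_along(pool)) {
    for (rest in oracle_selections(pool[i:length(pool)], m - 1L)) {
      out <- c(out, list(c(pool[i], rest)))
    }
  }
  out
}

oracle_locus <- function(a, b, addition = TRUE, loss = TRUE,
                         infinity = FALSE) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  k <- length(b)
  if (length(a) == k) return(oracle_assign(a, b) / k)
  m <- k - length(a)
  branches <- c()
  if (addition) {
    vals <- vapply(oracle_selections(a, m),
                   function(p) oracle_assign(c(a, p), b) / k, numeric(1))
    branches <- c(branches, mean(vals))
  }
  if (loss) {
    vals <- vapply(oracle_selections(b, m),
                   function(p) oracle_assign(c(a, p), b) / k, numeric(1))
    branches <- c(branches, mean(vals))
  }
  if (infinity) {
    # best injective matching of the smaller set; unmatched cost 1 each
    inj <- function(a, b) {
      if (length(a) == 0L) return(0)
      best <- Inf
      for (i in seq_along(b)) {
        v <- oracle_allele(a[1], b[i]) + inj(a[-1], b[-i])
        if (v < best) best <- v
      }
      best
    }
    branches <- c(branches, (inj(a, b) + m) / k)
  }
  mean(branches)
}

# literal distance-AMOVA transcription (double loops)
oracle_amova <- function(D, labels) {
  N <- nrow(D)
  ss_total <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    ss_total <- ss_total + D[i, j]^2
  }
  ss_total <- ss_total / N
  ss_w <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    s <- 0
    for (i in idx) for (j in idx) if (i < j) s <- s + D[i, j]^2
    ss_w <- ss_w + s / length(idx)
  }
  ss_a <- ss_total - ss_w
  G <- length(unique(labels))
  n_g <- as.numeric(table(labels))
  s2w <- ss_w / (N - G)
  n0 <- (N - sum(n_g^2) / N) / (G - 1)
  s2a <- (ss_a / (G - 1) - s2w) / n0
  list(ss_total = ss_total, ss_a = ss_a, ss_w = ss_w,
       s2a = s2a, s2w = s2w,
       pct = 100 * max(s2a, 0) / (max(s2a, 0) + s2w))
}

# random allele set of 1..kmax distinct repeat counts
random_allele_set <- function(kmax = 4L, lo = 5L, hi = 40L) {
  k <- sample.int(kmax, 1L)
  sort(sample(lo:hi, k))
}
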