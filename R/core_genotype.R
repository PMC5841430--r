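#' Alleles statistically associated with polyploid isolates
#'
#' Diploid-triploid complexes defeat most classical population-genetic
#' machinery, so the collection is reduced to its core diploid genotype:
#' alleles carried preferentially by the polyploid class are identified and
#' removed. For every distinct (locus, allele) a 2x2 presence/absence by
#' ploidy-class table is tested with Pearson's chi-square (1 df, no
#' continuity correction); alleles with p below `alpha` *and* a higher
#' carrier frequency in the polyploid class are marked for exclusion
#' (alleles specific to the diploid class are core by definition and
#' kept). The polyploid class contains every isolate showing at least
#' `min_alleles` distinct alleles at one or more loci.
#'
#' @param ds an `msat_dataset`.
#' @param ploidy output of [infer_ploidy()] for `ds`.
#' @param alpha significance threshold (default 0.01).
#' @param min_alleles allele count defining the polyploid class (default 3).
#' @return data.frame with one row per observed (locus, allele): carrier
#'   counts in each class, `chi2`, `p`, `excluded`. Attribute
#'   `"n_polyploid"` records the polyploid class size.
#' @export
triploid_associated_alleles <- function(ds, ploidy = infer_ploidy(ds),
                                        alpha = 0.01, min_alleles = 3L) {
  stopifnot(inherits(ds, "msat_dataset"))
  if (!all(rownames(ds$calls) %in% ploidy$isolate_id)) {
    stop("ploidy calls do not cover all isolates")
  }
  ploidy <- ploidy[match(rownames(ds$calls), ploidy$isolate_id), ]
  poly <- !is.na(ploidy$max_alleles) & ploidy$max_alleles >= min_alleles
  n_poly <- sum(poly)
  n_dip <- sum(!poly)
  if (n_poly == 0L || n_dip == 0L) {
    stop("both ploidy classes must be non-empty (",
         n_poly, " polyploid, ", n_dip, " diploid-class)")
  }
  rows <- list()
  low_expected <- 0L
  for (j in seq_len(ncol(ds$calls))) {
    sets <- lapply(seq_len(nrow(ds$calls)), function(i) ds$calls[[i, j]])
    alleles <- sort(unique(unlist(sets)))
    for (al in alleles) {
      carrier <- vapply(sets, function(s) !is.null(s) && al %in% s, logical(1))
      a <- sum(carrier & poly);  b <- sum(!carrier & poly)
      c_ <- sum(carrier & !poly); d <- sum(!carrier & !poly)
      if (a + c_ == 0L) next                     # carried by nobody
      tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        chi2 <- 0; p <- 1
      } else {
        if (any(outer(rowSums(tab), colSums(tab)) / sum(tab) < 5)) {
          low_expected <- low_expected + 1L
        }
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        chi2 <- unname(ct$statistic); p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus = colnames(ds$calls)[j], allele = al,
        carriers_poly = a, noncarriers_poly = b,
        carriers_dip = c_, noncarriers_dip = d,
        chi2 = chi2, p = p,
        excluded = is.finite(p) && p < alpha &&
          a / max(n_poly, 1L) > c_ / max(n_dip, 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (low_expected > 0L) {
    message(low_expected, " chi-square table(s) with expected counts < 5; ",
            "chi-square approximation retained")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_polyploid") <- n_poly
  out
}

#' Build the core diploid dataset
#'
#' Removes the excluded (polyploid-associated) alleles from every call.
#' Calls left empty become missing; calls still holding more than 2 alleles
#' after removal also become missing -- the residual polyploid signal is
#' treated as unscorable rather than forced into a diploid genotype.
#'
#' @param ds an `msat_dataset`.
#' @param assoc output of [triploid_associated_alleles()], or any
#'   data.frame with columns `locus`, `allele`, `excluded`.
#' @return A new `msat_dataset` in which no call exceeds 2 alleles.
#' @export
build_core_dataset <- function(ds, assoc) {
  stopifnot(inherits(ds, "msat_dataset"),
            all(c("locus", "allele", "excluded") %in% names(assoc)))
  drop <- assoc[assoc$excluded, c("locus", "allele")]
  calls <- ds$calls
  for (j in seq_len(ncol(calls))) {
    bad <- drop$allele[drop$locus == colnames(calls)[j]]
    for (i in seq_len(nrow(calls))) {
      a <- calls[[i, j]]
      if (is.null(a)) next
      a <- setdiff(a, bad)
      calls[i, j] <- if (length(a) == 0L || length(a) > 2L) list(NULL) else list(a)
    }
  }
  msat_dataset(calls, ds$loci, ds$meta)
}
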