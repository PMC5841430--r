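#' Microsatellite dataset for mixed-ploidy collections
#'
#' An `msat_dataset` holds allele calls for a collection of isolates typed at
#' a panel of microsatellite loci, together with per-locus definitions and
#' per-isolate metadata. Alleles are stored as repeat counts (integers), not
#' fragment sizes; a call at one locus is the *set* of distinct alleles
#' observed there, so diploids show 1-2 alleles and triploids up to 3.
#' A missing call is `NULL`.
#'
#' @param calls list-matrix (isolates x loci); each cell a sorted integer
#'   vector of distinct repeat counts, or `NULL` for a missing call.
#'   Row names are isolate ids, column names locus names.
#' @param loci data.frame with columns `name`, `repeat_unit_bp`, `offset_bp`.
#' @param meta data.frame with column `isolate_id` plus optional `country`,
#'   `substrate`, `group`, `lat`, `lon`. Row order must match `calls`.
#' @return An object of class `msat_dataset`.
#' @export
msat_dataset <- function(calls, loci, meta) {
  stopifnot(is.matrix(calls), is.list(calls))
  stopifnot(is.data.frame(loci), all(c("name", "repeat_unit_bp", "offset_bp") %in% names(loci)))
  stopifnot(is.data.frame(meta), "isolate_id" %in% names(meta))
  if (nrow(calls) != nrow(meta)) {
    stop("calls has ", nrow(calls), " rows but meta describes ", nrow(meta), " isolates")
  }
  if (ncol(calls) != nrow(loci)) {
    stop("calls has ", ncol(calls), " columns but loci defines ", nrow(loci), " loci")
  }
  if (anyDuplicated(meta$isolate_id)) {
    stop("duplicated isolate ids: ",
         paste(unique(meta$isolate_id[duplicated(meta$isolate_id)]), collapse = ", "))
  }
  if (any(loci$repeat_unit_bp < 1)) stop("repeat_unit_bp must be >= 1")
  if (any(loci$offset_bp < 0)) stop("offset_bp must be >= 0")
  rownames(calls) <- as.character(meta$isolate_id)
  colnames(calls) <- as.character(loci$name)
  for (j in seq_len(ncol(calls))) {
    for (i in seq_len(nrow(calls))) {
      a <- calls[[i, j]]
      if (is.null(a)) next
      if (!is.numeric(a) || any(a != round(a)) || any(a < 0)) {
        stop("invalid allele set for isolate ", rownames(calls)[i],
             " at locus ", colnames(calls)[j])
      }
      if (length(a) > 5L) {
        stop("more than 5 alleles for isolate ", rownames(calls)[i],
             " at locus ", colnames(calls)[j])
      }
      calls[[i, j]] <- sort(unique(as.integer(a)))
    }
  }
  structure(list(calls = calls, loci = loci, meta = meta),
            class = "msat_dataset")
}

#' @export
print.msat_dataset <- function(x, ...) {
  n_missing <- sum(vapply(x$calls, is.null, logical(1)))
  cat("msat_dataset:", nrow(x$calls), "isolates x", ncol(x$calls), "loci\n")
  cat("  missing calls:", n_missing,
      sprintf("(%.1f%%)", 100 * n_missing / length(x$calls)), "\n")
  if (!is.null(x$meta$group)) {
    cat("  groups:", paste(names(table(x$meta$group)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.msat_dataset <- function(x) dim(x$calls)

#' Subset an msat_dataset by isolates and/or loci
#'
#' @param x an `msat_dataset`.
#' @param isolates character or integer index of isolates to keep.
#' @param loci character or integer index of loci to keep.
#' @return A new `msat_dataset`.
#' @export
subset_dataset <- function(x, isolates = NULL, loci = NULL) {
  stopifnot(inherits(x, "msat_dataset"))
  ii <- if (is.null(isolates)) seq_len(nrow(x$calls)) else isolates
  jj <- if (is.null(loci)) seq_len(ncol(x$calls)) else loci
  if (is.character(ii)) ii <- match(ii, rownames(x$calls))
  if (is.character(jj)) jj <- match(jj, colnames(x$calls))
  if (anyNA(ii)) stop("unknown isolate id(s)")
  if (anyNA(jj)) stop("unknown locus name(s)")
  msat_dataset(x$calls[ii, jj, drop = FALSE],
               x$loci[jj, , drop = FALSE],
               x$meta[ii, , drop = FALSE])
}

# canonical string key for one allele set ("" never occurs; NULL -> ".")
.set_key <- function(a) if (is.null(a)) "." else paste(a, collapse = ",")

# canonical multilocus genotype key for row i
.genotype_key <- function(calls, i) {
  paste(vapply(seq_len(ncol(calls)), function(j) .set_key(calls[[i, j]]),
               character(1)), collapse = "|")
}
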