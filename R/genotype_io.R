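#' Read a mixed-ploidy microsatellite dataset from delimited files
#'
#' Parses three tables: an allele table (one row per isolate, one column per
#' locus, cells holding semicolon-separated fragment sizes in bp, blank for
#' missing), a locus-definition table (`name`, `repeat_unit_bp`, `offset_bp`)
#' and an isolate metadata table (`isolate_id`, `country`, `substrate`,
#' optional `group`, `lat`, `lon`). Fragment sizes are converted to repeat
#' counts with `round((size - offset_bp) / repeat_unit_bp)`; sizes more than
#' 0.34 repeat units off the motif grid trigger a warning (fragment calls
#' drift by a base pair or so between runs), negative repeat counts are
#' rejected. Duplicate sizes within a cell collapse to one allele.
#'
#' @param allele_file path to the allele table (CSV/TSV; delimiter sniffed).
#' @param locus_file path to the locus table.
#' @param meta_file path to the metadata table.
#' @param id_col name of the isolate-id column in the allele table.
#' @return An [msat_dataset()].
#' @export
read_genotypes <- function(allele_file, locus_file, meta_file,
                           id_col = "isolate_id") {
  loci <- .read_delim(locus_file)
  need <- c("name", "repeat_unit_bp", "offset_bp")
  if (!all(need %in% names(loci))) {
    stop("locus table must have columns: ", paste(need, collapse = ", "))
  }
  meta <- .read_delim(meta_file)
  if (!"isolate_id" %in% names(meta)) stop("meta table must have isolate_id")
  alle <- .read_delim(allele_file, as_char = TRUE)
  if (!id_col %in% names(alle)) {
    stop("allele table lacks id column '", id_col, "'")
  }
  locus_cols <- setdiff(names(alle), id_col)
  unknown <- setdiff(locus_cols, loci$name)
  if (length(unknown)) {
    stop("allele table columns not in locus table: ",
         paste(unknown, collapse = ", "))
  }
  absent <- setdiff(loci$name, locus_cols)
  if (length(absent)) {
    stop("loci defined but absent from allele table: ",
         paste(absent, collapse = ", "))
  }
  ids <- as.character(alle[[id_col]])
  missing_meta <- setdiff(ids, as.character(meta$isolate_id))
  if (length(missing_meta)) {
    stop("isolates without metadata: ",
         paste(utils::head(missing_meta, 5), collapse = ", "))
  }
  meta <- meta[match(ids, as.character(meta$isolate_id)), , drop = FALSE]
  rownames(meta) <- NULL
  loci <- loci[match(locus_cols, loci$name), , drop = FALSE]
  rownames(loci) <- NULL

  calls <- matrix(vector("list", length(ids) * nrow(loci)),
                  nrow = length(ids), ncol = nrow(loci))
  off_grid <- 0L
  for (j in seq_len(nrow(loci))) {
    unit <- loci$repeat_unit_bp[j]
    offset <- loci$offset_bp[j]
    cells <- alle[[locus_cols[j]]]
    for (i in seq_along(ids)) {
      cell <- cells[i]
      if (is.na(cell) || !nzchar(trimws(cell))) next
      sizes <- suppressWarnings(as.numeric(strsplit(trimws(cell), ";")[[1]]))
      if (anyNA(sizes)) {
        stop("unparseable allele cell '", cell, "' for isolate ", ids[i],
             " at locus ", locus_cols[j])
      }
      exact <- (sizes - offset) / unit
      reps <- round(exact)
      if (any(abs(exact - reps) > 0.34)) off_grid <- off_grid + 1L
      if (any(reps < 0)) {
        stop("negative repeat count for isolate ", ids[i], " at locus ",
             locus_cols[j], " (size ", paste(sizes, collapse = ";"),
             ", offset ", offset, ")")
      }
      calls[[i, j]] <- sort(unique(as.integer(reps)))
    }
  }
  if (off_grid > 0L) {
    warning(off_grid, " allele cell(s) deviate >0.34 repeat units from the ",
            "motif grid; rounded to the nearest repeat count")
  }
  msat_dataset(calls, loci, meta)
}

.read_delim <- function(path, as_char = FALSE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = if (as_char) "character" else NA,
                    check.names = FALSE, quote = "\"", comment.char = "")
}

#' Write a dataset as delimited text
#'
#' Emits the same dialect [read_genotypes()] consumes: an allele table in bp
#' (cells `"a;b"`, blank = missing), the locus table and the metadata table.
#'
#' @param ds an `msat_dataset`.
#' @param allele_file,locus_file,meta_file output paths.
#' @return Invisibly, `ds`.
#' @export
write_genotypes <- function(ds, allele_file, locus_file, meta_file) {
  stopifnot(inherits(ds, "msat_dataset"))
  n <- nrow(ds$calls)
  out <- data.frame(isolate_id = rownames(ds$calls), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(ds$calls))) {
    unit <- ds$loci$repeat_unit_bp[j]
    offset <- ds$loci$offset_bp[j]
    out[[colnames(ds$calls)[j]]] <- vapply(seq_len(n), function(i) {
      a <- ds$calls[[i, j]]
      if (is.null(a)) "" else paste(a * unit + offset, collapse = ";")
    }, character(1))
  }
  utils::write.csv(out, allele_file, row.names = FALSE)
  utils::write.csv(ds$loci, locus_file, row.names = FALSE)
  utils::write.csv(ds$meta, meta_file, row.names = FALSE)
  invisible(ds)
}

#' Infer ploidy class from maximum allele counts
#'
#' The maximum number of distinct alleles observed at any locus classifies an
#' isolate: up to 2 alleles per locus is called diploid (2n), up to 3
#' triploid (3n), and 4 or 5 tetra-/pentaploid (4n/5n). The number of loci
#' with 3 or more alleles is recorded as well, separating triploids with
#' one or two such loci from those with more. Missing loci are ignored;
#' an isolate missing every locus gets an `NA` class and is flagged.
#'
#' @param ds an `msat_dataset`.
#' @return data.frame with columns `isolate_id`, `max_alleles`,
#'   `n_loci_ge3`, `klass` (factor `2n`/`3n`/`4n/5n`), `all_missing`.
#' @export
infer_ploidy <- function(ds) {
  stopifnot(inherits(ds, "msat_dataset"))
  n <- nrow(ds$calls)
  if (n == 0L) stop("empty dataset")
  counts <- matrix(NA_integer_, n, ncol(ds$calls))
  for (j in seq_len(ncol(ds$calls))) {
    counts[, j] <- vapply(seq_len(n), function(i) {
      a <- ds$calls[[i, j]]
      if (is.null(a)) NA_integer_ else length(a)
    }, integer(1))
  }
  max_alleles <- apply(counts, 1, function(r) {
    if (all(is.na(r))) NA_integer_ else max(r, na.rm = TRUE)
  })
  n_ge3 <- apply(counts, 1, function(r) sum(r >= 3L, na.rm = TRUE))
  klass <- rep(NA_character_, n)
  klass[!is.na(max_alleles) & max_alleles <= 2L] <- "2n"
  klass[!is.na(max_alleles) & max_alleles == 3L] <- "3n"
  klass[!is.na(max_alleles) & max_alleles >= 4L] <- "4n/5n"
  res <- data.frame(
    isolate_id = rownames(ds$calls),
    max_alleles = max_alleles,
    n_loci_ge3 = n_ge3,
    klass = factor(klass, levels = c("2n", "3n", "4n/5n")),
    all_missing = is.na(max_alleles),
    stringsAsFactors = FALSE
  )
  if (any(res$all_missing)) {
    warning(sum(res$all_missing), " isolate(s) missing at every locus; ",
            "ploidy class undefined")
  }
  res
}

#' Collapse clonal isolates to unique multilocus genotypes
#'
#' Two isolates share a genotype iff their allele sets are identical at every
#' locus, including missing status (a missing call never matches a called
#' one). Clonal collections therefore reduce to far fewer genotypes than
#' isolates.
#'
#' @param ds an `msat_dataset`.
#' @return data.frame with one row per genotype: `genotype_id`,
#'   `multiplicity`, `representative` (first isolate id in dataset order)
#'   and `isolates` (`;`-separated member ids). Multiplicities sum to the
#'   isolate count.
#' @export
collapse_clones <- function(ds) {
  stopifnot(inherits(ds, "msat_dataset"))
  n <- nrow(ds$calls)
  keys <- vapply(seq_len(n), function(i) .genotype_key(ds$calls, i),
                 character(1))
  first <- !duplicated(keys)
  uniq <- keys[first]
  idx <- match(keys, uniq)
  members <- split(rownames(ds$calls), idx)
  data.frame(
    genotype_id = sprintf("MLG%03d", seq_along(uniq)),
    multiplicity = as.integer(lengths(members)),
    representative = vapply(members, `[[`, character(1), 1L),
    isolates = vapply(members, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
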