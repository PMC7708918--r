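# Genotype table: accessions x markers matrix of canonical co-dominant calls
# plus accession metadata. The central container of the package.

METADATA_COLUMNS <- c("accession_id", "name", "species", "ploidy",
                      "parent1", "parent2", "lineage_group")

#' Construct a genotype table
#'
#' @param calls character matrix (accessions x markers) of genotype cells in
#'   any accepted spelling ("a/b", "b/a", single allele, "-"/NA missing);
#'   cells are canonicalized. Row names, if present, must match
#'   `accessions$accession_id`.
#' @param accessions data.frame of accession metadata with at least
#'   `accession_id`; recognised columns are `name`, `species`, `ploidy`
#'   (default 2), `parent1`, `parent2`, `lineage_group`. Parents are free-text
#'   names or NA/"Unknown".
#' @param marker_info optional data.frame with columns `marker_id` and any of
#'   `chrom`, `pos`, `size_I`, `size_D` used by exports and validation.
#' @return an object of class `genotype_table` with elements `calls`
#'   (canonical character matrix), `accessions`, `markers`, `marker_info`.
#' @export
genotype_table <- function(calls, accessions, marker_info = NULL) {
  calls <- as.matrix(calls)
  if (is.null(colnames(calls))) stop("`calls` must have marker column names")
  accessions <- as.data.frame(accessions, stringsAsFactors = FALSE)
  if (!"accession_id" %in% names(accessions))
    stop("`accessions` must contain an `accession_id` column")
  accessions$accession_id <- as.character(accessions$accession_id)
  if (anyDuplicated(accessions$accession_id))
    stop("accession_ids must be unique")
  if (anyDuplicated(colnames(calls)))
    stop("marker_ids must be unique")
  if (nrow(calls) != nrow(accessions))
    stop("`calls` and `accessions` disagree on the number of accessions")
  for (col in c("name", "species", "parent1", "parent2", "lineage_group"))
    if (!col %in% names(accessions)) accessions[[col]] <- NA_character_
  if (!"ploidy" %in% names(accessions)) accessions$ploidy <- 2L
  accessions$ploidy <- as.integer(accessions$ploidy)
  if (any(is.na(accessions$ploidy)) || any(accessions$ploidy < 2L))
    stop("ploidy must be an integer >= 2")
  if (is.null(accessions$name) || all(is.na(accessions$name)))
    accessions$name <- accessions$accession_id
  canon <- matrix(
    canonicalize_calls(calls, rep(accessions$ploidy, times = ncol(calls))),
    nrow = nrow(calls), ncol = ncol(calls),
    dimnames = list(accessions$accession_id, colnames(calls)))
  bad <- which(!vapply(calls_allele_list(canon),
                       function(a) length(a) == 0L || valid_allele_labels(a),
                       logical(1)))
  if (length(bad)) {
    i <- bad[1L]
    stop(sprintf(
      "non-numeric allele where a fragment size or I/D was expected in cell [%s, %s]: \"%s\"",
      rownames(canon)[(i - 1L) %% nrow(canon) + 1L],
      colnames(canon)[(i - 1L) %/% nrow(canon) + 1L],
      canon[i]))
  }
  # polyploids carry <= 2 recorded alleles with unknown dosage
  accessions$dosage_unknown <- accessions$ploidy > 2L
  structure(list(calls = canon, accessions = accessions,
                 markers = colnames(canon), marker_info = marker_info),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d accessions x %d markers\n",
              nrow(x$calls), ncol(x$calls)))
  sp <- table(x$accessions$species, useNA = "ifany")
  if (length(sp) > 1L || !is.na(names(sp)[1L]))
    cat("  populations:", paste(sprintf("%s (%d)", names(sp), sp),
                                collapse = ", "), "\n")
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$calls))))
  n_poly <- sum(x$accessions$ploidy > 2L)
  if (n_poly) cat(sprintf("  polyploid accessions (dosage unknown): %d\n", n_poly))
  invisible(x)
}

#' @export
summary.genotype_table <- function(object, ...) {
  print(object)
  nall <- apply(object$calls, 2L, function(col)
    length(unique(unlist(calls_allele_list(col)))))
  cat(sprintf("  alleles per marker: min %d, median %s, max %d\n",
              min(nall), format(stats::median(nall)), max(nall)))
  invisible(list(n_alleles = nall))
}

#' Subset a genotype table by accession and/or marker
#' @param x a `genotype_table`.
#' @param i accession ids (character) or indices.
#' @param j marker ids or indices.
#' @param ... unused.
#' @export
`[.genotype_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(i)) i <- match(i, rownames(x$calls))
  if (anyNA(i)) stop("unknown accession id in subset")
  calls <- x$calls[i, j, drop = FALSE]
  mi <- x$marker_info
  if (!is.null(mi)) mi <- mi[mi$marker_id %in% colnames(calls), , drop = FALSE]
  structure(list(calls = calls, accessions = x$accessions[i, , drop = FALSE],
                 markers = colnames(calls), marker_info = mi),
            class = "genotype_table")
}

#' Read a genotype table from CSV/TSV
#'
#' Expected layout: a header row naming the metadata columns (at minimum
#' `accession_id`; optionally `name`, `species`, `ploidy`, `parent1`,
#' `parent2`, `lineage_group`) followed by one column per marker. Genotype
#' cells are "a/b", a single "a" (homozygote shorthand) or "-" (missing).
#' The delimiter is sniffed from the header when `sep = NULL`.
#'
#' @param path file path.
#' @param sep field delimiter, or NULL to auto-detect ("," vs tab).
#' @return a [genotype_table()].
#' @export
read_genotype_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(sep))
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
               lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))) "\t" else ","
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged row in %s: line %d has %d fields, header has %d",
                 path, bad, nf[bad], nf[1L]))
  }
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  meta_cols <- intersect(names(df), METADATA_COLUMNS)
  if (!"accession_id" %in% meta_cols)
    stop("genotype table must have an `accession_id` column")
  marker_cols <- setdiff(names(df), METADATA_COLUMNS)
  if (length(marker_cols) == 0L) stop("no marker columns found")
  meta <- df[, meta_cols, drop = FALSE]
  if ("ploidy" %in% names(meta)) meta$ploidy <- as.integer(meta$ploidy)
  for (col in c("parent1", "parent2", "lineage_group", "species", "name"))
    if (col %in% names(meta))
      meta[[col]][meta[[col]] %in% c("", "NA", "Unknown", "unknown")] <- NA_character_
  genotype_table(as.matrix(df[, marker_cols, drop = FALSE]), meta)
}

#' Write a genotype table to CSV/TSV
#' @param table a `genotype_table`.
#' @param path output path.
#' @param sep delimiter (default tab).
#' @export
write_genotype_table <- function(table, path, sep = "\t") {
  meta <- table$accessions[, intersect(METADATA_COLUMNS, names(table$accessions)),
                           drop = FALSE]
  calls <- table$calls
  calls[is.na(calls)] <- "-"
  df <- cbind(meta, as.data.frame(calls, stringsAsFactors = FALSE,
                                  check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Validate a genotype table
#'
#' Returns findings rather than raising: diploid calls with more than two
#' distinct alleles, alleles outside a marker's declared size set (when
#' `marker_info` carries `size_I`/`size_D`), monomorphic markers, and the
#' per-marker missing rate.
#'
#' @param table a `genotype_table`.
#' @return data.frame with columns `finding`, `accession_id`, `marker`,
#'   `detail` (one row per finding; missing-rate rows have finding
#'   `"missing_rate"` and the rate in `detail`).
#' @export
validate_table <- function(table) {
  findings <- list()
  add <- function(finding, accession_id = NA, marker = NA, detail = "") {
    findings[[length(findings) + 1L]] <<- data.frame(
      finding = finding, accession_id = accession_id, marker = marker,
      detail = as.character(detail), stringsAsFactors = FALSE)
  }
  alleles <- calls_allele_list(table$calls)
  dim(alleles) <- dim(table$calls)
  diploid <- table$accessions$ploidy == 2L
  for (j in seq_along(table$markers)) {
    col <- alleles[, j]
    n_distinct <- vapply(col, function(a) length(unique(a)), integer(1))
    bad <- which(diploid & n_distinct > 2L)
    for (i in bad)
      add("excess_alleles_diploid", table$accessions$accession_id[i],
          table$markers[j], table$calls[i, j])
    observed <- unique(unlist(col))
    if (length(observed) == 1L)
      add("monomorphic_marker", marker = table$markers[j], detail = observed)
    mi <- table$marker_info
    if (!is.null(mi) && all(c("size_I", "size_D") %in% names(mi))) {
      row <- mi[mi$marker_id == table$markers[j], , drop = FALSE]
      if (nrow(row) == 1L && !anyNA(c(row$size_I, row$size_D))) {
        declared <- as.character(c(row$size_I, row$size_D))
        off <- setdiff(observed, c(declared, "I", "D"))
        for (al in off)
          add("allele_outside_declared_set", marker = table$markers[j],
              detail = al)
      }
    }
    miss <- mean(is.na(table$calls[, j]))
    if (miss > 0)
      add("missing_rate", marker = table$markers[j],
          detail = format(miss, digits = 4))
  }
  if (length(findings) == 0L)
    return(data.frame(finding = character(0), accession_id = character(0),
                      marker = character(0), detail = character(0)))
  do.call(rbind, findings)
}
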