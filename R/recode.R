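# Biallelic I/D recoding and interoperability exports (PLINK, STRUCTURE,
# GenAlEx). Fragment-length alleles map to I (larger product, insertion
# allele) and D (smaller product, deletion allele).

#' Recode a genotype table to biallelic I/D coding
#'
#' A marker is biallelic iff exactly two distinct alleles are observed among
#' the chosen accessions; the larger fragment maps to `I`, the smaller to
#' `D`. Markers with three or more observed alleles are excluded and listed;
#' markers with a single observed allele are retained as monomorphic (coded
#' `D`) and flagged.
#'
#' @param table a [genotype_table()].
#' @param accessions optional character vector of accession ids defining the
#'   subpopulation over which allele counts are assessed (default: all).
#' @return list of class `biallelic_recode`: `table` (coded genotype_table
#'   restricted to biallelic + monomorphic markers), `biallelic_markers`,
#'   `monomorphic_markers`, `excluded_markers` (>= 3 alleles),
#'   `allele_map` (marker, size_I, size_D).
#' @export
recode_biallelic <- function(table, accessions = NULL) {
  sub <- if (is.null(accessions)) table else table[accessions, ]
  obs <- lapply(seq_along(table$markers), function(j)
    sort(unique(unlist(calls_allele_list(sub$calls[, j])))))
  n_obs <- lengths(obs)
  biallelic <- table$markers[n_obs == 2L]
  monomorphic <- table$markers[n_obs == 1L]
  excluded <- table$markers[n_obs >= 3L]
  keep <- table$markers[n_obs %in% c(1L, 2L)]
  maps <- list()
  coded <- table$calls[, keep, drop = FALSE]
  for (m in keep) {
    al <- obs[[match(m, table$markers)]]
    if (identical(sort(al), c("D", "I")) || identical(al, "I") ||
        identical(al, "D")) {
      map <- stats::setNames(al, al)
    } else {
      num <- as.numeric(al)
      if (anyNA(num))
        stop("marker ", m, " mixes numeric and symbolic alleles")
      map <- if (length(al) == 2L)
        stats::setNames(c("D", "I"), al[order(num)])
      else stats::setNames("D", al)
    }
    col <- coded[, m]
    ok <- !is.na(col)
    coded[ok, m] <- vapply(strsplit(col[ok], "/", fixed = TRUE), function(a) {
      a2 <- unname(map[a])
      if (anyNA(a2)) return(NA_character_)  # allele unseen in subpopulation
      paste(sort(a2), collapse = "/")
    }, character(1))
    size_I <- if ("I" %in% map) names(map)[map == "I"] else NA_character_
    size_D <- if ("D" %in% map) names(map)[map == "D"] else NA_character_
    maps[[m]] <- data.frame(marker = m, size_I = size_I, size_D = size_D,
                            stringsAsFactors = FALSE)
  }
  coded_table <- genotype_table(coded, table$accessions,
                                marker_info = table$marker_info)
  structure(list(table = coded_table,
                 biallelic_markers = biallelic,
                 monomorphic_markers = monomorphic,
                 excluded_markers = excluded,
                 allele_map = do.call(rbind, c(maps, list(make.row.names = FALSE)))),
            class = "biallelic_recode")
}

#' @export
print.biallelic_recode <- function(x, ...) {
  cat(sprintf("biallelic recode: %d biallelic, %d monomorphic (flagged), %d excluded (>=3 alleles)\n",
              length(x$biallelic_markers), length(x$monomorphic_markers),
              length(x$excluded_markers)))
  invisible(x)
}

#' Restore fragment sizes on an I/D-coded table
#'
#' Inverse of [recode_biallelic()] on biallelic markers (identity round trip).
#' @param recode a `biallelic_recode` object.
#' @return a `genotype_table` with fragment-size alleles.
#' @export
restore_sizes <- function(recode) {
  tab <- recode$table
  calls <- tab$calls
  for (m in recode$biallelic_markers) {
    row <- recode$allele_map[recode$allele_map$marker == m, ]
    back <- stats::setNames(c(row$size_I, row$size_D), c("I", "D"))
    col <- calls[, m]
    ok <- !is.na(col)
    calls[ok, m] <- vapply(strsplit(col[ok], "/", fixed = TRUE), function(a)
      paste(back[a][order(as.numeric(back[a]))], collapse = "/"), character(1))
  }
  genotype_table(calls, tab$accessions, marker_info = tab$marker_info)
}

# Integer genotype codes for an I/D-coded table: count of I alleles per cell
# (0 = D/D, 1 = I/D, 2 = I/I), NA missing. Fast path for popgen.
genotype_codes <- function(coded_table) {
  calls <- if (inherits(coded_table, "biallelic_recode"))
    coded_table$table$calls else coded_table$calls
  codes <- matrix(NA_integer_, nrow(calls), ncol(calls),
                  dimnames = dimnames(calls))
  codes[calls == "D/D"] <- 0L
  codes[calls == "I/D" | calls == "D/I"] <- 1L
  codes[calls == "I/I"] <- 2L
  if (any(is.na(codes) & !is.na(calls)))
    stop("table is not I/D coded; run recode_biallelic() first")
  codes
}

#' Export a coded genotype table as PLINK PED/MAP
#'
#' Biallelic markers only; I maps to allele 1, D to allele 2, missing to
#' "0 0". Monomorphic or multiallelic markers are excluded with a warning.
#'
#' @param recode a `biallelic_recode` object.
#' @param prefix output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @return invisibly, the two paths written.
#' @export
export_plink <- function(recode, prefix) {
  keep <- recode$biallelic_markers
  drop <- setdiff(recode$table$markers, keep)
  if (length(drop))
    warning("excluding ", length(drop),
            " non-biallelic marker(s) from PLINK export")
  codes <- genotype_codes(recode)[, keep, drop = FALSE]
  acc <- recode$table$accessions
  a1 <- matrix("0", nrow(codes), ncol(codes))
  a2 <- a1
  a1[codes == 2L] <- "1"; a2[codes == 2L] <- "1"
  a1[codes == 1L] <- "1"; a2[codes == 1L] <- "2"
  a1[codes == 0L] <- "2"; a2[codes == 0L] <- "2"
  geno <- matrix("", nrow(codes), 2L * ncol(codes))
  geno[, seq(1L, 2L * ncol(codes), by = 2L)] <- a1
  geno[, seq(2L, 2L * ncol(codes), by = 2L)] <- a2
  ped <- cbind(acc$accession_id, acc$accession_id, "0", "0", "0", "-9", geno)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  utils::write.table(ped, ped_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  mi <- recode$table$marker_info
  chrom <- rep("0", length(keep)); pos <- rep(0L, length(keep))
  if (!is.null(mi) && all(c("chrom", "pos") %in% names(mi))) {
    idx <- match(keep, mi$marker_id)
    chrom <- ifelse(is.na(idx), "0", as.character(mi$chrom[idx]))
    pos <- ifelse(is.na(idx), 0L, mi$pos[idx])
  }
  utils::write.table(data.frame(chrom, keep, 0L, pos), map_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(ped_path, map_path))
}

#' Export a coded genotype table in STRUCTURE format
#'
#' Two rows per individual, one column per marker; alleles coded 1 (I) and
#' 2 (D); missing is -9. A header row carries the marker names.
#'
#' @param recode a `biallelic_recode` object.
#' @param path output path.
#' @param grouping metadata column used as the population column
#'   (default "species"); populations are written as integer codes.
#' @return invisibly, `path`.
#' @export
export_structure <- function(recode, path, grouping = "species") {
  keep <- recode$biallelic_markers
  codes <- genotype_codes(recode)[, keep, drop = FALSE]
  acc <- recode$table$accessions
  pop <- as.integer(factor(acc[[grouping]]))
  pop[is.na(pop)] <- 0L
  a1 <- ifelse(is.na(codes), -9L, ifelse(codes >= 1L, 1L, 2L))
  a2 <- ifelse(is.na(codes), -9L, ifelse(codes == 2L, 1L, 2L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(keep, collapse = "\t"), con)
  for (i in seq_len(nrow(codes))) {
    writeLines(paste(c(acc$accession_id[i], pop[i], a1[i, ]), collapse = "\t"), con)
    writeLines(paste(c(acc$accession_id[i], pop[i], a2[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Export a genotype table as a GenAlEx-style codominant CSV
#'
#' Standard GenAlEx layout: two title rows (counts, then population sizes),
#' a header row, then one row per accession with two columns per marker
#' (numeric allele labels, 0 = missing).
#'
#' @param table a `genotype_table` (fragment sizes or I/D coding; I/D are
#'   written as 1/2).
#' @param path output CSV path.
#' @param grouping metadata column naming populations (default "species").
#' @return invisibly, `path`.
#' @export
export_genalex <- function(table, path, grouping = "species") {
  acc <- table$accessions
  pop <- acc[[grouping]]
  pop[is.na(pop)] <- "unassigned"
  pops <- unique(pop)
  L <- length(table$markers)
  n <- nrow(table$calls)
  al <- calls_allele_list(table$calls)
  dim(al) <- dim(table$calls)
  num <- function(a) {
    a[a == "I"] <- "1"; a[a == "D"] <- "2"
    a
  }
  rows <- t(vapply(seq_len(n), function(i) {
    unlist(lapply(seq_len(L), function(j) {
      a <- num(al[i, j][[1]])
      if (length(a) == 0L) c("0", "0") else c(a[1L], a[length(a)])
    }))
  }, character(2L * L)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(L, n, length(pops), table(factor(pop, levels = pops))),
                   collapse = ","), con)
  writeLines(paste(c("", "", "", pops), collapse = ","), con)
  hdr <- c("accession_id", "pop",
           as.vector(rbind(table$markers, rep("", L))))
  writeLines(paste(hdr, collapse = ","), con)
  for (i in seq_len(n))
    writeLines(paste(c(acc$accession_id[i], pop[i], rows[i, ]),
                     collapse = ","), con)
  invisible(path)
}
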