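# Canonical handling of co-dominant fragment-length genotype calls.
#
# A call is stored as a single string "a/b" with the alleles sorted
# (numerically when all alleles are numeric, otherwise lexicographically),
# or NA for a missing call. Allele order within a cell is never significant.

#' Canonicalize genotype call strings
#'
#' Parses raw genotype cells ("248/236", "236", "I/D", "-", "") into the
#' canonical sorted form used throughout the package. A single allele is
#' expanded to a homozygote for diploids (capillary chromatograms report one
#' peak for homozygotes); "-", "" and NA are missing.
#'
#' @param x character vector of raw cells.
#' @param ploidy integer vector (recycled); alleles beyond 2 are kept as-is
#'   but a diploid single allele is duplicated.
#' @return character vector of canonical calls; NA for missing.
#' @keywords internal
canonicalize_calls <- function(x, ploidy = 2L) {
  x <- as.character(x)
  ploidy <- rep_len(as.integer(ploidy), length(x))
  out <- rep(NA_character_, length(x))
  nonmiss <- !is.na(x) & !(trimws(x) %in% c("", "-", "./.", ".", "?"))
  if (!any(nonmiss)) return(out)
  # memoize over distinct (cell, ploidy) pairs: tables carry few distinct cells
  key <- paste(x[nonmiss], ploidy[nonmiss])
  uniq <- !duplicated(key)
  canon1 <- function(cell, pl) {
    al <- trimws(strsplit(trimws(cell), "[/|]")[[1]])
    al <- al[al != ""]
    if (length(al) == 0L) return(NA_character_)
    if (length(al) == 1L && pl == 2L) al <- rep(al, 2L)
    num <- suppressWarnings(as.numeric(al))
    if (!anyNA(num)) al <- al[order(num)] else al <- sort(al)
    paste(al, collapse = "/")
  }
  mapped <- mapply(canon1, x[nonmiss][uniq], ploidy[nonmiss][uniq],
                   USE.NAMES = FALSE)
  out[nonmiss] <- mapped[match(key, key[uniq])]
  out
}

#' Split a canonical call into its allele multiset
#' @param call canonical call string or NA.
#' @return character vector of alleles (length 0 when missing).
#' @keywords internal
call_alleles <- function(call) {
  if (is.na(call)) return(character(0))
  strsplit(call, "/", fixed = TRUE)[[1]]
}

# Alleles of many calls at once: list of character vectors.
calls_allele_list <- function(calls) {
  out <- vector("list", length(calls))
  ok <- !is.na(calls)
  out[ok] <- strsplit(calls[ok], "/", fixed = TRUE)
  out[!ok] <- list(character(0))
  out
}

# TRUE when the alleles of a call are valid labels: numeric sizes or I/D.
valid_allele_labels <- function(alleles) {
  num <- suppressWarnings(as.numeric(alleles))
  all(!is.na(num) | alleles %in% c("I", "D"))
}
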