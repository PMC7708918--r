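# Mendelian-exclusion parentage analysis for co-dominant markers:
# duo/trio locus compatibility, hypothesis scoring with a confidence and a
# mismatch-threshold rule, and collection-wide candidate scans.

#' Duo compatibility of two calls at one locus
#'
#' Uninformative when either call is missing; compatible iff the two allele
#' multisets share at least one allele.
#'
#' @param offspring_call,parent_call canonical call strings (or NA).
#' @return "compatible", "incompatible" or "uninformative".
#' @export
duo_compatible <- function(offspring_call, parent_call) {
  o <- call_alleles(offspring_call)
  p <- call_alleles(parent_call)
  if (length(o) == 0L || length(p) == 0L) return("uninformative")
  if (any(o %in% p)) "compatible" else "incompatible"
}

#' Trio compatibility of an offspring call with two parent calls
#'
#' Compatible iff the offspring's two alleles admit an assignment of one
#' allele to each parent (in either order); uninformative when any call is
#' missing.
#'
#' @param offspring_call,p1_call,p2_call canonical diploid call strings.
#' @return "compatible", "incompatible" or "uninformative".
#' @export
trio_compatible <- function(offspring_call, p1_call, p2_call) {
  o <- call_alleles(offspring_call)
  p1 <- call_alleles(p1_call)
  p2 <- call_alleles(p2_call)
  if (length(o) == 0L || length(p1) == 0L || length(p2) == 0L)
    return("uninformative")
  ok <- (o[1L] %in% p1 && o[2L] %in% p2) || (o[2L] %in% p1 && o[1L] %in% p2)
  if (ok) "compatible" else "incompatible"
}

#' Evaluate one parentage hypothesis
#'
#' Informative loci are those where the offspring and every named parent are
#' typed. Confidence C is the fraction of informative loci compatible; the
#' hypothesis is accepted iff `C > min_confidence` AND
#' `n_mismatch <= threshold`. With one parent UNKNOWN (or NULL) the duo rule
#' applies.
#'
#' @param table a [genotype_table()].
#' @param offspring,parent1,parent2 accession ids; `parent2` may be NULL or
#'   `"UNKNOWN"` for a duo test.
#' @param min_confidence accept only if confidence strictly exceeds this
#'   (default 0.98).
#' @param threshold maximum allowed mismatching loci (default 1), absorbing
#'   somatic mutations and null alleles.
#' @return list of class `parentage_verdict`: offspring, parent1, parent2,
#'   mode, n_informative, n_compatible, n_mismatch, confidence, accepted
#'   (NA with `undefined = TRUE` when no locus is informative).
#' @export
evaluate_hypothesis <- function(table, offspring, parent1, parent2 = NULL,
                                min_confidence = 0.98, threshold = 1) {
  ids <- table$accessions$accession_id
  if (is.null(parent2) || identical(toupper(parent2), "UNKNOWN"))
    parent2 <- NA_character_
  named <- c(offspring, parent1, if (!is.na(parent2)) parent2)
  missing_ids <- setdiff(named, ids)
  if (length(missing_ids)) stop("unknown accession(s): ",
                                paste(missing_ids, collapse = ", "))
  if (offspring %in% stats::na.omit(c(parent1, parent2)))
    stop("offspring cannot be its own parent")
  o <- table$calls[match(offspring, ids), ]
  p1 <- table$calls[match(parent1, ids), ]
  mode <- if (is.na(parent2)) "duo" else "trio"
  status <- if (mode == "duo") {
    vapply(seq_along(o), function(j) duo_compatible(o[j], p1[j]), character(1))
  } else {
    p2 <- table$calls[match(parent2, ids), ]
    vapply(seq_along(o), function(j) trio_compatible(o[j], p1[j], p2[j]),
           character(1))
  }
  n_inf <- sum(status != "uninformative")
  n_comp <- sum(status == "compatible")
  conf <- if (n_inf > 0L) n_comp / n_inf else NA_real_
  structure(list(offspring = offspring, parent1 = parent1, parent2 = parent2,
                 mode = mode, n_informative = n_inf, n_compatible = n_comp,
                 n_mismatch = n_inf - n_comp, confidence = conf,
                 undefined = n_inf == 0L,
                 accepted = if (n_inf == 0L) NA else
                   (conf > min_confidence && (n_inf - n_comp) <= threshold),
                 min_confidence = min_confidence, threshold = threshold,
                 mismatch_markers = table$markers[status == "incompatible"]),
            class = "parentage_verdict")
}

#' @export
print.parentage_verdict <- function(x, ...) {
  pair <- if (x$mode == "trio") paste(x$parent1, "x", x$parent2) else
    paste(x$parent1, "x UNKNOWN")
  if (x$undefined) {
    cat(sprintf("%s <- %s: verdict undefined (no informative locus)\n",
                x$offspring, pair))
  } else {
    cat(sprintf("%s <- %s: %d/%d loci compatible (C = %.4f, %d mismatch) -> %s\n",
                x$offspring, pair, x$n_compatible, x$n_informative,
                x$confidence, x$n_mismatch,
                if (x$accepted) "ACCEPTED" else "rejected"))
  }
  invisible(x)
}

# Integer allele-id matrices for fast scans: per marker, alleles mapped to
# 1..k; returns list(a1, a2) with NA for missing calls.
allele_id_matrices <- function(table) {
  n <- nrow(table$calls); L <- ncol(table$calls)
  a1 <- matrix(NA_integer_, n, L, dimnames = dimnames(table$calls))
  a2 <- a1
  for (j in seq_len(L)) {
    al <- calls_allele_list(table$calls[, j])
    lev <- sort(unique(unlist(al)))
    typed <- lengths(al) > 0L
    a1[typed, j] <- match(vapply(al[typed], `[`, character(1), 1L), lev)
    a2[typed, j] <- match(vapply(al[typed], `[`, character(1), 2L), lev)
  }
  list(a1 = a1, a2 = a2)
}

#' Scan a collection for compatible parents
#'
#' Evaluates candidate parent pairs (trio mode) or single parents (duo mode)
#' for each focal accession against a candidate pool, after collapsing
#' clones (one representative per identity group) so that signature-identical
#' accessions are not reported as interchangeable parents. Accepted
#' hypotheses are ranked by mismatches ascending, confidence descending,
#' then lexicographic ids. Documented parents present in the table are
#' evaluated and reported alongside.
#'
#' @param table a `genotype_table`.
#' @param focal accession ids to scan (default: accessions with at least one
#'   documented parent).
#' @param pool candidate parent ids (default: all accessions); the focal
#'   accession and its clones are excluded per scan.
#' @param mode "trio" (default) or "duo".
#' @param min_confidence,threshold acceptance rule, see
#'   [evaluate_hypothesis()].
#' @param collapse_clones collapse signature-identical accessions to one
#'   representative before scanning (default TRUE).
#' @return data.frame of class `parentage_scan`: offspring, parent1, parent2,
#'   n_informative, n_mismatch, confidence, accepted, documented_match
#'   (TRUE when the hypothesis matches the documented parents up to order
#'   and identity group). Attribute `documented` holds verdicts for the
#'   documented parents; attribute `groups` the identity groups used for
#'   clone collapse.
#' @export
scan_parentage <- function(table, focal = NULL, pool = NULL,
                           mode = c("trio", "duo"),
                           min_confidence = 0.98, threshold = 1,
                           collapse_clones = TRUE) {
  mode <- match.arg(mode)
  ids <- table$accessions$accession_id
  if (is.null(focal)) {
    has_parent <- !is.na(table$accessions$parent1) |
      !is.na(table$accessions$parent2)
    focal <- ids[has_parent]
  }
  if (is.null(pool)) pool <- ids
  groups <- group_by_signature(table)
  rep_of <- stats::setNames(
    rep(vapply(groups$groups, `[`, character(1), 1L),
        lengths(groups$groups)),
    unlist(groups$groups))
  pool_reps <- if (collapse_clones) unique(rep_of[pool]) else pool
  am <- allele_id_matrices(table)
  row_of <- stats::setNames(seq_along(ids), ids)
  results <- list()
  documented <- list()
  for (f in focal) {
    cand <- setdiff(pool_reps, f)
    if (collapse_clones) cand <- setdiff(cand, rep_of[f])
    if (length(cand) == 0L) next
    o1 <- am$a1[row_of[f], ]; o2 <- am$a2[row_of[f], ]
    typed_o <- !is.na(o1)
    C1 <- am$a1[row_of[cand], , drop = FALSE]
    C2 <- am$a2[row_of[cand], , drop = FALSE]
    typed_c <- !is.na(C1)
    # carrier indicators: does candidate c carry offspring allele 1 / 2
    M1 <- (C1 == rep(o1, each = length(cand))) |
      (C2 == rep(o1, each = length(cand)))
    M2 <- (C1 == rep(o2, each = length(cand))) |
      (C2 == rep(o2, each = length(cand)))
    M1[!typed_c | rep(!typed_o, each = length(cand))] <- FALSE
    M2[!typed_c | rep(!typed_o, each = length(cand))] <- FALSE
    inf_c <- typed_c & rep(typed_o, each = length(cand))
    if (mode == "duo") {
      n_inf <- rowSums(inf_c)
      n_comp <- rowSums(M1 | M2)
      res <- data.frame(offspring = f, parent1 = cand,
                        parent2 = NA_character_,
                        n_informative = n_inf, n_mismatch = n_inf - n_comp,
                        confidence = ifelse(n_inf > 0, n_comp / n_inf, NA),
                        stringsAsFactors = FALSE)
    } else {
      # trio counts via three matrix products (inclusion-exclusion over the
      # two transmission assignments), informative = all three typed
      sI <- 1 * inf_c
      m1 <- 1 * M1; m2 <- 1 * M2; m12 <- 1 * (M1 & M2)
      n_inf <- sI %*% t(sI)          # both candidates typed where o typed
      A <- (m1 * sI) %*% t(m2)       # o1 from P, o2 from Q (both informative)
      B <- (m2 * sI) %*% t(m1)
      AB <- (m12 * sI) %*% t(m12)
      n_comp <- A + B - AB
      iu <- which(upper.tri(n_inf, diag = FALSE), arr.ind = TRUE)
      res <- data.frame(offspring = f,
                        parent1 = cand[iu[, 1L]], parent2 = cand[iu[, 2L]],
                        n_informative = n_inf[iu],
                        n_mismatch = n_inf[iu] - n_comp[iu],
                        confidence = ifelse(n_inf[iu] > 0,
                                            n_comp[iu] / n_inf[iu], NA),
                        stringsAsFactors = FALSE)
    }
    res$accepted <- !is.na(res$confidence) &
      res$confidence > min_confidence & res$n_mismatch <= threshold
    results[[f]] <- res[res$accepted, , drop = FALSE]
    # documented parents, evaluated alongside
    meta <- table$accessions[row_of[f], ]
    doc <- stats::na.omit(c(meta$parent1, meta$parent2))
    doc <- doc[doc %in% ids]
    if (length(doc) >= 1L) {
      documented[[f]] <- evaluate_hypothesis(
        table, f, doc[1L], if (length(doc) >= 2L) doc[2L] else NULL,
        min_confidence, threshold)
    }
  }
  out <- if (length(results)) do.call(rbind, results) else
    data.frame(offspring = character(0), parent1 = character(0),
               parent2 = character(0), n_informative = integer(0),
               n_mismatch = integer(0), confidence = numeric(0),
               accepted = logical(0))
  if (nrow(out)) {
    p_lo <- pmin(out$parent1, out$parent2, na.rm = TRUE)
    out <- out[order(out$offspring, out$n_mismatch, -out$confidence, p_lo), ]
    # documented_match: accepted hypothesis equals the documented parent set
    # up to order and clone group
    doc1 <- table$accessions$parent1[match(out$offspring, ids)]
    doc2 <- table$accessions$parent2[match(out$offspring, ids)]
    canon <- function(a, b) {
      a_rep <- ifelse(!is.na(a) & a %in% names(rep_of), rep_of[a], a)
      b_rep <- ifelse(!is.na(b) & b %in% names(rep_of), rep_of[b], b)
      paste(pmin(a_rep, b_rep, na.rm = TRUE), pmax(a_rep, b_rep, na.rm = TRUE))
    }
    out$documented_match <- !is.na(doc1) &
      canon(out$parent1, out$parent2) == canon(doc1, doc2)
  } else out$documented_match <- logical(0)
  rownames(out) <- NULL
  attr(out, "documented") <- documented
  attr(out, "groups") <- groups
  class(out) <- c("parentage_scan", "data.frame")
  out
}

#' @export
print.parentage_scan <- function(x, ...) {
  cat(sprintf("parentage scan: %d accepted hypothesis(es) for %d offspring\n",
              nrow(x), length(unique(x$offspring))))
  if (nrow(x)) print.data.frame(utils::head(x, 10L), row.names = FALSE)
  invisible(x)
}

#' Write parentage scan results as CSV
#' @param scan a `parentage_scan`.
#' @param path output path.
#' @export
write_parentage_csv <- function(scan, path) {
  utils::write.csv(as.data.frame(scan), path, row.names = FALSE)
  invisible(path)
}
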