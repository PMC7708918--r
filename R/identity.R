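# Identity signatures: canonical fingerprint strings over the marker panel,
# duplicate grouping, synonym/homonym/replicate classification, bud-sport
# discriminability and QR payloads.

#' Canonical identity signature strings for all accessions
#'
#' Each accession's signature is `"marker=alleleA|alleleB"` with fields
#' sorted by marker id and joined by ";"; missing calls are encoded `"?"`.
#' Equal genotype multisets give equal strings regardless of marker, allele,
#' row or column order.
#'
#' @param table a [genotype_table()].
#' @return named character vector (accession_id -> canonical string).
#' @export
signature_strings <- function(table) {
  if (ncol(table$calls) == 0L) stop("empty marker panel")
  ord <- order(table$markers)
  cells <- table$calls[, ord, drop = FALSE]
  cells[is.na(cells)] <- "?"
  cells <- gsub("/", "|", cells, fixed = TRUE)
  fields <- matrix(paste0(rep(paste0(table$markers[ord], "="),
                              each = nrow(cells)), cells),
                   nrow = nrow(cells))
  stats::setNames(apply(fields, 1L, paste, collapse = ";"),
                  table$accessions$accession_id)
}

#' Identity signature of one accession
#'
#' @param table a `genotype_table`.
#' @param accession_id accession to sign.
#' @return list of class `identity_signature` with `accession_id`,
#'   `canonical_string` and `digest` (SHA-256 of the canonical string,
#'   hex-encoded).
#' @export
signature_of <- function(table, accession_id) {
  s <- signature_strings(table)
  if (!accession_id %in% names(s)) stop("unknown accession: ", accession_id)
  structure(list(accession_id = accession_id,
                 canonical_string = unname(s[accession_id]),
                 digest = digest::digest(unname(s[accession_id]),
                                         algo = "sha256", serialize = FALSE)),
            class = "identity_signature")
}

#' @export
print.identity_signature <- function(x, ...) {
  cat("identity signature for", x$accession_id, "\n")
  cat("  digest:", x$digest, "\n")
  str <- x$canonical_string
  if (nchar(str) > 70) str <- paste0(substr(str, 1, 67), "...")
  cat("  ", str, "\n", sep = "")
  invisible(x)
}

#' Group accessions by identity signature
#'
#' Exact mode groups accessions whose canonical strings are identical
#' (missing `"?"` is an ordinary symbol). `wildcard_report` mode additionally
#' reports pairs that would become identical if missing cells were ignored;
#' because wildcard matching is not transitive these pairs are reported,
#' never merged.
#'
#' @param table a `genotype_table`.
#' @param match_mode "exact" (default) or "wildcard_report".
#' @return list of class `identity_groups`: `groups` (list of accession-id
#'   vectors, one per distinct signature, decreasing size), `signature`
#'   (canonical string per group), `membership` (accession -> group index),
#'   `summary` (n_accessions, n_distinct, n_singleton, n_shared_groups,
#'   n_in_shared), and `possible_duplicates` (data.frame of wildcard pairs,
#'   only in wildcard_report mode).
#' @export
group_by_signature <- function(table, match_mode = c("exact", "wildcard_report")) {
  match_mode <- match.arg(match_mode)
  sig <- signature_strings(table)
  f <- factor(sig, levels = unique(sig))
  groups <- split(names(sig), f)
  sizes <- lengths(groups)
  ord <- order(sizes, decreasing = TRUE)
  groups <- groups[ord]
  sig_strings <- levels(f)[ord]
  membership <- stats::setNames(rep(seq_along(groups), lengths(groups)),
                                unlist(groups))
  membership <- membership[names(sig)]
  summary <- c(n_accessions = length(sig),
               n_distinct = length(groups),
               n_singleton = sum(lengths(groups) == 1L),
               n_shared_groups = sum(lengths(groups) > 1L),
               n_in_shared = sum(lengths(groups)[lengths(groups) > 1L]))
  out <- list(groups = groups, signature = sig_strings,
              membership = membership, summary = summary,
              match_mode = match_mode)
  if (match_mode == "wildcard_report") {
    out$possible_duplicates <- wildcard_pairs(table, membership)
  }
  structure(out, class = "identity_groups")
}

# Pairs of accessions in different exact groups whose calls agree on every
# marker typed in both (missing treated as wildcard). Report only.
wildcard_pairs <- function(table, membership) {
  has_missing <- rowSums(is.na(table$calls)) > 0L
  ids <- table$accessions$accession_id
  res <- list()
  cand <- which(has_missing)
  for (i in cand) {
    cells_i <- table$calls[i, ]
    typed_i <- !is.na(cells_i)
    cmp <- which(seq_along(ids) > i | (!has_missing & seq_along(ids) != i))
    cmp <- cmp[membership[cmp] != membership[i]]
    if (length(cmp) == 0L) next
    sub <- table$calls[cmp, , drop = FALSE]
    both <- !is.na(sub) & rep(typed_i, each = length(cmp))
    agree <- sub == rep(cells_i, each = length(cmp))
    match_all <- vapply(seq_along(cmp), function(r)
      all(agree[r, both[r, ]]), logical(1))
    for (r in which(match_all)) {
      a <- sort(c(ids[i], ids[cmp[r]]))
      res[[paste(a, collapse = "\r")]] <- data.frame(
        accession_a = a[1L], accession_b = a[2L], stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L)
    return(data.frame(accession_a = character(0), accession_b = character(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @export
print.identity_groups <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "identity groups: %d accessions -> %d distinct signatures\n  %d unique (singletons), %d accessions share %d multi-member patterns\n",
    s["n_accessions"], s["n_distinct"], s["n_singleton"],
    s["n_in_shared"], s["n_shared_groups"]))
  if (!is.null(x$possible_duplicates) && nrow(x$possible_duplicates))
    cat(sprintf("  %d possible duplicate pair(s) if missing calls are ignored (report only)\n",
                nrow(x$possible_duplicates)))
  invisible(x)
}

# Conservative cultivar-name normalization: case-fold, strip punctuation and
# whitespace; user-supplied alias map applied first (raw name -> canonical).
normalize_names <- function(names, alias_map = NULL) {
  if (!is.null(alias_map)) {
    hit <- match(names, names(alias_map))
    names[!is.na(hit)] <- unlist(alias_map)[hit[!is.na(hit)]]
  }
  tolower(gsub("[^[:alnum:]]", "", names))
}

#' Classify accession names against identity groups
#'
#' Labels each accession: `replicate` (same signature and same normalized
#' name as another accession), `synonym` (same signature, different name),
#' `homonym` (same normalized name, different signature), else `unique`.
#' Precedence: replicate > synonym > homonym.
#'
#' @param groups an `identity_groups` object.
#' @param metadata the accession metadata data.frame (needs `accession_id`,
#'   `name`), typically `table$accessions`.
#' @param alias_map optional named character vector mapping raw names to
#'   curated canonical names before normalization.
#' @return list of class `name_classification`: `labels` (named character),
#'   `counts`, `synonym_clusters`, `homonym_clusters` (lists of accession
#'   ids).
#' @export
classify_names <- function(groups, metadata, alias_map = NULL) {
  ids <- metadata$accession_id
  norm <- normalize_names(metadata$name, alias_map)
  grp <- groups$membership[ids]
  if (anyNA(grp)) stop("metadata and identity groups disagree on accessions")
  labels <- stats::setNames(rep("unique", length(ids)), ids)
  name_of <- stats::setNames(norm, ids)
  # same signature, same name
  for (g in which(lengths(groups$groups) > 1L)) {
    members <- groups$groups[[g]]
    nm <- name_of[members]
    dup_name <- nm %in% nm[duplicated(nm)]
    labels[members[dup_name]] <- "replicate"
    # in a multi-member group, any member with a non-duplicated name shares
    # its signature with a differently named accession
    labels[members[!dup_name]] <- "synonym"
  }
  # same name, different signature
  by_name <- split(ids, norm)
  homonym_clusters <- list()
  for (nm in names(by_name)) {
    members <- by_name[[nm]]
    if (length(members) < 2L) next
    if (length(unique(grp[members])) > 1L) {
      homonym_clusters[[nm]] <- members
      upgrade <- labels[members] == "unique"
      labels[members[upgrade]] <- "homonym"
    }
  }
  synonym_clusters <- lapply(
    groups$groups[vapply(groups$groups, function(m)
      any(labels[m] == "synonym"), logical(1))],
    function(m) m)
  structure(list(labels = labels,
                 counts = table(factor(labels, levels = c(
                   "unique", "synonym", "homonym", "replicate"))),
                 synonym_clusters = unname(synonym_clusters),
                 homonym_clusters = homonym_clusters),
            class = "name_classification")
}

#' @export
print.name_classification <- function(x, ...) {
  cat("name classification:\n")
  for (lab in names(x$counts))
    cat(sprintf("  %s: %d\n", lab, x$counts[lab]))
  invisible(x)
}

#' Bud-sport discriminability within clonal lineages
#'
#' Within each lineage (`lineage_group` metadata), an accession is
#' distinguishable iff its signature is unique within that lineage; the rest
#' are partitioned into shared-signature subgroups.
#'
#' @param table a `genotype_table` with `lineage_group` set for sports.
#' @param lineages optional subset of lineage labels (default: all non-NA).
#' @return data.frame of class `sport_report`: `lineage`, `n`,
#'   `n_distinguishable`, `percent` (1 decimal), `n_subgroups`; attribute
#'   `subgroups` holds the shared-signature partitions per lineage.
#' @export
sport_discrimination <- function(table, lineages = NULL) {
  lg <- table$accessions$lineage_group
  if (is.null(lineages)) lineages <- sort(unique(stats::na.omit(lg)))
  sig <- signature_strings(table)
  rows <- list()
  subgroups <- list()
  for (ln in lineages) {
    members <- table$accessions$accession_id[!is.na(lg) & lg == ln]
    if (length(members) == 0L) next  # lineage with n = 0 omitted
    s <- sig[members]
    tab <- table(s)
    uniq <- names(tab)[tab == 1L]
    shared <- split(members[s %in% names(tab)[tab > 1L]],
                    s[s %in% names(tab)[tab > 1L]])
    rows[[ln]] <- data.frame(
      lineage = ln, n = length(members),
      n_distinguishable = sum(s %in% uniq),
      percent = round(100 * sum(s %in% uniq) / length(members), 1L),
      n_subgroups = length(shared), stringsAsFactors = FALSE)
    subgroups[[ln]] <- unname(shared)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "subgroups") <- subgroups
  class(out) <- c("sport_report", "data.frame")
  out
}

#' Compare a bud sport to its wildtype cultivar
#'
#' @param table a `genotype_table`.
#' @param sport_id,wildtype_id accession ids.
#' @return list with `polymorphic` (markers whose canonical calls differ,
#'   both typed) and `uncomparable` (markers missing in exactly one of the
#'   two accessions).
#' @export
compare_to_wildtype <- function(table, sport_id, wildtype_id) {
  ids <- table$accessions$accession_id
  for (a in c(sport_id, wildtype_id))
    if (!a %in% ids) stop("unknown accession: ", a)
  s <- table$calls[match(sport_id, ids), ]
  w <- table$calls[match(wildtype_id, ids), ]
  both <- !is.na(s) & !is.na(w)
  one <- xor(is.na(s), is.na(w))
  list(polymorphic = table$markers[both & s != w],
       uncomparable = table$markers[one])
}

QR_PAYLOAD_PREFIX <- "GIK"

#' QR payload text for an accession's identity signature
#'
#' Deterministic text payload: `GIK|v=<panel_version>|id=<accession>|` then
#' either the full canonical signature string or (digest mode)
#' `digest=<sha256>`. The full payload is decodable back to the genotype map
#' with [parse_qr_payload()]. Image rendering is delegated to any external
#' QR encoder.
#'
#' @param table a `genotype_table`.
#' @param accession_id accession to encode.
#' @param panel_version free-text panel version tag (default the marker
#'   count, e.g. "panel102").
#' @param mode "full" (default) or "digest".
#' @param max_chars payload capacity guard; a full payload longer than this
#'   errors with a suggestion to use digest mode (default 2953, the byte
#'   capacity of a version-40 QR code at error-correction level L).
#' @return payload string.
#' @export
qr_payload <- function(table, accession_id, panel_version = NULL,
                       mode = c("full", "digest"), max_chars = 2953) {
  mode <- match.arg(mode)
  if (is.null(panel_version))
    panel_version <- paste0("panel", ncol(table$calls))
  sig <- signature_of(table, accession_id)
  body <- if (mode == "full") sig$canonical_string
    else paste0("digest=", sig$digest)
  payload <- paste(QR_PAYLOAD_PREFIX, paste0("v=", panel_version),
                   paste0("id=", accession_id), body, sep = "|")
  if (mode == "full" && nchar(payload) > max_chars)
    stop("payload (", nchar(payload), " chars) exceeds QR capacity (",
         max_chars, "); use mode = \"digest\"")
  payload
}

#' Parse a QR payload back to its genotype map
#'
#' @param payload string produced by [qr_payload()].
#' @return list with `accession_id`, `panel_version`, and either `genotypes`
#'   (named character: marker -> canonical call, NA missing) or `digest`.
#' @export
parse_qr_payload <- function(payload) {
  parts <- strsplit(payload, "|", fixed = TRUE)[[1]]
  if (length(parts) < 4L || parts[1L] != QR_PAYLOAD_PREFIX ||
      !startsWith(parts[2L], "v=") || !startsWith(parts[3L], "id="))
    stop("not a recognizable identity payload")
  out <- list(accession_id = sub("^id=", "", parts[3L]),
              panel_version = sub("^v=", "", parts[2L]))
  body <- paste(parts[-(1:3)], collapse = "|")
  if (startsWith(body, "digest=")) {
    out$digest <- sub("^digest=", "", body)
  } else {
    fields <- strsplit(body, ";", fixed = TRUE)[[1]]
    markers <- sub("=.*$", "", fields)
    calls <- sub("^[^=]*=", "", fields)
    calls <- ifelse(calls == "?", NA_character_,
                    gsub("|", "/", calls, fixed = TRUE))
    out$genotypes <- stats::setNames(calls, markers)
  }
  out
}
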