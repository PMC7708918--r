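# Structural-variant triage into an InDel genotyping panel: parse Delly-style
# VCF, summarize SV classes, filter InDel candidates by length, select a
# genome-spaced panel and pack it into fluorescent multiplex PCR groups.

SV_TYPES <- c("DEL", "INS", "INV", "ITX", "CTX")

#' Read structural-variant calls from a VCF file
#'
#' Parses Delly-style records. Non-BND records map directly to DEL/INS/INV
#' (legacy `SVTYPE=TRA` records are classified ITX/CTX from `CHR2`). BND
#' records are resolved in mate pairs — via `MATEID` when present, otherwise
#' by reciprocal coordinates parsed from the ALT breakend string — and each
#' pair is emitted once, as ITX when both breakends share a chromosome and
#' CTX otherwise. BND records whose mate cannot be resolved are skipped and
#' counted in a warning.
#'
#' @param path VCF file (plain or bgzipped).
#' @return data.frame of class `sv_records` with columns `chrom`, `start`,
#'   `end`, `svtype`, `length`, `quality_pass` (and `chrom2`, `pos2` for
#'   translocations). Attribute `n_skipped_bnd` counts unresolved breakends.
#' @export
read_sv_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  body <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  nf <- lengths(regmatches(body, gregexpr("\t", body))) + 1L
  if (length(body) && any(nf < 8L)) {
    bad <- which(nf < 8L)[1L]
    n_header <- sum(startsWith(readLines(path), "#"))
    stop(sprintf("malformed VCF %s: line %d has %d fields (expected >= 8)",
                 path, n_header + bad, nf[bad]))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  info <- function(key) vcfR::extract.info(vcf, element = key)
  svtype <- info("SVTYPE")
  end <- suppressWarnings(as.integer(info("END")))
  svlen <- suppressWarnings(as.integer(info("SVLEN")))
  inslen <- suppressWarnings(as.integer(info("INSLEN")))
  chr2 <- info("CHR2")
  mateid <- info("MATEID")
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  id <- fix[, "ID"]
  alt <- fix[, "ALT"]
  filter <- fix[, "FILTER"]
  pass <- is.na(filter) | filter %in% c("PASS", ".")
  n <- length(chrom)
  if (n == 0L)
    return(empty_sv_records())
  if (any(is.na(svtype)))
    stop("VCF record(s) without SVTYPE INFO key: ",
         paste(utils::head(id[is.na(svtype)], 3L), collapse = ", "))

  rows <- list()
  add_row <- function(chrom, start, end, svtype, length, pass,
                      chrom2 = NA_character_, pos2 = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, svtype = svtype,
      length = length, quality_pass = pass, chrom2 = chrom2, pos2 = pos2,
      stringsAsFactors = FALSE)
  }

  is_bnd <- svtype == "BND"
  for (i in which(!is_bnd)) {
    st <- svtype[i]
    if (st == "TRA") {
      c2 <- chr2[i]
      if (is.na(c2)) stop("TRA record without CHR2: ", id[i])
      st <- if (identical(c2, chrom[i])) "ITX" else "CTX"
      add_row(chrom[i], pos[i],
              if (st == "ITX" && !is.na(end[i])) end[i] else pos[i],
              st, max(1L, abs(if (!is.na(end[i]) && st == "ITX") end[i] - pos[i] else 1L)),
              pass[i], c2, end[i])
    } else if (st %in% c("DEL", "INV")) {
      e <- end[i]
      if (is.na(e)) e <- pos[i] + abs(svlen[i])
      add_row(chrom[i], pos[i], e, st, e - pos[i], pass[i])
    } else if (st == "INS") {
      len <- abs(svlen[i])
      if (is.na(len)) len <- abs(inslen[i])
      if (is.na(len)) stop("INS record without SVLEN/INSLEN: ", id[i])
      add_row(chrom[i], pos[i], if (!is.na(end[i])) end[i] else pos[i],
              "INS", len, pass[i])
    } else stop("unknown SVTYPE \"", st, "\" in record ", id[i])
  }

  # BND mate resolution
  n_skipped <- 0L
  if (any(is_bnd)) {
    bnd <- which(is_bnd)
    # mate coordinates from the ALT breakend string, e.g. N[chr5:1200[
    mate <- regmatches(alt[bnd],
                       regexpr("[\\[\\]]([^\\[\\]:]+):([0-9]+)[\\[\\]]",
                               alt[bnd], perl = TRUE))
    mchrom <- rep(NA_character_, length(bnd))
    mpos <- rep(NA_integer_, length(bnd))
    okm <- lengths(regmatches(alt[bnd], gregexpr("[][]", alt[bnd]))) >= 2L &
      vapply(mate, length, integer(1)) == 1L
    parsed <- sub("^[][]", "", sub("[][]$", "", unlist(mate[okm])))
    if (length(parsed)) {
      mchrom[okm] <- sub(":.*", "", parsed)
      mpos[okm] <- as.integer(sub(".*:", "", parsed))
    }
    used <- rep(FALSE, length(bnd))
    key <- paste(chrom[bnd], pos[bnd], sep = ":")
    for (k in seq_along(bnd)) {
      if (used[k]) next
      i <- bnd[k]
      partner <- NA_integer_
      if (!is.na(mateid[i])) {
        hit <- which(id[bnd] == mateid[i] & !used)
        if (length(hit)) partner <- hit[1L]
      }
      if (is.na(partner) && !is.na(mchrom[k])) {
        hit <- which(key == paste(mchrom[k], mpos[k], sep = ":") & !used &
                       seq_along(bnd) != k)
        if (length(hit)) partner <- hit[1L]
      }
      if (is.na(partner)) {
        n_skipped <- n_skipped + 1L
        used[k] <- TRUE
        next
      }
      used[c(k, partner)] <- TRUE
      j <- bnd[partner]
      st <- if (identical(chrom[i], chrom[j])) "ITX" else "CTX"
      len <- if (st == "ITX") abs(pos[j] - pos[i]) else 1L
      add_row(chrom[i], min(pos[i], if (st == "ITX") pos[j] else pos[i]),
              max(pos[i], if (st == "ITX") pos[j] else pos[i]),
              st, max(1L, len), pass[i] && pass[j], chrom[j], pos[j])
    }
  }
  if (n_skipped > 0L)
    warning(n_skipped, " BND record(s) without a resolvable mate were skipped")
  out <- if (length(rows)) do.call(rbind, rows) else empty_sv_records()
  attr(out, "n_skipped_bnd") <- n_skipped
  class(out) <- c("sv_records", "data.frame")
  out
}

empty_sv_records <- function() {
  structure(data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), svtype = character(0),
                       length = integer(0), quality_pass = logical(0),
                       chrom2 = character(0), pos2 = integer(0),
                       stringsAsFactors = FALSE),
            n_skipped_bnd = 0L, class = c("sv_records", "data.frame"))
}

#' Summarize structural-variant calls
#'
#' Counts per SV class (always reporting all five classes), a fragment-length
#' histogram for DEL and INS, and the fraction of each type with length in
#' a target range (default the 50-400 bp window used for marker candidates).
#'
#' @param records `sv_records` from [read_sv_vcf()].
#' @param bin_width histogram bin width in bp (default 50).
#' @param max_len upper edge of the last regular bin; longer records fall in
#'   an overflow bin (default 1000).
#' @param range length window for the in-range fraction (default c(50, 400),
#'   inclusive).
#' @return list of class `sv_summary`: `counts` (named integer, five types),
#'   `hist` (data.frame bin x type counts for DEL/INS), `fraction_in_range`
#'   (named numeric per type, NA when no records of the type).
#' @export
summarize_svs <- function(records, bin_width = 50, max_len = 1000,
                          range = c(50, 400)) {
  counts <- stats::setNames(integer(length(SV_TYPES)), SV_TYPES)
  tab <- table(factor(records$svtype, levels = SV_TYPES))
  counts[names(tab)] <- as.integer(tab)
  breaks <- c(seq(0, max_len, by = bin_width), Inf)
  labels <- c(paste0("(", utils::head(breaks, -2L), ",",
                     breaks[-c(1L, length(breaks))], "]"),
              paste0(">", max_len))
  hist <- data.frame(bin = labels)
  for (tp in c("DEL", "INS")) {
    len <- records$length[records$svtype == tp]
    hist[[tp]] <- as.integer(table(cut(len, breaks = breaks, labels = labels)))
  }
  frac <- vapply(SV_TYPES, function(tp) {
    len <- records$length[records$svtype == tp]
    if (length(len) == 0L) return(NA_real_)
    mean(len >= range[1L] & len <= range[2L])
  }, numeric(1))
  structure(list(counts = counts, hist = hist, fraction_in_range = frac,
                 range = range, n = nrow(records)),
            class = "sv_summary")
}

#' @export
print.sv_summary <- function(x, ...) {
  cat("structural-variant summary (", x$n, " records)\n", sep = "")
  for (tp in names(x$counts)) {
    extra <- if (!is.na(x$fraction_in_range[tp]))
      sprintf("  (%.2f%% in [%d,%d] bp)", 100 * x$fraction_in_range[tp],
              x$range[1L], x$range[2L]) else ""
    cat(sprintf("  %s: %d%s\n", tp, x$counts[tp], extra))
  }
  invisible(x)
}

#' Filter InDel marker candidates
#'
#' Keeps DEL/INS records with length inside `[min_len, max_len]` (bounds
#' inclusive) that pass the VCF quality filter (when `require_pass`).
#'
#' @param records `sv_records`.
#' @param min_len,max_len inclusive length bounds in bp (defaults 50, 400).
#' @param require_pass drop records failing the VCF FILTER (default TRUE).
#' @return `sv_records` subset.
#' @export
filter_indel_candidates <- function(records, min_len = 50, max_len = 400,
                                    require_pass = TRUE) {
  if (min_len > max_len)
    stop("min_len (", min_len, ") must be <= max_len (", max_len, ")")
  keep <- records$svtype %in% c("DEL", "INS") &
    records$length >= min_len & records$length <= max_len
  if (require_pass) keep <- keep & records$quality_pass
  out <- records[keep, , drop = FALSE]
  class(out) <- c("sv_records", "data.frame")
  out
}

# Chromosome serial from a label like "Chr07"/"chr7"/"7"; NA when no digits.
chrom_number <- function(chrom) {
  num <- suppressWarnings(as.integer(gsub("[^0-9]", "", chrom)))
  num
}

# Exact max-min-gap selection of k positions from a sorted vector, both
# extremes forced in (an optimal solution containing both extremes always
# exists: sliding the outermost chosen points to the candidate extremes never
# shrinks a pairwise gap). DP over (points used, end index); ties broken
# toward smaller coordinates via backtracking order.
select_spaced <- function(pos, k) {
  n <- length(pos)
  ord <- order(pos)
  x <- pos[ord]
  if (k >= n) return(sort(ord))
  if (k == 1L) {
    mid <- (x[1L] + x[n]) / 2
    best <- which.min(abs(x - mid))  # ties -> smaller coordinate
    return(ord[best])
  }
  dp <- matrix(-Inf, nrow = k, ncol = n)
  choice <- matrix(NA_integer_, nrow = k, ncol = n)
  dp[1L, 1L] <- Inf
  for (j in 2L:k) {
    for (i in j:n) {
      prev <- (j - 1L):(i - 1L)
      val <- pmin(dp[j - 1L, prev], x[i] - x[prev])
      best <- which.max(val)  # first max -> smallest predecessor coordinate
      dp[j, i] <- val[best]
      choice[j, i] <- prev[best]
    }
  }
  sel <- integer(k)
  sel[k] <- n
  for (j in k:2L) sel[j - 1L] <- choice[j, sel[j]]
  sort(ord[sel])
}

#' Select a genome-spaced marker panel
#'
#' Picks up to `per_chrom` candidates per chromosome, maximizing the minimum
#' pairwise physical distance among the selected loci (exact dynamic
#' program; for `per_chrom = 1` the candidate closest to the chromosome
#' midpoint, ties to the smaller coordinate). Marker ids follow the
#' "C" + 2-digit chromosome + 3-digit serial convention, the serial being
#' the candidate's rank by position on its chromosome.
#'
#' @param candidates `sv_records` of InDel candidates (see
#'   [filter_indel_candidates()]).
#' @param per_chrom markers per chromosome (default 10).
#' @param base_size expected PCR product size of the deletion allele in bp;
#'   the insertion allele is `base_size + length` (default 60).
#' @return data.frame of class `marker_panel`: `marker_id`, `chrom`, `pos`,
#'   `svtype`, `length`, `size_I`, `size_D`, `dye`, `multiplex_group`.
#' @export
select_panel <- function(candidates, per_chrom = 10, base_size = 60) {
  if (nrow(candidates) == 0L) stop("no candidates to select from")
  chroms <- unique(candidates$chrom)
  panels <- list()
  for (ch in chroms) {
    sub <- candidates[candidates$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("chromosome ", ch, " has no candidates; omitted")
      next
    }
    idx <- select_spaced(sub$start, min(per_chrom, nrow(sub)))
    chn <- chrom_number(ch)
    serial <- idx  # rank by position among this chromosome's candidates
    sel <- sub[idx, , drop = FALSE]
    sel$marker_id <- sprintf("C%02d%03d",
                             if (is.na(chn)) match(ch, chroms) else chn,
                             serial)
    panels[[ch]] <- sel
  }
  if (length(panels) == 0L) stop("no chromosome yielded candidates")
  sel <- do.call(rbind, panels)
  out <- data.frame(marker_id = sel$marker_id, chrom = sel$chrom,
                    pos = sel$start, svtype = sel$svtype,
                    length = sel$length,
                    size_I = base_size + sel$length, size_D = base_size,
                    dye = NA_character_, multiplex_group = NA_integer_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("marker_panel", "data.frame")
  out
}

#' Pack a marker panel into fluorescent multiplex PCR groups
#'
#' First-fit-decreasing by product-size span: markers are sorted by
#' decreasing span `[size_D, size_I]` and each is placed on the first
#' (group, dye) slot where its span, padded by `size_gap`, does not overlap
#' any same-dye member of the group; a new group is opened when none fits.
#'
#' @param panel a `marker_panel` (or data.frame with `marker_id`, `size_I`,
#'   `size_D`).
#' @param dyes dye names cycled within groups (default FAM/HEX/NED/PET).
#' @param size_gap minimum bp separation between same-dye product ranges
#'   (default 20, a capillary-electrophoresis binning safety margin).
#' @param max_group_size maximum markers per group (default 24).
#' @param detect_range detectable product-size window; a marker whose own
#'   allele span exceeds it is rejected with a warning (default c(50, 500)).
#' @return the panel with `dye` and `multiplex_group` filled, plus attributes
#'   `n_groups` and `rejected` (marker ids outside the detectable range).
#' @export
design_multiplex <- function(panel, dyes = c("FAM", "HEX", "NED", "PET"),
                             size_gap = 20, max_group_size = 24,
                             detect_range = c(50, 500)) {
  if (anyNA(panel$size_I) || anyNA(panel$size_D))
    stop("every marker needs both product sizes")
  lo <- pmin(panel$size_I, panel$size_D)
  hi <- pmax(panel$size_I, panel$size_D)
  bad <- lo < detect_range[1L] | hi > detect_range[2L]
  rejected <- panel$marker_id[bad]
  if (length(rejected))
    warning("rejected ", length(rejected),
            " marker(s) whose product span exceeds the detectable range [",
            detect_range[1L], ",", detect_range[2L], "]: ",
            paste(rejected, collapse = ", "))
  keep <- which(!bad)
  ord <- keep[order(hi[keep] - lo[keep], decreasing = TRUE)]
  groups <- list()  # each: list(dye -> matrix of [lo, hi]) and member count
  assign_dye <- rep(NA_character_, nrow(panel))
  assign_grp <- rep(NA_integer_, nrow(panel))
  for (i in ord) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (groups[[g]]$n >= max_group_size) next
      for (dye in dyes) {
        iv <- groups[[g]]$iv[[dye]]
        conflict <- !is.null(iv) &&
          any(lo[i] - size_gap < iv[, 2L] & hi[i] + size_gap > iv[, 1L])
        if (!conflict) {
          groups[[g]]$iv[[dye]] <- rbind(iv, c(lo[i], hi[i]))
          groups[[g]]$n <- groups[[g]]$n + 1L
          assign_dye[i] <- dye
          assign_grp[i] <- g
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) {
      g <- length(groups) + 1L
      groups[[g]] <- list(iv = stats::setNames(vector("list", length(dyes)), dyes),
                          n = 1L)
      groups[[g]]$iv[[dyes[1L]]] <- matrix(c(lo[i], hi[i]), nrow = 1L)
      assign_dye[i] <- dyes[1L]
      assign_grp[i] <- g
    }
  }
  out <- panel
  out$dye <- assign_dye
  out$multiplex_group <- assign_grp
  attr(out, "n_groups") <- length(groups)
  attr(out, "rejected") <- rejected
  class(out) <- c("marker_panel", "data.frame")
  out
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker panel: %d markers on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (!all(is.na(x$multiplex_group)))
    cat(sprintf("  multiplex groups: %d (sizes %s)\n",
                length(unique(stats::na.omit(x$multiplex_group))),
                paste(sort(table(x$multiplex_group)), collapse = ", ")))
  invisible(x)
}

#' Write a marker panel as TSV
#' @param panel a `marker_panel`.
#' @param path output path.
#' @export
write_panel_tsv <- function(panel, path) {
  utils::write.table(
    panel[, c("marker_id", "chrom", "pos", "size_I", "size_D", "dye",
              "multiplex_group")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write marker loci as BED (0-based half-open)
#' @param panel a `marker_panel`.
#' @param path output path.
#' @export
write_panel_bed <- function(panel, path) {
  bed <- data.frame(panel$chrom, panel$pos - 1L, panel$pos + panel$length,
                    panel$marker_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
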