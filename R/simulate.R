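# Synthetic germplasm collections with the statistical structure the
# analyses assume: structured populations at controlled divergence
# (Balding-Nichols), Hardy-Weinberg genotypes within populations, pedigreed
# offspring, clonal bud-sport lineages with somatic mutation, missing data,
# and name metadata with planted synonyms/homonyms/replicates — plus a
# machine-readable truth log. Also writes synthetic Delly-style SV VCFs.

#' Simulation configuration
#'
#' Defaults emulate a large apple-type germplasm collection: 1251 accessions
#' over seven species-like populations plus a pooled "other" group, 102
#' biallelic fragment-length markers on 17 chromosomes, seven clonal
#' bud-sport lineages (160/60/60/14/10/10/6 sports), 40 pedigreed offspring
#' (6 of them with a mis-documented parent), planted name errors, tetraploid
#' duplicates of two diploid founders, and 1% missing calls.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_markers number of markers (default 102).
#' @param species data.frame with columns `name`, `n` (founder individuals)
#'   and `phi` (Balding-Nichols divergence, the expected Fst scale, in
#'   (0, 1)).
#' @param ancestral_beta shape parameters of the Beta from which ancestral
#'   allele frequencies are drawn (default c(1, 1)).
#' @param ancestral_range truncation interval for ancestral frequencies
#'   (default c(0.05, 0.95)).
#' @param pedigree_spec data.frame `n_offspring` rows are generated from
#'   random founder pairs of the first species when NULL; otherwise columns
#'   `parent1`, `parent2` (founder indices within species 1, or NA to draw),
#'   one row per cross.
#' @param n_offspring number of pedigreed offspring (default 40).
#' @param n_misdocumented offspring whose recorded parent2 is deliberately
#'   wrong in the metadata while the truth log keeps the real one
#'   (default 6).
#' @param clone_spec data.frame with columns `lineage` (wildtype cultivar
#'   name), `n_clones`, `mu` (per-locus somatic mutation rate per clone).
#'   Default: seven lineages with 160/60/60/14/10/10/6 clones at mu = 0.005.
#' @param missing_rate per-cell missing probability. The default is 0: a
#'   validated multiplex panel yields an essentially complete matrix, and
#'   exact-signature grouping treats a missing call as a distinct symbol, so
#'   missingness directly perturbs identity statistics (see the vignette).
#' @param name_error_spec named integer vector: `synonym_pairs`,
#'   `homonym_pairs`, `replicate_pairs` (defaults 10, 10, 4).
#' @param n_tetraploid_duplicates tetraploid accessions duplicating the
#'   genotype of a diploid founder (default 2).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_markers = 102L,
                       species = NULL,
                       ancestral_beta = c(1, 1),
                       ancestral_range = c(0.05, 0.95),
                       pedigree_spec = NULL,
                       n_offspring = 40L,
                       n_misdocumented = 6L,
                       clone_spec = NULL,
                       missing_rate = 0,
                       name_error_spec = c(synonym_pairs = 10L,
                                           homonym_pairs = 10L,
                                           replicate_pairs = 4L),
                       n_tetraploid_duplicates = 2L) {
  if (is.null(clone_spec))
    clone_spec <- data.frame(
      lineage = c("Fuji", "Red Delicious", "Gala", "Golden Delicious",
                  "Tsugaru", "Jonathan", "Ralls Janet"),
      n_clones = c(160L, 60L, 60L, 14L, 10L, 10L, 6L),
      mu = 0.005, stringsAsFactors = FALSE)
  if (is.null(species)) {
    extras <- n_offspring + name_error_spec[["synonym_pairs"]] +
      name_error_spec[["replicate_pairs"]] + n_tetraploid_duplicates
    clone_total <- sum(clone_spec$n_clones)
    species <- data.frame(
      name = c("M_domestica", "M_sieversii", "M_asiatica", "M_pumila",
               "M_robusta", "M_prunifolia", "M_baccata", "M_other"),
      n = c(981L - clone_total - extras, 49L, 20L, 31L, 21L, 25L, 13L, 111L),
      phi = c(0.06, 0.03, 0.03, 0.03, 0.025, 0.03, 0.16, 0.05),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(species$phi > 0), all(species$phi < 1),
            all(species$n >= 0), n_markers >= 1L,
            missing_rate >= 0, missing_rate < 1,
            all(clone_spec$mu >= 0), all(clone_spec$mu <= 1))
  if (sum(species$n) < 2L * (nrow(clone_spec) + 2L))
    stop("species 1 needs enough founders for clone lineages and pedigrees")
  structure(list(seed = as.integer(seed), n_markers = as.integer(n_markers),
                 species = species, ancestral_beta = ancestral_beta,
                 ancestral_range = ancestral_range,
                 pedigree_spec = pedigree_spec,
                 n_offspring = as.integer(n_offspring),
                 n_misdocumented = as.integer(n_misdocumented),
                 clone_spec = clone_spec, missing_rate = missing_rate,
                 name_error_spec = name_error_spec,
                 n_tetraploid_duplicates = as.integer(n_tetraploid_duplicates)),
            class = "sim_config")
}

# run expr with a private RNG stream seeded from `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Per-species allele frequencies under the Balding-Nichols model
#'
#' Ancestral frequencies p are drawn from a Beta truncated to
#' `ancestral_range`; each species' frequency is Beta(p (1 - phi)/phi,
#' (1 - p)(1 - phi)/phi), so E = p and Var = phi p (1 - p): phi is the
#' expected Fst of the species against the ancestral pool.
#'
#' @param config a [sim_config()].
#' @return list of class `species_freqs`: `ancestral` (length n_markers),
#'   `species` (matrix species x markers of insertion-allele frequencies),
#'   `marker_ids`, `sizes` (data.frame marker, chrom, pos, size_I, size_D).
#' @export
simulate_species_freqs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    L <- config$n_markers
    lo <- config$ancestral_range[1L]; hi <- config$ancestral_range[2L]
    p <- numeric(0)
    while (length(p) < L) {
      draw <- stats::rbeta(2L * L, config$ancestral_beta[1L],
                           config$ancestral_beta[2L])
      p <- c(p, draw[draw >= lo & draw <= hi])
    }
    p <- p[seq_len(L)]
    sp <- config$species
    freqs <- matrix(NA_real_, nrow(sp), L,
                    dimnames = list(sp$name, NULL))
    for (s in seq_len(nrow(sp))) {
      phi <- sp$phi[s]
      freqs[s, ] <- stats::rbeta(L, p * (1 - phi) / phi,
                                 (1 - p) * (1 - phi) / phi)
    }
    # markers spread over 17 chromosomes, fragment sizes in the assay window
    chrom <- rep(seq_len(17L), length.out = L)
    serial <- stats::ave(chrom, chrom, FUN = seq_along)
    marker_ids <- sprintf("C%02d%03d", chrom, serial)
    size_D <- sample(60:200, L, replace = TRUE)
    size_I <- size_D + sample(50:400, L, replace = TRUE)
    colnames(freqs) <- marker_ids
    structure(list(ancestral = stats::setNames(p, marker_ids),
                   species = freqs, marker_ids = marker_ids,
                   sizes = data.frame(marker_id = marker_ids, chrom = chrom,
                                      pos = serial * 1e6L, size_I = size_I,
                                      size_D = size_D,
                                      stringsAsFactors = FALSE)),
              class = "species_freqs")
  })
}

#' Hardy-Weinberg genotypes from allele frequencies
#'
#' Two alleles drawn independently per individual per locus (binomial
#' sampling of insertion-allele copies).
#'
#' @param freqs numeric vector of insertion-allele frequencies (one per
#'   locus).
#' @param n individuals.
#' @return integer matrix n x L of insertion-allele counts (0/1/2).
#' @export
simulate_genotypes <- function(freqs, n) {
  L <- length(freqs)
  matrix(stats::rbinom(n * L, 2L, rep(freqs, each = n)), nrow = n, ncol = L)
}

#' Mendelian offspring from two parental genotype vectors
#'
#' One allele sampled uniformly from each parent per locus; by construction
#' every generated trio is compatible at every typed locus.
#'
#' @param p1_codes,p2_codes integer vectors of parental insertion-allele
#'   counts (0/1/2).
#' @param n offspring to generate.
#' @return integer matrix n x L of offspring codes.
#' @export
simulate_offspring <- function(p1_codes, p2_codes, n) {
  L <- length(p1_codes)
  stopifnot(length(p2_codes) == L)
  gamete <- function(codes) {
    prob <- codes / 2
    matrix(stats::rbinom(n * L, 1L, rep(prob, each = n)), nrow = n)
  }
  gamete(p1_codes) + gamete(p2_codes)
}

#' Clonal copies with somatic mutation
#'
#' Each clone copies the founder; each locus independently mutates with
#' probability `mu` by replacing one allele with the other allele of the
#' marker's two-allele set (no novel fragment lengths, mirroring
#' fragment-size genotyping): D/D -> I/D, I/I -> I/D, I/D -> I/I or D/D with
#' equal probability.
#'
#' @param founder_codes integer vector (0/1/2).
#' @param n clones.
#' @param mu per-locus mutation probability per clone.
#' @return list: `codes` (n x L integer matrix), `mutations` (data.frame
#'   clone, locus, from, to).
#' @export
simulate_clones <- function(founder_codes, n, mu) {
  L <- length(founder_codes)
  codes <- matrix(rep(founder_codes, each = n), nrow = n)
  hit <- which(matrix(stats::runif(n * L) < mu, nrow = n))
  log <- NULL
  if (length(hit)) {
    from <- codes[hit]
    to <- ifelse(from == 0L, 1L,
                 ifelse(from == 2L, 1L,
                        ifelse(stats::runif(length(hit)) < 0.5, 0L, 2L)))
    codes[hit] <- to
    log <- data.frame(clone = (hit - 1L) %% n + 1L,
                      locus = (hit - 1L) %/% n + 1L,
                      from = from, to = to)
    log <- log[order(log$clone, log$locus), , drop = FALSE]
    rownames(log) <- NULL
  } else {
    log <- data.frame(clone = integer(0), locus = integer(0),
                      from = integer(0), to = integer(0))
  }
  list(codes = codes, mutations = log)
}

# canonical call strings from 0/1/2 codes and per-marker fragment sizes
codes_to_calls <- function(codes, size_I, size_D) {
  L <- ncol(codes)
  out <- matrix(NA_character_, nrow(codes), L)
  for (j in seq_len(L)) {
    lab <- c(paste0(size_D[j], "/", size_D[j]),
             paste0(min(size_D[j], size_I[j]), "/", max(size_D[j], size_I[j])),
             paste0(size_I[j], "/", size_I[j]))
    out[, j] <- lab[codes[, j] + 1L]
  }
  out
}

#' Assemble a synthetic germplasm collection
#'
#' Merges species samples, pedigrees and clonal lineages, applies missing
#' data, plants name-metadata errors and polyploid duplicates, and returns
#' the genotype table together with a truth log explaining every generated
#' accession and cell. Byte-identical for equal seeds.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_collection`: `table` (a [genotype_table()]),
#'   `truth` (list: `accessions` data.frame with species, true parents,
#'   clone_family, name_class; `species_freqs`; `mutation_log`;
#'   `missing_cells`; `planted` name-error details; `config`).
#' @export
assemble_collection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sf <- simulate_species_freqs(config)
  with_seed(config$seed + 1L, {
    sp <- config$species
    L <- config$n_markers
    codes <- list(); meta <- list(); truth <- list()
    add <- function(code_mat, ids, names, species, ploidy = 2L,
                    parent1 = NA, parent2 = NA, lineage = NA,
                    true_p1 = NA, true_p2 = NA, clone_family = NA,
                    name_class = "none") {
      codes[[length(codes) + 1L]] <<- code_mat
      meta[[length(meta) + 1L]] <<- data.frame(
        accession_id = ids, name = names, species = species,
        ploidy = ploidy, parent1 = parent1, parent2 = parent2,
        lineage_group = lineage, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <<- data.frame(
        accession_id = ids, species = species,
        true_parent1 = true_p1, true_parent2 = true_p2,
        clone_family = clone_family, name_class = name_class,
        stringsAsFactors = FALSE)
    }
    # founders per species
    founder_ids <- list()
    for (s in seq_len(nrow(sp))) {
      n <- sp$n[s]
      if (n == 0L) next
      g <- simulate_genotypes(sf$species[s, ], n)
      pre <- gsub("^M_", "", sp$name[s])
      ids <- sprintf("%s-%04d", toupper(substr(pre, 1L, 3L)), seq_len(n))
      founder_ids[[sp$name[s]]] <- ids
      add(g, ids, names = sprintf("%s seedling %d", pre, seq_len(n)),
          species = sp$name[s])
    }
    dom <- sp$name[1L]
    dom_ids <- founder_ids[[dom]]
    dom_codes <- codes[[1L]]
    take <- function(k) {  # draw founder rows from species 1 without reuse
      picked <- sample(seq_along(dom_ids), k)
      picked
    }
    # clonal bud-sport lineages: each anchored at a named wildtype founder
    cs <- config$clone_spec
    wt_rows <- take(nrow(cs))
    mutation_log <- list()
    for (i in seq_len(nrow(cs))) {
      # the wildtype keeps lineage_group NA: lineage reports count sports only
      wt <- wt_rows[i]
      meta[[1L]]$name[wt] <- cs$lineage[i]
      cl <- simulate_clones(dom_codes[wt, ], cs$n_clones[i], cs$mu[i])
      ids <- sprintf("%s-S%03d", gsub("[^A-Za-z0-9]", "", cs$lineage[i]),
                     seq_len(cs$n_clones[i]))
      add(cl$codes, ids,
          names = sprintf("%s Sport %d", cs$lineage[i], seq_len(cs$n_clones[i])),
          species = dom, lineage = cs$lineage[i],
          clone_family = cs$lineage[i], name_class = "clone")
      if (nrow(cl$mutations)) {
        cl$mutations$accession_id <- ids[cl$mutations$clone]
        cl$mutations$marker <- sf$marker_ids[cl$mutations$locus]
        mutation_log[[i]] <- cl$mutations
      }
    }
    # pedigreed offspring (first species), some with mis-documented parents
    ped <- config$pedigree_spec
    if (is.null(ped) && config$n_offspring > 0L) {
      pairs <- matrix(sample(seq_along(dom_ids), 2L * config$n_offspring,
                             replace = TRUE), ncol = 2L)
      pairs[pairs[, 1L] == pairs[, 2L], 2L] <-
        (pairs[pairs[, 1L] == pairs[, 2L], 2L] %% length(dom_ids)) + 1L
      ped <- data.frame(parent1 = pairs[, 1L], parent2 = pairs[, 2L])
    }
    if (!is.null(ped) && nrow(ped)) {
      off_codes <- t(vapply(seq_len(nrow(ped)), function(i)
        simulate_offspring(dom_codes[ped$parent1[i], ],
                           dom_codes[ped$parent2[i], ], 1L)[1L, ],
        integer(L)))
      ids <- sprintf("PED-%03d", seq_len(nrow(ped)))
      doc_p2 <- dom_ids[ped$parent2]
      mis <- seq_len(min(config$n_misdocumented, nrow(ped)))
      if (length(mis)) {
        wrong <- vapply(mis, function(i) {
          repeat {
            w <- sample(seq_along(dom_ids), 1L)
            if (!w %in% c(ped$parent1[i], ped$parent2[i])) return(dom_ids[w])
          }
        }, character(1))
        doc_p2[mis] <- wrong
      }
      add(off_codes, ids, names = sprintf("Cross %03d", seq_len(nrow(ped))),
          species = dom,
          parent1 = dom_ids[ped$parent1], parent2 = doc_p2,
          true_p1 = dom_ids[ped$parent1], true_p2 = dom_ids[ped$parent2],
          name_class = "pedigree")
    }
    # planted name errors and tetraploid duplicates
    nes <- config$name_error_spec
    base_meta <- do.call(rbind, meta)
    avail <- setdiff(seq_len(nrow(base_meta)),
                     which(!is.na(base_meta$lineage_group) |
                             base_meta$name %in% cs$lineage))
    pick <- sample(avail, nes[["synonym_pairs"]] + nes[["replicate_pairs"]] +
                     config$n_tetraploid_duplicates)
    all_codes <- do.call(rbind, codes)
    n_base <- nrow(all_codes)
    dup_src <- integer(0)  # source row per appended duplicate accession
    k <- 0L
    planted <- list()
    if (nes[["synonym_pairs"]] > 0L) {
      src <- pick[k + seq_len(nes[["synonym_pairs"]])]; k <- k + length(src)
      ids <- sprintf("SYN-%03d", seq_along(src))
      add(all_codes[src, , drop = FALSE], ids,
          names = sprintf("Alias %03d", seq_along(src)),
          species = base_meta$species[src],
          name_class = "synonym")
      planted$synonyms <- data.frame(accession_id = ids,
                                     duplicates = base_meta$accession_id[src])
      dup_src <- c(dup_src, src)
    }
    if (nes[["replicate_pairs"]] > 0L) {
      src <- pick[k + seq_len(nes[["replicate_pairs"]])]; k <- k + length(src)
      ids <- sprintf("REP-%03d", seq_along(src))
      add(all_codes[src, , drop = FALSE], ids,
          names = base_meta$name[src],  # same name, same genotype
          species = base_meta$species[src],
          name_class = "replicate")
      planted$replicates <- data.frame(accession_id = ids,
                                       duplicates = base_meta$accession_id[src])
      dup_src <- c(dup_src, src)
    }
    if (config$n_tetraploid_duplicates > 0L) {
      src <- pick[k + seq_len(config$n_tetraploid_duplicates)]
      ids <- sprintf("TET-%03d", seq_along(src))
      add(all_codes[src, , drop = FALSE], ids,
          names = paste(base_meta$name[src], "4x"),
          species = base_meta$species[src], ploidy = 4L,
          name_class = "tetraploid_duplicate")
      planted$tetraploids <- data.frame(accession_id = ids,
                                        duplicates = base_meta$accession_id[src])
      dup_src <- c(dup_src, src)
    }
    meta_all <- do.call(rbind, meta)
    truth_all <- do.call(rbind, truth)
    codes_all <- do.call(rbind, codes)
    # homonyms: rename pairs of distinct-genotype accessions to a shared name
    if (nes[["homonym_pairs"]] > 0L) {
      eligible <- setdiff(which(truth_all$name_class == "none"), dup_src)
      hom_src <- matrix(sample(eligible, 2L * nes[["homonym_pairs"]]),
                        ncol = 2L)
      for (i in seq_len(nrow(hom_src))) {
        nm <- sprintf("Landrace %03d", i)
        meta_all$name[hom_src[i, ]] <- nm
        truth_all$name_class[hom_src[i, ]] <- "homonym"
      }
      planted$homonyms <- data.frame(
        accession_a = meta_all$accession_id[hom_src[, 1L]],
        accession_b = meta_all$accession_id[hom_src[, 2L]])
    }
    # missing data; planted duplicates copy their source's observed record
    # (a re-filed collection entry), so they inherit its missing cells
    miss <- matrix(stats::runif(length(codes_all)) < config$missing_rate,
                   nrow = nrow(codes_all))
    if (length(dup_src))
      miss[n_base + seq_along(dup_src), ] <- miss[dup_src, , drop = FALSE]
    calls <- codes_to_calls(codes_all, sf$sizes$size_I, sf$sizes$size_D)
    calls[miss] <- NA_character_
    colnames(calls) <- sf$marker_ids
    tab <- genotype_table(calls, meta_all,
                          marker_info = sf$sizes)
    missing_cells <- which(miss, arr.ind = TRUE)
    mutation_log <- if (length(mutation_log)) do.call(rbind, mutation_log) else
      data.frame(accession_id = character(0), marker = character(0),
                 from = integer(0), to = integer(0))
    structure(list(
      table = tab,
      truth = list(
        accessions = truth_all,
        species_freqs = sf,
        mutation_log = mutation_log[, c("accession_id", "marker", "from", "to")],
        missing_cells = data.frame(
          accession_id = meta_all$accession_id[missing_cells[, 1L]],
          marker = sf$marker_ids[missing_cells[, 2L]]),
        planted = planted,
        config = config)),
      class = "sim_collection")
  })
}

#' @export
print.sim_collection <- function(x, ...) {
  cat("synthetic germplasm collection\n")
  print(x$table)
  cat(sprintf("  planted: %d somatic mutations, %d missing cells\n",
              nrow(x$truth$mutation_log), nrow(x$truth$missing_cells)))
  invisible(x)
}

#' Write the truth log as JSON
#' @param collection a `sim_collection`.
#' @param path output path.
#' @export
write_truth_json <- function(collection, path) {
  tr <- collection$truth
  jsonlite::write_json(
    list(accessions = tr$accessions,
         ancestral_freqs = as.list(tr$species_freqs$ancestral),
         species_freqs = as.data.frame(t(tr$species_freqs$species)),
         mutation_log = tr$mutation_log,
         missing_cells = tr$missing_cells,
         planted = tr$planted),
    path, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a synthetic Delly-style structural-variant VCF
#'
#' Generates records with a known type composition for exercising the SV
#' triage: DEL/INV (SVTYPE + END), INS (SVTYPE + SVLEN), and ITX/CTX as BND
#' mate pairs with MATEID. Lengths for DEL/INS are drawn from a mixture with
#' a known in-[50,400] fraction.
#'
#' @param path output VCF path.
#' @param n_per_type named integer vector over DEL/INS/INV/ITX/CTX.
#' @param seed integer seed.
#' @param prob_in_range probability that a DEL/INS length falls inside
#'   [50, 400] (default 0.8).
#' @param n_chrom chromosomes to scatter records over (default 17).
#' @return invisibly, the truth data.frame (one row per logical SV:
#'   svtype, chrom, pos, length, in_range).
#' @export
simulate_sv_vcf <- function(path, n_per_type = c(DEL = 40L, INS = 30L,
                                                 INV = 5L, ITX = 5L,
                                                 CTX = 10L),
                            seed = 1L, prob_in_range = 0.8, n_chrom = 17L) {
  with_seed(seed, {
    chroms <- sprintf("Chr%02d", seq_len(n_chrom))
    draw_len <- function(n) {
      inr <- stats::runif(n) < prob_in_range
      len <- integer(n)
      len[inr] <- sample(50:400, sum(inr), replace = TRUE)
      len[!inr] <- sample(c(20:49, 401:900), sum(!inr), replace = TRUE)
      list(len = len, in_range = inr)
    }
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=gikit-synthetic",
      "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
      "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
      "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
      "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Mate chromosome\">",
      "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate id\">",
      paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                          "FILTER", "INFO"), collapse = "\t")))
    lines <- character(0)
    truth <- list()
    rec_id <- 0L
    emit <- function(chrom, pos, id, alt, info) {
      lines[[length(lines) + 1L]] <<- paste(chrom, pos, id, "N", alt, 60,
                                            "PASS", info, sep = "\t")
    }
    for (tp in names(n_per_type)) {
      n <- n_per_type[[tp]]
      if (n == 0L) next
      if (tp %in% c("DEL", "INS", "INV")) {
        dl <- if (tp == "INV") list(len = sample(500:5000, n, replace = TRUE),
                                    in_range = rep(NA, n)) else draw_len(n)
        for (i in seq_len(n)) {
          rec_id <- rec_id + 1L
          chrom <- sample(chroms, 1L)
          pos <- sample.int(3e7L, 1L)
          info <- switch(tp,
            DEL = sprintf("SVTYPE=DEL;END=%d", pos + dl$len[i]),
            INV = sprintf("SVTYPE=INV;END=%d", pos + dl$len[i]),
            INS = sprintf("SVTYPE=INS;END=%d;SVLEN=%d", pos, dl$len[i]))
          emit(chrom, pos, sprintf("%s%05d", tp, rec_id),
               sprintf("<%s>", tp), info)
          truth[[length(truth) + 1L]] <- data.frame(
            svtype = tp, chrom = chrom, pos = pos, length = dl$len[i],
            in_range = dl$len[i] >= 50 && dl$len[i] <= 400)
        }
      } else {
        for (i in seq_len(n)) {
          rec_id <- rec_id + 1L
          c1 <- sample(chroms, 1L)
          c2 <- if (tp == "ITX") c1 else sample(setdiff(chroms, c1), 1L)
          p1 <- sample.int(3e7L, 1L)
          p2 <- if (tp == "ITX") p1 + sample(1000:100000, 1L) else
            sample.int(3e7L, 1L)
          ida <- sprintf("BND%05da", rec_id)
          idb <- sprintf("BND%05db", rec_id)
          emit(c1, p1, ida, sprintf("N[%s:%d[", c2, p2),
               sprintf("SVTYPE=BND;CHR2=%s;MATEID=%s", c2, idb))
          emit(c2, p2, idb, sprintf("]%s:%d]N", c1, p1),
               sprintf("SVTYPE=BND;CHR2=%s;MATEID=%s", c1, ida))
          truth[[length(truth) + 1L]] <- data.frame(
            svtype = tp, chrom = c1, pos = p1,
            length = if (tp == "ITX") p2 - p1 else 1L, in_range = NA)
        }
      }
    }
    writeLines(c(header, unlist(lines)), path)
    invisible(do.call(rbind, truth))
  })
}
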