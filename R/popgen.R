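# Population genetics over co-dominant marker tables: allele frequencies,
# per-locus and per-population diversity (Na, Ne, I, Ho, He, F), pairwise
# Weir-Cockerham theta / Nei Gst with exact differentiation tests, the
# Hardy-Weinberg exact test, and genotype-frequency pattern classification.

# Accessions contributing to population statistics: diploids by default
# (polyploids carry unknown dosage and are excluded, as is conventional).
popgen_accessions <- function(table, diploids_only = TRUE) {
  if (diploids_only) which(table$accessions$ploidy == 2L)
  else seq_len(nrow(table$calls))
}

pop_factor <- function(table, grouping, idx) {
  pop <- if (length(grouping) == 1L && grouping %in% names(table$accessions))
    table$accessions[[grouping]] else {
      if (length(grouping) != nrow(table$calls))
        stop("`grouping` must be a metadata column name or a vector over accessions")
      as.character(grouping)
    }
  pop[idx]
}

#' Allele frequencies per population and marker
#'
#' Frequencies are allele counts over `2 * n_typed` non-missing diploid
#' calls. Population/marker combinations with no typed individual are
#' flagged and carry an empty frequency vector.
#'
#' @param table a [genotype_table()].
#' @param grouping metadata column name (default "species") or a vector of
#'   population labels over accessions.
#' @param diploids_only exclude polyploids (default TRUE).
#' @return list of class `allele_freq_table`: `freq` (list population ->
#'   marker -> named numeric), `n_typed` (population x marker matrix),
#'   `het` (observed heterozygote fraction, same shape), `populations`,
#'   `markers`.
#' @export
allele_frequencies <- function(table, grouping = "species",
                               diploids_only = TRUE) {
  idx <- popgen_accessions(table, diploids_only)
  pop <- pop_factor(table, grouping, idx)
  keep <- !is.na(pop)
  idx <- idx[keep]; pop <- pop[keep]
  pops <- sort(unique(pop))
  markers <- table$markers
  n_typed <- matrix(0L, length(pops), length(markers),
                    dimnames = list(pops, markers))
  het <- matrix(NA_real_, length(pops), length(markers),
                dimnames = list(pops, markers))
  freq <- stats::setNames(vector("list", length(pops)), pops)
  al <- calls_allele_list(table$calls[idx, , drop = FALSE])
  dim(al) <- c(length(idx), length(markers))
  for (p in pops) {
    rows <- which(pop == p)
    freq[[p]] <- stats::setNames(vector("list", length(markers)), markers)
    for (j in seq_along(markers)) {
      a <- al[rows, j]
      typed <- lengths(a) > 0L
      n_typed[p, j] <- sum(typed)
      if (n_typed[p, j] == 0L) {
        freq[[p]][[j]] <- numeric(0)  # flagged: no typed individuals
        next
      }
      counts <- table(unlist(a[typed]))
      freq[[p]][[j]] <- counts / sum(counts)
      het[p, j] <- mean(vapply(a[typed], function(x)
        length(unique(x)) > 1L, logical(1)))
    }
  }
  structure(list(freq = freq, n_typed = n_typed, het = het,
                 populations = pops, markers = markers),
            class = "allele_freq_table")
}

#' Per-locus diversity statistics
#'
#' For each population x marker with typed individuals: Na (observed allele
#' count), Ne = 1/sum(p^2), I = -sum(p log p), Ho (observed heterozygote
#' fraction), He = 1 - sum(p^2) (uncorrected), uHe = 2n/(2n-1) He, and
#' F = (He - Ho)/He (NA at monomorphic loci where He = 0).
#'
#' @param freqs an `allele_freq_table` from [allele_frequencies()], or a
#'   `genotype_table` (frequencies are computed with the defaults).
#' @param grouping,diploids_only forwarded to [allele_frequencies()] when a
#'   `genotype_table` is given.
#' @return data.frame of class `locus_diversity`: population, marker,
#'   n_typed, Na, Ne, I, Ho, He, uHe, F.
#' @export
locus_diversity <- function(freqs, grouping = "species", diploids_only = TRUE) {
  if (inherits(freqs, "genotype_table"))
    freqs <- allele_frequencies(freqs, grouping, diploids_only)
  rows <- list()
  for (p in freqs$populations) {
    for (m in freqs$markers) {
      f <- freqs$freq[[p]][[m]]
      n <- freqs$n_typed[p, m]
      if (n == 0L || length(f) == 0L) next
      sp2 <- sum(f^2)
      he <- 1 - sp2
      ho <- freqs$het[p, m]
      rows[[length(rows) + 1L]] <- data.frame(
        population = p, marker = m, n_typed = n,
        Na = length(f), Ne = 1 / sp2,
        I = -sum(f * log(f)),
        Ho = ho, He = he,
        uHe = if (n > 0) 2 * n / (2 * n - 1) * he else NA_real_,
        F = if (he > 0) (he - ho) / he else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("locus_diversity", "data.frame")
  out
}

#' Population diversity summary (Table-2-style layout)
#'
#' Unweighted across-locus means of the per-locus statistics for each
#' population; F is averaged over loci where it is defined (mean of per-locus
#' ratios, the GenAlEx convention), configurable to the ratio-of-means
#' 1 - mean(Ho)/mean(He).
#'
#' @param x a `locus_diversity` data.frame, `allele_freq_table`, or
#'   `genotype_table`.
#' @param grouping,diploids_only forwarded when `x` is a `genotype_table`.
#' @param f_mode "mean_of_ratios" (default) or "ratio_of_means".
#' @param polymorphic_only restrict the means to loci polymorphic within the
#'   population (default FALSE: all loci enter Na/Ne/I/Ho/He means).
#' @return data.frame of class `pop_diversity`: population, n_loci, Na, Ne,
#'   I, Ho, He, uHe, F.
#' @export
summarize_population <- function(x, grouping = "species", diploids_only = TRUE,
                                 f_mode = c("mean_of_ratios", "ratio_of_means"),
                                 polymorphic_only = FALSE) {
  f_mode <- match.arg(f_mode)
  if (!inherits(x, "locus_diversity"))
    x <- locus_diversity(x, grouping, diploids_only)
  rows <- lapply(split(x, x$population), function(d) {
    if (polymorphic_only) d <- d[d$Na > 1L, , drop = FALSE]
    f <- if (f_mode == "mean_of_ratios") mean(d$F, na.rm = TRUE)
      else 1 - mean(d$Ho) / mean(d$He)
    data.frame(population = d$population[1L], n_loci = nrow(d),
               Na = mean(d$Na), Ne = mean(d$Ne), I = mean(d$I),
               Ho = mean(d$Ho), He = mean(d$He), uHe = mean(d$uHe),
               F = f, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pop_diversity", "data.frame")
  out
}

#' @export
print.pop_diversity <- function(x, digits = 3, ...) {
  cat("per-population diversity (across-locus means):\n")
  print.data.frame(cbind(x[1:2], round(x[3:9], digits)), row.names = FALSE)
  invisible(x)
}

# Weir-Cockerham (1984) variance components for one allele at one locus,
# two populations, vectorized over loci. p1/p2: allele frequency; h1/h2:
# frequency of heterozygotes carrying the allele; n1/n2: typed individuals.
wc_components <- function(p1, p2, h1, h2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Multilocus Weir-Cockerham theta from genotype-code matrices
#'
#' Fast path for biallelic loci: inputs are individuals x loci integer
#' matrices of allele copy counts (0/1/2, NA missing), one per population,
#' as produced by [simulate_genotypes()] or `genotype_codes()` on an
#' I/D-coded table. Identical to [pairwise_fst()] with `estimator = "wc84"`
#' on the corresponding table.
#'
#' @param g1,g2 genotype-code matrices with the same loci.
#' @return multilocus theta (ratio of summed variance components).
#' @export
wc_theta <- function(g1, g2) {
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  ok <- n1 > 0 & n2 > 0
  p1 <- colMeans(g1, na.rm = TRUE)[ok] / 2
  p2 <- colMeans(g2, na.rm = TRUE)[ok] / 2
  h1 <- colMeans(g1 == 1L, na.rm = TRUE)[ok]
  h2 <- colMeans(g2 == 1L, na.rm = TRUE)[ok]
  comp <- wc_components(p1, p2, h1, h2, n1[ok], n2[ok])
  # biallelic: both alleles contribute identical components; the ratio of
  # sums is unchanged, so one allele per locus suffices
  sum(comp$a) / sum(comp$a + comp$b + comp$c)
}

#' Pairwise Fst between two populations
#'
#' Default estimator is the Weir-Cockerham (1984) theta: per-locus,
#' per-allele variance components a (among populations), b (among
#' individuals within populations), c (within individuals), combined as
#' `sum(a) / sum(a + b + c)` across loci. Nei's Gst = (Ht - Hs)/Ht is the
#' secondary estimator. Handles multiallelic loci (components summed over
#' alleles).
#'
#' @param table a `genotype_table`.
#' @param popA,popB population labels.
#' @param grouping metadata column or label vector (default "species").
#' @param estimator "wc84" (default) or "nei_gst".
#' @param diploids_only exclude polyploids (default TRUE).
#' @return list of class `fst_result`: `estimator`, `fst`, `n_loci`,
#'   `per_locus` (marker, a, b, c for wc84; marker, hs, ht for nei_gst).
#' @export
pairwise_fst <- function(table, popA, popB, grouping = "species",
                         estimator = c("wc84", "nei_gst"),
                         diploids_only = TRUE) {
  estimator <- match.arg(estimator)
  idx <- popgen_accessions(table, diploids_only)
  pop <- pop_factor(table, grouping, idx)
  iA <- idx[!is.na(pop) & pop == popA]
  iB <- idx[!is.na(pop) & pop == popB]
  if (length(iA) == 0L || length(iB) == 0L)
    stop("population not found or empty: ", if (length(iA)) popB else popA)
  alA <- calls_allele_list(table$calls[iA, , drop = FALSE])
  alB <- calls_allele_list(table$calls[iB, , drop = FALSE])
  dim(alA) <- c(length(iA), ncol(table$calls))
  dim(alB) <- c(length(iB), ncol(table$calls))
  per <- list()
  for (j in seq_along(table$markers)) {
    aA <- alA[, j]; aB <- alB[, j]
    tA <- lengths(aA) > 0L; tB <- lengths(aB) > 0L
    n1 <- sum(tA); n2 <- sum(tB)
    if (n1 == 0L || n2 == 0L) next
    alleles <- sort(unique(c(unlist(aA[tA]), unlist(aB[tB]))))
    if (length(alleles) < 2L) {
      per[[length(per) + 1L]] <- data.frame(
        marker = table$markers[j], a = 0, b = 0, c = 0,
        hs = 0, ht = 0, stringsAsFactors = FALSE)
      next
    }
    cntA <- table(factor(unlist(aA[tA]), levels = alleles))
    cntB <- table(factor(unlist(aB[tB]), levels = alleles))
    pA <- as.numeric(cntA) / (2 * n1)
    pB <- as.numeric(cntB) / (2 * n2)
    a <- b <- cc <- 0
    for (u in seq_along(alleles)) {
      hA <- mean(vapply(aA[tA], function(x)
        alleles[u] %in% x && length(unique(x)) > 1L, logical(1)))
      hB <- mean(vapply(aB[tB], function(x)
        alleles[u] %in% x && length(unique(x)) > 1L, logical(1)))
      comp <- wc_components(pA[u], pB[u], hA, hB, n1, n2)
      a <- a + comp$a; b <- b + comp$b; cc <- cc + comp$c
    }
    pbar <- (n1 * pA + n2 * pB) / (n1 + n2)
    per[[length(per) + 1L]] <- data.frame(
      marker = table$markers[j], a = a, b = b, c = cc,
      hs = ((1 - sum(pA^2)) + (1 - sum(pB^2))) / 2,
      ht = 1 - sum(pbar^2), stringsAsFactors = FALSE)
  }
  if (length(per) == 0L)
    stop("populations ", popA, " and ", popB, " share no co-typed loci")
  per <- do.call(rbind, per)
  fst <- if (estimator == "wc84")
    sum(per$a) / sum(per$a + per$b + per$c)
  else (mean(per$ht) - mean(per$hs)) / mean(per$ht)
  structure(list(estimator = estimator, fst = fst, n_loci = nrow(per),
                 popA = popA, popB = popB, per_locus = per),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Fst (%s) %s vs %s over %d loci: %.4f\n",
              x$estimator, x$popA, x$popB, x$n_loci, x$fst))
  invisible(x)
}

#' Pairwise Fst matrix over all populations
#'
#' @inheritParams pairwise_fst
#' @param test also run [differentiation_test()] per pair and return combined
#'   p-values (default TRUE).
#' @return list of class `fst_matrix`: `fst` (lower-triangular matrix),
#'   `p_value` (same shape, NA when `test = FALSE`), `estimator`.
#' @export
fst_matrix <- function(table, grouping = "species",
                       estimator = c("wc84", "nei_gst"),
                       diploids_only = TRUE, test = TRUE) {
  estimator <- match.arg(estimator)
  idx <- popgen_accessions(table, diploids_only)
  pop <- pop_factor(table, grouping, idx)
  pops <- sort(unique(stats::na.omit(pop)))
  fst <- matrix(NA_real_, length(pops), length(pops),
                dimnames = list(pops, pops))
  pval <- fst
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    fst[i, j] <- pairwise_fst(table, pops[i], pops[j], grouping,
                              estimator, diploids_only)$fst
    if (test)
      pval[i, j] <- differentiation_test(table, pops[i], pops[j], grouping,
                                         diploids_only)$p_combined
  }
  structure(list(fst = fst, p_value = pval, estimator = estimator),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, digits = 3, ...) {
  cat("pairwise Fst (", x$estimator, "):\n", sep = "")
  print(round(x$fst, digits), na.print = "-")
  invisible(x)
}

#' Exact test of allelic differentiation between two populations
#'
#' Per biallelic locus, a two-sided Fisher exact test on the 2 x 2 table of
#' allele counts; across loci, Fisher's combining statistic
#' `-2 sum(log p)` against a chi-square with 2L degrees of freedom.
#' Loci monomorphic across both populations are skipped.
#'
#' @inheritParams pairwise_fst
#' @return list of class `differentiation_test`: `per_locus` (marker, p),
#'   `statistic`, `df`, `p_combined` (NA with a note when no polymorphic
#'   locus is available).
#' @export
differentiation_test <- function(table, popA, popB, grouping = "species",
                                 diploids_only = TRUE) {
  idx <- popgen_accessions(table, diploids_only)
  pop <- pop_factor(table, grouping, idx)
  iA <- idx[!is.na(pop) & pop == popA]
  iB <- idx[!is.na(pop) & pop == popB]
  rows <- list()
  for (j in seq_along(table$markers)) {
    aA <- unlist(calls_allele_list(table$calls[iA, j]))
    aB <- unlist(calls_allele_list(table$calls[iB, j]))
    alleles <- sort(unique(c(aA, aB)))
    if (length(alleles) < 2L) next
    if (length(alleles) > 2L) next  # exact 2x2 test is for biallelic loci
    m <- rbind(table(factor(aA, levels = alleles)),
               table(factor(aB, levels = alleles)))
    rows[[length(rows) + 1L]] <- data.frame(
      marker = table$markers[j],
      p = stats::fisher.test(m)$p.value, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(structure(list(per_locus = NULL, statistic = NA_real_, df = 0L,
                          p_combined = NA_real_,
                          note = "no polymorphic biallelic locus"),
                     class = "differentiation_test"))
  per <- do.call(rbind, rows)
  stat <- -2 * sum(log(per$p))
  df <- 2L * nrow(per)
  structure(list(per_locus = per, statistic = stat, df = df,
                 p_combined = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "differentiation_test")
}

#' @export
print.differentiation_test <- function(x, ...) {
  if (is.null(x$per_locus)) {
    cat("differentiation test: ", x$note, "\n", sep = "")
  } else {
    cat(sprintf("differentiation test over %d loci: chi2 = %.2f (df %d), combined p = %.3g\n",
                nrow(x$per_locus), x$statistic, x$df, x$p_combined))
  }
  invisible(x)
}

#' Hardy-Weinberg exact test for a biallelic locus
#'
#' Conditional exact test (Levene/Haldane): given the observed allele
#' counts, the p-value sums the probabilities of all heterozygote counts of
#' the same parity that are no more probable than the observed one.
#'
#' @param n_II,n_ID,n_DD genotype counts (non-negative).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact <- function(n_II, n_ID, n_DD) {
  counts <- c(n_II, n_ID, n_DD)
  if (any(is.na(counts)) || any(counts < 0))
    stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n < 1L) stop("need at least one typed individual")
  nA <- 2L * n_II + n_ID
  nB <- 2L * n_DD + n_ID
  rare <- min(nA, nB)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- vapply(hets, function(h) {
    homA <- (min(nA, nB) - h) / 2
    homB <- (max(nA, nB) - h) / 2
    lfactorial(n) - lfactorial(homA) - lfactorial(h) - lfactorial(homB) +
      h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2L * n)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_ID, hets)]
  sum(prob[prob <= obs * (1 + 1e-9)])
}

#' Hardy-Weinberg exact p-values across a table
#'
#' Runs [hwe_exact()] for every population x biallelic-coded marker with at
#' least one typed diploid.
#'
#' @param coded a `biallelic_recode` object (or I/D-coded `genotype_table`).
#' @param grouping metadata column or label vector (default "species").
#' @return matrix of p-values (population x marker), NA where untestable.
#' @export
hwe_test <- function(coded, grouping = "species") {
  tab <- if (inherits(coded, "biallelic_recode")) coded$table else coded
  codes <- genotype_codes(coded)
  idx <- popgen_accessions(tab, TRUE)
  pop <- pop_factor(tab, grouping, idx)
  pops <- sort(unique(stats::na.omit(pop)))
  out <- matrix(NA_real_, length(pops), ncol(codes),
                dimnames = list(pops, colnames(codes)))
  for (p in pops) {
    g <- codes[idx[!is.na(pop) & pop == p], , drop = FALSE]
    for (j in seq_len(ncol(codes))) {
      v <- g[, j]
      nII <- sum(v == 2L, na.rm = TRUE)
      nID <- sum(v == 1L, na.rm = TRUE)
      nDD <- sum(v == 0L, na.rm = TRUE)
      if (nII + nID + nDD >= 1L)
        out[p, j] <- hwe_exact(nII, nID, nDD)
    }
  }
  out
}

#' Genotype-frequency matrix for pattern analysis
#'
#' Rows are biallelic markers; columns are (population x genotype class)
#' frequencies over {I/I, I/D, D/D} among typed diploids, so each marker's
#' three entries per population sum to 1.
#'
#' @param coded a `biallelic_recode` object.
#' @param grouping metadata column or label vector (default "species").
#' @return numeric matrix markers x (population:class) with attribute
#'   `populations`.
#' @export
genotype_frequency_matrix <- function(coded, grouping = "species") {
  tab <- coded$table
  codes <- genotype_codes(coded)[, coded$biallelic_markers, drop = FALSE]
  idx <- popgen_accessions(tab, TRUE)
  pop <- pop_factor(tab, grouping, idx)
  pops <- sort(unique(stats::na.omit(pop)))
  cls <- c("II", "ID", "DD")
  out <- matrix(NA_real_, ncol(codes), length(pops) * 3L,
                dimnames = list(colnames(codes),
                                paste(rep(pops, each = 3L), cls, sep = ":")))
  for (k in seq_along(pops)) {
    g <- codes[idx[!is.na(pop) & pop == pops[k]], , drop = FALSE]
    n <- colSums(!is.na(g))
    out[, (k - 1L) * 3L + 1L] <- colSums(g == 2L, na.rm = TRUE) / n
    out[, (k - 1L) * 3L + 2L] <- colSums(g == 1L, na.rm = TRUE) / n
    out[, (k - 1L) * 3L + 3L] <- colSums(g == 0L, na.rm = TRUE) / n
  }
  attr(out, "populations") <- pops
  out
}

#' Classify markers into genotype-frequency patterns
#'
#' Agglomerative clustering of the genotype-frequency matrix (complete
#' linkage on Euclidean distances, the pheatmap defaults) cut at `k`
#' clusters. Clusters are annotated with their centroid and labelled with
#' roman numerals in a documented priority order: the cluster with the
#' highest mean heterozygote frequency is IV; among the rest, the cluster
#' maximizing homozygous-D minus homozygous-I frequency in the focal
#' population is I; the cluster with the lowest mean homozygous-D frequency
#' is II; remaining clusters are III, V, ... by increasing size.
#'
#' @param mat matrix from [genotype_frequency_matrix()].
#' @param k number of clusters (default 5).
#' @param focal_population population used for the pattern-I rule (default
#'   the largest-sample population, first column group otherwise).
#' @return list of class `pattern_assignment`: `assignment` (data.frame
#'   marker, cluster, label), `centroids`, `tree` (hclust).
#' @export
classify_patterns <- function(mat, k = 5, focal_population = NULL) {
  if (k > nrow(mat)) stop("k (", k, ") exceeds the number of markers (",
                          nrow(mat), ")")
  pops <- attr(mat, "populations")
  if (is.null(focal_population)) focal_population <- pops[1L]
  tree <- stats::hclust(stats::dist(mat, method = "euclidean"),
                        method = "complete")
  cluster <- stats::cutree(tree, k = k)
  centroids <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(mat[cluster == g, , drop = FALSE])))
  id_cols <- grep(":ID$", colnames(mat))
  dd_cols <- grep(":DD$", colnames(mat))
  focal_ii <- paste0(focal_population, ":II")
  focal_dd <- paste0(focal_population, ":DD")
  lab <- rep(NA_character_, k)
  remaining <- seq_len(k)
  pick <- function(scores, remaining) remaining[which.max(scores[remaining])]
  if (k >= 2L) {
    g4 <- pick(rowMeans(centroids[, id_cols, drop = FALSE]), remaining)
    lab[g4] <- "IV"; remaining <- setdiff(remaining, g4)
    g1 <- pick(centroids[, focal_dd] - centroids[, focal_ii], remaining)
    lab[g1] <- "I"; remaining <- setdiff(remaining, g1)
    if (length(remaining)) {
      g2 <- remaining[which.min(rowMeans(centroids[, dd_cols, drop = FALSE])[remaining])]
      lab[g2] <- "II"; remaining <- setdiff(remaining, g2)
    }
    rest_labels <- setdiff(as.character(utils::as.roman(seq_len(k + 2L))),
                           c("I", "II", "IV"))
    sizes <- table(factor(cluster, levels = seq_len(k)))
    remaining <- remaining[order(sizes[remaining])]
    lab[remaining] <- rest_labels[seq_along(remaining)]
  } else lab <- "I"
  assignment <- data.frame(marker = rownames(mat),
                           cluster = unname(cluster),
                           label = lab[cluster], stringsAsFactors = FALSE)
  rownames(centroids) <- lab
  structure(list(assignment = assignment, centroids = centroids, tree = tree,
                 k = k, focal_population = focal_population),
            class = "pattern_assignment")
}

#' @export
print.pattern_assignment <- function(x, ...) {
  cat("genotype-frequency patterns (k = ", x$k, "):\n", sep = "")
  print(table(x$assignment$label))
  invisible(x)
}
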