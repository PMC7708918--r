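# Independent oracles used across the suite. Each re-derives the quantity
# by brute force or an alternative route, never by calling the code under
# test.

# Exact Hardy-Weinberg null distribution by brute-force allele placement:
# all choose(2n, nA) placements of the A alleles into 2n ordered slots are
# equally likely under the conditional null; slots are paired consecutively
# into individuals. Returns the exact p-value for the observed het count.
hwe_enum_oracle <- function(n_II, n_ID, n_DD) {
  n <- n_II + n_ID + n_DD
  nA <- 2L * n_II + n_ID
  slots <- 2L * n
  if (nA == 0L || nA == slots) return(1)
  placements <- utils::combn(slots, nA)
  # slots pair consecutively into individuals; combn columns are sorted, so
  # an individual holds two A alleles iff adjacent rows share its pair id
  pairs <- ceiling(placements / 2)
  n_homA <- if (nA >= 2L)
    colSums(pairs[-1L, , drop = FALSE] == pairs[-nA, , drop = FALSE])
  else rep(0L, ncol(placements))
  het_of <- nA - 2L * n_homA
  tab <- table(het_of) / ncol(placements)
  p_obs <- tab[[as.character(n_ID)]]
  sum(tab[tab <= p_obs * (1 + 1e-9)])
}

# Weir-Cockerham theta via the independent mean-squares (ANOVA) route for
# two populations at biallelic loci given 0/1/2 genotype-code matrices.
wc_theta_ms_oracle <- function(g1, g2) {
  num <- den <- 0
  for (j in seq_len(ncol(g1))) {
    x1 <- g1[, j][!is.na(g1[, j])] / 2  # individual allele frequencies
    x2 <- g2[, j][!is.na(g2[, j])] / 2
    n1 <- length(x1); n2 <- length(x2)
    if (n1 == 0 || n2 == 0) next
    h1 <- mean(g1[, j] == 1L, na.rm = TRUE)
    h2 <- mean(g2[, j] == 1L, na.rm = TRUE)
    p1 <- mean(x1); p2 <- mean(x2)
    nt <- n1 + n2
    nc <- (nt - (n1^2 + n2^2) / nt)  # r - 1 = 1
    pbar <- (n1 * p1 + n2 * p2) / nt
    hbar <- (n1 * h1 + n2 * h2) / nt
    # mean squares for allele counts grouped by population / individual
    MSP <- (2 * n1 * (p1 - pbar)^2 + 2 * n2 * (p2 - pbar)^2) / 1
    MSI <- (2 * (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) - hbar * nt / 2) /
      (nt - 2)
    MSG <- hbar / 2
    a <- (MSP - MSI) / (2 * nc)
    b <- (MSI - MSG) / 2
    cc <- MSG
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Exhaustive max-min-gap over all k-subsets of candidate positions.
best_min_gap_oracle <- function(pos, k) {
  pos <- sort(pos)
  if (k <= 1L) return(Inf)
  subsets <- utils::combn(length(pos), k)
  gaps <- apply(subsets, 2L, function(ix) min(diff(pos[ix])))
  max(gaps)
}

# O(n^2) multiplex conflict checker: within one (group, dye), padded product
# intervals must be pairwise disjoint; group sizes within bound.
multiplex_conflict_oracle <- function(panel, size_gap = 20,
                                      max_group_size = 24) {
  assigned <- panel[!is.na(panel$multiplex_group), , drop = FALSE]
  if (any(table(assigned$multiplex_group) > max_group_size)) return(FALSE)
  lo <- pmin(assigned$size_I, assigned$size_D)
  hi <- pmax(assigned$size_I, assigned$size_D)
  for (i in seq_len(nrow(assigned))) {
    for (j in seq_len(i - 1L)) {
      if (assigned$multiplex_group[i] != assigned$multiplex_group[j]) next
      if (assigned$dye[i] != assigned$dye[j]) next
      if (lo[i] - size_gap < hi[j] && hi[i] + size_gap > lo[j]) return(FALSE)
    }
  }
  TRUE
}

# Brute-force complete-linkage criterion: minimal achievable maximum
# intra-cluster diameter over all k-partitions (exhaustive over labelings).
best_max_diameter_oracle <- function(mat, k) {
  n <- nrow(mat)
  d <- as.matrix(dist(mat))
  labelings <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (r in seq_len(nrow(labelings))) {
    lab <- as.integer(labelings[r, ])
    if (length(unique(lab)) != k) next
    diam <- max(vapply(seq_len(k), function(g) {
      ix <- which(lab == g)
      if (length(ix) < 2L) 0 else max(d[ix, ix])
    }, numeric(1)))
    best <- min(best, diam)
  }
  best
}

max_diameter_of <- function(mat, labels) {
  d <- as.matrix(dist(mat))
  max(vapply(unique(labels), function(g) {
    ix <- which(labels == g)
    if (length(ix) < 2L) 0 else max(d[ix, ix])
  }, numeric(1)))
}
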