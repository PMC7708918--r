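# Diversity statistics, Weir-Cockerham theta, exact tests, genotype
# frequency patterns.

test_that("allele frequencies equal a brute-force tally", {
  calls <- rbind(A = "I/I", B = "I/D", C = "D/D")
  colnames(calls) <- "M1"
  tab <- genotype_table(calls, data.frame(accession_id = c("A", "B", "C"),
                                          species = "sp"))
  af <- allele_frequencies(tab)
  expect_equal(unname(af$freq[["sp"]][["M1"]][["I"]]), 0.5)
  expect_equal(unname(af$n_typed["sp", "M1"]), 3L)
  # all missing at a marker -> flagged (empty frequency vector)
  calls2 <- rbind(A = c("I/I", "-"), B = c("I/D", "-"))
  colnames(calls2) <- c("M1", "M2")
  tab2 <- genotype_table(calls2, data.frame(accession_id = c("A", "B"),
                                            species = "sp"))
  af2 <- allele_frequencies(tab2)
  expect_length(af2$freq[["sp"]][["M2"]], 0L)
  expect_equal(unname(af2$n_typed["sp", "M2"]), 0L)
  # random table vs independent tally
  tab3 <- random_coded_table(n_per_pop = 12, L = 6, seed = 17)
  af3 <- allele_frequencies(tab3)
  for (m in tab3$markers) {
    cells <- tab3$calls[tab3$accessions$species == "popA", m]
    alleles <- unlist(strsplit(cells[!is.na(cells)], "/"))
    expect_equal(unname(af3$freq[["popA"]][[m]]["I"]),
                 unname(mean(alleles == "I")), tolerance = 1e-12)
  }
})

test_that("per-locus diversity matches closed forms and invariants", {
  calls <- rbind(A = c("I/D", "I/I"), B = c("I/D", "I/I"),
                 C = c("I/D", "I/I"), D = c("I/D", "I/I"))
  colnames(calls) <- c("M1", "M2")
  tab <- genotype_table(calls, data.frame(accession_id = LETTERS[1:4],
                                          species = "sp"))
  ld <- locus_diversity(tab)
  m1 <- ld[ld$marker == "M1", ]
  expect_equal(m1$He, 0.5)
  expect_equal(m1$Ne, 2)
  expect_equal(m1$I, log(2))
  expect_equal(m1$Ho, 1)
  expect_equal(m1$F, (0.5 - 1) / 0.5)
  m2 <- ld[ld$marker == "M2", ]  # monomorphic
  expect_equal(m2$Na, 1L)
  expect_equal(m2$Ne, 1)
  expect_equal(m2$He, 0)
  expect_equal(m2$I, 0)
  expect_true(is.na(m2$F))
  # biallelic identity Ne = 1/(1 - He) on random tables
  tab3 <- random_coded_table(n_per_pop = 20, L = 10, seed = 2)
  ld3 <- locus_diversity(tab3)
  expect_equal(ld3$Ne, 1 / (1 - ld3$He), tolerance = 1e-12)
  # bounds
  expect_true(all(ld3$Ho >= 0 & ld3$Ho <= 1))
  expect_true(all(ld3$He >= 0 & ld3$He < 1))
  expect_true(all(ld3$Ne <= ld3$Na + 1e-12))
  expect_true(all(ld3$I >= 0))
  expect_true(all(is.na(ld3$F) | (ld3$F >= -1 & ld3$F <= 1)))
})

test_that("population summaries are unweighted across-locus means with both F modes", {
  tab <- random_coded_table(n_per_pop = 20, L = 12, seed = 4)
  ld <- locus_diversity(tab)
  s_mr <- summarize_population(ld)
  s_rm <- summarize_population(ld, f_mode = "ratio_of_means")
  a <- ld[ld$population == "popA", ]
  expect_equal(s_mr$He[s_mr$population == "popA"], mean(a$He))
  expect_equal(s_mr$F[s_mr$population == "popA"], mean(a$F, na.rm = TRUE))
  expect_equal(s_rm$F[s_rm$population == "popA"], 1 - mean(a$Ho) / mean(a$He))
})

test_that("theta is 1 for fixed alternative alleles and ~0 for identical frequencies", {
  calls <- rbind(matrix("I/I", 20, 5), matrix("D/D", 20, 5))
  colnames(calls) <- sprintf("M%d", 1:5)
  tab <- genotype_table(calls, data.frame(
    accession_id = sprintf("S%02d", 1:40),
    species = rep(c("A", "B"), each = 20)))
  expect_equal(pairwise_fst(tab, "A", "B")$fst, 1)
  # identical frequencies, n = 200 per population: |theta| < 0.02
  set.seed(10)
  thetas <- replicate(10, {
    p <- runif(50, 0.2, 0.8)
    g1 <- simulate_genotypes(p, 200)
    g2 <- simulate_genotypes(p, 200)
    wc_theta(g1, g2)
  })
  expect_true(all(abs(thetas) < 0.02))
})

test_that("theta from the table equals the independent mean-squares route", {
  tab <- random_coded_table(n_per_pop = 25, L = 15, seed = 12)
  got <- pairwise_fst(tab, "popA", "popB")$fst
  codes <- gikit:::genotype_codes(tab)
  g1 <- codes[tab$accessions$species == "popA", , drop = FALSE]
  g2 <- codes[tab$accessions$species == "popB", , drop = FALSE]
  expect_equal(got, wc_theta_ms_oracle(g1, g2), tolerance = 1e-10)
  # the fast matrix path agrees with the general multiallelic path
  expect_equal(got, wc_theta(g1, g2), tolerance = 1e-10)
  # Nei Gst alternative is available and sane
  gst <- pairwise_fst(tab, "popA", "popB", estimator = "nei_gst")$fst
  expect_true(is.finite(gst) && gst < 1)
})

test_that("theta handles missing data and multiallelic loci", {
  set.seed(33)
  tab <- random_coded_table(n_per_pop = 15, L = 8, seed = 33)
  calls <- tab$calls
  calls[sample(length(calls), 20)] <- NA
  # add a triallelic marker
  tri <- sample(c("100/100", "100/150", "150/200", "200/200"), 30, TRUE)
  calls <- cbind(calls, M_tri = tri)
  tab2 <- genotype_table(calls, tab$accessions)
  f <- pairwise_fst(tab2, "popA", "popB")
  expect_true(is.finite(f$fst))
  expect_equal(f$n_loci, 9L)
})

test_that("differentiation exact test matches hypergeometric enumeration", {
  # identical allele counts -> p = 1 per locus, combined p = 1
  calls <- rbind(matrix("I/D", 10, 3), matrix("I/D", 10, 3))
  colnames(calls) <- sprintf("M%d", 1:3)
  tab <- genotype_table(calls, data.frame(
    accession_id = sprintf("S%02d", 1:20),
    species = rep(c("A", "B"), each = 10)))
  dt <- differentiation_test(tab, "A", "B")
  expect_equal(dt$per_locus$p, rep(1, 3), tolerance = 1e-9)
  expect_equal(dt$p_combined, 1, tolerance = 1e-6)
  # 20 x I/I vs 20 x D/D at one locus: p equals the enumerated tail
  calls2 <- cbind(M1 = c(rep("I/I", 20), rep("D/D", 20)))
  tab2 <- genotype_table(calls2, data.frame(
    accession_id = sprintf("S%02d", 1:40),
    species = rep(c("A", "B"), each = 20)))
  p_got <- differentiation_test(tab2, "A", "B")$per_locus$p
  # enumeration: 2x2 table with margins (40, 40) x (40, 40); two-sided
  # Fisher p sums dhyper values <= that of the observed table
  dh <- dhyper(0:40, 40, 40, 40)
  p_oracle <- sum(dh[dh <= dh[41] * (1 + 1e-7)])
  expect_equal(p_got, p_oracle, tolerance = 1e-9)
  # Fisher-combined p decreases monotonically as a per-locus p decreases
  combine <- function(ps) pchisq(-2 * sum(log(ps)), 2 * length(ps),
                                 lower.tail = FALSE)
  ps <- c(0.5, 0.2, 0.8)
  expect_lt(combine(c(0.1, 0.2, 0.8)), combine(ps))
})

test_that("hwe_exact agrees with brute-force enumeration and handles edge cases", {
  expect_equal(hwe_exact(5, 0, 0), 1)      # monomorphic: single outcome
  expect_equal(hwe_exact(1, 0, 1), hwe_enum_oracle(1, 0, 1))
  for (tr in list(c(3, 1, 2), c(0, 5, 0), c(2, 2, 2), c(4, 0, 4))) {
    expect_equal(hwe_exact(tr[1], tr[2], tr[3]),
                 hwe_enum_oracle(tr[1], tr[2], tr[3]),
                 tolerance = 1e-9,
                 info = paste(tr, collapse = ","))
  }
  expect_error(hwe_exact(-1, 0, 1), "non-negative")
  expect_error(hwe_exact(0, 0, 0), "at least one")
  # p in (0, 1]
  set.seed(1)
  for (i in 1:20) {
    tr <- rmultinom(1, 12, c(0.3, 0.4, 0.3))
    p <- hwe_exact(tr[1], tr[2], tr[3])
    expect_true(p > 0 && p <= 1)
  }
})

test_that("hwe_test p-values are roughly uniform under HWE sampling", {
  set.seed(8)
  p <- runif(400, 0.2, 0.8)
  codes <- matrix(rbinom(50 * 400, 2, rep(p, each = 50)), 50, 400)
  pv <- apply(codes, 2L, function(v)
    hwe_exact(sum(v == 2), sum(v == 1), sum(v == 0)))
  # exact-test p-values are super-uniform: type-I error <= nominal
  expect_lte(mean(pv <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
  expect_gt(mean(pv <= 0.5), 0.2)  # but not degenerate
})

test_that("genotype frequency matrix rows sum to one per population block", {
  tab <- random_coded_table(n_per_pop = 25, L = 10, seed = 6)
  rec <- recode_biallelic(tab)
  gm <- genotype_frequency_matrix(rec)
  pops <- attr(gm, "populations")
  for (p in pops) {
    block <- gm[, paste(p, c("II", "ID", "DD"), sep = ":")]
    expect_equal(unname(rowSums(block)), rep(1, nrow(gm)))
  }
})

test_that("pattern classification recovers planted structure and matches the exhaustive partition", {
  # k groups of identical rows -> perfect recovery
  centers <- matrix(c(0.7, 0.2, 0.1, 0.1, 0.8, 0.1, 0.1, 0.1, 0.8), 3,
                    byrow = TRUE)
  mat <- centers[rep(1:3, each = 4), ]
  rownames(mat) <- sprintf("M%02d", 1:12)
  colnames(mat) <- paste("sp", c("II", "ID", "DD"), sep = ":")
  attr(mat, "populations") <- "sp"
  pa <- classify_patterns(mat, k = 3)
  expect_equal(length(unique(pa$assignment$label)), 3L)
  expect_true(all(tapply(pa$assignment$cluster,
                         rep(1:3, each = 4),
                         function(x) length(unique(x))) == 1L))
  # 8-marker toy: cutree partition attains the exhaustive-search optimal
  # maximum intra-cluster diameter (complete-linkage criterion)
  set.seed(14)
  toy <- centers[c(1, 1, 1, 2, 2, 3, 3, 3), ] +
    matrix(rnorm(24, sd = 0.02), 8, 3)
  rownames(toy) <- sprintf("T%d", 1:8)
  colnames(toy) <- colnames(mat)
  attr(toy, "populations") <- "sp"
  pa2 <- classify_patterns(toy, k = 3)
  expect_equal(max_diameter_of(toy, pa2$assignment$cluster),
               best_max_diameter_oracle(toy, 3), tolerance = 1e-12)
  expect_error(classify_patterns(toy, k = 99), "exceeds")
})

test_that("pattern labels follow the documented priority rules", {
  # construct centroids: one heterozygote-dominated cluster (IV), one with
  # high focal DD / low focal II (I), one with rare DD (II)
  rows <- rbind(
    c(0.07, 0.21, 0.72),  # pattern-I-like (low II, very high DD in focal)
    c(0.06, 0.22, 0.72),
    c(0.10, 0.80, 0.10),  # pattern-IV-like (heterozygote excess)
    c(0.12, 0.78, 0.10),
    c(0.60, 0.38, 0.02),  # pattern-II-like (homozygous D rare)
    c(0.58, 0.40, 0.02),
    c(0.33, 0.33, 0.34),  # undistorted
    c(0.30, 0.36, 0.34))
  mat <- rows
  rownames(mat) <- sprintf("M%d", 1:8)
  colnames(mat) <- paste("M_domestica", c("II", "ID", "DD"), sep = ":")
  attr(mat, "populations") <- "M_domestica"
  pa <- classify_patterns(mat, k = 4, focal_population = "M_domestica")
  lab <- pa$assignment$label
  expect_equal(lab[1:2], c("I", "I"))
  expect_equal(lab[3:4], c("IV", "IV"))
  expect_equal(lab[5:6], c("II", "II"))
  expect_equal(lab[7:8], c("III", "III"))
})
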