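# Mendelian-exclusion parentage: locus rules, hypothesis scoring, scans.

test_that("duo and trio locus rules follow Mendelian transmission", {
  expect_equal(duo_compatible("I/D", "D/D"), "compatible")
  expect_equal(duo_compatible("I/I", "D/D"), "incompatible")
  expect_equal(duo_compatible("I/D", NA), "uninformative")
  expect_equal(trio_compatible("I/D", "I/I", "D/D"), "compatible")
  expect_equal(trio_compatible("D/D", "I/I", "I/D"), "incompatible")
  expect_equal(trio_compatible("I/D", "I/D", "I/D"), "compatible")
  expect_equal(trio_compatible("I/D", NA, "I/D"), "uninformative")
})

test_that("trio compatibility is symmetric and implies duo compatibility", {
  set.seed(7)
  gts <- c("I/I", "I/D", "D/D", NA)
  for (i in 1:50) {
    o <- sample(gts, 1); p1 <- sample(gts, 1); p2 <- sample(gts, 1)
    expect_identical(trio_compatible(o, p1, p2), trio_compatible(o, p2, p1))
    if (identical(trio_compatible(o, p1, p2), "compatible")) {
      expect_equal(duo_compatible(o, p1), "compatible")
      expect_equal(duo_compatible(o, p2), "compatible")
    }
  }
  # the converse fails: both duos compatible, trio incompatible
  expect_equal(duo_compatible("I/D", "I/I"), "compatible")
  expect_equal(trio_compatible("I/D", "I/I", "I/I"), "incompatible")
})

# table where offspring OFF mismatches parents P1 x P2 at exactly k loci
mismatch_table <- function(k, L = 102) {
  p1 <- rep("I/I", L)
  p2 <- rep("D/D", L)
  off <- rep("I/D", L)
  off[seq_len(k)] <- "I/I"  # impossible: one D must come from P2
  calls <- rbind(OFF = off, P1 = p1, P2 = p2)
  colnames(calls) <- sprintf("M%03d", seq_len(L))
  genotype_table(calls, data.frame(accession_id = c("OFF", "P1", "P2")))
}

test_that("acceptance needs both confidence AND mismatch threshold", {
  v0 <- evaluate_hypothesis(mismatch_table(0), "OFF", "P1", "P2")
  expect_equal(v0$confidence, 1)
  expect_true(v0$accepted)
  v1 <- evaluate_hypothesis(mismatch_table(1), "OFF", "P1", "P2")
  expect_equal(v1$confidence, 101 / 102)
  expect_true(v1$accepted)   # C ~ 0.9902 > 0.98 and 1 <= threshold
  v2 <- evaluate_hypothesis(mismatch_table(2), "OFF", "P1", "P2")
  expect_equal(v2$confidence, 100 / 102)
  expect_false(v2$accepted)  # C ~ 0.9804 > 0.98 but 2 mismatches > threshold
  expect_equal(v2$n_mismatch, 2L)
})

test_that("verdicts handle duos, undefined cases and argument errors", {
  tab <- mismatch_table(0, L = 10)
  duo <- evaluate_hypothesis(tab, "OFF", "P1")
  expect_equal(duo$mode, "duo")
  expect_true(duo$accepted)
  # no informative locus -> undefined verdict
  calls <- rbind(O = c(NA, NA), P = c("I/I", "D/D"))
  colnames(calls) <- c("M1", "M2")
  tab2 <- genotype_table(calls, data.frame(accession_id = c("O", "P")))
  v <- evaluate_hypothesis(tab2, "O", "P")
  expect_true(v$undefined)
  expect_true(is.na(v$accepted))
  expect_error(evaluate_hypothesis(tab, "OFF", "OFF"), "own parent")
  expect_error(evaluate_hypothesis(tab, "OFF", "nope"), "unknown")
})

test_that("the vectorized scan agrees with per-hypothesis evaluation", {
  col <- assemble_collection(sim_config(
    seed = 23, n_markers = 30,
    species = data.frame(name = "sp", n = 20L, phi = 0.05),
    n_offspring = 4L, n_misdocumented = 0L,
    clone_spec = data.frame(lineage = "wt", n_clones = 2L, mu = 0.01),
    missing_rate = 0.03,
    name_error_spec = c(synonym_pairs = 0L, homonym_pairs = 0L,
                        replicate_pairs = 0L),
    n_tetraploid_duplicates = 0L))
  tab <- col$table
  scan <- scan_parentage(tab, mode = "trio", collapse_clones = FALSE,
                         min_confidence = 0, threshold = 30)
  # every reported row must match evaluate_hypothesis exactly
  for (r in seq_len(min(nrow(scan), 40L))) {
    v <- evaluate_hypothesis(tab, scan$offspring[r], scan$parent1[r],
                             scan$parent2[r], min_confidence = 0,
                             threshold = 30)
    expect_equal(scan$n_informative[r], v$n_informative)
    expect_equal(scan$n_mismatch[r], v$n_mismatch)
  }
})

test_that("scans recover simulated pedigrees and reject absent parents", {
  col <- assemble_collection(sim_config(
    seed = 29, n_markers = 100,
    species = data.frame(name = "sp", n = 40L, phi = 0.05),
    n_offspring = 10L, n_misdocumented = 2L,
    clone_spec = data.frame(lineage = "wt", n_clones = 2L, mu = 0),
    name_error_spec = c(synonym_pairs = 0L, homonym_pairs = 0L,
                        replicate_pairs = 0L),
    n_tetraploid_duplicates = 0L))
  tab <- col$table
  truth <- col$truth$accessions
  off <- truth$accession_id[!is.na(truth$true_parent1)]
  scan <- scan_parentage(tab, focal = off, mode = "trio")
  for (o in off) {
    hits <- scan[scan$offspring == o, ]
    expect_equal(nrow(hits), 1L)
    tp <- sort(c(truth$true_parent1[truth$accession_id == o],
                 truth$true_parent2[truth$accession_id == o]))
    expect_equal(sort(c(hits$parent1, hits$parent2)), tp)
  }
  # documented parents are evaluated alongside; the mis-documented ones fail
  doc <- attr(scan, "documented")
  mis <- truth$accession_id[!is.na(truth$true_parent2) &
                              tab$accessions$parent2[
                                match(truth$accession_id,
                                      tab$accessions$accession_id)] !=
                              truth$true_parent2]
  mis <- mis[!is.na(mis)]
  expect_true(length(mis) == 2L)
  for (o in mis) expect_false(doc[[o]]$accepted)
  # parents absent from the pool: no trio accepted
  pool_without_parents <- setdiff(tab$accessions$accession_id,
                                  c(off, unique(c(truth$true_parent1,
                                                  truth$true_parent2))))
  scan2 <- scan_parentage(tab, focal = off[1:3], pool = pool_without_parents,
                          mode = "trio")
  expect_equal(nrow(scan2), 0L)
})

test_that("clone collapse prevents interchangeable sport parents", {
  col <- assemble_collection(sim_config(
    seed = 41, n_markers = 60,
    species = data.frame(name = "sp", n = 30L, phi = 0.05),
    n_offspring = 0L, n_misdocumented = 0L,
    clone_spec = data.frame(lineage = "wt", n_clones = 5L, mu = 0),
    name_error_spec = c(synonym_pairs = 0L, homonym_pairs = 0L,
                        replicate_pairs = 0L),
    n_tetraploid_duplicates = 0L))
  tab <- recode_biallelic(col$table)$table  # uniform I/D coding
  wt_id <- tab$accessions$accession_id[tab$accessions$name == "wt"]
  other <- setdiff(tab$accessions$accession_id,
                   c(wt_id, col$truth$accessions$accession_id[
                     !is.na(col$truth$accessions$clone_family)]))[1]
  codes <- gikit:::genotype_codes(tab)
  off_codes <- simulate_offspring(codes[wt_id, ], codes[other, ], 1)[1, ]
  calls <- rbind(tab$calls,
                 NEW = c("D/D", "I/D", "I/I")[off_codes + 1L])
  meta <- rbind(tab$accessions[, c("accession_id", "name", "species", "ploidy",
                                   "parent1", "parent2", "lineage_group")],
                data.frame(accession_id = "NEW", name = "NEW", species = "sp",
                           ploidy = 2L, parent1 = NA, parent2 = NA,
                           lineage_group = NA))
  tab2 <- genotype_table(calls, meta)
  scan <- scan_parentage(tab2, focal = "NEW", mode = "trio")
  # with collapse, the wt clone family contributes one representative, so the
  # accepted hypotheses do not multiply across identical sports
  expect_true(nrow(scan) >= 1L)
  reps <- unique(c(scan$parent1, scan$parent2))
  fam <- c(wt_id, col$truth$accessions$accession_id[
    !is.na(col$truth$accessions$clone_family)])
  expect_lte(sum(reps %in% fam), 1L)
})

test_that("random non-parent trio pass rate falls with marker count", {
  set.seed(55)
  pass_rate <- vapply(c(10, 25, 50, 100), function(L) {
    p <- runif(L, 0.3, 0.7)
    n <- 30
    codes <- simulate_genotypes(p, n)
    calls <- matrix(c("D/D", "I/D", "I/I")[codes + 1L], n, L)
    colnames(calls) <- sprintf("M%03d", seq_len(L))
    tab <- genotype_table(calls, data.frame(
      accession_id = sprintf("S%02d", seq_len(n))))
    hits <- 0L; total <- 0L
    for (i in 1:40) {
      trio <- sample(n, 3)
      v <- evaluate_hypothesis(tab, sprintf("S%02d", trio[1]),
                               sprintf("S%02d", trio[2]),
                               sprintf("S%02d", trio[3]))
      total <- total + 1L
      if (isTRUE(v$accepted)) hits <- hits + 1L
    }
    hits / total
  }, numeric(1))
  expect_true(all(diff(pass_rate) <= 0))
  expect_lt(pass_rate[4], pass_rate[1] + 1e-9)
  expect_equal(pass_rate[4], 0)
})
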