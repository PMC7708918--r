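# Identity signatures, duplicate groups, name classes, bud sports, QR.

test_that("signature string follows the documented format and is order-invariant", {
  calls <- rbind(A = c("236/248", "-"))
  colnames(calls) <- c("C01001", "C01002")
  tab <- genotype_table(calls, data.frame(accession_id = "A"))
  expect_equal(unname(signature_strings(tab)),
               "C01001=236|248;C01002=?")
  # column order does not matter
  tab2 <- genotype_table(calls[, 2:1, drop = FALSE],
                         data.frame(accession_id = "A"))
  expect_identical(signature_of(tab, "A")$digest, signature_of(tab2, "A")$digest)
  # one allele difference changes the digest
  calls3 <- calls; calls3[1, 1] <- "236/236"
  tab3 <- genotype_table(calls3, data.frame(accession_id = "A"))
  expect_false(identical(signature_of(tab, "A")$digest,
                         signature_of(tab3, "A")$digest))
  expect_error(signature_strings(tab[, integer(0)]), "empty marker panel")
})

test_that("grouping partitions accessions and its summary counts are consistent", {
  tab <- random_coded_table(n_per_pop = 10, L = 30, seed = 21)
  g <- group_by_signature(tab)
  s <- g$summary
  expect_equal(sum(lengths(g$groups)), unname(s["n_accessions"]))
  expect_equal(unname(s["n_distinct"]),
               unname(s["n_singleton"] + s["n_shared_groups"]))
  expect_equal(unname(s["n_singleton"] + s["n_in_shared"]),
               unname(s["n_accessions"]))
  # 5 distinct accessions -> 5 singleton groups
  small <- tab[1:5, ]
  expect_equal(unname(group_by_signature(small)$summary["n_singleton"]), 5L)
})

test_that("planted clone families at mu = 0 form exactly one group each", {
  col <- assemble_collection(sim_config(
    seed = 13, n_markers = 40,
    species = data.frame(name = "sp", n = 60L, phi = 0.05),
    n_offspring = 0L, n_misdocumented = 0L,
    clone_spec = data.frame(lineage = c("wtA", "wtB", "wtC"),
                            n_clones = c(6L, 4L, 3L), mu = 0),
    name_error_spec = c(synonym_pairs = 0L, homonym_pairs = 0L,
                        replicate_pairs = 0L),
    n_tetraploid_duplicates = 0L))
  g <- group_by_signature(col$table)
  truth <- col$truth$accessions
  shared <- g$groups[lengths(g$groups) > 1L]
  expect_equal(length(shared), 3L)
  for (fam in c("wtA", "wtB", "wtC")) {
    members <- truth$accession_id[!is.na(truth$clone_family) &
                                    truth$clone_family == fam]
    wt <- col$table$accessions$accession_id[col$table$accessions$name == fam]
    hit <- vapply(shared, function(gr) all(c(members, wt) %in% gr), logical(1))
    expect_equal(sum(hit), 1L)
  }
})

test_that("name classification follows replicate > synonym > homonym precedence", {
  calls <- rbind(A = "1/2", B = "1/2", C = "1/2", D = "1/1", E = "3/3", F = "1/3")
  colnames(calls) <- "M1"
  tab <- genotype_table(calls, data.frame(
    accession_id = c("A", "B", "C", "D", "E", "F"),
    name = c("Fuji", "Fuji", "Nai", "Gala", "Gala", "Pingguo")))
  g <- group_by_signature(tab)
  cls <- classify_names(g, tab$accessions)
  expect_equal(unname(cls$labels[c("A", "B")]), c("replicate", "replicate"))
  expect_equal(unname(cls$labels["C"]), "synonym")  # shares signature, new name
  expect_equal(unname(cls$labels[c("D", "E")]), c("homonym", "homonym"))
  expect_equal(unname(cls$labels["F"]), "unique")
})

test_that("planted name errors are recovered exactly from the simulator", {
  col <- assemble_collection(sim_config(
    seed = 31, n_markers = 50,
    species = data.frame(name = c("sp1", "sp2"), n = c(80L, 30L),
                         phi = c(0.05, 0.08)),
    n_offspring = 0L, n_misdocumented = 0L,
    clone_spec = data.frame(lineage = "wt", n_clones = 3L, mu = 0.01),
    name_error_spec = c(synonym_pairs = 5L, homonym_pairs = 4L,
                        replicate_pairs = 3L),
    n_tetraploid_duplicates = 0L))
  g <- group_by_signature(col$table)
  cls <- classify_names(g, col$table$accessions)
  planted <- col$truth$planted
  # every planted synonym accession and its source are labelled synonym
  for (i in seq_len(nrow(planted$synonyms))) {
    pair <- c(planted$synonyms$accession_id[i], planted$synonyms$duplicates[i])
    expect_equal(unname(cls$labels[pair]), c("synonym", "synonym"))
  }
  for (i in seq_len(nrow(planted$replicates))) {
    pair <- c(planted$replicates$accession_id[i], planted$replicates$duplicates[i])
    expect_equal(unname(cls$labels[pair]), c("replicate", "replicate"))
  }
  for (i in seq_len(nrow(planted$homonyms))) {
    pair <- c(planted$homonyms$accession_a[i], planted$homonyms$accession_b[i])
    expect_equal(unname(cls$labels[pair]), c("homonym", "homonym"))
  }
})

test_that("wildcard mode reports, but never merges, missing-compatible pairs", {
  calls <- rbind(A = c("1/2", "3/4"), B = c("1/2", "-"), C = c("5/5", "3/4"))
  colnames(calls) <- c("M1", "M2")
  tab <- genotype_table(calls, data.frame(accession_id = c("A", "B", "C")))
  g <- group_by_signature(tab, match_mode = "wildcard_report")
  expect_equal(unname(g$summary["n_distinct"]), 3L)  # not merged
  expect_equal(nrow(g$possible_duplicates), 1L)
  expect_setequal(unlist(g$possible_duplicates[1, ]), c("A", "B"))
})

test_that("sport discriminability matches an independent recount", {
  # all-identical clones: none distinguishable, one subgroup
  col0 <- assemble_collection(sim_config(
    seed = 5, n_markers = 30,
    species = data.frame(name = "sp", n = 20L, phi = 0.05),
    n_offspring = 0L, n_misdocumented = 0L,
    clone_spec = data.frame(lineage = "wt", n_clones = 8L, mu = 0),
    name_error_spec = c(synonym_pairs = 0L, homonym_pairs = 0L,
                        replicate_pairs = 0L),
    n_tetraploid_duplicates = 0L))
  r0 <- sport_discrimination(col0$table)
  expect_equal(r0$n_distinguishable, 0L)
  expect_equal(r0$percent, 0)
  expect_equal(r0$n_subgroups, 1L)
  # somatic rate 0.05: percent equals a direct recount over signatures
  col <- assemble_collection(sim_config(
    seed = 6, n_markers = 30,
    species = data.frame(name = "sp", n = 30L, phi = 0.05),
    n_offspring = 0L, n_misdocumented = 0L,
    clone_spec = data.frame(lineage = c("wt1", "wt2"),
                            n_clones = c(20L, 12L), mu = 0.05),
    name_error_spec = c(synonym_pairs = 0L, homonym_pairs = 0L,
                        replicate_pairs = 0L),
    n_tetraploid_duplicates = 0L))
  rep <- sport_discrimination(col$table)
  sig <- signature_strings(col$table)
  lg <- col$table$accessions$lineage_group
  for (i in seq_len(nrow(rep))) {
    members <- col$table$accessions$accession_id[
      !is.na(lg) & lg == rep$lineage[i]]
    tab <- table(sig[members])
    expect_equal(rep$n[i], length(members))
    expect_equal(rep$n_distinguishable[i], sum(tab == 1L))
    expect_equal(rep$percent[i],
                 round(100 * sum(tab == 1L) / length(members), 1))
    expect_equal(rep$n_subgroups[i], sum(tab > 1L))
  }
})

test_that("wildtype comparison equals a per-cell set-difference oracle", {
  tab <- toy_table()
  expect_length(compare_to_wildtype(tab, "A1", "A2")$polymorphic, 0L)
  cmp <- compare_to_wildtype(tab, "A1", "A4")
  oracle <- colnames(tab$calls)[!is.na(tab$calls["A1", ]) &
                                  !is.na(tab$calls["A4", ]) &
                                  tab$calls["A1", ] != tab$calls["A4", ]]
  expect_equal(cmp$polymorphic, oracle)
  # missing-vs-called is uncomparable, not polymorphic
  cmp2 <- compare_to_wildtype(tab, "A1", "A3")
  expect_true("C02001" %in% cmp2$uncomparable)
  expect_false("C02001" %in% cmp2$polymorphic)
  expect_error(compare_to_wildtype(tab, "A1", "nope"), "unknown accession")
})

test_that("QR payloads are deterministic and decode back to the genotype map", {
  tab <- toy_table()
  p1 <- qr_payload(tab, "A1")
  p2 <- qr_payload(tab, "A1")
  expect_identical(p1, p2)
  parsed <- parse_qr_payload(p1)
  expect_equal(parsed$accession_id, "A1")
  expect_equal(unname(parsed$genotypes[tab$markers]),
               unname(tab$calls["A1", ]))
  # digest mode carries digest and panel version
  pd <- parse_qr_payload(qr_payload(tab, "A1", mode = "digest",
                                    panel_version = "v9"))
  expect_equal(pd$panel_version, "v9")
  expect_equal(pd$digest, signature_of(tab, "A1")$digest)
  # capacity guard suggests digest mode
  expect_error(qr_payload(tab, "A1", max_chars = 10), "digest")
})

test_that("founder collision probability is negligible with >= 50 polymorphic markers", {
  # distinct founders drawn from non-degenerate frequencies: over many
  # replicates of modest collections, no two founders ever collide
  set.seed(99)
  collisions <- 0L
  n_rep <- 300L
  for (r in seq_len(n_rep)) {
    p <- runif(50, 0.2, 0.8)
    codes <- matrix(rbinom(40 * 50, 2, rep(p, each = 40)), 40, 50)
    collisions <- collisions + (anyDuplicated(apply(
      codes, 1L, paste, collapse = "")) > 0L)
  }
  expect_equal(collisions, 0L)
})
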