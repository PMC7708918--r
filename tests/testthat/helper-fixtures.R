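# Small in-code fixtures.

# hand-built 4-accession, 3-marker table
toy_table <- function() {
  calls <- rbind(
    A1 = c("236/248", "300", "180/200"),
    A2 = c("248/236", "300/300", "200/180"),
    A3 = c("236/236", "310/300", "-"),
    A4 = c("248/248", "300/310", "180/180"))
  colnames(calls) <- c("C01001", "C01002", "C02001")
  genotype_table(calls, data.frame(
    accession_id = rownames(calls),
    name = c("Fuji", "Benifuji", "Gala", "Gala"),
    species = "M_domestica", stringsAsFactors = FALSE))
}

# random I/D-coded table with two populations at Hardy-Weinberg
random_coded_table <- function(n_per_pop = 30, L = 20, seed = 1) {
  set.seed(seed)
  p1 <- runif(L, 0.1, 0.9)
  p2 <- runif(L, 0.1, 0.9)
  geno <- function(p, n) {
    codes <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
    matrix(c("D/D", "I/D", "I/I")[codes + 1L], n, L)
  }
  calls <- rbind(geno(p1, n_per_pop), geno(p2, n_per_pop))
  colnames(calls) <- sprintf("M%03d", seq_len(L))
  genotype_table(calls, data.frame(
    accession_id = sprintf("S%03d", seq_len(2 * n_per_pop)),
    species = rep(c("popA", "popB"), each = n_per_pop),
    stringsAsFactors = FALSE))
}

# write a VCF given body lines (adds a minimal header)
write_test_vcf <- function(body, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"t\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"t\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"t\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    body), path)
  path
}
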