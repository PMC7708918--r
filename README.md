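# gikit — InDel marker panels, identity signatures and population genetics for clonal crop germplasm

Germplasm collections of clonally propagated crops (apple being the
motivating case) hold thousands of accessions whose labels drift over
decades: duplicates, synonyms (one genotype under several names), homonyms
(one name over several genotypes), bud sports (somatic mutants of a named
cultivar) and mis-recorded pedigrees. A panel of co-dominant
insertion/deletion (InDel) markers, typed as PCR fragment lengths on a
capillary sequencer, gives each accession a cheap, reproducible DNA
fingerprint that resolves all of these questions at once.

`gikit` implements the complete workflow around such a panel:

* **Panel design** — parse structural-variant calls (Delly-style VCF),
  summarise SV classes, filter 50–400 bp InDel candidates, select a
  genome-spaced panel (exact max-min-gap optimisation per chromosome) and
  pack it into fluorescent multiplex PCR groups (FAM/HEX/NED/PET,
  non-overlapping size windows).
* **Identity** — canonical signature strings and SHA-256 digests, exact
  duplicate grouping, synonym/homonym/replicate classification, bud-sport
  discriminability, wildtype comparison, QR text payloads.
* **Population genetics** — allele frequencies; Na, Ne (=1/Σp²), Shannon I,
  Ho, He (=1−Σp²), F (=(He−Ho)/He) per locus and population;
  Weir–Cockerham θ (variance components a, b, c combined as Σa/Σ(a+b+c))
  with Nei Gst as alternative; Fisher exact differentiation tests combined
  across loci; the Levene/Haldane Hardy–Weinberg exact test; genotype-
  frequency pattern clustering (complete linkage, Euclidean, k = 5).
* **Parentage** — Mendelian exclusion for duos and trios; a hypothesis is
  accepted iff confidence C = (compatible / informative loci) > 0.98 *and*
  mismatches ≤ 1 (both knobs configurable); vectorised collection-wide
  scans with clone collapse.
* **Synthetic collections** — a Balding–Nichols generator (structured
  populations at controlled Fst, Hardy–Weinberg genotypes, pedigrees,
  clonal lineages with somatic mutation, planted name errors, missing data)
  with a machine-readable truth log.
* **Pipeline** — `run_pipeline()` drives markers → identity → popgen →
  parentage from a config list or YAML file, writing CSV outputs, a run log
  and a digest-bearing MANIFEST; `inst/cli/gik.R` is a thin command-line
  wrapper (`simulate`, `run`).

## Worked example

Generate the default study-shaped collection (1251 accessions, 102 markers,
seven species-like populations, seven bud-sport lineages, 40 pedigreed
offspring of which 6 carry a planted registration error) and analyse it:

```r
library(gikit)

col <- assemble_collection(sim_config(seed = 42))
group_by_signature(col$table)
#> identity groups: 1251 accessions -> 1031 distinct signatures
#>   1001 unique (singletons), 250 accessions share 30 multi-member patterns

sport_discrimination(col$table)
#>            lineage   n n_distinguishable percent n_subgroups
#> 1             Fuji 160                56    35.0           6
#> 2             Gala  60                17    28.3           2
#> ...
```

1031 distinct signatures out of 1251: the shortfall is exactly the planted
structure — clones that acquired no somatic mutation, plus the planted
synonym/replicate/tetraploid duplicates. Within the 'Fuji'-like lineage of
160 sports, 35% are distinguishable (at the default somatic rate
μ = 0.005/locus) and the rest collapse into 6 shared-signature subgroups.

```r
summarize_population(col$table, grouping = "species")
#> per-population diversity (across-locus means):
#>    population n_loci    Na    Ne     I    Ho    He   uHe      F
#>     M_baccata    102 1.853 1.490 0.429 0.306 0.286 0.297 -0.070
#>   M_domestica    102 2.000 1.564 0.497 0.330 0.331 0.331  0.006
#>   ...

pairwise_fst(col$table, "M_domestica", "M_baccata")
#> Fst (wc84) M_domestica vs M_baccata over 102 loci: 0.1241
```

The most diverged population pair (generator φ = 0.06 and 0.16, so an
expected pairwise θ near 0.11) is estimated at 0.124. Pedigree checks flag
the planted registration error and find the true parent:

```r
evaluate_hypothesis(col$table, "PED-001", "DOM-0358", "DOM-0405")  # documented
#> PED-001 <- DOM-0358 x DOM-0405: 90/102 loci compatible (C = 0.8824, 12 mismatch) -> rejected

scan_parentage(col$table, focal = "PED-001", mode = "trio")
#> parentage scan: 1 accepted hypothesis(es) for 1 offspring
#>  offspring  parent1  parent2 n_informative n_mismatch confidence accepted documented_match
#>    PED-001 DOM-0100 DOM-0358           102          0          1     TRUE            FALSE
```

The documented cross is excluded at 12 mismatching loci; the scan accepts
exactly one pair — the true parents in the generator's truth log
(`col$truth$accessions`).

## Genotype table dialect

CSV/TSV with a header row: metadata columns `accession_id` (required) and
optionally `name`, `species`, `ploidy`, `parent1`, `parent2`,
`lineage_group`, followed by one column per marker. Cells are `"a/b"`
(fragment sizes in bp, or symbolic `I`/`D`), a single `"a"` for a
homozygote, `"-"` for missing. The delimiter is auto-detected. Exports:
PLINK PED/MAP, STRUCTURE, GenAlEx CSV, panel TSV/BED.

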