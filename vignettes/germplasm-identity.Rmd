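---
title: "Fingerprinting clonal crop germplasm with co-dominant InDel markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprinting clonal crop germplasm with co-dominant InDel markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gikit)
```

## The problem

Large germplasm collections of clonally propagated crops — apples are the
motivating case — accumulate duplicates, synonyms (one genotype under several
names), homonyms (one name over several genotypes) and bud sports (somatic
mutants of a named cultivar). Managing such a collection, releasing new
cultivars (distinctness/uniformity/stability testing) and verifying recorded
pedigrees all require a cheap, reproducible DNA fingerprint. A panel of
co-dominant insertion/deletion (InDel) markers typed as PCR fragment lengths
is well suited: long InDels are abundant genome-wide, stable, scoreable on a
capillary sequencer, and co-dominant, so heterozygotes are observed directly.

`gikit` implements the full workflow around such a panel:

1. **Panel design** (`read_sv_vcf`, `filter_indel_candidates`,
   `select_panel`, `design_multiplex`): triage structural-variant calls into
   InDel candidates, pick a genome-spaced subset, pack it into fluorescent
   multiplex PCR groups.
2. **Identity** (`signature_of`, `group_by_signature`, `classify_names`,
   `sport_discrimination`, `qr_payload`): canonical signatures, duplicate
   groups, name diagnostics, bud-sport resolution.
3. **Population genetics** (`summarize_population`, `pairwise_fst`,
   `differentiation_test`, `hwe_exact`, `classify_patterns`): diversity and
   differentiation over species or other groupings.
4. **Parentage** (`duo_compatible`, `trio_compatible`,
   `evaluate_hypothesis`, `scan_parentage`): Mendelian-exclusion pedigree
   verification and candidate scans.
5. **Synthetic collections** (`sim_config`, `assemble_collection`): a
   generator with a machine-readable truth log, used as the test bed for
   everything above.

## Data model

A `genotype_table` is an accessions × markers matrix of canonical calls plus
accession metadata. A call is an unordered allele multiset written
`"a/b"` with alleles sorted (numerically when numeric); a single observed
fragment is expanded to a homozygote, because a capillary chromatogram shows
one peak for a homozygote. Missing is `NA` (`"-"` on disk). Allele order,
row order and column order never affect any downstream result; this is
asserted by property tests.

Polyploid accessions (e.g. tetraploid duplicates of diploid cultivars) carry
at most two recorded alleles with unknown dosage. They are flagged
`dosage_unknown`, *included* in identity matching — a tetraploid sport of a
diploid cultivar shares its fingerprint — and *excluded* from
Hardy–Weinberg, diversity and Fst computations, which assume known diploid
genotype counts.

## Identity signatures

The signature is the string `marker=alleleA|alleleB;...` over the panel,
fields sorted by marker id, missing encoded `?`, plus a SHA-256 digest for
stable cross-platform identifiers. Grouping is **exact**: `?` is an ordinary
symbol. Ignoring missing cells ("wildcard" matching) is not transitive, so
it can only ever be reported as candidate duplicate pairs
(`match_mode = "wildcard_report"`), never used to merge groups.

A consequence worth knowing: every missing call makes an accession look
unique. On a panel of 100+ markers even a 1% missing rate leaves most
accessions with at least one `?`, which inflates distinct-signature counts.
The workflow therefore presumes a validated panel with an essentially
complete matrix; the per-marker missing-rate report from `validate_table()`
is the first thing to check on real data.

Name diagnostics compare normalized names (case folded, punctuation
stripped; curated alias maps are user-supplied) within and across signature
groups: *replicate* = same signature and same name, *synonym* = same
signature under different names, *homonym* = same name over different
signatures, with precedence replicate > synonym > homonym.

For bud sports, discriminability within a lineage is the fraction of sports
whose signature is unique inside that lineage; the remainder partition into
shared-signature subgroups. Somatic mutations are rare, so most sports are
expected to be indistinguishable from their wildtype — parallel mutation,
chimerism and epigenetic variation all cap what any DNA panel can resolve.

## Population statistics

Per locus and population, with allele frequencies $p_i$ over typed diploids:
$N_a$ = observed allele count, $N_e = 1/\sum p_i^2$,
$I = -\sum p_i \ln p_i$, $H_o$ = observed heterozygote fraction,
$H_e = 1 - \sum p_i^2$ (uncorrected; the unbiased
$uH_e = \frac{2n}{2n-1} H_e$ is also reported), and
$F = (H_e - H_o)/H_e$, undefined at monomorphic loci. Population summaries
are unweighted across-locus means. Two averaging conventions for $F$ exist
in the field's tools; the default is the mean of per-locus ratios, with
`f_mode = "ratio_of_means"` giving $1 - \bar{H_o}/\bar{H_e}$. For biallelic
loci $N_e = 1/(1 - H_e)$ exactly, which the tests assert on every run.

Differentiation uses the Weir–Cockerham (1984) estimator: per locus and
allele, variance components $a$ (among populations), $b$ (among individuals
within populations) and $c$ (within individuals), combined over loci as
$\hat\theta = \sum a / \sum (a+b+c)$. Nei's $G_{st} = (H_t - H_s)/H_t$ is
provided as a secondary estimator because published Fst tables do not always
state their estimator. $\hat\theta$ is validated two ways: against an
independently coded mean-squares (ANOVA) route, and by parameter recovery —
on Balding–Nichols data with divergence $\varphi$ the multilocus
$\hat\theta$ recovers $\varphi$ with $|\text{bias}| < 0.01$ at 100 loci ×
100 diploids/population over 200 replicates.

Significance of differentiation comes from a two-sided Fisher exact test on
the 2×2 allele-count table per biallelic locus, combined across loci by
Fisher's method ($-2\sum\ln p$ against $\chi^2_{2L}$) — the behaviour of the
classic exact-test software for biallelic loci.

The Hardy–Weinberg exact test is the conditional (Levene/Haldane) test:
given the allele counts, the p-value sums the probabilities of all
heterozygote counts no more probable than the observed one. It equals a
brute-force enumeration over all allele placements for every count
configuration with $n \le 10$ (checked exhaustively).

Genotype-frequency **patterns** summarise how biallelic marker genotypes
(I/I, I/D, D/D) distribute across species groups: markers are rows of a
frequency matrix, clustered by complete-linkage on Euclidean distance (the
defaults of the heatmap tool this reproduces) and cut at `k = 5`. Cluster
labels I–V are assigned by a documented priority: highest mean heterozygote
frequency → IV; then highest focal-population D/D minus I/I → I; then lowest
mean D/D → II; remaining clusters get III, V, … by increasing size. The
labels are annotations for matching clusters to verbal descriptions, not
statements of statistical identity.

## Parentage

Exclusion-based, no likelihood model: a duo is compatible at a locus when
offspring and candidate share an allele; a trio when the offspring's two
alleles admit one-from-each-parent assignment. Over the informative loci
(all participants typed), confidence $C$ is the compatible fraction, and a
hypothesis is accepted iff $C >$ `min_confidence` (default 0.98) **and**
mismatches $\le$ `threshold` (default 1). The threshold absorbs somatic
mutations and null alleles; the published parameterisation names these two
knobs without printing the formula, and this is the simplest definition
consistent with both. With 102 markers the rule accepts one mismatch
($C \approx 0.990$) and rejects two ($C \approx 0.980$, above the confidence
bar but over the mismatch threshold) — the two conditions are genuinely
conjunctive.

Collection-wide scans collapse clones first (one representative per
signature group) so that signature-identical sports are not enumerated as
interchangeable parents, and evaluate documented parents alongside. The
candidate pool matters: progeny of a true parent are themselves
Mendelian-compatible relatives and can pass at `threshold = 1`, so candidate
pools should be restricted to the generation that could plausibly be parents
when that is known.

## The synthetic collection generator

`sim_config()` defaults define the study conditions the package is tested
under, emulating a real apple germplasm collection of 1251 accessions typed
at 102 biallelic fragment-length markers spread over 17 chromosomes:

* **Species structure.** Seven species-like populations plus a pooled
  "other" group (981 of the accessions in the first, dominant species,
  counting its sports and pedigree material; 49/20/31/21/25/13/111 in the
  rest). Divergence follows the Balding–Nichols model: per marker with
  ancestral frequency $p$ (Beta(1,1) truncated to [0.05, 0.95]), a
  population at divergence $\varphi$ draws its frequency from
  Beta$(p\frac{1-\varphi}{\varphi}, (1-p)\frac{1-\varphi}{\varphi})$, so
  the expected pairwise Weir–Cockerham $\theta$ between two populations at
  equal $\varphi$ is $\varphi$. Default $\varphi$ values (0.06, 0.03, 0.03,
  0.03, 0.025, 0.03, 0.16, 0.05) span pairwise differentiation of roughly
  0.03–0.11, the 0.02–0.13 range reported for *Malus* species.
* **Clonal lineages.** Seven bud-sport lineages of 160/60/60/14/10/10/6
  clones. Somatic mutation replaces one allele at a locus with the marker's
  other allele (fragment-length panels essentially never create novel
  lengths) at rate `mu` per locus per clone, default 0.005: with 102 loci
  this leaves $(1-0.005)^{102} \approx 60\%$ of sports identical to their
  founder, matching the observed 30–45% discriminability of real sport
  lineages.
* **Pedigrees.** 40 offspring of random founder crosses in the dominant
  species, 6 of them with one deliberately mis-documented parent in the
  metadata (the truth log keeps the real one), emulating registration
  errors that parentage scans are meant to catch.
* **Name errors.** 10 planted synonym pairs, 10 homonym pairs, 4 replicate
  pairs and 2 tetraploid duplicates of diploid founders. Planted duplicates
  copy the source's *observed* record (including its missing cells): they
  model re-filed catalogue entries, and independent missingness would make
  exact signatures of true duplicates differ — precisely the artefact the
  exact-matching caveat above describes.
* **Missing data.** Default rate 0 — a validated multiplex panel yields an
  essentially complete matrix, and the identity analyses presume that; the
  rate is configurable and non-zero rates are exercised by tests.

Everything is driven by one seed; two runs with equal seeds are
byte-identical, and the truth log explains every accession (species, true
parents, clone family, planted name class), every somatic mutation and
every missing cell.

**What the generator does not emulate:** marker ascertainment (real panels
are discovered in one or two cultivars of the dominant species, depressing
diversity estimates in distant relatives — visible in real data as low
$H_e$ in outgroup species and absent here, where all species share the
ancestral frequency distribution); linkage between markers; genotyping
error other than missingness; admixed individuals and interspecific
hybrids; multiallelic markers (sizes are drawn per marker but each marker is
biallelic). Passing tests on synthetic data therefore validate the
estimators and the bookkeeping, not the population-genetic realism of any
particular collection.

## Numerical and design choices

* **Panel spacing.** The published procedure says only "ten per
  chromosome"; the objective here is to maximise the minimum pairwise
  distance among selected loci, which reproduces "well distributed on
  chromosomes". This is solved *exactly* by a dynamic program over sorted
  candidate positions with both extreme candidates forced in (an optimal
  solution containing the extremes always exists: sliding the outermost
  selected loci outward never shrinks a gap). A greedy heuristic was
  considered and rejected because it does not always attain the optimum the
  package's own tests demand. Ties break toward smaller coordinates;
  `per_chrom = 1` takes the candidate nearest the chromosome midpoint.
* **Marker ids** follow `C` + two-digit chromosome + three-digit serial,
  the serial being the candidate's positional rank on its chromosome.
* **Multiplex packing** is first-fit-decreasing by product-size span with a
  `size_gap` (default 20 bp, a capillary binning safety margin) enforced
  between same-dye spans within a group; group size is capped (default 24).
  The assignment is validated by an independent $O(n^2)$ conflict checker
  in the tests. Markers whose own allele span exceeds the detectable window
  (default 50–500 bp) are rejected with a warning.
* **InDel length bounds** for candidates are inclusive, $50 \le L \le 400$
  bp, reading the conventional "50–400 bp" as a closed interval; insertion
  lengths come from `SVLEN`/`INSLEN` since POS = END for insertions, and
  the length filter is applied to the InDel length, which equals the
  product-size difference.
* **Breakend handling**: translocations arrive as BND mate pairs in modern
  SV callers; mates are paired by `MATEID` (falling back to reciprocal ALT
  coordinates), classified ITX/CTX by chromosome identity, and emitted once
  per pair; orphan breakends are skipped and tallied in a warning.
* **HWE p-value ties** are compared with a $1 + 10^{-9}$ relative slack so
  that equal-probability outcomes (exact rational ties computed in floating
  point) land on the inclusive side, matching the enumeration oracle.
* **Degenerate inputs**: loci monomorphic across both populations
  contribute zero variance components (they cancel from $\hat\theta$);
  populations with no typed individuals at a marker are flagged and
  excluded from means; $F$ is undefined (NA) where $H_e = 0$; a parentage
  verdict with no informative locus is reported `undefined`, never
  accepted.

## Problem sizes used in the checks

The bundled tests and the acceptance script run entirely on generated data
at the study's own scale where that is cheap (the 1251 × 102 default
collection) and at reduced replicate counts where the full Monte-Carlo
would add nothing: $\theta$ recovery uses 200 replicates of 100 loci × 100
diploids per population per $\varphi \in \{0.02, 0.05, 0.13\}$; parentage
recovery uses a 50-family, 100-founder, 100-marker pedigree; panel-spacing
optimality is checked exhaustively on instances of up to 20 candidates
(choose(20, 10) subsets); the HWE oracle enumerates every count
configuration up to $n = 10$.

## Limitations

Reproducing the published headline numbers of the motivating study (1018
distinct signatures among 1251 accessions, the 78-marker biallelic subset,
per-species diversity tables) requires its supplementary genotype matrix,
which is third-party data not shipped with the package; the acceptance
tests document a drop-in path for it and fail informatively in its absence.
Exclusion-based parentage cannot distinguish a true parent from its clones
(hence clone collapse) and loses power for relatives of true parents;
likelihood/LOD ranking is a possible extension, deliberately out of scope.
QR rendering is delegated to external encoders — the package produces and
parses the deterministic text payload only.
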