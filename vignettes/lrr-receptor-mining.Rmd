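---
title: "Mining LRR-containing immune receptor genes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining LRR-containing immune receptor genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrrminer)
```

## The problem

Plant genomes encode two large classes of leucine-rich-repeat (LRR) immune
receptors. Intracellular **NBS-LRR** proteins (nucleotide-binding site +
LRR), the products of classical resistance (R) genes, subdivide by their
N-terminus into **TNLs** (Toll/interleukin-1-receptor domain) and **CNLs**
(coiled-coil motif). Cell-surface **LRR-RLKs** combine extracellular LRRs, a
transmembrane helix and a cytoplasmic kinase; **LRR-RLPs** lack the kinase.
Genome-wide catalogs of both classes are built from protein-domain evidence
and then characterized by chromosomal clustering, duplication structure and
phylogeny. `lrrminer` implements that workflow as a tested pipeline whose
every stage can be exercised on synthetic genomes with a known ground
truth.

## Candidate identification from domain hits

The pipeline consumes a Pfam-style domain-hit table in HMMER3
`--domtblout` dialect. Hits are thresholded on the **independent-domain
E-value** column at `evalue_max = 1e-4`. The boundary is *inclusive*
(`evalue <= 1e-4`): the conventional cutoff statement ("set to 1e-4") does
not specify strictness, and keeping the boundary hit matches common HMMER
reporting practice. Accession version suffixes (`PF00931.25`) are stripped
before role mapping. The default role map is

| accession | role |
|---|---|
| PF00931 (NB-ARC) | NBS |
| PF00560, PF08263, PF12799 | LRR |
| PF00069 (Pkinase) | KINASE |
| PF01582 (TIR) | TIR |

PF01582 is used for the TIR role because it is the standard Pfam TIR
family; it is overridable through the `role_map` argument of
`parse_domtbl()`.

Catalogs are role-presence intersections: NBS genes (≥1 NBS hit), NBS-LRR
genes (NBS ∩ LRR), RLK genes (≥1 KINASE hit), LRR-RLK genes (KINASE ∩
LRR). Redundant entries — *identical* sequences at *overlapping* loci on
the same chromosome — are collapsed to the lexicographically smallest gene
id and logged. Requiring both conditions is deliberately conservative:
identical sequences at distinct loci are tandem paralogs, not annotation
redundancy, and manual curation of redundancy is not reproducible, so the
rule errs toward keeping genes and making every removal auditable.

## Coiled-coil detection and TNL/CNL classification

No maintained, scriptable implementation of the classic sliding-window
coiled-coil predictor is available as an R dependency, so the scorer is
implemented in-package following the Lupas approach: for every window
placement (window ∈ {14, 21, 28}, default 21 residues) and each of the 7
heptad frames, the window score is the geometric mean of per-residue
propensities at their assigned register (a–g); the per-residue score is the
maximum over covering windows and frames; a two-Gaussian decision rule
converts scores to probabilities, `P = G_cc / (G_cc + G_glob)`.

The shipped propensity tables are the published MTK (myosin/tropomyosin/
keratin) and MTIDK heptad-frequency tables as commonly redistributed with
coiled-coil scanners. The **two-Gaussian parameters are this package's own
calibration**, not constants copied from the original tool (those derive
from its internal reference databases): the globular mean/SD per window
were measured on windows of random sequence drawn from the packaged
background amino-acid composition, and the coiled-coil mean was anchored at
the score of an ideal heptad repeat (Leu at a/d, E/K elsewhere), SD 0.30.
With the default window this puts the `P = 0.9` crossing near score 1.6
while the maximum background window score observed in calibration was about
1.5 — random sequence essentially never qualifies, ideal heptads always do.
The parameters live in the matrix files (`inst/extdata/coils_*.tsv`) and
are versioned with the package. Shorter windows (14) are noisier, as for
any sliding-window scorer; the default is 21.

A gene is called **CNL** when ≥ `min_run = 7` *consecutive* residues reach
probability ≥ 0.9 (both boundaries inclusive) within the region N-terminal
of the first NBS-role hit; when no NBS hit is available the whole protein
is scanned and the fallback is flagged in the output. A TIR-role hit makes
the gene **TNL** and takes precedence over any coiled-coil signal — the
binary TNL/CNL split implies a precedence rule and TIR evidence is the
more specific signal. Genes with neither are **NL**; `strict = TRUE` drops
them from the catalog (off by default: a published 147 CNL + 4 TNL split
that sums to the full 151-gene catalog indicates that, in practice, no gene
was removed at this step, so dropping is surfaced as an explicit log rather
than silently applied).

The 0.9 threshold is the conventional cutoff for this scorer family; no
threshold is inherent to the method, so it is a documented, configurable
default rather than a fitted constant.

## Clusters and chromosomal distribution

A gene cluster is ≥ 2 catalog genes residing within a 200-kb window
(`cluster_config()`), the classical definition. The chain rule sorts genes
by start position (ties by gene id, for determinism) and joins a gene to
the open cluster when its gap to the previous gene is ≤ 200,000 bp,
boundary inclusive. The gap is measured **start-to-start** by default:
start coordinates are robust to annotation differences in gene length,
while end-to-start (intergenic) gaps shrink when a gene model is extended.
An `end_to_start` mode is provided for comparison. Two-member clusters are
designated `PAIR`, larger ones `MULTIGENE`. All coordinates are 1-based
inclusive (GFF3 convention) everywhere in the package; the BED export
converts to 0-based half-open at write time.

## Duplication families

Candidate duplicate pairs are scored by **global affine-gap alignment**
(Needleman–Wunsch via `Biostrings::pairwiseAlignment`) under BLOSUM62 with
gap existence 11 and extension 1, so a gap of length L costs 11 + L. A
pair is a duplicate when

* the alignment covers **more than 70%** of the longer sequence (strict
  boundary, following the usual "> 70%" phrasing), and
* the aligned region is **at least 70%** identical (inclusive boundary;
  "70% identity" without strictness).

Coverage is measured over the matched core (columns between the first and
last position where both sequences carry a residue), counted on the longer
sequence and divided by its full length; identity is identical columns over
all columns of that core region, gaps included (the BLAST convention).
Both thresholds are configurable (`dup_criteria()`).

Global rather than local alignment keeps the computation deterministic and
dependency-free; at the 70/70 thresholds the decision outcome is the same
for the planted test regime (substitution-only mutants vs unrelated
sequences), and `all_pair_stats()` accepts any sequence set, so externally
computed alignments can be substituted for real-data work.

Families are connected components of the duplicate relation (single
linkage) with ≥ 2 members, computed with `igraph`; the family id is the
smallest member id. Summaries follow fixed rounding conventions: half-up,
one decimal for mean family size, two decimals for percentages.

An optional shared k-mer prefilter (k = 5) skips pairs with no common
k-mer in all-vs-all mode; a 70%-identical pair over 70% of the longer
sequence cannot avoid sharing 5-mers, so the filter is decision-neutral
(and the tests compare filtered and exhaustive runs).

## Homology and phylogeny

`identity_similarity()` reproduces the MatGat-style pairwise table from a
global alignment: terminal gap columns are trimmed, the denominator is the
remaining core columns, identity counts identical columns and similarity
counts columns whose residue pair scores > 0 under BLOSUM62 (identities
included). The exact denominator conventions of the original tool are not
published; this documented convention is fixed, reproducible, and close in
practice.

`progressive_align()` is a ClustalW-style progressive scheme: a UPGMA
guide tree on fractional shared k-mer distances (k = 3), then
profile–profile global affine alignment with mean-of-pairs column scores.
Its contract — every input row is recovered exactly by deleting gaps — is
property-tested.

`pdistance_matrix()` uses the uncorrected p-distance (mismatches over
columns where both rows carry residues). Distance-model options beyond
p-distance were deliberately left out of the default path: the reference
workflow's settings are unstated, and p-distance keeps bootstrap
replicates cheap and exactly reproducible.

`neighbor_joining()` is the Saitou–Nei algorithm with deterministic
tie-breaking (smallest row, then column index). Negative branch lengths
are clamped to zero with the difference transferred to the sibling branch,
preserving the joined pair's path length. On additive matrices the
generating tree is recovered exactly (tested on random 4–8-taxon trees,
with `ape::nj` as an independent cross-check). `bootstrap_support()`
resamples alignment columns with replacement, recomputes p-distance + NJ
per replicate, and reports the percentage of replicates containing each
internal bipartition (counted with `ape::prop.clades`), deterministically
per seed. The default is 1,000 replicates, the value most commonly quoted
for this analysis scale.

## The synthetic genome generator

`simulate_genome()` plants: domain architectures (NBS-only, CNL, TNL,
NBS-LRR without an N-terminal motif, kinase-only, LRR-RLK, LRR-RLP,
decoys), duplicate families at a controlled identity, and gene clusters.
Its defaults are the study conditions used throughout the acceptance
tests, mirroring the curated maize B73 catalog at full scale:

* 217 NBS-encoding genes of which 151 NBS-LRR (147 CNL + 4 TNL), 226
  LRR-RLK, 74 kinase-only, 6 LRR-RLP, 100 decoys, on 10 chromosomes of
  200 Mb;
* 16 CNL families at the curated sizes (2,2,2,3,2,8,2,2,3,4,2,2,2,4,14,2 —
  56 genes, one size-14 tandem array) at 80% planted identity, the size-14
  and size-8 families placed as 50-kb tandem clusters; one LRR-RLK family
  of 4 (it feeds the phylogeny stage);
* protein lengths 250–400 aa; independent placements separated by
  300 kb – 1 Mb start-to-start so only planted clusters fall within the
  200-kb window; half of the decoys carry an above-threshold nuisance hit.

Family members are substitution-only mutants of a founder (`
mutate_to_identity()` substitutes exactly `round(L × (1 − t/100))`
positions), so planted identity is exact and coverage stays 100% — the two
duplicate thresholds decouple, and indel robustness is exercised separately
in the alignment unit tests. Coiled coils are re-planted after mutation so
CNL members keep a detectable motif. Planted hits are written directly to
the hit table with sub-threshold E-values; sequence content is made
motif-consistent only where a stage actually reads the sequence (the
coiled-coil scorer, the aligners).

What the generator does **not** emulate: nucleotide sequence, introns,
broken gene models, partial domains, compositional biases, E-value noise
near the threshold, or families related by anything subtler than uniform
substitution. Passing the synthetic recovery tests therefore demonstrates
that the machinery is correct and exactly recovers planted structure under
clean conditions — not that the thresholds are optimal for any real
genome.

## Numerical and reproducibility choices

* All randomness flows from explicit integer seeds; the simulator and the
  bootstrap restore the caller's RNG state. Identical configurations
  produce byte-identical output files (tested).
* Rounding is half-up at the precision each table conventionally prints
  (counts integer, means 1 dp, percentages 2 dp): `round_half_up()`
  avoids R's round-half-to-even surprises in printed tables.
* Alignment traceback determinism is delegated to
  `Biostrings::pairwiseAlignment`; the profile aligner breaks ties
  diagonal > up > left.
* Degenerate inputs: empty gene sets flow through every stage as empty
  tables; sequences shorter than the scan window get an all-zero coil
  profile (not an error); `pdistance_matrix()` refuses pairs with no
  comparable columns.

## Problem sizes

The test suite runs the full-scale synthetic recovery (623 genes,
exhaustive 151-gene all-vs-all for the NBS-LRR set plus k-mer-prefiltered
226-gene LRR-RLK set) in about half a minute on one core; unit tests use
20–40-gene genomes. `scripts/acceptance.R` repeats the full-scale run from
scratch at the caller's seed. These sizes were chosen to match the curated
catalog exactly while keeping a complete run interactive.

## Known limitations

* The coiled-coil decision parameters are calibrated, not fitted to
  curated coiled-coil databases; absolute probabilities should not be
  compared against other tools' outputs, only the decisions at the
  documented threshold.
* Duplication detection uses global alignment; highly domain-shuffled
  duplicates that only align locally can be missed relative to a local
  aligner at the same thresholds.
* The LRR-RLK catalog of the curated reference contains one family-count
  inconsistency between its summary (46 families, mean 2.4) and its
  itemized listing (47 numbered families, 110 genes); the package reports
  what it computes from the listing and does not assert the family count
  or mean for that set.
* Tandem vs segmental duplication mechanisms, Ka/Ks dating, synteny and
  signal-peptide/TM *prediction* are out of scope; TM and signal-peptide
  segments are consumed as annotations.
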