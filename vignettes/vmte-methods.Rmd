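---
title: "Methods: clade-resolved analysis of variably methylated transposable elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clade-resolved analysis of variably methylated transposable elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Intracisternal A-particles (IAPs) are young, active mouse endogenous
retroviruses that are normally silenced by sequence-specific KRAB
zinc-finger proteins (KZFPs) recruiting the KAP1/TRIM28 corepressor. A
small subset of IAP copies is *variably methylated* (VM): genetically
identical individuals show different, tissue-consistent methylation at the
same copy — the classic metastable epiallele. `vmte` implements, as one
tested pipeline, the chain of analyses that connects this behaviour to

1. **sequence clades** within an LTR subfamily (variants that lose KZFP
   binding),
2. **loss of KZFP/KAP1 binding signal** along the element consensus,
3. **CpG density** (observed/expected CpG score) that attracts ZF-CxxC
   readers such as CFP1 and TET1,
4. **genomic context** (proximity to constitutively expressed genes and
   enhancers),
5. **strain polymorphism** (young, still-segregating copies),
6. **methylation regimes** across individuals, and
7. **genotype-dependent chromatin** (novel H3K4me3 peaks under Trim28
   haploinsufficiency).

Every stage is exercisable end-to-end on synthetic data with planted
ground truth, because the genome-scale inputs of the original analyses
(reference genomes, public ChIP-seq/WGBS accessions, VM-locus lists from
prior work) are not reproducible at desk scale. The package therefore
ships a first-class generator whose outputs are ordinary files in the
standard formats (FASTA, RepeatMasker `.out`, BED, bedGraph, TSV), read
back through the same parsers a real dataset would use.

## Coordinates and containers

All intervals are BED-style: 0-based, half-open `[start, end)`. The only
1-based input is RepeatMasker `.out`, converted at the parsing boundary.
Coverage is held as dense per-base vectors per chromosome; "missing" is a
distinct state (`NA`) and never 0 — a gap in an alignment means *no data*,
not *zero signal*. Interval algebra (overlap, nearest, union-merge,
containment) is delegated to `GenomicRanges`/`IRanges`; sequences are
handled with `Biostrings`.

## Clade calling: alignment, trimming, tree, cut

The original analyses aligned elements with MAFFT, trimmed with trimAl,
and clustered with PhyML, cutting clades by eye. Those external binaries
are replaced by an in-repo, oracle-testable chain with explicitly fixed
semantics:

* **Pairwise and profile–profile Needleman–Wunsch** with a linear gap
  penalty and the fixed scheme match/mismatch/gap = +1/−1/−2. `N` matches
  nothing (always a mismatch); gap-against-gap scores 0 in profile
  columns; profile–column scores are the mean pairwise symbol score.
  Traceback ties resolve diagonal → up → left, so alignments are
  deterministic. A linear (not affine) penalty keeps the dynamic program
  equal to a brute-force enumeration oracle on short strings, and the
  synthetic regime is substitution-dominated, so affine gaps would buy
  nothing testable.
* **Guide tree** from Jaccard distances on 6-mer presence sets.
* **Column trimming** removes alignment columns occupied in strictly less
  than 10% of rows (a 10%-occupied column survives), recording a
  `column_map` so that base-wise signal projections — computed on the
  untrimmed alignment, since trimming discards columns, not bases — can be
  subset consistently.
* **p-distance + UPGMA** replaces maximum-likelihood clustering. The tree
  is only ever used to delineate clades, and average-linkage agglomeration
  on mismatch fractions is transparent, ultrametric, and checkable against
  a from-the-definition oracle. Ties break toward the lowest cluster
  creation index, making the tree a pure function of the matrix.
* **Clade cutting** removes the k−1 highest (equivalently, last) merges;
  `k` is a user choice per element set, mirroring the original "clades
  were selected empirically" — defaults of 4 for LTR-like sets and 3 for
  internal-element sets. Labels are ordered by each clade's smallest
  member index.

Pairs with fewer than 20 comparable (both non-gap) columns are flagged;
a pair with none is an error rather than a silent distance of zero.

## Signal projection into consensus space

Per-base coverage over an element is read 5'→3' in element orientation
(minus-strand copies reversed), and the j-th base's value is placed into
the alignment column holding that row's j-th non-gap symbol. Column means
per clade ignore missing values. The 5'-anchor heatmap variant centres a
window of `2 × flank` bp (default flank 2000, a configuration parameter —
no canonical value exists) on each element's 5' end, again read in element
orientation, with off-chromosome positions missing.

## CpG observed/expected score

The score of a window is `n_CpG × N / (n_C × n_G)` — approximately 1 for
i.i.d. sequence, far below 1 genome-wide in vertebrates, and 1–2 at CpG
islands. Elements are scanned with 200 bp windows (the minimal CpG-island
size) at 10 bp steps and summarized by their maximum window. Two
boundary choices the original description leaves open: elements shorter
than the window are scored with one whole-element window (`N` = element
length), so short solo LTRs are not discarded; and a final end-anchored
window is evaluated whenever the step grid does not reach the 3' end, so
no element end goes unscored. Subfamily summaries drop low-copy
subfamilies (default `min_copy = 50`; no threshold is printed in the
original, and the synthetic configuration uses 10 because its background
subfamilies have 12 copies each). An element is VM if it overlaps a VM
locus by at least 1 bp. Background scores are drawn from random intervals
length-matched per element, uniform over all valid placements.

## Genomic context

A gene is *constitutively expressed* when FPKM exceeds 2 in strictly more
than 90% of samples (both thresholds strict: 9/10 samples fails, 10/11
passes). Context classification is precedence-ordered: within 50 kb
(inclusive) of a constitutive gene → `constitutive_proximal`; otherwise
strictly less than 1 kb from an enhancer → `enhancer_proximal`; otherwise
`distal`. The two boundary conventions differ deliberately, following the
wording "within 50 kb" versus "less than 1 kb". Distances are
edge-to-edge gaps to gene bodies (not TSSs), 0 on overlap or adjacency.
A threshold sweep evaluates the constitutive-proximal fraction over a
full factorial FPKM × distance grid.

## Statistics

* **Fisher exact** (two-sided) sums hypergeometric probabilities of all
  tables, with fixed margins, no more probable than the observed one, with
  a relative tie tolerance of 1e-7; factorials in log space. A zero margin
  returns p = 1. Per-clade VM enrichment tests (in-clade vs rest) ×
  (VM vs not), reporting the sample odds ratio with a Haldane +0.5
  correction when any cell is zero.
* **Wilcoxon rank-sum** is exact by enumeration when `n_x + n_y ≤ 20`
  and tie-free, otherwise the normal approximation with tie and continuity
  corrections (delegated to `stats::wilcox.test`, whose semantics are
  exactly these); the statistic is Mann–Whitney U.
* **Age enrichment** assigns each VM locus to the TE it overlaps most
  (ties to the leftmost), then to that subfamily's age bin, and compares
  observed bin counts to the mean over `R = 1000` replicate sets of
  uniformly placed, length-matched random loci, reporting O/E per bin with
  an empirical 95% null interval. Random placement is uniform over valid
  start positions genome-wide, with no blacklist masking (none is used in
  the original); an optional exclusion set can be supplied. The original
  does not print its replicate count; 1000 keeps the null mean's Monte
  Carlo error well below the acceptance tolerances.

## Strain conservation

An element is *fully deleted* in a strain only when a **single** deletion
record contains it entirely (the per-feature semantics of
`bedtools intersect -f 1.0`); adjacent deletions jointly covering it do
not count, and any partial overlap leaves the element "present". Strains
collapse into ordered phylogeny branches, a branch scoring present if any
member strain retains the element; an element absent from at least one
branch is polymorphic.

## Methylation and peak summaries

Per-region methylation retains CpGs with strictly more than 5 reads and
averages their fractions unweighted (matching per-CpG-island averaging; a
region with no retained CpG is undefined, never 0). Replicate peak sets
are union-merged into maximal intervals whose support is the number of
distinct replicates contributing an overlapping peak; support ≥ 2 ("found
in two animals") is required, and merged peaks overlapping an unmappable
exclusion set are dropped. A *novel* peak is a mutant merged peak with
zero overlap against any wild-type merged peak and mean
mutant/wild-type coverage ratio ≥ 3 over the interval, with a 0.5
pseudocount on both means to keep zero-coverage wild type finite.
Expression-responsive subfamilies (`padj < 0.05`, positive log2 fold
change, from an upstream differential-expression table that is consumed,
not fitted) are compared on mean maximum CpG score against an equal-size
seeded sample of non-responsive subfamilies.

## The synthetic-data generator

The generator is the package's study-condition definition, not a test
dial; its defaults are fixed once:

* **Clade structure** — 4 clades × 50 copies of a 330 bp LTR consensus;
  each clade carries 8 private diagnostic substitutions (so any two clades
  differ at 16 planted sites) on top of 2% i.i.d. within-copy divergence.
  The highest-index clade is the *escape* clade. About half of all copies
  are reverse-complemented into the genome. Half the LTRs get an adjacent
  1.5 kb internal element at a ≤ 25 bp strand-aware 5'-gap, exercising the
  flanked-internal selection.
* **CpG density** — the consensus is enriched to O/E ≈ 1.5 (IAP-like
  CpG-island density); the background genome and old background
  subfamilies are depleted to O/E ≈ 0.25, vertebrate-like.
* **Binding** — each factor has a consensus sub-interval profile whose
  height is clade-dependent (escape clade lowest, 1 vs 6–8), with
  per-base Poisson noise.
* **Methylation** — silenced copies draw per-CpG fractions near 0.85,
  escaped near 0.10, and variable copies draw one uniform [0.1, 0.9]
  level per individual per element shared across that element's CpGs — a
  coherent epiallele, the defining VM behaviour. Read depths are Poisson
  (mean 20), comfortably above the >5× filter. Escape-clade copies are
  variable with probability 0.6 (else escaped); other clades are silenced
  with a 2% variable leak.
* **Context** — class probabilities follow the printed fractions of the
  original study (VM: 83% constitutive-proximal / 17% enhancer-proximal;
  non-VM: 12% / 7% / 81% distal). Distances are scaled to desk scale:
  each primary element owns a 16 kb territory, constitutive genes are
  planted within 5 kb and enhancers within 200 bp, and the pipeline's
  synthetic configuration classifies with those same thresholds. The
  geometry (feature extents vs territory size) guarantees planted distal
  elements really are distal. `classify_context()` itself defaults to the
  real-data 50 kb / 1 kb rules.
* **Strains** — 8 strains in 4 branches; deletions fully cover selected
  elements with probability 0.25 per strain for the escape clade and 0.05
  otherwise, making the escape clade the most polymorphic.
* **Peaks** — 15 escape-clade elements carry mutant-only peaks (≥ 2 of 3
  replicates, 10× coverage vs 0 in wild type); 40 background peaks are
  shared by both genotypes; single-replicate noise peaks and dead-zone
  decoy peaks exercise the support and exclusion filters.
* **Seeds** — one root seed deterministically derives per-stage sub-seeds,
  so any stage can be regenerated in isolation and all outputs are
  byte-identical under a fixed root seed.

What the generator deliberately does **not** emulate: indel evolution and
alignment-fragmenting rearrangements, read-level noise (FASTQ),
GC-coupled coverage biases, chromatin-state correlation structure, and
recombination between elements. Passing tests therefore demonstrate that
the implementation recovers planted structure through the full file-format
round trip — not that the biological conclusions of any particular real
dataset would reproduce.

## Problem sizes and numerical choices

The default synthetic genome is ~3.4 Mb (200 × 16 kb territories plus a
~0.3 Mb background-subfamily chromosome). The acceptance checks use the
default 4 × 50 clade design; enrichment calibration uses a constructed
1 Mb genome with 30% TE coverage, 4000 uniform loci and R = 1000
replicates — sizes chosen so each age bin's expected count (~300) puts
the ±20% calibration band at more than three null standard deviations.
Alignment oracles run at string lengths ≤ 7 (exhaustive enumeration),
UPGMA oracles at n ≤ 7 over 500 random matrices, and the Fisher oracle
enumerates every 2×2 table with total ≤ 40.

Degenerate inputs are errors, not warnings: empty sequences, all-gap
alignments after trimming, row pairs with no comparable columns,
overlapping bedGraph records (ambiguous signal), methylation counts
exceeding totals, and zero-sample expression matrices all abort with a
named message. The one deliberate convention is Fisher's p = 1 for
zero-margin tables.

## Known limitations

* The progressive aligner has no iterative refinement and a linear gap
  penalty; it is a desk-scale surrogate adequate for
  substitution-dominated divergence, not a MAFFT replacement for deeply
  indel-divergent families.
* UPGMA assumes clock-like divergence; strongly rate-heterogeneous clades
  could be split differently than by maximum likelihood. Clade boundaries
  on real data remain a user choice of `k`.
* Dense per-base coverage vectors are convenient at desk scale but would
  need run-length or on-disk representations for mammalian genomes.
* Fragmented RepeatMasker hits are treated as independent instances (no
  defragmentation), matching the all-LTRs-independent analysis design.
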