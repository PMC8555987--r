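# vmte — clade-resolved analysis of variably methylated transposable elements

Intracisternal A-particles (IAPs) are young mouse endogenous retroviruses
that are normally shut down by KRAB zinc-finger proteins (KZFPs) and the
KAP1/TRIM28 corepressor. A handful of copies are *variably methylated*
(VM): genetically identical individuals methylate them differently, but
each individual does so consistently across tissues — metastable
epialleles, of which the agouti viable yellow allele is the famous
example. `vmte` is an R package for the analysis chain that asks **which
copies escape silencing and why**: it clusters an LTR subfamily into
sequence clades, projects KZFP/KAP1 binding signal into alignment
(consensus) coordinates, scores CpG density, classifies genomic context,
measures strain polymorphism, summarizes per-CpG methylation into
per-element regimes, detects replicate-consistent and genotype-specific
("novel") H3K4me3 peaks, and tests VM enrichment per clade and per TE age
bin. It is written for regulatory-genomics researchers who want each of
those steps as a tested, reusable function rather than a one-off script.

The core quantities:

* **CpG observed/expected score** of a window:
  `O/E = n_CpG · N / (n_C · n_G)`, maximized over 200 bp windows at 10 bp
  steps per element (≈ 1 for random sequence, 1–2 at CpG islands).
* **Sequence clades**: progressive multiple alignment (linear-gap
  Needleman–Wunsch, +1/−1/−2), columns occupied in < 10% of rows trimmed,
  p-distance + UPGMA, tree cut into *k* clades.
* **Consensus-space signal**: per-base coverage mapped through each row's
  non-gap columns (gaps are missing data, never zero), averaged per clade.
* **Enrichment**: two-sided Fisher exact tests per clade (VM × clade
  membership) and observed/expected VM-locus counts per TE age bin
  against `R = 1000` sets of length-matched random loci.
* **Rules taken literally**: LTRs > 300 bp; first 150 bp of flanked
  internal elements; FPKM > 2 in > 90% of samples; within 50 kb of a
  constitutive gene, else < 1 kb from an enhancer; CpGs with > 5×
  coverage; peaks in ≥ 2 replicates; novel peaks absent from wild type
  with ≥ 3× signal; "fully deleted" = contained in a single deletion call.

Because the original inputs are genome-scale public datasets, the package
ships a deterministic synthetic-data generator that plants clades,
clade-dependent binding, methylation regimes, context, strain deletions
and genotype-specific peaks, writes everything in standard formats
(FASTA, RepeatMasker `.out`, BED, bedGraph, TSV), and records the ground
truth — so the entire pipeline is testable end-to-end offline.

## Worked example

```r
library(vmte)

ds  <- simulate_dataset(sim_config(seed = 7))          # planted truth
dir <- file.path(tempdir(), "vmte-demo")
write_synthetic_dataset(ds, dir)                       # standard formats

report <- run_pipeline(pipeline_config(dir, k = 4, seed = 11))
print(report)
```

```
vmte pipeline report
  LTRs profiled: 200 (clades: clade1=50, clade2=50, clade3=50, clade4=50)
  most VM-enriched clade: clade2 (Fisher p = 8.85e-25, OR = 172.67)
  lowest KAP1-like signal: clade2
  most polymorphic clade: clade2
  novel peaks: 15
```

Reading: the 200 LTR copies cluster into four clades of 50; one called
clade (here `clade2` — labels come from tree order, not from the
generator) is simultaneously the most VM-enriched (Fisher exact
p ≈ 9e-25, odds ratio ≈ 173), the one with the weakest KAP1-like binding,
and the most strain-polymorphic — the planted escape clade recovered from
the data alone. All 15 planted genotype-specific H3K4me3 loci are
detected. `report$tables` holds the per-stage tables (clade calls, signal
matrices, CpG summaries, context calls, O/E age enrichment, polymorphism
rates, methylation, peaks); `write_report(report, outdir)` writes them as
TSV plus a `summary.json`.

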