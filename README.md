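# lincChIN

Chromatin interaction network analysis of lincRNA regulatory function.

## What this package is for

Long intergenic noncoding RNAs (lincRNAs) mostly lack functional
annotation. RNAPII-mediated ChIA-PET experiments capture which genomic
regions are in physical contact during transcription, and a lincRNA's
contact profile — protein-coding promoters, other noncoding genes, distal
regulatory elements (DREs) — carries information about what it does.
lincChIN turns ChIA-PET interaction clusters plus a GENCODE-style
annotation into a **chromatin interaction network (ChIN)** and
characterizes the lincRNAs in it. It is aimed at regulatory-genomics
analysts who have interaction clusters (BEDPE), coverage tracks
(bedGraph), peak calls (narrowPeak/BED), a ChromHMM segmentation, an
expression matrix, and a GWAS catalog extract — or who want a fully
synthetic, seeded stand-in for all of these.

The core pieces:

- **ChIN construction** — overlapping/abutting ChIA-PET anchors merge into
  nodes; clusters become edges (weight = cluster count, `total_pet`
  retained); nodes overlapping a ±2.5 kb promoter window by ≥ 1 bp are
  promoter nodes, the rest are DREs.
- **Interaction categories C1–C5** — a deterministic cascade per lincRNA:
  C1 interacts with protein-coding genes; C2 only with other annotated
  genes; C3 only with DREs (single-gene model); C4 no interactions but an
  RNAPII promoter peak (basal promoter); C5 neither.
- **Enhancer-like vs promoter-like promoters** — the sign of
  `log2((H3K4me1_2kb + eps) / (H3K4me3_2kb + eps))` over the ±1 kb core of
  the promoter window (20-bin profiles over ±2.5 kb reported alongside).
- **ChromHMM labelling of DREs** under the fixed priority: strong enhancer >
  weak enhancer > transcriptional transition/elongation > weak transcribed >
  insulator > polycomb-repressed > heterochromatin/repetitive > others.
- **Permutation colocalization** of any two region sets: overlap count vs
  length-preserving uniform relocation, `p = (1 + #{perm ≥ obs})/(1 + n_perm)`,
  z-score from the null moments.
- **Guilt-by-association** — correlation-ranked preranked GSEA per lincRNA
  (weighted KS running sum, gene-label permutation null, BH FDR 0.01) and a
  k-means-clustered lincRNA × term association matrix; hypergeometric
  enrichment for network communities of ≥ 20 nodes.
- **k-hop RNA-target prediction** — genes within 3 hops of a lincRNA's
  promoter node, intersected with CHART/ChIRP binding peaks (genic region
  ≥ 1 bp overlap) and expression correlation (> 0.6), with permutation
  enrichment of peaks inside the neighborhood.
- **Cell specificity** (max-over-fractions fold change ≥ 2) and **GWAS SNP
  mapping** through chromatin loops to candidate target genes.
- **A seeded synthetic-data generator** producing every input with a
  manifest of planted truth (categories, promoter labels, correlations,
  specific genes, enrichment factor, degree exponent), so each stage has a
  recoverable ground truth.

## Worked example

Generate the desk-scale synthetic inputs (2 chromosomes × 1 Mb, 200 genes,
~500 interaction clusters), build the network, classify, and test binding
enrichment around the focus lincRNA:

```r
library(lincChIN)

sim <- simulate_inputs(seed = 1, outdir = "sim")   # writes GTF/BEDPE/... + manifest.json
sim$chin
#> ChIN: 274 nodes ( 149 promoter / 125 DRE ), 341 edges

cats <- classify_categories(sim$truth$gene_id, sim$chin, sim$genes,
                            sim$tracks$rnapii_peaks, sim$expression)
table(cats$category)
#> C1 C2 C3 C4 C5
#> 14  5  5  6 20

enr <- binding_enrichment_in_neighborhood(sim$focus_lincrna, sim$chin,
  sim$aux$chart_peaks, sim$genome$chrom_sizes, k = 3, n_perm = 200, seed = 3)
enr
#> Permutation colocalization: observed 14, null 2.21 +/- 1.41, z = 8.378,
#> p = 0.004975 (n_perm = 200, seed = 3)
```

Reading the output: the 515 generated clusters merge into 274 nodes, 149 of
which overlap a promoter window. The category table matches the generator's
planted truth exactly (the cascade is deterministic). For the focus lincRNA,
14 of the CHART peaks fall on nodes within 3 hops of its promoter node,
against 2.2 ± 1.4 under length-preserving random relocation — the minimal
attainable p at 200 permutations (1/201), z ≈ 8.4.

The same analysis runs end-to-end from files:

```r
cfg <- pipeline_config(inputs = as.list(sim$paths[names(sim$paths) != "manifest"]),
                       seed = 1)
run_pipeline(cfg, "out")   # categories.tsv, promoter_profiles.tsv, dre_states.tsv,
                           # snp_targets.tsv, network.graphml, gsea.tsv, run.log, ...
```

Reruns with the same configuration and seed are byte-identical.

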