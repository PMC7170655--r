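# tadakit

Analysis toolkit for **Targeted DamID (TaDa)** protein–DNA binding
profiles and **CATaDa** chromatin accessibility, at the assay's native
resolution of GATC fragments.

In DamID, a protein of interest is fused to *E. coli* Dam methylase;
adenine methylation at GATC sites near binding locations is amplified
and sequenced, so every signal lives on the partition of the genome
into GATC-to-GATC fragments. A Dam-only control sample normalises the
fusion signal and — because untethered Dam preferentially methylates
open chromatin — doubles as an accessibility assay. tadakit implements
the full downstream analysis:

* **Fragment maps** — `build_fragment_map()` cuts chromosomes at every
  GATC motif; readers/writers for FASTA, GFF3, BED and bedGraph.
* **Signal tracks** — reads-per-million normalisation, the per-fragment
  binding signal `log2((RPM_fusion + c)/(RPM_control + c))`, and
  Spearman replicate-concordance QC.
* **Peak calling** — candidate peaks are maximal runs of ≥ 2
  consecutive enriched fragments; each run's false discovery rate is
  estimated from a permutation null (values shuffled across fragments,
  peaks re-detected, joint tail counts over run length and mean
  occupancy):

  `FDR(n, m) = E_shuffles[#null peaks ≥ (n, m)] / #observed peaks ≥ (n, m)`

  Peaks with FDR < 0.01 % are significant, and significant peaks
  present in both replicates form the final peak set (union span of
  each cross-replicate overlap component).
* **Annotation** — peaks map to putatively regulated genes within 5 kb
  with no intervening gene; peaks classify by midpoint into
  promoter-TSS / TTS / exon / intron / intergenic; Venn-style gene-set
  intersection counts.
* **Accessibility** — accessible-region calling on the Dam-only RPM
  track (genome-wide quantile threshold), average signal profiles
  around region centres, chromatin-state enrichment, and the
  binding–accessibility correlation.
* **Expression integration** — strict DE thresholds (padj < 0.05,
  |log2FC| > 1), one-sided Fisher's exact overlap tests (hypergeometric
  upper tail), bound-fraction reports, and tissue-of-origin calls from
  an FPKM matrix (FPKM > 2 = expressed).
* **Synthetic data** — a fully deterministic generator for genomes with
  renewal-process GATC spacing, gene annotations, replicate
  negative-binomial DamID counts with planted bound regions of known
  log2 effect, accessibility structure, chromatin-state maps, DE
  tables and FPKM matrices, for ground-truth validation.

## Worked example

The pipeline orchestrator simulates a complete study (one 4 Mb
chromosome, ~20,000 GATC fragments, 40 planted bound regions of 5
fragments at log2 effect 2, two replicates at 50× coverage) and runs
every stage:

```r
library(tadakit)
cfg <- default_config(seed = 42L)
res <- run_pipeline(cfg, outdir = "tada_out")
#> [tadakit] simulate: seed=42
#> [tadakit] fragments: 19803; genes: 400; replicates: 2
#> [tadakit] rep1: candidates=2306 significant=31
#> [tadakit] rep2: candidates=2289 significant=39
#> [tadakit] final peaks: 30
#> [tadakit] binding-accessibility Spearman r = -0.193
```

Of ~2,300 candidate runs per replicate, 31 and 39 survive the 0.01 %
FDR bar, and 30 final peaks are present in both replicates — planted
bound regions recovered with no false positives at this seed. The
negative Spearman correlation reflects the construction: binding was
planted preferentially in low-accessibility fragments, as observed for
condensin binding in neural cells. `tada_out/` then contains
`final_peaks.bed`, per-replicate occupancy bedGraphs and significant
peak tables, `gene_assignments.tsv` (5 kb rule), a feature breakdown,
accessible regions with an open-chromatin metaprofile, a
chromatin-state enrichment table and a summary:

```
fragments         19803
genes             400
final_peaks       30
assigned_genes    41
accessible_regions 47
binding_accessibility_spearman  -0.193179
up_bound_fraction   0.65
down_bound_fraction 0.65
```

Every output carries a `#` header with version, parameters and seed;
re-running the same configuration reproduces each file byte for byte.
A thin command-line wrapper lives at
`inst/scripts/damid_pipeline.R`:

```sh
Rscript inst/scripts/damid_pipeline.R --out tada_out --seed 42
```

The methods vignette (`vignettes/tadakit-methods.Rmd`) documents the
model, every tunable parameter, the synthetic-data design and the
package's numerical choices.

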