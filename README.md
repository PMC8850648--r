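# xdosage

Analysis of X-chromosome dosage compensation and inactivation escape in
sex-chromosome aneuploidies (47,XXY Klinefelter syndrome through 49,XXXXY),
for bulk and single-cell transcriptomes.

In cells with $n_X$ X chromosomes, X inactivation silences $n_X - 1$ copies,
but silencing is incomplete: pseudoautosomal (PAR) genes are expressed from
**every** sex chromosome, a minority of non-PAR genes escape inactivation,
and the XIST RNA coats each inactive X. The expected dosage laws are

| gene class            | expected expression ∝ |
|-----------------------|-----------------------|
| PAR1 / PAR2           | $n_X + n_Y$           |
| non-PAR escape        | $n_X$                 |
| subject to XCI        | constant (one active X) |
| XIST                  | $n_X - 1$             |

The package implements the full analysis path around these laws:

* **ASE calling** — per-SNP biallelic/monoallelic classification
  (reference-allele fraction in [0.1, 0.9] = biallelic; site filters:
  DNA-confirmed variant whitelist, depth > 6, non-intronic, unique gene,
  XIST exempt), gene calls (≥ 1 biallelic SNP), region-class summaries, and
  **X-erosion flagging** (≥ 2× the cohort median of biallelic non-PAR X
  genes, floor 30).
* **Bulk dosage statistics** — X:A expression ratio
  (X mean-FPKM over the average per-autosome mean-FPKM), male-median fold
  change, loess moving average of log2 FC along X (span 0.45), DEG
  thresholding (FDR < 0.05, |log2FC| > 0.25), and per-gene dosage-trend
  classification (OLS of log2 expression on $n_X$, or $n_X + n_Y$ for PAR
  genes).
* **Co-expression modules** — signed network (soft power 20), signed
  topological overlap, average-linkage clustering, ANOVA filtering of
  module eigengenes across karyotypes, dosage-trend **supermodules**, and
  hypergeometric gene-set enrichment.
* **Single-cell tests** — XIST by karyotype (Kruskal–Wallis), per-karyotype
  Pearson correlation of escape genes with XIST (independence at p > 0.05),
  cell-cycle-phase independence.
* **Promoter motif enrichment** — −1,500/+500 TSS windows, JASPAR PWM
  scanning at deficit 0.15 (hit iff score ≥ s_max − 0.15·(s_max − s_min)),
  Fisher's exact gene-coverage test, recurrence across supermodules.
* **Synthetic cohorts** — a seeded generator encoding the dosage laws with
  truth tables (karyotypes 46,XY…49,XXXXY, binomial allele counts with
  monoallelic leakage, an eroded clone with a 2.5× biallelic excess,
  negative-binomial single cells, block-correlated module structure), so
  the whole pipeline runs and is scored with no downloads.

## Worked example

```r
library(xdosage)

cfg  <- sim_config(seed = 1, eroded_samples = "XXY_r4")
bulk <- simulate_bulk_cohort(cfg)
ase  <- simulate_allele_counts(cfg, bulk$annotation, bulk$meta)

calls <- call_genes(classify_snp(ase$counts[!ase$counts$intronic, ]))
flag_erosion(summarize_ase(calls, bulk$annotation))
#>  sample_id n_biallelic_nonpar median_others eroded
#>   XXXXY_r1                 19            20  FALSE
#>     XXY_r1                 23            20  FALSE
#>     XXY_r4                 52            20   TRUE
#>      XY_r1                  0            20  FALSE
```

The eroded clone `XXY_r4` carries 52 biallelic non-PAR X genes against a
cohort median of 20 — the 2.5× excess the generator planted — and is the
only flagged sample. 46,XY samples show 0 (a single X has no heterozygous
sites).

```r
xa <- x_a_ratio(filter_expressed(bulk$expr), bulk$annotation)
aggregate(ratio ~ karyotype, merge(xa, bulk$meta), mean)
#>  karyotype ratio
#>      46,XY 0.610
#>     47,XXY 0.746
#>    48,XXXY 0.894
#>   49,XXXXY 1.026
```

The X:A ratio rises with the X count but stays near the 0.5–1 band:
escape and PAR genes add dosage while the silenced majority stays flat.

```r
trends <- classify_dosage_trend(bulk$expr, bulk$meta, bulk$annotation)
table(merge(trends, bulk$truth)$law, trends$trend[match(bulk$truth$gene_id, trends$gene_id)])
#>                 flat inverse proportional
#>   autosome_down    0      20            0
#>   autosome_flat  257       2            1
#>   autosome_up      0       0           20
#>   escape           0       0           20
#>   par              0       0           20
#>   x_inactive      79       0            0
#>   xist             0       0            1
```

Every PAR, escape and planted trend gene is classified correctly; 3 of 260
flat genes (~1%) are false calls at the 5% FDR.

The full pipeline (simulate → ASE → dosage → modules → single cell →
motifs, with all TSV/JSON artifacts and a deterministic run manifest):

```r
run_pipeline(list(seed = 1, outdir = "run1"))
```

A thin CLI wrapper is installed at `inst/scripts/xdosage`
(`xdosage simulate|run-all|validate`).

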