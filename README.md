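# utrapa

Discovery, quantification and cross-dataset comparison of **3′UTR
alternative-polyadenylation (APA) isoforms** from bulk RNA-Seq coverage,
designed for **clustered gene families** such as the mouse odorant-receptor
(*Olfr*) genes.

## The problem

Most mammalian genes produce mRNAs with several 3′UTR lengths by using
alternative cleavage/polyadenylation sites. For a large, densely clustered
family like the ~1100 mouse *Olfr* genes — expressed monogenically in
olfactory sensory neurons and therefore at low bulk abundance — generic
transcript assemblers miss or merge these isoforms. `utrapa` implements a
dedicated pipeline:

1. **Mask** — build genomic regions around runs of consecutive target-family
   CDSs, bounded by the proximal CDS ends of the flanking non-target genes
   (25 kb default when a flank is missing).
2. **Coverage** — load per-base depth (bedGraph) restricted to the mask,
   with O(1) cumulative-count interval queries.
3. **3′ end detection** — change-point segmentation of the coverage
   downstream of each stop codon: a piecewise-constant Poisson mean model is
   fit by binary segmentation. A split at position *t* is accepted when both
   segments are ≥ 100 nt, the downstream mean *d* and upstream mean *u*
   satisfy *d < u* and *d/u ≤ min_fold* (default 0.8), and the
   log-likelihood improvement exceeds a BIC penalty `log(L)`. Zero-coverage
   gaps ≤ `merge_radius` (200 nt) are bridged; longer gaps truncate the
   scan. The last covered base is the extinction end.
4. **PolyA sites & catalog** — single-linkage merge of ends closer than the
   100-nt precision window; fusion transcripts (isoforms running into a
   neighboring gene) are discarded; isoforms are ranked by length into
   sUTR (single), pUTR (proximal) and dUTR1..n (distal) categories.
5. **PAS scan** — canonical AATAAA/ATTAAA hexamers in an inclusive
   [−100, +100] nt window around any member end of a site; sites with no
   canonical signal are rescanned for 16 configurable variant hexamers in an
   upstream-only [−100, 0] window.
6. **Quantification** — with nested isoforms, the mean depth *d\[i\]* of the
   segment between adjacent 3′ ends equals the summed abundance of the
   isoforms ending at or beyond it, so relative abundances are

   RA\[i\] = (d\[i\] − d\[i+1\]) / d\[1\],  RA\[n\] = d\[n\] / d\[1\]

   (negatives clamped, vector renormalized). Genes are classified into
   quantitative profiles: **P1** single isoform, **P2** proximal > 80 %,
   **P3** remaining genes with the distal sum (third isoform onward) < 10 %,
   **P4** otherwise.
7. **Introns & conservation** — 3′UTR splice junctions (depth > 1) are
   classified obligatory/optional by retained intronic coverage; catalogs
   from 2–4 datasets are compared per gene and rank (conserved when
   |Δlength| < 200 nt) with ROBUST / SEX-SPE / EXP-SPE summary flags in a
   2-sex × 2-series design.

A fully ground-truthed **synthetic-data generator**
(`synthetic_gene()`, `synthetic_truth()`, `generate_dataset()`) emulates
clustered genes on both strands, nested isoforms with stepwise coverage
drops, planted PAS hexamers, Poisson per-base noise, 3′ positional bias,
coverage gaps and 3′UTR introns, so the whole pipeline is testable without
sequencing data.

## Worked example

```r
library(utrapa)
library(dplyr)

genes <- bind_rows(
  synthetic_gene("OlfrX1", "+", cds_len = 1000,
                 utr_ends = c(500, 1200, 2400), abundances = c(0.5, 0.3, 0.2)),
  synthetic_gene("OlfrX2", "-", cds_len = 900,
                 utr_ends = c(800, 1900), abundances = c(0.6, 0.4)),
  synthetic_gene("OlfrX3", "+", cds_len = 1200, utr_ends = 1500, abundances = 1))
truth <- synthetic_truth(genes, depth_scale = 15000, seed = 42)
bundle <- generate_dataset(truth, dir = "demo")

run <- run_apa_pipeline(
  gtf = bundle$paths$gtf,
  bedgraphs = list(`+` = bundle$paths$bedgraph_plus,
                   `-` = bundle$paths$bedgraph_minus),
  fasta = bundle$paths$fasta,
  target_pattern = "^Olfr")

run
#> <apa_run> 3 annotated gene(s), 6 isoform(s), 66.7% with APA

tidy(run) |> select(gene_id, rank, length, category, relative_abundance)
#> # A tibble: 6 × 5
#>   gene_id  rank length category relative_abundance
#>   <chr>   <int>  <dbl> <chr>                 <dbl>
#> 1 OlfrX1      1    502 pUTR                  0.491
#> 2 OlfrX1      2   1199 dUTR1                 0.304
#> 3 OlfrX1      3   2400 dUTR2                 0.205
#> 4 OlfrX2      1    801 pUTR                  0.604
#> 5 OlfrX2      2   1900 dUTR1                 0.396
#> 6 OlfrX3      1   1500 sUTR                  1

glance(run)
#> # A tibble: 1 × 8
#>   n_genes n_isoforms pct_apa pct_p1 pct_p2 pct_p3 pct_p4 pct_canonical_pas
#>     <int>      <int>   <dbl>  <dbl>  <dbl>  <dbl>  <dbl>             <dbl>
#> 1       3          6    66.7   33.3      0   33.3   33.3               100
```

The planted 3′ ends (500/1200/2400, 800/1900, 1500 nt after the stop codon)
are recovered within a few nt, the planted abundance vectors within a few
percent, and every planted polyA signal is matched. `plot_gene_coverage(run,
"OlfrX1")` shows the coverage staircase with the called ends;
`autoplot(run)` summarizes the P1–P4 profiles. Multi-dataset runs feed
`compare_catalogs()` / `summary_flags()` for conservation analysis.

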