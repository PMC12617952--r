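# polyAdiff

Read-level statistics for poly(A) phenotypes in nanopore direct RNA
sequencing (DRS). Each aligned DRS read reports two per-molecule
quantities short reads cannot: the genomic position of its 3' end (which
poly(A) site the transcript used) and an estimated poly(A) tail length in
nucleotides. `polyAdiff` tests, gene by gene, whether either quantity's
*distribution* differs between two conditions — the analyses behind
phenotypes such as the genome-wide proximal poly(A)-site shifts and
temperature-sensitive tail-length changes of *Arabidopsis* m6A writer
complex mutants. It is written for transcriptomics analysts who already
have aligned reads with tail estimates and want calibrated, reproducible
per-gene tests rather than global density plots.

## The statistic

Both tests use the first Wasserstein (earth-mover) distance between the
conditions' empirical distributions,

```
W1(A, B) = ∫ |F_A(x) − F_B(x)| dx        (nt)
```

which is well-defined for unequal read counts, equals |δ| for a pure δ-nt
shift, and — unlike a difference of means — catches usage swaps between
poly(A) sites that barely move the mean. Significance comes from label
permutation (999 shuffles by default) with the add-one estimator
`p = (1 + #{W_perm ≥ W_obs}) / (n_perm + 1)`, Benjamini–Hochberg FDR
across genes, and direction calls (`proximal`/`distal` for 3'-end shifts
in transcript orientation, `shorter`/`longer` for tails) gated at
FDR < 0.05. Genes need ≥ 10 reads per condition (replicates pooled);
spike-in calibration transcripts are summarized but never tested. A
gene-level 2×2 Fisher exact test relates category membership (e.g.
defence annotation) to m6A-modification status over a
coverage-filtered background (> 20 mean baseline reads). A synthetic
cohort generator (poly(A)-site mixtures, gamma tails with an optional
~30 nt periodic component, negative-binomial depth, a 30 nt constant-tail
spike-in) provides ground truth for every claim.

See `vignettes/wasserstein-polyA-methods.Rmd` for the model, defaults,
and design decisions.

## Worked example

```r
library(polyAdiff)

scenario <- paper_like_scenario("combined", n_genes = 100, seed = 42)
cohort   <- generate_cohort(scenario)

apa <- run_apa_analysis(cohort$reads, cohort$annotation, cohort$manifest,
                        n_perm = 999, seed = 42)
head(apa[apa$direction != "none", ], 3)
#>     gene_id   n_A   n_B   emd_nt p_value   fdr mean_shift_nt direction
#> 1: GENE0001    57    48 242.7895   0.001  0.01     -242.7895  proximal
#> 2: GENE0002    49    77 304.4545   0.001  0.01     -304.4545  proximal
#> 3: GENE0003    48    74 204.1025   0.001  0.01     -204.1025  proximal

tl <- run_tail_analysis(cohort$reads, cohort$annotation, cohort$manifest,
                        n_perm = 999, seed = 42)
table(tl$results$direction)
#> longer   none
#>      7     93
tl$summary
#> global_tail_summary: 9616 tail-bearing reads, 500-bin densities on [0, 500] nt
#>   spike-in median tail (nt): mut_rep1=29.8, mut_rep2=29.9, WT_rep1=30.1, WT_rep2=29.6
```

Reading the output: `GENE0001` moves 243 nt of transport distance between
conditions with the smallest attainable p (0.001 at 999 permutations);
the negative mean shift means condition B's 3' ends sit promoter-proximal
of condition A's. The cohort planted proximal usage swaps in 10 of the
100 genes (`GENE0001`–`GENE0010`) and +20 nt tails in the next 10; the
tail scan recovers 7 of its 10 at this depth. The spike-in medians sit at
its nominal 30 nt tail, confirming tail calibration.

Real data enter the same way through files: `read_annotation()` (BED6 +
optional flags TSV), `read_manifest()` (sample-to-condition TSV), and
`read_read_table()` (one aligned read per row: gene, 3'-end coordinate,
tail length or `.`, sample).

## The analysis workflow

`analysis/` holds the numbered drivers that reproduce the full study-like
workflow on a simulated 1000-gene cohort, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort + ground truth
Rscript analysis/02_apa_shift.R         # poly(A)-site usage scan
Rscript analysis/03_tail_length.R       # tail-length scan + summaries
Rscript analysis/04_enrichment.R        # defence × m6A Fisher test
Rscript analysis/05_null_calibration.R  # type-I error check
```

`run_pipeline(run_config(...))` chains the same stages
programmatically with provenance and a run-summary sidecar.

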