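#!/usr/bin/env Rscript
# Differential poly(A)-site usage: per-gene Wasserstein distance between
# the two conditions' transcript-oriented read 3'-end distributions,
# permutation p-values (999 label shuffles), BH FDR, and strand-aware
# proximal/distal direction calls; then a check against the simulated
# ground truth.

library(polyAdiff)
library(data.table)

seed <- 1234L
cohort <- read_cohort("results/cohort")

apa <- run_apa_analysis(cohort$reads, cohort$annotation, cohort$manifest,
                        n_perm = 999, seed = seed, min_reads = 10,
                        fdr_threshold = 0.05)
write_results(apa, "results/apa_results.tsv")

cat(sprintf("genes tested: %d (skipped below read filter: %d)\n",
            nrow(apa), nrow(attr(apa, "skipped"))))
print(table(apa$direction))

m <- merge(apa, cohort$ground_truth, by = "gene_id")
planted <- m[apa_shifted == TRUE]
calls <- m[direction != "none"]
cat(sprintf("recall of planted proximal shifts: %.3f (%d genes)\n",
            mean(planted$direction == "proximal"), nrow(planted)))
cat(sprintf("false-discovery proportion among calls: %.3f (%d calls)\n",
            if (nrow(calls)) mean(!calls$apa_shifted) else 0, nrow(calls)))
cat(sprintf("median distance at planted genes: %.0f nt (programmed: 0.6 x separation)\n",
            median(planted$emd_nt)))
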