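---
title: "Methods: Wasserstein permutation tests for poly(A) phenotypes in direct RNA sequencing"
author: "polyAdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Wasserstein permutation tests for poly(A) phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Nanopore direct RNA sequencing reads native mRNA molecules end to end, so
each aligned read carries two quantities that short-read data cannot give
per molecule: the genomic position of its 3' end (which poly(A) site the
transcript used) and an estimate of its poly(A) tail length in
nucleotides. In plants, mutants of the mRNA m6A writer complex (e.g.
VIRILIZER-class mutants in *Arabidopsis*) show genome-wide shifts towards
promoter-proximal poly(A)-site usage and temperature-sensitive changes in
poly(A) tail-length distributions, alongside autoimmune gene expression.
This package implements the read-level statistics needed to detect those
phenotypes gene by gene from a table of aligned-read summaries, together
with a synthetic cohort generator that provides ground truth for
validating every claim the tests make.

The package deliberately consumes *summaries*: basecalling, alignment,
tail-length estimation from raw signal, and m6A site calling are all
upstream tools' jobs. m6A status enters only as a per-gene boolean (a gene
counts as modified when the upstream caller reports at least one site
above its probability-modified threshold of 0.9 in a baseline sample).

## The test statistic

Both differential analyses use the first Wasserstein (earth-mover)
distance between the two conditions' empirical distributions. For
one-dimensional distributions with CDFs $F_A$ and $F_B$,

$$ W_1(A, B) = \int_{-\infty}^{\infty} \lvert F_A(x) - F_B(x) \rvert \, dx, $$

with each read carrying mass $1/n_A$ (respectively $1/n_B$) within its
sample. This is the only definition that is well-defined for arbitrary,
unequal read counts, and it equals the optimal-transport cost on uniform
point masses; the test suite verifies the implementation against an
explicit linear-programming transport solver to $10^{-9}$. $W_1$ is in
nucleotides in both applications: nt of genome for 3'-end shifts, nt of
tail for tail-length shifts. Unlike a difference of means, it detects
usage swaps between poly(A) sites that leave the mean nearly unchanged,
and for a pure location shift of $\delta$ nt it equals $|\delta|$ exactly.

For the 3'-end analysis, coordinates are first transformed into
transcript orientation (`+` strand as-is, `-` strand negated) so that
"larger" always means "more distal"; a negative mean shift in condition B
is a proximal (promoter-ward) shift. The tests are provably invariant
under mirroring a locus to the opposite strand.

## Permutation inference

Significance is assessed by label permutation: the pooled reads are
randomly re-partitioned, without replacement, into groups of the original
sizes, 999 times by default, and

$$ p = \frac{1 + \#\{W^{perm} \ge W^{obs}\}}{n_{perm} + 1}. $$

The add-one estimator keeps $p$ valid and strictly positive (the floor is
$1/(n_{perm}+1) = 0.001$ at the default), and ties count as exceedances,
which is conservative. Replicates are pooled within condition before
testing; the permutation null therefore speaks to the read-level mixing
of the two pooled libraries, not to biological replicate variance (see
Limitations).

Each gene's permutation stream is seeded by a deterministic hash of
(master seed, gene id), so results are independent of the order in which
genes are scanned and of any parallel scheduling, and two runs with the
same configuration are byte-identical.

Across genes, raw p-values get Benjamini–Hochberg step-up adjustment —
the field default; direction labels (`proximal`/`distal`,
`shorter`/`longer`) are only assigned below the FDR threshold (default
0.05), with no additional effect-size floor. Genes need at least 10 reads
in each condition to be tested (the standard filter for the tail
analysis, applied uniformly to both tests); spike-in transcripts are
excluded from testing and from the FDR family but always summarized.

One reading of the protocol would compare the observed distance only to
the *maximum* permuted distance; the standard full-distribution
permutation p is used instead, with the maximum retained in
`max_perm_distance` for diagnostics. Likewise, the per-gene statistic is
the distance between full distributions; the mean difference is reported
alongside (`mean_shift_nt` / `delta_mean_nt`) because direction must be a
scalar.

## Enrichment test

The category-vs-m6A analysis is a gene-level 2×2 Fisher exact test:
background = genes with mean read count strictly greater than 20 across
the designated baseline samples (strict inequality; a gene at exactly the
threshold is excluded), cross-classified by category membership (e.g. a
defence annotation) and the m6A flag. The reported odds ratio is the
sample odds ratio $(ad)/(bc)$ — not the conditional-MLE estimate — with
the exact two-sided hypergeometric p. Exact Fisher p-values are discrete
and conservative: under random flags their distribution is super-uniform
(mean above 0.5), so calibration checks assert validity at each level and
distributional agreement with an independent enumeration oracle rather
than literal uniformity.

## The synthetic cohort generator

The generator emulates the statistical structure the analyses assume, per
gene and sample:

* **Read depth**: negative binomial with (mean, dispersion)
  parameterization, variance $\mu + \mu^2/\phi$ ($\phi$ is `size` in
  `rnbinom`). Stated explicitly to avoid the two-convention trap.
* **3' ends**: a mixture over poly(A)-site clusters with
  condition-dependent usage weights; each read adds rounded Gaussian
  positional noise (site cluster sd 15 nt, a typical direct-RNA 3'-end
  spread). Offsets are defined in transcript orientation and reflected
  onto the genome for `-` strand genes.
* **Tail lengths**: gamma distributed per condition, optionally location
  shifted; an optional periodic component multiplies the density by
  $1 + a \cos(2\pi x / T)$ (renormalized, sampled by rejection) with
  $T = 30$ nt and $a = 0.25$ by default, emulating the
  poly(A)-binding-protein footprint periodicity visible in real tail
  estimates. A single cosine term was chosen over a Gaussian comb: one
  parameter, trivially renormalizable, and sufficient to reproduce the
  spectral peak at $1/T$ that the tests assert. Gaussian measurement
  noise (sd 3 nt) is added and tails are floored at 0; 5% of reads carry
  no tail estimate, as not every read yields one.
* **Spike-in**: one transcript with a degenerate 30 nt tail plus
  measurement noise, a synthetic stand-in for the yeast enolase
  calibration standard; its per-sample median is reported against the
  nominal length.
* **Flags**: m6A status is Bernoulli(0.4) and independent of the
  "defence" category (10% of genes) unless a coupling is requested
  (`category_m6a_prob = 0.2` plants an odds ratio of 0.375).

Preset scenarios fix the study conditions: the `null` preset uses broad
gamma(shape 4, scale 20) tails (mean 80, sd 40 nt) and ~30 reads per
condition for type-I calibration; the effect presets (`apa_shift`,
`tail_shift`, `combined`) give 10% of genes an 80/20→20/80 usage swap
between sites 300–500 nt apart, or a +20 nt tail shift, at ~50 reads per
condition, with per-gene baseline tails gamma(shape 16) and gene-specific
means uniform on 60–100 nt (per-gene sd 15–25 nt, the narrower spread
realistic for a single gene's tail distribution as opposed to the global
mixture). At these settings the tail test's recall of planted shifts sits
around 0.9 and fluctuates a few points between cohorts; the usage-swap
effect is much stronger (recall ~1) because a 240+ nt transport distance
dwarfs the 15 nt within-site spread.

What the generator does **not** emulate: basecalling and alignment error,
splice structure, gene-family cross-mapping, batch effects between
replicates, any mechanistic link between m6A loss and tail length, and
biological replicate variance beyond NB depth noise. Passing tests
therefore demonstrate that the statistics do what they claim on data with
the assumed structure — calibrated nulls, recoverable planted effects —
not that real libraries satisfy those assumptions.

## Numerical choices

* The distance is computed by one sort of the pooled sample and an
  $O(n)$ walk of the CDF difference; tied values contribute zero-width
  intervals, so tie order is irrelevant and identical multisets give
  exactly 0.
* Permutations shuffle only the group indicator over the pooled sorted
  values (Fisher–Yates on R's RNG), so a permutation that reproduces the
  original partition reproduces the observed distance bit for bit, and
  the tie rule engages exactly.
* Result tables are written with 17 significant digits, so a write/read
  round trip reproduces every double exactly; missing values are `"."`.
* Global tail densities use fixed 1-nt bins on [0, 500] nt; values
  outside the range are clamped into the terminal bins so every curve
  integrates to 1 (to $10^{-9}$).
* Coordinates are 0-based half-open throughout (the BED dialect); a
  gene's 3'-most base is `end - 1` on `+` and `start` on `-`.

## Problem sizes

Calibration and recovery properties are exercised at the sizes they are
stated for: 1000-gene cohorts (~1e5 reads) for the null rejection rate,
p-value uniformity, and planted-effect recovery; 200-instance oracle
comparisons for the transport distance; 200-replicate flag simulations
for enrichment calibration. A full 1000-gene scan with 999 permutations
per gene takes a few seconds on one core.

## Limitations

* Pooling replicates ignores between-replicate variance; a significant
  gene means the pooled libraries differ, which is the protocol's claim,
  but stratified or hierarchical permutation would be needed to
  generalize to replicate populations.
* The 3'-end test compares full end-position distributions; it does not
  cluster reads into discrete poly(A) sites or name which site gained
  usage.
* Tail-length estimates are taken at face value; estimator bias (e.g.
  the spike-in's nominal 30 nt reading as ~33 nt in real data) is
  reported via the spike-in medians, not corrected.
* The enrichment test is gene-level; a site-level analysis could weight
  genes by their number of m6A sites and reach different conclusions.
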