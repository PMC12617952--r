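#' Aggregate poly(A) tail lengths per gene and condition
#'
#' Pools replicates within each contrast condition and collects, per gene,
#' the multiset of estimated tail lengths in each condition. Reads without
#' a tail estimate are dropped here (their count is reported via a
#' message); genes with no tail-bearing reads are simply absent. Spike-in
#' genes are retained — they are excluded from testing downstream but used
#' for calibration reporting.
#'
#' @param reads Read table.
#' @param manifest Condition manifest.
#' @return A named list (one element per gene) of `list(A = , B = )`
#'   numeric tail-length vectors.
#' @export
aggregate_tails_by_gene <- function(reads, manifest) {
  reads <- data.table::as.data.table(reads)
  manifest <- read_manifest(manifest)
  n_missing <- sum(is.na(reads$tail_length))
  if (n_missing > 0)
    message(sprintf(
      "aggregate_tails_by_gene: dropping %d reads without tail estimate",
      n_missing))
  rd <- reads[!is.na(tail_length)]
  grp <- manifest$group[match(rd$sample_id, manifest$sample_id)]
  rd <- rd[grp %in% c("A", "B")]
  grp <- grp[grp %in% c("A", "B")]
  rd[, grp := grp]
  lapply(split(rd[, list(tail_length, grp)], rd$gene_id), function(v) {
    list(A = v$tail_length[v$grp == "A"], B = v$tail_length[v$grp == "B"])
  })
}

#' Permutation test for a tail-length distribution difference at one gene
#'
#' Identical machinery to [test_gene_shift()] but on estimated poly(A)
#' tail lengths: 1-Wasserstein distance between the two conditions' tail
#' distributions, label-permutation p-value, and the signed mean
#' difference (positive = condition B tails longer).
#'
#' @param A,B Numeric tail-length vectors for the two conditions.
#' @param n_perm Permutations (default 999).
#' @param seed Integer seed.
#' @param min_reads Per-condition filter (default 10, the standard filter
#'   for this analysis); below it the gene is not testable and `NULL` is
#'   returned.
#' @return A one-row `data.table` with `n_A`, `n_B`, `wasserstein_nt`,
#'   `p_value`, `delta_mean_nt`, or `NULL` below the filter.
#' @export
test_gene_tails <- function(A, B, n_perm = 999L, seed, min_reads = 10L) {
  if (length(A) < min_reads || length(B) < min_reads) return(NULL)
  pt <- permutation_test(A, B, n_perm = n_perm, seed = seed)
  data.table::data.table(
    n_A = length(A), n_B = length(B),
    wasserstein_nt = pt$observed_distance, p_value = pt$p_value,
    delta_mean_nt = mean(B) - mean(A)
  )
}

# Normalized histogram density over fixed bin edges; values outside the
# range are clamped into the terminal bins so every curve integrates to 1.
.tail_density <- function(values, edges) {
  values <- pmin(pmax(values, edges[1]), edges[length(edges)])
  h <- graphics::hist(values, breaks = edges, plot = FALSE)
  h$counts / (length(values) * diff(edges))
}

#' Global poly(A) tail-length summary
#'
#' Histogram densities of estimated tail lengths on fixed bins (default
#' 1-nt bins over 0–500 nt), pooled per condition and separately per
#' sample, plus the per-sample median tail of spike-in reads compared to
#' calibration expectations.
#'
#' @param reads Read table.
#' @param annotation Annotation table (spike-in flags used).
#' @param manifest Condition manifest.
#' @param bin_edges Bin edges in nt; default `0:500`.
#' @return An object of class `"global_tail_summary"`: list with
#'   `bin_edges`, `condition_density` (named list `A`, `B`, reads pooled
#'   over replicates, spike-ins excluded), `sample_density` (one curve per
#'   sample), `spikein_median_nt` (named per-sample medians; `NULL` when
#'   no spike-in reads exist), and `n_reads`.
#' @export
global_tail_summary <- function(reads, annotation, manifest,
                                bin_edges = 0:500) {
  reads <- data.table::as.data.table(reads)
  annotation <- data.table::as.data.table(annotation)
  manifest <- read_manifest(manifest)
  rd <- reads[!is.na(tail_length)]
  spike <- isTRUE_vec(annotation$is_spikein[match(rd$gene_id,
                                                  annotation$gene_id)])
  grp <- manifest$group[match(rd$sample_id, manifest$sample_id)]

  main <- rd[!spike & grp %in% c("A", "B")]
  main_grp <- grp[!spike & grp %in% c("A", "B")]
  cond_density <- lapply(c(A = "A", B = "B"), function(g)
    .tail_density(main$tail_length[main_grp == g], bin_edges))
  sample_density <- lapply(
    stats::setNames(nm = sort(unique(main$sample_id))),
    function(s) .tail_density(main$tail_length[main$sample_id == s],
                              bin_edges))

  spikes <- rd[spike]
  spikein_median <- if (nrow(spikes) == 0L) NULL else
    vapply(split(spikes$tail_length, spikes$sample_id), stats::median,
           numeric(1))

  structure(
    list(bin_edges = bin_edges, condition_density = cond_density,
         sample_density = sample_density,
         spikein_median_nt = spikein_median, n_reads = nrow(main)),
    class = "global_tail_summary"
  )
}

#' @export
print.global_tail_summary <- function(x, ...) {
  cat(sprintf(
    "global_tail_summary: %d tail-bearing reads, %d-bin densities on [%g, %g] nt\n",
    x$n_reads, length(x$bin_edges) - 1L, min(x$bin_edges), max(x$bin_edges)))
  if (!is.null(x$spikein_median_nt)) {
    cat("  spike-in median tail (nt):",
        paste(sprintf("%s=%.1f", names(x$spikein_median_nt),
                      x$spikein_median_nt), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten a tail summary to a long table
#'
#' @param x A `global_tail_summary`.
#' @param ... Unused.
#' @return A data.frame with columns `curve` (`condition:A`, `sample:WT_rep1`,
#'   ...), `bin_left`, `bin_right`, `density`.
#' @export
as.data.frame.global_tail_summary <- function(x, ...) {
  edges <- x$bin_edges
  one <- function(label, d) data.frame(
    curve = label, bin_left = edges[-length(edges)], bin_right = edges[-1],
    density = d)
  curves <- c(
    lapply(names(x$condition_density), function(g)
      one(paste0("condition:", g), x$condition_density[[g]])),
    lapply(names(x$sample_density), function(s)
      one(paste0("sample:", s), x$sample_density[[s]]))
  )
  do.call(rbind, curves)
}

#' Per-gene differential poly(A) tail-length scan with global summary
#'
#' For every gene with at least `min_reads` tail-bearing reads in each
#' condition (replicates pooled; spike-ins excluded from testing and from
#' the FDR family), compares the two conditions' tail-length distributions
#' with the 1-Wasserstein distance and a label-permutation p-value;
#' Benjamini-Hochberg FDR across tested genes gates the `shorter`/`longer`
#' direction call (sign of the mean difference, B relative to A). Also
#' returns the [global_tail_summary()] of all tail-bearing reads,
#' including per-sample spike-in medians.
#'
#' @inheritParams run_apa_analysis
#' @param bin_edges Bin edges for the global summary; default `0:500` nt.
#' @return A list with `results` (a `data.table` sorted by `gene_id`:
#'   `gene_id`, `n_A`, `n_B`, `wasserstein_nt`, `p_value`, `fdr`,
#'   `delta_mean_nt`, `direction`; skipped genes in `attr(, "skipped")`)
#'   and `summary` (a `global_tail_summary`).
#' @export
run_tail_analysis <- function(reads, annotation, manifest, n_perm = 999L,
                              seed, min_reads = 10L, fdr_threshold = 0.05,
                              bin_edges = 0:500) {
  reads <- data.table::as.data.table(reads)
  annotation <- data.table::as.data.table(annotation)
  manifest <- read_manifest(manifest)

  summary <- global_tail_summary(reads, annotation, manifest, bin_edges)

  rd <- reads[!is.na(tail_length)]
  spike <- isTRUE_vec(annotation$is_spikein[match(rd$gene_id,
                                                  annotation$gene_id)])
  tbl <- data.table::data.table(
    gene_id = rd$gene_id, value = rd$tail_length,
    grp = manifest$group[match(rd$sample_id, manifest$sample_id)],
    spike = spike
  )
  tbl <- tbl[grp %in% c("A", "B") & !spike]

  scan <- .permutation_scan(tbl, n_perm = n_perm, seed = seed,
                            min_reads = min_reads)
  res <- scan$results
  if (nrow(res) == 0L) {
    warning("run_tail_analysis: no gene meets the read filter in both conditions")
    out <- data.table::data.table(
      gene_id = character(0), n_A = integer(0), n_B = integer(0),
      wasserstein_nt = numeric(0), p_value = numeric(0), fdr = numeric(0),
      delta_mean_nt = numeric(0), direction = character(0))
    data.table::setattr(out, "skipped", scan$skipped)
    return(list(results = out, summary = summary))
  }
  data.table::setnames(res, c("distance", "shift"),
                       c("wasserstein_nt", "delta_mean_nt"))
  res[, fdr := bh_fdr(p_value)]
  res[, direction := ifelse(fdr >= fdr_threshold, "none",
                     ifelse(delta_mean_nt > 0, "longer",
                     ifelse(delta_mean_nt < 0, "shorter", "none")))]
  data.table::setcolorder(res, c("gene_id", "n_A", "n_B", "wasserstein_nt",
                                 "p_value", "fdr", "delta_mean_nt",
                                 "direction"))
  data.table::setorder(res, gene_id)
  data.table::setattr(res, "skipped", scan$skipped)
  list(results = res, summary = summary)
}

#' Tail-length summaries stratified by m6A-modification status
#'
#' Computes [global_tail_summary()] separately for genes flagged as
#' m6A-modified and for unflagged genes (identical binning). Genes whose
#' flag is missing are left out of both strata; an empty stratum is
#' omitted with a warning.
#'
#' @inheritParams global_tail_summary
#' @return A named list with elements `m6a_modified` and/or
#'   `not_modified`, each a `global_tail_summary`.
#' @export
summarize_by_m6a_status <- function(reads, annotation, manifest,
                                    bin_edges = 0:500) {
  annotation <- data.table::as.data.table(annotation)
  reads <- data.table::as.data.table(reads)
  if (all(is.na(annotation$is_m6a_modified)))
    stop("summarize_by_m6a_status: no is_m6a_modified flags present; ",
         "omit this step")
  strata <- list(
    m6a_modified = annotation$gene_id[isTRUE_vec(annotation$is_m6a_modified)],
    not_modified = annotation$gene_id[!is.na(annotation$is_m6a_modified) &
                                        !annotation$is_m6a_modified]
  )
  out <- list()
  for (nm in names(strata)) {
    rd <- reads[gene_id %in% strata[[nm]]]
    if (nrow(rd[!is.na(tail_length)]) == 0L) {
      warning("summarize_by_m6a_status: stratum ", nm,
              " has no tail-bearing reads; omitted")
      next
    }
    out[[nm]] <- global_tail_summary(rd, annotation, manifest, bin_edges)
  }
  out
}
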