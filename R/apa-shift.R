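# Transform genomic 3'-end coordinates into transcript orientation so that
# larger values are always more distal (closer to the annotated 3' end):
# + strand coordinates pass through, - strand coordinates are negated.
.orient_ends <- function(end_pos, strand) {
  ifelse(strand == "+", as.numeric(end_pos), -as.numeric(end_pos))
}

# Shared per-gene permutation scan. `tbl` has columns gene_id, value, grp
# ("A"/"B"). Returns list(results, skipped): results has one row per gene
# meeting min_reads in both groups, with a deterministic per-gene sub-seed
# derived from (seed, gene_id) so results do not depend on scan order.
.permutation_scan <- function(tbl, n_perm, seed, min_reads,
                              direction_stat = c("mean", "median")) {
  direction_stat <- match.arg(direction_stat)
  centre <- if (direction_stat == "mean") mean else stats::median
  counts <- tbl[, list(n_A = sum(grp == "A"), n_B = sum(grp == "B")),
                by = gene_id]
  data.table::setorder(counts, gene_id)
  eligible <- counts[n_A >= min_reads & n_B >= min_reads]
  skipped <- counts[n_A < min_reads | n_B < min_reads]
  skipped <- skipped[, list(gene_id, n_A, n_B,
                            reason = sprintf("fewer than %d reads in condition %s",
                                             min_reads,
                                             ifelse(n_A < min_reads, "A", "B")))]
  if (nrow(eligible) == 0L) {
    return(list(results = data.table::data.table(
      gene_id = character(0), n_A = integer(0), n_B = integer(0),
      distance = numeric(0), p_value = numeric(0), shift = numeric(0)),
      skipped = skipped))
  }
  vals <- split(tbl[, list(value, grp)], tbl$gene_id)
  res <- vector("list", nrow(eligible))
  for (i in seq_len(nrow(eligible))) {
    gid <- eligible$gene_id[i]
    v <- vals[[gid]]
    a <- v$value[v$grp == "A"]
    b <- v$value[v$grp == "B"]
    pt <- permutation_test(a, b, n_perm = n_perm,
                           seed = gene_seed(seed, gid))
    res[[i]] <- data.table::data.table(
      gene_id = gid, n_A = length(a), n_B = length(b),
      distance = pt$observed_distance, p_value = pt$p_value,
      shift = centre(b) - centre(a)
    )
  }
  list(results = data.table::rbindlist(res), skipped = skipped)
}

#' Collect transcript-oriented 3'-end positions for one gene
#'
#' Groups a gene's reads into the two contrast conditions and transforms
#' their genomic 3'-end coordinates into transcript orientation (larger =
#' more distal). Reads without a tail-length estimate are included: the
#' 3'-end analysis needs no tail estimate.
#'
#' @param reads Read table (already restricted to, or containing, this
#'   gene's reads).
#' @param gene A single-row annotation entry, or a gene id present in
#'   `annotation`-style tables passed via `reads`.
#' @param manifest Condition manifest.
#' @return `list(A = numeric, B = numeric)` of transformed end positions.
#' @export
collect_end_positions <- function(reads, gene, manifest) {
  reads <- data.table::as.data.table(reads)
  manifest <- read_manifest(manifest)
  gene <- data.table::as.data.table(gene)
  if (nrow(gene) != 1L)
    stop("collect_end_positions: `gene` must be a single annotation row")
  rd <- reads[gene_id == gene$gene_id]
  if (nrow(rd) == 0L)
    return(list(A = numeric(0), B = numeric(0)))
  grp <- manifest$group[match(rd$sample_id, manifest$sample_id)]
  if (anyNA(grp))
    stop("collect_end_positions: read sample absent from manifest")
  val <- .orient_ends(rd$end_pos, rep(gene$strand, nrow(rd)))
  list(A = val[grp == "A"], B = val[grp == "B"])
}

#' Permutation test for a 3'-end usage shift at one gene
#'
#' Earth-mover distance between the two conditions' transcript-oriented
#' 3'-end position distributions, with a label-permutation p-value and the
#' signed mean shift (positive = condition B's 3' ends lie distal of
#' condition A's).
#'
#' @param A,B Numeric vectors of transcript-oriented end positions.
#' @param n_perm Permutations (default 999).
#' @param seed Integer seed.
#' @param min_reads Minimum reads required in each condition (default 10);
#'   below it the gene is not testable and `NULL` is returned.
#' @return A one-row `data.table` with `n_A`, `n_B`, `emd_nt`, `p_value`,
#'   `mean_shift_nt`, or `NULL` when below `min_reads`.
#' @export
test_gene_shift <- function(A, B, n_perm = 999L, seed, min_reads = 10L) {
  if (length(A) < min_reads || length(B) < min_reads) return(NULL)
  pt <- permutation_test(A, B, n_perm = n_perm, seed = seed)
  data.table::data.table(
    n_A = length(A), n_B = length(B),
    emd_nt = pt$observed_distance, p_value = pt$p_value,
    mean_shift_nt = mean(B) - mean(A)
  )
}

#' Per-gene differential poly(A)-site usage scan
#'
#' For every gene with at least `min_reads` reads in each condition
#' (replicates pooled within condition; spike-in genes excluded), tests
#' whether the distribution of read 3'-end positions differs between the
#' two conditions: the statistic is the 1-Wasserstein distance between the
#' transcript-oriented end-position distributions, significance comes from
#' label permutation, and Benjamini-Hochberg FDR is applied across all
#' tested genes. Genes passing the FDR threshold are called `proximal`
#' (condition B's ends shifted towards the promoter, negative mean shift)
#' or `distal`; all others are `none`.
#'
#' @param reads Read table ([read_read_table()] or [generate_cohort()]).
#' @param annotation Annotation table.
#' @param manifest Condition manifest.
#' @param n_perm Permutations per gene; default 999.
#' @param seed Master seed; per-gene sub-seeds come from [gene_seed()].
#' @param min_reads Per-condition read filter; default 10.
#' @param fdr_threshold FDR threshold gating direction calls; default 0.05.
#' @param direction_stat `"mean"` (default) or `"median"`: the location
#'   statistic defining the signed shift.
#' @return A `data.table` sorted by `gene_id` with columns `gene_id`,
#'   `n_A`, `n_B`, `emd_nt`, `p_value`, `fdr`, `mean_shift_nt`,
#'   `direction`; skipped genes (and why) in `attr(, "skipped")`.
#' @export
run_apa_analysis <- function(reads, annotation, manifest, n_perm = 999L,
                             seed, min_reads = 10L, fdr_threshold = 0.05,
                             direction_stat = c("mean", "median")) {
  reads <- data.table::as.data.table(reads)
  annotation <- data.table::as.data.table(annotation)
  manifest <- read_manifest(manifest)

  idx <- match(reads$gene_id, annotation$gene_id)
  if (anyNA(idx)) stop("run_apa_analysis: reads reference unknown genes")
  tbl <- data.table::data.table(
    gene_id = reads$gene_id,
    value = .orient_ends(reads$end_pos, annotation$strand[idx]),
    grp = manifest$group[match(reads$sample_id, manifest$sample_id)],
    spike = isTRUE_vec(annotation$is_spikein[idx])
  )
  tbl <- tbl[grp %in% c("A", "B") & !spike]

  scan <- .permutation_scan(tbl, n_perm = n_perm, seed = seed,
                            min_reads = min_reads,
                            direction_stat = direction_stat)
  res <- scan$results
  if (nrow(res) == 0L) {
    warning("run_apa_analysis: no gene meets the read filter in both conditions")
    out <- data.table::data.table(
      gene_id = character(0), n_A = integer(0), n_B = integer(0),
      emd_nt = numeric(0), p_value = numeric(0), fdr = numeric(0),
      mean_shift_nt = numeric(0), direction = character(0))
    data.table::setattr(out, "skipped", scan$skipped)
    return(out)
  }
  data.table::setnames(res, c("distance", "shift"),
                       c("emd_nt", "mean_shift_nt"))
  res[, fdr := bh_fdr(p_value)]
  res[, direction := ifelse(fdr >= fdr_threshold, "none",
                     ifelse(mean_shift_nt < 0, "proximal",
                     ifelse(mean_shift_nt > 0, "distal", "none")))]
  data.table::setcolorder(res, c("gene_id", "n_A", "n_B", "emd_nt",
                                 "p_value", "fdr", "mean_shift_nt",
                                 "direction"))
  data.table::setorder(res, gene_id)
  data.table::setattr(res, "skipped", scan$skipped)
  res[]
}

# TRUE where x is TRUE; FALSE for FALSE/NA (flags may be absent)
isTRUE_vec <- function(x) !is.na(x) & x
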