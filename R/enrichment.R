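#' Per-gene mean read count over a set of baseline samples
#'
#' Coverage statistic for the enrichment background filter: the mean
#' number of reads per gene across the designated baseline samples
#' (mirroring a filter computed over the wild-type samples across both
#' temperatures). Genes present in the annotation but with no reads get 0.
#'
#' @param reads Read table.
#' @param annotation Annotation table.
#' @param manifest Condition manifest.
#' @param baseline_samples Character vector of sample ids defining the
#'   baseline; default: all samples in condition `A`.
#' @return Named numeric vector of mean counts, one per annotated gene.
#' @export
mean_reads_per_gene <- function(reads, annotation, manifest,
                                baseline_samples = NULL) {
  reads <- data.table::as.data.table(reads)
  annotation <- data.table::as.data.table(annotation)
  manifest <- read_manifest(manifest)
  if (is.null(baseline_samples))
    baseline_samples <- manifest$sample_id[manifest$group == "A"]
  unknown <- setdiff(baseline_samples, manifest$sample_id)
  if (length(unknown))
    stop("mean_reads_per_gene: unknown baseline sample(s): ",
         paste(unknown, collapse = ", "))
  rd <- reads[sample_id %in% baseline_samples]
  counts <- table(factor(rd$gene_id, levels = annotation$gene_id))
  stats::setNames(as.numeric(counts) / length(baseline_samples),
                  annotation$gene_id)
}

#' Build the category-by-m6A 2x2 contingency table
#'
#' Background = genes with mean baseline read count strictly greater than
#' `min_mean_reads` (a gene at exactly the threshold is excluded) and a
#' non-missing m6A flag; spike-ins are never part of the background. Rows
#' cross in-category / not-in-category with m6A-modified / not.
#'
#' @param annotation Annotation table carrying `is_m6a_modified` and
#'   `category`.
#' @param mean_counts Named per-gene mean read counts (see
#'   [mean_reads_per_gene()]).
#' @param category Category label to test (default `"defence"`).
#' @param min_mean_reads Coverage filter, strict inequality; default 20.
#' @return A 2x2 integer matrix with rows `in_category`/`other` and
#'   columns `m6a`/`not_m6a`.
#' @export
build_contingency <- function(annotation, mean_counts,
                              category = "defence", min_mean_reads = 20) {
  ann <- data.table::as.data.table(annotation)
  mc <- mean_counts[match(ann$gene_id, names(mean_counts))]
  if (anyNA(mc))
    stop("build_contingency: mean_counts missing for some annotated genes")
  keep <- mc > min_mean_reads & !isTRUE_vec(ann$is_spikein) &
    !is.na(ann$is_m6a_modified)
  if (!any(keep))
    stop("build_contingency: no gene passes the coverage filter")
  in_cat <- !is.na(ann$category[keep]) & ann$category[keep] == category
  m6a <- ann$is_m6a_modified[keep]
  tab <- matrix(
    c(sum(in_cat & m6a), sum(in_cat & !m6a),
      sum(!in_cat & m6a), sum(!in_cat & !m6a)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("in_category", "other"), c("m6a", "not_m6a"))
  )
  storage.mode(tab) <- "integer"
  tab
}

#' Category vs m6A-status enrichment scan
#'
#' For each requested gene category, cross-classifies the coverage-filtered
#' background by category membership and m6A-modification status and runs
#' the two-sided Fisher exact test. An odds ratio below 1 means category
#' genes are depleted of the m6A flag relative to the background.
#'
#' @param annotation Annotation table.
#' @param mean_counts Named per-gene mean baseline read counts.
#' @param categories Character vector of category labels; default
#'   `"defence"`.
#' @param min_mean_reads Coverage filter (strict `>`); default 20.
#' @return A `data.table` with one row per category: the four table cells
#'   (`n_cat_m6a`, `n_cat_not`, `n_other_m6a`, `n_other_not`),
#'   `n_background`, `odds_ratio`, `p_value`.
#' @export
run_enrichment <- function(annotation, mean_counts, categories = "defence",
                           min_mean_reads = 20) {
  rows <- lapply(categories, function(cat) {
    tab <- build_contingency(annotation, mean_counts, category = cat,
                             min_mean_reads = min_mean_reads)
    ft <- fisher_2x2(tab)
    data.table::data.table(
      category = cat,
      n_cat_m6a = tab[1, 1], n_cat_not = tab[1, 2],
      n_other_m6a = tab[2, 1], n_other_not = tab[2, 2],
      n_background = sum(tab),
      odds_ratio = ft$odds_ratio, p_value = ft$p_value
    )
  })
  data.table::rbindlist(rows)
}
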