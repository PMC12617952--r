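#' Read a gene annotation from a BED6 file
#'
#' Parses a BED6 file (0-based half-open coordinates, gene identifier in
#' the name column) into the annotation table the analyses consume.
#' Optional per-gene flags — spike-in status, m6A-modification status as
#' called upstream (a gene counts as modified when the caller reports at
#' least one site above its probability-modified threshold of 0.9;
#' consumed here as a boolean, never computed), and category labels such
#' as `"defence"` — are merged from a separate flags table because BED
#' cannot carry them.
#'
#' @param path Path to a BED file with at least 6 tab-separated columns:
#'   chrom, start, end, name (gene id), score (ignored), strand.
#' @param flags Optional path to a TSV, or a data.frame, with column
#'   `gene_id` and any of `is_spikein` (logical), `is_m6a_modified`
#'   (logical), `category` (string, `""`/`"."` for none).
#' @return A `data.table` with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `is_spikein`, `is_m6a_modified`,
#'   `category`, keyed by `gene_id`. On the + strand a gene's 3'-most base
#'   is `end - 1`; on the - strand it is `start`.
#' @export
read_annotation <- function(path, flags = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("read_annotation: empty BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 6L)
  if (length(bad))
    stop("read_annotation: line ", bad[1L], " has ", n_fields[bad[1L]],
         " fields; BED6 requires at least 6")
  chrom  <- vapply(fields, `[[`, "", 1L)
  start  <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end    <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  name   <- vapply(fields, `[[`, "", 4L)
  strand <- vapply(fields, `[[`, "", 6L)

  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad))
    stop("read_annotation: line ", bad[1L], ": non-integer coordinates")
  bad <- which(start < 0)
  if (length(bad))
    stop("read_annotation: line ", bad[1L], ": negative start coordinate")
  bad <- which(start >= end)
  if (length(bad))
    stop("read_annotation: line ", bad[1L],
         ": start must be < end (0-based half-open)")
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop("read_annotation: line ", bad[1L], ": strand must be '+' or '-'")
  dup <- name[duplicated(name)]
  if (length(dup))
    stop("read_annotation: duplicate gene_id: ",
         paste(unique(dup), collapse = ", "))

  ann <- data.table::data.table(
    gene_id = name, chrom = chrom,
    start = as.integer(start), end = as.integer(end), strand = strand,
    is_spikein = FALSE, is_m6a_modified = NA, category = NA_character_
  )
  if (!is.null(flags)) {
    fl <- if (is.character(flags)) {
      data.table::fread(flags, sep = "\t", header = TRUE,
                        na.strings = c("", ".", "NA"))
    } else data.table::as.data.table(flags)
    if (!"gene_id" %in% names(fl))
      stop("read_annotation: flags table needs a gene_id column")
    unknown <- setdiff(fl$gene_id, ann$gene_id)
    if (length(unknown))
      stop("read_annotation: flags for unknown gene_id: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    idx <- match(fl$gene_id, ann$gene_id)
    if ("is_spikein" %in% names(fl))
      ann$is_spikein[idx] <- as.logical(fl$is_spikein)
    if ("is_m6a_modified" %in% names(fl))
      ann$is_m6a_modified[idx] <- as.logical(fl$is_m6a_modified)
    if ("category" %in% names(fl))
      ann$category[idx] <- as.character(fl$category)
  }
  ann$is_m6a_modified <- as.logical(ann$is_m6a_modified)
  data.table::setkey(ann, gene_id)
  ann[]
}

#' Read a sample/condition manifest
#'
#' The manifest declares the two-level contrast: each sample is assigned to
#' condition A, condition B, or excluded.
#'
#' @param path Path to a TSV with header columns `sample_id`, `genotype`,
#'   `temperature_C`, `replicate`, `group` (values `A`, `B`, or `exclude`),
#'   or a data.frame with those columns.
#' @return A keyed `data.table`; both `A` and `B` must contain at least one
#'   sample.
#' @export
read_manifest <- function(path) {
  mf <- if (is.character(path)) {
    data.table::fread(path, sep = "\t", header = TRUE, colClasses = list(
      character = c("sample_id", "genotype", "group")))
  } else data.table::as.data.table(path)
  need <- c("sample_id", "genotype", "temperature_C", "replicate", "group")
  miss <- setdiff(need, names(mf))
  if (length(miss))
    stop("read_manifest: missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(mf$sample_id))
    stop("read_manifest: duplicate sample_id")
  bad <- setdiff(unique(mf$group), c("A", "B", "exclude"))
  if (length(bad))
    stop("read_manifest: group must be A, B or exclude; saw: ",
         paste(bad, collapse = ", "))
  for (g in c("A", "B"))
    if (!any(mf$group == g))
      stop("read_manifest: condition ", g, " has no samples")
  mf <- mf[, c("sample_id", "genotype", "temperature_C", "replicate", "group"),
           with = FALSE]
  data.table::setkey(mf, sample_id)
  mf[]
}

#' Read a read-level summary table
#'
#' Loads the per-read table (one aligned direct-RNA read per row) and
#' validates it against the annotation and manifest. Reads whose tail
#' length could not be estimated (empty or `"."` in `tail_length`) are
#' retained with `tail_length = NA`: they still contribute to the 3'-end
#' analysis and are dropped only by the tail-length analysis.
#'
#' @param path Path to a TSV with header columns `read_id`, `gene_id`,
#'   `chrom`, `end_pos` (0-based genomic coordinate of the read's 3'-most
#'   aligned base), `strand`, `tail_length` (nt; may be missing),
#'   `sample_id`.
#' @param annotation Annotation table from [read_annotation()].
#' @param manifest Manifest from [read_manifest()].
#' @return A `data.table` of validated read records. A message reports how
#'   many rows lack a tail estimate.
#' @export
read_read_table <- function(path, annotation, manifest) {
  rd <- data.table::fread(
    path, sep = "\t", header = TRUE, na.strings = c("", "."),
    colClasses = list(character = c("read_id", "gene_id", "chrom",
                                    "strand", "sample_id"))
  )
  need <- c("read_id", "gene_id", "chrom", "end_pos", "strand",
            "tail_length", "sample_id")
  miss <- setdiff(need, names(rd))
  if (length(miss))
    stop("read_read_table: missing columns: ", paste(miss, collapse = ", "))
  rd <- rd[, need, with = FALSE]
  rd[, end_pos := as.integer(end_pos)]
  rd[, tail_length := as.numeric(tail_length)]

  if (anyNA(rd$end_pos) || any(rd$end_pos < 0))
    stop("read_read_table: end_pos must be a non-negative integer")
  bad_tail <- !is.na(rd$tail_length) &
    (rd$tail_length < 0 | !is.finite(rd$tail_length))
  if (any(bad_tail))
    stop("read_read_table: tail_length must be non-negative and finite")
  unknown_g <- setdiff(unique(rd$gene_id), annotation$gene_id)
  if (length(unknown_g))
    stop("read_read_table: gene_id not in annotation: ",
         paste(utils::head(unknown_g, 5L), collapse = ", "))
  unknown_s <- setdiff(unique(rd$sample_id), manifest$sample_id)
  if (length(unknown_s))
    stop("read_read_table: sample_id not in manifest: ",
         paste(utils::head(unknown_s, 5L), collapse = ", "))

  n_missing <- sum(is.na(rd$tail_length))
  message(sprintf(
    "read_read_table: %d reads loaded (%d without tail estimate, retained for 3'-end analysis)",
    nrow(rd), n_missing))
  rd[]
}

# Format a table for stable text output: numeric columns at full
# round-trip precision (%.17g), missing values as ".".
.format_table <- function(df) {
  df <- data.table::as.data.table(df)
  out <- data.table::copy(df)
  for (col in names(out)) {
    v <- out[[col]]
    if (is.double(v)) {
      s <- vapply(v, function(x) {
        if (is.na(x)) "." else sprintf("%.17g", x)
      }, "")
      data.table::set(out, j = col, value = s)
    } else if (is.logical(v) || is.integer(v)) {
      s <- as.character(v)
      s[is.na(s)] <- "."
      data.table::set(out, j = col, value = s)
    } else {
      s <- as.character(v)
      s[is.na(s)] <- "."
      data.table::set(out, j = col, value = s)
    }
  }
  out
}

#' Write a per-gene results table to TSV
#'
#' Rows are sorted by `gene_id`; floating-point columns are written with 17
#' significant digits so that reading the file back reproduces the values
#' exactly; missing values are written as `"."`. An empty collection yields
#' a header-only file.
#'
#' @param results A results table (e.g. from [run_apa_analysis()] or
#'   [run_tail_analysis()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  res <- data.table::as.data.table(results)
  if ("gene_id" %in% names(res)) data.table::setorder(res, gene_id)
  data.table::fwrite(.format_table(res), path, sep = "\t", quote = FALSE,
                     na = ".")
  invisible(path)
}

#' Write a cohort (reads, annotation, manifest, ground truth) to a directory
#'
#' Companion to [generate_cohort()]; writes `reads.tsv`, `genes.bed`,
#' `gene_flags.tsv`, `manifest.tsv` and, when present, `ground_truth.tsv`
#' in the formats the readers in this package consume.
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ann <- data.table::as.data.table(cohort$annotation)
  bed <- ann[, list(chrom, start, end, gene_id, score = 0L, strand)]
  data.table::fwrite(bed, file.path(dir, "genes.bed"), sep = "\t",
                     quote = FALSE, col.names = FALSE)
  flags <- ann[, list(gene_id, is_spikein, is_m6a_modified, category)]
  data.table::fwrite(.format_table(flags), file.path(dir, "gene_flags.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(.format_table(cohort$manifest),
                     file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(.format_table(cohort$reads), file.path(dir, "reads.tsv"),
                     sep = "\t", quote = FALSE)
  if (!is.null(cohort$ground_truth))
    data.table::fwrite(.format_table(cohort$ground_truth),
                       file.path(dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `genes.bed`, `gene_flags.tsv`,
#'   `manifest.tsv`, `reads.tsv`.
#' @return A list with `reads`, `annotation`, `manifest` (and
#'   `ground_truth` when the file is present).
#' @export
read_cohort <- function(dir) {
  ann <- read_annotation(file.path(dir, "genes.bed"),
                         flags = file.path(dir, "gene_flags.tsv"))
  mf <- read_manifest(file.path(dir, "manifest.tsv"))
  rd <- read_read_table(file.path(dir, "reads.tsv"), ann, mf)
  out <- list(reads = rd, annotation = ann, manifest = mf)
  gt <- file.path(dir, "ground_truth.tsv")
  if (file.exists(gt))
    out$ground_truth <- data.table::fread(gt, sep = "\t", header = TRUE,
                                          na.strings = c("", "."))
  out
}
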