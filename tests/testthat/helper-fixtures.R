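# In-code fixtures shared across test files.

write_bed <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

tiny_annotation <- function() {
  data.table::data.table(
    gene_id = c("G1", "G2"), chrom = "Chr1",
    start = c(100L, 5000L), end = c(2100L, 7000L),
    strand = c("+", "-"),
    is_spikein = FALSE, is_m6a_modified = c(TRUE, FALSE),
    category = c("defence", NA_character_)
  )
}

tiny_manifest <- function() {
  data.table::data.table(
    sample_id = c("s1", "s2", "s3", "s4"),
    genotype = c("WT", "WT", "mut", "mut"),
    temperature_C = 17, replicate = c(1L, 2L, 1L, 2L),
    group = c("A", "A", "B", "B")
  )
}

# Clamped histogram density on fixed edges (mirrors the package's summary
# binning; kept separate so summary tests don't depend on package internals).
.tail_density_for_test <- function(values, edges) {
  values <- pmin(pmax(values, edges[1]), edges[length(edges)])
  h <- hist(values, breaks = edges, plot = FALSE)
  h$counts / (length(values) * diff(edges))
}

# Hand-built read table: `ends`/`tails` are named lists gene -> condition
# -> vector; reads are split evenly between the condition's two samples.
tiny_reads <- function(ends, tails = NULL) {
  rows <- list()
  samples <- list(A = c("s1", "s2"), B = c("s3", "s4"))
  for (g in names(ends)) {
    for (cond in names(ends[[g]])) {
      e <- ends[[g]][[cond]]
      tl <- if (is.null(tails)) rep(NA_real_, length(e))
        else tails[[g]][[cond]]
      sm <- rep(samples[[cond]], length.out = length(e))
      rows[[paste(g, cond)]] <- data.table::data.table(
        read_id = sprintf("%s.%s.%03d", g, cond, seq_along(e)),
        gene_id = g, chrom = "Chr1", end_pos = as.integer(e),
        strand = "+", tail_length = tl, sample_id = sm
      )
    }
  }
  data.table::rbindlist(rows)
}
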