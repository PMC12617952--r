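test_that("collect_end_positions applies the strand convention", {
  ann <- tiny_annotation()
  mf <- tiny_manifest()
  reads <- tiny_reads(list(G1 = list(A = c(100, 200), B = c(150, 250)),
                           G2 = list(A = c(5100, 5200), B = c(5150, 5250))))
  plus <- collect_end_positions(reads, ann[gene_id == "G1"], mf)
  expect_equal(sort(plus$A), c(100, 200))
  # minus strand: coordinates negated, so genomically-upstream (larger
  # transformed) positions are distal
  minus <- collect_end_positions(reads, ann[gene_id == "G2"], mf)
  expect_equal(sort(minus$A), c(-5200, -5100))
  expect_gt(-5100, -5200)  # 5100 is distal of 5200 on the - strand
  expect_error(collect_end_positions(reads, ann, mf), "single annotation row")
})

test_that("test_gene_shift: identity, point-mass shift, sign convention", {
  same <- test_gene_shift(rep(100, 20), rep(100, 20), seed = 1)
  expect_equal(same$emd_nt, 0)
  expect_equal(same$p_value, 1)

  shift <- test_gene_shift(rep(500, 20), rep(300, 20), seed = 1)
  expect_equal(shift$emd_nt, 200)
  expect_equal(shift$mean_shift_nt, -200)  # B upstream of A: proximal
  expect_equal(shift$p_value, 0.001)

  expect_null(test_gene_shift(rep(1, 5), rep(2, 50), seed = 1,
                              min_reads = 10))
})

test_that("two-site usage swap has the closed-form distance", {
  # 80/20 -> 20/80 usage of two sites 400 nt apart: W1 = |0.8-0.2|*400
  A <- c(rep(100, 10), rep(500, 40))
  B <- c(rep(100, 40), rep(500, 10))
  expect_equal(wasserstein_1d(A, B), 0.6 * 400)
})

test_that("the per-gene scan filters, adjusts, and calls direction", {
  ann <- tiny_annotation()
  mf <- tiny_manifest()
  reads <- tiny_reads(list(
    G1 = list(A = rep(500, 20), B = rep(300, 20)),   # strong proximal shift
    G2 = list(A = 5100 + 0:14, B = 5100 + 0:8)       # B below min_reads
  ))
  expect_warning(
    res <- run_apa_analysis(reads, ann, mf, n_perm = 99, seed = 9),
    regexp = NA)
  expect_equal(res$gene_id, "G1")
  expect_equal(res$direction, "proximal")
  expect_equal(res$fdr, res$p_value)  # single tested gene
  skipped <- attr(res, "skipped")
  expect_equal(skipped$gene_id, "G2")
  expect_match(skipped$reason, "condition B")
})

test_that("results are invariant to read order and to coordinate offsets", {
  sc <- paper_like_scenario("apa_shift", n_genes = 30, seed = 5)
  co <- generate_cohort(sc)
  res1 <- run_apa_analysis(co$reads, co$annotation, co$manifest,
                           n_perm = 99, seed = 5)
  shuf <- co$reads[sample(nrow(co$reads))]
  res2 <- run_apa_analysis(shuf, co$annotation, co$manifest,
                           n_perm = 99, seed = 5)
  expect_equal(res1, res2, ignore_attr = TRUE)

  # adding a constant to every coordinate of one gene's reads leaves the
  # distance unchanged
  g <- res1$gene_id[1]
  rd <- co$reads[gene_id == g]
  rd2 <- data.table::copy(rd)[, end_pos := end_pos + 10000L]
  mfx <- co$manifest
  annx <- co$annotation[gene_id == g]
  s1 <- collect_end_positions(rd, annx, mfx)
  s2 <- collect_end_positions(rd2, annx, mfx)
  expect_equal(wasserstein_1d(s1$A, s1$B), wasserstein_1d(s2$A, s2$B))
})

test_that("mirroring a + strand gene onto the - strand preserves the call", {
  mf <- tiny_manifest()
  # + strand gene [1000, 3000): B shifted proximal by 200 nt
  ends_plus <- list(A = rep(2500L, 15) + rep(c(-3L, 3L), length.out = 15),
                    B = rep(2300L, 15) + rep(c(-3L, 3L), length.out = 15))
  # mirror through K: position p -> K - p, interval flips strand
  K <- 10000L
  ann <- data.table::data.table(
    gene_id = c("FWD", "REV"), chrom = "Chr1",
    start = c(1000L, K - 3000L + 1L), end = c(3000L, K - 1000L + 1L),
    strand = c("+", "-"), is_spikein = FALSE, is_m6a_modified = NA,
    category = NA_character_)
  reads <- data.table::rbindlist(list(
    tiny_reads(list(FWD = ends_plus)),
    tiny_reads(list(REV = lapply(ends_plus, function(e) K - e)))
  ))
  reads[gene_id == "REV", strand := "-"]
  sf <- collect_end_positions(reads, ann[gene_id == "FWD"], mf)
  sr <- collect_end_positions(reads, ann[gene_id == "REV"], mf)
  # transformed coordinates differ only by a constant, so with the same
  # permutation seed distance, p and sign are identical
  fwd <- test_gene_shift(sf$A, sf$B, n_perm = 199, seed = 31)
  rev <- test_gene_shift(sr$A, sr$B, n_perm = 199, seed = 31)
  expect_equal(fwd$emd_nt, rev$emd_nt)
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$mean_shift_nt, rev$mean_shift_nt)
  expect_lt(fwd$mean_shift_nt, 0)  # proximal shift in B

  # and through the full scan both mirror images are called proximal
  res <- run_apa_analysis(reads, ann, mf, n_perm = 199, seed = 31)
  expect_identical(res[gene_id == "FWD", direction], "proximal")
  expect_identical(res[gene_id == "REV", direction], "proximal")
  expect_equal(res[gene_id == "FWD", emd_nt], res[gene_id == "REV", emd_nt])
})

test_that("spike-in genes are excluded from testing and FDR", {
  sc <- paper_like_scenario("null", n_genes = 15, seed = 3)
  co <- generate_cohort(sc)
  res <- run_apa_analysis(co$reads, co$annotation, co$manifest,
                          n_perm = 49, seed = 3)
  expect_false("SPIKEIN_ENO2_SYNTH" %in% res$gene_id)
  expect_false("SPIKEIN_ENO2_SYNTH" %in% attr(res, "skipped")$gene_id)
})
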