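test_that("cohort generation is a pure function of the scenario", {
  sc <- paper_like_scenario("combined", n_genes = 20, seed = 41)
  c1 <- generate_cohort(sc)
  c2 <- generate_cohort(sc)
  expect_identical(c1$reads, c2$reads)
  expect_identical(c1$ground_truth, c2$ground_truth)
  c3 <- generate_cohort(paper_like_scenario("combined", n_genes = 20,
                                            seed = 42))
  expect_false(identical(c1$reads$end_pos, c3$reads$end_pos))
})

test_that("degenerate scenarios collapse to their deterministic limits", {
  genes <- data.table::data.table(
    gene_id = "G1", chrom = "Chr1", start = 10000L, end = 13000L,
    strand = "+", site_offsets = list(2800), site_sd = 0,
    weights_A = list(1), weights_B = list(1),
    tail_shape_A = 1, tail_scale_A = 1, tail_shift_A = 0,
    tail_shape_B = 1, tail_scale_B = 1, tail_shift_B = 0,
    depth_mean_A = 40, depth_mean_B = 40, depth_disp = 10,
    is_spikein = TRUE, spike_tail_nt = 30,
    is_m6a_modified = NA, category = NA_character_,
    apa_shifted = FALSE, tail_shifted = FALSE, tail_delta_nt = 0)
  sc <- sim_scenario(genes, tiny_manifest(), measurement_noise_sd = 0,
                     tail_missing_rate = 0, periodicity = NULL, seed = 2)
  co <- generate_cohort(sc)
  # degenerate tail, no noise: every tail exactly 30
  expect_true(all(co$reads$tail_length == 30))
  # single site, sd 0: every end position at the site
  expect_true(all(co$reads$end_pos == 10000L + 2800L))
})

test_that("scenario validation names the offending field", {
  genes <- paper_like_scenario("null", n_genes = 3, seed = 1)$genes
  mf <- tiny_manifest()
  bad <- data.table::copy(genes)
  bad$weights_A[[1]] <- c(0.5, 0.6)
  expect_error(sim_scenario(bad, mf), "weights_A")
  bad2 <- data.table::copy(genes)[, depth_disp := -1]
  expect_error(sim_scenario(bad2, mf), "depth_disp")
  expect_error(sim_scenario(genes, mf, measurement_noise_sd = -1),
               "measurement_noise_sd")
  expect_error(sim_scenario(genes, mf,
                            periodicity = list(period = 30, amplitude = 1)),
               "amplitude")
})

test_that("presets encode their programmed contrasts", {
  expect_error(paper_like_scenario("bogus"), "arg")

  null_sc <- paper_like_scenario("null", n_genes = 50, seed = 3)
  g <- null_sc$genes
  expect_identical(g$weights_A, g$weights_B)
  expect_true(all(g$tail_shift_B == 0))
  expect_equal(sum(g$apa_shifted), 0)

  tl <- paper_like_scenario("tail_shift", n_genes = 50, seed = 3)
  expect_equal(sum(tl$genes$tail_shifted), ceiling(0.1 * 50))
  expect_true(all(tl$genes[tail_shifted == TRUE, tail_shift_B] == 20))

  ap <- paper_like_scenario("apa_shift", n_genes = 50, seed = 3)
  aff <- ap$genes[apa_shifted == TRUE]
  expect_equal(nrow(aff), ceiling(0.1 * 50))
  seps <- vapply(aff$site_offsets, function(o) diff(range(o)), 0)
  expect_true(all(seps >= 300 & seps <= 500))
  expect_identical(aff$weights_A[[1]], c(0.2, 0.8))
  expect_identical(aff$weights_B[[1]], c(0.8, 0.2))

  cb <- paper_like_scenario("combined", n_genes = 50, seed = 3)
  expect_equal(sum(cb$genes$apa_shifted & cb$genes$tail_shifted), 0)
})

test_that("read depth follows the (mean, dispersion) NB parameterization", {
  sc <- paper_like_scenario("null", n_genes = 400, seed = 19,
                            depth_mean = 15)
  co <- generate_cohort(sc)
  counts <- co$reads[gene_id != "SPIKEIN_ENO2_SYNTH",
                     .N, by = list(gene_id, sample_id)]$N
  # variance = mu + mu^2/dispersion = 15 + 225/10 = 37.5
  expect_equal(mean(counts), 15, tolerance = 0.05)
  expect_equal(stats::var(counts), 37.5, tolerance = 0.15)
})

test_that("simulated tail means track the scenario parameters", {
  sc <- paper_like_scenario("tail_shift", n_genes = 150, seed = 37)
  co <- generate_cohort(sc)
  agg <- suppressMessages(aggregate_tails_by_gene(co$reads, co$manifest))
  gt <- co$ground_truth
  obs <- data.table::rbindlist(lapply(names(agg), function(g) {
    data.table::data.table(gene_id = g, mA = mean(agg[[g]]$A),
                           mB = mean(agg[[g]]$B))
  }))
  m <- merge(obs, gt, by = "gene_id")
  m <- m[is_spikein == FALSE]
  # periodic re-weighting and the 0-floor perturb the mean only slightly
  expect_lt(mean(abs(m$mA - m$mean_tail_A)), 4)
  delta <- m[tail_shifted == TRUE, mB - mA]
  expect_equal(mean(delta), 20, tolerance = 0.15)
})

test_that("periodic re-weighting leaves a spectral peak at 1/period", {
  genes <- paper_like_scenario("null", n_genes = 1, seed = 1)$genes[1]
  genes[, `:=`(depth_mean_A = 60000, depth_mean_B = 60000,
               tail_shape_A = 4, tail_scale_A = 20,
               tail_shape_B = 4, tail_scale_B = 20)]
  mf2 <- data.table::data.table(
    sample_id = c("a1", "b1"), genotype = c("WT", "mut"),
    temperature_C = 17, replicate = 1L, group = c("A", "B"))
  sc <- sim_scenario(genes, mf2, measurement_noise_sd = 0,
                     tail_missing_rate = 0,
                     periodicity = list(period = 30, amplitude = 0.5),
                     seed = 91)
  co <- generate_cohort(sc)
  tails <- co$reads$tail_length
  expect_gt(length(tails), 1e5)
  edges <- 0:400
  dens <- .tail_density_for_test(tails, edges)
  spec <- Mod(stats::fft(dens - mean(dens)))^2
  freq <- (seq_along(spec) - 1) / length(dens)
  band <- freq >= 1/35 & freq <= 1/25     # around the programmed 1/30
  flank <- (freq >= 1/60 & freq <= 1/40) | (freq >= 1/22 & freq <= 1/15)
  expect_gt(max(spec[band]), 5 * max(spec[flank]))
})
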