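#' Construct and validate a simulation scenario
#'
#' A scenario fully parameterizes a synthetic direct-RNA-seq cohort: per
#' gene, a mixture of poly(A)-site clusters with condition-dependent usage
#' weights, a condition-dependent gamma tail-length distribution (optional
#' location shift), negative-binomial read depth, and flags (spike-in,
#' m6A status, category); globally, a sample manifest, tail measurement
#' noise, the rate of reads without a tail estimate, and an optional
#' periodic re-weighting of the tail density emulating the ~30 nt
#' poly(A)-binding-protein footprint pattern seen in real tail estimates.
#'
#' The negative binomial is parameterized by (mean, dispersion) with
#' variance `mean + mean^2/dispersion` (i.e. dispersion is the `size`
#' parameter of [stats::rnbinom()]).
#'
#' @param genes A data.frame with one row per gene; see
#'   [paper_like_scenario()] for the construction used by the presets.
#'   Required columns: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `site_offsets` (list of transcript-orientation offsets from the gene
#'   start, nt), `site_sd`, `weights_A`, `weights_B` (list, simplex),
#'   `tail_shape_A`, `tail_scale_A`, `tail_shift_A`, `tail_shape_B`,
#'   `tail_scale_B`, `tail_shift_B`, `depth_mean_A`, `depth_mean_B`,
#'   `depth_disp`, `is_spikein`, `spike_tail_nt`, `is_m6a_modified`,
#'   `category`, `apa_shifted`, `tail_shifted`, `tail_delta_nt`.
#' @param samples Manifest data.frame (see [read_manifest()]).
#' @param measurement_noise_sd Gaussian sd (nt) added to every simulated
#'   tail-length estimate; default 3.
#' @param tail_missing_rate Fraction of reads with no tail estimate
#'   (`tail_length = NA`); default 0.05.
#' @param periodicity `NULL`, or `list(period, amplitude)` with amplitude
#'   in `[0, 1)`: the tail density is multiplied by
#'   `1 + amplitude * cos(2*pi*x/period)` and renormalized.
#' @param seed Integer seed owned by the scenario; [generate_cohort()] is a
#'   pure function of the scenario, including this seed.
#' @return An object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(genes, samples, measurement_noise_sd = 3,
                         tail_missing_rate = 0.05, periodicity = NULL,
                         seed = 1L) {
  genes <- data.table::as.data.table(genes)
  samples <- read_manifest(samples)
  sc <- structure(
    list(genes = genes, samples = samples,
         measurement_noise_sd = measurement_noise_sd,
         tail_missing_rate = tail_missing_rate,
         periodicity = periodicity, seed = as.integer(seed)),
    class = "sim_scenario"
  )
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  g <- sc$genes
  need <- c("gene_id", "chrom", "start", "end", "strand", "site_offsets",
            "site_sd", "weights_A", "weights_B",
            "tail_shape_A", "tail_scale_A", "tail_shift_A",
            "tail_shape_B", "tail_scale_B", "tail_shift_B",
            "depth_mean_A", "depth_mean_B", "depth_disp",
            "is_spikein", "spike_tail_nt", "is_m6a_modified", "category",
            "apa_shifted", "tail_shifted", "tail_delta_nt")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop("sim_scenario: genes table missing field(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(g$gene_id)) stop("sim_scenario: duplicate gene_id")
  for (i in seq_len(nrow(g))) {
    for (cond in c("A", "B")) {
      w <- g[[paste0("weights_", cond)]][[i]]
      k <- length(g$site_offsets[[i]])
      if (length(w) != k)
        stop("sim_scenario: gene ", g$gene_id[i], ": weights_", cond,
             " length != number of sites")
      if (abs(sum(w) - 1) > 1e-8 || any(w < 0))
        stop("sim_scenario: gene ", g$gene_id[i], ": weights_", cond,
             " must be a simplex vector")
    }
  }
  non_spike <- !g$is_spikein
  if (any(g$site_sd < 0)) stop("sim_scenario: site_sd must be >= 0")
  pos_cols <- c("tail_shape_A", "tail_scale_A", "tail_shape_B",
                "tail_scale_B", "depth_disp")
  for (col in pos_cols)
    if (any(g[[col]][non_spike] <= 0))
      stop("sim_scenario: field ", col, " must be > 0")
  if (any(c(g$depth_mean_A, g$depth_mean_B) <= 0))
    stop("sim_scenario: field depth_mean must be > 0")
  if (any(g$is_spikein & !is.finite(g$spike_tail_nt)))
    stop("sim_scenario: field spike_tail_nt required for spike-in genes")
  if (sc$measurement_noise_sd < 0)
    stop("sim_scenario: field measurement_noise_sd must be >= 0")
  if (sc$tail_missing_rate < 0 || sc$tail_missing_rate >= 1)
    stop("sim_scenario: field tail_missing_rate must be in [0, 1)")
  if (!is.null(sc$periodicity)) {
    p <- sc$periodicity
    if (!is.list(p) || is.null(p$period) || is.null(p$amplitude))
      stop("sim_scenario: field periodicity must be list(period, amplitude)")
    if (p$period <= 0) stop("sim_scenario: field periodicity$period must be > 0")
    if (p$amplitude < 0 || p$amplitude >= 1)
      stop("sim_scenario: field periodicity$amplitude must be in [0, 1)")
  }
  invisible(sc)
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "sim_scenario: %d genes (%d spike-in), %d samples, seed %d\n",
    nrow(x$genes), sum(x$genes$is_spikein), nrow(x$samples), x$seed))
  cat(sprintf("  apa-shifted: %d, tail-shifted: %d, periodicity: %s\n",
              sum(x$genes$apa_shifted), sum(x$genes$tail_shifted),
              if (is.null(x$periodicity)) "off" else
                sprintf("period %g nt, amplitude %g",
                        x$periodicity$period, x$periodicity$amplitude)))
  invisible(x)
}

#' Preset scenarios mirroring the study's qualitative conditions
#'
#' Builds a documented scenario for one of four presets:
#' \describe{
#'   \item{`null`}{All per-condition parameters identical. Tail lengths are
#'     gamma(shape 4, scale 20) (mean 80 nt, broad); read depth averages
#'     ~15 reads per sample, i.e. ~30 per condition with the default two
#'     replicates — the configuration used for type-I-error calibration.}
#'   \item{`apa_shift`}{10\% of genes carry two poly(A) sites 300–500 nt
#'     apart whose usage swaps from 20/80 (proximal/distal) in condition A
#'     to 80/20 in condition B — a proximal shift in B. ~25 reads per
#'     sample per gene.}
#'   \item{`tail_shift`}{10\% of genes have condition-B tails shifted +20 nt
#'     in mean (location shift of the gamma).}
#'   \item{`combined`}{Disjoint 10\% apa-shifted and 10\% tail-shifted gene
#'     sets in one cohort.}
#' }
#' All presets include one spike-in gene (`SPIKEIN_ENO2_SYNTH`, a synthetic
#' stand-in for the yeast enolase calibration standard) with a degenerate
#' 30 nt tail, a ~30 nt periodic component in the tail densities, 3 nt
#' tail measurement noise, and two replicates per condition (genotype
#' labels `WT`/`mut` at 17 C).
#'
#' In effect presets, per-gene baseline tail distributions are gamma with
#' shape 16 and gene-specific mean drawn uniformly from 60–100 nt
#' (per-gene sd 15–25 nt); the `null` preset instead uses the broad
#' gamma(4, 20) calibration condition for every gene.
#'
#' @param preset One of `"null"`, `"apa_shift"`, `"tail_shift"`,
#'   `"combined"`.
#' @param n_genes Number of genes (spike-in added on top); default 1000.
#' @param seed Scenario seed.
#' @param n_replicates Replicates per condition; default 2.
#' @param depth_mean Mean reads per gene per sample; default 15 for
#'   `null`, 25 otherwise.
#' @param effect_frac Fraction of genes carrying each programmed effect;
#'   default 0.1.
#' @param m6a_prob Probability a background gene is flagged m6A-modified;
#'   default 0.4.
#' @param category_frac Fraction of genes labelled with the `"defence"`
#'   category; default 0.1.
#' @param category_m6a_prob m6A probability for category genes; `NULL`
#'   (default) means equal to `m6a_prob`, i.e. the flag is independent of
#'   the category unless a coupling is requested explicitly.
#' @return A `sim_scenario`.
#' @export
paper_like_scenario <- function(preset = c("null", "apa_shift", "tail_shift",
                                           "combined"),
                                n_genes = 1000L, seed = 1L,
                                n_replicates = 2L, depth_mean = NULL,
                                effect_frac = 0.1, m6a_prob = 0.4,
                                category_frac = 0.1,
                                category_m6a_prob = NULL) {
  preset <- match.arg(preset)
  n_genes <- as.integer(n_genes)
  if (is.null(depth_mean)) depth_mean <- if (preset == "null") 15 else 25
  if (is.null(category_m6a_prob)) category_m6a_prob <- m6a_prob

  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))

  gene_len <- 3000L
  gid <- sprintf("GENE%04d", seq_len(n_genes))
  n_apa <- if (preset %in% c("apa_shift", "combined"))
    ceiling(effect_frac * n_genes) else 0L
  n_tail <- if (preset %in% c("tail_shift", "combined"))
    ceiling(effect_frac * n_genes) else 0L
  if (n_apa + n_tail > n_genes)
    stop("paper_like_scenario: effect_frac too large for n_genes")
  apa_idx <- seq_len(n_apa)
  tail_idx <- if (n_tail > 0) n_apa + seq_len(n_tail) else integer(0)

  site_offsets <- vector("list", n_genes)
  weights_A <- vector("list", n_genes)
  weights_B <- vector("list", n_genes)
  distal <- gene_len - 200
  for (i in seq_len(n_genes)) {
    if (i %in% apa_idx) {
      sep <- round(runif(1, 300, 500))
      site_offsets[[i]] <- c(distal - sep, distal)   # proximal, distal
      weights_A[[i]] <- c(0.2, 0.8)
      weights_B[[i]] <- c(0.8, 0.2)
    } else if (runif(1) < 0.3) {
      sep <- round(runif(1, 150, 400))
      w <- runif(1, 0.5, 0.9)
      site_offsets[[i]] <- c(distal - sep, distal)
      weights_A[[i]] <- weights_B[[i]] <- c(1 - w, w)
    } else {
      site_offsets[[i]] <- distal
      weights_A[[i]] <- weights_B[[i]] <- 1
    }
  }

  if (preset == "null") {
    shape <- rep(4, n_genes)
    scale <- rep(20, n_genes)
  } else {
    shape <- rep(16, n_genes)
    scale <- runif(n_genes, 60, 100) / 16
  }
  tail_delta <- numeric(n_genes)
  tail_delta[tail_idx] <- 20

  strand <- rep(c("+", "-"), length.out = n_genes)
  category <- rep(NA_character_, n_genes)
  category[runif(n_genes) < category_frac] <- "defence"
  p_m6a <- ifelse(!is.na(category) & category == "defence",
                  category_m6a_prob, m6a_prob)
  is_m6a <- runif(n_genes) < p_m6a

  genes <- data.table::data.table(
    gene_id = gid, chrom = "Chr1",
    start = 10000L + (seq_len(n_genes) - 1L) * 10000L,
    strand = strand,
    site_offsets = site_offsets, site_sd = 15,
    weights_A = weights_A, weights_B = weights_B,
    tail_shape_A = shape, tail_scale_A = scale, tail_shift_A = 0,
    tail_shape_B = shape, tail_scale_B = scale, tail_shift_B = tail_delta,
    depth_mean_A = depth_mean, depth_mean_B = depth_mean, depth_disp = 10,
    is_spikein = FALSE, spike_tail_nt = NA_real_,
    is_m6a_modified = is_m6a, category = category,
    apa_shifted = seq_len(n_genes) %in% apa_idx,
    tail_shifted = seq_len(n_genes) %in% tail_idx,
    tail_delta_nt = tail_delta
  )
  genes[, end := start + gene_len]

  spike <- data.table::data.table(
    gene_id = "SPIKEIN_ENO2_SYNTH", chrom = "SpikeIn",
    start = 1000L, end = 1000L + 1500L, strand = "+",
    site_offsets = list(1300), site_sd = 5,
    weights_A = list(1), weights_B = list(1),
    tail_shape_A = 1, tail_scale_A = 1, tail_shift_A = 0,
    tail_shape_B = 1, tail_scale_B = 1, tail_shift_B = 0,
    depth_mean_A = 100, depth_mean_B = 100, depth_disp = 10,
    is_spikein = TRUE, spike_tail_nt = 30,
    is_m6a_modified = NA, category = NA_character_,
    apa_shifted = FALSE, tail_shifted = FALSE, tail_delta_nt = 0
  )
  genes <- rbind(genes, spike)

  samples <- data.table::data.table(
    sample_id = c(sprintf("WT_rep%d", seq_len(n_replicates)),
                  sprintf("mut_rep%d", seq_len(n_replicates))),
    genotype = rep(c("WT", "mut"), each = n_replicates),
    temperature_C = 17,
    replicate = rep(seq_len(n_replicates), 2L),
    group = rep(c("A", "B"), each = n_replicates)
  )

  sim_scenario(genes, samples,
               measurement_noise_sd = 3, tail_missing_rate = 0.05,
               periodicity = list(period = 30, amplitude = 0.25),
               seed = seed)
}

# Draw n tail lengths from gamma(shape, scale) + shift, optionally
# re-weighted by 1 + amplitude*cos(2*pi*x/period) (renormalized) via
# rejection sampling with acceptance probability
# (1 + a*cos(.))/(1 + a) <= 1.
.draw_tails <- function(n, shape, scale, shift, periodicity) {
  if (n == 0L) return(numeric(0))
  if (is.null(periodicity) || periodicity$amplitude == 0)
    return(rgamma(n, shape = shape, scale = scale) + shift)
  a <- periodicity$amplitude
  per <- periodicity$period
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(ceiling((n - length(out)) / (1 - a / 2)), 16L)
    x <- rgamma(m, shape = shape, scale = scale) + shift
    keep <- runif(m) < (1 + a * cos(2 * pi * x / per)) / (1 + a)
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

#' Generate a synthetic read-level cohort from a scenario
#'
#' Simulates, per gene and sample: a negative-binomial read count; for each
#' read a 3'-end position obtained by sampling a poly(A)-site cluster
#' according to the condition's usage weights and adding rounded Gaussian
#' positional noise (offsets are reflected onto the genome for `-` strand
#' genes); and a tail-length estimate drawn from the condition's gamma
#' distribution (optionally periodicity-re-weighted), plus Gaussian
#' measurement noise, floored at 0. Spike-in genes have a degenerate tail
#' at their nominal length plus measurement noise. A fraction of reads
#' carries no tail estimate (`NA`). Output is byte-identical for identical
#' scenarios (the seed is part of the scenario).
#'
#' @param scenario A `sim_scenario`.
#' @return A list with `reads` (read-record table), `annotation`,
#'   `manifest`, and `ground_truth` (per-gene programmed effects and true
#'   parameter values).
#' @export
generate_cohort <- function(scenario) {
  validate_scenario(scenario)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(scenario$seed)

  g <- scenario$genes
  mf <- scenario$samples
  noise_sd <- scenario$measurement_noise_sd
  miss_rate <- scenario$tail_missing_rate

  chunks <- vector("list", nrow(g) * nrow(mf))
  ci <- 0L
  for (i in seq_len(nrow(g))) {
    offs <- g$site_offsets[[i]]
    for (j in seq_len(nrow(mf))) {
      cond <- mf$group[j]
      if (cond == "exclude") next
      mu <- if (cond == "A") g$depth_mean_A[i] else g$depth_mean_B[i]
      count <- rnbinom(1L, size = g$depth_disp[i], mu = mu)
      if (count == 0L) next
      w <- if (cond == "A") g$weights_A[[i]] else g$weights_B[[i]]
      site <- if (length(offs) == 1L) rep(1L, count)
        else sample.int(length(offs), count, replace = TRUE, prob = w)
      off <- offs[site] + round(rnorm(count, 0, g$site_sd[i]))
      pos <- if (g$strand[i] == "+") g$start[i] + off
        else g$end[i] - 1L - off
      if (g$is_spikein[i]) {
        tails <- rep(g$spike_tail_nt[i], count)
      } else if (cond == "A") {
        tails <- .draw_tails(count, g$tail_shape_A[i], g$tail_scale_A[i],
                             g$tail_shift_A[i], scenario$periodicity)
      } else {
        tails <- .draw_tails(count, g$tail_shape_B[i], g$tail_scale_B[i],
                             g$tail_shift_B[i], scenario$periodicity)
      }
      tails <- pmax(tails + rnorm(count, 0, noise_sd), 0)
      if (miss_rate > 0) tails[runif(count) < miss_rate] <- NA_real_
      ci <- ci + 1L
      chunks[[ci]] <- data.table::data.table(
        read_id = sprintf("%s.%s.r%04d", g$gene_id[i], mf$sample_id[j],
                          seq_len(count)),
        gene_id = g$gene_id[i], chrom = g$chrom[i],
        end_pos = as.integer(pos), strand = g$strand[i],
        tail_length = tails, sample_id = mf$sample_id[j]
      )
    }
  }
  reads <- data.table::rbindlist(chunks[seq_len(ci)])

  annotation <- g[, list(gene_id, chrom, start, end, strand, is_spikein,
                         is_m6a_modified, category)]
  data.table::setkey(annotation, gene_id)

  ground_truth <- g[, list(
    gene_id, is_spikein, is_m6a_modified, category,
    apa_shifted, tail_shifted, tail_delta_nt,
    expected_apa_direction = ifelse(apa_shifted, "proximal", NA_character_),
    expected_tail_direction = ifelse(tail_shifted & tail_delta_nt > 0,
                                     "longer",
                              ifelse(tail_shifted, "shorter", NA_character_)),
    mean_tail_A = ifelse(is_spikein, spike_tail_nt,
                         tail_shape_A * tail_scale_A + tail_shift_A),
    mean_tail_B = ifelse(is_spikein, spike_tail_nt,
                         tail_shape_B * tail_scale_B + tail_shift_B),
    usage_A = vapply(weights_A, function(w) paste(signif(w, 6),
                                                  collapse = ","), ""),
    usage_B = vapply(weights_B, function(w) paste(signif(w, 6),
                                                  collapse = ","), "")
  )]

  list(reads = reads, annotation = annotation, manifest = mf,
       ground_truth = ground_truth)
}
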