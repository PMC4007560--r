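#' Configuration for the matched microarray / RNA-Seq simulator
#'
#' Defaults emulate the study design the package targets: 29 brain regions
#' (22 neocortical + 7 transcriptionally distinct non-neocortical), sampled
#' in both hemispheres with two replicates each, in two donors — 116 samples
#' per donor. Genes draw a baseline log2 abundance from N(1, 2.5), so about
#' a third sit below TPM = 1, the regime where counting error and array
#' background dominate. A configured fraction of genes carries region
#' effects (stronger outside neocortex); donors contribute per-gene location
#' and scale effects (the batch signal the empirical-Bayes adjustment
#' removes). On-target probes are inverse-linear transforms of the gene's
#' noise-free log2 TPM with slope/intercept drawn per probe, softplus-floored
#' at the background and clipped at saturation; off-target probes track a
#' different random gene; bright probes emit high constant intensity.
#' Sequencing counts are Poisson around the expected fragment share.
#'
#' @param n_genes number of genes (default 2000).
#' @param probe_count_probs probabilities of a gene having 1, 2, ... probes
#'   (default `c(0.3, 0.6, 0.1)`, mean 1.8).
#' @param n_regions_neocortex,n_regions_other region counts (22, 7).
#' @param donors donor labels (default `c("brain1", "brain2")`).
#' @param hemispheres,replicates_per_hemisphere design constants (2, 2).
#' @param baseline_mean,baseline_sd prior on gene log2 abundance (1, 2.5).
#' @param frac_region_de fraction of genes with *strong* region effects
#'   (0.3). All genes additionally carry a small ubiquitous regional
#'   modulation: expression varies across brain regions for nearly every
#'   gene, which is what makes probe quality measurable from cross-sample
#'   correlation in the first place.
#' @param region_effect_sd_neocortex,region_effect_sd_other per-region
#'   effect sds for strongly differential genes (0.25, 1.0) — non-neocortex
#'   is more distinct.
#' @param region_effect_sd_base_neocortex,region_effect_sd_base_other
#'   per-region effect sds for all remaining genes (0.1, 0.3).
#' @param donor_location_sd,donor_scale_sd per-gene donor batch effects:
#'   additive log2 shift sd (0.3) and log-normal sd of the noise-scale
#'   multiplier (0.2).
#' @param array_noise_sd,seq_noise_sd replicate noise sds in log2 space
#'   (0.3, 0.2), tuned to replicate correlations near 0.98 / 0.99.
#' @param depth expected sequenced fragments per sample (1e5: the scaled-down
#'   working size; real experiments run ~3e7).
#' @param count_noise draw Poisson counts (TRUE); FALSE emits exact expected
#'   TPM (the noise-free closure regime).
#' @param m_meanlog,m_sdlog log-normal prior on the true probe slope
#'   (median ~1.41, ~50% of slopes in \[1, 2\]).
#' @param intensity_center mean log2 intensity of a probe whose gene sits at
#'   the baseline abundance (4.0). Vendor-normalized arrays put all probes on
#'   a common intensity range, so each probe's *mean* intensity tracks its
#'   gene's mean log2 TPM (the tight mean-vs-mean cloud seen between
#'   platforms); the slope prior then acts on dynamic range, not location.
#'   The intercept `b_true` is derived from this pivot.
#' @param intensity_jitter_sd per-probe scatter of mean intensity about that
#'   relation (1.5 log2 units, putting the between-method mean-level
#'   correlation near the ~0.78 typical of array/RNA-Seq comparisons).
#' @param off_target_fraction probes tracking the wrong gene (0.10).
#' @param bright_fraction probes with constant bright intensity (0.02).
#' @param background_floor log2 intensity floor (1.0); `-Inf` disables.
#' @param saturation_ceiling log2 intensity ceiling (14); `Inf` disables.
#' @param bright_level mean log2 intensity of bright probes (14, the
#'   saturation ceiling): these emulate probes reading out orders of
#'   magnitude above their gene's expression (histone/keratin-like
#'   off-target hybridization pinned near saturation).
#' @param length_meanlog,length_sdlog log-normal transcript lengths
#'   (used only as a binning sort key).
#' @param seed integer seed; all randomness derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       probe_count_probs = c(0.3, 0.6, 0.1),
                       n_regions_neocortex = 22,
                       n_regions_other = 7,
                       donors = c("brain1", "brain2"),
                       hemispheres = 2,
                       replicates_per_hemisphere = 2,
                       baseline_mean = 1, baseline_sd = 2.5,
                       frac_region_de = 0.3,
                       region_effect_sd_neocortex = 0.25,
                       region_effect_sd_other = 1.0,
                       region_effect_sd_base_neocortex = 0.1,
                       region_effect_sd_base_other = 0.3,
                       donor_location_sd = 0.3,
                       donor_scale_sd = 0.2,
                       array_noise_sd = 0.3,
                       seq_noise_sd = 0.2,
                       depth = 1e5,
                       count_noise = TRUE,
                       m_meanlog = log(1.41), m_sdlog = 0.51,
                       intensity_center = 4.0,
                       intensity_jitter_sd = 1.5,
                       off_target_fraction = 0.10,
                       bright_fraction = 0.02,
                       background_floor = 1.0,
                       saturation_ceiling = 14,
                       bright_level = 14,
                       length_meanlog = log(2500), length_sdlog = 0.8,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (any(probe_count_probs < 0) || sum(probe_count_probs) <= 0)
    stop("invalid probe_count_probs")
  if (cfg$n_genes < 2) stop("need at least 2 genes")
  stopifnot(baseline_sd >= 0, array_noise_sd >= 0, seq_noise_sd >= 0,
            donor_location_sd >= 0, donor_scale_sd >= 0,
            region_effect_sd_neocortex >= 0, region_effect_sd_other >= 0,
            region_effect_sd_base_neocortex >= 0,
            region_effect_sd_base_other >= 0)
  if (off_target_fraction < 0 || off_target_fraction > 1 ||
      bright_fraction < 0 || bright_fraction > 1)
    stop("fractions must be in [0, 1]")
  if (depth <= 0) stop("depth must be positive")
  structure(cfg, class = "sim_config")
}

#' Simulate a matched microarray / RNA-Seq dataset with known truth
#'
#' See [sim_config()] for the generative model. Given a config, emits the
#' full artifact set every other module consumes, plus the ground truth
#' needed for recovery scoring.
#'
#' @param cfg a [sim_config()].
#' @return list with elements
#'   \describe{
#'   \item{array}{linear-intensity `ExpressionMatrix`, probes x samples.}
#'   \item{seq_tpm}{linear TPM `ExpressionMatrix`, genes x samples (columns
#'     sum to 1e6).}
#'   \item{seq_counts}{fragment-count `ExpressionMatrix`.}
#'   \item{presence}{logical probes x samples matrix of array present calls
#'     (true signal above the background floor).}
#'   \item{annot}{probe annotation data.frame.}
#'   \item{meta}{sample metadata data.frame.}
#'   \item{truth}{list: `probes` (per-probe `m_true`, `b_true`, `on_target`,
#'     `bright`, `tracked_gene`), `signal_log2_tpm` (noise-free expected
#'     log2 TPM, genes x samples), `array_signal_log2` (noise-free floored
#'     log2 intensity, probes x samples), `de_genes`, `gene_lengths`,
#'     `depth`, and the config.}
#'   }
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  G <- cfg$n_genes
  genes <- sprintf("gene%04d", seq_len(G))
  regions <- c(sprintf("ctx%02d", seq_len(cfg$n_regions_neocortex)),
               sprintf("sub%02d", seq_len(cfg$n_regions_other)))
  region_class <- c(rep("neocortex", cfg$n_regions_neocortex),
                    rep("non_neocortex", cfg$n_regions_other))
  hemis <- c("L", "R")[seq_len(cfg$hemispheres)]
  reps <- seq_len(cfg$replicates_per_hemisphere)

  meta <- expand.grid(replicate = reps, hemisphere = hemis,
                      region_i = seq_along(regions), donor = cfg$donors,
                      stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = sprintf("%s_%s_%s_r%d", meta$donor, regions[meta$region_i],
                        meta$hemisphere, meta$replicate),
    donor = meta$donor, region = regions[meta$region_i],
    region_class = region_class[meta$region_i],
    hemisphere = meta$hemisphere, replicate = meta$replicate,
    batch = meta$donor, stringsAsFactors = FALSE)
  S <- nrow(meta)

  # gene-level truth
  baseline <- stats::rnorm(G, cfg$baseline_mean, cfg$baseline_sd)
  de_genes <- stats::runif(G) < cfg$frac_region_de
  sd_strong <- ifelse(region_class == "neocortex",
                      cfg$region_effect_sd_neocortex,
                      cfg$region_effect_sd_other)
  sd_base <- ifelse(region_class == "neocortex",
                    cfg$region_effect_sd_base_neocortex,
                    cfg$region_effect_sd_base_other)
  # per-gene, per-region sd: strong for the DE fraction, small but nonzero
  # for everything else
  sd_gr <- matrix(rep(sd_base, each = G), G, length(regions))
  sd_gr[de_genes, ] <- rep(sd_strong, each = sum(de_genes))
  region_eff <- matrix(stats::rnorm(G * length(regions)), G,
                       length(regions)) * sd_gr
  dimnames(region_eff) <- list(genes, regions)
  donor_loc <- matrix(stats::rnorm(G * length(cfg$donors),
                                   0, cfg$donor_location_sd),
                      G, length(cfg$donors),
                      dimnames = list(genes, cfg$donors))
  donor_scale <- matrix(exp(stats::rnorm(G * length(cfg$donors),
                                         0, cfg$donor_scale_sd)),
                        G, length(cfg$donors),
                        dimnames = list(genes, cfg$donors))

  di <- match(meta$donor, cfg$donors)
  ri <- match(meta$region, regions)
  # noise-free per-sample signal in log2 abundance units
  signal <- baseline + region_eff[, ri, drop = FALSE] +
    donor_loc[, di, drop = FALSE]
  dimnames(signal) <- list(genes, meta$sample_id)

  # expected TPM from the noise-free signal (shared latent scale for both
  # platforms)
  p0 <- 2^signal
  p0 <- sweep(p0, 2L, colSums(p0), "/")
  signal_log2_tpm <- log2(p0 * 1e6)

  # sequencing replicate noise (fixed-count RNG consumption)
  seq_noise <- matrix(stats::rnorm(G * S), G, S) * cfg$seq_noise_sd *
    donor_scale[, di, drop = FALSE]

  # probes
  n_probes_per_gene <- sample.int(length(cfg$probe_count_probs), G,
                                  replace = TRUE,
                                  prob = cfg$probe_count_probs)
  probe_gene <- rep(genes, n_probes_per_gene)
  P <- length(probe_gene)
  probes <- sprintf("probe%05d", seq_len(P))
  annot <- data.frame(probe_id = probes, gene_id = probe_gene,
                      stringsAsFactors = FALSE)

  u <- stats::runif(P)
  bright <- u < cfg$bright_fraction
  off_target <- !bright & u < cfg$bright_fraction + cfg$off_target_fraction
  tracked <- probe_gene
  if (any(off_target)) {
    # track a different random gene
    alt <- sample(genes, sum(off_target), replace = TRUE)
    same <- alt == probe_gene[off_target]
    while (any(same)) {
      alt[same] <- sample(genes, sum(same), replace = TRUE)
      same <- alt == probe_gene[off_target]
    }
    tracked[off_target] <- alt
  }
  m_true <- stats::rlnorm(P, cfg$m_meanlog, cfg$m_sdlog)
  # anchor each probe's expected intensity to its tracked gene's *prior*
  # abundance on the log2 TPM scale (pivot construction): the probe line is a
  # physical property of the probe, so the anchor must not depend on the
  # tissue profile being simulated — parameters then transfer across
  # simulations that share a seed, as real scaling parameters transfer
  # across experiments on the same array
  tot_expect <- cfg$n_genes * 2^cfg$baseline_mean *
    exp((cfg$baseline_sd * log(2))^2 / 2)
  t_ref <- baseline - log2(tot_expect) + log2(1e6)
  t_ref_center <- cfg$baseline_mean - log2(tot_expect) + log2(1e6)
  t_bar <- t_ref[match(tracked, genes)]
  x_bar <- cfg$intensity_center + (t_bar - t_ref_center) / exp(cfg$m_meanlog) +
    stats::rnorm(P, 0, cfg$intensity_jitter_sd)
  b_true <- t_bar - m_true * x_bar

  x0 <- (signal_log2_tpm[tracked, , drop = FALSE] - b_true) / m_true
  if (any(bright))
    x0[bright, ] <- cfg$bright_level
  presence <- x0 > cfg$background_floor
  # softplus floor, saturation clip
  y0 <- if (is.finite(cfg$background_floor))
    log2(2^x0 + 2^cfg$background_floor) else x0
  if (is.finite(cfg$saturation_ceiling))
    y0 <- pmin(y0, cfg$saturation_ceiling)
  arr_noise <- matrix(stats::rnorm(P * S), P, S) * cfg$array_noise_sd *
    donor_scale[probe_gene, di, drop = FALSE]
  y <- y0 + arr_noise
  dimnames(y) <- dimnames(y0) <- dimnames(presence) <-
    list(probes, meta$sample_id)

  gene_lengths <- stats::setNames(
    stats::rlnorm(G, cfg$length_meanlog, cfg$length_sdlog), genes)

  # Poisson counting comes last: rpois consumes a data-dependent number of
  # RNG draws, and everything above must stay seed-stable across tissue
  # profiles so that probe identities transfer between simulations
  a <- 2^(signal + seq_noise)
  p_s <- sweep(a, 2L, colSums(a), "/")
  if (cfg$count_noise) {
    counts <- matrix(stats::rpois(G * S, lambda = cfg$depth * p_s), G, S,
                     dimnames = dimnames(signal))
    totals <- colSums(counts)
    if (any(totals == 0)) stop("a sample drew zero fragments; raise depth")
    tpm <- sweep(counts, 2L, totals, "/") * 1e6
  } else {
    # no counting error: TPM is the (replicate-noisy) expected fragment share
    tpm <- p_s * 1e6
    counts <- round(cfg$depth * p_s)
    dimnames(counts) <- dimnames(signal)
  }
  dimnames(tpm) <- dimnames(signal)

  list(
    array = ExpressionMatrix(2^y, "linear", "microarray", "intensity"),
    seq_tpm = ExpressionMatrix(tpm, "linear", "rnaseq", "TPM"),
    seq_counts = ExpressionMatrix(counts, "linear", "rnaseq", "counts"),
    presence = presence,
    annot = annot,
    meta = validate_sample_metadata(meta),
    truth = list(
      probes = data.frame(probe_id = probes, gene_id = probe_gene,
                          tracked_gene = tracked, m_true = m_true,
                          b_true = b_true,
                          on_target = !off_target & !bright,
                          bright = bright, stringsAsFactors = FALSE),
      signal_log2_tpm = signal_log2_tpm,
      array_signal_log2 = y0,
      de_genes = stats::setNames(de_genes, genes),
      gene_lengths = gene_lengths,
      depth = cfg$depth,
      config = cfg))
}

#' Score QC and scaling recovery against the generator's ground truth
#'
#' @param truth the `truth` element of [simulate_dataset()] output.
#' @param qc probe QC records (with `pass`, and optionally `is_best`).
#' @param params scaling parameters from [fit_scaling()] (optional).
#' @return list: `off_target_sensitivity` (fraction of off-target probes
#'   correctly failed), `pass_fdr` (fraction of passing probes that are
#'   off-target or bright), `bright_sensitivity`, `best_probe_recovery`
#'   (fraction of multi-probe genes with an on-target probe whose best probe
#'   is on-target), and when `params` is given, `m_abs_error` / `b_abs_error`
#'   quantiles (25/50/75%) over on-target scaled probes.
#' @export
truth_scorecard <- function(truth, qc, params = NULL) {
  tp <- truth$probes
  if (!all(qc$probe_id %in% tp$probe_id))
    stop("QC records contain probes unknown to the truth")
  idx <- match(qc$probe_id, tp$probe_id)
  bad <- !tp$on_target[idx]
  passed <- !is.na(qc$pass) & qc$pass

  out <- list(
    off_target_sensitivity = if (any(bad)) mean(!passed[bad]) else NA_real_,
    pass_fdr = if (any(passed)) mean(bad[passed]) else NA_real_,
    bright_sensitivity = if (any(tp$bright[idx]))
      mean(!passed[tp$bright[idx]]) else NA_real_)

  if ("is_best" %in% colnames(qc)) {
    per_gene <- split(seq_len(nrow(qc)), qc$gene_id)
    eligible <- vapply(per_gene, function(i)
      length(i) >= 2 && any(tp$on_target[idx[i]]), logical(1))
    hit <- vapply(per_gene[eligible], function(i) {
      best <- i[qc$is_best[i]]
      length(best) == 1 && tp$on_target[idx[best]]
    }, logical(1))
    out$best_probe_recovery <- if (length(hit)) mean(hit) else NA_real_
  }

  if (!is.null(params) && nrow(params) > 0) {
    pidx <- match(params$probe_id, tp$probe_id)
    on <- tp$on_target[pidx]
    if (any(on)) {
      out$m_abs_error <- stats::quantile(abs(params$m[on] - tp$m_true[pidx][on]),
                                         c(0.25, 0.5, 0.75))
      out$b_abs_error <- stats::quantile(abs(params$b[on] - tp$b_true[pidx][on]),
                                         c(0.25, 0.5, 0.75))
    }
  }
  out
}
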