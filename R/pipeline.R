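#' Fit pipeline: normalize, score probes, fit scaling parameters
#'
#' Runs the training-side flow end to end: sample scaling of the RNA-Seq
#' TPMs on non-differentially-expressed genes (neocortex vs non-neocortex
#' indicator), log2 transform of both platforms, probe QC on the training
#' donor's samples, and the quantile-anchored scaling fit. The fit is
#' deliberately performed on data *before* any cross-donor batch adjustment,
#' so held-out donors stay independent. When `outdir` is given, the combined
#' scaling/QC table is written as CSV with a header recording the package
#' version, a config hash and the seed.
#'
#' @param array `ExpressionMatrix`, linear intensities (probes x samples).
#' @param seq_tpm `ExpressionMatrix`, linear TPM (genes x samples).
#' @param annot probe annotation.
#' @param meta sample metadata for all samples.
#' @param train_donor donor whose samples train the fit (default
#'   `"brain2"`).
#' @param q_threshold QC q-value cutoff (default 0.1).
#' @param lower_prob,upper_prob anchor quantiles (0.05, 0.95).
#' @param epsilon log2 offset.
#' @param tbt run the non-DE-gene sample scaling on the TPMs first
#'   (default TRUE).
#' @param cfg optional [qc_config()]; overrides `q_threshold` if supplied.
#' @param outdir optional output directory for `scaling_table.csv`.
#' @param seed integer recorded in output headers (the fit itself is
#'   deterministic).
#' @return list: `qc` (probe QC records), `params` (scaling parameters),
#'   `tbt` (normalization result or NULL), `array_log2`, `seq_log2`,
#'   `train_samples`, and `log` (stage counts).
#' @export
run_fit_pipeline <- function(array, seq_tpm, annot, meta,
                             train_donor = "brain2", q_threshold = 0.1,
                             lower_prob = 0.05, upper_prob = 0.95,
                             epsilon = 2^-10, tbt = TRUE, cfg = NULL,
                             outdir = NULL, seed = 0L) {
  meta <- validate_sample_metadata(meta)
  check_samples_annotated(array, meta)
  check_samples_annotated(seq_tpm, meta)
  if (is.null(cfg)) cfg <- qc_config(q_threshold = q_threshold)

  tbt_res <- NULL
  if (tbt) {
    m2 <- meta[match(colnames(seq_tpm$values), meta$sample_id), ]
    groups <- m2$region_class == "neocortex"
    tbt_res <- tbt_normalize(seq_tpm, groups, epsilon = epsilon)
    seq_tpm <- tbt_res$matrix
  }
  array_log2 <- log_transform(array, epsilon)
  seq_log2 <- log_transform(seq_tpm, epsilon)

  train_samples <- meta$sample_id[meta$donor == train_donor &
                                    meta$sample_id %in% colnames(array$values) &
                                    meta$sample_id %in% colnames(seq_tpm$values)]
  if (length(train_samples) == 0)
    stop("no training samples for donor '", train_donor, "'")

  qc <- probe_qc(array_log2, seq_log2, annot, train_samples, meta, cfg)
  params <- fit_scaling(array_log2, seq_log2, annot, qc, train_samples,
                        lower_prob = lower_prob, upper_prob = upper_prob)

  log <- list(n_probes_in = nrow(annot),
              n_scored = sum(!is.na(qc$pass)),
              n_passed = sum(qc$pass, na.rm = TRUE),
              n_scaled = nrow(params),
              n_train = length(train_samples))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    header <- output_header(seed, list(train_donor = train_donor,
                                       q_threshold = cfg$q_threshold,
                                       lower_prob = lower_prob,
                                       upper_prob = upper_prob,
                                       epsilon = epsilon, tbt = tbt))
    write_scaling_table(qc, params, file.path(outdir, "scaling_table.csv"),
                        comments = header)
  }
  list(qc = qc, params = params, tbt = tbt_res,
       array_log2 = array_log2, seq_log2 = seq_log2,
       train_samples = train_samples, log = log)
}

#' Evaluation pipeline: transfer scaling to a held-out donor
#'
#' Applies a fitted scaling table to the microarray samples of a held-out
#' donor and assembles the comparison battery: per-sample between-method
#' correlation before and after scaling, replicate correlations per
#' platform, and between-donor fold-change concordance of the RNA-Seq data
#' before and after batch adjustment. Batch adjustment of the scaled
#' intensities (for reporting parity) is toggleable.
#'
#' @param fit result of [run_fit_pipeline()].
#' @param meta sample metadata.
#' @param heldout_donor donor excluded from training (default `"brain1"`).
#' @param annot probe annotation.
#' @param combat also batch-adjust (donor batches) the RNA-Seq log2 matrix
#'   and report fold-change concordance before/after (default TRUE).
#' @param n_draws fold-change draws (default 1e5).
#' @param region_class region filter for fold-change draws (default
#'   `"non_neocortex"`, the transcriptionally diverse set).
#' @param seed integer seed for the resampling draws.
#' @return list: `transfer` (per-sample data.frame from
#'   [transfer_evaluation()]), `frac_improved`, `replicates_array`,
#'   `replicates_seq`, `fc_between_donor_raw`, `fc_between_donor_adjusted`
#'   (NULL unless `combat`), `ssmi` (the scaled held-out matrix).
#' @export
run_evaluate_pipeline <- function(fit, meta, heldout_donor = "brain1",
                                  annot, combat = TRUE, n_draws = 1e5,
                                  region_class = "non_neocortex",
                                  seed = 1L) {
  meta <- validate_sample_metadata(meta)
  held <- meta$sample_id[meta$donor == heldout_donor]
  held <- intersect(held, colnames(fit$array_log2$values))
  if (length(held) == 0) stop("no held-out samples for donor '",
                              heldout_donor, "'")
  if (length(intersect(held, fit$train_samples)) > 0)
    stop("held-out donor overlaps the training samples")

  arr_held <- fit$array_log2[, held]
  seq_held <- fit$seq_log2[, intersect(held, colnames(fit$seq_log2$values))]
  transfer <- transfer_evaluation(fit$params, arr_held, seq_held, annot,
                                  qc = fit$qc)
  ssmi <- apply_scaling(arr_held, fit$params)

  rep_arr <- replicate_correlations(fit$array_log2, meta)
  rep_seq <- replicate_correlations(fit$seq_log2, meta)

  donors <- unique(meta$donor[meta$sample_id %in% colnames(fit$seq_log2$values)])
  fc_raw <- fc_adj <- NULL
  if (length(donors) >= 2) {
    dA <- meta$sample_id[meta$donor == donors[1]]
    dB <- meta$sample_id[meta$donor == donors[2]]
    seqA <- fit$seq_log2[, intersect(dA, colnames(fit$seq_log2$values))]
    seqB <- fit$seq_log2[, intersect(dB, colnames(fit$seq_log2$values))]
    fc_raw <- foldchange_concordance(seqA, seqB, meta, n_draws = n_draws,
                                     region_class = region_class, seed = seed)
    if (combat) {
      batches <- meta$donor[match(colnames(fit$seq_log2$values),
                                  meta$sample_id)]
      adj <- combat_adjust(fit$seq_log2, batches)$matrix
      adjA <- adj[, colnames(seqA$values)]
      adjB <- adj[, colnames(seqB$values)]
      fc_adj <- foldchange_concordance(adjA, adjB, meta, n_draws = n_draws,
                                       region_class = region_class,
                                       seed = seed)
    }
  }
  list(transfer = transfer,
       frac_improved = mean(transfer$delta >= 0),
       replicates_array = rep_arr, replicates_seq = rep_seq,
       fc_between_donor_raw = if (!is.null(fc_raw)) fc_raw$R else NULL,
       fc_between_donor_adjusted = if (!is.null(fc_adj)) fc_adj$R else NULL,
       ssmi = ssmi)
}

# header comment lines for output files: version, config hash, seed
output_header <- function(seed, config) {
  txt <- paste(names(config), vapply(config, function(x)
    paste(format(x), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  hash <- config_hash(txt)
  c(paste0("ssmi version ", as.character(utils::packageVersion("ssmi"))),
    paste0("config_hash=", hash),
    paste0("seed=", seed),
    paste0("config: ", txt))
}

# small polynomial string hash (hex); avoids external digest dependencies
config_hash <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
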