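#' Fit quantile-anchored linear scaling parameters per probe
#'
#' For each probe that passed QC, computes the lower/upper quantiles
#' (default 5th and 95th, linear interpolation between order statistics —
#' quantile type 7) of its log2 intensities and of its gene's log2 TPM
#' values across the training samples, and solves the two-point line
#' `m = (q95_seq - q05_seq) / (q95_array - q05_array)`,
#' `b = q05_seq - m * q05_array`. Applying `m * x + b` then maps the probe's
#' anchor quantiles exactly onto the gene's TPM anchors.
#'
#' Probes with a degenerate intensity range (upper anchor equal to lower)
#' cannot be scaled and are excluded with a message.
#'
#' @param array_log2,seq_log2 log2 `ExpressionMatrix` objects (intensity /
#'   TPM).
#' @param annot probe annotation.
#' @param qc probe QC records with a `pass` column; only passing probes are
#'   fitted.
#' @param train_samples training sample ids (the training donor).
#' @param lower_prob,upper_prob anchor probabilities, `0 <= lower < upper <= 1`.
#' @return data.frame of scaling parameters: `probe_id`, `gene_id`, `m`,
#'   `b`, `q05_array`, `q95_array`, `q05_seq`, `q95_seq`, `n_train`.
#' @export
fit_scaling <- function(array_log2, seq_log2, annot, qc, train_samples,
                        lower_prob = 0.05, upper_prob = 0.95) {
  if (!(lower_prob >= 0 && lower_prob < upper_prob && upper_prob <= 1))
    stop("need 0 <= lower_prob < upper_prob <= 1")
  keep <- qc$probe_id[!is.na(qc$pass) & qc$pass]
  keep <- keep[keep %in% rownames(array_log2$values)]
  ann <- annot[match(keep, annot$probe_id), , drop = FALSE]
  ann <- ann[ann$gene_id %in% rownames(seq_log2$values), , drop = FALSE]
  if (nrow(ann) == 0)
    return(data.frame(probe_id = character(0), gene_id = character(0),
                      m = numeric(0), b = numeric(0),
                      q05_array = numeric(0), q95_array = numeric(0),
                      q05_seq = numeric(0), q95_seq = numeric(0),
                      n_train = integer(0), stringsAsFactors = FALSE))

  X <- array_log2$values[ann$probe_id, train_samples, drop = FALSE]
  Y <- seq_log2$values[ann$gene_id, train_samples, drop = FALSE]
  qa <- t(apply(X, 1L, stats::quantile, probs = c(lower_prob, upper_prob),
                names = FALSE, type = 7))
  qs <- t(apply(Y, 1L, stats::quantile, probs = c(lower_prob, upper_prob),
                names = FALSE, type = 7))
  span <- qa[, 2] - qa[, 1]
  unscalable <- span <= 0
  if (any(unscalable))
    message(sum(unscalable),
            " probe(s) unscalable (constant intensity across anchors), excluded")
  ok <- !unscalable
  m <- (qs[ok, 2] - qs[ok, 1]) / span[ok]
  b <- qs[ok, 1] - m * qa[ok, 1]
  data.frame(probe_id = ann$probe_id[ok], gene_id = ann$gene_id[ok],
             m = unname(m), b = unname(b),
             q05_array = unname(qa[ok, 1]), q95_array = unname(qa[ok, 2]),
             q05_seq = unname(qs[ok, 1]), q95_seq = unname(qs[ok, 2]),
             n_train = length(train_samples), stringsAsFactors = FALSE)
}

#' Apply scaling parameters to produce SSMIs
#'
#' Transforms each probe's log2 intensities by its fitted line,
#' `SSMI = m * log2(intensity) + b`. Probes without a parameter record are
#' dropped (their count is attached as attribute `"n_dropped"`).
#'
#' @param array_log2 log2 intensity `ExpressionMatrix`.
#' @param params scaling parameters from [fit_scaling()].
#' @return `ExpressionMatrix` in log2 space with unit `"SSMI"`, rows limited
#'   to scaled probes.
#' @export
apply_scaling <- function(array_log2, params) {
  stopifnot(inherits(array_log2, "ExpressionMatrix"))
  if (array_log2$space != "log2")
    stop("apply_scaling expects log2 intensities")
  have <- params$probe_id %in% rownames(array_log2$values)
  params <- params[have, , drop = FALSE]
  n_dropped <- nrow(array_log2$values) - nrow(params)
  v <- array_log2$values[params$probe_id, , drop = FALSE]
  v <- v * params$m + params$b
  out <- structure(list(values = v, space = "log2",
                        platform = "microarray", unit = "SSMI"),
                   class = "ExpressionMatrix")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Evaluate scaling parameters transferred to an independent donor
#'
#' Applies parameters fitted on one donor to the microarray samples of a
#' held-out donor (or another tissue) and, per sample, compares the Pearson
#' correlation of absolute levels between SSMI and log2 TPM against the
#' correlation between unscaled intensity and log2 TPM. The improvement in
#' each sample's delta is the headline transfer result.
#'
#' @param params scaling parameters fitted on the training donor.
#' @param array_log2 held-out donor's log2 intensities.
#' @param seq_log2 held-out donor's log2 TPM.
#' @param annot probe annotation.
#' @param qc optional probe QC records: when given, the comparison uses only
#'   each gene's best passing probe (the convention for between-method
#'   summaries); otherwise all scaled probes enter.
#' @return data.frame per common sample: `sample_id`, `r_unscaled`,
#'   `r_ssmi`, `delta` (= `r_ssmi - r_unscaled`).
#' @export
transfer_evaluation <- function(params, array_log2, seq_log2, annot,
                                qc = NULL) {
  samples <- intersect(colnames(array_log2$values), colnames(seq_log2$values))
  if (length(samples) == 0) stop("no common samples between matrices")
  probes <- params$probe_id
  if (!is.null(qc))
    probes <- intersect(probes, qc$probe_id[qc$is_best & !is.na(qc$pass) & qc$pass])
  params <- params[params$probe_id %in% probes, , drop = FALSE]
  params <- params[params$probe_id %in% rownames(array_log2$values), , drop = FALSE]
  genes <- annot$gene_id[match(params$probe_id, annot$probe_id)]
  ok <- genes %in% rownames(seq_log2$values)
  params <- params[ok, , drop = FALSE]; genes <- genes[ok]
  if (nrow(params) < 2) stop("fewer than 2 common genes for evaluation")

  X <- array_log2$values[params$probe_id, samples, drop = FALSE]
  S <- X * params$m + params$b
  Y <- seq_log2$values[genes, samples, drop = FALSE]
  r_un <- vapply(seq_along(samples), function(j)
    stats::cor(X[, j], Y[, j]), numeric(1))
  r_ss <- vapply(seq_along(samples), function(j)
    stats::cor(S[, j], Y[, j]), numeric(1))
  data.frame(sample_id = samples, r_unscaled = r_un, r_ssmi = r_ss,
             delta = r_ss - r_un, stringsAsFactors = FALSE)
}
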