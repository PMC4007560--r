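#' Correlate each probe's intensities with its gene's RNA-Seq profile
#'
#' For every annotated probe whose gene is present in the RNA-Seq matrix,
#' computes the Pearson correlation `r` between the probe's log2 intensities
#' and the gene's log2 TPM values across the training samples, and a p-value
#' from the t statistic \code{r * sqrt((n - 2) / (1 - r^2))} on `n - 2` degrees of
#' freedom. The default test is one-sided for positive correlation, because
#' only probes tracking their gene positively can be calibrated. Probes with
#' zero variance in either vector get \code{r = NA}, \code{p = 1}.
#'
#' @param array_log2 `ExpressionMatrix` of probe log2 intensities.
#' @param seq_log2 `ExpressionMatrix` of gene log2 TPM values.
#' @param annot probe annotation (`probe_id`, `gene_id`).
#' @param train_samples sample ids present in both matrices.
#' @param side `"one_sided_positive"` (default) or `"two_sided"`.
#' @return data.frame: `probe_id`, `gene_id`, `r`, `p`, `n_train`. Probes
#'   whose gene is absent from the RNA-Seq matrix are skipped (with a
#'   message).
#' @export
probe_correlation <- function(array_log2, seq_log2, annot, train_samples,
                              side = c("one_sided_positive", "two_sided")) {
  side <- match.arg(side)
  stopifnot(inherits(array_log2, "ExpressionMatrix"),
            inherits(seq_log2, "ExpressionMatrix"))
  if (!all(train_samples %in% colnames(array_log2$values)) ||
      !all(train_samples %in% colnames(seq_log2$values)))
    stop("train_samples must be present in both matrices")
  n <- length(train_samples)
  if (n < 3) stop("need at least 3 training samples")

  annot <- annot[annot$probe_id %in% rownames(array_log2$values), , drop = FALSE]
  scorable <- annot$gene_id %in% rownames(seq_log2$values)
  if (any(!scorable))
    message(sum(!scorable), " probe(s) skipped: gene absent from RNA-Seq matrix")
  annot <- annot[scorable, , drop = FALSE]

  X <- array_log2$values[annot$probe_id, train_samples, drop = FALSE]
  Y <- seq_log2$values[annot$gene_id, train_samples, drop = FALSE]
  xc <- X - rowMeans(X)
  yc <- Y - rowMeans(Y)
  sxx <- rowSums(xc^2); syy <- rowSums(yc^2)
  r <- rowSums(xc * yc) / sqrt(sxx * syy)
  r[sxx == 0 | syy == 0] <- NA_real_
  r <- pmin(pmax(r, -1), 1)

  p <- rep(1, length(r))
  ok <- !is.na(r)
  tt <- r[ok] * sqrt((n - 2) / pmax(1 - r[ok]^2, .Machine$double.eps))
  p[ok] <- if (side == "one_sided_positive") {
    stats::pt(tt, df = n - 2, lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  data.frame(probe_id = annot$probe_id, gene_id = annot$gene_id,
             r = unname(r), p = unname(p), n_train = n,
             stringsAsFactors = FALSE)
}

#' Storey-style q-values
#'
#' Converts p-values to q-values: the proportion of true nulls `pi0` is
#' estimated by averaging `#\{p > lambda\} / (m (1 - lambda))` over the grid
#' `lambda = 0.05, 0.10, ..., 0.90` (clipped to (0, 1]), and
#' `q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j)`, capped at 1.
#' With `pi0 = 1` this reduces exactly to Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param pi0 optionally force the null proportion (e.g. `1` for plain BH).
#' @param lambda grid for the pi0 estimate.
#' @return numeric vector of q-values (same order as `pvals`), with the
#'   estimated `pi0` attached as attribute `"pi0"`. Empty input returns an
#'   empty vector.
#' @export
qvalues <- function(pvals, pi0 = NULL, lambda = seq(0.05, 0.90, by = 0.05)) {
  if (length(pvals) == 0)
    return(structure(numeric(0), pi0 = if (is.null(pi0)) NA_real_ else pi0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must be in [0, 1] with no NAs")
  m <- length(pvals)
  if (is.null(pi0)) {
    est <- vapply(lambda, function(l) sum(pvals > l) / (m * (1 - l)),
                  numeric(1))
    pi0 <- mean(est)
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  }
  o <- order(pvals, decreasing = TRUE)
  ranks <- m:1  # rank of the i-th largest p among m
  q_sorted <- cummin(pmin(pi0 * m * pvals[o] / ranks, 1))
  q <- numeric(m)
  q[o] <- q_sorted
  structure(q, pi0 = pi0)
}

#' QC configuration for probe pass/fail
#'
#' @param q_threshold q-value cutoff for passing (default 0.1).
#' @param side correlation test sidedness (see [probe_correlation()]).
#' @param min_train_samples minimum training set size (>= 3).
#' @return list of class `qc_config`.
#' @export
qc_config <- function(q_threshold = 0.1,
                      side = c("one_sided_positive", "two_sided"),
                      min_train_samples = 3) {
  side <- match.arg(side)
  if (!(q_threshold > 0 && q_threshold < 1))
    stop("q_threshold must be in (0, 1)")
  if (min_train_samples < 3) stop("min_train_samples must be >= 3")
  structure(list(q_threshold = q_threshold, side = side,
                 min_train_samples = min_train_samples),
            class = "qc_config")
}

#' Assign pass/fail calls from correlation records
#'
#' A probe passes when its correlation is positive and its q-value falls
#' below the threshold. Probes with undefined `r` fail.
#'
#' @param records data.frame from [probe_correlation()] (columns `r`, `p`).
#' @param cfg a [qc_config()].
#' @return `records` with columns `q` and `pass` added.
#' @export
assign_pass <- function(records, cfg = qc_config()) {
  q <- qvalues(records$p)
  records$q <- as.numeric(q)
  records$pass <- !is.na(records$r) & records$r > 0 & records$q < cfg$q_threshold
  attr(records, "pi0") <- attr(q, "pi0")
  records
}

#' Designate the best, worst and highest-expressed probe per gene
#'
#' Per gene: `is_best` marks the probe with the maximal between-method
#' correlation, `is_worst` the minimal, and `is_highest` the probe with the
#' highest mean expression across region means (the classical
#' intensity-only selection rule). Ties break lexicographically by
#' `probe_id`; probes with undefined `r` are not eligible for best/worst.
#'
#' @param records data.frame with `probe_id`, `gene_id`, `r`.
#' @param region_means features x regions matrix of mean log2 intensity
#'   (see [region_mean_matrix()]); rows must cover the probes in `records`.
#' @return `records` with logical columns `is_best`, `is_worst`,
#'   `is_highest`.
#' @export
designate_probes <- function(records, region_means) {
  records$is_best <- FALSE
  records$is_worst <- FALSE
  records$is_highest <- FALSE
  avg_expr <- rowMeans(region_means)[records$probe_id]
  for (ids in split(seq_len(nrow(records)), records$gene_id)) {
    r <- records$r[ids]
    pid <- records$probe_id[ids]
    ok <- which(!is.na(r))
    if (length(ok)) {
      best <- ok[order(-r[ok], pid[ok])][1]
      worst <- ok[order(r[ok], pid[ok])][1]
      records$is_best[ids[best]] <- TRUE
      records$is_worst[ids[worst]] <- TRUE
    }
    e <- avg_expr[ids]
    hi <- order(-e, pid)[1]
    records$is_highest[ids[hi]] <- TRUE
  }
  records
}

#' Score, pass/fail and designate all probes in one call
#'
#' Convenience wrapper running [probe_correlation()], [qvalues()] via
#' [assign_pass()], and [designate_probes()].
#'
#' @inheritParams probe_correlation
#' @param meta sample metadata (used for region means on the training
#'   samples).
#' @param cfg a [qc_config()].
#' @return data.frame of probe QC records: `probe_id`, `gene_id`, `r`, `p`,
#'   `q`, `pass`, `n_train`, `is_best`, `is_worst`, `is_highest`.
#' @export
probe_qc <- function(array_log2, seq_log2, annot, train_samples, meta,
                     cfg = qc_config()) {
  if (length(train_samples) < cfg$min_train_samples)
    stop("fewer training samples than min_train_samples")
  rec <- probe_correlation(array_log2, seq_log2, annot, train_samples,
                           side = cfg$side)
  rec <- assign_pass(rec, cfg)
  rm_mat <- region_mean_matrix(array_log2[, train_samples], meta)
  rec <- designate_probes(rec, rm_mat)
  # probes whose gene is missing from the RNA-Seq matrix: recorded, pass = NA
  missing <- annot[annot$probe_id %in% rownames(array_log2$values) &
                     !(annot$probe_id %in% rec$probe_id), , drop = FALSE]
  if (nrow(missing)) {
    rec <- rbind(rec, data.frame(
      probe_id = missing$probe_id, gene_id = missing$gene_id,
      r = NA_real_, p = NA_real_, q = NA_real_, pass = NA,
      n_train = length(train_samples),
      is_best = FALSE, is_worst = FALSE, is_highest = FALSE,
      stringsAsFactors = FALSE))
  }
  rec
}

#' Flag probes far brighter than their gene's RNA-Seq level
#'
#' Fits a least-squares line of mean log2 intensity on mean log2 TPM across
#' all probes and flags probes whose positive residual exceeds
#' `n_sd` residual standard deviations — probes with much higher intensity
#' than their TPM predicts, a signature of off-target or non-specific
#' hybridization.
#'
#' @param array_means named per-probe mean log2 intensity.
#' @param seq_means per-probe mean log2 TPM of the probe's gene, aligned to
#'   `array_means`.
#' @param n_sd residual-sd threshold (default 3).
#' @return character vector of flagged probe ids.
#' @export
flag_bright_probes <- function(array_means, seq_means, n_sd = 3) {
  if (length(array_means) != length(seq_means))
    stop("array_means and seq_means must be aligned")
  if (length(array_means) < 10)
    stop("need at least 10 probes to fit the intensity-vs-TPM line")
  fit <- stats::lm.fit(cbind(1, seq_means), array_means)
  res <- fit$residuals
  s <- stats::sd(res)
  # a numerically perfect line leaves only rounding noise: nothing to flag
  if (s <= 1e-10 * max(1, stats::sd(array_means))) return(character(0))
  names(array_means)[res > n_sd * s]
}
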