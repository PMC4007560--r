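#' Correlations between replicate sample pairs
#'
#' Replicate pairs share donor, region and hemisphere and differ only in
#' replicate index. Reports the Pearson correlation over features for every
#' pair, plus the median as attribute `"median_r"`.
#'
#' @param mat an `ExpressionMatrix` (any space; log2 is conventional).
#' @param meta sample metadata covering `mat`'s samples.
#' @return data.frame: `sample_a`, `sample_b`, `r`.
#' @export
replicate_correlations <- function(mat, meta) {
  check_samples_annotated(mat, meta)
  meta <- meta[meta$sample_id %in% colnames(mat$values), , drop = FALSE]
  key <- interaction(meta$donor, meta$region, meta$hemisphere, drop = TRUE)
  out <- list()
  for (ids in split(meta$sample_id, key)) {
    if (length(ids) < 2) next
    cmb <- utils::combn(sort(ids), 2)
    for (k in seq_len(ncol(cmb))) {
      out[[length(out) + 1L]] <- data.frame(
        sample_a = cmb[1, k], sample_b = cmb[2, k],
        r = stats::cor(mat$values[, cmb[1, k]], mat$values[, cmb[2, k]]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) stop("no replicate pairs found in metadata")
  res <- do.call(rbind, out)
  attr(res, "median_r") <- stats::median(res$r)
  res
}

#' Present-call concordance between platforms
#'
#' A gene is "present" on the array at threshold `t` when its vendor
#' detection flag is set in at least a fraction `t` of samples, and present
#' in RNA-Seq when at least one fragment aligned to it in at least that
#' fraction of samples. Reports, per threshold, the counts present by each
#' platform and their overlap.
#'
#' @param flags_array logical genes x samples matrix of array present calls
#'   (vendor flags, already collapsed to genes).
#' @param counts_seq numeric genes x samples matrix of RNA-Seq fragment
#'   counts; rows must share names with `flags_array`.
#' @param thresholds sample-fraction thresholds (default 5%, 50%, 95%).
#' @return data.frame per threshold: `threshold`, `n_array`, `n_seq`,
#'   `n_overlap`, `overlap_frac` (overlap over the union).
#' @export
presence_summary <- function(flags_array, counts_seq,
                             thresholds = c(0.05, 0.50, 0.95)) {
  genes <- intersect(rownames(flags_array), rownames(counts_seq))
  if (length(genes) == 0) stop("no common genes")
  fa <- flags_array[genes, , drop = FALSE]
  cs <- counts_seq[genes, , drop = FALSE] >= 1
  frac_a <- rowMeans(fa)
  frac_s <- rowMeans(cs)
  do.call(rbind, lapply(thresholds, function(t) {
    pa <- frac_a >= t
    ps <- frac_s >= t
    n_union <- sum(pa | ps)
    data.frame(threshold = t, n_array = sum(pa), n_seq = sum(ps),
               n_overlap = sum(pa & ps),
               overlap_frac = if (n_union > 0) sum(pa & ps) / n_union else NA_real_)
  }))
}

#' Fold-change concordance between two matrices by random resampling
#'
#' Draws `(gene, region A, region B)` triples uniformly with replacement
#' (regions distinct, unordered) from a region set, computes each draw's
#' log2 fold change — the difference of region mean log2 expression — in
#' both matrices, and returns the Pearson correlation across draws. The two
#' matrices may be two donors of one platform (between-donor concordance)
#' or two platforms over the same samples (between-method concordance).
#'
#' @param matA,matB log2 `ExpressionMatrix` objects sharing feature names.
#' @param meta metadata covering the samples of both matrices.
#' @param n_draws number of random triples (default 100000).
#' @param region_class optional filter (`"neocortex"`/`"non_neocortex"`),
#'   conventionally the 7 transcriptionally distinct non-neocortical
#'   regions.
#' @param seed integer seed; draws are reproducible.
#' @return list with `R` (Pearson correlation), `n_draws`, and `draws`
#'   (data.frame of `gene`, `region_a`, `region_b`, `fc_a`, `fc_b`).
#' @export
foldchange_concordance <- function(matA, matB, meta, n_draws = 1e5,
                                   region_class = NULL, seed = 1L) {
  genes <- intersect(rownames(matA$values), rownames(matB$values))
  if (length(genes) == 0) stop("matrices share no features")
  rmA <- region_mean_matrix(matA, meta, region_class)
  rmB <- region_mean_matrix(matB, meta, region_class)
  regions <- intersect(colnames(rmA), colnames(rmB))
  if (length(regions) < 2) stop("need at least 2 regions after filtering")
  rmA <- rmA[genes, regions, drop = FALSE]
  rmB <- rmB[genes, regions, drop = FALSE]

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  gi <- sample.int(length(genes), n_draws, replace = TRUE)
  ra <- sample.int(length(regions), n_draws, replace = TRUE)
  shift <- sample.int(length(regions) - 1L, n_draws, replace = TRUE)
  rb <- 1L + (ra - 1L + shift) %% length(regions)  # distinct from ra

  fcA <- rmA[cbind(gi, ra)] - rmA[cbind(gi, rb)]
  fcB <- rmB[cbind(gi, ra)] - rmB[cbind(gi, rb)]
  list(R = stats::cor(fcA, fcB), n_draws = n_draws,
       draws = data.frame(gene = genes[gi], region_a = regions[ra],
                          region_b = regions[rb], fc_a = fcA, fc_b = fcB,
                          stringsAsFactors = FALSE))
}

#' Per-gene between-donor reproducibility
#'
#' For each gene, computes the vector of region mean log2 expression in each
#' of two donors (matrices restricted to one donor's samples each) and the
#' Pearson correlation between the two vectors — the gene-level biological
#' reproducibility score.
#'
#' @param matA,matB log2 `ExpressionMatrix` objects for the two donors,
#'   sharing feature names.
#' @param meta metadata covering both; both donors must cover the same
#'   regions.
#' @return named numeric vector of per-gene correlations; genes with a
#'   constant region profile in either donor are `NA`.
#' @export
per_gene_reproducibility <- function(matA, matB, meta) {
  genes <- intersect(rownames(matA$values), rownames(matB$values))
  if (length(genes) == 0) stop("matrices share no features")
  rmA <- region_mean_matrix(matA, meta)
  rmB <- region_mean_matrix(matB, meta)
  regions <- intersect(colnames(rmA), colnames(rmB))
  if (length(regions) < 3) stop("need at least 3 common regions")
  if (!setequal(colnames(rmA), colnames(rmB)))
    stop("donors must cover the same regions")
  A <- rmA[genes, regions, drop = FALSE]
  B <- rmB[genes, regions, drop = FALSE]
  ac <- A - rowMeans(A); bc <- B - rowMeans(B)
  sa <- rowSums(ac^2); sb <- rowSums(bc^2)
  r <- rowSums(ac * bc) / sqrt(sa * sb)
  r[sa == 0 | sb == 0] <- NA_real_
  n_na <- sum(is.na(r))
  if (n_na > 0)
    message(n_na, " gene(s) with constant region profile: r = NA")
  stats::setNames(pmin(pmax(r, -1), 1), genes)
}

#' Bin per-gene reproducibility by expression or transcript length
#'
#' Sorts genes by `sort_values`, splits them into `n_bins` near-equal bins
#' (any remainder spread over the leading bins), and reports each bin's mean
#' correlation and standard error of the mean. Genes with `NA` correlation
#' are excluded before binning.
#'
#' @param per_gene_r named per-gene correlations
#'   (from [per_gene_reproducibility()]).
#' @param sort_values named numeric sort key aligned to the same genes
#'   (mean expression, or transcript length).
#' @param n_bins number of bins (default 20).
#' @param key label for the sort key (`"expression"` or
#'   `"transcript_length"`).
#' @return data.frame per bin: `bin`, `n`, `mean_r`, `sem`, `min_sort`,
#'   `max_sort`, `key`.
#' @export
binned_reproducibility <- function(per_gene_r, sort_values, n_bins = 20,
                                   key = c("expression", "transcript_length")) {
  key <- match.arg(key)
  genes <- names(per_gene_r)[!is.na(per_gene_r)]
  if (length(genes) < n_bins)
    stop("fewer genes with defined correlation than bins")
  sv <- sort_values[genes]
  if (anyNA(sv)) stop("sort_values missing for some genes")
  o <- order(sv)
  genes <- genes[o]; sv <- sv[o]
  n <- length(genes)
  base <- n %/% n_bins; extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  idx <- rep(seq_len(n_bins), times = sizes)
  do.call(rbind, lapply(seq_len(n_bins), function(b) {
    g <- genes[idx == b]
    r <- per_gene_r[g]
    data.frame(bin = b, n = length(g), mean_r = mean(r),
               sem = stats::sd(r) / sqrt(length(g)),
               min_sort = min(sv[idx == b]), max_sort = max(sv[idx == b]),
               key = key, stringsAsFactors = FALSE)
  }))
}

#' One-way ANOVA across regions, per gene
#'
#' For every gene, a fixed-effects one-way ANOVA of log2 expression across
#' the regions of one region class, computed from sums of squares
#' (`F = (SSB/(k-1)) / (SSW/(N-k))`). Genes with zero total variance get
#' `p = 1` by convention. Bonferroni significance uses
#' `p * n_genes < alpha`.
#'
#' @param mat log2 `ExpressionMatrix`.
#' @param meta sample metadata covering `mat`'s samples.
#' @param region_class `"neocortex"` or `"non_neocortex"`.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame per gene: `gene_id`, `F`, `p`, `significant`
#'   (Bonferroni), with the significant count as attribute `"n_significant"`.
#' @export
region_anova <- function(mat, meta, region_class, alpha = 0.05) {
  check_samples_annotated(mat, meta)
  meta <- meta[meta$sample_id %in% colnames(mat$values) &
                 meta$region_class == region_class, , drop = FALSE]
  regions <- unique(meta$region)
  if (length(regions) < 2) stop("need at least 2 regions")
  cnt <- table(meta$region)
  if (any(cnt < 2)) stop("every region needs at least 2 samples")

  v <- mat$values[, meta$sample_id, drop = FALSE]
  grp <- factor(meta$region)
  k <- nlevels(grp); N <- ncol(v)
  ind <- stats::model.matrix(~ grp - 1)
  n_g <- colSums(ind)
  grand <- rowMeans(v)
  vc <- v - grand
  gm <- (vc %*% ind) / matrix(n_g, nrow(v), k, byrow = TRUE)
  ssb <- rowSums(sweep(gm^2, 2, n_g, "*"))
  sst <- rowSums(vc^2)
  ssw <- pmax(sst - ssb, 0)
  Fv <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- stats::pf(Fv, k - 1, N - k, lower.tail = FALSE)
  degenerate <- sst <= 1e-12 * N * pmax(grand^2, 1)
  if (any(degenerate)) {
    Fv[degenerate] <- 0
    p[degenerate] <- 1
  }
  res <- data.frame(gene_id = rownames(v), F = unname(Fv), p = unname(p),
                    significant = unname(p * nrow(v) < alpha),
                    stringsAsFactors = FALSE)
  attr(res, "n_significant") <- sum(res$significant)
  res
}

#' Stability of probe QC and scaling under training-set subsampling
#'
#' Repeats probe scoring (and optionally the quantile fit) on
#' region-stratified subsets of the training samples of increasing size, to
#' show how the probe pass rate grows and levels off with more training
#' samples. "Carefully selected" subsets maximize tissue diversity: the
#' draw takes one sample per region class first, then one per region, then
#' fills uniformly at random.
#'
#' @param array_log2,seq_log2 log2 matrices.
#' @param annot probe annotation.
#' @param meta sample metadata.
#' @param train_donor donor whose samples form the training pool.
#' @param sizes subset sizes (all >= 3 and <= the pool size).
#' @param n_rep random repeats per size (default 3).
#' @param seed integer seed.
#' @param cfg a [qc_config()].
#' @param fit also refit scaling parameters per subset and record the median
#'   absolute deviation of `m` and `b` from the full-pool fit (default TRUE).
#' @return data.frame per (size, rep): `size`, `rep`, `pass_rate`,
#'   `m_mad`, `b_mad` (NA when `fit = FALSE`).
#' @export
subsample_stability <- function(array_log2, seq_log2, annot, meta,
                                train_donor, sizes, n_rep = 3, seed = 1L,
                                cfg = qc_config(), fit = TRUE) {
  pool <- meta[meta$donor == train_donor &
                 meta$sample_id %in% colnames(array_log2$values) &
                 meta$sample_id %in% colnames(seq_log2$values), , drop = FALSE]
  if (any(sizes < 3)) stop("sizes must be >= 3")
  if (any(sizes > nrow(pool))) stop("size exceeds available training samples")

  full_rec <- assign_pass(probe_correlation(array_log2, seq_log2, annot,
                                            pool$sample_id, side = cfg$side), cfg)
  full_fit <- if (fit)
    fit_scaling(array_log2, seq_log2, annot, full_rec, pool$sample_id)
  else NULL

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  out <- list()
  for (size in sizes) {
    for (rep_i in seq_len(n_rep)) {
      ids <- if (size == nrow(pool)) pool$sample_id
             else stratified_sample(pool, size)
      rec <- assign_pass(probe_correlation(array_log2, seq_log2, annot, ids,
                                           side = cfg$side), cfg)
      pr <- mean(rec$pass, na.rm = TRUE)
      m_mad <- b_mad <- NA_real_
      if (fit) {
        fs <- fit_scaling(array_log2, seq_log2, annot, rec, ids)
        common <- intersect(fs$probe_id, full_fit$probe_id)
        if (length(common)) {
          i1 <- match(common, fs$probe_id); i2 <- match(common, full_fit$probe_id)
          m_mad <- stats::median(abs(fs$m[i1] - full_fit$m[i2]))
          b_mad <- stats::median(abs(fs$b[i1] - full_fit$b[i2]))
        }
      }
      out[[length(out) + 1L]] <- data.frame(size = size, rep = rep_i,
                                            pass_rate = pr, m_mad = m_mad,
                                            b_mad = b_mad)
      if (size == nrow(pool)) break  # no randomness at full size
    }
  }
  do.call(rbind, out)
}

# one sample per region class, then per region, then uniform fill
stratified_sample <- function(pool, size) {
  chosen <- character(0)
  remaining <- pool
  pick <- function(df, by) {
    ids <- character(0)
    for (lv in unique(df[[by]])) {
      cand <- df$sample_id[df[[by]] == lv]
      ids <- c(ids, sample(cand, 1))
    }
    ids
  }
  cls <- pick(remaining, "region_class")
  chosen <- utils::head(cls, size)
  remaining <- remaining[!(remaining$sample_id %in% chosen), , drop = FALSE]
  if (length(chosen) < size) {
    regs <- remaining[!(remaining$region %in%
                          pool$region[pool$sample_id %in% chosen]), , drop = FALSE]
    if (nrow(regs)) {
      by_reg <- pick(regs, "region")
      by_reg <- sample(by_reg)  # random region order
      add <- utils::head(by_reg, size - length(chosen))
      chosen <- c(chosen, add)
      remaining <- remaining[!(remaining$sample_id %in% chosen), , drop = FALSE]
    }
  }
  if (length(chosen) < size)
    chosen <- c(chosen, sample(remaining$sample_id, size - length(chosen)))
  chosen
}
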