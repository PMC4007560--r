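#' Scale samples by their total signal over non-differentially-expressed genes
#'
#' Library-size style normalization that, instead of the raw total, scales
#' each sample by its summed expression over genes judged *not*
#' differentially expressed between two sample groups (here typically
#' neocortex vs non-neocortex). Candidate DE genes are flagged by a per-gene
#' Wilcoxon rank-sum test at Benjamini-Hochberg FDR < `de_alpha`; each
#' sample is divided by its sum over the remaining genes (factors normalized
#' to mean 1 so they are identifiable), and finally one global multiplicative
#' constant is applied in linear space so that the matrix-wide total
#' `sum(log2(value + epsilon))` is conserved.
#'
#' Genes with identical values across all samples are passed through
#' unchanged (they carry no scaling information) and reported in the result.
#'
#' @param mat `ExpressionMatrix` in linear space, strictly non-negative.
#' @param groups logical per sample (aligned to columns): the two-group
#'   indicator used by the DE screen. Both values must be present with at
#'   least 2 samples each.
#' @param epsilon offset used in the conservation constraint (and in any
#'   subsequent [log_transform()]).
#' @param de_alpha BH FDR threshold for the DE flag (default 0.05).
#' @param rescale_scope `"matrix"` conserves the matrix-wide log2 total with
#'   one constant; `"sample"` conserves each sample's own log2 total.
#' @return list with `matrix` (normalized `ExpressionMatrix`) and `result`,
#'   a list with `scale_factors` (per sample), `de_flags` (per gene),
#'   `constant_genes`, and `global_rescale_constant` (for `"matrix"` scope).
#' @export
tbt_normalize <- function(mat, groups, epsilon = 2^-10, de_alpha = 0.05,
                          rescale_scope = c("matrix", "sample")) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  rescale_scope <- match.arg(rescale_scope)
  if (mat$space != "linear")
    stop("tbt_normalize operates in linear space")
  v <- mat$values
  if (!is.logical(groups) || length(groups) != ncol(v))
    stop("'groups' must be a logical vector, one value per sample")
  if (sum(groups) < 2 || sum(!groups) < 2)
    stop("each group needs at least 2 samples")

  const_gene <- apply(v, 1L, function(r) max(r) == min(r))
  de <- rep(FALSE, nrow(v))
  idx <- which(!const_gene)
  if (length(idx)) {
    p <- vapply(idx, function(g) {
      suppressWarnings(
        stats::wilcox.test(v[g, groups], v[g, !groups], exact = FALSE)$p.value)
    }, numeric(1))
    p[is.na(p)] <- 1
    de[idx] <- stats::p.adjust(p, method = "BH") < de_alpha
  }
  use <- !de
  if (!any(use))
    stop("no genes available for scaling: all genes flagged DE")

  sums <- colSums(v[use, , drop = FALSE])
  if (any(sums <= 0))
    stop("a sample has zero total over scaling genes")
  factors <- sums / mean(sums)
  scaled <- sweep(v, 2L, factors, "/")
  # constant genes carry no between-sample information: pass through unchanged
  scaled[const_gene, ] <- v[const_gene, , drop = FALSE]

  # conservation: one multiplicative constant (in linear space) chosen so the
  # log2 total matches the pre-normalization total
  solve_const <- function(x_scalable, x_fixed, target) {
    if (length(x_scalable) == 0) return(0)
    f <- function(k) sum(log2(2^k * x_scalable + epsilon)) +
      sum(log2(x_fixed + epsilon)) - target
    stats::uniroot(f, lower = -40, upper = 40, tol = 1e-13)$root
  }
  if (rescale_scope == "matrix") {
    target <- sum(log2(v + epsilon))
    k <- solve_const(scaled[!const_gene, , drop = FALSE],
                     scaled[const_gene, , drop = FALSE], target)
    scaled[!const_gene, ] <- 2^k * scaled[!const_gene, , drop = FALSE]
    const <- 2^k
  } else {
    const <- numeric(ncol(v))
    for (j in seq_len(ncol(v))) {
      target <- sum(log2(v[, j] + epsilon))
      k <- solve_const(scaled[!const_gene, j], scaled[const_gene, j], target)
      scaled[!const_gene, j] <- 2^k * scaled[!const_gene, j]
      const[j] <- 2^k
    }
  }

  out <- mat
  out$values <- scaled
  list(matrix = out,
       result = list(scale_factors = stats::setNames(factors, colnames(v)),
                     de_flags = stats::setNames(de, rownames(v)),
                     constant_genes = rownames(v)[const_gene],
                     global_rescale_constant = const))
}

#' Parametric empirical-Bayes batch adjustment in log2 space
#'
#' Removes per-batch location and scale effects gene by gene using the
#' parametric empirical-Bayes model of Johnson, Li & Rabinovic (2007).
#' Per gene, the grand mean (batch-size weighted) and the pooled standard
#' deviation of residuals about batch means standardize the data; per batch,
#' the observed batch means and variances of the standardized data are
#' shrunk toward method-of-moments normal / inverse-gamma priors by
#' iterating the posterior updates to a fixed point.
#'
#' @param mat `ExpressionMatrix` in log2 space.
#' @param batches batch label per sample (aligned to columns). At least two
#'   batches with at least two samples each.
#' @param tol convergence tolerance on the maximum absolute change of the
#'   per-batch posteriors (default 1e-4).
#' @param max_iter maximum fixed-point iterations per batch (default 500).
#' @return list with `matrix` (adjusted `ExpressionMatrix`) and `model`, a
#'   list holding `alpha` (grand means), `sigma` (pooled sds),
#'   `gamma_star`/`delta2_star` (per-batch posterior location/scale, genes x
#'   batches), hyperparameters `gamma_bar`, `tau2`, `lambda`, `theta`,
#'   `iterations` per batch, and `skipped_genes` (zero pooled variance,
#'   passed through unadjusted).
#' @references Johnson WE, Li C, Rabinovic A (2007). Adjusting batch effects
#'   in microarray expression data using empirical Bayes methods.
#'   Biostatistics 8(1):118-127.
#' @export
combat_adjust <- function(mat, batches, tol = 1e-4, max_iter = 500) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (mat$space != "log2")
    stop("combat_adjust operates in log2 space")
  v <- mat$values
  if (length(batches) != ncol(v))
    stop("'batches' must have one label per sample")
  batches <- as.character(batches)
  lv <- unique(batches)
  if (length(lv) < 2) stop("need at least 2 batches")
  n_i <- vapply(lv, function(b) sum(batches == b), integer(1))
  if (any(n_i < 2)) stop("every batch needs at least 2 samples")
  N <- ncol(v); G <- nrow(v)

  batch_means <- vapply(lv, function(b)
    rowMeans(v[, batches == b, drop = FALSE]), numeric(G))
  alpha <- as.vector(batch_means %*% (n_i / N))
  resid <- v - batch_means[, match(batches, lv), drop = FALSE]
  sigma2 <- rowSums(resid^2) / N
  skipped <- sigma2 <= 0
  out_vals <- v

  if (any(!skipped)) {
    keep <- which(!skipped)
    sg <- sqrt(sigma2[keep])
    Z <- (v[keep, , drop = FALSE] - alpha[keep]) / sg

    gamma_star <- matrix(NA_real_, length(keep), length(lv),
                         dimnames = list(rownames(v)[keep], lv))
    delta2_star <- gamma_star
    gamma_bar <- tau2 <- lambda <- theta <- stats::setNames(numeric(length(lv)), lv)
    iters <- stats::setNames(integer(length(lv)), lv)

    for (bi in seq_along(lv)) {
      cols <- which(batches == lv[bi])
      n <- length(cols)
      Zb <- Z[, cols, drop = FALSE]
      g_hat <- rowMeans(Zb)
      d2_hat <- apply(Zb, 1L, stats::var)
      gamma_bar[bi] <- mean(g_hat)
      tau2[bi] <- stats::var(g_hat)
      V <- mean(d2_hat); S <- stats::var(d2_hat)
      lambda[bi] <- V^2 / S + 2
      theta[bi] <- V * (lambda[bi] - 1)

      sum_z <- rowSums(Zb)
      sum_z2 <- rowSums(Zb^2)
      g_new <- g_hat; d2_new <- d2_hat
      it <- 0L
      repeat {
        it <- it + 1L
        g_old <- g_new; d2_old <- d2_new
        # degenerate hyperpriors: tau2 = 0 (all batch means identical after
        # standardization) gives a point-mass location prior; S = 0 likewise
        # for the scale prior
        g_new <- if (tau2[bi] > 0) {
          (n * tau2[bi] * g_hat + d2_old * gamma_bar[bi]) /
            (n * tau2[bi] + d2_old)
        } else rep(gamma_bar[bi], length(g_hat))
        if (S > 0) {
          ss <- sum_z2 - 2 * g_new * sum_z + n * g_new^2
          d2_new <- (theta[bi] + 0.5 * ss) / (n / 2 + lambda[bi] - 1)
        } else d2_new <- rep(V, length(d2_hat))
        change <- max(abs(g_new - g_old), abs(d2_new - d2_old))
        if (change < tol) break
        if (it >= max_iter)
          stop(sprintf(
            "batch adjustment did not converge for batch '%s': %d iterations, last max change %.3g (tol %.3g)",
            lv[bi], it, change, tol))
      }
      iters[bi] <- it
      gamma_star[, bi] <- g_new
      delta2_star[, bi] <- d2_new
      # adjusted values for this batch
      out_vals[keep, cols] <- (sg / sqrt(d2_new)) * (Zb - g_new) + alpha[keep]
    }
    model <- list(alpha = stats::setNames(alpha, rownames(v)),
                  sigma = stats::setNames(sqrt(sigma2), rownames(v)),
                  gamma_star = gamma_star, delta2_star = delta2_star,
                  gamma_bar = gamma_bar, tau2 = tau2,
                  lambda = lambda, theta = theta,
                  iterations = iters, tol = tol,
                  skipped_genes = rownames(v)[skipped])
  } else {
    stop("all genes have zero pooled variance; nothing to adjust")
  }
  if (any(skipped))
    message(sum(skipped), " gene(s) with zero pooled variance passed through unadjusted")

  out <- mat
  out$values <- out_vals
  list(matrix = out, model = model)
}
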