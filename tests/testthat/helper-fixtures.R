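# shared fixture builders and independent oracles

make_em <- function(values, space = "log2", platform = "microarray",
                    unit = "intensity",
                    features = sprintf("f%02d", seq_len(nrow(values))),
                    samples = sprintf("s%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(features, samples)
  ExpressionMatrix(values, space, platform, unit)
}

# minimal metadata for a vector of sample ids laid out as
# donor x region x hemisphere x replicate
make_meta <- function(donors, regions, region_class, hemis = c("L", "R"),
                      reps = 1:2) {
  g <- expand.grid(replicate = reps, hemisphere = hemis, region = regions,
                   donor = donors, stringsAsFactors = FALSE)
  g$region_class <- region_class[match(g$region, regions)]
  g$sample_id <- sprintf("%s_%s_%s_r%d", g$donor, g$region, g$hemisphere,
                         g$replicate)
  g$batch <- g$donor
  validate_sample_metadata(
    g[, c("sample_id", "donor", "region", "region_class", "hemisphere",
          "replicate", "batch")])
}

# ---- independent oracles -------------------------------------------------

# brute-force Storey q-values: literal double loop over the definition
qvalues_bruteforce <- function(p, pi0 = NULL,
                               lambda = seq(0.05, 0.90, by = 0.05)) {
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- mean(sapply(lambda, function(l) sum(p > l) / (m * (1 - l))))
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  }
  rank_of <- function(pj) sum(p <= pj)
  sapply(p, function(pi_) {
    cand <- p[p >= pi_]
    min(1, min(sapply(cand, function(pj) pi0 * m * pj / rank_of(pj))))
  })
}

# permutation p-value for a one-sided positive-correlation test
perm_cor_pvalue <- function(x, y, n_perm = 1e5, seed = 42) {
  set.seed(seed)
  r_obs <- cor(x, y)
  n <- length(x)
  xc <- scale(x)[, 1]
  r_perm <- replicate(n_perm, {
    yp <- sample(y)
    sum(xc * scale(yp)[, 1]) / (n - 1)
  })
  (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
}

# scalar, per-gene fixed-point evaluation of the parametric EB batch model:
# deliberately loop-based and structured differently from the package code
combat_oracle <- function(v, batches, tol = 1e-10, max_iter = 10000) {
  lv <- unique(batches)
  n_i <- sapply(lv, function(b) sum(batches == b))
  N <- ncol(v); G <- nrow(v)
  bm <- sapply(lv, function(b) rowMeans(v[, batches == b, drop = FALSE]))
  alpha <- as.vector(bm %*% (n_i / N))
  sig2 <- numeric(G)
  for (g in 1:G) {
    res <- 0
    for (j in 1:N) res <- res + (v[g, j] - bm[g, match(batches[j], lv)])^2
    sig2[g] <- res / N
  }
  Z <- (v - alpha) / sqrt(sig2)
  out <- v
  for (bi in seq_along(lv)) {
    cols <- which(batches == lv[bi]); n <- length(cols)
    g_hat <- rowMeans(Z[, cols, drop = FALSE])
    d2_hat <- apply(Z[, cols, drop = FALSE], 1, var)
    gbar <- mean(g_hat); t2 <- var(g_hat)
    V <- mean(d2_hat); S <- var(d2_hat)
    lam <- V^2 / S + 2; th <- V * (lam - 1)
    for (g in 1:G) {
      gs <- g_hat[g]; d2 <- d2_hat[g]
      for (it in 1:max_iter) {
        gs_new <- (n * t2 * g_hat[g] + d2 * gbar) / (n * t2 + d2)
        ss <- sum((Z[g, cols] - gs_new)^2)
        d2_new <- (th + 0.5 * ss) / (n / 2 + lam - 1)
        if (max(abs(gs_new - gs), abs(d2_new - d2)) < tol) {
          gs <- gs_new; d2 <- d2_new; break
        }
        gs <- gs_new; d2 <- d2_new
      }
      out[g, cols] <- sqrt(sig2[g] / d2) * (Z[g, cols] - gs) + alpha[g]
    }
  }
  out
}

# closed-form power of the one-sided correlation t-test at level alpha,
# Fisher z approximation
cor_test_power <- function(rho, n, alpha) {
  r_alpha <- uniroot(function(r) {
    t <- r * sqrt((n - 2) / (1 - r^2))
    pt(t, n - 2, lower.tail = FALSE) - alpha
  }, c(1e-8, 1 - 1e-8))$root
  pnorm((atanh(rho) - atanh(r_alpha)) * sqrt(n - 3))
}

# conditional population correlation of each scored probe with the realized
# RNA-Seq vector: corr(noise-free array signal, observed seq log2),
# attenuated by the known array noise
probe_true_correlation <- function(sim, records, train, seq_log2) {
  y0 <- sim$truth$array_signal_log2[records$probe_id, train, drop = FALSE]
  Y <- seq_log2$values[records$gene_id, train, drop = FALSE]
  v0 <- apply(y0, 1, var)
  r0 <- vapply(seq_len(nrow(y0)), function(i)
    if (v0[i] > 0) cor(y0[i, ], Y[i, ]) else 0, numeric(1))
  sa2 <- sim$truth$config$array_noise_sd^2
  r0 * sqrt(v0 / (v0 + sa2))
}
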