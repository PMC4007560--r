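test_that("replicate pairs are found by metadata and scored by correlation", {
  meta <- make_meta("d1", c("rA", "rB"), c("neocortex", "non_neocortex"))
  set.seed(61)
  v <- matrix(rnorm(50 * nrow(meta), 5, 2), 50, nrow(meta),
              dimnames = list(paste0("g", 1:50), meta$sample_id))
  # make replicate 2 a duplicate of replicate 1 in every site
  r1 <- meta$sample_id[meta$replicate == 1]
  r2 <- meta$sample_id[meta$replicate == 2]
  v[, r2] <- v[, r1]
  em <- ExpressionMatrix(v, "log2", "microarray", "intensity")
  rc <- replicate_correlations(em, meta)
  expect_equal(nrow(rc), 4)  # 2 regions x 2 hemispheres
  expect_equal(rc$r, rep(1, 4), tolerance = 1e-12)
  expect_equal(attr(rc, "median_r"), 1)

  # independent Gaussian columns: near-zero correlation with many genes
  set.seed(62)
  v2 <- matrix(rnorm(1e4 * 4), 1e4, 4,
               dimnames = list(NULL, meta$sample_id[1:4]))
  rownames(v2) <- paste0("g", seq_len(nrow(v2)))
  em2 <- ExpressionMatrix(v2, "log2", "microarray", "intensity")
  rc2 <- replicate_correlations(em2, meta[1:4, ])
  expect_true(all(abs(rc2$r) < 0.05))

  # no pairs -> error
  expect_error(replicate_correlations(em2[, 1], meta[1, ]), "no replicate")
})

test_that("presence summary applies thresholds per platform and bounds overlap", {
  genes <- paste0("g", 1:4)
  samples <- paste0("s", 1:20)
  flags <- matrix(FALSE, 4, 20, dimnames = list(genes, samples))
  flags[1, ] <- TRUE          # always present on array
  flags[2, 1:10] <- TRUE      # present in half
  counts <- matrix(0, 4, 20, dimnames = list(genes, samples))
  counts[1, ] <- 5
  counts[3, 1] <- 1           # single aligned fragment in one sample
  out <- presence_summary(flags, counts)

  at <- function(t) out[out$threshold == t, ]
  # one fragment in 1/20 samples: present in seq at the 5% threshold only
  expect_equal(at(0.05)$n_seq, 2)
  expect_equal(at(0.50)$n_seq, 1)
  # all-zero counts gene absent at all thresholds
  expect_true(all(out$n_seq < 4))
  expect_equal(at(0.50)$n_array, 2)
  expect_equal(at(0.95)$n_array, 1)
  expect_true(all(out$n_overlap <= pmin(out$n_array, out$n_seq)))

  # generator: collapse probe-level array flags to genes, compare with counts
  sim <- simulate_dataset(sim_config(seed = 63))
  flags_gene <- rowsum(sim$presence * 1L, sim$annot$gene_id) > 0
  ps <- presence_summary(flags_gene, sim$seq_counts$values, thresholds = 0.5)
  expect_true(ps$overlap_frac > 0.3 && ps$overlap_frac <= 1)
  expect_lte(ps$n_overlap, min(ps$n_array, ps$n_seq))
})

test_that("fold-change concordance: identity, permutation null, reproducibility", {
  meta <- make_meta("d1", paste0("r", 1:5),
                    rep("non_neocortex", 5))
  set.seed(64)
  v <- matrix(rnorm(400 * nrow(meta), 4, 2), 400, nrow(meta),
              dimnames = list(paste0("g", 1:400), meta$sample_id))
  em <- ExpressionMatrix(v, "log2", "microarray", "intensity")
  idt <- foldchange_concordance(em, em, meta, n_draws = 5000, seed = 9)
  expect_equal(idt$R, 1, tolerance = 1e-12)

  # permuted gene labels: null concordance
  v2 <- v[sample(nrow(v)), ]
  rownames(v2) <- rownames(v)
  em2 <- ExpressionMatrix(v2, "log2", "microarray", "intensity")
  null <- foldchange_concordance(em, em2, meta, n_draws = 1e5, seed = 9)
  expect_lt(abs(null$R), 0.02)

  # same seed reproduces draws exactly; different seed differs
  again <- foldchange_concordance(em, em2, meta, n_draws = 1e5, seed = 9)
  expect_identical(null$R, again$R)
  expect_identical(null$draws, again$draws)
  other <- foldchange_concordance(em, em2, meta, n_draws = 1e5, seed = 10)
  expect_false(identical(null$R, other$R))
  # drawn regions are always distinct
  expect_true(all(null$draws$region_a != null$draws$region_b))

  meta1 <- meta[meta$region == "r1", ]
  em1 <- em[, meta1$sample_id]
  expect_error(foldchange_concordance(em1, em1, meta1, n_draws = 10, seed = 1),
               "at least 2 regions")
})

test_that("fold-change concordance approaches the variance-component prediction", {
  # two donors share region effects; donor noise attenuates the correlation:
  # R_theory = s2_region / (s2_region + s2_noise_of_region_mean_difference)
  set.seed(65)
  G <- 2000; n_regions <- 6; n_per <- 4
  region_eff <- matrix(rnorm(G * n_regions, 0, 1), G, n_regions)
  sd_noise <- 0.5
  meta <- make_meta(c("d1", "d2"), paste0("r", 1:n_regions),
                    rep("non_neocortex", n_regions))
  mats <- lapply(c("d1", "d2"), function(d) {
    ids <- meta$sample_id[meta$donor == d]
    ri <- match(meta$region[match(ids, meta$sample_id)], paste0("r", 1:n_regions))
    v <- 5 + region_eff[, ri] + matrix(rnorm(G * length(ids), 0, sd_noise),
                                       G, length(ids))
    dimnames(v) <- list(paste0("g", 1:G), ids)
    ExpressionMatrix(v, "log2", "microarray", "intensity")
  })
  fc <- foldchange_concordance(mats[[1]], mats[[2]], meta, n_draws = 1e5,
                               seed = 3)
  s2_fc <- 2 * 1          # var of fold change from region effects
  s2_noise <- 2 * sd_noise^2 / n_per  # two region means per donor
  r_theory <- s2_fc / (s2_fc + s2_noise)
  expect_lt(abs(fc$R - r_theory), 0.02)
})

test_that("per-gene reproducibility scores region profiles", {
  meta <- make_meta(c("d1", "d2"), paste0("r", 1:4),
                    rep("neocortex", 4))
  prof <- c(1, 3, 2, 5)
  build <- function(d, gene_rows) {
    ids <- meta$sample_id[meta$donor == d]
    ri <- match(meta$region[match(ids, meta$sample_id)], paste0("r", 1:4))
    v <- gene_rows[, ri, drop = FALSE]
    dimnames(v) <- list(rownames(gene_rows), ids)
    ExpressionMatrix(v, "log2", "microarray", "intensity")
  }
  rows <- rbind(same = prof, reversed = prof, const = rep(2, 4))
  mA <- build("d1", rows)
  rowsB <- rbind(same = prof, reversed = max(prof) + min(prof) - prof,
                 const = rep(2, 4))
  mB <- build("d2", rowsB)
  r <- suppressMessages(per_gene_reproducibility(mA, mB, meta))
  expect_equal(unname(r["same"]), 1, tolerance = 1e-12)
  expect_equal(unname(r["reversed"]), -1, tolerance = 1e-12)
  expect_true(is.na(r["const"]))

  # null: no region effects -> correlations centered at zero
  set.seed(66)
  G <- 500
  vA <- matrix(rnorm(G * 16, 5, 1), G, 16)
  vB <- matrix(rnorm(G * 16, 5, 1), G, 16)
  rownames(vA) <- rownames(vB) <- paste0("g", 1:G)
  colnames(vA) <- meta$sample_id[meta$donor == "d1"]
  colnames(vB) <- meta$sample_id[meta$donor == "d2"]
  rn <- per_gene_reproducibility(
    ExpressionMatrix(vA, "log2", "microarray", "intensity"),
    ExpressionMatrix(vB, "log2", "microarray", "intensity"), meta)
  expect_lt(abs(mean(rn, na.rm = TRUE)), 0.1)
})

test_that("binned reproducibility partitions genes and summarizes bins", {
  r <- setNames(rep(0.7, 40), paste0("g", 1:40))
  sv <- setNames(seq_len(40), names(r))
  b <- binned_reproducibility(r, sv, n_bins = 20)
  expect_equal(b$n, rep(2, 20))
  expect_equal(b$mean_r, rep(0.7, 20))
  expect_equal(b$sem, rep(0, 20))
  # remainder spread over leading bins
  r43 <- setNames(runif(43), paste0("g", 1:43))
  sv43 <- setNames(rnorm(43), names(r43))
  b43 <- binned_reproducibility(r43, sv43, n_bins = 20)
  expect_equal(b43$n, c(rep(3, 3), rep(2, 17)))
  expect_equal(sum(b43$n), 43)
  # bins follow the sort order
  expect_true(all(diff(b43$min_sort) > 0))
  expect_error(binned_reproducibility(r43[1:10], sv43[1:10], n_bins = 20),
               "fewer genes")
})

test_that("region ANOVA matches aov and hand sums of squares", {
  meta <- make_meta("d1", paste0("r", 1:3), rep("non_neocortex", 3))
  set.seed(67)
  v <- matrix(rnorm(6 * nrow(meta), 5, 1), 6, nrow(meta),
              dimnames = list(paste0("g", 1:6), meta$sample_id))
  v[1, ] <- v[1, ] + 10 * (meta$region == "r2")  # huge region effect
  v[2, ] <- 3                                     # constant gene
  em <- ExpressionMatrix(v, "log2", "microarray", "intensity")
  res <- region_anova(em, meta, "non_neocortex")

  # oracle 1: hand sums of squares for gene 3
  g <- v[3, ]; grp <- meta$region
  k <- 3; N <- length(g)
  means <- tapply(g, grp, mean); counts <- table(grp)
  ssb <- sum(counts * (means - mean(g))^2)
  ssw <- sum((g - means[grp])^2)
  F_hand <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_lt(abs(res$F[3] - F_hand), 1e-10)

  # oracle 2: stats::aov agrees for every non-degenerate gene
  for (i in c(1, 3, 4)) {
    f_aov <- summary(aov(v[i, ] ~ factor(meta$region)))[[1]]$`F value`[1]
    expect_equal(res$F[i], f_aov, tolerance = 1e-10)
  }

  expect_lt(res$p[1], 1e-8)
  expect_true(res$significant[1])
  expect_equal(res$p[2], 1)   # degenerate gene: p = 1 by convention
  expect_false(res$significant[2])
  expect_equal(attr(res, "n_significant"), sum(res$significant))
})

test_that("region ANOVA is calibrated under the null", {
  # generator with no region effects and Gaussian-only noise: uniform p,
  # and (usually) no Bonferroni hits in 1000 genes
  zeros <- 0L
  for (s in 1:3) {
    sim <- simulate_dataset(sim_config(
      seed = 100 + s, n_genes = 1000, frac_region_de = 0,
      region_effect_sd_base_neocortex = 0, region_effect_sd_base_other = 0,
      donor_location_sd = 0, donor_scale_sd = 0, count_noise = FALSE,
      seq_noise_sd = 0.4))
    sl <- log_transform(sim$seq_tpm)
    res <- region_anova(sl, sim$meta, "non_neocortex")
    if (attr(res, "n_significant") == 0) zeros <- zeros + 1L
    if (s == 1) {
      ks <- suppressWarnings(ks.test(res$p, "punif"))
      expect_gt(ks$p.value, 0.01)
    }
  }
  expect_gte(zeros, 2L)
})

test_that("subsampling reproduces the full fit at full size and improves with size", {
  sim <- simulate_dataset(sim_config(seed = 71, n_genes = 600))
  al <- log_transform(sim$array)
  sl <- log_transform(sim$seq_tpm)
  pool_n <- sum(sim$meta$donor == "brain2")
  res <- subsample_stability(al, sl, sim$annot, sim$meta, "brain2",
                             sizes = c(4, 16, pool_n), n_rep = 2, seed = 5)
  full_row <- res[res$size == pool_n, ]
  expect_equal(nrow(full_row), 1)  # no resampling needed at full size
  rec_full <- assign_pass(probe_correlation(al, sl, sim$annot,
                                            sim$meta$sample_id[sim$meta$donor == "brain2"]))
  expect_equal(full_row$pass_rate, mean(rec_full$pass, na.rm = TRUE))
  expect_equal(full_row$m_mad, 0)
  expect_equal(full_row$b_mad, 0)

  means <- tapply(res$pass_rate, res$size, mean)
  expect_true(means[as.character(pool_n)] >= means["4"])
  expect_error(subsample_stability(al, sl, sim$annot, sim$meta, "brain2",
                                   sizes = 2), ">= 3")
})
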