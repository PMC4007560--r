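test_that("probe correlation: perfect linearity, symmetric null, degenerate vectors", {
  arr <- make_em(rbind(p1 = c(1, 2, 3, 4), p2 = c(4, 4, 4, 4)),
                 features = c("p1", "p2"))
  seq <- make_em(rbind(g1 = c(10, 20, 30, 40)), platform = "rnaseq",
                 unit = "TPM", features = "g1",
                 samples = colnames(arr$values))
  annot <- data.frame(probe_id = c("p1", "p2"), gene_id = "g1")
  rec <- probe_correlation(arr, seq, annot, colnames(arr$values))
  expect_equal(rec$r[rec$probe_id == "p1"], 1, tolerance = 1e-12)
  # zero-variance probe: r undefined, p = 1
  expect_true(is.na(rec$r[rec$probe_id == "p2"]))
  expect_equal(rec$p[rec$probe_id == "p2"], 1)

  # r = 0 gives one-sided p = 0.5 (symmetric null)
  arr2 <- make_em(rbind(p1 = c(1, 2, 1, 2, 1, 2)), features = "p1")
  seq2 <- make_em(rbind(g1 = c(1, 1, 2, 2, 1.5, 1.5)), platform = "rnaseq",
                  unit = "TPM", features = "g1",
                  samples = colnames(arr2$values))
  rec2 <- probe_correlation(arr2, seq2,
                            data.frame(probe_id = "p1", gene_id = "g1"),
                            colnames(arr2$values))
  expect_equal(rec2$r, 0, tolerance = 1e-12)
  expect_equal(rec2$p, 0.5, tolerance = 1e-12)

  # probes with genes missing from the seq matrix are skipped with a message
  annot3 <- rbind(annot, data.frame(probe_id = "p3", gene_id = "gX"))
  arr3 <- make_em(rbind(p1 = c(1, 2, 3, 4), p2 = c(4, 4, 4, 4),
                        p3 = c(1, 3, 2, 4)),
                  features = c("p1", "p2", "p3"))
  expect_message(rec3 <- probe_correlation(arr3, seq, annot3,
                                           colnames(arr3$values)),
                 "skipped")
  expect_false("p3" %in% rec3$probe_id)
})

test_that("one-sided correlation p-values match a permutation oracle", {
  set.seed(99)
  n <- 10
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n)  # moderate correlation: p in a testable range
  arr <- make_em(matrix(x, 1, n), features = "p1", samples = paste0("s", 1:n))
  seq <- make_em(matrix(y, 1, n), features = "g1", samples = paste0("s", 1:n),
                 platform = "rnaseq", unit = "TPM")
  rec <- probe_correlation(arr, seq,
                           data.frame(probe_id = "p1", gene_id = "g1"),
                           paste0("s", 1:n))
  p_perm <- perm_cor_pvalue(x, y, n_perm = 1e5)
  expect_lt(abs(rec$p - p_perm), 0.02)
})

test_that("q-values match a brute-force evaluation and reduce to BH at pi0 = 1", {
  set.seed(12)
  p <- c(runif(900), rbeta(100, 0.1, 1))
  q <- qvalues(p)
  q_bf <- qvalues_bruteforce(p)
  expect_equal(as.numeric(q), q_bf, tolerance = 1e-12)
  expect_true(attr(q, "pi0") > 0 && attr(q, "pi0") <= 1)

  # pi0 forced to 1: exact BH equivalence
  expect_equal(as.numeric(qvalues(p, pi0 = 1)), p.adjust(p, "BH"),
               tolerance = 1e-14)

  # monotone non-decreasing in p, capped at 1
  o <- order(p)
  expect_true(all(diff(as.numeric(q)[o]) >= 0))
  expect_true(all(q <= 1))

  # degenerate cases
  expect_length(qvalues(numeric(0)), 0)
  q1 <- qvalues(0.01)
  expect_lte(as.numeric(q1), 0.01)
  qt <- qvalues(rep(0.5, 8))
  expect_true(all(abs(qt - qt[1]) < 1e-15))
  expect_lte(qt[1], attr(qt, "pi0") * 0.5)
})

test_that("pass rule requires positive correlation and q below threshold", {
  rec <- data.frame(probe_id = c("a", "b", "c", "d"),
                    gene_id = c("g1", "g1", "g2", "g2"),
                    r = c(0.9, -0.9, 0.5, NA),
                    p = c(1e-6, 0.999, 0.2, 1), n_train = 20L)
  out <- assign_pass(rec, qc_config(q_threshold = 0.1))
  expect_true(out$pass[1])
  expect_false(out$pass[2])   # strong but negative: fails by rule
  expect_false(out$pass[4])   # undefined r fails
  expect_true(all(out$q >= 0 & out$q <= 1))
})

test_that("per-gene designations pick best, worst and highest with stable ties", {
  rec <- data.frame(
    probe_id = c("pA", "pB", "pC", "single"),
    gene_id = c("g1", "g1", "g1", "g2"),
    r = c(0.9, 0.2, -0.1, 0.4))
  rm_mat <- matrix(c(5, 7, 2, 3), 4, 2,
                   dimnames = list(c("pA", "pB", "pC", "single"),
                                   c("r1", "r2")))
  out <- designate_probes(rec, rm_mat)
  # per multi-probe gene, max r is best and min r is worst; the single-probe
  # gene is its own best and worst
  expect_setequal(out$probe_id[out$is_best], c("pA", "single"))
  expect_setequal(out$probe_id[out$is_worst], c("pC", "single"))
  expect_true(out$is_highest[out$probe_id == "pB"])  # max mean expression in g1
  # a single-probe gene is simultaneously best, worst and highest
  s <- out[out$probe_id == "single", ]
  expect_true(s$is_best && s$is_worst && s$is_highest)
  # at most one of each designation per gene
  per_gene <- split(out, out$gene_id)
  for (g in per_gene) {
    expect_lte(sum(g$is_best), 1)
    expect_lte(sum(g$is_worst), 1)
    expect_equal(sum(g$is_highest), 1)
  }
  # lexicographic tie-break on equal r
  tie <- data.frame(probe_id = c("z", "a"), gene_id = "g", r = c(0.5, 0.5))
  rt <- matrix(c(1, 1), 2, 1, dimnames = list(c("z", "a"), "r1"))
  out2 <- designate_probes(tie, rt)
  expect_equal(out2$probe_id[out2$is_best], "a")
})

test_that("bright probes are flagged by the positive-residual rule", {
  set.seed(2)
  x <- rnorm(100, 3, 2)
  y <- 1.5 * x + 1  # exactly on a line
  names(x) <- names(y) <- sprintf("p%03d", 1:100)
  expect_length(flag_bright_probes(y, x), 0)

  y2 <- y; y2[7] <- y2[7] + 10
  expect_equal(flag_bright_probes(y2, x), "p007")
  # a matching *negative* outlier is not flagged
  y3 <- y; y3[7] <- y3[7] - 10
  expect_length(flag_bright_probes(y3, x), 0)

  expect_error(flag_bright_probes(y[1:5], x[1:5]), "at least 10")

  # generator's constant-bright probes: high sensitivity, low false positives
  sim <- simulate_dataset(sim_config(seed = 15, bright_fraction = 0.05))
  al <- log_transform(sim$array)
  sl <- log_transform(sim$seq_tpm)
  am <- rowMeans(al$values)
  gm <- rowMeans(sl$values)[sim$annot$gene_id]
  flagged <- flag_bright_probes(am, gm)
  tp <- sim$truth$probes
  bright <- tp$probe_id[tp$bright]
  sens <- mean(bright %in% flagged)
  fpr <- mean(setdiff(tp$probe_id, bright) %in% flagged)
  expect_gte(sens, 0.90)
  expect_lte(fpr, 0.05)
})

test_that("probes below the background floor fail far more often than bright expressers", {
  sim <- simulate_dataset(sim_config(seed = 22))
  al <- log_transform(sim$array)
  sl <- log_transform(sim$seq_tpm)
  train <- sim$meta$sample_id[sim$meta$donor == "brain2"]
  rec <- assign_pass(probe_correlation(al, sl, sim$annot, train))
  tp <- sim$truth$probes
  on <- tp$on_target[match(rec$probe_id, tp$probe_id)]
  mean_int <- rowMeans(al$values[rec$probe_id, train])
  floor <- sim$truth$config$background_floor
  # the softplus floor maps everything to at least floor + 1; "low" probes
  # hug that bound, "high" probes sit well clear of it
  low <- on & mean_int < floor + 1.6
  high <- on & mean_int > floor + 4
  expect_gt(sum(low), 20)
  expect_gt(sum(high), 20)
  expect_gt(mean(rec$pass[high]), 2 * mean(rec$pass[low]))
})

test_that("pass rate over on-target probes rises with training-set size", {
  sim <- simulate_dataset(sim_config(seed = 31))
  al <- log_transform(sim$array)
  sl <- log_transform(sim$seq_tpm)
  pool <- sim$meta[sim$meta$donor == "brain2", ]
  tp <- sim$truth$probes
  set.seed(5)
  rates <- sapply(c(6, 24, 96), function(k) {
    ids <- sample(pool$sample_id, k)
    rec <- assign_pass(probe_correlation(al, sl, sim$annot, ids))
    on <- tp$on_target[match(rec$probe_id, tp$probe_id)]
    mean(rec$pass[on])
  })
  expect_true(all(diff(rates) > 0))
})
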