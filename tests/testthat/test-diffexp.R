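test_that("a gene is present when any of its probes is present", {
  ds <- tiny_dataset()
  P <- gene_presence(ds)
  expect_true(all(P["g1", ]))                       # one probe always P
  expect_equal(unname(P["g2", ]),
               ds$samples$condition == "post")      # P only after treatment
  expect_false(any(P["g3", ]))                      # marginal counts as absent
})

test_that("presence matches a per-cell oracle on random call matrices", {
  withr::with_seed(42, {
    probes <- paste0("p", 1:9)
    genes <- rep(c("gA", "gB", "gC"), each = 3)
    samples <- data.frame(sample_id = paste0("s", 1:4),
                          condition = rep(c("pre", "post"), 2))
    calls <- matrix(sample(c("P", "M", "A"), 36, replace = TRUE), 9, 4,
                    dimnames = list(probes, samples$sample_id))
    expr <- matrix(2^stats::rnorm(36, 7), 9, 4,
                   dimnames = dimnames(calls))
    ds <- detection_dataset(expr, calls,
                            data.frame(probe = probes, gene = genes), samples)
    P <- gene_presence(ds)
    for (g in unique(genes)) for (s in samples$sample_id) {
      expect_identical(P[g, s], any(calls[genes == g, s] == "P"))
    }
  })
})

test_that("marginal calls can be counted as present on request", {
  ds <- tiny_dataset()
  ds2 <- detection_dataset(ds$expr, ds$calls, ds$probe_map, ds$samples,
                           marginal_present = TRUE)
  expect_true(all(gene_presence(ds2)["g3", ]))
})

test_that("McNemar statistic follows its closed form and degenerate rule", {
  expect_equal(mcnemar_stat(5, 1)$chi2, 16 / 6)
  expect_equal(mcnemar_stat(0, 0), list(chi2 = 0, p_value = 1))
  expect_equal(mcnemar_stat(3, 3)$chi2, 0)
  expect_equal(mcnemar_stat(3, 3)$p_value, 1)
  # symmetry
  expect_equal(mcnemar_stat(7, 2), mcnemar_stat(2, 7))
  expect_error(mcnemar_stat(-1, 2), "nonnegative")
  # agreement with the stock implementation (no correction)
  for (bc in list(c(5, 1), c(9, 4), c(12, 0))) {
    tab <- matrix(c(10, bc[1], bc[2], 10), 2)
    ref <- stats::mcnemar.test(tab, correct = FALSE)
    expect_equal(mcnemar_stat(bc[1], bc[2])$chi2, unname(ref$statistic))
    expect_equal(mcnemar_stat(bc[1], bc[2])$p_value, ref$p.value)
  }
})

test_that("Pearson chi-square matches the stock test and handles zero margins", {
  tab <- matrix(c(30, 10, 10, 30), 2)
  expect_equal(chisq_presence(tab)$chi2, 20)
  expect_equal(chisq_presence(matrix(c(5, 5, 7, 7), 2))$chi2, 0)
  expect_equal(chisq_presence(matrix(c(0, 0, 3, 4), 2))$p_value, 1)
  expect_error(chisq_presence(matrix(0, 2, 2)), "all-zero")
  withr::with_seed(7, {
    for (i in 1:10) {
      tab <- matrix(rpois(4, 12) + 1, 2)
      ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      expect_equal(chisq_presence(tab)$chi2, unname(ref$statistic))
      expect_equal(chisq_presence(tab)$p_value, ref$p.value)
      # invariance to row and column swaps
      expect_equal(chisq_presence(tab[2:1, ])$chi2, chisq_presence(tab)$chi2)
      expect_equal(chisq_presence(tab[, 2:1])$chi2, chisq_presence(tab)$chi2)
    }
  })
})

test_that("log fold change is log2 of the mean ratio with up meaning FC > 1", {
  expect_equal(log_fold_change(10, 10), 0)
  expect_equal(log_fold_change(10, 20), 1)
  expect_equal(log_fold_change(40, 10), -2)
  expect_true(log_fold_change(3, 5) > 0)  # upregulated after treatment
})

test_that("gene_stats agrees with per-gene manual computation", {
  ds <- tiny_dataset()
  st <- gene_stats(ds, paired = TRUE)
  expect_setequal(st$gene, c("g1", "g2", "g3"))
  g1 <- st[st$gene == "g1", ]
  expect_equal(g1$delta_e, 1)       # g1 doubles after treatment (max probe)
  expect_equal(g1$chi2, 0)          # presence never changes
  expect_equal(g1$direction, "up")
  g2 <- st[st$gene == "g2", ]
  expect_equal(g2$chi2, 4)          # b = 0, c = 4 discordant pairs
  expect_equal(g2$p_value, stats::pchisq(4, 1, lower.tail = FALSE))
  expect_true(g2$is_de)
  # unpaired path on the same data: 2x2 of presence x condition
  stu <- gene_stats(ds, paired = FALSE)
  ref <- chisq_presence(matrix(c(0, 4, 4, 0), 2))
  expect_equal(stu[stu$gene == "g2", "chi2"], ref$chi2)
})

test_that("paired mode validates its pair structure", {
  ds <- tiny_dataset()
  bad <- ds$samples
  bad$pair_id[1] <- bad$pair_id[2]
  expect_error(gene_stats(ds, paired = TRUE, samples = bad), "pair")
  expect_error(gene_stats(tiny_dataset(paired = FALSE), paired = TRUE),
               "pair_id")
})

test_that("null data give both DE tests a type-I error near the nominal rate", {
  ds <- generate_expression(synthetic_spec(n_genes = 1000, seed = 421))
  st <- gene_stats(ds, paired = TRUE)
  expect_gt(mean(st$p_value < 0.05), 0.03)
  expect_lt(mean(st$p_value < 0.05), 0.07)
  dsu <- generate_expression(synthetic_spec(n_genes = 1000, n_samples_pre = 50,
                                            n_samples_post = 50, paired = FALSE,
                                            seed = 422))
  stu <- gene_stats(dsu, paired = FALSE)
  expect_gt(mean(stu$p_value < 0.05), 0.03)
  expect_lt(mean(stu$p_value < 0.05), 0.07)
})

test_that("the gene-list overlap test matches exact enumeration", {
  ov <- overlap_test(letters[1:5], letters[1:5], 10)
  expect_equal(ov$overlap, 5L)
  expect_equal(ov$p_value, 1 / choose(10, 5))
  # disjoint sets in a large universe
  ov2 <- overlap_test(letters[1:3], letters[10:12], 500)
  expect_equal(ov2$overlap, 0L)
  expect_equal(ov2$p_value, 1)
  expect_error(overlap_test(letters[1:5], letters[1:3], 4), "universe")
  withr::with_seed(11, {
    universe <- paste0("u", 1:15)
    for (i in 1:10) {
      a <- sample(universe, sample(2:8, 1))
      b <- sample(universe, sample(2:8, 1))
      k <- length(intersect(a, b))
      expect_equal(overlap_test(a, b, 15)$p_value,
                   hyper_tail_oracle(k, length(a), 15, length(b)))
    }
  })
})
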