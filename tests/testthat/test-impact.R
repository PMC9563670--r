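mk_chain <- function(genes, signs) {
  list(labels = genes, genes = as.list(genes),
       kinds = rep("simple", length(genes)), signs = as.integer(signs))
}

mk_stats <- function(genes, delta_e, chi2, is_de = TRUE) {
  data.frame(gene = genes, delta_e = delta_e, chi2 = chi2,
             p_value = NA_real_, is_de = is_de,
             direction = ifelse(delta_e > 0, "up",
                                ifelse(delta_e < 0, "down", "none")),
             stringsAsFactors = FALSE)
}

test_that("perturbation factors follow the chain recursion", {
  # single node: PF is its own evidence
  expect_equal(perturbation_factors(mk_chain("g1", integer()),
                                    mk_stats("g1", 1, 4)),
               4)
  st <- mk_stats(c("g1", "g2"), c(1, 0.5), c(4, 2))
  expect_equal(perturbation_factors(mk_chain(c("g1", "g2"), 1L), st),
               c(4, 5))
  # an inhibition step subtracts the upstream factor
  expect_equal(perturbation_factors(mk_chain(c("g1", "g2"), -1L), st),
               c(4, -3))
})

test_that("a gene without expression data contributes zero to its own term", {
  st <- mk_stats("g1", 2, 3)
  pf <- perturbation_factors(mk_chain(c("g1", "missing", "g1b"), c(1L, 1L)), st)
  expect_equal(pf, c(6, 6, 6))  # middle node only relays the upstream signal
})

test_that("terminal PF of an all-activation chain telescopes to the sum", {
  withr::with_seed(5, {
    for (len in 1:10) {
      genes <- paste0("x", seq_len(len))
      st <- mk_stats(genes, stats::rnorm(len), stats::rchisq(len, 1))
      pf <- perturbation_factors(mk_chain(genes, rep(1L, len - 1)), st)
      expect_equal(pf[len], sum(st$delta_e * st$chi2))
    }
  })
})

test_that("negating every fold change negates every perturbation factor", {
  withr::with_seed(6, {
    for (i in 1:10) {
      len <- sample(2:10, 1)
      genes <- paste0("x", seq_len(len))
      de <- stats::rnorm(len); x2 <- stats::rchisq(len, 1)
      signs <- sample(c(-1L, 1L), len - 1, replace = TRUE)
      pf_pos <- perturbation_factors(mk_chain(genes, signs), mk_stats(genes, de, x2))
      pf_neg <- perturbation_factors(mk_chain(genes, signs), mk_stats(genes, -de, x2))
      expect_equal(pf_neg, -pf_pos)
    }
  })
})

test_that("merged binding nodes use the strongest member, loops the mean", {
  st <- mk_stats(c("a", "b"), c(0.2, 2), c(1, 5))
  bind_chain <- list(labels = "a+b", genes = list(c("a", "b")),
                     kinds = "merged_binding", signs = integer())
  expect_equal(perturbation_factors(bind_chain, st), 10)      # max |dE*chi2|
  expect_equal(perturbation_factors(bind_chain, st, binding_agg = "mean"),
               mean(c(0.2, 2)) * mean(c(1, 5)))
  loop_chain <- list(labels = "a+b", genes = list(c("a", "b")),
                     kinds = "condensed_loop", signs = integer())
  expect_equal(perturbation_factors(loop_chain, st),
               mean(c(0.2, 2)) * mean(c(1, 5)))
})

test_that("the impact factor combines enrichment and normalized perturbation", {
  expect_equal(impact_factor(c(4, 5), exp(-1), n_de = 2,
                             mean_abs_delta_e = 0.75),
               7)
  expect_equal(impact_factor(numeric(), 1, 0, 0), 0)
  # doubling |PF| doubles the perturbation term
  base <- impact_factor(c(4, 5), 1, 2, 0.75)
  expect_equal(impact_factor(c(8, 10), 1, 2, 0.75), 2 * base)
  # degenerate guard: no DE genes drop the second term
  expect_equal(impact_factor(c(100, 50), exp(-2), 0, 0), 2)
  expect_error(impact_factor(1, 0, 1, 1), "0, 1")
  expect_error(impact_factor(1, 1.2, 1, 1), "0, 1")
})

test_that("impact factors are always nonnegative", {
  withr::with_seed(8, {
    for (i in 1:50) {
      pf <- stats::rnorm(sample(1:6, 1), sd = 10)
      p <- stats::runif(1)
      nde <- sample(0:3, 1)
      expect_gte(impact_factor(pf, p, nde, abs(stats::rnorm(1))), 0)
    }
  })
})

test_that("permuted label streams are reproducible and structure-preserving", {
  samples <- generate_expression(synthetic_spec(n_genes = 5, seed = 2))$samples
  a <- permute_labels(samples, paired = TRUE, n_permutations = 5, seed = 9)
  b <- permute_labels(samples, paired = TRUE, n_permutations = 5, seed = 9)
  expect_identical(a, b)
  for (perm in a) {
    by_pair <- split(perm$condition, perm$pair_id)
    expect_true(all(vapply(by_pair, function(x) setequal(x, c("pre", "post")),
                           logical(1))))
  }
  u <- permute_labels(samples, paired = FALSE, n_permutations = 5, seed = 10)
  for (perm in u) {
    expect_equal(table(perm$condition), table(samples$condition))
  }
  expect_error(permute_labels(samples, n_permutations = 0), ">= 1")
})

test_that("empirical p-values follow the add-one tail rule", {
  null <- c(1, 2, 3, 4, 5)
  expect_equal(empirical_pvalue(10, null), 1 / 6)
  expect_equal(empirical_pvalue(1, null), 1)      # every null score >= obs
  expect_equal(empirical_pvalue(3.5, null), 3 / 6)
  withr::with_seed(12, {
    null <- stats::rnorm(999)
    expect_equal(empirical_pvalue(stats::median(null), null), 0.5,
                 tolerance = 0.01)
  })
  expect_error(empirical_pvalue(1, numeric()), "empty")
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(0.03, 4)), rep(0.03, 4))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("two-cohort subpathway overlap applies both filters", {
  base <- data.frame(
    pathway_id = "p", chain = c("A>B", "C>D", "E>F"), length = 2L,
    impact_factor = c(5, 4, 3), terminal_pf = c(2, -1, 2),
    n_de = 1L, mean_abs_delta_e = 1, p_path = 0.5, top_gene = "A",
    direction = "up", stringsAsFactors = FALSE
  )
  a <- base; a$empirical_p <- c(0.01, 0.01, 0.20); a$fdr_q <- a$empirical_p * 2
  b <- base; b$empirical_p <- c(0.02, 0.01, 0.01); b$fdr_q <- b$empirical_p * 2
  ov <- overlap_subpathways(a, b)
  # A>B significant in both with positive signal; C>D is downregulated;
  # E>F significant in b only
  expect_equal(ov$subpathways$chain, "A>B")
  expect_equal(ov$summary$n_overlap, 1L)
  b2 <- b; b2$chain[3] <- "X>Y"
  expect_error(overlap_subpathways(a, b2), "universes")
})
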