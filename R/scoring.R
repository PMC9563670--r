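#' Full subpathway impact analysis of one cohort
#'
#' Runs the complete scoring pipeline on a dataset and a set of pathway
#' graphs: enumerate chains, compute per-gene statistics, score every chain's
#' impact factor, then build a length-stratified permutation null by
#' re-labelling the samples and recomputing all statistics (fold changes,
#' presence tests and enrichment included) on every permuted dataset.
#' Empirical p-values compare each observed impact factor with the pooled
#' null scores of chains of identical length, and are adjusted by
#' Benjamini-Hochberg.
#'
#' @param ds A [detection_dataset()].
#' @param graphs List of [pathway_graph()] objects.
#' @param paired Paired (McNemar) or unpaired (chi-square) presence testing.
#' @param n_permutations Number of label permutations forming the null
#'   (default 10; larger values give finer p-value resolution).
#' @param seed Integer seed for the permutation stream.
#' @param config [enumeration_config()] for chain extraction.
#' @param p_threshold Per-gene DE significance threshold.
#' @param de_direction DE genes feeding the enrichment term (`"all"`, `"up"`,
#'   `"down"`).
#' @param binding_agg Member summary for merged binding nodes, see
#'   [perturbation_factors()].
#' @return Data frame as from [score_subpathways()] with extra columns
#'   `empirical_p` and `fdr_q`. The permutation null is attached as attribute
#'   `"null"` (list of score vectors keyed by chain length).
#' @export
subpathway_impact <- function(ds, graphs, paired = TRUE,
                              n_permutations = 10L, seed = 1L,
                              config = enumeration_config(),
                              p_threshold = 0.05,
                              de_direction = "all",
                              binding_agg = "max") {
  if (inherits(graphs, "pathway_graph")) graphs <- list(graphs)
  subpath_sets <- lapply(graphs, enumerate_subpathways, config = config)
  stats <- gene_stats(ds, paired = paired, p_threshold = p_threshold)
  observed <- score_subpathways(subpath_sets, stats, graphs,
                                de_direction = de_direction,
                                binding_agg = binding_agg)

  perms <- permute_labels(ds$samples, paired = paired,
                          n_permutations = n_permutations, seed = seed)
  null_by_len <- list()
  for (perm in perms) {
    pstats <- gene_stats(ds, paired = paired, p_threshold = p_threshold,
                         samples = perm)
    pscore <- score_subpathways(subpath_sets, pstats, graphs,
                                de_direction = de_direction,
                                binding_agg = binding_agg)
    for (L in unique(pscore$length)) {
      key <- as.character(L)
      null_by_len[[key]] <- c(null_by_len[[key]],
                              pscore$impact_factor[pscore$length == L])
    }
  }

  observed$empirical_p <- NA_real_
  for (L in unique(observed$length)) {
    null <- null_by_len[[as.character(L)]]
    sel <- observed$length == L
    observed$empirical_p[sel] <- empirical_pvalue(observed$impact_factor[sel],
                                                  null)
  }
  observed$fdr_q <- fdr_adjust(observed$empirical_p)
  attr(observed, "null") <- null_by_len
  observed
}

#' Overlap of significant upregulated subpathways between two cohorts
#'
#' A chain is retained when its empirical p-value falls below `alpha` in both
#' cohorts and its propagated signal is upregulated in both (positive terminal
#' perturbation factor, i.e. the chain's output node carries a positive
#' signal). Both score tables must cover the same subpathway universe.
#'
#' @param scores_a,scores_b Results of [subpathway_impact()] on the two
#'   cohorts.
#' @param alpha Per-cohort significance threshold (default 0.05).
#' @return List with `subpathways` (retained chains with both cohorts'
#'   statistics and a combined `fdr_overlap = max(fdr_q_a, fdr_q_b)`) and
#'   `summary` (per-pathway counts of significant chains in each cohort, the
#'   overlap count, the mean combined FDR over retained chains and the top
#'   perturbation-factor gene labels).
#' @export
overlap_subpathways <- function(scores_a, scores_b, alpha = 0.05) {
  key_a <- paste(scores_a$pathway_id, scores_a$chain)
  key_b <- paste(scores_b$pathway_id, scores_b$chain)
  if (!setequal(key_a, key_b)) {
    stop("cohorts were scored on different subpathway universes", call. = FALSE)
  }
  scores_b <- scores_b[match(key_a, key_b), , drop = FALSE]
  keep <- scores_a$empirical_p < alpha & scores_b$empirical_p < alpha &
    scores_a$terminal_pf > 0 & scores_b$terminal_pf > 0

  sub <- data.frame(
    pathway_id = scores_a$pathway_id[keep],
    chain = scores_a$chain[keep],
    length = scores_a$length[keep],
    impact_factor_a = scores_a$impact_factor[keep],
    impact_factor_b = scores_b$impact_factor[keep],
    empirical_p_a = scores_a$empirical_p[keep],
    empirical_p_b = scores_b$empirical_p[keep],
    fdr_overlap = pmax(scores_a$fdr_q[keep], scores_b$fdr_q[keep]),
    top_gene_a = scores_a$top_gene[keep],
    top_gene_b = scores_b$top_gene[keep],
    stringsAsFactors = FALSE
  )

  pids <- sort(unique(scores_a$pathway_id))
  summary <- do.call(rbind, lapply(pids, function(pid) {
    ia <- scores_a$pathway_id == pid
    ib <- scores_b$pathway_id == pid
    io <- sub$pathway_id == pid
    data.frame(
      pathway_id = pid,
      n_subpathways = sum(ia),
      n_sig_a = sum(scores_a$empirical_p[ia] < alpha),
      n_sig_b = sum(scores_b$empirical_p[ib] < alpha),
      n_overlap = sum(io),
      fdr_overlap = if (any(io)) mean(sub$fdr_overlap[io]) else NA_real_,
      top_genes = paste(unique(sub$top_gene_a[io]), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summary) <- NULL
  list(subpathways = sub, summary = summary)
}
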