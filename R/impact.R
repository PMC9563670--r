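# Resolve per-node delta_e and chi2 from per-gene statistics.
# A simple node uses its gene's statistics; a merged binding node is
# represented by the member with the strongest own perturbation |delta_e*chi2|
# (optionally the member mean); a condensed loop node, being conjunctive,
# takes the mean over its members. Genes without data contribute 0.
node_stat <- function(genes, kind, idx, binding_agg = c("max", "mean")) {
  binding_agg <- match.arg(binding_agg)
  de <- idx$delta_e[genes]
  x2 <- idx$chi2[genes]
  de[is.na(de)] <- 0
  x2[is.na(x2)] <- 0
  if (length(genes) == 1L || kind == "simple") {
    return(c(delta_e = unname(de[1]), chi2 = unname(x2[1])))
  }
  if (kind == "condensed_loop" || (kind == "merged_binding" && binding_agg == "mean")) {
    return(c(delta_e = mean(de), chi2 = mean(x2)))
  }
  i <- which.max(abs(de * x2))
  c(delta_e = unname(de[i]), chi2 = unname(x2[i]))
}

stats_index <- function(stats) {
  list(delta_e = stats::setNames(stats$delta_e, stats$gene),
       chi2 = stats::setNames(stats$chi2, stats$gene),
       is_de = stats::setNames(stats$is_de, stats$gene))
}

#' Perturbation factors along a single-chain subpathway
#'
#' Propagates the perturbation signal along the chain: the entry node's
#' perturbation factor is its own evidence `delta_e * chi2`, and every
#' downstream node adds the upstream factor weighted by the step sign
#' (`+1` induction, `-1` inhibition):
#' `PF(g) = delta_e(g) * chi2(g) + beta * PF(upstream)`.
#' In a single chain each node has exactly one upstream, so for an
#' all-induction chain the terminal factor telescopes to
#' `sum_i delta_e_i * chi2_i`.
#'
#' @param subpathway One chain from a `subpathway_set` (list with `labels`,
#'   `genes`, `kinds`, `signs`).
#' @param stats Per-gene statistics from [gene_stats()], or a prebuilt index
#'   from the internal `stats_index()`.
#' @param binding_agg How a merged binding node summarizes member statistics:
#'   `"max"` keeps the member with largest `|delta_e * chi2|`, `"mean"`
#'   averages. Condensed loop nodes always average (conjunctive semantics).
#' @return Numeric vector of perturbation factors, one per chain node.
#' @examples
#' sp <- list(labels = c("g1", "g2"), genes = list("g1", "g2"),
#'            kinds = c("simple", "simple"), signs = 1L)
#' st <- data.frame(gene = c("g1", "g2"), delta_e = c(1, 0.5),
#'                  chi2 = c(4, 2), is_de = TRUE)
#' perturbation_factors(sp, st)  # c(4, 5)
#' @export
perturbation_factors <- function(subpathway, stats, binding_agg = "max") {
  idx <- if (is.data.frame(stats)) stats_index(stats) else stats
  n <- length(subpathway$labels)
  stopifnot(n >= 1L, length(subpathway$signs) == n - 1L)
  pf <- numeric(n)
  for (i in seq_len(n)) {
    ns <- node_stat(subpathway$genes[[i]], subpathway$kinds[i], idx,
                    binding_agg = binding_agg)
    own <- ns[["delta_e"]] * ns[["chi2"]]
    pf[i] <- if (i == 1L) own else own + subpathway$signs[i - 1L] * pf[i - 1L]
  }
  pf
}

#' Impact factor of a subpathway
#'
#' Combines the pathway-level enrichment evidence with the accumulated
#' perturbation along the chain:
#' `IF = log(1 / P_path) + sum(|PF|) / (mean|delta_e over DE genes| * N_de)`,
#' with the natural log. `N_de` is the number of differentially expressed
#' genes among the chain's member genes and the mean absolute log fold change
#' is taken over those same genes. When the chain holds no DE gene (or their
#' mean |delta_e| is zero) the perturbation term is defined as 0, so the score
#' stays finite and nonnegative.
#'
#' @param pf Perturbation factors from [perturbation_factors()].
#' @param p_path Pathway enrichment probability in `(0, 1]`, see
#'   [hypergeom_enrich()].
#' @param n_de Number of DE genes in the chain.
#' @param mean_abs_delta_e Mean `|delta_e|` over those DE genes.
#' @return Nonnegative impact factor.
#' @examples
#' impact_factor(c(4, 5), exp(-1), n_de = 2, mean_abs_delta_e = 0.75)  # 7
#' @export
impact_factor <- function(pf, p_path, n_de, mean_abs_delta_e) {
  if (p_path <= 0 || p_path > 1) {
    stop("p_path must lie in (0, 1]", call. = FALSE)
  }
  evidence <- log(1 / p_path)
  perturb <- if (n_de == 0 || mean_abs_delta_e == 0) 0 else {
    sum(abs(pf)) / (mean_abs_delta_e * n_de)
  }
  evidence + perturb
}

# DE summary of a chain: count of DE member genes and their mean |delta_e|
chain_de_summary <- function(subpathway, idx) {
  genes <- unique(unlist(subpathway$genes, use.names = FALSE))
  de <- idx$is_de[genes]
  de <- names(de)[!is.na(de) & de]
  if (!length(de)) return(list(n_de = 0L, mean_abs_delta_e = 0))
  list(n_de = length(de), mean_abs_delta_e = mean(abs(idx$delta_e[de])))
}

#' Score every subpathway of one or more pathways against gene statistics
#'
#' Computes perturbation factors and the impact factor for each chain. The
#' pathway enrichment probability is computed from the supplied DE gene list
#' over the given universe.
#'
#' @param subpath_sets A `subpathway_set` or list of them (one per pathway).
#' @param stats Per-gene statistics from [gene_stats()].
#' @param graphs List of the corresponding [pathway_graph()] objects (used for
#'   pathway membership in the enrichment term); must cover every
#'   `pathway_id` in `subpath_sets`.
#' @param universe Gene universe for enrichment; defaults to the genes shared
#'   between `stats` and the pathways.
#' @param de_direction Which DE genes feed the enrichment term: `"all"`
#'   (default), `"up"` or `"down"`.
#' @param binding_agg Passed to [perturbation_factors()].
#' @return Data frame with one row per subpathway: `pathway_id`, `chain`,
#'   `length`, `impact_factor`, `terminal_pf`, `direction`, `n_de`,
#'   `mean_abs_delta_e`, `p_path`, `top_gene` (chain node with largest |PF|).
#' @export
score_subpathways <- function(subpath_sets, stats, graphs,
                              universe = NULL, de_direction = c("all", "up", "down"),
                              binding_agg = "max") {
  de_direction <- match.arg(de_direction)
  if (inherits(subpath_sets, "subpathway_set")) subpath_sets <- list(subpath_sets)
  path_genes <- lapply(graphs, pathway_genes)
  names(path_genes) <- vapply(graphs, `[[`, character(1), "pathway_id")
  if (is.null(universe)) {
    universe <- intersect(stats$gene,
                          unique(unlist(path_genes, use.names = FALSE)))
  }
  de <- stats$gene[stats$is_de]
  if (de_direction == "up") de <- intersect(de, stats$gene[stats$delta_e > 0])
  if (de_direction == "down") de <- intersect(de, stats$gene[stats$delta_e < 0])
  idx <- stats_index(stats)

  rows <- list()
  for (ss in subpath_sets) {
    pid <- ss$pathway_id
    if (!pid %in% names(path_genes)) {
      stop("no pathway graph supplied for ", pid, call. = FALSE)
    }
    p_path <- hypergeom_enrich(de, path_genes[[pid]], universe)$p_value
    for (sp in ss$subpaths) {
      pf <- perturbation_factors(sp, idx, binding_agg = binding_agg)
      des <- chain_de_summary(sp, idx)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_id = pid,
        chain = paste(sp$labels, collapse = ">"),
        length = length(sp$labels),
        impact_factor = impact_factor(pf, p_path, des$n_de,
                                      des$mean_abs_delta_e),
        terminal_pf = pf[length(pf)],
        direction = if (pf[length(pf)] > 0) "up" else if (pf[length(pf)] < 0) "down" else "none",
        n_de = des$n_de,
        mean_abs_delta_e = des$mean_abs_delta_e,
        p_path = p_path,
        top_gene = sp$labels[which.max(abs(pf))],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(pathway_id = character(), chain = character(),
               length = integer(), impact_factor = numeric(),
               terminal_pf = numeric(), direction = character(),
               n_de = integer(), mean_abs_delta_e = numeric(),
               p_path = numeric(), top_gene = character(),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
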