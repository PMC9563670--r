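#' Hypergeometric pathway enrichment
#'
#' Tests whether a pathway contains more differentially expressed genes than
#' expected by chance, using the upper-tail hypergeometric probability
#' `P(X >= k)` with universe size `N`, pathway size `K`, draw size
#' `n = |de_genes|` and observed overlap `k`. The tail includes the observed
#' count, so `k = 0` gives p = 1. This probability also enters the impact
#' factor as its pathway-evidence term.
#'
#' @param de_genes Character vector of differentially expressed genes
#'   (restricted to the universe).
#' @param pathway_genes Character vector of pathway member genes
#'   (restricted to the universe).
#' @param universe Character vector of all genes eligible for testing
#'   (typically the genes shared between the expression platform and the
#'   loaded pathways).
#' @return List of class `enrichment_result` with `pathway_id` (`NA` unless
#'   set by the caller), `n_pathway_genes`, `n_de_in_pathway`, `n_de`,
#'   `n_universe` and `p_value`.
#' @examples
#' hypergeom_enrich(letters[1:5], letters[1:5], letters[1:10])$p_value # 1/252
#' @export
hypergeom_enrich <- function(de_genes, pathway_genes, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  de_genes <- intersect(unique(de_genes), universe)
  pathway_genes <- intersect(unique(pathway_genes), universe)
  N <- length(universe)
  K <- length(pathway_genes)
  n <- length(de_genes)
  k <- length(intersect(de_genes, pathway_genes))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(
    list(pathway_id = NA_character_, n_pathway_genes = K,
         n_de_in_pathway = k, n_de = n, n_universe = N, p_value = p),
    class = "enrichment_result"
  )
}

#' Two-cohort enrichment report
#'
#' Mirrors the overlap-style pathway report: a pathway is retained when its
#' enrichment p-value falls below the threshold in both cohorts, and rows are
#' ordered by combined significance (product of the two p-values).
#'
#' @param results_a,results_b Data frames with columns `pathway_id`,
#'   `n_pathway_genes`, `n_de_in_pathway`, `p_value`, one row per pathway;
#'   both cohorts must cover the same pathways.
#' @param threshold Per-cohort significance threshold (default 0.05).
#' @return Data frame with per-cohort DE counts and p-values for the retained
#'   pathways.
#' @export
enrichment_report <- function(results_a, results_b, threshold = 0.05) {
  results_a <- as.data.frame(results_a, stringsAsFactors = FALSE)
  results_b <- as.data.frame(results_b, stringsAsFactors = FALSE)
  if (!setequal(results_a$pathway_id, results_b$pathway_id)) {
    stop("cohorts tested different pathway sets", call. = FALSE)
  }
  results_b <- results_b[match(results_a$pathway_id, results_b$pathway_id), ,
                         drop = FALSE]
  keep <- results_a$p_value < threshold & results_b$p_value < threshold
  out <- data.frame(
    pathway_id = results_a$pathway_id[keep],
    n_pathway_genes = results_a$n_pathway_genes[keep],
    n_de_a = results_a$n_de_in_pathway[keep],
    n_de_b = results_b$n_de_in_pathway[keep],
    p_value_a = results_a$p_value[keep],
    p_value_b = results_b$p_value[keep],
    stringsAsFactors = FALSE
  )
  out[order(out$p_value_a * out$p_value_b, out$pathway_id), , drop = FALSE]
}

#' Enrichment over a list of pathway graphs
#'
#' Convenience wrapper running [hypergeom_enrich()] for each pathway graph
#' against a common universe.
#'
#' @param de_genes Character vector of DE genes.
#' @param graphs List of [pathway_graph()] objects.
#' @param universe Gene universe; defaults to the union of all pathway genes.
#' @return Data frame with one row per pathway.
#' @export
enrich_pathways <- function(de_genes, graphs, universe = NULL) {
  if (is.null(universe)) {
    universe <- sort(unique(unlist(lapply(graphs, pathway_genes))))
  }
  rows <- lapply(graphs, function(g) {
    r <- hypergeom_enrich(de_genes, pathway_genes(g), universe)
    data.frame(pathway_id = g$pathway_id,
               n_pathway_genes = r$n_pathway_genes,
               n_de_in_pathway = r$n_de_in_pathway,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
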