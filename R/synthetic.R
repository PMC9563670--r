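#' Generate a random KGML pathway with controlled motifs
#'
#' Builds a connected directed pathway whose topology contains a requested
#' number of binding events (two genes in parallel joined by a
#' binding/association relation) and feedback loops (a three-gene directed
#' cycle), embedded between an entry gene and an end gene. Remaining genes
#' form simple chain positions, with optional extra forward shortcut edges.
#' The document is valid KGML parseable by [parse_kgml()] and is byte-
#' identical across runs with the same arguments.
#'
#' @param n_nodes Total number of gene nodes (needs at least
#'   `2 + 2 * n_bindings + 3 * n_loops`).
#' @param edge_prob Probability of an extra forward edge between simple chain
#'   positions.
#' @param n_bindings Number of binding events.
#' @param n_loops Number of three-gene feedback loops.
#' @param inhibition_frac Fraction of directed relations drawn as inhibition
#'   rather than activation.
#' @param seed Integer seed.
#' @param pathway_id Pathway identifier; defaults to `synthetic_<seed>`.
#' @param gene_prefix Prefix for generated gene symbols (`G1`, `G2`, ...).
#' @return KGML XML text.
#' @examples
#' parse_kgml(generate_pathway(4, n_bindings = 1, seed = 1))
#' @export
generate_pathway <- function(n_nodes, edge_prob = 0.15, n_bindings = 0L,
                             n_loops = 0L, inhibition_frac = 0.2, seed = 1L,
                             pathway_id = NULL,
                             gene_prefix = "G") {
  n_simple <- n_nodes - 2L * n_bindings - 3L * n_loops
  if (n_simple < 2L) {
    stop("infeasible motif request: need at least ",
         2L + 2L * n_bindings + 3L * n_loops, " nodes", call. = FALSE)
  }
  if (is.null(pathway_id)) pathway_id <- paste0("synthetic_", seed)

  with_seed(seed, {
    # slot layout: entry, shuffled middle motifs, end
    middle <- c(rep("binding", n_bindings), rep("loop", n_loops),
                rep("simple", n_simple - 2L))
    if (length(middle) > 1L) middle <- sample(middle)
    slots <- c("simple", middle, "simple")

    gene_i <- 0L
    next_gene <- function() {
      gene_i <<- gene_i + 1L
      paste0(gene_prefix, gene_i)
    }
    slot_nodes <- lapply(slots, function(kind) {
      switch(kind,
             simple = next_gene(),
             binding = c(next_gene(), next_gene()),
             loop = c(next_gene(), next_gene(), next_gene()))
    })

    ef <- character(); et <- character(); esub <- character()
    draw_subtype <- function() {
      if (stats::runif(1) < inhibition_frac) "inhibition" else "activation"
    }
    add <- function(from, to, subtype) {
      ef <<- c(ef, from); et <<- c(et, to); esub <<- c(esub, subtype)
    }

    for (i in seq_along(slots)) {
      kind <- slots[i]
      nodes <- slot_nodes[[i]]
      if (kind == "binding") add(nodes[1], nodes[2], "binding/association")
      if (kind == "loop") {
        add(nodes[1], nodes[2], draw_subtype())
        add(nodes[2], nodes[3], draw_subtype())
        add(nodes[3], nodes[1], draw_subtype())
      }
      if (i > 1L) {
        prev <- slot_nodes[[i - 1L]]
        exits <- switch(slots[i - 1L], simple = prev, binding = prev,
                        loop = prev[length(prev)])
        entries <- switch(kind, simple = nodes, binding = nodes,
                          loop = nodes[1])
        for (a in exits) for (b in entries) add(a, b, draw_subtype())
      }
    }

    # extra forward shortcuts between non-adjacent simple slots
    simple_idx <- which(slots == "simple")
    for (a in simple_idx) for (b in simple_idx) {
      if (b > a + 1L && stats::runif(1) < edge_prob) {
        add(slot_nodes[[a]], slot_nodes[[b]], draw_subtype())
      }
    }

    all_genes <- unlist(slot_nodes, use.names = FALSE)
    sign_tab <- kegg_relation_signs()
    g <- pathway_graph(
      pathway_id,
      nodes = data.frame(id = all_genes, genes = all_genes,
                         kind = "simple", stringsAsFactors = FALSE),
      edges = data.frame(from = ef, to = et,
                         sign = as.integer(sign_tab[esub]),
                         subtype = esub, stringsAsFactors = FALSE)
    )
    write_kgml(g)
  })
}

#' Pathway of disjoint parallel chains
#'
#' Builds a pathway graph consisting of `n_chains` gene chains of identical
#' length running in parallel from separate entry nodes to separate end nodes,
#' with no shared genes. This layout gives a length stratum with many mutually
#' independent chains and is the backbone of the planted-signal and
#' calibration benchmarks.
#'
#' @param n_chains Number of parallel chains.
#' @param chain_length Number of genes per chain.
#' @param pathway_id Pathway identifier.
#' @param gene_prefix Prefix for generated gene symbols.
#' @return A [pathway_graph()]; chain `i` holds genes
#'   `<prefix><i>.1 ... <prefix><i>.<chain_length>` connected by activation.
#' @export
parallel_chain_pathway <- function(n_chains, chain_length,
                                   pathway_id = "parallel",
                                   gene_prefix = "C") {
  stopifnot(n_chains >= 1L, chain_length >= 1L)
  nodes <- character(); ef <- character(); et <- character()
  for (i in seq_len(n_chains)) {
    chain <- paste0(gene_prefix, i, ".", seq_len(chain_length))
    nodes <- c(nodes, chain)
    if (chain_length > 1L) {
      ef <- c(ef, chain[-chain_length])
      et <- c(et, chain[-1L])
    }
  }
  pathway_graph(
    pathway_id,
    nodes = data.frame(id = nodes, genes = nodes, kind = "simple",
                       stringsAsFactors = FALSE),
    edges = data.frame(from = ef, to = et, sign = 1L,
                       subtype = "activation", stringsAsFactors = FALSE)
  )
}

#' Planted-signal benchmark layout
#'
#' Standard two-pathway benchmark for recovery experiments: a target pathway
#' of `n_target_chains` parallel chains of `target_length` genes, the first
#' of which carries the planted activation, plus a decoy pathway of
#' `n_decoy_chains` chains of `decoy_length` genes with no signal. The target
#' pathway becomes genuinely enriched once the planted genes are
#' differentially expressed, so the benchmark exercises both terms of the
#' impact factor; the planted chain's length stratum contains its sibling
#' chains as competitors.
#'
#' @param n_target_chains,target_length Layout of the target pathway.
#' @param n_decoy_chains,decoy_length Layout of the decoy pathway.
#' @return List with `graphs` (two [pathway_graph()]s), `planted_chain`
#'   (gene symbols) and `planted_label` (the chain string as reported by
#'   [score_subpathways()]).
#' @export
planted_benchmark <- function(n_target_chains = 5L, target_length = 4L,
                              n_decoy_chains = 15L, decoy_length = 5L) {
  target <- parallel_chain_pathway(n_target_chains, target_length,
                                   pathway_id = "target", gene_prefix = "T")
  decoy <- parallel_chain_pathway(n_decoy_chains, decoy_length,
                                  pathway_id = "decoy", gene_prefix = "D")
  planted <- paste0("T1.", seq_len(target_length))
  list(graphs = list(target, decoy),
       planted_chain = planted,
       planted_label = paste(planted, collapse = ">"))
}

#' Null-calibration benchmark layout
#'
#' Pathway collection used to check that empirical subpathway p-values are
#' calibrated under the null: 20 pathways of parallel chains covering four
#' length strata (16 to 19 genes) with five distinct chain counts (8 to 12)
#' per stratum — 200 chains over 3500 genes. Distinct pathway sizes keep the
#' hypergeometric enrichment term from tying across pathways, and large
#' pathways make a zero-enrichment floor (impact factor exactly 0) rare, so
#' the score distribution is close to continuous and a uniformity test of the
#' p-values is meaningful.
#'
#' @return List of [pathway_graph()] objects.
#' @export
calibration_benchmark <- function() {
  lens <- rep(16:19, each = 5)
  cnts <- rep(c(8L, 9L, 10L, 11L, 12L), times = 4)
  Map(function(l, m, i) {
    parallel_chain_pathway(m, l, pathway_id = paste0("cal", i),
                           gene_prefix = paste0("K", i, "x"))
  }, lens, cnts, seq_along(lens))
}

#' Parameters of the planted-signal expression generator
#'
#' Describes a two-condition (pre/post treatment) microarray-style dataset
#' with an optional activated chain planted into the post-treatment samples.
#' The defaults emulate the paired study design the scoring method targets:
#' 40 patient pairs, a strong planted effect (log2 fold change 1.5 and a 0.4
#' increase in the presence-call probability after treatment) over a moderate
#' baseline presence of 0.5.
#'
#' @param n_genes Total number of genes (background genes are added beyond the
#'   planted and pathway genes).
#' @param n_samples_pre,n_samples_post Samples per condition; in paired mode
#'   both must equal the number of pairs.
#' @param paired Paired design (per-patient pre/post samples)?
#' @param planted_chain Gene symbols carrying the planted activation.
#' @param delta_e_effect Log2 expression effect added to planted genes after
#'   treatment.
#' @param presence_shift Increase in presence-call probability of planted
#'   genes after treatment.
#' @param baseline_presence Presence-call probability of any gene otherwise.
#' @param noise_sd Standard deviation of log2 expression noise.
#' @param seed Integer seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 200L, n_samples_pre = 40L,
                           n_samples_post = 40L, paired = TRUE,
                           planted_chain = character(),
                           delta_e_effect = 1.5, presence_shift = 0.4,
                           baseline_presence = 0.5, noise_sd = 0.5,
                           seed = 1L) {
  stopifnot(baseline_presence >= 0, baseline_presence <= 1,
            presence_shift >= -1, presence_shift <= 1,
            n_genes >= 1L, noise_sd >= 0)
  if (paired && n_samples_pre != n_samples_post) {
    stop("paired design needs equal pre and post sample counts", call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes),
         n_samples_pre = as.integer(n_samples_pre),
         n_samples_post = as.integer(n_samples_post),
         paired = isTRUE(paired),
         planted_chain = as.character(planted_chain),
         delta_e_effect = delta_e_effect,
         presence_shift = presence_shift,
         baseline_presence = baseline_presence,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a two-condition expression dataset with detection calls
#'
#' Simulates a probe-level Affymetrix-style dataset. Presence calls are
#' Bernoulli at `baseline_presence`, shifted up by `presence_shift` for
#' planted genes after treatment. Detection calls and intensities are coupled
#' the way array summarization couples them: a sample where the gene is
#' absent sits at a background intensity `call_gap` log2 units below the
#' gene's signal level, so a presence shift always carries an expression fold
#' change with it. Expression is log-normal: each gene has a baseline log2
#' level, paired designs share a per-patient random intercept between the pre
#' and post sample, and planted genes gain `delta_e_effect` log2 units in
#' present post-treatment samples. A present gene always has at least one
#' probe called `P`, and absent probes are occasionally called `M`
#' (marginal). Two probes per gene are emitted. Sample metadata includes
#' randomly drawn age, race and ER/PR/HER2 status so cohort summaries can be
#' exercised.
#'
#' @param spec A [synthetic_spec()].
#' @param pathway_genes Gene symbols that must exist in the universe (e.g.
#'   all genes of the loaded pathways); planted genes must be among the
#'   universe.
#' @param call_gap Log2 distance between a gene's signal level and its
#'   background (absent-call) intensity.
#' @return A [detection_dataset()] with the generator parameters attached as
#'   attribute `"spec"`.
#' @export
generate_expression <- function(spec, pathway_genes = character(),
                                call_gap = 2.5) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- unique(c(spec$planted_chain, pathway_genes))
  if (length(spec$planted_chain) &&
      !all(spec$planted_chain %in% genes)) {
    stop("planted gene outside the gene universe", call. = FALSE)
  }
  n_bg <- spec$n_genes - length(genes)
  if (n_bg > 0L) genes <- c(genes, sprintf("BG%04d", seq_len(n_bg)))
  genes <- sort(genes)

  n_pre <- spec$n_samples_pre
  n_post <- spec$n_samples_post
  if (spec$paired) {
    pair_id <- sprintf("PT%03d", seq_len(n_pre))
    samples <- data.frame(
      sample_id = c(paste0(pair_id, "_pre"), paste0(pair_id, "_post")),
      condition = rep(c("pre", "post"), each = n_pre),
      pair_id = rep(pair_id, 2L),
      stringsAsFactors = FALSE
    )
  } else {
    samples <- data.frame(
      sample_id = c(sprintf("S%03d_pre", seq_len(n_pre)),
                    sprintf("S%03d_post", seq_len(n_post))),
      condition = rep(c("pre", "post"), c(n_pre, n_post)),
      pair_id = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  n_smp <- nrow(samples)
  is_post <- samples$condition == "post"
  planted <- genes %in% spec$planted_chain

  with_seed(spec$seed, {
    # clinical covariates for cohort summaries
    samples$age <- round(stats::rnorm(n_smp, 55, 8))
    samples$race <- sample(c("white", "non-white"), n_smp, replace = TRUE)
    samples$ER <- sample(c("+", "-"), n_smp, replace = TRUE)
    samples$PR <- sample(c("+", "-"), n_smp, replace = TRUE)
    samples$HER2 <- sample(c("+", "-"), n_smp, replace = TRUE)

    p_present <- matrix(spec$baseline_presence, length(genes), n_smp)
    p_present[planted, is_post] <-
      pmin(1, spec$baseline_presence + spec$presence_shift)
    present <- matrix(stats::runif(length(p_present)) < p_present,
                      length(genes), n_smp)

    mu <- stats::rnorm(length(genes), 7, 1)
    log2e <- matrix(stats::rnorm(length(genes) * n_smp, 0, spec$noise_sd),
                    length(genes), n_smp)
    log2e <- log2e + mu
    if (spec$paired) {
      intercept <- matrix(stats::rnorm(length(genes) * n_pre, 0, 0.7),
                          length(genes), n_pre)
      pair_col <- match(samples$pair_id, unique(samples$pair_id))
      log2e <- log2e + intercept[, pair_col]
    }
    # absent samples sit at background; planted effect acts on expressed
    # post-treatment samples
    log2e[!present] <- log2e[!present] - call_gap
    eff <- matrix(0, length(genes), n_smp)
    eff[planted, is_post] <- spec$delta_e_effect
    log2e <- log2e + eff * present

    # two probes per gene; a present gene has probe 1 called P and probe 2
    # present half the time; absent probes are A with an occasional M
    absent_call <- function(n) {
      ifelse(stats::runif(n) < 0.1, "M", "A")
    }
    probes <- c(rbind(paste0(genes, "_at1"), paste0(genes, "_at2")))
    expr <- matrix(0, length(probes), n_smp,
                   dimnames = list(probes, samples$sample_id))
    calls <- matrix("A", length(probes), n_smp,
                    dimnames = list(probes, samples$sample_id))
    g1 <- seq(1L, by = 2L, length.out = length(genes))
    noise2 <- matrix(stats::rnorm(length(genes) * n_smp, 0, 0.2),
                     length(genes), n_smp)
    expr[g1, ] <- 2^log2e
    expr[g1 + 1L, ] <- 2^(log2e + noise2)
    calls[g1, ] <- ifelse(present, "P", absent_call(length(present)))
    p2 <- present & matrix(stats::runif(length(present)) < 0.5,
                           length(genes), n_smp)
    calls[g1 + 1L, ] <- ifelse(p2, "P", absent_call(length(present)))

    probe_map <- data.frame(probe = probes,
                            gene = rep(genes, each = 2L),
                            stringsAsFactors = FALSE)
    ds <- detection_dataset(expr, calls, probe_map, samples)
    attr(ds, "spec") <- spec
    ds
  })
}
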