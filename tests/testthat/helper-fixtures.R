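# shared fixtures and independent oracles

# diamond with a binding event: A activates B and C, B/C bound, both activate D
fig_binding_graph <- function() {
  pathway_graph(
    "binding_demo",
    nodes = data.frame(id = c("A", "B", "C", "D"),
                       genes = c("A", "B", "C", "D"),
                       kind = "simple", stringsAsFactors = FALSE),
    edges = data.frame(
      from = c("A", "A", "B", "C", "B"),
      to = c("B", "C", "D", "D", "C"),
      sign = 1L,
      subtype = c("activation", "activation", "activation", "activation",
                  "binding/association"),
      stringsAsFactors = FALSE
    )
  )
}

# feedback loop B->C->D->E->B embedded between A and F
fig_loop_graph <- function() {
  pathway_graph(
    "loop_demo",
    nodes = data.frame(id = LETTERS[1:6], genes = LETTERS[1:6],
                       kind = "simple", stringsAsFactors = FALSE),
    edges = data.frame(
      from = c("A", "B", "C", "D", "E", "E"),
      to = c("B", "C", "D", "E", "B", "F"),
      sign = 1L, subtype = "activation", stringsAsFactors = FALSE
    )
  )
}

# random DAG on n nodes: edges only forward in a random node order
random_dag <- function(n, p, seed) {
  withr::with_seed(seed, {
    ord <- sample(LETTERS[seq_len(n)])
    ef <- character(); et <- character()
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (stats::runif(1) < p) {
        ef <- c(ef, ord[i]); et <- c(et, ord[j])
      }
    }
    pathway_graph(
      paste0("dag", seed),
      nodes = data.frame(id = sort(ord), genes = sort(ord), kind = "simple",
                         stringsAsFactors = FALSE),
      edges = data.frame(from = ef, to = et,
                         sign = rep(1L, length(ef)),
                         subtype = rep("activation", length(ef)),
                         stringsAsFactors = FALSE)
    )
  })
}

# random digraph (cycles allowed)
random_digraph <- function(n, p, seed) {
  withr::with_seed(seed, {
    ids <- LETTERS[seq_len(n)]
    ef <- character(); et <- character()
    for (i in ids) for (j in ids) {
      if (i != j && stats::runif(1) < p) {
        ef <- c(ef, i); et <- c(et, j)
      }
    }
    pathway_graph(
      paste0("dig", seed),
      nodes = data.frame(id = ids, genes = ids, kind = "simple",
                         stringsAsFactors = FALSE),
      edges = data.frame(from = ef, to = et,
                         sign = rep(1L, length(ef)),
                         subtype = rep("activation", length(ef)),
                         stringsAsFactors = FALSE)
    )
  })
}

# oracle: all entry-to-end simple paths via igraph, as sorted chain strings
igraph_path_oracle <- function(g) {
  ig <- igraph::graph_from_data_frame(
    g$edges[g$edges$subtype != "binding/association", c("from", "to")],
    directed = TRUE,
    vertices = data.frame(name = g$nodes$id)
  )
  indeg <- igraph::degree(ig, mode = "in")
  outdeg <- igraph::degree(ig, mode = "out")
  entries <- names(indeg)[indeg == 0]
  ends <- names(outdeg)[outdeg == 0]
  out <- character()
  for (s in entries) {
    if (s %in% ends) out <- c(out, s)
    paths <- igraph::all_simple_paths(ig, from = s, to = setdiff(ends, s),
                                      mode = "out")
    out <- c(out, vapply(paths, function(p) paste(names(p), collapse = ">"),
                         character(1)))
  }
  sort(unique(out))
}

# oracle: strongly connected components by mutual reachability
reachability_scc_oracle <- function(g) {
  ids <- g$nodes$id
  n <- length(ids)
  reach <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  diag(reach) <- TRUE
  ed <- g$edges[g$edges$subtype != "binding/association", , drop = FALSE]
  for (k in seq_len(n)) {      # iterate closure to fixpoint
    prev <- reach
    for (e in seq_len(nrow(ed))) {
      reach[, ed$to[e]] <- reach[, ed$to[e]] | reach[, ed$from[e]]
    }
    if (identical(prev, reach)) break
  }
  mutual <- reach & t(reach)
  comps <- unique(apply(mutual, 1, function(r) paste(ids[r], collapse = ",")))
  sort(comps)
}

# oracle: upper-tail hypergeometric by explicit binomial-coefficient sums
hyper_tail_oracle <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# small deterministic detection dataset built by hand
tiny_dataset <- function(paired = TRUE) {
  genes <- c("g1", "g2", "g3")
  n_pairs <- 4L
  samples <- data.frame(
    sample_id = c(paste0("p", 1:n_pairs, "_pre"), paste0("p", 1:n_pairs, "_post")),
    condition = rep(c("pre", "post"), each = n_pairs),
    pair_id = if (paired) rep(paste0("p", 1:n_pairs), 2) else NA_character_,
    stringsAsFactors = FALSE
  )
  probes <- c("g1_a", "g1_b", "g2_a", "g3_a")
  expr <- matrix(2^6, length(probes), nrow(samples),
                 dimnames = list(probes, samples$sample_id))
  expr["g1_a", samples$condition == "post"] <- 2^7
  calls <- matrix("A", length(probes), nrow(samples),
                  dimnames = list(probes, samples$sample_id))
  calls["g1_a", ] <- "P"
  calls["g2_a", samples$condition == "post"] <- "P"
  calls["g3_a", ] <- "M"
  detection_dataset(
    expr, calls,
    probe_map = data.frame(probe = probes,
                           gene = c("g1", "g1", "g2", "g3"),
                           stringsAsFactors = FALSE),
    samples = samples
  )
}
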