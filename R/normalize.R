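#' Condense directed cycles into conjunctive loop nodes
#'
#' A feedback loop such as B -> C -> D -> E -> B is collapsed into a single
#' node carrying all member genes; edges entering or leaving the loop are
#' re-attached to the condensed node. The condensed node is treated as active
#' downstream only when all member genes are active, which is reflected later
#' in scoring by averaging the members' statistics. The result is acyclic in
#' its directed (non-binding) edges.
#'
#' @param g A [pathway_graph()].
#' @return A [pathway_graph()] with every nontrivial strongly connected
#'   component replaced by one `condensed_loop` node and no self-edges.
#' @export
condense_loops <- function(g) {
  validate_pathway_graph(g)
  if (nrow(g$nodes) == 0L) return(g)
  ig <- as_igraph_directed(g)
  comp <- igraph::components(ig, mode = "strong")
  memb <- comp$membership
  genes <- node_genes(g)

  new_id <- g$nodes$id
  names(new_id) <- g$nodes$id
  nodes <- g$nodes
  for (k in seq_len(comp$no)) {
    members <- names(memb)[memb == k]
    if (length(members) < 2L) next
    members <- sort(members)
    cid <- paste0("loop.", paste(members, collapse = "."))
    new_id[members] <- cid
    merged <- data.frame(
      id = cid,
      genes = paste(sort(unique(unlist(genes[members]))), collapse = ";"),
      kind = "condensed_loop",
      stringsAsFactors = FALSE
    )
    nodes <- rbind(nodes[!nodes$id %in% members, , drop = FALSE], merged)
  }

  edges <- g$edges
  if (nrow(edges)) {
    edges$from <- unname(new_id[edges$from])
    edges$to <- unname(new_id[edges$to])
    edges <- edges[edges$from != edges$to, , drop = FALSE]
    edges <- edges[order(edges$from, edges$to, edges$subtype, edges$sign), ,
                   drop = FALSE]
    edges <- edges[!duplicated(edges[, c("from", "to", "subtype")]), ,
                   drop = FALSE]
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  pathway_graph(g$pathway_id, nodes, edges)
}

#' Expand binding events into alternative graph variants
#'
#' A binding/association event between genes B and C means the bound position
#' in a chain can be occupied by B alone, by C alone, or by the complex B+C
#' (the chain is active if at least one member is present). For each maximal
#' connected set of nodes linked by binding edges, one variant is produced per
#' single member plus one variant with all members merged into a
#' `merged_binding` node; independent binding events combine multiplicatively.
#'
#' @param g An acyclic [pathway_graph()] (run [condense_loops()] first).
#' @param cap Maximum number of variants to return; enumeration order is
#'   deterministic (lexicographic in the choice per binding component) and the
#'   tail is dropped with a warning when the product exceeds `cap`.
#' @return List of [pathway_graph()] variants without binding edges. A graph
#'   with no binding edges yields a single variant identical to the input.
#' @export
expand_bindings <- function(g, cap = 81L) {
  validate_pathway_graph(g)
  be <- binding_edges(g)
  base_edges <- directed_edges(g)
  if (nrow(be) == 0L) {
    out <- pathway_graph(g$pathway_id, g$nodes, base_edges)
    return(list(out))
  }

  bg <- igraph::graph_from_data_frame(
    be[, c("from", "to"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = sort(unique(c(be$from, be$to))))
  )
  comp <- igraph::components(bg)
  comps <- split(names(comp$membership), comp$membership)
  comps <- lapply(comps, sort)
  comps <- comps[order(vapply(comps, `[`, character(1), 1L))]

  # choice j in 1..m selects member j alone; choice m+1 merges all members
  n_choice <- vapply(comps, length, integer(1)) + 1L
  total <- prod(n_choice)
  grid <- rev(expand.grid(rev(lapply(n_choice, seq_len))))
  if (total > cap) {
    warning("binding expansion yields ", total, " variants; keeping first ",
            cap, call. = FALSE)
    grid <- grid[seq_len(cap), , drop = FALSE]
  }

  genes <- node_genes(g)
  variants <- vector("list", nrow(grid))
  for (v in seq_len(nrow(grid))) {
    nodes <- g$nodes
    edges <- base_edges
    for (ci in seq_along(comps)) {
      members <- comps[[ci]]
      choice <- grid[v, ci]
      if (choice <= length(members)) {
        drop <- setdiff(members, members[choice])
        nodes <- nodes[!nodes$id %in% drop, , drop = FALSE]
        if (nrow(edges)) {
          edges <- edges[!(edges$from %in% drop | edges$to %in% drop), ,
                         drop = FALSE]
        }
      } else {
        mid <- paste0("bind.", paste(members, collapse = "."))
        merged <- data.frame(
          id = mid,
          genes = paste(sort(unique(unlist(genes[members]))), collapse = ";"),
          kind = "merged_binding",
          stringsAsFactors = FALSE
        )
        nodes <- rbind(nodes[!nodes$id %in% members, , drop = FALSE], merged)
        if (nrow(edges)) {
          edges$from[edges$from %in% members] <- mid
          edges$to[edges$to %in% members] <- mid
          edges <- edges[edges$from != edges$to, , drop = FALSE]
        }
      }
    }
    if (nrow(edges)) {
      edges <- edges[order(edges$from, edges$to, edges$subtype, edges$sign), ,
                     drop = FALSE]
      edges <- edges[!duplicated(edges[, c("from", "to", "subtype")]), ,
                     drop = FALSE]
    }
    nodes <- nodes[order(nodes$id), , drop = FALSE]
    rownames(nodes) <- rownames(edges) <- NULL
    variants[[v]] <- pathway_graph(g$pathway_id, nodes, edges)
  }
  variants
}
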