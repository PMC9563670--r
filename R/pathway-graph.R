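#' Construct a pathway graph
#'
#' A `pathway_graph` is a signed directed graph of gene nodes. Nodes may carry
#' several gene symbols: a `merged_binding` node stands for two (or more) genes
#' bound in a complex and is considered active when at least one member is
#' present; a `condensed_loop` node stands for a directed cycle collapsed into
#' a single conjunctive node, active only when all members are present.
#'
#' @param pathway_id Character scalar identifying the pathway.
#' @param nodes Data frame with columns `id` (character, unique), `genes`
#'   (character, one or more gene symbols joined by `";"`), and `kind`
#'   (one of `"simple"`, `"merged_binding"`, `"condensed_loop"`).
#' @param edges Data frame with columns `from`, `to` (node ids), `sign`
#'   (`+1`/`-1`) and `subtype` (character). Binding/association edges are
#'   interpreted as undirected binding events by [expand_bindings()].
#' @return An object of class `pathway_graph`.
#' @seealso [parse_kgml()], [condense_loops()], [enumerate_subpathways()]
#' @export
pathway_graph <- function(pathway_id, nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(nodes) == 0L) {
    nodes <- data.frame(id = character(), genes = character(),
                        kind = character(), stringsAsFactors = FALSE)
  }
  if (nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        sign = integer(), subtype = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "genes", "kind") %in% names(nodes)),
            all(c("from", "to", "sign", "subtype") %in% names(edges)))
  nodes$id <- as.character(nodes$id)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$sign <- as.integer(edges$sign)
  g <- structure(
    list(pathway_id = as.character(pathway_id), nodes = nodes, edges = edges),
    class = "pathway_graph"
  )
  validate_pathway_graph(g)
}

validate_pathway_graph <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  if (anyDuplicated(g$nodes$id)) stop("duplicate node ids", call. = FALSE)
  bad_kind <- setdiff(g$nodes$kind, c("simple", "merged_binding", "condensed_loop"))
  if (length(bad_kind)) stop("unknown node kind: ", bad_kind[1], call. = FALSE)
  if (nrow(g$edges)) {
    missing <- setdiff(c(g$edges$from, g$edges$to), g$nodes$id)
    if (length(missing)) {
      stop("edge endpoint not in node set: ", missing[1], call. = FALSE)
    }
    if (any(!g$edges$sign %in% c(1L, -1L))) {
      stop("edge signs must be +1 or -1", call. = FALSE)
    }
  }
  g
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph> ", x$pathway_id, ": ",
      nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Gene symbols carried by each node
#'
#' @param g A `pathway_graph`.
#' @return Named list of character vectors, one per node id.
#' @export
node_genes <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  out <- strsplit(g$nodes$genes, ";", fixed = TRUE)
  names(out) <- g$nodes$id
  out
}

#' All gene symbols appearing in a pathway graph
#'
#' @param g A `pathway_graph`.
#' @return Sorted character vector of unique gene symbols.
#' @export
pathway_genes <- function(g) {
  sort(unique(unlist(node_genes(g), use.names = FALSE)))
}

# directed (non-binding) edges of a graph
directed_edges <- function(g) {
  g$edges[g$edges$subtype != "binding/association", , drop = FALSE]
}

binding_edges <- function(g) {
  g$edges[g$edges$subtype == "binding/association", , drop = FALSE]
}

as_igraph_directed <- function(g) {
  ed <- directed_edges(g)
  igraph::graph_from_data_frame(
    ed[, c("from", "to"), drop = FALSE],
    directed = TRUE,
    vertices = data.frame(name = g$nodes$id, stringsAsFactors = FALSE)
  )
}

# Human-readable node label: member genes joined by "+"
node_label <- function(g, id) {
  genes <- node_genes(g)
  vapply(id, function(i) paste(genes[[i]], collapse = "+"), character(1))
}

#' Graph equality on (nodes, signed edges)
#'
#' Two pathway graphs are considered equal when their node gene sets (with
#' kinds) and signed directed edge sets coincide, irrespective of node ids or
#' row order. Used to verify KGML round-trips.
#'
#' @param a,b `pathway_graph` objects.
#' @return Logical scalar.
#' @export
graphs_equal <- function(a, b) {
  canon <- function(g) {
    lab <- vapply(node_genes(g), function(x) paste(sort(x), collapse = "+"),
                  character(1))
    nodes <- sort(paste(lab[g$nodes$id], g$nodes$kind))
    if (nrow(g$edges)) {
      ed <- sort(paste(lab[g$edges$from], "->", lab[g$edges$to],
                       g$edges$sign, g$edges$subtype))
    } else ed <- character()
    list(nodes = nodes, edges = ed)
  }
  identical(canon(a), canon(b))
}
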