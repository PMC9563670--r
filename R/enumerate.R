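#' Enumeration settings for subpathway extraction
#'
#' @param max_path_length Maximum chain length in nodes; longer paths are
#'   pruned during the search.
#' @param max_paths_per_pathway Hard cap on the number of chains collected per
#'   pathway; the depth-first search visits neighbours in lexicographic node
#'   order, so truncation is deterministic.
#' @param binding_subset_cap Cap on binding-expansion variants, see
#'   [expand_bindings()].
#' @param start_policy `"entry_only"` starts chains at entry nodes (no parent);
#'   `"any_node"` starts at every node, which additionally yields all suffix
#'   chains.
#' @return A list of class `enumeration_config`.
#' @export
enumeration_config <- function(max_path_length = 30L,
                               max_paths_per_pathway = 50000L,
                               binding_subset_cap = 81L,
                               start_policy = c("entry_only", "any_node")) {
  start_policy <- match.arg(start_policy)
  stopifnot(max_path_length >= 1L, max_paths_per_pathway >= 1L,
            binding_subset_cap >= 1L)
  structure(
    list(max_path_length = as.integer(max_path_length),
         max_paths_per_pathway = as.integer(max_paths_per_pathway),
         binding_subset_cap = as.integer(binding_subset_cap),
         start_policy = start_policy),
    class = "enumeration_config"
  )
}

#' Enumerate single-chain subpathways of a pathway graph
#'
#' Normalizes the graph (loop condensation, then binding expansion) and lists
#' every chain from an entry node (a node without parent) to an end node (a
#' node without child) across all binding variants. A node that is both entry
#' and end yields a chain of length 1. Chains are deduplicated by their node
#' label sequence and returned in lexicographic order, so enumeration is fully
#' deterministic.
#'
#' @param g A [pathway_graph()], raw or already normalized.
#' @param config An [enumeration_config()].
#' @return A `subpathway_set`: list with elements `pathway_id` and `subpaths`,
#'   the latter a list of chains, each carrying `labels` (display name per
#'   node, complex members joined by `+`), `genes` (list of member gene
#'   vectors), `kinds` (node kinds) and `signs` (step signs, one per edge).
#' @examples
#' g <- parse_kgml(generate_pathway(n_nodes = 4, n_bindings = 1, seed = 1))
#' length(enumerate_subpathways(g)$subpaths)  # 3 chains: B, C, B+C variants
#' @export
enumerate_subpathways <- function(g, config = enumeration_config()) {
  stopifnot(inherits(config, "enumeration_config"))
  gc <- condense_loops(g)
  variants <- expand_bindings(gc, cap = config$binding_subset_cap)

  chains <- list()
  n_found <- 0L
  truncated <- FALSE
  for (vg in variants) {
    if (nrow(vg$nodes) == 0L) next
    ids <- vg$nodes$id
    ed <- vg$edges
    adj <- lapply(stats::setNames(ids, ids), function(i) {
      nb <- sort(ed$to[ed$from == i])
      nb
    })
    sign_of <- stats::setNames(ed$sign, paste(ed$from, ed$to, sep = "\r"))
    indeg <- table(factor(ed$to, levels = ids))
    outdeg <- table(factor(ed$from, levels = ids))
    starts <- if (config$start_policy == "entry_only") ids[indeg == 0L] else ids
    ends <- ids[outdeg == 0L]

    glist <- node_genes(vg)
    kind_of <- stats::setNames(vg$nodes$kind, vg$nodes$id)
    labels <- stats::setNames(
      vapply(glist, function(x) paste(x, collapse = "+"), character(1)), ids)

    dfs <- function(path) {
      if (n_found >= config$max_paths_per_pathway) {
        truncated <<- TRUE
        return()
      }
      node <- path[length(path)]
      if (node %in% ends) {
        key <- paste(labels[path], collapse = ">")
        if (is.null(chains[[key]])) {
          signs <- if (length(path) > 1L) {
            unname(sign_of[paste(path[-length(path)], path[-1L], sep = "\r")])
          } else integer()
          chains[[key]] <<- list(
            labels = unname(labels[path]),
            genes = unname(glist[path]),
            kinds = unname(kind_of[path]),
            signs = as.integer(signs)
          )
          n_found <<- n_found + 1L
        }
      }
      if (length(path) >= config$max_path_length) return()
      for (nb in adj[[node]]) {
        if (!nb %in% path) dfs(c(path, nb))
      }
    }
    for (s in sort(starts)) dfs(s)
  }
  if (truncated) {
    warning("subpathway enumeration truncated at ",
            config$max_paths_per_pathway, " chains", call. = FALSE)
  }
  chains <- chains[order(names(chains), method = "radix")]
  structure(list(pathway_id = g$pathway_id, subpaths = unname(chains)),
            class = "subpathway_set")
}

#' @export
print.subpathway_set <- function(x, ...) {
  cat("<subpathway_set> ", x$pathway_id, ": ", length(x$subpaths),
      " chains\n", sep = "")
  if (length(x$subpaths)) {
    show <- utils::head(vapply(x$subpaths, function(s)
      paste(s$labels, collapse = ">"), character(1)), 5L)
    cat(paste0("  ", show, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.subpathway_set <- function(x, ...) {
  if (!length(x$subpaths)) {
    return(data.frame(pathway_id = character(), chain = character(),
                      signs = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    pathway_id = x$pathway_id,
    chain = vapply(x$subpaths, function(s) paste(s$labels, collapse = ">"),
                   character(1)),
    signs = vapply(x$subpaths, function(s) paste(s$signs, collapse = ","),
                   character(1)),
    length = vapply(x$subpaths, function(s) length(s$labels), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a subpathway set as TSV
#'
#' Columns: `pathway_id`, `chain` (node labels joined by `>`), `signs`
#' (comma-separated step signs) and `length`.
#'
#' @param x A `subpathway_set` or a list of them.
#' @param path Output file path.
#' @return The written data frame, invisibly.
#' @export
export_subpathways <- function(x, path) {
  if (inherits(x, "subpathway_set")) x <- list(x)
  df <- do.call(rbind, lapply(x, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
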