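#' Parse a KGML pathway document into a pathway graph
#'
#' Reads a KEGG Markup Language (KGML) XML document and builds the signed
#' directed graph used throughout the package. Only entries of type `"gene"`
#' become nodes; compound, map and other entry types are dropped. `group`
#' entries (protein complexes) are translated into binding/association events
#' among their gene components, and relations addressed to a group are
#' redirected to every component. Each relation whose subtype appears in the
#' sign table becomes one signed edge.
#'
#' @param x KGML document: a file path, a literal XML string, or an
#'   `xml_document`.
#' @param sign_table Subtype sign coding, see [kegg_relation_signs()].
#' @param unknown_subtype What to do with a relation subtype absent from the
#'   sign table: `"error"` (default) or `"skip"` (drop the relation with a
#'   warning).
#' @return A [pathway_graph()].
#' @examples
#' doc <- generate_pathway(n_nodes = 4, n_bindings = 1, seed = 1)
#' parse_kgml(doc)
#' @export
parse_kgml <- function(x, sign_table = kegg_relation_signs(),
                       unknown_subtype = c("error", "skip")) {
  unknown_subtype <- match.arg(unknown_subtype)
  doc <- if (inherits(x, "xml_document")) {
    x
  } else if (is.character(x) && length(x) == 1L && !grepl("<", x, fixed = TRUE)) {
    xml2::read_xml(x)  # file path
  } else {
    xml2::read_xml(paste(x, collapse = "\n"))
  }

  root <- xml2::xml_root(doc)
  pathway_id <- xml2::xml_attr(root, "name")
  if (is.na(pathway_id)) pathway_id <- "pathway"

  entries <- xml2::xml_find_all(doc, ".//entry")
  ids <- xml2::xml_attr(entries, "id")
  types <- xml2::xml_attr(entries, "type")

  gene_ids <- ids[types == "gene"]
  symbols <- lapply(entries[types == "gene"], kgml_entry_symbols)
  names(symbols) <- gene_ids

  nodes <- data.frame(
    id = gene_ids,
    genes = vapply(symbols, paste, character(1), collapse = ";"),
    kind = rep("simple", length(gene_ids)),
    stringsAsFactors = FALSE
  )

  # group entries: map group id -> member gene entry ids
  group_members <- list()
  for (ge in entries[types == "group"]) {
    gid <- xml2::xml_attr(ge, "id")
    comp <- xml2::xml_attr(xml2::xml_find_all(ge, ".//component"), "id")
    group_members[[gid]] <- intersect(comp, gene_ids)
  }

  ef <- character(); et <- character(); es <- integer(); esub <- character()
  add_edge <- function(from, to, sign, subtype) {
    ef <<- c(ef, from); et <<- c(et, to)
    es <<- c(es, sign); esub <<- c(esub, subtype)
  }

  # binding among the members of each complex
  for (members in group_members) {
    if (length(members) >= 2L) {
      pairs <- utils::combn(sort(members), 2L)
      for (j in seq_len(ncol(pairs))) {
        add_edge(pairs[1, j], pairs[2, j], 1L, "binding/association")
      }
    }
  }

  resolve <- function(id) {
    if (id %in% gene_ids) return(id)
    if (id %in% names(group_members)) return(group_members[[id]])
    character()
  }

  for (rel in xml2::xml_find_all(doc, ".//relation")) {
    e1 <- resolve(xml2::xml_attr(rel, "entry1"))
    e2 <- resolve(xml2::xml_attr(rel, "entry2"))
    if (!length(e1) || !length(e2)) {
      warning("relation references a non-gene or missing entry; edge skipped",
              call. = FALSE)
      next
    }
    subs <- tolower(xml2::xml_attr(xml2::xml_find_all(rel, ".//subtype"), "name"))
    if (!length(subs)) next
    known <- subs[subs %in% names(sign_table)]
    if (!length(known)) {
      if (unknown_subtype == "error") {
        stop("relation subtype not in sign table: '", subs[1], "'",
             call. = FALSE)
      }
      warning("relation subtype not in sign table: '", subs[1],
              "'; edge skipped", call. = FALSE)
      next
    }
    # a binding subtype marks the relation as a binding event; otherwise the
    # first recognized subtype determines the sign
    subtype <- if ("binding/association" %in% known) "binding/association" else known[1]
    sgn <- as.integer(sign_table[[subtype]])
    for (a in e1) for (b in e2) {
      if (a != b) add_edge(a, b, sgn, subtype)
    }
  }

  edges <- unique(data.frame(from = ef, to = et, sign = es, subtype = esub,
                             stringsAsFactors = FALSE))
  # order-independent canonical form
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  if (nrow(edges)) {
    edges <- edges[order(edges$from, edges$to, edges$subtype), , drop = FALSE]
  }
  rownames(nodes) <- rownames(edges) <- NULL
  pathway_graph(pathway_id, nodes, edges)
}

kgml_entry_symbols <- function(entry) {
  gname <- xml2::xml_attr(xml2::xml_find_first(entry, ".//graphics"), "name")
  if (!is.na(gname) && nzchar(gname)) {
    syms <- trimws(strsplit(gname, ",", fixed = TRUE)[[1]])
    syms <- sub("\\.\\.\\.$", "", syms)
    syms <- syms[nzchar(syms)]
    if (length(syms)) return(unique(syms))
  }
  syms <- strsplit(trimws(xml2::xml_attr(entry, "name")), "\\s+")[[1]]
  syms[nzchar(syms)]
}

kgml_subtype_glyph <- c(
  "activation" = "--&gt;", "inhibition" = "--|", "expression" = "--&gt;",
  "repression" = "--|", "indirect effect" = "..&gt;", "state change" = "...",
  "binding/association" = "---", "dissociation" = "-+-",
  "missing interaction" = "-/-", "phosphorylation" = "+p",
  "dephosphorylation" = "-p", "glycosylation" = "+g",
  "ubiquitination" = "+u", "methylation" = "+m"
)

#' Serialize a pathway graph as KGML
#'
#' Writes a valid KGML document whose re-parse with [parse_kgml()] recovers the
#' same node gene sets and signed edge set (see [graphs_equal()]). Mainly used
#' by the synthetic-pathway generator and for round-trip testing.
#'
#' @param g A [pathway_graph()].
#' @param path Optional file path; when given the document is written there and
#'   the text returned invisibly.
#' @return KGML XML text (single character scalar).
#' @export
write_kgml <- function(g, path = NULL) {
  validate_pathway_graph(g)
  genes <- node_genes(g)
  if (any(!vapply(genes, length, integer(1)))) {
    stop("every node must carry at least one gene symbol", call. = FALSE)
  }
  num <- seq_len(nrow(g$nodes))
  names(num) <- g$nodes$id

  lines <- c(
    '<?xml version="1.0"?>',
    sprintf('<pathway name="%s" org="hsa" number="0" title="%s">',
            xml_escape(g$pathway_id), xml_escape(g$pathway_id))
  )
  for (i in seq_len(nrow(g$nodes))) {
    lines <- c(lines, sprintf(
      '  <entry id="%d" name="hsa:%d" type="gene"><graphics name="%s" type="rectangle"/></entry>',
      num[i], num[i],
      xml_escape(paste(genes[[g$nodes$id[i]]], collapse = ", "))
    ))
  }
  if (nrow(g$edges)) {
    for (j in seq_len(nrow(g$edges))) {
      st <- g$edges$subtype[j]
      glyph <- kgml_subtype_glyph[[st]]
      if (is.null(glyph)) glyph <- "-&gt;"
      rtype <- if (st == "binding/association") "PPrel" else "GErel"
      lines <- c(lines, sprintf(
        '  <relation entry1="%d" entry2="%d" type="%s"><subtype name="%s" value="%s"/></relation>',
        num[[g$edges$from[j]]], num[[g$edges$to[j]]], rtype,
        xml_escape(st), glyph
      ))
    }
  }
  lines <- c(lines, "</pathway>")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}
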