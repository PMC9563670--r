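#' Signed coding of KEGG relation subtypes
#'
#' KEGG pathways annotate each relation between two gene nodes with a subtype
#' (activation, inhibition, phosphorylation, ...). For signal propagation every
#' subtype is collapsed to a sign: `+1` for inducing relations and `-1` for
#' inhibiting ones. This table supplies the weight applied to the upstream
#' perturbation factor when a signal crosses the edge.
#'
#' The default table covers the 14 standard KGML subtypes. Note the
#' less-obvious codings: repression, missing interaction and ubiquitination
#' all carry `+1`, while dissociation and dephosphorylation carry `-1`.
#'
#' @return Named integer vector mapping subtype label to `+1` or `-1`.
#' @examples
#' kegg_relation_signs()[["dephosphorylation"]]
#' @export
kegg_relation_signs <- function() {
  c(
    "activation"          = 1L,
    "inhibition"          = -1L,
    "expression"          = 1L,
    "repression"          = 1L,
    "indirect effect"     = 1L,
    "state change"        = 1L,
    "binding/association" = 1L,
    "dissociation"        = -1L,
    "missing interaction" = 1L,
    "phosphorylation"     = 1L,
    "dephosphorylation"   = -1L,
    "glycosylation"       = 1L,
    "ubiquitination"      = 1L,
    "methylation"         = 1L
  )
}

#' Look up the sign of a relation subtype
#'
#' @param subtype Character label of a KEGG relation subtype
#'   (e.g. `"activation"`). Matching is case-insensitive.
#' @param sign_table Named integer vector of subtype signs; defaults to
#'   [kegg_relation_signs()]. Supplying a different table overrides or extends
#'   the coding.
#' @return `+1L` or `-1L`.
#' @examples
#' relation_sign("activation")
#' relation_sign("dissociation")
#' @export
relation_sign <- function(subtype, sign_table = kegg_relation_signs()) {
  stopifnot(is.character(subtype), length(subtype) == 1L)
  key <- tolower(trimws(subtype))
  if (!key %in% names(sign_table)) {
    stop("unrecognized relation subtype: '", subtype, "'", call. = FALSE)
  }
  v <- as.integer(sign_table[[key]])
  if (!v %in% c(1L, -1L)) {
    stop("sign table entry for '", subtype, "' must be +1 or -1", call. = FALSE)
  }
  v
}
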