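#' The 13 chemical-gene relation types
#'
#' The DrugProt annotation schema distinguishes 13 typed interactions
#' between a chemical compound (the head) and a gene or protein (the
#' tail). All label vectors, classifier heads, threshold maps and
#' evaluation reports in this package are indexed by this vector, in this
#' order.
#'
#' @return Character vector of length 13.
#' @export
#' @examples
#' relation_types()
relation_types <- function() {
  c(
    "INDIRECT-DOWNREGULATOR", "INDIRECT-UPREGULATOR", "DIRECT-REGULATOR",
    "ACTIVATOR", "INHIBITOR", "AGONIST", "ANTAGONIST",
    "AGONIST-ACTIVATOR", "AGONIST-INHIBITOR", "PRODUCT-OF",
    "SUBSTRATE", "SUBSTRATE_PRODUCT-OF", "PART-OF"
  )
}

#' The three entity mention types
#'
#' Chemicals, normalizable genes (GENE-Y, linkable to an NCBI Gene record)
#' and non-normalizable genes (GENE-N).
#'
#' @return Character vector of length 3.
#' @export
entity_types <- function() c("CHEMICAL", "GENE-Y", "GENE-N")

#' Entity marker tokens
#'
#' Sentinel tokens inserted around the chemical (head) and gene (tail)
#' mentions of a candidate pair so that an encoder can localize the pair
#' within its sentence.
#'
#' @return Named character vector with elements `head_start`, `head_end`,
#'   `tail_start`, `tail_end`.
#' @export
marker_tokens <- function() {
  c(
    head_start = "[HEAD-S]", head_end = "[HEAD-E]",
    tail_start = "[TAIL-S]", tail_end = "[TAIL-E]"
  )
}

# Validate a vector of relation type strings, error naming offenders.
assert_relation_types <- function(rtype, context = "relation type") {
  bad <- setdiff(unique(rtype), relation_types())
  if (length(bad) > 0) {
    abort(sprintf(
      "Invalid %s: %s (must be one of the 13 relation types)",
      context, paste(bad, collapse = ", ")
    ))
  }
  invisible(rtype)
}
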