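#' Load a description table
#'
#' Reads a two-column tab-separated table mapping a normalized identifier
#' (a MeSH ID for chemicals, an NCBI Gene ID for genes, a UniProt
#' accession for proteins) to a free-text description. Chemical
#' definitions follow the CTD convention of keeping only the first
#' sentence of the definition field; apply [first_sentence()] when
#' loading raw definitions.
#'
#' @param path Path to a UTF-8 TSV with columns (key, text), no header.
#'   Extra tab-separated fields are folded back into the text.
#' @param source One of `"CTD_CHEMICAL"`, `"ENTREZ_GENE"`,
#'   `"UNIPROT_PROTEIN"`.
#' @return A tibble with columns `key`, `text`, `source`; one row per
#'   unique key. Duplicate keys keep the last occurrence with a warning.
#' @export
load_description_table <- function(path, source = c("CTD_CHEMICAL", "ENTREZ_GENE", "UNIPROT_PROTEIN")) {
  source <- match.arg(source)
  lines <- read_corpus_lines(path)
  if (length(lines) == 0) {
    return(tibble(key = character(), text = character(), source = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tab <- tibble(
    key = vapply(parts, `[[`, "", 1),
    text = vapply(parts, function(p) if (length(p) >= 2) paste(p[-1], collapse = "\t") else "", ""),
    source = source
  )
  if (any(!nzchar(tab$key))) abort(sprintf("Empty key in description table '%s'", path))
  if (anyDuplicated(tab$key)) {
    dups <- unique(tab$key[duplicated(tab$key)])
    warn(sprintf(
      "Duplicate key(s) in '%s' (last occurrence kept): %s",
      path, paste(head(dups, 5), collapse = ", ")
    ))
    tab <- tab[!duplicated(tab$key, fromLast = TRUE), ]
  }
  tab
}

#' Extract the first sentence of a description
#'
#' Applies the package's deterministic boundary rule (terminal
#' punctuation followed by whitespace and an uppercase letter or digit,
#' with a small abbreviation stop-list). Text with no detected boundary
#' is returned unchanged. Idempotent and vectorized.
#'
#' @param text Character vector.
#' @return Character vector of first sentences.
#' @export
#' @examples
#' first_sentence("A kinase inhibitor. It binds ATP pockets.")
first_sentence <- function(text) {
  vapply(text, function(x) {
    if (is.na(x) || !nzchar(x)) return(x)
    b <- sentence_boundary_positions(x)
    if (length(b) == 0) x else sub("[ \t\n]+$", "", substr(x, 1L, b[1]))
  }, character(1), USE.NAMES = FALSE)
}

#' Look up descriptions by key
#'
#' Missing keys and `NA` keys (e.g. GENE-N mentions, which carry no
#' normalized identifier) return the empty string, never an error, so
#' augmentation degrades gracefully to the sentence-only case.
#'
#' @param key Character vector of identifiers (may contain `NA`).
#' @param table Tibble from [load_description_table()].
#' @return Character vector of description texts, `""` where unknown.
#' @export
lookup_description <- function(key, table) {
  if (length(key) == 0) return(character())
  idx <- match(key, table$key)
  out <- ifelse(is.na(idx), "", table$text[idx])
  out[is.na(key)] <- ""
  out
}
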