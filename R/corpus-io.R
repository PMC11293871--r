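#' Read a DrugProt-style abstracts file
#'
#' Each line carries `doc_id`, `title` and `abstract` separated by tabs
#' (any further tab-separated fields are folded back into the abstract).
#' The working text of a document, `full_text`, is the title and abstract
#' joined by a single tab character; all entity character offsets in this
#' package are 0-based, half-open intervals over `full_text` (the dialect
#' used by the DrugProt distribution itself).
#'
#' @param path Path to a UTF-8 tab-separated file with no header.
#' @return A tibble with columns `doc_id`, `title`, `abstract`,
#'   `full_text`, one row per document, in file order.
#' @export
read_abstracts <- function(path) {
  lines <- read_corpus_lines(path)
  if (length(lines) == 0) {
    return(tibble(
      doc_id = character(), title = character(),
      abstract = character(), full_text = character()
    ))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    abort(sprintf(
      "Malformed abstracts line %d in '%s': expected >= 3 tab-separated fields, got %d",
      which(nf < 3)[1], path, nf[which(nf < 3)[1]]
    ))
  }
  docs <- tibble(
    doc_id = vapply(parts, `[[`, "", 1),
    title = vapply(parts, `[[`, "", 2),
    abstract = vapply(parts, function(p) paste(p[-(1:2)], collapse = "\t"), "")
  )
  dup <- docs$doc_id[duplicated(docs$doc_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate doc_id in '%s': %s", path, paste(unique(dup), collapse = ", ")))
  }
  mutate(docs, full_text = paste(.data$title, .data$abstract, sep = "\t"))
}

#' Read a DrugProt-style entity mention file
#'
#' Lines carry `doc_id`, `mention_id`, `etype`, `start`, `end`, `surface`
#' and optionally a seventh `norm_id` field (MeSH identifier for
#' chemicals, NCBI Gene identifier for GENE-Y mentions; empty or absent
#' for GENE-N). Offsets are 0-based half-open over the document
#' `full_text`.
#'
#' @param path Path to a UTF-8 tab-separated file with no header.
#' @param documents Optional tibble from [read_abstracts()]. When given,
#'   every mention's `surface` is checked against
#'   `substr(full_text, start + 1, end)` and mismatches raise an error
#'   naming the mention.
#' @return A tibble with columns `doc_id`, `mention_id`, `etype`,
#'   `start`, `end`, `surface`, `norm_id` (`NA` when absent).
#' @export
read_entities <- function(path, documents = NULL) {
  lines <- read_corpus_lines(path)
  empty <- tibble(
    doc_id = character(), mention_id = character(), etype = character(),
    start = integer(), end = integer(), surface = character(),
    norm_id = character()
  )
  if (length(lines) == 0) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6)) {
    abort(sprintf(
      "Malformed entities line %d in '%s': expected >= 6 fields, got %d",
      which(nf < 6)[1], path, nf[which(nf < 6)[1]]
    ))
  }
  ents <- tibble(
    doc_id = vapply(parts, `[[`, "", 1),
    mention_id = vapply(parts, `[[`, "", 2),
    etype = vapply(parts, `[[`, "", 3),
    start = as.integer(vapply(parts, `[[`, "", 4)),
    end = as.integer(vapply(parts, `[[`, "", 5)),
    surface = vapply(parts, `[[`, "", 6),
    norm_id = vapply(parts, function(p) if (length(p) >= 7 && nzchar(p[7])) p[7] else NA_character_, "")
  )
  bad_type <- setdiff(unique(ents$etype), entity_types())
  if (length(bad_type) > 0) {
    abort(sprintf(
      "Unknown entity type(s) in '%s': %s (expected CHEMICAL, GENE-Y or GENE-N)",
      path, paste(bad_type, collapse = ", ")
    ))
  }
  if (any(is.na(ents$start)) || any(is.na(ents$end)) || any(ents$start < 0) || any(ents$start >= ents$end)) {
    i <- which(is.na(ents$start) | is.na(ents$end) | ents$start < 0 | ents$start >= ents$end)[1]
    abort(sprintf("Invalid offsets for mention '%s' in document %s", ents$mention_id[i], ents$doc_id[i]))
  }
  if (!is.null(documents)) validate_entity_offsets(ents, documents)
  ents
}

validate_entity_offsets <- function(entities, documents) {
  m <- left_join(entities, select(documents, "doc_id", "full_text"), by = "doc_id")
  if (any(is.na(m$full_text))) {
    i <- which(is.na(m$full_text))[1]
    abort(sprintf("Mention '%s' refers to unknown document %s", m$mention_id[i], m$doc_id[i]))
  }
  observed <- substr(m$full_text, m$start + 1L, m$end)
  bad <- which(observed != m$surface)
  if (length(bad) > 0) {
    i <- bad[1]
    abort(sprintf(
      "Offset mismatch for mention '%s' in document %s: expected surface '%s' but full_text[%d,%d) is '%s'",
      m$mention_id[i], m$doc_id[i], m$surface[i], m$start[i], m$end[i], observed[i]
    ))
  }
  invisible(entities)
}

#' Read a DrugProt-style relation (gold or prediction) file
#'
#' Lines carry `doc_id`, `rtype`, `Arg1:<mention_id>`, `Arg2:<mention_id>`.
#' `Arg1` is the chemical (head), `Arg2` the gene (tail). Duplicate rows
#' are kept on read; [write_predictions()] deduplicates on write.
#'
#' @param path Path to a UTF-8 tab-separated file with no header.
#' @param entities Optional tibble from [read_entities()]. When given,
#'   every argument must resolve to a mention of that document, `Arg1` to
#'   a CHEMICAL and `Arg2` to a gene mention.
#' @return A tibble with columns `doc_id`, `rtype`, `arg1`, `arg2`.
#' @export
read_relations <- function(path, entities = NULL) {
  lines <- read_corpus_lines(path)
  empty <- tibble(doc_id = character(), rtype = character(), arg1 = character(), arg2 = character())
  if (length(lines) == 0) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4)) {
    abort(sprintf(
      "Malformed relations line %d in '%s': expected >= 4 fields, got %d",
      which(nf < 4)[1], path, nf[which(nf < 4)[1]]
    ))
  }
  rel <- tibble(
    doc_id = vapply(parts, `[[`, "", 1),
    rtype = vapply(parts, `[[`, "", 2),
    arg1 = sub("^Arg1:", "", vapply(parts, `[[`, "", 3)),
    arg2 = sub("^Arg2:", "", vapply(parts, `[[`, "", 4))
  )
  assert_relation_types(rel$rtype, context = sprintf("relation type in '%s'", path))
  if (!is.null(entities)) {
    key <- paste(entities$doc_id, entities$mention_id)
    chem_key <- key[entities$etype == "CHEMICAL"]
    gene_key <- key[entities$etype %in% c("GENE-Y", "GENE-N")]
    bad1 <- which(!(paste(rel$doc_id, rel$arg1) %in% chem_key))
    bad2 <- which(!(paste(rel$doc_id, rel$arg2) %in% gene_key))
    if (length(bad1) > 0) {
      abort(sprintf(
        "Relation Arg1 '%s' in document %s does not resolve to a CHEMICAL mention",
        rel$arg1[bad1[1]], rel$doc_id[bad1[1]]
      ))
    }
    if (length(bad2) > 0) {
      abort(sprintf(
        "Relation Arg2 '%s' in document %s does not resolve to a gene mention",
        rel$arg2[bad2[1]], rel$doc_id[bad2[1]]
      ))
    }
  }
  rel
}

#' Write predictions in the challenge exchange format
#'
#' Rows are written as `doc_id<TAB>rtype<TAB>Arg1:<id><TAB>Arg2:<id>`,
#' deduplicated and sorted by document, relation type and arguments so
#' output is deterministic and directly consumable by challenge-style
#' scorers.
#'
#' @param predictions Tibble with columns `doc_id`, `rtype`, `arg1`, `arg2`.
#' @param path Output file path.
#' @return `predictions` (deduplicated, sorted), invisibly.
#' @export
write_predictions <- function(predictions, path) {
  assert_relation_types(predictions$rtype)
  out <- predictions |>
    select("doc_id", "rtype", "arg1", "arg2") |>
    distinct() |>
    arrange(.data$doc_id, .data$rtype, .data$arg1, .data$arg2)
  lines <- sprintf("%s\t%s\tArg1:%s\tArg2:%s", out$doc_id, out$rtype, out$arg1, out$arg2)
  writeLines(lines, path, useBytes = TRUE)
  invisible(out)
}

#' Summarize a corpus
#'
#' Counts documents, chemical and gene mentions, and relation rows per
#' type (all 13 types reported, zero-filled).
#'
#' @param documents,entities,relations Tibbles as returned by the
#'   `read_*` family (or the synthetic generator).
#' @return An object of class `dti_corpus_stats`: a list with
#'   `n_documents`, `n_chemical_mentions`, `n_gene_mentions` and a
#'   `relation_counts` tibble (`rtype`, `n`).
#' @export
corpus_stats <- function(documents, entities, relations) {
  counts <- relations |>
    count(.data$rtype) |>
    right_join_types()
  out <- list(
    n_documents = nrow(documents),
    n_chemical_mentions = sum(entities$etype == "CHEMICAL"),
    n_gene_mentions = sum(entities$etype %in% c("GENE-Y", "GENE-N")),
    relation_counts = counts
  )
  structure(out, class = "dti_corpus_stats")
}

right_join_types <- function(counts) {
  all_types <- tibble(rtype = relation_types())
  out <- left_join(all_types, counts, by = "rtype")
  out$n[is.na(out$n)] <- 0L
  out
}

#' @export
print.dti_corpus_stats <- function(x, ...) {
  cat(sprintf(
    "Corpus: %d documents, %d chemical and %d gene mentions, %d relations\n",
    x$n_documents, x$n_chemical_mentions, x$n_gene_mentions,
    sum(x$relation_counts$n)
  ))
  print(arrange(x$relation_counts, dplyr::desc(.data$n)), n = 13)
  invisible(x)
}

#' @export
tidy.dti_corpus_stats <- function(x, ...) x$relation_counts

# Shared line reader: UTF-8, drops trailing blank lines only.
read_corpus_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines[nzchar(lines)]
}
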