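# Small hand-built corpus fixtures shared across test files.

# Bare-bones instance tibble from raw texts (bypasses marker insertion),
# for classifier-level tests.
make_instances <- function(texts, labels = NULL) {
  n <- length(texts)
  lab <- lapply(seq_len(n), function(i) {
    v <- stats::setNames(integer(13), relation_types())
    if (!is.null(labels)) v[labels[[i]]] <- 1L
    v
  })
  tibble::tibble(
    instance_id = paste0("i", seq_len(n)), doc_id = "1",
    head_id = "T1", tail_id = "T2",
    head_norm_id = NA_character_, tail_norm_id = NA_character_,
    sentence = texts, marked_text = texts, model_text = texts,
    chem_desc = "", gene_desc = "", label = lab
  )
}

# One document, one sentence with two chemicals and one gene, plus a
# second sentence with a lone gene (for cross-sentence cases).
tiny_corpus <- function() {
  title <- "Ozone study."
  abstract <- "Ozone and nitric oxide increased IL-6 levels. STAT3 was unchanged."
  full_text <- paste(title, abstract, sep = "\t")
  documents <- tibble::tibble(
    doc_id = "1001", title = title, abstract = abstract, full_text = full_text
  )
  surfaces <- c("Ozone", "nitric oxide", "IL-6", "STAT3")
  # offsets into full_text (0-based, half-open); title is 12 chars + tab
  starts <- vapply(surfaces, function(s) {
    as.integer(regexpr(s, substr(full_text, 14, nchar(full_text)), fixed = TRUE)) + 12L
  }, integer(1))
  entities <- tibble::tibble(
    doc_id = "1001",
    mention_id = c("T1", "T2", "T3", "T4"),
    etype = c("CHEMICAL", "CHEMICAL", "GENE-Y", "GENE-N"),
    start = unname(starts),
    end = unname(starts) + nchar(surfaces),
    surface = surfaces,
    norm_id = c("MESH:D010126", "MESH:D009569", "3569", NA)
  )
  relations <- tibble::tibble(
    doc_id = "1001",
    rtype = c("INDIRECT-UPREGULATOR", "INDIRECT-UPREGULATOR"),
    arg1 = c("T1", "T2"), arg2 = c("T3", "T3")
  )
  list(documents = documents, entities = entities, relations = relations)
}

write_tiny_corpus <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  cx <- tiny_corpus()
  d <- cx$documents
  writeLines(sprintf("%s\t%s\t%s", d$doc_id, d$title, d$abstract),
             file.path(dir, "abstracts.tsv"), useBytes = TRUE)
  e <- cx$entities
  writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s", e$doc_id, e$mention_id, e$etype,
                     e$start, e$end, e$surface, ifelse(is.na(e$norm_id), "", e$norm_id)),
             file.path(dir, "entities.tsv"), useBytes = TRUE)
  r <- cx$relations
  writeLines(sprintf("%s\t%s\tArg1:%s\tArg2:%s", r$doc_id, r$rtype, r$arg1, r$arg2),
             file.path(dir, "relations.tsv"), useBytes = TRUE)
  dir
}

# Random single-document corpus used for pair-enumeration oracles: a few
# sentences, each with a random number of chemical and gene mentions.
random_annotated_doc <- function(doc_id, n_sent = sample(1:4, 1)) {
  sent_parts <- character(n_sent)
  ents <- list()
  cursor <- NA_integer_
  title <- sprintf("Random doc %s.", doc_id)
  cursor <- nchar(title) + 1L
  t_id <- 0L
  for (s in seq_len(n_sent)) {
    n_chem <- sample(0:3, 1)
    n_gene <- sample(0:2, 1)
    words <- c(
      sprintf("drug%d%s", seq_len(n_chem), letters[s]),
      sprintf("prot%d%s", seq_len(n_gene), letters[s])
    )
    # leading capitalized filler keeps sentence starts detectable
    words <- c("Xq", sample(c(words, "binds", "cells")))
    sent <- paste0(paste(words, collapse = " "), ".")
    for (w_i in seq_along(words)) {
      w <- words[w_i]
      if (!grepl("^(drug|prot)", w)) next
      t_id <- t_id + 1L
      off <- cursor + nchar(paste(words[seq_len(w_i - 1)], collapse = " ")) +
        (if (w_i > 1) 1L else 0L)
      ents[[length(ents) + 1]] <- tibble::tibble(
        doc_id = doc_id, mention_id = paste0("T", t_id),
        etype = if (grepl("^drug", w)) "CHEMICAL" else sample(c("GENE-Y", "GENE-N"), 1),
        start = off, end = off + nchar(w), surface = w, norm_id = NA_character_,
        sent = s
      )
    }
    sent_parts[s] <- sent
    cursor <- cursor + nchar(sent) + 1L
  }
  abstract <- paste(sent_parts, collapse = " ")
  empty_ents <- tibble::tibble(
    doc_id = character(), mention_id = character(), etype = character(),
    start = integer(), end = integer(), surface = character(),
    norm_id = character(), sent = integer()
  )
  list(
    document = tibble::tibble(doc_id = doc_id, title = title, abstract = abstract,
                              full_text = paste(title, abstract, sep = "\t")),
    entities = dplyr::bind_rows(c(list(empty_ents), ents))
  )
}
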