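#' Split a document into sentence spans
#'
#' Returns 0-based, half-open character intervals over `full_text`. The
#' title (the text before the tab separating title from abstract) is
#' always its own sentence; the abstract is split with the package's
#' boundary rule. Spans are trimmed of surrounding whitespace, sorted and
#' non-overlapping, and jointly cover all non-whitespace text.
#'
#' @param full_text Document text as built by [read_abstracts()]
#'   (title, a single tab, abstract).
#' @return A tibble with integer columns `start`, `end`.
#' @export
split_sentences <- function(full_text) {
  stopifnot(length(full_text) == 1)
  tab_pos <- regexpr("\t", full_text, fixed = TRUE)
  if (tab_pos == -1) {
    return(split_text_spans(full_text))
  }
  title <- substr(full_text, 1L, tab_pos - 1L)
  abstract <- substr(full_text, tab_pos + 1L, nchar(full_text))
  title_span <- if (nzchar(trimws(title))) {
    lead <- nchar(title) - nchar(sub("^[ \t]+", "", title))
    trail <- nchar(title) - nchar(sub("[ \t]+$", "", title))
    tibble(start = lead, end = nchar(title) - trail)
  } else {
    tibble(start = integer(), end = integer())
  }
  abs_spans <- split_text_spans(abstract)
  abs_spans$start <- abs_spans$start + as.integer(tab_pos) # tab_pos = nchar(title) + 1 - 1 + 1
  abs_spans$end <- abs_spans$end + as.integer(tab_pos)
  bind_rows(title_span, abs_spans)
}

#' Generate marker-tagged relation instances
#'
#' Builds exactly one candidate instance per (chemical mention, gene
#' mention) pair whose spans both fall inside the same sentence. The
#' sentence is tagged with the four entity markers (`[HEAD-S]`,
#' `[HEAD-E]` around the chemical; `[TAIL-S]`, `[TAIL-E]` around the
#' gene), each followed/preceded by a single space so that deleting the
#' marker-plus-space strings recovers the original sentence byte for
#' byte. The 13-dimensional multi-hot label has a 1 for every gold
#' relation type annotated on the pair; candidate pairs with no gold
#' relation carry the all-zero label (there is no explicit NONE class).
#'
#' Gold relations whose two arguments never share a sentence cannot be
#' represented as same-sentence instances; they are counted in the
#' `unreachable_gold` attribute because they bound attainable recall.
#' Pairs with overlapping chemical/gene spans are skipped with a warning.
#' Mentions that straddle the title/abstract tab separator raise an
#' error; mentions that straddle an internal sentence boundary are
#' dropped from pairing with a warning.
#'
#' @param documents,entities,relations Corpus tibbles (see `read_*`).
#' @return A tibble of class `dti_instances` with columns `instance_id`,
#'   `doc_id`, `head_id`, `tail_id`, `head_norm_id`, `tail_norm_id`,
#'   `sentence`, `marked_text`, `model_text` (initially equal to
#'   `marked_text`), `chem_desc`, `gene_desc` (initially `""`) and
#'   `label` (list-column of named 0/1 integer vectors of length 13).
#'   Attribute `unreachable_gold` counts cross-sentence gold relations.
#' @export
generate_instances <- function(documents, entities, relations) {
  validate_entity_offsets(entities, documents)
  assert_relation_types(relations$rtype)
  per_doc <- lapply(seq_len(nrow(documents)), function(i) {
    doc <- documents[i, ]
    generate_doc_instances(
      doc,
      entities[entities$doc_id == doc$doc_id, , drop = FALSE],
      relations[relations$doc_id == doc$doc_id, , drop = FALSE]
    )
  })
  inst <- bind_rows(lapply(per_doc, `[[`, "instances"))
  if (nrow(inst) == 0) {
    inst <- empty_instances()
  }
  reachable_keys <- paste(inst$doc_id, inst$head_id, inst$tail_id)
  gold_keys <- paste(relations$doc_id, relations$arg1, relations$arg2)
  unreachable <- sum(!(unique(gold_keys) %in% reachable_keys))
  if (unreachable > 0) {
    inform(sprintf(
      "%d gold relation pair(s) never share a sentence and cannot be recovered by same-sentence instances",
      unreachable
    ))
  }
  attr(inst, "unreachable_gold") <- unreachable
  class(inst) <- c("dti_instances", class(inst))
  inst
}

empty_instances <- function() {
  tibble(
    instance_id = character(), doc_id = character(),
    head_id = character(), tail_id = character(),
    head_norm_id = character(), tail_norm_id = character(),
    sentence = character(), marked_text = character(),
    model_text = character(), chem_desc = character(),
    gene_desc = character(), label = list()
  )
}

generate_doc_instances <- function(doc, entities, relations) {
  spans <- split_sentences(doc$full_text)
  tab_pos0 <- regexpr("\t", doc$full_text, fixed = TRUE) - 1L # 0-based tab offset
  if (tab_pos0 >= 0) {
    straddle <- entities$start <= tab_pos0 & entities$end > tab_pos0
    if (any(straddle)) {
      abort(sprintf(
        "Mention '%s' in document %s spans the title/abstract separator",
        entities$mention_id[which(straddle)[1]], doc$doc_id
      ))
    }
  }
  # assign each mention to the sentence that fully contains it
  sent_of <- vapply(seq_len(nrow(entities)), function(i) {
    j <- which(spans$start <= entities$start[i] & entities$end[i] <= spans$end)
    if (length(j) == 0) NA_integer_ else j[1]
  }, integer(1))
  if (any(is.na(sent_of)) && nrow(entities) > 0) {
    warn(sprintf(
      "%d mention(s) in document %s straddle a sentence boundary and are excluded from pairing",
      sum(is.na(sent_of)), doc$doc_id
    ))
  }
  chems <- which(entities$etype == "CHEMICAL" & !is.na(sent_of))
  genes <- which(entities$etype %in% c("GENE-Y", "GENE-N") & !is.na(sent_of))
  if (length(chems) == 0 || length(genes) == 0) {
    return(list(instances = empty_instances()))
  }
  pairs <- expand.grid(ci = chems, gi = genes)
  pairs <- pairs[sent_of[pairs$ci] == sent_of[pairs$gi], , drop = FALSE]
  if (nrow(pairs) == 0) return(list(instances = empty_instances()))

  label_template <- setNames(integer(13), relation_types())
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    ci <- pairs$ci[k]; gi <- pairs$gi[k]
    if (entities$start[ci] < entities$end[gi] && entities$start[gi] < entities$end[ci]) {
      warn(sprintf(
        "Overlapping chemical/gene spans (%s, %s) in document %s: pair skipped",
        entities$mention_id[ci], entities$mention_id[gi], doc$doc_id
      ))
      return(NULL)
    }
    s <- spans[sent_of[ci], ]
    sentence <- substr(doc$full_text, s$start + 1L, s$end)
    marked <- insert_markers(
      sentence,
      head_start = entities$start[ci] - s$start, head_end = entities$end[ci] - s$start,
      tail_start = entities$start[gi] - s$start, tail_end = entities$end[gi] - s$start
    )
    gold <- relations$rtype[relations$arg1 == entities$mention_id[ci] &
      relations$arg2 == entities$mention_id[gi]]
    label <- label_template
    label[unique(gold)] <- 1L
    tibble(
      instance_id = paste(doc$doc_id, entities$mention_id[ci], entities$mention_id[gi], sep = ":"),
      doc_id = doc$doc_id,
      head_id = entities$mention_id[ci], tail_id = entities$mention_id[gi],
      head_norm_id = entities$norm_id[ci], tail_norm_id = entities$norm_id[gi],
      sentence = sentence, marked_text = marked, model_text = marked,
      chem_desc = "", gene_desc = "",
      label = list(label),
      .sent_start = s$start, .head_start = entities$start[ci], .tail_start = entities$start[gi]
    )
  })
  inst <- bind_rows(rows)
  if (nrow(inst) == 0) return(list(instances = empty_instances()))
  inst <- arrange(inst, .data$.sent_start, .data$.head_start, .data$.tail_start)
  inst <- select(inst, -".sent_start", -".head_start", -".tail_start")
  list(instances = inst)
}

# Insert the four marker tokens into `sentence` at the given 0-based
# offsets (relative to the sentence). Marker start tokens are written as
# "<MARK> " and end tokens as " <MARK>", so removing the fixed
# marker-with-space strings restores the sentence exactly.
insert_markers <- function(sentence, head_start, head_end, tail_start, tail_end) {
  mk <- marker_tokens()
  piece <- function(a, b) substr(sentence, a + 1L, b) # 0-based half-open
  n <- nchar(sentence)
  if (head_end <= tail_start) {
    paste0(
      piece(0, head_start), mk[["head_start"]], " ", piece(head_start, head_end),
      " ", mk[["head_end"]], piece(head_end, tail_start),
      mk[["tail_start"]], " ", piece(tail_start, tail_end),
      " ", mk[["tail_end"]], piece(tail_end, n)
    )
  } else {
    paste0(
      piece(0, tail_start), mk[["tail_start"]], " ", piece(tail_start, tail_end),
      " ", mk[["tail_end"]], piece(tail_end, head_start),
      mk[["head_start"]], " ", piece(head_start, head_end),
      " ", mk[["head_end"]], piece(head_end, n)
    )
  }
}

#' Remove entity markers from marked text
#'
#' Inverse of the marker insertion performed by [generate_instances()];
#' recovers the original sentence exactly.
#'
#' @param marked_text Character vector.
#' @return Character vector with the four marker tokens (and the single
#'   spaces inserted with them) removed.
#' @export
strip_markers <- function(marked_text) {
  mk <- marker_tokens()
  out <- marked_text
  out <- gsub(paste0(mk[["head_start"]], " "), "", out, fixed = TRUE)
  out <- gsub(paste0(" ", mk[["head_end"]]), "", out, fixed = TRUE)
  out <- gsub(paste0(mk[["tail_start"]], " "), "", out, fixed = TRUE)
  out <- gsub(paste0(" ", mk[["tail_end"]]), "", out, fixed = TRUE)
  out
}

#' Append entity descriptions to instance text
#'
#' Looks up the chemical definition (by MeSH ID) and the gene summary
#' (by NCBI Gene ID) for each instance and rebuilds `model_text` as
#' `marked_text [SEP] chem_desc [SEP] gene_desc`. Mentions without a
#' normalized identifier (GENE-N) or without a table entry contribute an
#' empty description; with both descriptions empty and no token budget
#' pressure, `model_text` reduces to `marked_text` unchanged.
#'
#' A whitespace-token budget caps the augmented text: the marked sentence
#' is always kept whole (it carries the label signal), then the chemical
#' description, then the gene description is truncated to fit.
#'
#' @param instances A `dti_instances` tibble.
#' @param chem_table,gene_table Description tables from
#'   [load_description_table()]; `NULL` disables that augmentation.
#' @param max_tokens Whitespace-token budget for `model_text`
#'   (default 512).
#' @return The instances tibble with `chem_desc`, `gene_desc` and
#'   `model_text` filled in.
#' @export
augment_instances <- function(instances, chem_table = NULL, gene_table = NULL, max_tokens = 512) {
  chem_desc <- if (is.null(chem_table)) rep("", nrow(instances)) else lookup_description(instances$head_norm_id, chem_table)
  gene_desc <- if (is.null(gene_table)) rep("", nrow(instances)) else lookup_description(instances$tail_norm_id, gene_table)
  instances$chem_desc <- chem_desc
  instances$gene_desc <- gene_desc
  instances$model_text <- vapply(seq_len(nrow(instances)), function(i) {
    compose_model_text(instances$marked_text[i], chem_desc[i], gene_desc[i], max_tokens)
  }, character(1))
  instances
}

compose_model_text <- function(marked_text, chem_desc, gene_desc, max_tokens) {
  if (!nzchar(chem_desc) && !nzchar(gene_desc)) return(marked_text)
  n_tok <- function(x) if (!nzchar(x)) 0L else length(strsplit(trimws(x), "[ \t\n]+")[[1]])
  trunc_tok <- function(x, k) {
    if (k <= 0L) return("")
    toks <- strsplit(trimws(x), "[ \t\n]+")[[1]]
    paste(toks[seq_len(min(k, length(toks)))], collapse = " ")
  }
  budget <- max_tokens - n_tok(marked_text)
  parts <- marked_text
  if (nzchar(chem_desc)) {
    budget <- budget - 1L # [SEP]
    kept <- trunc_tok(chem_desc, budget)
    budget <- budget - n_tok(kept)
    if (nzchar(kept)) parts <- paste(parts, "[SEP]", kept)
  }
  if (nzchar(gene_desc)) {
    budget <- budget - 1L
    kept <- trunc_tok(gene_desc, budget)
    if (nzchar(kept)) parts <- paste(parts, "[SEP]", kept)
  }
  parts
}

#' Stack instance labels into a matrix
#'
#' @param instances A `dti_instances` tibble.
#' @return An integer matrix, one row per instance, 13 columns named by
#'   [relation_types()].
#' @export
label_matrix <- function(instances) {
  if (nrow(instances) == 0) {
    return(matrix(integer(), ncol = 13, dimnames = list(NULL, relation_types())))
  }
  out <- do.call(rbind, instances$label)
  colnames(out) <- relation_types()
  rownames(out) <- instances$instance_id
  out
}

#' Convert predicted or gold instance labels to relation tuples
#'
#' @param instances A `dti_instances` tibble.
#' @param labels Binary matrix aligned with `instances` rows (defaults to
#'   the instances' own gold labels).
#' @return Tibble with `doc_id`, `rtype`, `arg1`, `arg2` for every 1.
#' @export
instances_to_relations <- function(instances, labels = label_matrix(instances)) {
  idx <- which(labels == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble(doc_id = character(), rtype = character(), arg1 = character(), arg2 = character()))
  }
  tibble(
    doc_id = instances$doc_id[idx[, 1]],
    rtype = colnames(labels)[idx[, 2]],
    arg1 = instances$head_id[idx[, 1]],
    arg2 = instances$tail_id[idx[, 1]]
  ) |> arrange(.data$doc_id, .data$rtype, .data$arg1, .data$arg2)
}
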