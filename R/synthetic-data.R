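#' Class prior mirroring the DrugProt training-set skew
#'
#' A heavily imbalanced distribution over the 13 relation types, built
#' from the published training-set counts where stated (INHIBITOR 5388,
#' DIRECT-REGULATOR 2247, AGONIST-INHIBITOR 13, SUBSTRATE_PRODUCT-OF 24,
#' AGONIST-ACTIVATOR 29) and plausible mid-range counts for the
#' remaining types, normalized to sum to 1. INHIBITOR dominates;
#' AGONIST-INHIBITOR sits near 0.1%, which is what makes the rare-class
#' threshold override worth testing.
#'
#' @return Named numeric vector of length 13 summing to 1.
#' @export
drugprot_class_prior <- function() {
  counts <- c(
    "INDIRECT-DOWNREGULATOR" = 1330, "INDIRECT-UPREGULATOR" = 1379,
    "DIRECT-REGULATOR" = 2247, "ACTIVATOR" = 1429, "INHIBITOR" = 5388,
    "AGONIST" = 659, "ANTAGONIST" = 972, "AGONIST-ACTIVATOR" = 29,
    "AGONIST-INHIBITOR" = 13, "PRODUCT-OF" = 921, "SUBSTRATE" = 2003,
    "SUBSTRATE_PRODUCT-OF" = 24, "PART-OF" = 886
  )
  counts[relation_types()] / sum(counts)
}

#' Trigger lexicon
#'
#' One unique, otherwise-unused lexeme per relation class. When a
#' generated relation sentence carries its class trigger the corpus is
#' linearly separable by construction in any bag-of-tokens feature
#' space, which turns end-to-end learnability tests into a constructive
#' guarantee rather than an empirical hope.
#'
#' @return Named character vector (names are relation types).
#' @export
trigger_lexicon <- function() {
  setNames(paste0("xx", tolower(gsub("[^A-Za-z]", "", relation_types()))), relation_types())
}

#' Configuration for the synthetic corpus generator
#'
#' @param n_docs Number of documents.
#' @param sentences_per_doc Integer range `c(min, max)` of abstract
#'   sentences per document.
#' @param class_distribution Probability of each relation type for a
#'   positive pair; must sum to 1 (default [drugprot_class_prior()]).
#' @param negative_pair_rate Probability that a generated
#'   chemical-gene sentence carries no gold relation.
#' @param trigger_strength Probability that a relation sentence contains
#'   its class trigger lexeme.
#' @param description_informativeness Probability that, when the
#'   sentence trigger was withheld, the gene's description embeds the
#'   class cue instead (emulating abstracts where the interaction type
#'   is only inferable from what is known about the gene).
#' @param gene_n_rate Fraction of gene mentions that are GENE-N
#'   (non-normalizable, hence without descriptions).
#' @param label_flip_rate Probability of re-sampling a positive pair's
#'   class uniformly (simple annotation-noise knob), default 0.
#' @param chem_pool,gene_pool Number of distinct chemical and gene
#'   surface names the corpus draws from. Names recur across documents
#'   -- as compound and gene symbols do in real abstracts -- so a
#'   classifier cannot memorize entity names and must rely on the
#'   recurring lexical signal. Chemicals keep one MeSH ID per surface;
#'   gene mentions receive mention-unique NCBI Gene IDs (gene symbols
#'   are ambiguous; the normalizer is assumed to have resolved each
#'   occurrence), which is what lets gene descriptions carry
#'   pair-specific cues.
#' @param vocab_size Size of the filler vocabulary.
#' @param seed Integer seed; all randomness in the generator flows from
#'   it.
#' @return A validated list of class `dti_sim_config`.
#' @export
synthetic_corpus_config <- function(n_docs = 100, sentences_per_doc = c(2, 5),
                                    class_distribution = drugprot_class_prior(),
                                    negative_pair_rate = 0.3,
                                    trigger_strength = 1,
                                    description_informativeness = 0,
                                    gene_n_rate = 0.1,
                                    label_flip_rate = 0,
                                    chem_pool = 40, gene_pool = 40,
                                    vocab_size = 200, seed = 1) {
  if (n_docs < 1) abort("n_docs must be >= 1")
  assert_relation_types(names(class_distribution), "class_distribution name")
  if (abs(sum(class_distribution) - 1) > 1e-8) abort("class_distribution must sum to 1")
  probs <- c(negative_pair_rate, trigger_strength, description_informativeness,
             gene_n_rate, label_flip_rate)
  if (any(probs < 0 | probs > 1)) abort("All rate parameters must lie in [0, 1]")
  structure(list(
    n_docs = as.integer(n_docs), sentences_per_doc = as.integer(sentences_per_doc),
    class_distribution = class_distribution[relation_types()],
    negative_pair_rate = negative_pair_rate, trigger_strength = trigger_strength,
    description_informativeness = description_informativeness,
    gene_n_rate = gene_n_rate, label_flip_rate = label_flip_rate,
    chem_pool = as.integer(chem_pool), gene_pool = as.integer(gene_pool),
    vocab_size = as.integer(vocab_size), seed = as.integer(seed)
  ), class = "dti_sim_config")
}

#' Generate a synthetic DrugProt-format corpus
#'
#' Builds seeded documents whose abstract sentences each contain one
#' chemical and one gene mention plus filler words. Each sentence is
#' either a negative pair (neutral verb, no gold relation) or a positive
#' pair whose class is drawn from `class_distribution`; with probability
#' `trigger_strength` the sentence contains the class trigger lexeme,
#' otherwise the verb is neutral and the signal can only be planted in
#' the gene's description by [generate_description_tables()]. Offsets
#' follow the package's corpus dialect (0-based, half-open, over
#' title-TAB-abstract) and round-trip through the `read_*` functions.
#'
#' The returned ledger records every generated pair: its class (or `NA`
#' for negatives) and where its signal lives (`"sentence"`,
#' `"description"` when delegated to the description table, `"none"`).
#' The ledger is a complete oracle for corpus statistics.
#'
#' @param config A `dti_sim_config`.
#' @return List of class `dti_synthetic_corpus`: tibbles `documents`,
#'   `entities`, `relations`, `ledger`, plus the `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "dti_sim_config"))
  withr_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  filler <- sprintf("w%03d", seq_len(config$vocab_size))
  chem_names <- sprintf("chem%02d", seq_len(config$chem_pool))
  gene_names <- sprintf("gene%02d", seq_len(config$gene_pool))
  triggers <- trigger_lexicon()
  neutral_verbs <- c("was measured with", "was observed alongside", "was assayed with")
  docs <- list(); ents <- list(); rels <- list(); ledg <- list()
  pair_counter <- 0L
  for (d in seq_len(config$n_docs)) {
    doc_id <- sprintf("9%06d", d)
    title <- sprintf("Report %d on compound protein interaction screening.", d)
    n_sent <- sample(config$sentences_per_doc[1]:config$sentences_per_doc[2], 1)
    sent_texts <- character(n_sent)
    doc_ents <- list(); doc_rels <- list()
    cursor <- nchar(title) + 1L # 0-based offset where the abstract begins
    for (s in seq_len(n_sent)) {
      pair_counter <- pair_counter + 1L
      chem_i <- sample(config$chem_pool, 1)
      chem <- chem_names[chem_i]
      gene <- sample(gene_names, 1)
      chem_norm <- sprintf("MESH:D%06d", chem_i) # one MeSH ID per chemical surface
      is_gene_n <- runif(1) < config$gene_n_rate
      gene_norm <- if (is_gene_n) NA_character_ else sprintf("%d", 100000 + pair_counter)
      is_negative <- runif(1) < config$negative_pair_rate
      rtype <- NA_character_; signal <- "none"; verb <- sample(neutral_verbs, 1)
      if (!is_negative) {
        rtype <- sample(relation_types(), 1, prob = config$class_distribution)
        if (config$label_flip_rate > 0 && runif(1) < config$label_flip_rate) {
          rtype <- sample(relation_types(), 1)
        }
        if (runif(1) < config$trigger_strength) {
          verb <- paste(triggers[[rtype]], "the target")
          signal <- "sentence"
        }
      }
      pad <- paste(sample(filler, 3), collapse = " ")
      prefix <- "The compound "
      mid <- sprintf(" %s ", verb)
      suffix <- sprintf(" in %s cells.", pad)
      sent_texts[s] <- paste0(prefix, chem, mid, gene, suffix)
      chem_start <- cursor + nchar(prefix)
      gene_start <- chem_start + nchar(chem) + nchar(mid)
      chem_mid <- paste0("T", 2L * s - 1L)
      gene_mid <- paste0("T", 2L * s)
      doc_ents[[s]] <- tibble(
        doc_id = doc_id, mention_id = c(chem_mid, gene_mid),
        etype = c("CHEMICAL", if (is_gene_n) "GENE-N" else "GENE-Y"),
        start = c(chem_start, gene_start),
        end = c(chem_start + nchar(chem), gene_start + nchar(gene)),
        surface = c(chem, gene), norm_id = c(chem_norm, gene_norm)
      )
      ledg[[pair_counter]] <- tibble(
        doc_id = doc_id, chem_id = chem_mid, gene_id = gene_mid,
        chem = chem, gene = gene, chem_norm = chem_norm, gene_norm = gene_norm,
        rtype = rtype, signal = signal, gene_is_normalizable = !is_gene_n
      )
      if (!is.na(rtype)) {
        doc_rels[[s]] <- tibble(doc_id = doc_id, rtype = rtype, arg1 = chem_mid, arg2 = gene_mid)
      }
      cursor <- cursor + nchar(sent_texts[s]) + 1L # joined with a single space
    }
    abstract <- paste(sent_texts, collapse = " ")
    docs[[d]] <- tibble(doc_id = doc_id, title = title, abstract = abstract,
                        full_text = paste(title, abstract, sep = "\t"))
    ents[[d]] <- bind_rows(doc_ents)
    rels[[d]] <- bind_rows(doc_rels)
  }
  empty_rel <- tibble(doc_id = character(), rtype = character(), arg1 = character(), arg2 = character())
  structure(list(
    documents = bind_rows(docs), entities = bind_rows(ents),
    relations = bind_rows(c(list(empty_rel), rels)), ledger = bind_rows(ledg),
    config = config
  ), class = "dti_synthetic_corpus")
}

#' Generate description tables for a synthetic corpus
#'
#' Every normalized entity receives a description. Gene descriptions of
#' positive pairs whose sentence signal was withheld embed the class cue
#' lexeme with probability `description_informativeness`, emulating the
#' situation where a relation is invisible from the sentence alone but
#' inferable from what is known about the gene. The ledger's `signal`
#' column is updated (`"description"`) for pairs whose cue was planted.
#'
#' @param corpus A `dti_synthetic_corpus`.
#' @return The corpus with `chem_table` and `gene_table` tibbles added
#'   and the ledger updated.
#' @export
generate_description_tables <- function(corpus) {
  config <- corpus$config
  withr_seed(config$seed + 104729L, {
    led <- corpus$ledger
    triggers <- trigger_lexicon()
    chem_table <- tibble(
      key = unique(led$chem_norm),
      text = sprintf("%s is a synthetic small molecule prepared for screening.",
                     led$chem[match(unique(led$chem_norm), led$chem_norm)]),
      source = "CTD_CHEMICAL"
    )
    gene_rows <- led[!is.na(led$gene_norm), , drop = FALSE]
    cue <- character(nrow(gene_rows))
    new_signal <- gene_rows$signal
    for (i in seq_len(nrow(gene_rows))) {
      informative <- !is.na(gene_rows$rtype[i]) && gene_rows$signal[i] == "none" &&
        runif(1) < config$description_informativeness
      if (informative) {
        cue[i] <- paste("It mediates", triggers[[gene_rows$rtype[i]]], "signaling.")
        new_signal[i] <- "description"
      } else {
        cue[i] <- "It participates in general cellular signaling."
      }
    }
    gene_table <- tibble(
      key = gene_rows$gene_norm,
      text = sprintf("%s is a synthetic protein. %s", gene_rows$gene, cue),
      source = "ENTREZ_GENE"
    )
    led$signal[match(gene_rows$gene_norm, led$gene_norm)] <- new_signal
    corpus$ledger <- led
    corpus$chem_table <- chem_table
    corpus$gene_table <- gene_table
    corpus
  })
}

#' Generate random protein sequences for a synthetic corpus
#'
#' One uniformly random amino acid sequence per normalizable gene, with
#' lengths drawn from `length_range`; seeded from the corpus config.
#'
#' @param corpus A `dti_synthetic_corpus`.
#' @param length_range Integer range `c(min, max)` of sequence lengths.
#' @return The corpus with a `sequences` tibble (`id` = gene norm ID,
#'   `seq`) added.
#' @export
generate_fasta_sequences <- function(corpus, length_range = c(80, 300)) {
  config <- corpus$config
  ids <- unique(corpus$ledger$gene_norm[!is.na(corpus$ledger$gene_norm)])
  withr_seed(config$seed + 7919L, {
    seqs <- vapply(ids, function(id) {
      paste(sample(amino_acids(), sample(length_range[1]:length_range[2], 1), replace = TRUE),
            collapse = "")
    }, character(1))
    corpus$sequences <- tibble(id = ids, seq = unname(seqs))
    corpus
  })
}

#' Write a synthetic corpus to DrugProt-format files
#'
#' Writes `abstracts.tsv`, `entities.tsv`, `relations.tsv`, the
#' description tables (`chem_descriptions.tsv`, `gene_descriptions.tsv`
#' when present), `sequences.fasta` (when present) and `ledger.json`
#' into `dir`.
#'
#' @param corpus A `dti_synthetic_corpus`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    abstracts = file.path(dir, "abstracts.tsv"),
    entities = file.path(dir, "entities.tsv"),
    relations = file.path(dir, "relations.tsv"),
    ledger = file.path(dir, "ledger.json")
  )
  d <- corpus$documents
  writeLines(sprintf("%s\t%s\t%s", d$doc_id, d$title, d$abstract), paths[["abstracts"]], useBytes = TRUE)
  e <- corpus$entities
  writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s", e$doc_id, e$mention_id, e$etype,
                     e$start, e$end, e$surface, ifelse(is.na(e$norm_id), "", e$norm_id)),
             paths[["entities"]], useBytes = TRUE)
  r <- corpus$relations
  writeLines(sprintf("%s\t%s\tArg1:%s\tArg2:%s", r$doc_id, r$rtype, r$arg1, r$arg2),
             paths[["relations"]], useBytes = TRUE)
  jsonlite::write_json(corpus$ledger, paths[["ledger"]], dataframe = "rows", na = "null")
  if (!is.null(corpus$chem_table)) {
    p <- file.path(dir, "chem_descriptions.tsv")
    writeLines(sprintf("%s\t%s", corpus$chem_table$key, corpus$chem_table$text), p, useBytes = TRUE)
    paths <- c(paths, chem_descriptions = p)
  }
  if (!is.null(corpus$gene_table)) {
    p <- file.path(dir, "gene_descriptions.tsv")
    writeLines(sprintf("%s\t%s", corpus$gene_table$key, corpus$gene_table$text), p, useBytes = TRUE)
    paths <- c(paths, gene_descriptions = p)
  }
  if (!is.null(corpus$sequences)) {
    p <- file.path(dir, "sequences.fasta")
    seqinr::write.fasta(as.list(corpus$sequences$seq), corpus$sequences$id, p)
    paths <- c(paths, sequences = p)
  }
  invisible(paths)
}
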