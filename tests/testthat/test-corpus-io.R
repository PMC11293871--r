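test_that("read_abstracts parses documents and derives full_text", {
  dir <- write_tiny_corpus()
  docs <- read_abstracts(file.path(dir, "abstracts.tsv"))
  expect_equal(nrow(docs), 1)
  expect_equal(docs$doc_id, "1001")
  expect_equal(docs$full_text, paste(docs$title, docs$abstract, sep = "\t"))

  # several lines, file order preserved
  p <- withr::local_tempfile()
  writeLines(c("1\tA title.\tBody one.", "2\tB title.\tBody two.", "3\tC.\tBody three."), p)
  docs3 <- read_abstracts(p)
  expect_equal(docs3$doc_id, c("1", "2", "3"))

  # empty file
  p2 <- withr::local_tempfile()
  writeLines(character(), p2)
  expect_equal(nrow(read_abstracts(p2)), 0)
})

test_that("read_abstracts rejects malformed lines and duplicate ids", {
  p <- withr::local_tempfile()
  writeLines(c("1\tTitle.\tBody.", "2\tonly-two-fields"), p)
  expect_error(read_abstracts(p), "line 2")
  p2 <- withr::local_tempfile()
  writeLines(c("1\tT.\tB.", "1\tT.\tB."), p2)
  expect_error(read_abstracts(p2), "Duplicate doc_id")
})

test_that("read_entities maps fields and validates offsets against documents", {
  dir <- write_tiny_corpus()
  docs <- read_abstracts(file.path(dir, "abstracts.tsv"))
  ents <- read_entities(file.path(dir, "entities.tsv"), documents = docs)
  expect_equal(nrow(ents), 4)
  expect_equal(ents$etype[1], "CHEMICAL")
  expect_true(is.na(ents$norm_id[4])) # GENE-N has no normalized id
  expect_equal(
    unname(substring(docs$full_text, ents$start + 1, ents$end)),
    ents$surface
  )

  # unknown entity type
  p <- withr::local_tempfile()
  writeLines("1001\tT1\tPROTEIN\t0\t5\tOzone", p)
  expect_error(read_entities(p), "PROTEIN")

  # offsets pointing at the wrong surface
  p2 <- withr::local_tempfile()
  writeLines("1001\tT1\tCHEMICAL\t0\t5\tWRONG", p2)
  expect_error(read_entities(p2, documents = docs), "T1")
})

test_that("read_relations strips Arg prefixes and validates the enum", {
  dir <- write_tiny_corpus()
  rel <- read_relations(file.path(dir, "relations.tsv"))
  expect_equal(nrow(rel), 2)
  expect_equal(rel$arg1, c("T1", "T2"))
  expect_equal(rel$arg2, c("T3", "T3"))

  p <- withr::local_tempfile()
  writeLines("1001\tREGULATOR\tArg1:T1\tArg2:T3", p)
  expect_error(read_relations(p), "REGULATOR")

  # dangling mention id when entities supplied
  ents <- read_entities(file.path(dir, "entities.tsv"))
  p2 <- withr::local_tempfile()
  writeLines("1001\tINHIBITOR\tArg1:T99\tArg2:T3", p2)
  expect_error(read_relations(p2, entities = ents), "T99")
  # Arg1 must be a chemical
  p3 <- withr::local_tempfile()
  writeLines("1001\tINHIBITOR\tArg1:T3\tArg2:T4", p3)
  expect_error(read_relations(p3, entities = ents), "CHEMICAL")
})

test_that("write_predictions deduplicates, sorts, and round-trips", {
  preds <- tibble::tibble(
    doc_id = c("2", "1", "1", "1"),
    rtype = c("INHIBITOR", "ACTIVATOR", "ACTIVATOR", "AGONIST"),
    arg1 = c("T1", "T5", "T5", "T1"),
    arg2 = c("T2", "T6", "T6", "T2")
  )
  p <- withr::local_tempfile()
  out <- write_predictions(preds, p)
  lines <- readLines(p)
  expect_length(lines, 3) # duplicate removed
  expect_equal(lines[1], "1\tACTIVATOR\tArg1:T5\tArg2:T6")
  back <- read_relations(p)
  expect_equal(
    dplyr::arrange(dplyr::distinct(preds), doc_id, rtype, arg1, arg2),
    dplyr::arrange(back, doc_id, rtype, arg1, arg2)
  )
})

test_that("corpus files written by the generator round-trip exactly", {
  cfg <- synthetic_corpus_config(n_docs = 12, seed = 5)
  corp <- generate_corpus(cfg)
  dir <- withr::local_tempdir()
  write_corpus(corp, dir)
  docs <- read_abstracts(file.path(dir, "abstracts.tsv"))
  ents <- read_entities(file.path(dir, "entities.tsv"), documents = docs)
  rels <- read_relations(file.path(dir, "relations.tsv"), entities = ents)
  expect_equal(docs, corp$documents)
  expect_equal(ents, corp$entities)
  expect_equal(as.data.frame(rels), as.data.frame(corp$relations))
})

test_that("corpus_stats counts documents, mentions and relations exactly", {
  empty <- corpus_stats(
    tibble::tibble(doc_id = character()),
    tibble::tibble(etype = character()),
    tibble::tibble(rtype = character())
  )
  expect_equal(empty$n_documents, 0)
  expect_equal(sum(empty$relation_counts$n), 0)

  # generator ledger is the ground truth for counts
  cfg <- synthetic_corpus_config(n_docs = 40, seed = 9)
  corp <- generate_corpus(cfg)
  st <- corpus_stats(corp$documents, corp$entities, corp$relations)
  expect_equal(st$n_documents, 40)
  expect_equal(st$n_chemical_mentions, sum(corp$entities$etype == "CHEMICAL"))
  ledger_counts <- table(corp$ledger$rtype[!is.na(corp$ledger$rtype)])
  for (rt in names(ledger_counts)) {
    expect_equal(
      st$relation_counts$n[st$relation_counts$rtype == rt],
      as.integer(ledger_counts[[rt]])
    )
  }
  expect_equal(sum(st$relation_counts$n), nrow(corp$relations))
  expect_equal(tidy(st), st$relation_counts)
})

test_that("relation counts of a DrugProt-format file are reproduced exactly", {
  # fixture with a known, skewed class distribution written in the
  # exchange format, then recounted through the package reader
  set.seed(42)
  n_per <- c(INHIBITOR = 53, `DIRECT-REGULATOR` = 22, `AGONIST-INHIBITOR` = 1)
  rows <- unlist(lapply(names(n_per), function(rt) {
    sprintf("%d\t%s\tArg1:T1\tArg2:T2", sample(1e6, n_per[[rt]]), rt)
  }))
  p <- withr::local_tempfile()
  writeLines(sample(rows), p)
  rel <- read_relations(p)
  st <- corpus_stats(tibble::tibble(doc_id = unique(rel$doc_id)),
                     tibble::tibble(etype = character()), rel)
  expect_equal(st$relation_counts$n[st$relation_counts$rtype == "INHIBITOR"], 53L)
  expect_equal(st$relation_counts$n[st$relation_counts$rtype == "DIRECT-REGULATOR"], 22L)
  expect_equal(st$relation_counts$n[st$relation_counts$rtype == "AGONIST-INHIBITOR"], 1L)
})
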