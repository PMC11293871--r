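#' End-to-end pipeline on a synthetic corpus
#'
#' Runs the full workflow with one configuration object: generate a
#' seeded corpus (with description tables and, for the SFTDE preset,
#' protein sequences), split documents into training and held-out sets,
#' build marker-tagged instances, attach descriptions according to the
#' chosen ensemble preset, train one classifier per seed, average the
#' member probabilities, threshold them into predictions and score them
#' against the held-out gold. Every artifact is written under `outdir`
#' and a run manifest (config snapshot, input digests, seeds, artifact
#' paths, package version) is written atomically at the end.
#'
#' Identical config and seed give an identical evaluation report.
#'
#' @param sim_config A `dti_sim_config` describing the corpus.
#' @param outdir Output directory for artifacts and the manifest.
#' @param preset Ensemble preset name (see [ensemble_preset()]).
#' @param seeds Integer vector of member training seeds.
#' @param encoder_dim Hashed encoder dimension (default 256).
#' @param epochs,learning_rate Training configuration.
#' @param loss `"focal"` (default) or `"bce"`.
#' @param test_fraction Fraction of documents held out for evaluation.
#' @return List of class `dti_run_manifest` with the evaluation report
#'   under `$report`.
#' @export
run_pipeline <- function(sim_config, outdir = tempfile("dti_run_"),
                         preset = "CGDE", seeds = c(1, 2, 3),
                         encoder_dim = 512, epochs = 1000, learning_rate = 0.3,
                         loss = "focal", test_fraction = 0.25) {
  t0 <- Sys.time()
  preset_cfg <- ensemble_preset(preset)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  # -- simulate ---------------------------------------------------------------
  corpus <- generate_corpus(sim_config)
  corpus <- generate_description_tables(corpus)
  if (preset_cfg$use_seq_features) corpus <- generate_fasta_sequences(corpus)
  corpus_dir <- file.path(outdir, "corpus")
  corpus_paths <- write_corpus(corpus, corpus_dir)

  # -- split ------------------------------------------------------------------
  n_docs <- nrow(corpus$documents)
  n_test <- max(1L, round(test_fraction * n_docs))
  test_ids <- withr_seed(sim_config$seed + 31L,
                         sample(corpus$documents$doc_id, n_test))
  split_of <- function(tab) list(
    train = tab[!(tab$doc_id %in% test_ids), , drop = FALSE],
    test = tab[tab$doc_id %in% test_ids, , drop = FALSE]
  )
  docs <- split_of(corpus$documents)
  ents <- split_of(corpus$entities)
  rels <- split_of(corpus$relations)

  # -- preprocess -------------------------------------------------------------
  make_instances <- function(d, e, r) {
    inst <- generate_instances(d, e, r)
    augment_instances(
      inst,
      chem_table = if (preset_cfg$use_chem_desc) corpus$chem_table else NULL,
      gene_table = if (preset_cfg$use_gene_desc) corpus$gene_table else NULL
    )
  }
  train_inst <- make_instances(docs$train, ents$train, rels$train)
  test_inst <- make_instances(docs$test, ents$test, rels$test)
  if (nrow(train_inst) == 0 || nrow(test_inst) == 0) {
    abort("Pipeline stage 'preprocess' failed: empty instance set after splitting")
  }

  # -- featurize --------------------------------------------------------------
  feats_for <- function(inst) {
    if (!preset_cfg$use_seq_features) return(NULL)
    feats <- featurize(setNames(corpus$sequences$seq, corpus$sequences$id), l2 = TRUE)
    fm <- feature_matrix(feats)
    idx <- match(inst$tail_norm_id, rownames(fm))
    out <- matrix(0, nrow = nrow(inst), ncol = ncol(fm))
    ok <- !is.na(idx)
    out[ok, ] <- fm[idx[ok], , drop = FALSE]
    out
  }
  train_feats <- feats_for(train_inst)
  test_feats <- feats_for(test_inst)

  # -- train x seeds ----------------------------------------------------------
  members <- lapply(seeds, function(s) {
    train_relation_classifier(
      train_inst, encoder = hashed_encoder(dim = encoder_dim, seed = s),
      seed = s, features = train_feats, loss = loss,
      epochs = epochs, learning_rate = learning_rate
    )
  })

  # -- ensemble + predict -----------------------------------------------------
  ens <- ensemble_config(members, default_threshold = preset_cfg$default_threshold,
                         class_overrides = preset_cfg$class_overrides)
  pred <- predict_ensemble(ens, test_inst, features = test_feats)
  pred_path <- file.path(outdir, "predictions.tsv")
  write_predictions(pred$predictions, pred_path)

  # -- evaluate ---------------------------------------------------------------
  report <- evaluate_predictions(rels$test, pred$predictions,
                                 unreachable_gold = attr(test_inst, "unreachable_gold") %||% 0L)
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(list(
    micro = report$micro, per_class = report$per_class,
    unreachable_gold = report$unreachable_gold
  ), report_path, dataframe = "rows", auto_unbox = TRUE, digits = NA)

  manifest <- structure(list(
    preset = preset, seeds = seeds,
    sim_config = unclass(sim_config),
    training = list(encoder_dim = encoder_dim, epochs = epochs,
                    learning_rate = learning_rate, loss = loss,
                    test_fraction = test_fraction),
    n_train_instances = nrow(train_inst), n_test_instances = nrow(test_inst),
    unreachable_gold = report$unreachable_gold,
    artifacts = c(corpus_paths, predictions = pred_path, report = report_path),
    digests = tools::md5sum(c(unname(corpus_paths), pred_path, report_path)),
    version = as.character(utils::packageVersion("dtirex")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    report = report
  ), class = "dti_run_manifest")

  # atomic manifest write: temp file then rename
  manifest_path <- file.path(outdir, "manifest.json")
  tmp <- paste0(manifest_path, ".tmp")
  jsonlite::write_json(manifest[setdiff(names(manifest), "report")], tmp,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  file.rename(tmp, manifest_path)
  manifest$manifest_path <- manifest_path
  manifest
}

#' @export
print.dti_run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run: preset %s, %d member seed(s), %d train / %d test instances\n",
              x$preset, length(x$seeds), x$n_train_instances, x$n_test_instances))
  print(x$report)
  invisible(x)
}
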