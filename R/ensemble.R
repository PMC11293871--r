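#' Ensemble configuration
#'
#' An ensemble is a list of trained member models whose predicted
#' probabilities are averaged, plus a thresholding policy: a default
#' probability threshold (inclusive, applied per class) and optional
#' per-class overrides for rare relation types.
#'
#' @param members List of `dti_classifier` states (at least one).
#' @param default_threshold Decision threshold in (0, 1), default 0.5;
#'   a class is predicted when its averaged probability is `>=` the
#'   threshold.
#' @param class_overrides Named numeric vector mapping relation types to
#'   thresholds (e.g. `c("AGONIST-INHIBITOR" = 0.2)`).
#' @return An object of class `dti_ensemble`.
#' @export
ensemble_config <- function(members, default_threshold = 0.5, class_overrides = numeric()) {
  if (length(members) < 1) abort("An ensemble needs at least one member")
  if (default_threshold <= 0 || default_threshold >= 1) abort("default_threshold must be in (0, 1)")
  if (length(class_overrides) > 0) assert_relation_types(names(class_overrides), "class_overrides name")
  structure(list(members = members, default_threshold = default_threshold,
                 class_overrides = class_overrides),
            class = "dti_ensemble")
}

#' Named ensemble presets
#'
#' The five experiment configurations: `SBE` (sentence-based ensemble,
#' no descriptions), `GDE` (gene description ensemble), `CDE` (chemical
#' description ensemble), `CGDE` (chemical and gene descriptions, with
#' the rare-class override that accepts AGONIST-INHIBITOR at probability
#' `>= 0.2` instead of `>= 0.5`) and `SFTDE` (gene descriptions plus
#' L2-normalized protein sequence features, standard thresholds).
#'
#' @param name One of `"SBE"`, `"GDE"`, `"CDE"`, `"CGDE"`, `"SFTDE"`.
#' @return A list describing the preset: which descriptions to attach,
#'   whether sequence features are fused, the default threshold and any
#'   per-class overrides.
#' @export
ensemble_preset <- function(name = c("SBE", "GDE", "CDE", "CGDE", "SFTDE")) {
  name <- match.arg(name)
  presets <- list(
    SBE = list(use_chem_desc = FALSE, use_gene_desc = FALSE, use_seq_features = FALSE,
               class_overrides = numeric()),
    GDE = list(use_chem_desc = FALSE, use_gene_desc = TRUE, use_seq_features = FALSE,
               class_overrides = numeric()),
    CDE = list(use_chem_desc = TRUE, use_gene_desc = FALSE, use_seq_features = FALSE,
               class_overrides = numeric()),
    CGDE = list(use_chem_desc = TRUE, use_gene_desc = TRUE, use_seq_features = FALSE,
                class_overrides = c("AGONIST-INHIBITOR" = 0.2)),
    SFTDE = list(use_chem_desc = FALSE, use_gene_desc = TRUE, use_seq_features = TRUE,
                 class_overrides = numeric())
  )
  c(list(name = name, default_threshold = 0.5), presets[[name]])
}

#' Average member probabilities
#'
#' Unweighted element-wise arithmetic mean of the members' n x 13
#' probability matrices.
#'
#' @param member_probs List of numeric matrices of identical shape.
#' @return Matrix of the common shape.
#' @export
average_probs <- function(member_probs) {
  if (length(member_probs) == 0) abort("No member probability matrices supplied")
  dims <- lapply(member_probs, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("Member probability matrices have mismatched shapes")
  }
  Reduce(`+`, member_probs) / length(member_probs)
}

#' Convert probabilities to relation predictions
#'
#' Class `c` is predicted for instance `i` when `probs[i, c] >=
#' threshold(c)`, where `threshold(c)` is the per-class override if one
#' exists, otherwise the default. The comparison is inclusive, so a
#' probability of exactly 0.5 is predicted at the default threshold. An
#' instance may yield zero, one or several relation types.
#'
#' @param probs n x 13 probability matrix, rows aligned with
#'   `instances`, columns named by [relation_types()].
#' @param instances The `dti_instances` tibble the rows refer to.
#' @param default_threshold Inclusive threshold, default 0.5.
#' @param class_overrides Named numeric vector of per-class thresholds.
#' @return Tibble of predictions (`doc_id`, `rtype`, `arg1`, `arg2`),
#'   deduplicated and sorted.
#' @export
apply_thresholds <- function(probs, instances, default_threshold = 0.5,
                             class_overrides = numeric()) {
  if (nrow(probs) != nrow(instances)) abort("probs rows do not align with instances")
  if (length(class_overrides) > 0) assert_relation_types(names(class_overrides), "class_overrides name")
  thr <- setNames(rep(default_threshold, 13), relation_types())
  thr[names(class_overrides)] <- class_overrides
  hits <- sweep(probs[, relation_types(), drop = FALSE], 2, thr, `>=`)
  instances_to_relations(instances, labels = ifelse(hits, 1L, 0L)) |> distinct()
}

#' Predict relations with an ensemble
#'
#' Runs every member on the instances, averages the probabilities and
#' applies the configured thresholds.
#'
#' @param config A `dti_ensemble` from [ensemble_config()].
#' @param instances A `dti_instances` tibble.
#' @param features Optional feature matrix passed to members trained
#'   with sequence features.
#' @return List with `probs` (averaged n x 13 matrix) and `predictions`
#'   (relation tibble).
#' @export
predict_ensemble <- function(config, instances, features = NULL) {
  member_probs <- lapply(config$members, predict_probs, instances = instances, features = features)
  probs <- average_probs(member_probs)
  preds <- apply_thresholds(probs, instances,
                            default_threshold = config$default_threshold,
                            class_overrides = config$class_overrides)
  list(probs = probs, predictions = preds)
}
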