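#' Match predictions against gold relations
#'
#' Challenge-style exact-tuple matching: both sides are collapsed to
#' sets of `(doc_id, rtype, arg1, arg2)` tuples; a prediction is a true
#' positive iff its exact tuple occurs in gold, otherwise a false
#' positive, and unmatched gold tuples are false negatives attributed to
#' their relation type.
#'
#' @param gold,pred Relation tibbles (`doc_id`, `rtype`, `arg1`, `arg2`).
#' @return Tibble with one row per relation type (all 13, zero-filled):
#'   `rtype`, `tp`, `fp`, `fn`.
#' @export
match_predictions <- function(gold, pred) {
  assert_relation_types(gold$rtype, "gold relation type")
  assert_relation_types(pred$rtype, "predicted relation type")
  g <- distinct(select(gold, "doc_id", "rtype", "arg1", "arg2"))
  p <- distinct(select(pred, "doc_id", "rtype", "arg1", "arg2"))
  gk <- paste(g$doc_id, g$rtype, g$arg1, g$arg2, sep = "\r")
  pk <- paste(p$doc_id, p$rtype, p$arg1, p$arg2, sep = "\r")
  is_tp <- pk %in% gk
  gold_missed <- !(gk %in% pk)
  tibble(rtype = relation_types()) |>
    mutate(
      tp = vapply(.data$rtype, function(r) sum(p$rtype == r & is_tp), integer(1), USE.NAMES = FALSE),
      fp = vapply(.data$rtype, function(r) sum(p$rtype == r & !is_tp), integer(1), USE.NAMES = FALSE),
      fn = vapply(.data$rtype, function(r) sum(g$rtype == r & gold_missed), integer(1), USE.NAMES = FALSE)
    )
}

prf <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(precision = 100 * precision, recall = 100 * recall, f1 = 100 * f1)
}

#' Micro-averaged precision, recall and F1
#'
#' Pools TP, FP and FN over all classes, then computes precision
#' `sum(TP)/sum(TP+FP)`, recall `sum(TP)/sum(TP+FN)` and their harmonic
#' mean, reported on the 0-100 scale. When there are no gold relations
#' and no predictions at all, the metrics are reported as 100 with the
#' `empty` flag set (nothing to find, nothing wrongly found); a
#' denominator of zero with a nonzero opposite count gives 0.
#'
#' @param counts Counts tibble from [match_predictions()].
#' @return One-row tibble: `precision`, `recall`, `f1` (0-100 scale),
#'   `tp`, `fp`, `fn`, `empty`.
#' @export
micro_f1 <- function(counts) {
  tp <- sum(counts$tp); fp <- sum(counts$fp); fn <- sum(counts$fn)
  if (tp + fp + fn == 0) {
    return(tibble(precision = 100, recall = 100, f1 = 100, tp = 0L, fp = 0L, fn = 0L, empty = TRUE))
  }
  m <- prf(tp, fp, fn)
  tibble(precision = m[["precision"]], recall = m[["recall"]], f1 = m[["f1"]],
         tp = tp, fp = fp, fn = fn, empty = FALSE)
}

#' Full evaluation report
#'
#' Per-class precision/recall/F1 over the 13 relation types plus the
#' micro aggregates, on the 0-100 scale. Classes with no gold and no
#' predicted tuples report zeros with `empty_class = TRUE`.
#'
#' @param gold,pred Relation tibbles.
#' @param unreachable_gold Count of gold relations whose arguments never
#'   share a sentence (bounds attainable recall; see
#'   [generate_instances()]).
#' @return An object of class `dti_eval_report`: list with `per_class`
#'   (tibble), `micro` (one-row tibble) and `unreachable_gold`.
#' @export
evaluate_predictions <- function(gold, pred, unreachable_gold = 0L) {
  counts <- match_predictions(gold, pred)
  per_class <- counts |>
    mutate(
      precision = purrr::pmap_dbl(list(.data$tp, .data$fp, .data$fn), function(tp, fp, fn) prf(tp, fp, fn)[["precision"]]),
      recall = purrr::pmap_dbl(list(.data$tp, .data$fp, .data$fn), function(tp, fp, fn) prf(tp, fp, fn)[["recall"]]),
      f1 = purrr::pmap_dbl(list(.data$tp, .data$fp, .data$fn), function(tp, fp, fn) prf(tp, fp, fn)[["f1"]]),
      empty_class = .data$tp + .data$fp + .data$fn == 0
    )
  structure(list(
    per_class = per_class,
    micro = micro_f1(counts),
    unreachable_gold = as.integer(unreachable_gold)
  ), class = "dti_eval_report")
}

#' @export
print.dti_eval_report <- function(x, ...) {
  m <- x$micro
  cat(sprintf("Micro-averaged: P = %.1f, R = %.1f, F1 = %.1f (TP %d, FP %d, FN %d)\n",
              m$precision, m$recall, m$f1, m$tp, m$fp, m$fn))
  if (x$unreachable_gold > 0) {
    cat(sprintf("Note: %d gold relation(s) are cross-sentence and unreachable\n", x$unreachable_gold))
  }
  print(select(x$per_class, "rtype", "tp", "fp", "fn", "precision", "recall", "f1"), n = 13)
  invisible(x)
}

#' @export
tidy.dti_eval_report <- function(x, ...) x$per_class

#' @export
glance.dti_eval_report <- function(x, ...) {
  mutate(x$micro, unreachable_gold = x$unreachable_gold)
}

#' Plot per-class F1 of an evaluation report
#'
#' @param object A `dti_eval_report`.
#' @param ... Unused.
#' @return A ggplot object: per-class F1 bars with the micro-F1 as a
#'   dashed reference line.
#' @export
autoplot.dti_eval_report <- function(object, ...) {
  df <- mutate(object$per_class, rtype = stats::reorder(.data$rtype, .data$f1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f1, y = .data$rtype)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$micro$f1, linetype = "dashed") +
    ggplot2::labs(x = "F1 (0-100)", y = NULL,
                  title = "Per-class F1",
                  subtitle = sprintf("micro-F1 = %.1f", object$micro$f1)) +
    ggplot2::theme_minimal()
}

#' Plot relation-type counts of a corpus
#'
#' @param object A `dti_corpus_stats` object.
#' @param ... Unused.
#' @return A ggplot bar chart of relation counts by type.
#' @export
autoplot.dti_corpus_stats <- function(object, ...) {
  df <- mutate(object$relation_counts, rtype = stats::reorder(.data$rtype, .data$n))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$rtype)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "Gold relations", y = NULL, title = "Relation type distribution") +
    ggplot2::theme_minimal()
}
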