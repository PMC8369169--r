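# Evaluation protocols: token-level "classification" over all positions,
# the stricter O-filtered "identification" protocol, and strict
# entity-level matching.

# Round half away from zero (commercial rounding) -- reported percents use
# this, not banker's rounding.
round_half_away <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Harmonic-mean F1 from precision and recall
#'
#' `F1 = 2 * precision * recall / (precision + recall)` on the percent
#' scale, rounded half away from zero to one decimal (the reporting
#' convention used throughout the package). Defined as 0 when both inputs
#' are 0.
#'
#' @param precision,recall Percentages in \[0, 100\] (vectorised).
#' @return F1 percentage rounded to one decimal.
#' @export
#' @examples
#' f1_from_pr(60.8, 30.6)
f1_from_pr <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 100),
            all(recall >= 0 & recall <= 100))
  out <- ifelse(precision + recall == 0, 0,
                2 * precision * recall / (precision + recall))
  round_half_away(out, 1L)
}

check_aligned <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop(sprintf("gold has %d sentences but pred has %d",
                 length(gold), length(pred)), call. = FALSE)
  }
  for (i in seq_along(gold)) {
    if (length(gold[[i]]) != length(pred[[i]])) {
      stop(sprintf(
        "sentence %d: gold has %d positions but pred has %d",
        i, length(gold[[i]]), length(pred[[i]])), call. = FALSE)
    }
  }
}

prf <- function(tp, n_pred, n_gold) {
  tp <- unname(tp); n_pred <- unname(n_pred); n_gold <- unname(n_gold)
  p <- if (n_pred > 0) tp / n_pred else 0
  r <- if (n_gold > 0) tp / n_gold else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

new_eval_report <- function(mode, tp, n_pred, n_gold, per_class, n_sentences,
                            n_positions) {
  structure(
    c(as.list(prf(tp, n_pred, n_gold)),
      list(mode = mode,
           counts = list(correct = tp, predicted = n_pred, gold = n_gold),
           per_class = per_class, n_sentences = n_sentences,
           n_positions = n_positions)),
    class = "ner_eval")
}

#' @export
print.ner_eval <- function(x, ...) {
  cat(sprintf("NER evaluation (%s): %d sentences, %d positions\n",
              x$mode, x$n_sentences, x$n_positions))
  cat(sprintf("  precision %5.1f  recall %5.1f  F1 %5.1f\n",
              round_half_away(100 * x$precision),
              round_half_away(100 * x$recall),
              round_half_away(100 * x$f1)))
  if (nrow(x$per_class)) {
    pc <- x$per_class
    pc$precision <- round_half_away(100 * pc$precision)
    pc$recall <- round_half_away(100 * pc$recall)
    pc$f1 <- round_half_away(100 * pc$f1)
    print(pc, row.names = FALSE)
  }
  invisible(x)
}

per_label_table <- function(gold_vec, pred_vec, labels) {
  rows <- lapply(labels, function(lb) {
    tp <- sum(gold_vec == lb & pred_vec == lb)
    m <- prf(tp, sum(pred_vec == lb), sum(gold_vec == lb))
    data.frame(label = lb, correct = tp, predicted = sum(pred_vec == lb),
               gold = sum(gold_vec == lb), precision = m[["precision"]],
               recall = m[["recall"]], f1 = m[["f1"]])
  })
  do.call(rbind, rows)
}

#' Token-level metrics over all positions ("classification" protocol)
#'
#' Micro-averaged precision/recall/F1 over all 11 tags at every position,
#' O included: since each position carries exactly one gold and one
#' predicted tag, the micro scores all equal token accuracy. A per-tag
#' breakdown is included, which is where all-O predictions and similar
#' pathologies become visible.
#'
#' @param gold,pred Lists of tag vectors, position-aligned.
#' @return A `ner_eval` report.
#' @export
classification_metrics <- function(gold, pred) {
  check_aligned(gold, pred)
  g <- unlist(gold); p <- unlist(pred)
  if (is.null(g)) g <- character(); if (is.null(p)) p <- character()
  sch <- tag_schema()
  tp <- sum(g == p)
  new_eval_report("classification", tp, length(p), length(g),
                  per_label_table(g, p, sch$tags), length(gold), length(g))
}

#' O-filtered metrics ("identification" protocol)
#'
#' Both sequences are restricted to the positions where the *gold* tag is a
#' target entity tag (gold != O); predictions are filtered by those same
#' positions. Micro precision counts a filtered position as predicted only
#' when the prediction is itself an entity tag, so a model predicting O at
#' an entity position loses recall but not precision.
#'
#' Metrics under this protocol are invariant to any prediction change at
#' gold-O positions.
#'
#' @inheritParams classification_metrics
#' @return A `ner_eval` report.
#' @export
identification_metrics <- function(gold, pred) {
  check_aligned(gold, pred)
  g <- unlist(gold); p <- unlist(pred)
  if (is.null(g)) g <- character(); if (is.null(p)) p <- character()
  keep <- g != "O"
  g <- g[keep]; p <- p[keep]
  sch <- tag_schema()
  entity_tags <- setdiff(sch$tags, "O")
  tp <- sum(g == p)
  new_eval_report("identification", tp, sum(p != "O"), length(g),
                  per_label_table(g, p, entity_tags), length(gold), length(g))
}

#' Strict entity-level metrics
#'
#' Both tag sequences are decoded to entities (with begin repair, see
#' [decode_tags()]); a predicted entity is correct iff its class, start and
#' end all match a gold entity. Precision is correct/predicted, recall
#' correct/gold.
#'
#' @inheritParams classification_metrics
#' @return A `ner_eval` report with a per-class breakdown.
#' @export
entity_strict_metrics <- function(gold, pred) {
  check_aligned(gold, pred)
  per <- stats::setNames(
    lapply(entity_classes(), function(cl) c(tp = 0L, np = 0L, ng = 0L)),
    entity_classes())
  tp <- 0L; n_pred <- 0L; n_gold <- 0L
  for (i in seq_along(gold)) {
    ge <- decode_tags(gold[[i]])
    pe <- decode_tags(pred[[i]])
    gk <- paste(ge$class, ge$start, ge$end)
    pk <- paste(pe$class, pe$start, pe$end)
    hit <- pk %in% gk
    tp <- tp + sum(hit); n_pred <- n_pred + nrow(pe); n_gold <- n_gold + nrow(ge)
    for (cl in entity_classes()) {
      per[[cl]] <- per[[cl]] + c(sum(hit & pe$class == cl),
                                 sum(pe$class == cl), sum(ge$class == cl))
    }
  }
  per_class <- do.call(rbind, lapply(entity_classes(), function(cl) {
    cnt <- unname(per[[cl]])
    m <- prf(cnt[1L], cnt[2L], cnt[3L])
    data.frame(label = cl, correct = cnt[1L], predicted = cnt[2L],
               gold = cnt[3L], precision = m[["precision"]],
               recall = m[["recall"]], f1 = m[["f1"]])
  }))
  new_eval_report("entity_strict", tp, n_pred, n_gold, per_class,
                  length(gold), length(unlist(gold)))
}

#' Evaluate predictions under one of the three protocols
#'
#' @inheritParams classification_metrics
#' @param mode Evaluation protocol.
#' @return A `ner_eval` report.
#' @export
evaluate_tags <- function(gold, pred,
                          mode = c("classification", "identification",
                                   "entity_strict")) {
  mode <- match.arg(mode)
  switch(mode,
         classification = classification_metrics(gold, pred),
         identification = identification_metrics(gold, pred),
         entity_strict = entity_strict_metrics(gold, pred))
}

#' Keep only samples containing exactly one entity class
#'
#' Used for per-class evaluation: for each class, a dataset is formed from
#' the samples whose gold entities all belong to that single class.
#'
#' @param samples A `ner_corpus` or list of samples with `tags`.
#' @param class Optional class name; when given, only single-class samples
#'   of that class are returned.
#' @return The filtered list of samples.
#' @export
single_class_samples <- function(samples, class = NULL) {
  corp <- as_ner_samples(samples)
  keep <- vapply(corp, function(s) {
    ent <- decode_tags(s$tags)
    n_cls <- length(unique(ent$class))
    n_cls == 1L && (is.null(class) || ent$class[1L] == class)
  }, logical(1))
  corp[keep]
}

#' Turn an evaluation report into a one-row data frame
#'
#' @param x A `ner_eval` report.
#' @param row.names,optional,... Passed for S3 compatibility, unused.
#' @return Data frame with mode, counts and percent metrics.
#' @export
as.data.frame.ner_eval <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(mode = x$mode, correct = x$counts$correct,
             predicted = x$counts$predicted, gold = x$counts$gold,
             precision = round_half_away(100 * x$precision),
             recall = round_half_away(100 * x$recall),
             f1 = round_half_away(100 * x$f1))
}
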