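pair_key <- function(df) {
  paste(df$doc_id, df$bacteria_id, df$location_id, sep = "\r")
}

prf_from_counts <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1_score(precision, recall)),
            class = "bb_prf")
}

#' F1 score from precision and recall
#'
#' `F1 = 2 P R / (P + R)` on the percent scale (0 when `P + R = 0`).
#'
#' @param precision,recall percent-scale values
#' @return percent-scale F1
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall <= 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Relation-level precision/recall/F1
#'
#' Compares predicted positive bacteria-location pairs against gold
#' positives, matching pairs by `(doc_id, bacteria_id, location_id)`. Gold
#' relations flagged as inter-sentence can never be produced by the
#' intra-sentence pipeline and are counted as false negatives
#' unconditionally. Duplicate predictions are collapsed with a warning.
#'
#' @param gold data.frame of gold positive relations with columns `doc_id`,
#'   `bacteria_id`, `location_id` and optionally logical `inter_sentence`
#' @param predicted data.frame of predicted positive pairs with the same id
#'   columns (e.g. the positive rows of [predict_relations()])
#' @return a `bb_prf`: list with integer `tp`, `fp`, `fn` and percent-scale
#'   `precision`, `recall`, `f1`
#' @export
prf_scores <- function(gold, predicted) {
  if (is.null(gold$inter_sentence)) gold$inter_sentence <- FALSE
  pred_keys <- pair_key(predicted)
  if (anyDuplicated(pred_keys)) {
    warning("duplicate predicted pairs collapsed", call. = FALSE)
    pred_keys <- unique(pred_keys)
  }
  intra_gold <- unique(pair_key(gold[!gold$inter_sentence, , drop = FALSE]))
  n_inter <- length(unique(pair_key(gold[gold$inter_sentence, ,
                                         drop = FALSE])))
  tp <- sum(pred_keys %in% intra_gold)
  fp <- length(pred_keys) - tp
  fn <- sum(!intra_gold %in% pred_keys) + n_inter
  prf_from_counts(tp, fp, fn)
}

#' @export
print.bb_prf <- function(x, ...) {
  cat(sprintf("P %.2f  R %.2f  F1 %.2f  (tp %d, fp %d, fn %d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Multi-seed robustness protocol
#'
#' Deep models are sensitive to random initialization, so a single run's
#' F1 is a noisy summary of an architecture. This protocol retrains the
#' same architecture under `n_seeds` consecutive seeds and aggregates the
#' resulting scores into mean, sample standard deviation, minimum and
#' maximum (the reference protocol uses 30 seeds).
#'
#' @param train_and_score function mapping a seed to an F1 score
#' @param n_seeds number of seeds (at least 2, else the SD is undefined)
#' @param base_seed first seed; seeds run `base_seed ... base_seed +
#'   n_seeds - 1`
#' @return a `seed_summary`: list with `scores`, `mean`, `sd`, `min`, `max`
#' @export
seed_protocol <- function(train_and_score, n_seeds = 30L, base_seed = 1L) {
  if (n_seeds < 2L) stop("at least 2 seeds are required for a defined SD")
  seeds <- base_seed + seq_len(n_seeds) - 1L
  scores <- vapply(seeds, train_and_score, numeric(1))
  summarize_scores(scores)
}

summarize_scores <- function(scores) {
  structure(list(scores = scores, mean = mean(scores),
                 sd = stats::sd(scores), min = min(scores),
                 max = max(scores)),
            class = "seed_summary")
}

#' @export
print.seed_summary <- function(x, ...) {
  cat(sprintf("F1 over %d seeds: mean %.2f  sd %.2f  min %.2f  max %.2f\n",
              length(x$scores), x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' Compare two models' score samples with a two-sample t-test
#'
#' Welch's unequal-variance two-sided t-test on two samples of per-seed F1
#' scores. When both samples have zero variance, equal means give `t = 0`,
#' `p = 1` by convention (and unequal means `p = 0`).
#'
#' @param scores_a,scores_b numeric score samples (each of length >= 2)
#' @return list with `t_statistic` and `p_value`
#' @export
compare_models_t_test <- function(scores_a, scores_b) {
  if (length(scores_a) < 2L || length(scores_b) < 2L) {
    stop("both samples must have at least 2 scores")
  }
  if (stats::sd(scores_a) == 0 && stats::sd(scores_b) == 0) {
    if (isTRUE(all.equal(mean(scores_a), mean(scores_b)))) {
      return(list(t_statistic = 0, p_value = 1))
    }
    return(list(t_statistic = sign(mean(scores_a) - mean(scores_b)) * Inf,
                p_value = 0))
  }
  tt <- stats::t.test(scores_a, scores_b, var.equal = FALSE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Precision-recall sweep over decision cut-offs
#'
#' Re-decides every prediction record at each cut-off (positive iff
#' `p_positive >= cutoff`) and scores the resulting positive set against
#' the gold relations, tracing the precision-recall trade-off. The default
#' grid includes the operating points 0.025 (recall-oriented), 0.5
#' (default) and 0.975 (precision-oriented).
#'
#' @param records data.frame with `doc_id`, `bacteria_id`, `location_id`
#'   and `p_positive` (e.g. from [predict_relations()])
#' @param gold as in [prf_scores()]
#' @param cutoffs numeric vector of thresholds
#' @return data.frame with one row per cut-off: `cutoff`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1`
#' @export
precision_recall_sweep <- function(records, gold,
                                   cutoffs = c(0.025,
                                               seq(0.05, 0.95, by = 0.05),
                                               0.975)) {
  if (!length(cutoffs)) stop("empty cut-off list")
  if (is.null(records$p_positive) || anyNA(records$p_positive)) {
    stop("prediction records must carry probabilities")
  }
  rows <- lapply(sort(cutoffs), function(ct) {
    pred <- records[records$p_positive >= ct, , drop = FALSE]
    prf <- prf_scores(gold, pred)
    data.frame(cutoff = ct, tp = prf$tp, fp = prf$fp, fn = prf$fn,
               precision = prf$precision, recall = prf$recall, f1 = prf$f1)
  })
  do.call(rbind, rows)
}
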