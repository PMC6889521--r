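# Recursive helpers over nested parameter lists -----------------------------

nested_add <- function(a, b) {
  if (is.list(a)) {
    for (k in seq_along(a)) a[[k]] <- nested_add(a[[k]], b[[k]])
    a
  } else a + b
}

nested_scale <- function(a, s) {
  if (is.list(a)) lapply(a, nested_scale, s = s) else a * s
}

adam_state <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- rec(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- b1 * m + (1 - b1) * g
      v2 <- b2 * v + (1 - b2) * g^2
      list(p = p - lr * (m2 / corr1) / (sqrt(v2 / corr2) + eps),
           m = m2, v = v2)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# ---------------------------------------------------------------------------

#' Train the hybrid relation-extraction model
#'
#' Mini-batch Adam on the categorical cross-entropy, with dropout on the
#' concatenated feature, per-epoch evaluation of the development F1 at
#' cut-off 0.5, and early stopping: training stops once the development F1
#' has not improved for `patience` epochs, and the best-development
#' checkpoint is returned. All randomness (parameter init, shuffling,
#' dropout) is driven by `tc$seed`, so equal seeds give identical runs.
#'
#' @param train_instances,dev_instances lists of labeled `bb_instance`
#' @param emb an [embedding_config()] (see [fit_embedding_config()])
#' @param enc an [encoder_config()]
#' @param tc a [train_config()]
#' @param provider a `word_provider` for token vectors
#' @param sentence_provider optional callable `f(instance) -> numeric
#'   vector` of length `sent_dim` (contextual sentence contract); when
#'   absent and the sentence block is enabled, zero vectors are used
#' @param sent_dim sentence-embedding dimension
#' @param verbose print per-epoch progress
#' @return a `bb_fit`: list with `model` (best checkpoint), `history`
#'   (data.frame: epoch, loss, dev_f1) and `best_epoch`
#' @export
train_model <- function(train_instances, dev_instances, emb, enc, tc,
                        provider, sentence_provider = NULL,
                        sent_dim = 768L, verbose = FALSE) {
  if (!length(train_instances)) stop("empty training set")
  if (any(vapply(train_instances, function(x) is.na(x$label), logical(1)))) {
    stop("training instances must carry labels")
  }
  if (!any(vapply(dev_instances, function(x)
    identical(x$label, "positive"), logical(1)))) {
    warning("development set has no positive instances; F1 treated as 0",
            call. = FALSE)
  }
  model <- init_model(emb, enc, tc, sent_dim)  # seeds the RNG from tc$seed
  prep_train <- lapply(train_instances, prepare_instance, provider = provider,
                       model = model)
  prep_dev <- lapply(dev_instances, prepare_instance, provider = provider,
                     model = model)
  sent_vecs <- function(instances) {
    if (!tc$use_sentence_embedding) return(vector("list", length(instances)))
    lapply(instances, function(x) {
      if (is.null(sentence_provider)) numeric(sent_dim)
      else sentence_provider(x)
    })
  }
  sv_train <- sent_vecs(train_instances)
  sv_dev <- sent_vecs(dev_instances)

  state <- adam_state(model$params)
  n <- length(prep_train)
  best <- list(f1 = -Inf, params = model$params, epoch = 0L)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        dev_f1 = numeric())
  stale <- 0L
  for (epoch in seq_len(tc$max_epochs)) {
    order <- sample.int(n)
    losses <- numeric()
    for (start in seq(1L, n, by = tc$batch_size)) {
      idx <- order[start:min(start + tc$batch_size - 1L, n)]
      grads <- NULL
      batch_loss <- 0
      for (i in idx) {
        fw <- model_forward(model, prep_train[[i]], sv_train[[i]],
                            training = TRUE)
        batch_loss <- batch_loss +
          categorical_ce(prep_train[[i]]$y, fw$probs)
        g <- model_backward(model, prep_train[[i]], fw)
        grads <- if (is.null(grads)) g else nested_add(grads, g)
      }
      grads <- nested_scale(grads, 1 / length(idx))
      st <- adam_step(model$params, grads, state, tc$learning_rate)
      model$params <- st$params
      state <- st$state
      losses <- c(losses, batch_loss / length(idx))
    }
    dev_f1 <- dev_f1_score(model, prep_dev, sv_dev)
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = mean(losses),
                                         dev_f1 = dev_f1))
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f dev F1 %.2f", epoch,
                      mean(losses), dev_f1))
    }
    if (dev_f1 > best$f1) {
      best <- list(f1 = dev_f1, params = model$params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= tc$patience) break
    }
  }
  model$params <- best$params
  structure(list(model = model, history = history,
                 best_epoch = best$epoch), class = "bb_fit")
}

categorical_ce <- function(y_index, probs) {
  p <- pmin(pmax(probs[y_index], 1e-7), 1 - 1e-7)
  -log(p)
}

# Instance-level F1 (percent) at cut-off 0.5 against instance labels.
dev_f1_score <- function(model, preps, svs) {
  tp <- fp <- fn <- 0L
  pos_class <- match("positive", model$classes)
  for (i in seq_along(preps)) {
    fw <- model_forward(model, preps[[i]], svs[[i]], training = FALSE)
    pred_pos <- fw$probs[pos_class] >= 0.5
    gold_pos <- identical(preps[[i]]$label, "positive")
    if (pred_pos && gold_pos) tp <- tp + 1L
    else if (pred_pos) fp <- fp + 1L
    else if (gold_pos) fn <- fn + 1L
  }
  prf_from_counts(tp, fp, fn)$f1
}

#' Predict candidate instances with a trained model
#'
#' Runs the forward pass without dropout and applies the decision rule
#' `positive` iff the positive-class probability is at least `cutoff`.
#'
#' @param fit a `bb_fit` from [train_model()] (or a bare `bb_model`)
#' @param instances list of `bb_instance`
#' @param provider the `word_provider` used in training
#' @param cutoff decision threshold in `[0, 1]`
#' @param sentence_provider as in [train_model()]
#' @return data.frame with `doc_id`, `bacteria_id`, `location_id`,
#'   `p_positive` and logical `decision`
#' @export
predict_relations <- function(fit, instances, provider, cutoff = 0.5,
                              sentence_provider = NULL) {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must be in [0, 1]")
  model <- if (inherits(fit, "bb_fit")) fit$model else fit
  pos_class <- match("positive", model$classes)
  p <- vapply(instances, function(inst) {
    prep <- prepare_instance(inst, provider, model)
    sv <- if (model$tc$use_sentence_embedding) {
      if (is.null(sentence_provider)) numeric(model$sent_dim)
      else sentence_provider(inst)
    } else NULL
    model_forward(model, prep, sv, training = FALSE)$probs[pos_class]
  }, numeric(1))
  data.frame(
    doc_id = vapply(instances, `[[`, character(1), "doc_id"),
    bacteria_id = vapply(instances, `[[`, character(1), "bacteria_id"),
    location_id = vapply(instances, `[[`, character(1), "location_id"),
    p_positive = p,
    decision = p >= cutoff,
    stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding every named weight array
#' together with the embedding, encoder and training configuration blocks.
#'
#' @param fit a `bb_fit` or `bb_model`
#' @param path checkpoint path
#' @return `load_checkpoint()`: the restored object
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit, path, version = 2)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
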