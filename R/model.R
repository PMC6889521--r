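#' Encoder configuration
#'
#' Structural hyper-parameters of the two feature extractors. Defaults are
#' the tuned setting for the bacteria-biotope task: 64 BLSTM hidden units
#' (use 32 for a full-sentence-only variant), three multi-head attention
#' stacks of 2 heads each, convolution windows 3/5/7 with 64 filters, and
#' SDPs padded or truncated to 10 positions (the corpus averages just under
#' 5 SDP tokens).
#'
#' @param blstm_hidden hidden units per LSTM direction
#' @param mha_stacks number of chained multi-head attention stacks
#' @param mha_heads heads per stack (must divide the model dimension)
#' @param cnn_windows convolution window sizes
#' @param cnn_filters filters per window
#' @param max_sdp_len padding target for SDP sequences
#' @return an `encoder_config` list
#' @export
encoder_config <- function(blstm_hidden = 64L, mha_stacks = 3L,
                           mha_heads = 2L, cnn_windows = c(3L, 5L, 7L),
                           cnn_filters = 64L, max_sdp_len = 10L) {
  if (max_sdp_len < 2L) stop("max_sdp_len must be at least 2")
  if (any(cnn_windows > max_sdp_len)) {
    stop("convolution window larger than the padded SDP length")
  }
  structure(list(blstm_hidden = as.integer(blstm_hidden),
                 mha_stacks = as.integer(mha_stacks),
                 mha_heads = as.integer(mha_heads),
                 cnn_windows = as.integer(cnn_windows),
                 cnn_filters = as.integer(cnn_filters),
                 max_sdp_len = as.integer(max_sdp_len)),
            class = "encoder_config")
}

#' Training configuration
#'
#' Optimization settings and ablation flags. Defaults follow the tuned
#' setting: Adam at learning rate 0.001, mini-batches of 4, dropout 0.5 on
#' the concatenated feature, early stopping on development F1 with a
#' patience of 2 epochs (training typically stops within 3-5 epochs).
#'
#' @param learning_rate Adam learning rate
#' @param batch_size mini-batch size
#' @param dropout dropout rate on the concatenated feature (training only)
#' @param max_epochs epoch cap
#' @param patience epochs without development-F1 improvement before stopping
#' @param seed seed controlling parameter init, shuffling and dropout
#' @param class_count number of output classes (2 for Lives_In)
#' @param use_full_sentence,use_sdp,use_sentence_embedding feature-block
#'   ablation flags
#' @param sdp_encoder `"mha"` (stacked multi-head attention) or `"cnn"`
#' @param use_additive,use_entity_oriented,use_pe attention / positional
#'   encoding ablation flags
#' @return a `train_config` list
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 4L,
                         dropout = 0.5, max_epochs = 10L, patience = 2L,
                         seed = 1L, class_count = 2L,
                         use_full_sentence = TRUE, use_sdp = TRUE,
                         use_sentence_embedding = FALSE,
                         sdp_encoder = c("mha", "cnn"),
                         use_additive = TRUE, use_entity_oriented = TRUE,
                         use_pe = TRUE) {
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (!use_full_sentence && !use_sdp && !use_sentence_embedding) {
    stop("at least one feature block must be enabled")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), dropout = dropout,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 class_count = as.integer(class_count),
                 use_full_sentence = use_full_sentence, use_sdp = use_sdp,
                 use_sentence_embedding = use_sentence_embedding,
                 sdp_encoder = match.arg(sdp_encoder),
                 use_additive = use_additive,
                 use_entity_oriented = use_entity_oriented,
                 use_pe = use_pe),
            class = "train_config")
}

#' Derive an embedding configuration from training instances
#'
#' Sets the distance-clipping bound `s` to the maximum absolute relative
#' distance observed in the instances and collects the POS vocabulary.
#'
#' @param instances list of `bb_instance`
#' @param ... further arguments passed to [embedding_config()]
#' @return an `embedding_config`
#' @export
fit_embedding_config <- function(instances, ...) {
  s <- max(1L, max(vapply(instances, function(x)
    max(abs(c(x$rel_dist1, x$rel_dist2))), integer(1))))
  tags <- sort(unique(unlist(lapply(instances, function(x) x$pos_tags))))
  embedding_config(s = s, pos_vocab = tags, ...)
}

model_dim <- function(emb) emb$word_dim + emb$pos_dim + 2L * emb$dist_dim

feature_dim <- function(emb, enc, tc, sent_dim = 768L) {
  d <- 0L
  if (tc$use_full_sentence) d <- d + 2L * enc$blstm_hidden
  if (tc$use_sdp) {
    d <- d + if (tc$sdp_encoder == "mha") {
      enc$max_sdp_len * model_dim(emb)
    } else {
      length(enc$cnn_windows) * enc$cnn_filters
    }
  }
  if (tc$use_sentence_embedding) d <- d + sent_dim
  d
}

#' Initialize model parameters
#'
#' Builds every trainable table and weight matrix for the hybrid model:
#' POS and distance embedding tables, the BLSTM, the additive-attention
#' vector, the multi-head attention stacks (or CNN filter banks), and the
#' softmax output layer. Initialization is fully determined by
#' `train_cfg$seed`.
#'
#' @param emb an [embedding_config()]
#' @param enc an [encoder_config()]
#' @param tc a [train_config()]
#' @param sent_dim sentence-embedding dimension (768 for the BERT-style
#'   provider contract)
#' @return a `bb_model` holding the three configs and a nested `params`
#'   list of numeric arrays
#' @export
init_model <- function(emb, enc, tc, sent_dim = 768L) {
  set.seed(tc$seed)
  D <- model_dim(emb)
  params <- list(
    pos_table = pos_embedding_table(emb),
    dist1 = distance_embedding_table(emb),
    dist2 = distance_embedding_table(emb))
  if (tc$use_full_sentence) {
    params$blstm <- blstm_init(D, enc$blstm_hidden)
    if (tc$use_additive) {
      params$v_a <- stats::rnorm(2L * enc$blstm_hidden, sd = 0.1)
    }
  }
  if (tc$use_sdp) {
    if (tc$sdp_encoder == "mha") {
      params$mha <- mha_encoder_init(D, enc$mha_stacks, enc$mha_heads)
    } else {
      params$cnn <- cnn_init(D, enc$cnn_windows, enc$cnn_filters)
    }
  }
  fd <- feature_dim(emb, enc, tc, sent_dim)
  params$W0 <- glorot(tc$class_count, fd)
  params$b0 <- numeric(tc$class_count)
  structure(list(emb = emb, enc = enc, tc = tc, sent_dim = sent_dim,
                 params = params, classes = c("negative", "positive")),
            class = "bb_model")
}

# Truncate an SDP index sequence to length L symmetrically around the
# midpoint, always keeping both entity endpoints.
truncate_sdp <- function(sdp, L) {
  n <- length(sdp)
  if (n <= L) return(sdp)
  k1 <- ceiling(L / 2)
  c(sdp[seq_len(k1)], sdp[seq.int(n - (L - k1) + 1L, n)])
}

# Precompute everything about an instance that does not depend on the
# trainable tables: fixed word vectors, PE, and lookup indices.
prepare_instance <- function(inst, provider, model) {
  emb <- model$emb; enc <- model$enc; tc <- model$tc
  M <- length(inst$tokens)
  wordmat <- lookup_word_vectors(inst$tokens, provider)
  pos_idx <- pos_row(inst$pos_tags, emb)
  d1_idx <- dist_row(inst$rel_dist1, emb$s)
  d2_idx <- dist_row(inst$rel_dist2, emb$s)
  eo <- if (tc$use_full_sentence && tc$use_entity_oriented) {
    entity_oriented_attention(wordmat, inst$entity1_pos, inst$entity2_pos)
  } else NULL
  prep <- list(M = M, wordmat = wordmat, pos_idx = pos_idx,
               d1_idx = d1_idx, d2_idx = d2_idx, eo = eo,
               label = inst$label,
               y = if (is.na(inst$label)) NA_integer_ else
                 match(inst$label, model$classes))
  if (tc$use_sdp) {
    L <- enc$max_sdp_len
    sdp <- truncate_sdp(inst$sdp_indices, L)
    n_real <- length(sdp)
    word_sdp <- wordmat[sdp, , drop = FALSE]
    if (tc$use_pe) {
      pe <- t(vapply(sdp - 1L, positional_encoding, numeric(emb$word_dim),
                     dim = emb$word_dim))
      word_sdp <- word_sdp + pe
    }
    prep$sdp <- list(
      n_real = n_real,
      mask = c(rep(TRUE, n_real), rep(FALSE, L - n_real)),
      word = rbind(word_sdp, matrix(0, L - n_real, emb$word_dim)),
      pos_idx = pos_idx[sdp], d1_idx = d1_idx[sdp], d2_idx = d2_idx[sdp])
  }
  prep
}

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like)
  else if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
  else numeric(length(x))
}

# Full forward pass for one prepared instance. Returns class probabilities
# plus the caches needed for the backward pass.
model_forward <- function(model, prep, sent_vec = NULL, training = FALSE) {
  p <- model$params; tc <- model$tc; emb <- model$emb
  caches <- list()
  feats <- list()
  if (tc$use_full_sentence) {
    Zf <- cbind(prep$wordmat,
                p$pos_table[prep$pos_idx, , drop = FALSE],
                p$dist1[prep$d1_idx, , drop = FALSE],
                p$dist2[prep$d2_idx, , drop = FALSE])
    scale <- if (!is.null(prep$eo)) prep$eo * prep$M else rep(1, prep$M)
    Zs <- Zf * scale
    bl <- blstm_forward(Zs, p$blstm)
    if (tc$use_additive) {
      at <- additive_attention_forward(bl$H, p$v_a)
      ctx <- at$context
    } else {
      H <- bl$H; hid <- model$enc$blstm_hidden
      ctx <- c(H[nrow(H), seq_len(hid)], H[1, hid + seq_len(hid)])
      at <- NULL
    }
    caches$full <- list(bl = bl, at = at, scale = scale)
    feats$full <- ctx
  }
  if (tc$use_sdp) {
    s <- prep$sdp
    L <- model$enc$max_sdp_len
    Zr <- cbind(s$word[s$mask, , drop = FALSE],
                p$pos_table[s$pos_idx, , drop = FALSE],
                p$dist1[s$d1_idx, , drop = FALSE],
                p$dist2[s$d2_idx, , drop = FALSE])
    Zsdp <- rbind(Zr, matrix(0, L - s$n_real, ncol(Zr)))
    if (tc$sdp_encoder == "mha") {
      enc_fw <- mha_encoder_forward(Zsdp, p$mha, emb$word_dim, s$mask)
    } else {
      enc_fw <- cnn_forward(Zsdp, p$cnn, s$mask)
    }
    caches$sdp <- enc_fw
    feats$sdp <- enc_fw$feature
  }
  if (tc$use_sentence_embedding) {
    feats$sent <- if (is.null(sent_vec)) numeric(model$sent_dim) else sent_vec
  }
  feat <- unlist(feats, use.names = FALSE)
  if (training && tc$dropout > 0) {
    keep <- stats::rbinom(length(feat), 1L, 1 - tc$dropout) / (1 - tc$dropout)
  } else {
    keep <- rep(1, length(feat))
  }
  fdrop <- feat * keep
  logits <- drop(p$W0 %*% fdrop + p$b0)
  probs <- softmax_vec(logits)
  list(probs = probs, feat = feat, keep = keep, fdrop = fdrop,
       caches = caches, feat_sizes = lengths(feats))
}

# Backward pass: cross-entropy gradient through the whole model for one
# instance. Returns a grads list with the same structure as model$params.
model_backward <- function(model, prep, fw) {
  p <- model$params; tc <- model$tc
  grads <- zero_like(p)
  y1 <- numeric(tc$class_count)
  y1[prep$y] <- 1
  dlogits <- fw$probs - y1
  grads$W0 <- tcrossprod(dlogits, fw$fdrop)
  grads$b0 <- dlogits
  dfeat <- drop(crossprod(p$W0, dlogits)) * fw$keep
  off <- 0L
  take <- function(n) {
    out <- dfeat[off + seq_len(n)]
    off <<- off + n
    out
  }
  if (tc$use_full_sentence) {
    dctx <- take(fw$feat_sizes[["full"]])
    cf <- fw$caches$full
    if (tc$use_additive) {
      ag <- additive_attention_grad(cf$at, p$v_a, dctx)
      dH <- ag$dH
      grads$v_a <- ag$dv_a
    } else {
      H <- cf$bl$H; hid <- model$enc$blstm_hidden
      dH <- matrix(0, nrow(H), ncol(H))
      dH[nrow(H), seq_len(hid)] <- dctx[seq_len(hid)]
      dH[1, hid + seq_len(hid)] <- dctx[hid + seq_len(hid)]
    }
    bg <- blstm_backward(cf$bl, p$blstm, dH)
    grads$blstm <- list(fwd = list(W = bg$fwd$dW, U = bg$fwd$dU,
                                   b = bg$fwd$db),
                        bwd = list(W = bg$bwd$dW, U = bg$bwd$dU,
                                   b = bg$bwd$db))
    dZf <- bg$dX * cf$scale
    scatter_embedding_grads(grads, model, dZf, prep$pos_idx, prep$d1_idx,
                            prep$d2_idx) -> grads
  }
  if (tc$use_sdp) {
    dfe <- take(fw$feat_sizes[["sdp"]])
    s <- prep$sdp
    if (tc$sdp_encoder == "mha") {
      eg <- mha_encoder_backward(fw$caches$sdp, p$mha, dfe)
      grads$mha <- relabel_mha_grads(eg$dstacks, p$mha)
      dZsdp <- eg$dZ
    } else {
      eg <- cnn_backward(fw$caches$sdp, p$cnn, dfe)
      grads$cnn <- lapply(seq_along(p$cnn), function(k) {
        list(W = eg$dparams[[k]]$dW, b = eg$dparams[[k]]$db)
      })
      dZsdp <- eg$dZ
    }
    dZr <- dZsdp[s$mask, , drop = FALSE]
    scatter_embedding_grads(grads, model, dZr, s$pos_idx, s$d1_idx,
                            s$d2_idx) -> grads
  }
  grads
}

# Route the gradient of a composed Z block back into the trainable POS and
# distance tables (the word block is fixed and discarded).
scatter_embedding_grads <- function(grads, model, dZ, pos_idx, d1_idx,
                                    d2_idx) {
  emb <- model$emb
  wcols <- emb$word_dim
  pcols <- wcols + seq_len(emb$pos_dim)
  d1cols <- wcols + emb$pos_dim + seq_len(emb$dist_dim)
  d2cols <- wcols + emb$pos_dim + emb$dist_dim + seq_len(emb$dist_dim)
  for (r in seq_len(nrow(dZ))) {
    grads$pos_table[pos_idx[r], ] <- grads$pos_table[pos_idx[r], ] +
      dZ[r, pcols]
    grads$dist1[d1_idx[r], ] <- grads$dist1[d1_idx[r], ] + dZ[r, d1cols]
    grads$dist2[d2_idx[r], ] <- grads$dist2[d2_idx[r], ] + dZ[r, d2cols]
  }
  grads
}

relabel_mha_grads <- function(dstacks, mha_params) {
  lapply(seq_along(mha_params), function(s) {
    list(heads = lapply(seq_along(mha_params[[s]]$heads), function(h) {
      g <- dstacks[[s]]$dheads[[h]]
      list(Wq = g$dWq, Wk = g$dWk, Wv = g$dWv)
    }), Wo = dstacks[[s]]$dWo)
  })
}

#' Classify a set of feature blocks
#'
#' Concatenates whichever feature blocks are supplied (absent blocks
#' contribute nothing; the weight matrix must match the concatenated
#' length), applies dropout to the concatenation when training, and returns
#' the softmax class probabilities `p(c|s) = softmax(W0 s + b0)`.
#'
#' @param params list with weight matrix `W0` (`classes x feature_dim`) and
#'   bias `b0`
#' @param full_sentence_feature,sdp_feature,sentence_embedding optional
#'   numeric feature vectors
#' @param dropout dropout rate applied when `training = TRUE`
#' @param training logical; dropout is inactive at prediction time
#' @return numeric probability vector summing to 1
#' @export
classify <- function(params, full_sentence_feature = NULL,
                     sdp_feature = NULL, sentence_embedding = NULL,
                     dropout = 0, training = FALSE) {
  feat <- c(full_sentence_feature, sdp_feature, sentence_embedding)
  if (!length(feat)) stop("no feature blocks supplied")
  if (ncol(params$W0) != length(feat)) {
    stop("feature length ", length(feat), " does not match W0 with ",
         ncol(params$W0), " columns")
  }
  if (training && dropout > 0) {
    feat <- feat * stats::rbinom(length(feat), 1L, 1 - dropout) / (1 - dropout)
  }
  softmax_vec(drop(params$W0 %*% feat + params$b0))
}

#' Cross-entropy loss
#'
#' Binary cross-entropy `J = -(y log p + (1 - y) log(1 - p))`, with the
#' predicted probability clamped to `[1e-7, 1 - 1e-7]` for numerical
#' safety.
#'
#' @param y binary indicator (0 or 1)
#' @param p predicted probability of the positive class
#' @return non-negative loss value
#' @export
cross_entropy <- function(y, p) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -(y * log(p) + (1 - y) * log(1 - p))
}
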