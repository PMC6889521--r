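test_that("classification layer is a softmax over concatenated blocks", {
  # zero weights give the uniform distribution
  expect_equal(classify(list(W0 = matrix(0, 2, 4), b0 = numeric(2)),
                        sdp_feature = rnorm(4)), c(0.5, 0.5))
  # probabilities sum to 1 on random inputs
  set.seed(6)
  par <- list(W0 = matrix(rnorm(12), 3), b0 = rnorm(3))
  for (k in 1:100) {
    p <- classify(par, full_sentence_feature = rnorm(2),
                  sdp_feature = rnorm(2))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  # hand-set 2x3 weights against an independent evaluation
  W0 <- matrix(c(0.1, -0.2, 0.3, 0.5, 0, -1), nrow = 2, byrow = TRUE)
  b0 <- c(0.05, -0.05)
  s <- c(1, 2, -1)
  logits <- drop(W0 %*% s + b0)
  expect_equal(classify(list(W0 = W0, b0 = b0), sdp_feature = s),
               exp(logits) / sum(exp(logits)), tolerance = 1e-12)
  expect_error(classify(list(W0 = W0, b0 = b0), sdp_feature = rnorm(5)),
               "does not match")
  expect_error(classify(list(W0 = W0, b0 = b0)), "no feature")
})

test_that("cross-entropy matches closed forms and the Bernoulli likelihood", {
  expect_equal(cross_entropy(1, 1), 0, tolerance = 1e-6)
  expect_equal(cross_entropy(0, 0.5), log(2))
  # independent oracle: -log of the Bernoulli density
  set.seed(10)
  for (k in 1:50) {
    y <- rbinom(1, 1, 0.5)
    p <- runif(1, 0.01, 0.99)
    expect_equal(cross_entropy(y, p), -dbinom(y, 1, p, log = TRUE),
                 tolerance = 1e-10)
  }
  # clamping keeps the loss finite at the boundaries
  expect_true(is.finite(cross_entropy(1, 0)))
})

test_that("prediction applies the cut-off rule", {
  su <- tiny_setup()
  model <- init_model(su$emb, su$enc, su$tc)
  instances <- lapply(1:6, function(k)
    toy_instance(c("entity_1", letters[k], "entity_2"), e1 = 1L, e2 = 3L,
                 label = if (k %% 2) "positive" else "negative"))
  p0 <- predict_relations(model, instances, su$provider, cutoff = 0)
  expect_true(all(p0$decision))
  p1 <- predict_relations(model, instances, su$provider, cutoff = 1)
  expect_true(all(!p1$decision[p1$p_positive < 1]))
  # cutoff 0.5 coincides with the 2-class argmax rule
  p5 <- predict_relations(model, instances, su$provider, cutoff = 0.5)
  expect_equal(p5$decision, p5$p_positive >= 1 - p5$p_positive)
  expect_error(predict_relations(model, instances, su$provider, cutoff = 2),
               "cutoff")
})

test_that("training memorizes a small labeled set and stays deterministic", {
  set.seed(30)
  words <- replicate(10, paste(sample(letters, 4), collapse = ""))
  instances <- lapply(1:10, function(k)
    toy_instance(c("entity_1", words[k], "entity_2"), e1 = 1L, e2 = 3L,
                 sdp = c(1L, 2L, 3L),
                 label = if (k <= 5) "positive" else "negative"))
  emb <- embedding_config(word_dim = 16L, pos_dim = 8L, dist_dim = 8L,
                          s = 5L, pos_vocab = "NN", seed = 1L)
  enc <- encoder_config(blstm_hidden = 8L, mha_stacks = 2L, mha_heads = 2L,
                        cnn_windows = 3L, cnn_filters = 4L, max_sdp_len = 4L)
  prov <- word_provider_hash(dim = 16L, seed = 9L)
  # 10 instances give only 3 updates per epoch, so memorization needs a
  # hotter optimizer than the corpus-scale default
  tc <- train_config(learning_rate = 0.01, dropout = 0, seed = 4L,
                     max_epochs = 60L, patience = 60L, batch_size = 4L)
  fit <- train_model(instances, instances, emb, enc, tc, prov)
  # the loss decreases overall and the set is memorized
  expect_lt(min(fit$history$loss), 0.05)
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
  preds <- predict_relations(fit, instances, prov)
  expect_equal(instance_f1(preds, instances)$f1, 100)

  # equal seeds reproduce the history and parameters exactly
  fit2 <- train_model(instances, instances, emb, enc, tc, prov)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model$params, fit2$model$params)
})

test_that("ablation flags change the classifier input dimension", {
  su <- tiny_setup()
  both <- init_model(su$emb, su$enc, su$tc)
  no_sdp <- init_model(su$emb, su$enc,
                       train_config(seed = 3L, use_sdp = FALSE))
  only_sdp <- init_model(su$emb, su$enc,
                         train_config(seed = 3L, use_full_sentence = FALSE))
  D <- bbrex:::model_dim(su$emb)
  expect_equal(ncol(both$params$W0),
               2L * su$enc$blstm_hidden + su$enc$max_sdp_len * D)
  expect_equal(ncol(no_sdp$params$W0), 2L * su$enc$blstm_hidden)
  expect_equal(ncol(only_sdp$params$W0), su$enc$max_sdp_len * D)
  expect_error(train_config(use_full_sentence = FALSE, use_sdp = FALSE),
               "at least one")
  # the CNN encoder yields windows x filters features
  cnn <- init_model(su$emb, su$enc,
                    train_config(seed = 3L, use_full_sentence = FALSE,
                                 sdp_encoder = "cnn"))
  expect_equal(ncol(cnn$params$W0),
               length(su$enc$cnn_windows) * su$enc$cnn_filters)
})

test_that("training guards its preconditions", {
  su <- tiny_setup()
  inst <- toy_instance(c("entity_1", "x", "entity_2"), e1 = 1L, e2 = 3L)
  expect_error(train_model(list(), list(inst), su$emb, su$enc, su$tc,
                           su$provider), "empty")
  unlabeled <- inst; unlabeled$label <- NA_character_
  expect_error(train_model(list(unlabeled), list(inst), su$emb, su$enc,
                           su$tc, su$provider), "labels")
  neg <- inst; neg$label <- "negative"
  tc <- train_config(seed = 2L, max_epochs = 1L, dropout = 0)
  expect_warning(train_model(list(inst), list(neg), su$emb, su$enc, tc,
                             su$provider), "no positive")
})

test_that("checkpoints round-trip through save/load", {
  su <- tiny_setup()
  model <- init_model(su$emb, su$enc, su$tc)
  p <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(model, p)
  back <- load_checkpoint(p)
  expect_identical(back$params, model$params)
  expect_identical(back$tc, model$tc)
})
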