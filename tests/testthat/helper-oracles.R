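# Independent oracles used across tests.

# Brute-force shortest simple path by DFS enumeration of all simple paths.
brute_shortest_path_length <- function(adj, from, to) {
  best <- Inf
  dfs <- function(node, visited, len) {
    if (node == to) {
      best <<- min(best, len)
      return(invisible())
    }
    for (nb in adj[[node]]) {
      if (!nb %in% visited) dfs(nb, c(visited, nb), len + 1L)
    }
  }
  dfs(from, from, 0L)
  best
}

# Random connected undirected graph on n nodes: a random spanning tree plus
# a few extra edges. Returns a bb_graph-shaped adjacency list.
random_connected_graph <- function(n, extra = 2L) {
  adj <- replicate(n, integer(), simplify = FALSE)
  link <- function(a, b) {
    adj[[a]] <<- sort(unique(c(adj[[a]], b)))
    adj[[b]] <<- sort(unique(c(adj[[b]], a)))
  }
  for (v in seq_len(n)[-1]) link(v, sample.int(v - 1L, 1L))
  for (k in seq_len(extra)) {
    ab <- sample.int(n, 2L)
    if (ab[1] != ab[2]) link(ab[1], ab[2])
  }
  structure(list(n = n, adj = adj), class = "bb_graph")
}

# Random projective-ish dependency tree over n tokens (head vector, 0 root).
random_tree_heads <- function(n) {
  heads <- integer(n)
  root <- sample.int(n, 1L)
  heads[root] <- 0L
  for (v in seq_len(n)[-root]) {
    pool <- c(root, setdiff(which(heads != 0L | seq_len(n) == root), v))
    heads[v] <- sample(rep(pool, 2L), 1L)
  }
  heads
}

# Small labeled instance for classifier tests, bypassing the corpus pipeline.
toy_instance <- function(tokens, label = "positive",
                         e1 = 1L, e2 = length(tokens),
                         sdp = c(e1, e2)) {
  n <- length(tokens)
  structure(list(
    doc_id = "toy", sent_index = 0L, bacteria_id = "T1", location_id = "T2",
    tokens = tokens, pos_tags = rep("NN", n),
    entity1_pos = e1, entity2_pos = e2, sdp_indices = as.integer(sdp),
    rel_dist1 = as.integer(e1 - seq_len(n)),
    rel_dist2 = as.integer(e2 - seq_len(n)),
    label = label, p_positive = NA_real_), class = "bb_instance")
}

# Tiny model configuration shared by gradient and determinism tests.
tiny_setup <- function(sdp_encoder = "mha", seed = 3L, dropout = 0,
                       use_sentence_embedding = FALSE) {
  list(
    emb = embedding_config(word_dim = 6L, pos_dim = 4L, dist_dim = 3L,
                           s = 5L, pos_vocab = c("NN", "VB"), seed = 1L),
    enc = encoder_config(blstm_hidden = 5L, mha_stacks = 2L, mha_heads = 2L,
                         cnn_windows = 3L, cnn_filters = 2L,
                         max_sdp_len = 4L),
    tc = train_config(dropout = dropout, seed = seed,
                      sdp_encoder = sdp_encoder,
                      use_sentence_embedding = use_sentence_embedding),
    provider = word_provider_hash(dim = 6L, seed = 9L))
}

# Synthetic train/dev/test splits derived from disjoint seeds.
synth_split <- function(n_train, n_dev, n_test, base_seed = 100L,
                        n_docs_per_100 = 30L, ...) {
  gen <- function(n_docs, seed) {
    corpus_instances(generate_corpus(
      synth_config(n_docs = n_docs, seed = seed, ...))$docs)$instances
  }
  take <- function(n, seed) {
    out <- gen(ceiling(n * n_docs_per_100 / 100) + 5L, seed)
    stopifnot(length(out) >= n)
    out[seq_len(n)]
  }
  list(train = take(n_train, base_seed),
       dev = take(n_dev, base_seed + 1L),
       test = take(n_test, base_seed + 2L))
}

# Finite-difference check of the full-model analytic gradient on a tiny
# instance; max absolute deviation over a random parameter sample must stay
# below tol.
fd_check <- function(sdp_encoder, n_checked = 80L, tol = 1e-4) {
  su <- tiny_setup(sdp_encoder = sdp_encoder)
  model <- init_model(su$emb, su$enc, su$tc)
  inst <- toy_instance(c("entity_1", "foo", "bar", "entity_2", "baz"),
                       e1 = 1L, e2 = 4L, sdp = c(1L, 2L, 4L))
  prep <- bbrex:::prepare_instance(inst, su$provider, model)
  loss_of <- function(params) {
    m2 <- model
    m2$params <- params
    fw <- bbrex:::model_forward(m2, prep, NULL, training = FALSE)
    bbrex:::categorical_ce(prep$y, fw$probs)
  }
  fw <- bbrex:::model_forward(model, prep, NULL, training = FALSE)
  analytic <- unlist(bbrex:::model_backward(model, prep, fw))
  flat <- unlist(model$params)
  expect_identical(names(analytic), names(flat))
  set.seed(17)
  idx <- sort(sample.int(length(flat), n_checked))
  eps <- 1e-6
  numeric_g <- vapply(idx, function(j) {
    up <- flat; up[j] <- up[j] + eps
    dn <- flat; dn[j] <- dn[j] - eps
    (loss_of(relist(up, model$params)) -
       loss_of(relist(dn, model$params))) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(numeric_g - analytic[idx])), tol)
}

# Instance-level PRF of predictions against instance labels.
instance_f1 <- function(preds, instances) {
  gold_pos <- vapply(instances, function(x)
    identical(x$label, "positive"), logical(1))
  tp <- sum(preds$decision & gold_pos)
  fp <- sum(preds$decision) - tp
  fn <- sum(gold_pos) - tp
  bbrex:::prf_from_counts(tp, fp, fn)
}
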