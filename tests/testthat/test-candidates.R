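test_that("mention-to-token alignment finds minimal covering spans", {
  fx <- make_worked_fixtures()
  al <- align_mentions_to_tokens(fx$hpylori)
  # single-token mention
  j <- al[al$mention_id == "T3", ]
  expect_equal(j$tok_end - j$tok_start, 0L)
  # two-token mention "Helicobacter pylori"
  hp <- al[al$mention_id == "T1", ]
  expect_equal(c(hp$tok_start, hp$tok_end), c(2L, 3L))
})

test_that("mentions straddling a sentence boundary are skipped", {
  text <- "Aaa bbb . Ccc ddd ."
  mentions <- data.frame(id = "T1", category = "Bacteria", start = 4L,
                         end = 13L, surface = "bbb . Ccc",
                         stringsAsFactors = FALSE)
  doc <- bbrex:::new_document("x", text, mentions, bbrex:::empty_relations())
  mk <- function(i, forms) bbrex:::new_sentence(i, data.frame(
    form = forms, pos = rep("NN", length(forms)),
    head = c(rep(length(forms), length(forms) - 1L), 0L),
    deprel = "dep", stringsAsFactors = FALSE))
  doc <- attach_sentences(doc, list(mk(0L, c("Aaa", "bbb", ".")),
                                    mk(1L, c("Ccc", "ddd", "."))))
  expect_warning(al <- align_mentions_to_tokens(doc), "skipped")
  expect_equal(nrow(al), 0L)
  expect_equal(attr(al, "n_unaligned"), 1L)
})

test_that("blinding collapses mentions and lowercases (worked example)", {
  fx <- make_worked_fixtures()
  res <- generate_candidates(fx$hpylori)
  expect_length(res$instances, 2L)
  blinded <- vapply(res$instances, function(x)
    paste(x$tokens, collapse = " "), character(1))
  expect_setequal(blinded, c(
    paste("long-term entity_1 infection and the development of atrophic",
          "gastritis and entity_2 cancer in japan ."),
    paste("long-term entity_1 infection and the development of atrophic",
          "gastritis and gastric cancer in entity_2 .")))
  # blinded entity token inherits the mention's first original POS
  inst <- res$instances[[1]]
  expect_equal(inst$pos_tags[inst$entity1_pos], "NN")
  # overlapping spans are rejected
  expect_error(blind_and_normalize(c("a", "b", "c"), c("NN", "NN", "NN"),
                                   c(1L, 2L), c(2L, 3L)), "overlap")
})

test_that("dependency graph construction collapses mention spans", {
  # chain a <- b <- c: heads (2, 3, 0)
  g <- build_dependency_graph(c(2L, 3L, 0L), 1:3)
  expect_equal(sum(lengths(g$adj)) / 2, 2)
  # collapsing tokens 1-2 removes the internal edge, re-attaches external
  g2 <- build_dependency_graph(c(2L, 3L, 0L), c(1L, 1L, 2L))
  expect_equal(g2$n, 2L)
  expect_equal(g2$adj[[1]], 2L)

  # random trees with an adjacent (head, dependent) pair collapsed, as a
  # contiguous mention is: the result is again a tree with n - 1 nodes,
  # so edge count equals n_after_collapse - 1
  set.seed(11)
  for (rep in 1:25) {
    heads <- random_tree_heads(8L)
    v <- sample(which(heads != 0L), 1L)
    h <- heads[v]
    pair <- sort(c(v, h))
    map <- seq_len(8L)
    map[pair[2]] <- pair[1]
    map[map > pair[2]] <- map[map > pair[2]] - 1L
    g <- build_dependency_graph(heads, map)
    n_edges <- sum(lengths(g$adj)) / 2
    expect_equal(n_edges, g$n - 1L)
    # connectivity: every node reachable
    expect_true(all(is.finite(bbrex:::dijkstra_distances(g, 1L))))
  }
})

test_that("shortest path matches brute-force enumeration and breaks ties", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(3:10, 1L)
    g <- random_connected_graph(n)
    ft <- sample.int(n, 2L)
    p <- shortest_dependency_path(g, ft[1], ft[2])
    expect_equal(length(p) - 1L,
                 brute_shortest_path_length(g$adj, ft[1], ft[2]))
    expect_equal(p[1], ft[1])
    expect_equal(p[length(p)], ft[2])
  }
  # deterministic lexicographic tie-break: 1-2-4 and 1-3-4 both shortest
  g <- structure(list(n = 4L, adj = list(c(2L, 3L), c(1L, 4L), c(1L, 4L),
                                         c(2L, 3L))), class = "bb_graph")
  expect_equal(shortest_dependency_path(g, 1L, 4L), c(1L, 2L, 4L))
  # disconnected nodes yield no path
  g <- structure(list(n = 3L, adj = list(2L, 1L, integer())),
                 class = "bb_graph")
  expect_null(shortest_dependency_path(g, 1L, 3L))
})

test_that("relative distances follow the entity-minus-token convention", {
  fx <- make_worked_fixtures()
  inst <- generate_candidates(fx$mycobacteria)$instances[[1]]
  probe <- which(inst$tokens == "in")
  expect_equal(inst$rel_dist1[probe], -4L)
  expect_equal(inst$rel_dist2[probe], 1L)
  expect_false(probe %in% inst$sdp_indices)
  expect_equal(inst$rel_dist1[inst$entity1_pos], 0L)
  # algebraic invariant: rel_dist1 - rel_dist2 is constant
  rd <- relative_distances(12L, 3L, 9L)
  expect_true(all(rd$rel_dist1 - rd$rel_dist2 == 3L - 9L))
})

test_that("candidate enumeration counts pairs and reconciles counters", {
  fx <- make_worked_fixtures()
  res <- generate_candidates(fx$hpylori)
  expect_length(res$instances, 2L)  # 1 bacteria x 2 locations

  # a corpus-level reconciliation: instances = intra - skipped
  corp <- generate_corpus(synth_config(n_docs = 15L, seed = 23L))
  ci <- corpus_instances(corp$docs)
  expect_equal(length(ci$instances),
               unname(ci$counts["pairs_intra"] -
                        ci$counts["skipped_no_sdp"] -
                        ci$counts["skipped_overlap"]))
  # SDP invariants: both entities on every path, path within the sentence
  for (inst in ci$instances) {
    expect_lte(length(inst$sdp_indices), length(inst$tokens))
    expect_true(inst$entity1_pos %in% inst$sdp_indices)
    expect_true(inst$entity2_pos %in% inst$sdp_indices)
  }
})

test_that("instances survive a JSONL round trip", {
  corp <- generate_corpus(synth_config(n_docs = 3L, seed = 9L))
  ci <- corpus_instances(corp$docs)
  p <- withr::local_tempfile(fileext = ".jsonl")
  write_instances(ci$instances, p)
  back <- read_instances(p)
  expect_length(back, length(ci$instances))
  for (k in seq_along(back)) {
    expect_equal(back[[k]]$tokens, ci$instances[[k]]$tokens)
    expect_equal(back[[k]]$sdp_indices, ci$instances[[k]]$sdp_indices)
    expect_equal(back[[k]]$label, ci$instances[[k]]$label)
  }
})
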