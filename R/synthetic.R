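#' Synthetic-corpus configuration
#'
#' Controls the toy-corpus generator. Sentences are built from templated
#' dependency trees over a random filler vocabulary; each sentence carries
#' bacteria and location mentions, and a pair's gold label follows a
#' planted rule: positive iff the cue token lies on the dependency path
#' between the two entities. The rule lives on the dependency path, not on
#' the surface sentence (the cue also appears off-path in purely negative
#' sentences), so path features are genuinely needed to reach ceiling
#' performance.
#'
#' @param n_docs number of documents
#' @param sentence_len_range `(min, max)` tokens per sentence (min >= 4)
#' @param bacteria_per_sentence,locations_per_sentence `(min, max)` mention
#'   counts per sentence
#' @param sentences_per_doc `(min, max)` sentences per document
#' @param cue_token the cue word whose presence on the path makes a pair
#'   positive
#' @param positive_rate probability that a location attaches on the cue
#'   path (controls class balance)
#' @param label_noise probability of flipping a rule label
#' @param vocab_size filler vocabulary size (> 10)
#' @param seed integer seed; equal seeds give byte-identical corpora
#' @return a `synth_config` list
#' @export
synth_config <- function(n_docs = 40L, sentence_len_range = c(8L, 14L),
                         bacteria_per_sentence = c(1L, 2L),
                         locations_per_sentence = c(1L, 2L),
                         sentences_per_doc = c(1L, 2L),
                         cue_token = "inhabits", positive_rate = 0.5,
                         label_noise = 0, vocab_size = 50L, seed = 1L) {
  if (sentence_len_range[1] < 4L) stop("minimum sentence length must be >= 4")
  if (vocab_size <= 10L) stop("vocab_size must be > 10")
  if (label_noise < 0 || label_noise >= 1) stop("label_noise must be in [0, 1)")
  core_max <- 2L * max(bacteria_per_sentence) +
    max(locations_per_sentence) + 4L
  if (core_max > max(sentence_len_range) + 6L) {
    stop("entities cannot fit in the configured sentence length")
  }
  structure(list(n_docs = as.integer(n_docs),
                 sentence_len_range = as.integer(sentence_len_range),
                 bacteria_per_sentence = as.integer(bacteria_per_sentence),
                 locations_per_sentence = as.integer(locations_per_sentence),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 cue_token = cue_token, positive_rate = positive_rate,
                 label_noise = label_noise,
                 vocab_size = as.integer(vocab_size),
                 seed = as.integer(seed)),
            class = "synth_config")
}

rand_word <- function(len_range = c(3L, 7L)) {
  paste(sample(letters, sample(len_range[1]:len_range[2], 1L),
               replace = TRUE), collapse = "")
}

capitalize <- function(w) {
  paste0(toupper(substring(w, 1, 1)), substring(w, 2))
}

# Unique path between two nodes of a dependency tree given head pointers
# (independent of the Dijkstra machinery: climbs to the root from both
# ends and joins at the lowest common ancestor).
tree_path <- function(heads, a, b) {
  anc <- function(x) {
    out <- x
    while (heads[x] != 0L) {
      x <- heads[x]
      out <- c(out, x)
    }
    out
  }
  pa <- anc(a); pb <- anc(b)
  lca <- pa[pa %in% pb][1]
  c(pa[seq_len(match(lca, pa))], rev(pb[seq_len(match(lca, pb) - 1L)]))
}

# Build one synthetic sentence: token table, mention spans, and per-pair
# rule labels.
synth_sentence <- function(cfg, vocab) {
  nb <- sample(cfg$bacteria_per_sentence[1]:cfg$bacteria_per_sentence[2], 1L)
  nl <- sample(cfg$locations_per_sentence[1]:cfg$locations_per_sentence[2], 1L)
  target_len <- sample(cfg$sentence_len_range[1]:cfg$sentence_len_range[2], 1L)
  loc_positive <- stats::runif(nl) < cfg$positive_rate
  has_pos <- any(loc_positive)
  cue_present <- has_pos || stats::runif(1) < 0.5

  form <- character(); pos <- character(); slot <- character()
  add <- function(f, p, s) {
    form <<- c(form, f); pos <<- c(pos, p); slot <<- c(slot, s)
    length(form)
  }
  bact_spans <- list()
  for (k in seq_len(nb)) {
    two <- stats::runif(1) < 0.3
    first <- add(capitalize(rand_word()), "NN", paste0("b", k))
    if (two) {
      last <- add(rand_word(), "NN", paste0("b", k))
      bact_spans[[k]] <- c(first, last)
    } else {
      bact_spans[[k]] <- c(first, first)
    }
  }
  core <- length(form) + 1L + nl + 1L + cue_present + (cue_present && !has_pos)
  n_fill <- max(0L, target_len - core)
  n_pre <- if (n_fill > 0L) sample(0:n_fill, 1L) else 0L
  for (k in seq_len(n_pre)) {
    add(vocab$fillers[sample.int(length(vocab$fillers), 1L)],
        sample(c("JJ", "DT", "IN"), 1L), "fill")
  }
  v_idx <- add(vocab$verbs[sample.int(length(vocab$verbs), 1L)], "VB", "V")
  cue_idx <- NA_integer_
  host_idx <- NA_integer_
  if (cue_present && has_pos) {
    cue_idx <- add(cfg$cue_token, "VB", "cue")
  } else if (cue_present) {
    host_idx <- add(vocab$fillers[sample.int(length(vocab$fillers), 1L)],
                    "NN", "host")
    cue_idx <- add(cfg$cue_token, "VB", "cue")
  }
  loc_idx <- integer(nl)
  loc_geo <- logical(nl)
  ord <- order(!loc_positive)  # positives first (they sit under the cue)
  for (k in ord) {
    loc_geo[k] <- stats::runif(1) < 0.5
    w <- vocab$fillers[sample.int(length(vocab$fillers), 1L)]
    loc_idx[k] <- add(if (loc_geo[k]) capitalize(w) else w, "NN",
                      paste0("l", k))
  }
  for (k in seq_len(n_fill - n_pre)) {
    add(vocab$fillers[sample.int(length(vocab$fillers), 1L)],
        sample(c("NN", "JJ", "IN", "DT"), 1L), "fill")
  }
  dot_idx <- add(".", ".", "punct")

  heads <- integer(length(form))
  for (k in seq_len(nb)) {
    sp <- bact_spans[[k]]
    if (sp[1] != sp[2]) heads[sp[1]] <- sp[2]
    heads[sp[2]] <- v_idx
  }
  heads[which(slot == "fill")] <- v_idx
  heads[v_idx] <- 0L
  if (!is.na(host_idx)) heads[host_idx] <- v_idx
  if (!is.na(cue_idx)) {
    heads[cue_idx] <- if (!is.na(host_idx)) host_idx else v_idx
  }
  for (k in seq_len(nl)) {
    heads[loc_idx[k]] <- if (loc_positive[k]) cue_idx else v_idx
  }
  heads[dot_idx] <- v_idx
  deprel <- ifelse(heads == 0L, "root", "dep")

  labels <- matrix(FALSE, nb, nl)
  for (bi in seq_len(nb)) {
    for (li in seq_len(nl)) {
      path <- tree_path(heads, bact_spans[[bi]][2], loc_idx[li])
      on_path <- !is.na(cue_idx) && cue_idx %in% path
      if (stats::runif(1) < cfg$label_noise) on_path <- !on_path
      labels[bi, li] <- on_path
    }
  }
  list(tokens = data.frame(form = form, pos = pos, head = heads,
                           deprel = deprel, stringsAsFactors = FALSE),
       bact_spans = bact_spans, loc_idx = loc_idx, loc_geo = loc_geo,
       labels = labels)
}

#' Generate a synthetic annotated, parsed corpus
#'
#' Produces documents in the exact standoff + CoNLL-U formats the real
#' pipeline ingests, with a planted dependency-path rule determining the
#' gold labels (see [synth_config()]). With `dir` given, writes
#' `<doc>.txt/.a1/.a2/.conllu` files; equal seeds give byte-identical
#' output.
#'
#' @param cfg a [synth_config()]
#' @param dir optional output directory
#' @return list with `docs` (list of `bb_document` with sentences
#'   attached) and `gold` (data.frame of positive relations: `doc_id`,
#'   `bacteria_id`, `location_id`, `inter_sentence`)
#' @export
generate_corpus <- function(cfg, dir = NULL) {
  set.seed(cfg$seed)
  vocab <- list(
    fillers = unique(replicate(cfg$vocab_size, rand_word())),
    verbs = unique(replicate(max(5L, cfg$vocab_size %/% 10L), rand_word())))
  vocab$fillers <- setdiff(vocab$fillers, cfg$cue_token)
  vocab$verbs <- setdiff(vocab$verbs, c(cfg$cue_token, vocab$fillers))
  if (!length(vocab$verbs)) vocab$verbs <- "told"

  docs <- list()
  gold <- data.frame(doc_id = character(), bacteria_id = character(),
                     location_id = character(), inter_sentence = logical(),
                     stringsAsFactors = FALSE)
  for (d in seq_len(cfg$n_docs)) {
    doc_id <- sprintf("synth-%03d", d)
    n_sent <- sample(cfg$sentences_per_doc[1]:cfg$sentences_per_doc[2], 1L)
    sents <- lapply(seq_len(n_sent), function(i) synth_sentence(cfg, vocab))
    text <- ""
    mentions <- empty_mentions()
    relations <- empty_relations()
    parsed <- list()
    t_counter <- 0L
    offset <- 0L
    for (si in seq_along(sents)) {
      s <- sents[[si]]
      forms <- s$tokens$form
      starts <- offset + c(0L, cumsum(nchar(forms) + 1L))[seq_along(forms)]
      ends <- starts + nchar(forms)
      sent_text <- paste(forms, collapse = " ")
      text <- if (nzchar(text)) paste(text, sent_text) else sent_text
      offset <- nchar(text) + 1L
      mk_mention <- function(category, tok_from, tok_to) {
        t_counter <<- t_counter + 1L
        id <- paste0("T", t_counter)
        mentions <<- rbind(mentions, data.frame(
          id = id, category = category, start = starts[tok_from],
          end = ends[tok_to],
          surface = paste(forms[tok_from:tok_to], collapse = " "),
          stringsAsFactors = FALSE))
        id
      }
      b_ids <- vapply(s$bact_spans, function(sp)
        mk_mention("Bacteria", sp[1], sp[2]), character(1))
      l_ids <- vapply(seq_along(s$loc_idx), function(k)
        mk_mention(if (s$loc_geo[k]) "Geographical" else "Habitat",
                   s$loc_idx[k], s$loc_idx[k]), character(1))
      for (bi in seq_along(b_ids)) {
        for (li in seq_along(l_ids)) {
          if (s$labels[bi, li]) {
            relations <- rbind(relations, data.frame(
              id = paste0("R", nrow(relations) + 1L),
              bacteria_id = b_ids[bi], location_id = l_ids[li],
              label = "positive", stringsAsFactors = FALSE))
            gold <- rbind(gold, data.frame(
              doc_id = doc_id, bacteria_id = b_ids[bi],
              location_id = l_ids[li], inter_sentence = FALSE,
              stringsAsFactors = FALSE))
          }
        }
      }
      parsed[[si]] <- new_sentence(si - 1L, s$tokens)
    }
    doc <- new_document(doc_id, text, mentions, relations)
    doc <- attach_sentences(doc, parsed)
    docs[[d]] <- doc
    if (!is.null(dir)) {
      write_standoff(doc, dir)
      write_conllu(parsed, file.path(dir, paste0(doc_id, ".conllu")))
      if (!nrow(relations)) {
        writeLines(character(), file.path(dir, paste0(doc_id, ".a2")))
      }
    }
  }
  list(docs = docs, gold = gold)
}

#' Candidate instances for a whole corpus
#'
#' Runs [generate_candidates()] over every document and pools the results.
#'
#' @param docs list of `bb_document` with attached sentences
#' @param labeled attach gold labels
#' @return list with `instances` and summed `counts`
#' @export
corpus_instances <- function(docs, labeled = TRUE) {
  instances <- list()
  counts <- NULL
  for (doc in docs) {
    res <- generate_candidates(doc, labeled = labeled)
    instances <- c(instances, res$instances)
    counts <- if (is.null(counts)) res$counts else counts + res$counts
  }
  list(instances = instances, counts = counts)
}

#' Worked-example fixtures
#'
#' Builds two small hand-annotated documents serving as worked examples
#' for the preprocessing pipeline:
#'
#' * `hpylori` — a sentence with one bacteria mention
#'   ("Helicobacter pylori") and two location mentions ("gastric",
#'   "Japan"), yielding exactly two candidate instances whose blinded,
#'   lowercased forms are known strings.
#' * `mycobacteria` — a sentence in which the bacteria token precedes the probe
#'   token "in" by 4 positions and the location follows it by 1, with a
#'   hand-built plausible parse in which "in" is off the entity-entity
#'   dependency path (so its relative distances are (-4, 1) and it is
#'   absent from the SDP).
#'
#' @return list of two `bb_document`s (`hpylori`, `mycobacteria`) with parses
#'   attached
#' @export
make_worked_fixtures <- function() {
  hp_text <- paste("Long-term Helicobacter pylori infection and the",
                   "development of atrophic gastritis and gastric cancer",
                   "in Japan.")
  hp_tokens <- data.frame(
    form = c("Long-term", "Helicobacter", "pylori", "infection", "and",
             "the", "development", "of", "atrophic", "gastritis", "and",
             "gastric", "cancer", "in", "Japan", "."),
    pos = c("JJ", "NN", "NN", "NN", "CC", "DT", "NN", "IN", "JJ", "NN",
            "CC", "JJ", "NN", "IN", "NNP", "."),
    head = c(4L, 3L, 4L, 0L, 4L, 7L, 4L, 7L, 10L, 8L, 10L, 13L, 10L, 13L,
             14L, 4L),
    deprel = c("amod", "nn", "nn", "root", "cc", "det", "conj", "prep",
               "amod", "pobj", "cc", "amod", "conj", "prep", "pobj",
               "punct"),
    stringsAsFactors = FALSE)
  find <- function(text, surface) {
    start <- regexpr(surface, text, fixed = TRUE)[1] - 1L
    c(start, start + nchar(surface))
  }
  m <- function(id, category, text, surface) {
    sp <- find(text, surface)
    data.frame(id = id, category = category, start = sp[1], end = sp[2],
               surface = surface, stringsAsFactors = FALSE)
  }
  hp_mentions <- rbind(
    m("T1", "Bacteria", hp_text, "Helicobacter pylori"),
    m("T2", "Habitat", hp_text, "gastric"),
    m("T3", "Geographical", hp_text, "Japan"))
  hpylori <- new_document("hpylori", hp_text, hp_mentions, empty_relations())
  hpylori <- attach_sentences(hpylori, list(new_sentence(0L, hp_tokens)))

  my_text <- "Mycobacteria were mostly identified in Queensland ."
  my_tokens <- data.frame(
    form = c("Mycobacteria", "were", "mostly", "identified", "in",
             "Queensland", "."),
    pos = c("NN", "VB", "RB", "VB", "IN", "NNP", "."),
    head = c(4L, 4L, 4L, 0L, 4L, 4L, 4L),
    deprel = c("nsubj", "aux", "advmod", "root", "prep", "pobj", "punct"),
    stringsAsFactors = FALSE)
  my_mentions <- rbind(
    m("T1", "Bacteria", my_text, "Mycobacteria"),
    m("T2", "Geographical", my_text, "Queensland"))
  my_relations <- data.frame(id = "R1", bacteria_id = "T1",
                             location_id = "T2", label = "positive",
                             stringsAsFactors = FALSE)
  mycobacteria <- new_document("mycobacteria", my_text, my_mentions, my_relations)
  mycobacteria <- attach_sentences(mycobacteria, list(new_sentence(0L, my_tokens)))

  list(hpylori = hpylori, mycobacteria = mycobacteria)
}
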