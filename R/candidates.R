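#' Attach dependency parses to a document
#'
#' Aligns each parsed sentence's tokens to the document text by sequential
#' matching (whitespace between tokens is skipped), recording per-token and
#' per-sentence character offsets. The tokenization must be consistent with
#' the raw text; a token that cannot be matched raises an error.
#'
#' @param doc a `bb_document` from [read_standoff()]
#' @param sentences list of `bb_sentence` from [read_conllu()]
#' @return the document with `sentences` attached; each sentence gains
#'   `char_start`/`char_end` and token columns `start`/`end` (0-based,
#'   half-open offsets into the document text)
#' @export
attach_sentences <- function(doc, sentences) {
  text <- doc$text
  n <- nchar(text)
  pos <- 0L  # 0-based offset of the next unread character
  chars <- strsplit(text, "")[[1]]
  for (si in seq_along(sentences)) {
    s <- sentences[[si]]
    t <- s$tokens
    starts <- integer(nrow(t))
    ends <- integer(nrow(t))
    for (k in seq_len(nrow(t))) {
      while (pos < n && grepl("^\\s$", chars[pos + 1L])) pos <- pos + 1L
      tok <- t$form[k]
      w <- nchar(tok)
      if (pos + w > n || substring(text, pos + 1L, pos + w) != tok) {
        stop("cannot align token '", tok, "' (sentence ", s$sent_index,
             ") at text offset ", pos, " of document '", doc$doc_id, "'")
      }
      starts[k] <- pos
      ends[k] <- pos + w
      pos <- pos + w
    }
    t$start <- starts
    t$end <- ends
    s$tokens <- t
    s$char_start <- starts[1]
    s$char_end <- ends[length(ends)]
    sentences[[si]] <- s
  }
  doc$sentences <- sentences
  doc
}

#' Map entity mentions to token spans
#'
#' Each mention is mapped to the minimal token span of a single sentence
#' whose character extent covers the mention. Mentions that straddle a
#' sentence boundary, or that no sentence's tokens cover, are skipped with a
#' warning (they cannot yield intra-sentence candidates).
#'
#' @param doc a `bb_document` with aligned sentences ([attach_sentences()])
#' @return data.frame with columns `mention_id`, `sent_index` (0-based),
#'   `tok_start`, `tok_end` (1-based, inclusive token indices); an attribute
#'   `n_unaligned` counts skipped mentions
#' @export
align_mentions_to_tokens <- function(doc) {
  if (!length(doc$sentences)) stop("document has no attached sentences")
  out <- data.frame(mention_id = character(), sent_index = integer(),
                    tok_start = integer(), tok_end = integer(),
                    stringsAsFactors = FALSE)
  n_unaligned <- 0L
  for (mi in seq_len(nrow(doc$mentions))) {
    m <- doc$mentions[mi, ]
    hit <- NULL
    for (s in doc$sentences) {
      t <- s$tokens
      cover <- which(t$end > m$start & t$start < m$end)
      if (!length(cover)) next
      span_start <- min(cover)
      span_end <- max(cover)
      if (t$start[span_start] > m$start || t$end[span_end] < m$end) {
        # tokens only partially cover the mention inside this sentence:
        # accept as long as the mention lies within the sentence extent
        if (m$start < s$char_start || m$end > s$char_end) next
      }
      hit <- data.frame(mention_id = m$id, sent_index = s$sent_index,
                        tok_start = span_start, tok_end = span_end,
                        stringsAsFactors = FALSE)
      break
    }
    if (is.null(hit)) {
      warning("mention ", m$id, " ('", m$surface,
              "') could not be aligned to a single sentence; skipped",
              call. = FALSE)
      n_unaligned <- n_unaligned + 1L
    } else {
      out <- rbind(out, hit)
    }
  }
  attr(out, "n_unaligned") <- n_unaligned
  out
}

#' Blind entity mentions and lowercase a sentence
#'
#' Collapses the bacteria mention span to the single token `entity_1` and
#' the location span to `entity_2`, lowercasing all remaining tokens. The
#' POS of a blinded token is the POS of the mention's first original token.
#'
#' @param tokens character vector of sentence tokens
#' @param pos_tags character vector of POS tags aligned to `tokens`
#' @param bacteria_span,location_span 1-based inclusive `(start, end)` token
#'   index pairs; spans must be disjoint
#' @return list with `tokens`, `pos_tags`, `entity1_pos`, `entity2_pos`
#'   (1-based positions in the blinded sequence) and `index_map` (original
#'   token index -> blinded index)
#' @export
blind_and_normalize <- function(tokens, pos_tags, bacteria_span,
                                location_span) {
  b <- bacteria_span; l <- location_span
  if (max(b[1], l[1]) <= min(b[2], l[2])) {
    stop("bacteria and location token spans overlap")
  }
  n <- length(tokens)
  index_map <- integer(n)
  out_tokens <- character()
  out_pos <- character()
  e1 <- e2 <- NA_integer_
  i <- 1L
  while (i <= n) {
    if (i == b[1]) {
      out_tokens <- c(out_tokens, "entity_1")
      out_pos <- c(out_pos, pos_tags[b[1]])
      e1 <- length(out_tokens)
      index_map[b[1]:b[2]] <- e1
      i <- b[2] + 1L
    } else if (i == l[1]) {
      out_tokens <- c(out_tokens, "entity_2")
      out_pos <- c(out_pos, pos_tags[l[1]])
      e2 <- length(out_tokens)
      index_map[l[1]:l[2]] <- e2
      i <- l[2] + 1L
    } else {
      out_tokens <- c(out_tokens, tolower(tokens[i]))
      out_pos <- c(out_pos, pos_tags[i])
      index_map[i] <- length(out_tokens)
      i <- i + 1L
    }
  }
  list(tokens = out_tokens, pos_tags = out_pos,
       entity1_pos = e1, entity2_pos = e2, index_map = index_map)
}

#' Build the undirected dependency graph of a blinded sentence
#'
#' One node per blinded token; an undirected unit-weight edge joins every
#' non-root token to its governor. Edges incident to tokens inside a
#' collapsed mention re-attach to the mention's single blinded node;
#' self-loops (internal mention edges) and duplicate edges are dropped.
#'
#' @param heads integer vector of original-token head indices (0 = root)
#' @param index_map original token index -> blinded token index, as returned
#'   by [blind_and_normalize()]
#' @return a `bb_graph`: list with `n` nodes and adjacency list `adj`
#'   (sorted integer neighbor vectors)
#' @export
build_dependency_graph <- function(heads, index_map) {
  n <- max(index_map)
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer()
  for (i in seq_along(heads)) {
    h <- heads[i]
    if (h == 0L) next
    a <- index_map[i]
    b <- index_map[h]
    if (a == b) next
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  for (k in seq_len(n)) adj[[k]] <- sort(unique(adj[[k]]))
  structure(list(n = n, adj = adj), class = "bb_graph")
}

#' Shortest dependency path between two entity tokens
#'
#' Dijkstra's algorithm on the undirected unit-weight dependency graph.
#' Among equally short paths the lexicographically smallest index sequence
#' is returned, so preprocessing is reproducible across runs and platforms.
#'
#' @param graph a `bb_graph` from [build_dependency_graph()]
#' @param from,to node indices (the two blinded entity positions)
#' @return integer vector of node indices from `from` to `to` inclusive, or
#'   `NULL` when the entities are not connected
#' @export
shortest_dependency_path <- function(graph, from, to) {
  n <- graph$n
  if (from < 1L || from > n || to < 1L || to > n) {
    stop("path endpoints must be graph nodes")
  }
  if (from == to) return(from)
  d_from <- dijkstra_distances(graph, from)
  if (!is.finite(d_from[to])) return(NULL)
  d_to <- dijkstra_distances(graph, to)
  total <- d_from[to]
  path <- integer(total + 1L)
  path[1] <- from
  cur <- from
  for (step in seq_len(total)) {
    nb <- graph$adj[[cur]]
    ok <- nb[d_from[nb] == d_from[cur] + 1 & d_from[nb] + d_to[nb] == total]
    cur <- min(ok)  # lexicographic tie-break
    path[step + 1L] <- cur
  }
  path
}

# Single-source Dijkstra with unit edge weights (O(n^2) scan; sentences are
# short). Returns the distance vector with Inf for unreachable nodes.
dijkstra_distances <- function(graph, source) {
  n <- graph$n
  dist <- rep(Inf, n)
  dist[source] <- 0
  visited <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which(!visited & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    visited[u] <- TRUE
    for (v in graph$adj[[u]]) {
      if (dist[u] + 1 < dist[v]) dist[v] <- dist[u] + 1
    }
  }
  dist
}

#' Per-token relative distances to the two entities
#'
#' For token `i`, the distance to entity `j` is `entity_j_pos - i` (in
#' tokens, on the blinded sequence): a token 4 positions after the bacteria
#' entity and 1 before the location gets the pair (-4, 1).
#'
#' @param n_tokens number of (blinded) tokens
#' @param entity1_pos,entity2_pos 1-based entity token positions
#' @return list with integer vectors `rel_dist1`, `rel_dist2`
#' @export
relative_distances <- function(n_tokens, entity1_pos, entity2_pos) {
  i <- seq_len(n_tokens)
  list(rel_dist1 = as.integer(entity1_pos - i),
       rel_dist2 = as.integer(entity2_pos - i))
}

#' Generate candidate instances from an annotated, parsed document
#'
#' Enumerates every (Bacteria, Habitat-or-Geographical) mention pair within
#' the same sentence and turns it into a classification instance: blinded
#' lowercased tokens, the shortest dependency path between the two entity
#' tokens, and per-token relative distances. Pairs with no dependency path
#' between the entities are dropped and counted, as are pairs whose mention
#' spans overlap; pairs in different sentences produce no instance but are
#' counted for false-negative bookkeeping.
#'
#' @param doc a `bb_document` with aligned sentences
#' @param labeled attach gold labels from `doc$relations` (a pair absent
#'   from the gold positives is labeled negative); when `FALSE`, labels are
#'   `NA`
#' @return list with `instances` (list of `bb_instance`) and `counts`
#'   (named integer vector: `pairs_intra`, `skipped_no_sdp`,
#'   `skipped_overlap`, `pairs_inter_sentence`, `mentions_unaligned`,
#'   `gold_inter_sentence`)
#' @export
generate_candidates <- function(doc, labeled = TRUE) {
  align <- align_mentions_to_tokens(doc)
  cat_of <- stats::setNames(doc$mentions$category, doc$mentions$id)
  gold_keys <- paste(doc$relations$bacteria_id, doc$relations$location_id)
  sent_of <- stats::setNames(align$sent_index, align$mention_id)

  bact_ids <- doc$mentions$id[cat_of[doc$mentions$id] == "Bacteria"]
  loc_ids <- doc$mentions$id[cat_of[doc$mentions$id] %in%
                               c("Habitat", "Geographical")]
  bact_ids <- bact_ids[bact_ids %in% align$mention_id]
  loc_ids <- loc_ids[loc_ids %in% align$mention_id]

  counts <- c(pairs_intra = 0L, skipped_no_sdp = 0L, skipped_overlap = 0L,
              pairs_inter_sentence = 0L,
              mentions_unaligned = attr(align, "n_unaligned"),
              gold_inter_sentence = 0L)
  instances <- list()

  for (b in bact_ids) {
    for (l in loc_ids) {
      if (sent_of[[b]] != sent_of[[l]]) {
        counts["pairs_inter_sentence"] <- counts["pairs_inter_sentence"] + 1L
        next
      }
      counts["pairs_intra"] <- counts["pairs_intra"] + 1L
      si <- sent_of[[b]]
      sent <- doc$sentences[[which(vapply(doc$sentences, function(s)
        s$sent_index, integer(1)) == si)]]
      ab <- align[align$mention_id == b, ]
      al <- align[align$mention_id == l, ]
      b_span <- c(ab$tok_start, ab$tok_end)
      l_span <- c(al$tok_start, al$tok_end)
      if (max(b_span[1], l_span[1]) <= min(b_span[2], l_span[2])) {
        warning("overlapping mention pair (", b, ", ", l, ") skipped",
                call. = FALSE)
        counts["skipped_overlap"] <- counts["skipped_overlap"] + 1L
        next
      }
      bl <- blind_and_normalize(sent$tokens$form, sent$tokens$pos,
                                b_span, l_span)
      graph <- build_dependency_graph(sent$tokens$head, bl$index_map)
      sdp <- shortest_dependency_path(graph, bl$entity1_pos, bl$entity2_pos)
      if (is.null(sdp)) {
        counts["skipped_no_sdp"] <- counts["skipped_no_sdp"] + 1L
        next
      }
      rd <- relative_distances(length(bl$tokens), bl$entity1_pos,
                               bl$entity2_pos)
      label <- if (!labeled) NA_character_ else
        if (paste(b, l) %in% gold_keys) "positive" else "negative"
      instances[[length(instances) + 1L]] <- structure(list(
        doc_id = doc$doc_id, sent_index = si,
        bacteria_id = b, location_id = l,
        tokens = bl$tokens, pos_tags = bl$pos_tags,
        entity1_pos = bl$entity1_pos, entity2_pos = bl$entity2_pos,
        sdp_indices = as.integer(sdp),
        rel_dist1 = rd$rel_dist1, rel_dist2 = rd$rel_dist2,
        label = label, p_positive = NA_real_), class = "bb_instance")
    }
  }

  # gold positives whose two mentions sit in different sentences: these can
  # never be predicted and are unconditional false negatives at evaluation
  if (nrow(doc$relations)) {
    for (ri in seq_len(nrow(doc$relations))) {
      r <- doc$relations[ri, ]
      sb <- unname(sent_of[r$bacteria_id])
      sl <- unname(sent_of[r$location_id])
      if (is.na(sb) || is.na(sl) || sb != sl) {
        counts["gold_inter_sentence"] <- counts["gold_inter_sentence"] + 1L
      }
    }
  }

  list(instances = instances, counts = counts)
}

#' Write / read candidate instances as JSON-lines
#'
#' One instance per line with the field names of the instance object;
#' consumed by the training and evaluation stages.
#'
#' @param instances list of `bb_instance`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_instances <- function(instances, path) {
  lines <- vapply(instances, function(x) {
    jsonlite::toJSON(unclass(x), auto_unbox = TRUE, null = "null",
                     na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_instances
#' @export
read_instances <- function(path) {
  lapply(readLines(path, warn = FALSE), function(line) {
    x <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    x$tokens <- as.character(x$tokens)
    x$pos_tags <- as.character(x$pos_tags)
    x$sdp_indices <- as.integer(x$sdp_indices)
    x$rel_dist1 <- as.integer(x$rel_dist1)
    x$rel_dist2 <- as.integer(x$rel_dist2)
    if (is.null(x$label)) x$label <- NA_character_
    if (is.null(x$p_positive)) x$p_positive <- NA_real_
    structure(x, class = "bb_instance")
  })
}
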