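ENTITY_CATEGORIES <- c("Bacteria", "Habitat", "Geographical")

#' Read a standoff-annotated document
#'
#' Reads a BioNLP-ST style document: the raw text (`.txt`), entity
#' annotations (`.a1`) and, optionally, gold `Lives_In` relations (`.a2`).
#' Entity annotation lines have the form
#' `Tn<TAB>Category start end<TAB>surface` with 0-based, half-open character
#' offsets into the text. Relation lines have the form
#' `Rn<TAB>Lives_In Bacterium:Tx Location:Ty`. Annotation types other than
#' Bacteria/Habitat/Geographical (e.g. `Title`, `Paragraph`) are skipped.
#'
#' Discontinuous mentions (offset lists separated by `;`) are normalized to
#' their covering span with a warning, because the downstream model consumes
#' contiguous token spans.
#'
#' @param txt path to the document text file (or a character scalar of text
#'   when `text_is_literal = TRUE`)
#' @param a1 path to the entity annotation file
#' @param a2 optional path to the relation annotation file; relations listed
#'   there are gold positives
#' @param doc_id document identifier; defaults to the `.txt` basename
#' @param text_is_literal treat `txt` as the document text itself
#' @return a `bb_document`: list with `doc_id`, `text`, `mentions`
#'   (data.frame: id, category, start, end, surface), `relations`
#'   (data.frame: id, bacteria_id, location_id, label) and `sentences`
#'   (empty until parses are attached, see [read_conllu()])
#' @export
read_standoff <- function(txt, a1, a2 = NULL, doc_id = NULL,
                          text_is_literal = FALSE) {
  if (text_is_literal) {
    text <- txt
    if (is.null(doc_id)) doc_id <- "doc"
  } else {
    text <- paste(readLines(txt, warn = FALSE), collapse = "\n")
    if (is.null(doc_id)) doc_id <- sub("\\.txt$", "", basename(txt))
  }
  mentions <- parse_a1(readLines(a1, warn = FALSE), text)
  relations <- if (is.null(a2)) {
    empty_relations()
  } else {
    parse_a2(readLines(a2, warn = FALSE), mentions)
  }
  new_document(doc_id, text, mentions, relations)
}

new_document <- function(doc_id, text, mentions, relations,
                         sentences = list()) {
  doc <- structure(
    list(doc_id = doc_id, text = text, mentions = mentions,
         relations = relations, sentences = sentences),
    class = "bb_document")
  validate_document(doc)
  doc
}

validate_document <- function(doc) {
  m <- doc$mentions
  if (anyDuplicated(m$id)) {
    stop("duplicate mention ids in document '", doc$doc_id, "'")
  }
  n <- nchar(doc$text)
  bad <- which(m$start < 0 | m$start >= m$end | m$end > n)
  if (length(bad)) {
    stop("mention ", m$id[bad[1]], ": offsets [", m$start[bad[1]], ", ",
         m$end[bad[1]], ") outside document text of length ", n)
  }
  slice <- substring(doc$text, m$start + 1L, m$end)
  bad <- which(slice != m$surface)
  if (length(bad)) {
    stop("mention ", m$id[bad[1]], ": surface '", m$surface[bad[1]],
         "' does not match text slice '", slice[bad[1]], "'")
  }
  r <- doc$relations
  missing <- setdiff(c(r$bacteria_id, r$location_id), m$id)
  if (length(missing)) {
    stop("relation references unknown mention id: ", missing[1])
  }
  if (nrow(r)) {
    cat_of <- stats::setNames(m$category, m$id)
    if (any(cat_of[r$bacteria_id] != "Bacteria")) {
      stop("relation Bacterium argument is not a Bacteria mention")
    }
    if (!all(cat_of[r$location_id] %in% c("Habitat", "Geographical"))) {
      stop("relation Location argument is not a Habitat/Geographical mention")
    }
  }
  invisible(doc)
}

empty_mentions <- function() {
  data.frame(id = character(), category = character(),
             start = integer(), end = integer(), surface = character(),
             stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(id = character(), bacteria_id = character(),
             location_id = character(), label = character(),
             stringsAsFactors = FALSE)
}

parse_a1 <- function(lines, text) {
  out <- empty_mentions()
  for (k in seq_along(lines)) {
    line <- lines[k]
    if (!nzchar(trimws(line))) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !grepl("^T", parts[1])) {
      stop("a1 line ", k, ": malformed annotation line: ", line)
    }
    ann <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    category <- ann[1]
    if (!category %in% ENTITY_CATEGORIES) next
    offsets <- paste(ann[-1], collapse = " ")
    if (grepl(";", offsets, fixed = TRUE)) {
      warning("a1 line ", k, ": discontinuous mention ", parts[1],
              " normalized to covering span", call. = FALSE)
    }
    nums <- suppressWarnings(as.integer(unlist(strsplit(offsets, "[ ;]+"))))
    if (anyNA(nums) || length(nums) < 2L) {
      stop("a1 line ", k, ": cannot parse offsets in: ", line)
    }
    start <- min(nums)
    end <- max(nums)
    surface <- substring(text, start + 1L, end)
    stated <- if (length(parts) >= 3L) parts[3] else surface
    if (!grepl(";", offsets, fixed = TRUE) && stated != surface) {
      stop("a1 line ", k, ": mention ", parts[1], " surface '", stated,
           "' does not match text slice '", surface, "'")
    }
    out <- rbind(out, data.frame(
      id = parts[1], category = category, start = start, end = end,
      surface = surface, stringsAsFactors = FALSE))
  }
  out
}

parse_a2 <- function(lines, mentions) {
  out <- empty_relations()
  for (k in seq_along(lines)) {
    line <- lines[k]
    if (!nzchar(trimws(line))) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !grepl("^R", parts[1])) {
      stop("a2 line ", k, ": malformed relation line: ", line)
    }
    fields <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    if (fields[1] != "Lives_In" || length(fields) != 3L) {
      stop("a2 line ", k, ": expected 'Lives_In Bacterium:Tx Location:Ty'")
    }
    bact <- sub("^Bacterium:", "", fields[grepl("^Bacterium:", fields)])
    loc <- sub("^Location:", "", fields[grepl("^Location:", fields)])
    if (length(bact) != 1L || length(loc) != 1L) {
      stop("a2 line ", k, ": missing Bacterium: or Location: argument")
    }
    if (!bact %in% mentions$id || !loc %in% mentions$id) {
      stop("a2 line ", k, ": relation references unknown mention id")
    }
    out <- rbind(out, data.frame(
      id = parts[1], bacteria_id = bact, location_id = loc,
      label = "positive", stringsAsFactors = FALSE))
  }
  out
}

#' Write a document back to standoff files
#'
#' Inverse of [read_standoff()]; used for synthetic corpora and round-trip
#' checks. Relations are written only when present.
#'
#' @param doc a `bb_document`
#' @param dir output directory
#' @return invisibly, the paths written
#' @export
write_standoff <- function(doc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, doc$doc_id)
  writeLines(doc$text, paste0(base, ".txt"))
  m <- doc$mentions
  a1 <- sprintf("%s\t%s %d %d\t%s", m$id, m$category, m$start, m$end,
                m$surface)
  writeLines(a1, paste0(base, ".a1"))
  paths <- paste0(base, c(".txt", ".a1"))
  r <- doc$relations
  if (nrow(r)) {
    a2 <- sprintf("%s\tLives_In Bacterium:%s Location:%s",
                  r$id, r$bacteria_id, r$location_id)
    writeLines(a2, paste0(base, ".a2"))
    paths <- c(paths, paste0(base, ".a2"))
  }
  invisible(paths)
}

#' Read dependency parses in CoNLL-U format
#'
#' Parses sentence blocks separated by blank lines. Only the columns ID,
#' FORM, UPOS (falling back to XPOS when UPOS is `_`), HEAD and DEPREL are
#' consumed. Multiword-token ranges (`1-2`) and empty nodes (`1.1`) are
#' skipped with a warning; comment lines are ignored.
#'
#' @param path path to a CoNLL-U file
#' @return a list of `bb_sentence` objects: each has `sent_index` and a
#'   data.frame `tokens` with columns `form`, `pos`, `head` (0 = root,
#'   otherwise 1-based index of the governing token) and `deprel`
#' @export
read_conllu <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sentences <- list()
  tok <- NULL
  flush <- function() {
    if (!is.null(tok) && nrow(tok)) {
      sentences[[length(sentences) + 1L]] <<- new_sentence(
        length(sentences), tok)
    }
    tok <<- NULL
  }
  for (k in seq_along(lines)) {
    line <- lines[k]
    if (!nzchar(trimws(line))) { flush(); next }
    if (startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) {
      stop("conllu line ", k, ": expected >= 8 tab-separated fields")
    }
    if (grepl("-", f[1], fixed = TRUE) || grepl(".", f[1], fixed = TRUE)) {
      warning("conllu line ", k, ": skipping multiword-token/empty-node '",
              f[1], "'", call. = FALSE)
      next
    }
    head <- suppressWarnings(as.integer(f[7]))
    if (is.na(head)) {
      stop("conllu line ", k, ": non-integer HEAD field '", f[7], "'")
    }
    pos <- if (f[4] != "_") f[4] else f[5]
    row <- data.frame(form = f[2], pos = pos, head = head, deprel = f[8],
                      stringsAsFactors = FALSE)
    tok <- if (is.null(tok)) row else rbind(tok, row)
  }
  flush()
  sentences
}

new_sentence <- function(sent_index, tokens) {
  n <- nrow(tokens)
  if (any(tokens$head < 0L | tokens$head > n)) {
    stop("sentence ", sent_index, ": HEAD index outside [0, ", n, "]")
  }
  structure(list(sent_index = sent_index, tokens = tokens),
            class = "bb_sentence")
}

#' Write sentences in CoNLL-U format
#'
#' @param sentences list of `bb_sentence` objects
#' @param path output path
#' @return invisibly, `path`
#' @export
write_conllu <- function(sentences, path) {
  out <- character()
  for (s in sentences) {
    t <- s$tokens
    out <- c(out,
             paste0("# sent_id = ", s$sent_index),
             sprintf("%d\t%s\t_\t%s\t_\t_\t%d\t%s\t_\t_",
                     seq_len(nrow(t)), t$form, t$pos, t$head, t$deprel),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write positive predictions as a2-format relation lines
#'
#' One `Lives_In` line per positively-decided candidate; negative decisions
#' emit nothing. Relation ids are numbered densely from `R1`.
#'
#' @param decisions data.frame with columns `bacteria_id`, `location_id` and
#'   logical `decision`
#' @return character vector of a2 lines (possibly empty)
#' @export
write_predictions_a2 <- function(decisions) {
  if (!"decision" %in% names(decisions) || anyNA(decisions$decision)) {
    stop("every candidate must carry a decision before writing predictions")
  }
  pos <- decisions[decisions$decision, , drop = FALSE]
  if (!nrow(pos)) return(character())
  sprintf("R%d\tLives_In Bacterium:%s Location:%s",
          seq_len(nrow(pos)), pos$bacteria_id, pos$location_id)
}

#' @export
print.bb_document <- function(x, ...) {
  cat("<bb_document> ", x$doc_id, ": ", nchar(x$text), " chars, ",
      nrow(x$mentions), " mentions, ", nrow(x$relations), " gold relations, ",
      length(x$sentences), " parsed sentences\n", sep = "")
  invisible(x)
}
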