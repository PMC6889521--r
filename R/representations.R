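#' Embedding configuration
#'
#' Collects the dimensionalities of every input-embedding component and the
#' vocabularies needed to build lookup tables. Defaults follow the tuned
#' setting for the bacteria-biotope task: 200-dimensional context-free word
#' vectors (400 when a contextual provider is plugged in), 100-dimensional
#' POS embeddings, and a 300-dimensional distance block formed by
#' concatenating one 150-dimensional embedding per entity. The positional
#' encoding has the word dimension, so the two can be summed.
#'
#' @param word_dim word-vector dimension
#' @param pos_dim POS-embedding dimension
#' @param dist_dim distance-embedding dimension per entity
#' @param s maximum absolute relative distance in the dataset; distances
#'   beyond `[-s, s]` are clipped to the boundary
#' @param pos_vocab character vector of POS tags (an `UNK` slot is added)
#' @param seed integer seed for random table initialization
#' @return an `embedding_config` list
#' @export
embedding_config <- function(word_dim = 200L, pos_dim = 100L,
                             dist_dim = 150L, s = 10L,
                             pos_vocab = c("NN", "VB", "IN", "JJ", "DT", "."),
                             seed = 1L) {
  stopifnot(word_dim > 0, pos_dim > 0, dist_dim > 0)
  if (s < 1) stop("maximum relative distance s must be >= 1")
  structure(list(word_dim = as.integer(word_dim),
                 pos_dim = as.integer(pos_dim),
                 dist_dim = as.integer(dist_dim),
                 pe_dim = as.integer(word_dim),
                 s = as.integer(s),
                 pos_vocab = unique(c("UNK", pos_vocab)),
                 seed = as.integer(seed)),
            class = "embedding_config")
}

#' Distance-embedding table
#'
#' Builds the initial distance-embedding table over relative distances
#' `l` in `[-s, s]`: every dimension of the embedding for distance `l` is
#' `tanh(l / s)`, where `s` is the maximum absolute relative distance.
#' The table is trainable after initialization.
#'
#' @param config an [embedding_config()]
#' @return matrix of dimension `(2s + 1) x dist_dim`; row `l + s + 1`
#'   holds the embedding of distance `l`
#' @export
distance_embedding_table <- function(config) {
  if (config$s == 0) stop("s = 0 is not a valid distance scale")
  l <- seq.int(-config$s, config$s)
  matrix(tanh(l / config$s), nrow = length(l), ncol = config$dist_dim)
}

#' Look up a single distance embedding
#'
#' @param l relative distance (clipped to `[-s, s]`)
#' @param table a distance table from [distance_embedding_table()]
#' @param config the matching [embedding_config()]
#' @return numeric vector of length `dist_dim`
#' @export
distance_embedding <- function(l, table, config) {
  table[dist_row(l, config$s), ]
}

dist_row <- function(l, s) {
  pmin(pmax(l, -s), s) + s + 1L
}

#' Sinusoidal positional encoding
#'
#' Fixed, non-trainable encoding of absolute token position: component
#' `2i` is `sin(position / 10000^(2i/dim))` and component `2i + 1` is
#' `cos(position / 10000^(2i/dim))` (components counted from zero).
#'
#' @param position non-negative integer position (0-based)
#' @param dim even embedding dimension
#' @return numeric vector of length `dim`
#' @export
positional_encoding <- function(position, dim) {
  if (dim %% 2L != 0L) stop("positional-encoding dimension must be even")
  if (position < 0) stop("position must be >= 0")
  i <- seq.int(0L, dim / 2L - 1L)
  freq <- position / 10000^(2 * i / dim)
  out <- numeric(dim)
  out[2 * i + 1L] <- sin(freq)
  out[2 * i + 2L] <- cos(freq)
  out
}

# --- word-vector providers -------------------------------------------------

#' Word-vector providers
#'
#' A provider maps a full token sequence to a matrix of per-token word
#' vectors. Three kinds are supported:
#'
#' * `word_provider_table()` — a static table in word2vec text format;
#'   out-of-vocabulary words receive a per-word random vector drawn once
#'   from a generator seeded by the word and the provider seed, and cached,
#'   so repeated lookups (in any process) agree.
#' * `word_provider_hash()` — a fully deterministic fallback that derives
#'   every word's vector from a string hash; useful for tests and synthetic
#'   corpora where no pre-trained table exists.
#' * `word_provider_contextual()` — wraps a callable `fn(tokens)` returning
#'   a `length(tokens) x dim` matrix, the contract a contextual
#'   (ELMo/BERT-style) encoder must satisfy; output dimensions are checked.
#'
#' @param table numeric matrix with words as rownames
#' @param dim vector dimension
#' @param seed integer seed controlling OOV / hash vectors
#' @param fn callable for the contextual contract
#' @return a `word_provider` object for [lookup_word_vectors()]
#' @export
word_provider_table <- function(table, seed = 1L) {
  structure(list(type = "table", table = table, dim = ncol(table),
                 seed = as.integer(seed), cache = new.env(parent = emptyenv())),
            class = "word_provider")
}

#' @rdname word_provider_table
#' @export
word_provider_hash <- function(dim = 200L, seed = 1L) {
  structure(list(type = "hash", dim = as.integer(dim),
                 seed = as.integer(seed)),
            class = "word_provider")
}

#' @rdname word_provider_table
#' @export
word_provider_contextual <- function(fn, dim) {
  structure(list(type = "contextual", fn = fn, dim = as.integer(dim)),
            class = "word_provider")
}

# 31-ary rolling string hash, kept below 2^31
string_hash <- function(word) {
  h <- 0
  for (code in utf8ToInt(word)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# Draw a word vector from a generator seeded by (word hash, provider seed)
# without disturbing the caller's RNG stream.
hashed_vector <- function(word, dim, seed) {
  mix <- (string_hash(word) + 1103515245 * (seed %% 1024)) %% 2147483647
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(mix))
  stats::rnorm(dim, sd = 0.1)
}

#' Look up word vectors for a token sequence
#'
#' @param tokens character vector of tokens (already blinded/lowercased)
#' @param provider a `word_provider`
#' @return numeric matrix, `length(tokens) x provider$dim`
#' @export
lookup_word_vectors <- function(tokens, provider) {
  stopifnot(inherits(provider, "word_provider"))
  if (provider$type == "contextual") {
    out <- provider$fn(tokens)
    if (!is.matrix(out) || nrow(out) != length(tokens) ||
        ncol(out) != provider$dim) {
      stop("contextual provider must return a ", length(tokens), " x ",
           provider$dim, " matrix")
    }
    return(out)
  }
  out <- matrix(0, nrow = length(tokens), ncol = provider$dim)
  for (k in seq_along(tokens)) {
    w <- tokens[k]
    if (provider$type == "table") {
      if (w %in% rownames(provider$table)) {
        out[k, ] <- provider$table[w, ]
      } else {
        if (is.null(provider$cache[[w]])) {
          provider$cache[[w]] <- hashed_vector(w, provider$dim, provider$seed)
        }
        out[k, ] <- provider$cache[[w]]
      }
    } else {
      out[k, ] <- hashed_vector(w, provider$dim, provider$seed)
    }
  }
  out
}

#' Read / write word vectors in word2vec text format
#'
#' The format is a header line `count dim` followed by one line per word:
#' the word, then `dim` numbers, space-separated.
#'
#' @param path file path
#' @return `read_word2vec()`: numeric matrix with words as rownames
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  n <- header[1]; d <- header[2]
  out <- matrix(0, nrow = n, ncol = d)
  words <- character(n)
  for (k in seq_len(n)) {
    f <- strsplit(trimws(lines[k + 1L]), "\\s+")[[1]]
    words[k] <- f[1]
    out[k, ] <- as.numeric(f[-1])
  }
  rownames(out) <- words
  out
}

#' @rdname read_word2vec
#' @param vectors numeric matrix with words as rownames
#' @export
write_word2vec <- function(vectors, path) {
  lines <- c(paste(nrow(vectors), ncol(vectors)),
             vapply(seq_len(nrow(vectors)), function(k) {
               paste(rownames(vectors)[k],
                     paste(format(vectors[k, ], scientific = FALSE,
                                  trim = TRUE), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Compose the per-token input representation
#'
#' Concatenates the word vector, POS embedding and the two distance
#' embeddings into the overall input representation
#' `z = [word ; pos ; dist1 ; dist2]`. For tokens on the shortest
#' dependency path the positional encoding is summed into the word
#' component (`word + PE`), not concatenated, before the same
#' concatenation.
#'
#' @param word_vec word vector (length `word_dim`)
#' @param pos_vec POS embedding (length `pos_dim`)
#' @param d1,d2 distance embeddings to entity 1 / entity 2
#' @param pe optional positional encoding to sum into the word component
#' @return numeric vector of length `word_dim + pos_dim + 2 * dist_dim`
#' @export
compose_token_representation <- function(word_vec, pos_vec, d1, d2,
                                         pe = NULL) {
  if (!is.null(pe)) {
    if (length(pe) != length(word_vec)) {
      stop("positional encoding length must equal the word dimension")
    }
    word_vec <- word_vec + pe
  }
  c(word_vec, pos_vec, d1, d2)
}

# POS-embedding table, randomly initialized at training start (trainable)
pos_embedding_table <- function(config) {
  n <- length(config$pos_vocab)
  matrix(stats::rnorm(n * config$pos_dim, sd = 0.1), nrow = n,
         dimnames = list(config$pos_vocab, NULL))
}

pos_row <- function(tag, config) {
  k <- match(tag, config$pos_vocab)
  ifelse(is.na(k), 1L, k)
}
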