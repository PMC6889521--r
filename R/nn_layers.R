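# Neural building blocks, written as explicit forward/backward pairs over
# plain matrices. Forward functions return caches consumed by the matching
# backward function; gradient correctness is checked against finite
# differences in the test suite.

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

glorot <- function(nout, nin) {
  limit <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nout * nin, -limit, limit), nrow = nout)
}

# --- additive attention (over BLSTM hidden states) -------------------------

#' Additive attention over hidden states
#'
#' Scores each hidden state with a single-hidden-layer feed-forward
#' network, `score(h_i) = v_a' tanh(h_i)`, normalizes the scores with a
#' softmax, and returns the context vector `c = sum_i a_i h_i`.
#'
#' @param hidden_states numeric matrix, one hidden state per row
#' @param v_a learned weight vector, length `ncol(hidden_states)`
#' @return list with `context` (numeric vector) and `weights`
#'   (non-negative, summing to 1)
#' @export
additive_attention <- function(hidden_states, v_a) {
  fw <- additive_attention_forward(hidden_states, v_a)
  list(context = fw$context, weights = fw$weights)
}

additive_attention_forward <- function(H, v_a) {
  if (!nrow(H)) stop("additive attention requires at least one state")
  if (length(v_a) != ncol(H)) {
    stop("v_a length must equal the hidden-state dimension")
  }
  Th <- tanh(H)
  u <- drop(Th %*% v_a)
  a <- softmax_vec(u)
  list(context = drop(crossprod(H, a)), weights = a, H = H, Th = Th)
}

additive_attention_grad <- function(fw, v_a, dcontext) {
  H <- fw$H; a <- fw$weights; Th <- fw$Th
  dH <- tcrossprod(a, dcontext)
  da <- drop(H %*% dcontext)
  du <- a * (da - sum(da * a))
  dv_a <- drop(crossprod(Th, du))
  dH <- dH + tcrossprod(du, v_a) * (1 - Th^2)
  list(dH = dH, dv_a = dv_a)
}

# --- entity-oriented attention ---------------------------------------------

#' Entity-oriented attention weights
#'
#' Weights each token by its average inner-product similarity to the two
#' entity word vectors: `S_i = (w_i . e_1 + w_i . e_2) / (2 sqrt(m))`, with
#' `m` the word-embedding dimension, followed by a softmax over all tokens.
#'
#' @param word_vectors numeric matrix of per-token word vectors (rows)
#' @param entity1_pos,entity2_pos 1-based row indices of the entity tokens
#' @return numeric weight vector (non-negative, sums to 1)
#' @export
entity_oriented_attention <- function(word_vectors, entity1_pos,
                                      entity2_pos) {
  M <- nrow(word_vectors)
  if (entity1_pos < 1 || entity1_pos > M || entity2_pos < 1 ||
      entity2_pos > M) {
    stop("entity positions out of range")
  }
  m <- ncol(word_vectors)
  s1 <- drop(word_vectors %*% word_vectors[entity1_pos, ])
  s2 <- drop(word_vectors %*% word_vectors[entity2_pos, ])
  softmax_vec((s1 + s2) / (2 * sqrt(m)))
}

# --- LSTM / BLSTM -----------------------------------------------------------

lstm_init <- function(input_dim, hidden) {
  W <- glorot(4L * hidden, input_dim)
  U <- glorot(4L * hidden, hidden)
  b <- numeric(4L * hidden)
  b[(hidden + 1L):(2L * hidden)] <- 1  # forget-gate bias
  list(W = W, U = U, b = b)
}

# One-direction LSTM over X (rows = timesteps). Gate order: input, forget,
# output, candidate.
lstm_forward <- function(X, par, hidden) {
  M <- nrow(X)
  H <- matrix(0, M, hidden)
  gi <- gf <- go <- gg <- Cst <- Tc <- matrix(0, M, hidden)
  h_prev <- numeric(hidden)
  c_prev <- numeric(hidden)
  idx <- function(k) ((k - 1L) * hidden + 1L):(k * hidden)
  for (t in seq_len(M)) {
    pre <- drop(par$W %*% X[t, ] + par$U %*% h_prev + par$b)
    i <- 1 / (1 + exp(-pre[idx(1)]))
    f <- 1 / (1 + exp(-pre[idx(2)]))
    o <- 1 / (1 + exp(-pre[idx(3)]))
    g <- tanh(pre[idx(4)])
    c_cur <- f * c_prev + i * g
    tc <- tanh(c_cur)
    h_prev_new <- o * tc
    gi[t, ] <- i; gf[t, ] <- f; go[t, ] <- o; gg[t, ] <- g
    Cst[t, ] <- c_cur; Tc[t, ] <- tc; H[t, ] <- h_prev_new
    h_prev <- h_prev_new
    c_prev <- c_cur
  }
  list(H = H, X = X, gi = gi, gf = gf, go = go, gg = gg, C = Cst, Tc = Tc,
       hidden = hidden)
}

lstm_backward <- function(fw, par, dH) {
  M <- nrow(fw$X)
  hidden <- fw$hidden
  dW <- matrix(0, nrow(par$W), ncol(par$W))
  dU <- matrix(0, nrow(par$U), ncol(par$U))
  db <- numeric(length(par$b))
  dX <- matrix(0, M, ncol(fw$X))
  dh_rec <- numeric(hidden)
  dc_next <- numeric(hidden)
  for (t in rev(seq_len(M))) {
    dh <- dH[t, ] + dh_rec
    i <- fw$gi[t, ]; f <- fw$gf[t, ]; o <- fw$go[t, ]; g <- fw$gg[t, ]
    tc <- fw$Tc[t, ]
    c_prev <- if (t > 1L) fw$C[t - 1L, ] else numeric(hidden)
    h_prev <- if (t > 1L) fw$H[t - 1L, ] else numeric(hidden)
    do_ <- dh * tc
    dc <- dh * o * (1 - tc^2) + dc_next
    di <- dc * g
    dg <- dc * i
    df <- dc * c_prev
    dc_next <- dc * f
    dpre <- c(di * i * (1 - i), df * f * (1 - f), do_ * o * (1 - o),
              dg * (1 - g^2))
    dW <- dW + tcrossprod(dpre, fw$X[t, ])
    dU <- dU + tcrossprod(dpre, h_prev)
    db <- db + dpre
    dX[t, ] <- drop(crossprod(par$W, dpre))
    dh_rec <- drop(crossprod(par$U, dpre))
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

blstm_init <- function(input_dim, hidden) {
  list(fwd = lstm_init(input_dim, hidden), bwd = lstm_init(input_dim, hidden))
}

blstm_hidden_of <- function(par) length(par$fwd$b) %/% 4L

blstm_forward <- function(X, par) {
  hidden <- blstm_hidden_of(par)
  fwd <- lstm_forward(X, par$fwd, hidden)
  Xr <- X[rev(seq_len(nrow(X))), , drop = FALSE]
  bwd <- lstm_forward(Xr, par$bwd, hidden)
  Hb <- bwd$H[rev(seq_len(nrow(X))), , drop = FALSE]
  list(H = cbind(fwd$H, Hb), fwd = fwd, bwd = bwd)
}

blstm_backward <- function(fw, par, dH) {
  hidden <- blstm_hidden_of(par)
  M <- nrow(dH)
  dHf <- dH[, seq_len(hidden), drop = FALSE]
  dHb <- dH[, hidden + seq_len(hidden), drop = FALSE]
  gf <- lstm_backward(fw$fwd, par$fwd, dHf)
  gb <- lstm_backward(fw$bwd, par$bwd, dHb[rev(seq_len(M)), , drop = FALSE])
  dX <- gf$dX + gb$dX[rev(seq_len(M)), , drop = FALSE]
  list(dX = dX,
       fwd = gf[c("dW", "dU", "db")],
       bwd = gb[c("dW", "dU", "db")])
}

#' Encode a token sequence with a bidirectional LSTM
#'
#' Runs one LSTM forward and one backward over the input rows and
#' concatenates the two hidden states at every position:
#' `h_k = [h_k_forward ; h_k_backward]`.
#'
#' @param token_vectors numeric matrix, one input vector per position
#' @param params parameter list from the model initializer (fields `fwd`,
#'   `bwd`, `hidden`)
#' @return matrix of hidden states, `nrow(token_vectors) x (2 * hidden)`
#' @export
blstm_encode <- function(token_vectors, params) {
  if (!nrow(token_vectors)) stop("cannot encode an empty sequence")
  blstm_forward(token_vectors, params)$H
}

# --- scaled dot-product self-attention / multi-head stacks ------------------

#' Scaled dot-product self-attention (one head)
#'
#' Projects the input rows into queries, keys and values with learned
#' weights, scores every query against every key scaled by `sqrt(m)` (the
#' word-embedding dimensionality), softmax-normalizes per query over the
#' unmasked keys, and returns the per-position context vectors
#' `c_i = sum_j a_ij v_j`. Masked (padding) positions neither attend nor
#' are attended to, and their outputs are zero.
#'
#' @param Z input matrix, one position per row
#' @param W_q,W_k,W_v projection matrices (`head_dim x ncol(Z)`)
#' @param m scaling dimensionality (word-embedding dimension)
#' @param mask logical vector marking real (non-padding) positions
#' @return list with `context` (matrix of per-position context vectors) and
#'   `weights` (attention matrix, rows sum to 1 on unmasked rows)
#' @export
scaled_dot_product_self_attention <- function(Z, W_q, W_k, W_v, m = ncol(Z),
                                              mask = rep(TRUE, nrow(Z))) {
  fw <- sdpa_forward(Z, list(Wq = W_q, Wk = W_k, Wv = W_v), m, mask)
  list(context = fw$C, weights = fw$A)
}

sdpa_forward <- function(Z, par, m, mask) {
  L <- nrow(Z)
  if (!any(mask)) stop("all positions are masked")
  Q <- Z %*% t(par$Wq)
  K <- Z %*% t(par$Wk)
  V <- Z %*% t(par$Wv)
  S <- tcrossprod(Q, K) / sqrt(m)
  S[, !mask] <- -Inf
  A <- matrix(0, L, L)
  for (i in which(mask)) A[i, ] <- softmax_vec_masked(S[i, ], mask)
  C <- A %*% V
  C[!mask, ] <- 0
  list(C = C, A = A, Q = Q, K = K, V = V, Z = Z, m = m, mask = mask)
}

softmax_vec_masked <- function(x, mask) {
  out <- numeric(length(x))
  e <- exp(x[mask] - max(x[mask]))
  out[mask] <- e / sum(e)
  out
}

sdpa_backward <- function(fw, par, dC) {
  dC[!fw$mask, ] <- 0
  dA <- tcrossprod(dC, fw$V)
  dV <- crossprod(fw$A, dC)
  dS <- fw$A * (dA - rowSums(dA * fw$A))
  dQ <- dS %*% fw$K / sqrt(fw$m)
  dK <- crossprod(dS, fw$Q) / sqrt(fw$m)
  dWq <- crossprod(dQ, fw$Z)
  dWk <- crossprod(dK, fw$Z)
  dWv <- crossprod(dV, fw$Z)
  dZ <- dQ %*% par$Wq + dK %*% par$Wk + dV %*% par$Wv
  list(dZ = dZ, dWq = dWq, dWk = dWk, dWv = dWv)
}

mha_stack_init <- function(model_dim, heads) {
  if (model_dim %% heads != 0L) {
    stop("number of heads must divide the model dimension")
  }
  dh <- model_dim %/% heads
  list(heads = lapply(seq_len(heads), function(h) {
    list(Wq = glorot(dh, model_dim), Wk = glorot(dh, model_dim),
         Wv = glorot(dh, model_dim))
  }), Wo = glorot(model_dim, model_dim))
}

# One multi-head stack: heads in parallel, concatenated, projected back to
# the model dimension, plus a residual connection from the stack input.
mha_stack_forward <- function(X, par, m, mask, residual = TRUE) {
  caches <- lapply(par$heads, function(hp) sdpa_forward(X, hp, m, mask))
  Ccat <- do.call(cbind, lapply(caches, function(cc) cc$C))
  out <- Ccat %*% t(par$Wo)
  out[!mask, ] <- 0
  Y <- if (residual) X + out else out
  Y[!mask, ] <- 0  # padding positions contribute zero vectors
  list(Y = Y, caches = caches, Ccat = Ccat, X = X, mask = mask,
       residual = residual)
}

mha_stack_backward <- function(fw, par, dY) {
  dY[!fw$mask, ] <- 0
  dout <- dY
  dCcat <- dout %*% par$Wo
  dWo <- crossprod(dout, fw$Ccat)
  dX <- if (fw$residual) dY else matrix(0, nrow(dY), ncol(dY))
  dh <- ncol(fw$caches[[1]]$C)
  dheads <- vector("list", length(par$heads))
  for (h in seq_along(par$heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    g <- sdpa_backward(fw$caches[[h]], par$heads[[h]],
                       dCcat[, cols, drop = FALSE])
    dX <- dX + g$dZ
    dheads[[h]] <- g[c("dWq", "dWk", "dWv")]
  }
  list(dX = dX, dheads = dheads, dWo = dWo)
}

mha_encoder_init <- function(model_dim, stacks, heads) {
  lapply(seq_len(stacks), function(s) mha_stack_init(model_dim, heads))
}

mha_encoder_forward <- function(Z, params, m, mask, residual = TRUE) {
  X <- Z
  caches <- vector("list", length(params))
  for (s in seq_along(params)) {
    caches[[s]] <- mha_stack_forward(X, params[[s]], m, mask, residual)
    X <- caches[[s]]$Y
  }
  list(feature = as.vector(t(X)), X = X, caches = caches)
}

mha_encoder_backward <- function(fw, params, dfeature) {
  L <- nrow(fw$X)
  dX <- matrix(dfeature, nrow = L, byrow = TRUE)
  dstacks <- vector("list", length(params))
  for (s in rev(seq_along(params))) {
    g <- mha_stack_backward(fw$caches[[s]], params[[s]], dX)
    dX <- g$dX
    dstacks[[s]] <- g[c("dheads", "dWo")]
  }
  list(dZ = dX, dstacks = dstacks)
}

#' Encode a padded SDP with stacked multi-head self-attention
#'
#' Applies a stack of multi-head self-attentions with residual connections
#' to the (padded, masked) shortest-dependency-path token vectors and
#' concatenates the per-position outputs over the padded length into one
#' fixed-size feature, so SDPs of any true length yield features of equal
#' dimension. Masked positions contribute zero vectors.
#'
#' @param Z padded SDP input matrix (`max_sdp_len x model_dim`)
#' @param params list of stack parameter sets from the model initializer
#' @param m scaling dimensionality (word-embedding dimension)
#' @param mask logical vector marking real positions
#' @return numeric feature vector of length `max_sdp_len * model_dim`
#' @export
multi_head_sdp_encoder <- function(Z, params, m = ncol(Z),
                                   mask = rep(TRUE, nrow(Z))) {
  if (nrow(Z) < 2L) stop("padded SDP length must be at least 2")
  mha_encoder_forward(Z, params, m, mask)$feature
}

# --- CNN SDP encoder --------------------------------------------------------

cnn_init <- function(model_dim, windows, filters) {
  lapply(windows, function(w) {
    list(W = glorot(filters, w * model_dim), b = numeric(filters))
  })
}

cnn_forward <- function(Z, params, mask) {
  L <- nrow(Z)
  D <- ncol(Z)
  X <- Z
  X[!mask, ] <- 0
  feats <- list()
  caches <- list()
  for (p in params) {
    w <- ncol(p$W) %/% D
    if (w > L) stop("convolution window ", w, " larger than padded length ", L)
    pad <- (w - 1L) %/% 2L
    Xpad <- rbind(matrix(0, pad, D), X, matrix(0, pad, D))
    Cin <- t(vapply(seq_len(L), function(i) {
      as.vector(t(Xpad[i:(i + w - 1L), , drop = FALSE]))
    }, numeric(w * D)))
    Pre <- Cin %*% t(p$W) + matrix(p$b, L, length(p$b), byrow = TRUE)
    Act <- pmax(Pre, 0)
    amax <- apply(Act, 2, which.max)
    pool <- Act[cbind(amax, seq_along(amax))]
    feats[[length(feats) + 1L]] <- pool
    caches[[length(caches) + 1L]] <- list(Cin = Cin, Pre = Pre, amax = amax,
                                          pad = pad, w = w)
  }
  list(feature = unlist(feats), caches = caches, L = L, D = D, mask = mask)
}

cnn_backward <- function(fw, params, dfeature) {
  L <- fw$L; D <- fw$D
  dZ <- matrix(0, L, D)
  dparams <- vector("list", length(params))
  off <- 0L
  for (k in seq_along(params)) {
    p <- params[[k]]
    cc <- fw$caches[[k]]
    F_ <- length(p$b)
    dpool <- dfeature[off + seq_len(F_)]
    off <- off + F_
    dAct <- matrix(0, L, F_)
    dAct[cbind(cc$amax, seq_len(F_))] <- dpool
    dPre <- dAct * (cc$Pre > 0)
    dW <- crossprod(dPre, cc$Cin)
    db <- colSums(dPre)
    dCin <- dPre %*% p$W
    pad <- cc$pad; w <- cc$w
    dXpad <- matrix(0, L + 2L * pad, D)
    for (i in seq_len(L)) {
      dXpad[i:(i + w - 1L), ] <- dXpad[i:(i + w - 1L), ] +
        matrix(dCin[i, ], w, D, byrow = TRUE)
    }
    dZ <- dZ + dXpad[pad + seq_len(L), , drop = FALSE]
    dparams[[k]] <- list(dW = dW, db = db)
  }
  dZ[!fw$mask, ] <- 0
  list(dZ = dZ, dparams = dparams)
}

#' Encode a padded SDP with a multiple-filter-width CNN
#'
#' For each configured window size, applies a bank of same-padding
#' convolutional filters with ReLU activation over the SDP positions and
#' max-pools over positions; the pooled vectors are concatenated (with the
#' default three windows and 64 filters, a 192-long feature).
#'
#' @inheritParams multi_head_sdp_encoder
#' @param params list of per-window filter banks from the model initializer
#' @return numeric feature vector, `length(windows) * filters`
#' @export
cnn_sdp_encoder <- function(Z, params, mask = rep(TRUE, nrow(Z))) {
  cnn_forward(Z, params, mask)$feature
}
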