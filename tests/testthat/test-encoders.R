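test_that("additive attention matches a step-by-step oracle", {
  # K = 1: the softmax of a singleton is 1 and c = h_1
  h1 <- matrix(rnorm(6), nrow = 1)
  r <- additive_attention(h1, rnorm(6))
  expect_equal(r$weights, 1)
  expect_equal(r$context, drop(h1))

  # equal states give uniform weights and c = h_1
  H <- matrix(rep(rnorm(4), each = 3), nrow = 3)
  r <- additive_attention(H, rnorm(4))
  expect_equal(r$weights, rep(1 / 3, 3))
  expect_equal(r$context, H[1, ])

  # K = 3 hand-set states: independent scalar evaluation of the formulas
  set.seed(7)
  H <- matrix(rnorm(12), nrow = 3)
  v_a <- rnorm(4)
  scores <- sapply(1:3, function(i) sum(v_a * tanh(H[i, ])))
  a <- exp(scores) / sum(exp(scores))
  c_expect <- a[1] * H[1, ] + a[2] * H[2, ] + a[3] * H[3, ]
  r <- additive_attention(H, v_a)
  expect_equal(r$weights, a, tolerance = 1e-12)
  expect_equal(r$context, c_expect, tolerance = 1e-12)
  expect_error(additive_attention(H, rnorm(5)), "dimension")
})

test_that("entity-oriented attention averages entity similarities", {
  # tokens orthogonal to both entity vectors score equally -> uniform
  W <- rbind(c(1, 0, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1), c(0, 1, 0, 0))
  a <- entity_oriented_attention(W, 1L, 4L)
  expect_equal(a[2], a[3])
  expect_equal(sum(a), 1)

  # M = 1 degenerates to weight 1
  expect_equal(entity_oriented_attention(matrix(rnorm(4), 1), 1L, 1L), 1)

  # 3 tokens, m = 4: independent evaluation of the score formulas
  set.seed(3)
  W <- matrix(rnorm(12), nrow = 3)
  s <- sapply(1:3, function(i)
    (sum(W[i, ] * W[1, ]) + sum(W[i, ] * W[3, ])) / (2 * sqrt(4)))
  expect_equal(entity_oriented_attention(W, 1L, 3L),
               exp(s) / sum(exp(s)), tolerance = 1e-12)

  # symmetric under swapping the two entities
  expect_equal(entity_oriented_attention(W, 1L, 3L),
               entity_oriented_attention(W, 3L, 1L))
  expect_error(entity_oriented_attention(W, 1L, 9L), "out of range")
})

test_that("BLSTM encoding has the contracted shape and cell semantics", {
  set.seed(5)
  par <- bbrex:::blstm_init(6L, 64L)
  X <- matrix(rnorm(5 * 6), nrow = 5)
  H <- blstm_encode(X, par)
  expect_equal(dim(H), c(5L, 128L))
  expect_error(blstm_encode(X[0, , drop = FALSE], par), "empty")

  # a length-1 sequence equals one LSTM cell step in each direction
  par <- bbrex:::blstm_init(3L, 2L)
  x <- rnorm(3)
  cell <- function(p) {
    pre <- drop(p$W %*% x + p$b)
    sig <- function(z) 1 / (1 + exp(-z))
    i <- sig(pre[1:2]); f <- sig(pre[3:4]); o <- sig(pre[5:6])
    g <- tanh(pre[7:8])
    o * tanh(i * g)
  }
  H1 <- blstm_encode(matrix(x, nrow = 1), par)
  expect_equal(drop(H1), c(cell(par$fwd), cell(par$bwd)), tolerance = 1e-12)

  # with shared direction weights, a palindrome of identical tokens gives
  # position-symmetric outputs (fwd at step t == bwd at step M + 1 - t)
  par$bwd <- par$fwd
  Xp <- matrix(rep(rnorm(3), each = 4), nrow = 4)
  Hp <- blstm_encode(Xp, par)
  expect_equal(Hp[1, 1:2], Hp[4, 3:4])
  expect_equal(Hp[2, 1:2], Hp[3, 3:4])
  # and with independent weights the two directions genuinely differ
  par2 <- bbrex:::blstm_init(3L, 2L)
  Hq <- blstm_encode(Xp, par2)
  expect_false(isTRUE(all.equal(Hq[1, 1:2], Hq[4, 3:4])))
})

test_that("scaled dot-product self-attention matches hand evaluation", {
  # N = 1: the context is v_1
  z <- matrix(rnorm(3), nrow = 1)
  Wq <- matrix(rnorm(6), 2); Wk <- matrix(rnorm(6), 2)
  Wv <- matrix(rnorm(6), 2)
  r <- scaled_dot_product_self_attention(z, Wq, Wk, Wv)
  expect_equal(r$context[1, ], drop(z %*% t(Wv)))

  # zero projections give uniform weights and the mean of the values
  Z <- matrix(rnorm(12), nrow = 4)
  r <- scaled_dot_product_self_attention(Z, 0 * Wq, 0 * Wk, Wv)
  expect_true(all(abs(r$weights - 0.25) < 1e-12))
  V <- Z %*% t(Wv)
  for (i in 1:4) expect_equal(r$context[i, ], colMeans(V))

  # N = 2, hand-set 2x2 projections: independent evaluation
  Z <- matrix(c(1, 2, -1, 0.5), nrow = 2, byrow = TRUE)
  Wq <- matrix(c(0.3, -0.1, 0.2, 0.4), 2)
  Wk <- matrix(c(-0.2, 0.5, 0.1, 0.3), 2)
  Wv <- matrix(c(1, 0, 0, 1), 2)
  m <- 2
  Q <- Z %*% t(Wq); K <- Z %*% t(Wk); V <- Z %*% t(Wv)
  S <- Q %*% t(K) / sqrt(m)
  A <- t(apply(S, 1, function(s) exp(s) / sum(exp(s))))
  r <- scaled_dot_product_self_attention(Z, Wq, Wk, Wv, m = m)
  expect_equal(r$weights, A, tolerance = 1e-12)
  expect_equal(r$context, A %*% V, tolerance = 1e-12)

  expect_error(scaled_dot_product_self_attention(Z, Wq, Wk, Wv,
                                                 mask = c(FALSE, FALSE)),
               "masked")
})

test_that("attention weights normalize and are shift-invariant", {
  set.seed(21)
  for (rep in 1:10) {
    H <- matrix(rnorm(20), nrow = 5)
    v_a <- rnorm(4)
    expect_equal(sum(additive_attention(H, v_a)$weights), 1,
                 tolerance = 1e-6)
    W <- matrix(rnorm(24), nrow = 6)
    expect_equal(sum(entity_oriented_attention(W, 1L, 2L)), 1,
                 tolerance = 1e-6)
    A <- scaled_dot_product_self_attention(
      W, matrix(rnorm(8), 2, 4), matrix(rnorm(8), 2, 4),
      matrix(rnorm(8), 2, 4))$weights
    expect_equal(rowSums(A), rep(1, 6), tolerance = 1e-6)
  }
  # softmax shift invariance at the score level
  s <- rnorm(6)
  expect_equal(bbrex:::softmax_vec(s), bbrex:::softmax_vec(s + 3.7),
               tolerance = 1e-12)
})

test_that("multi-head SDP encoder: shape, padding and composition", {
  set.seed(8)
  D <- 8L; L <- 5L
  params <- bbrex:::mha_encoder_init(D, 3L, 2L)
  Z <- matrix(rnorm(L * D), nrow = L)
  f <- multi_head_sdp_encoder(Z, params, m = D)
  expect_length(f, L * D)

  # two SDPs identical up to padding give identical features
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  Z2 <- Z; Z2[!mask, ] <- 0
  Z3 <- Z; Z3[!mask, ] <- rnorm(2 * D)  # junk in the padding
  expect_equal(multi_head_sdp_encoder(Z2, params, m = D, mask = mask),
               multi_head_sdp_encoder(Z3, params, m = D, mask = mask))

  # 1 stack / 1 head with no residual reduces to plain self-attention
  p1 <- bbrex:::mha_encoder_init(D, 1L, 1L)
  st <- bbrex:::mha_stack_forward(Z, p1[[1]], D, rep(TRUE, L),
                                  residual = FALSE)
  plain <- scaled_dot_product_self_attention(
    Z, p1[[1]]$heads[[1]]$Wq, p1[[1]]$heads[[1]]$Wk,
    p1[[1]]$heads[[1]]$Wv, m = D)$context
  expect_equal(st$Y, plain %*% t(p1[[1]]$Wo), tolerance = 1e-12)
  expect_error(multi_head_sdp_encoder(Z[1, , drop = FALSE], params),
               "at least 2")
})

test_that("CNN SDP encoder pools multiple filter widths", {
  set.seed(9)
  D <- 6L; L <- 10L
  params <- bbrex:::cnn_init(D, c(3L, 5L, 7L), 64L)
  Z <- matrix(rnorm(L * D), nrow = L)
  expect_length(cnn_sdp_encoder(Z, params), 3L * 64L)

  # constant input: all interior positions share one activation, and the
  # pooled value is the hand-computed max over positions
  p1 <- bbrex:::cnn_init(D, 3L, 4L)
  Zc <- matrix(rep(rnorm(D), each = L), nrow = L)
  f <- cnn_sdp_encoder(Zc, p1)
  padded <- rbind(0, Zc, 0)
  acts <- t(sapply(1:L, function(i)
    pmax(drop(p1[[1]]$W %*% as.vector(t(padded[i:(i + 2), ]))) + p1[[1]]$b,
         0)))
  expect_equal(f, apply(acts, 2, max), tolerance = 1e-12)
  expect_true(all(abs(sweep(acts[2:(L - 1), ], 2, acts[2, ])) < 1e-12))

  # single-window single-filter hand-computed convolution + max
  p <- list(list(W = matrix(c(0.5, -1, 2, 0.25, 1, -0.5), nrow = 1),
                 b = 0.1))
  Z1 <- matrix(c(1, 0, -1, 2, 0.5, 1), ncol = 2, byrow = TRUE)
  pad <- rbind(c(0, 0), Z1, c(0, 0))
  acts <- sapply(1:3, function(i)
    max(sum(p[[1]]$W * as.vector(t(pad[i:(i + 2), ]))) + 0.1, 0))
  expect_equal(cnn_sdp_encoder(Z1, p), max(acts), tolerance = 1e-12)

  # masked padding never changes the feature
  mask <- c(rep(TRUE, 6), rep(FALSE, 4))
  Zp <- Z; Zp[!mask, ] <- 5
  Z0 <- Z; Z0[!mask, ] <- 0
  expect_equal(cnn_sdp_encoder(Zp, params, mask = mask),
               cnn_sdp_encoder(Z0, params, mask = mask))
  expect_error(cnn_sdp_encoder(Z[1:2, ], params), "larger than")
})
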