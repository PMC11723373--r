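test_that("tokenization is row-major, stable, and adds positional embeddings", {
  mp <- array(0, c(2, 3, 4))
  for (i in 1:2) for (j in 1:3) mp[i, j, ] <- (i - 1) * 3 + j
  tok <- tokenize(mp)
  expect_equal(dim(tok), c(6L, 4L))
  expect_equal(tok[, 1], as.numeric(1:6))     # row-major order
  expect_identical(tokenize(mp), tok)
  pos <- matrix(rnorm(24), 6, 4)
  expect_equal(tokenize(mp, pos), tok + pos)
  # zero maps: tokens reduce to the positional embeddings
  expect_equal(tokenize(array(0, c(2, 3, 4)), pos), pos)
  # untokenize inverts tokenize
  expect_equal(seizcast:::untokenize(tok, 2L, 3L), mp)
  # the default stack yields 9 tokens of width 128
  sh <- stack_shapes(default_stack_config())
  expect_equal(sh$pooled_h[4] * sh$pooled_w[4], 9L)
  expect_equal(sh$K[4], 128L)
})

test_that("self-attention weights are row-stochastic and permutation equivariant", {
  set.seed(8)
  d <- 6L; n <- 5L
  p <- init_attention_params(d, n, seed = 3L)
  tok <- matrix(rnorm(n * d), n, d)
  sa <- self_attention(tok, p)
  expect_true(all(abs(rowSums(sa$weights) - 1) < 1e-12))
  # permuting tokens permutes outputs identically (no positional input here)
  perm <- c(3, 1, 5, 2, 4)
  sa_p <- self_attention(tok[perm, ], p)
  expect_equal(sa_p$tokens, sa$tokens[perm, ], tolerance = 1e-12)
  # single token: weight exactly 1, output = input + value-path transform
  t1 <- matrix(rnorm(d), 1, d)
  sa1 <- self_attention(t1, p)
  expect_equal(as.numeric(sa1$weights), 1)
  expect_equal(sa1$tokens, t1 + (t1 %*% p$Wv) %*% p$Wo, tolerance = 1e-12)
})

test_that("the encoder block is the identity at zero transform weights", {
  d <- 4L; n <- 3L
  p <- init_attention_params(d, n, seed = 2L)
  for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2")) p[[nm]][] <- 0
  tok <- matrix(rnorm(n * d, sd = 100), n, d)
  expect_equal(encoder_block(tok, p), tok, tolerance = 1e-12)
  # finite output for large-magnitude input
  p2 <- init_attention_params(d, n, seed = 4L)
  out <- encoder_block(matrix(1e3 * rnorm(n * d), n, d), p2)
  expect_true(all(is.finite(out)))
})

test_that("encoder gradients match finite differences on a 2-token toy", {
  set.seed(5)
  d <- 3L
  p <- init_attention_params(d, 2L, seed = 7L)
  for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2"))
    p[[nm]] <- p[[nm]] * 20      # make the transforms non-trivial
  tok <- matrix(rnorm(6), 2, 3)
  w_out <- matrix(rnorm(6), 2, 3)  # random linear functional of the output
  lossfn <- function(pp, tt) sum(w_out * seizcast:::encoder_forward(tt, pp)$T2)
  cache <- seizcast:::encoder_forward(tok, p)
  bk <- seizcast:::encoder_backward(w_out, cache, p)
  eps <- 1e-6
  for (nm in names(bk$grads)) {
    i <- sample(length(p[[nm]]), 1)
    p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
    p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - eps
    fd <- (lossfn(p2, tok) - lossfn(p3, tok)) / (2 * eps)
    expect_equal(bk$grads[[nm]][i], fd, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
  # input gradient
  i <- 4L
  t2 <- tok; t2[i] <- t2[i] + eps
  t3 <- tok; t3[i] <- t3[i] - eps
  fd <- (lossfn(p, t2) - lossfn(p, t3)) / (2 * eps)
  expect_equal(bk$dT0[i], fd, tolerance = 1e-4)
})

test_that("classification head produces calibrated simplex outputs", {
  set.seed(12)
  tok <- matrix(rnorm(9 * 5), 9, 5)
  hp <- init_head_params(5L, 4L)
  pr0 <- classify(tok, hp)
  expect_equal(sum(pr0), 1, tolerance = 1e-12)
  expect_true(all(abs(pr0 - 0.25) < 1e-12))   # zero head: uniform
  hp$Wc <- matrix(rnorm(20), 5, 4); hp$bc <- rnorm(4)
  pr1 <- classify(tok, hp)
  expect_equal(sum(pr1), 1, tolerance = 1e-12)
  hp2 <- hp; hp2$bc <- hp$bc + 7    # constant logit shift
  expect_equal(which.max(classify(tok, hp2)), which.max(pr1))
})

test_that("full-model backpropagation matches finite differences", {
  set.seed(42)
  cfg <- stack_config(list(
    list(K = 3L, k = 3L, pad = 0L, pool = 2L, lambda = 0.1),
    list(K = 4L, k = 2L, pad = 0L, pool = 2L, lambda = 0.1)))
  mdl <- seizcast_model(cfg, input_dim = c(10L, 10L, 3L), n_classes = 2L,
                        seed = 3L)
  mdl$head$Wc <- matrix(rnorm(mdl$d * 2, sd = 0.1), mdl$d, 2)
  v <- array(rnorm(300), dim = c(10, 10, 3))
  y <- 1L
  f2n <- rep(1 / sqrt(mdl$d), mdl$d)
  lossfn <- function(m) {
    ca <- model_forward(m, v, mode = "eval")
    nn <- seizcast:::l2n(ca$fbar)
    # probabilities can saturate to exactly 1 under finite-difference nudges
    suppressWarnings(main_loss(y, matrix(ca$probs, 1))) +
      0.11 * verification_loss(nn$fn, f2n, 0, 1)
  }
  ca <- model_forward(mdl, v, mode = "eval")
  nn <- seizcast:::l2n(ca$fbar)
  one <- c(0, 1)
  dfa <- seizcast:::l2n_backward(
    0.11 * seizcast:::verification_grad(nn$fn, f2n, 0, 1), nn)
  g <- model_backward(mdl, ca, ca$probs - one, dfa)
  gl <- seizcast:::grads_to_list(mdl, g)
  pl <- seizcast:::model_param_list(mdl)
  eps <- 1e-5
  for (nm in names(pl)) {
    i <- sample(length(pl[[nm]]), 1)
    p2 <- pl; p2[[nm]][i] <- p2[[nm]][i] + eps
    p3 <- pl; p3[[nm]][i] <- p3[[nm]][i] - eps
    fd <- (lossfn(seizcast:::model_set_params(mdl, p2)) -
           lossfn(seizcast:::model_set_params(mdl, p3))) / (2 * eps)
    expect_equal(gl[[nm]][i], fd, tolerance = 1e-3,
                 label = paste("grad", nm))
  }
})
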