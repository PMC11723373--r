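# Transformer-encoder head over tokens from the final hybrid feature maps:
# single-head scaled dot-product self-attention and a two-layer perceptron,
# both with residual connections (pre-norm), plus a linear softmax
# classifier over the mean-pooled token representation.

#' Initialize attention-head parameters
#'
#' @param d token width (final feature-map channel count)
#' @param n_tokens number of spatial tokens
#' @param hidden perceptron hidden width
#' @param seed RNG seed
#' @export
init_attention_params <- function(d, n_tokens, hidden = 2L * d, seed = 1L) {
  set.seed(seed)
  rnd <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  list(Wq = rnd(d, d), Wk = rnd(d, d), Wv = rnd(d, d), Wo = rnd(d, d),
       ln1_g = rep(1, d), ln1_b = rep(0, d),
       ln2_g = rep(1, d), ln2_b = rep(0, d),
       W1 = rnd(d, hidden), b1 = rep(0, hidden),
       W2 = rnd(hidden, d), b2 = rep(0, d),
       pos = rnd(n_tokens, d))
}

#' Initialize classifier-head parameters (zeros: uniform initial probabilities)
#' @export
init_head_params <- function(d, n_classes) {
  list(Wc = matrix(0, d, n_classes), bc = rep(0, n_classes))
}

#' Turn the final hybrid feature map into a token sequence
#'
#' Each spatial position becomes one token of width K, in row-major spatial
#' order; learned positional embeddings are added when supplied.
#' @param maps array `[Hp, Wp, K]`
#' @param pos optional positional-embedding matrix `[Hp*Wp, K]`
#' @return matrix `[n_tokens, K]`
#' @export
tokenize <- function(maps, pos = NULL) {
  d <- dim(maps)
  tok <- t(matrix(aperm(maps, c(3, 2, 1)), nrow = d[3]))  # row-major positions
  if (!is.null(pos)) {
    if (!all(dim(pos) == dim(tok))) stop("positional embedding shape mismatch")
    tok <- tok + pos
  }
  tok
}

# inverse of tokenize for gradients
untokenize <- function(tok, hp, wp) {
  k <- ncol(tok)
  aperm(array(t(tok), dim = c(k, wp, hp)), c(3, 2, 1))
}

layernorm_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  list(y = sweep(xhat, 2, g, "*") + matrix(b, nrow(x), ncol(x), byrow = TRUE),
       xhat = xhat, istd = istd)
}

layernorm_backward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$istd
  list(dx = dx, dg = dg, db = db)
}

softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# scaled dot-product self-attention core (no residual), with cache
sa_core_forward <- function(u, p, norm = "softmax") {
  d <- ncol(u)
  Q <- u %*% p$Wq; K <- u %*% p$Wk; V <- u %*% p$Wv
  S <- Q %*% t(K) / sqrt(d)
  A <- if (norm == "softmax") softmax_rows(S) else S
  O <- A %*% V
  out <- O %*% p$Wo
  list(out = out, u = u, Q = Q, K = K, V = V, S = S, A = A, O = O,
       norm = norm)
}

sa_core_backward <- function(dout, cache, p) {
  d <- ncol(cache$u)
  dWo <- t(cache$O) %*% dout
  dO <- dout %*% t(p$Wo)
  dA <- dO %*% t(cache$V)
  dV <- t(cache$A) %*% dO
  dS <- if (cache$norm == "softmax") {
    rs <- rowSums(dA * cache$A)
    cache$A * (dA - rs)
  } else dA
  dQ <- dS %*% cache$K / sqrt(d)
  dK <- t(dS) %*% cache$Q / sqrt(d)
  du <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(du = du, dWq = t(cache$u) %*% dQ, dWk = t(cache$u) %*% dK,
       dWv = t(cache$u) %*% dV, dWo = dWo)
}

#' Self-attention block with residual connection
#'
#' Scaled dot-product attention over the tokens with row-normalized
#' (softmax) weights; the transformed values are added residually to the
#' input. `norm = "none"` uses the raw scaled dot products instead of the
#' softmax (ablation option).
#' @param tokens matrix `[n_tokens, d]`
#' @param params as from [init_attention_params()]
#' @return list(tokens, weights) — transformed tokens and attention weights
#' @export
self_attention <- function(tokens, params, norm = c("softmax", "none")) {
  norm <- match.arg(norm)
  sa <- sa_core_forward(tokens, params, norm)
  list(tokens = tokens + sa$out, weights = sa$A)
}

# full encoder block with pre-norm and cache
encoder_forward <- function(T0, p, norm = "softmax") {
  ln1 <- layernorm_forward(T0, p$ln1_g, p$ln1_b)
  sa <- sa_core_forward(ln1$y, p, norm)
  T1 <- T0 + sa$out
  ln2 <- layernorm_forward(T1, p$ln2_g, p$ln2_b)
  pre <- ln2$y %*% p$W1 + matrix(p$b1, nrow(T1), length(p$b1), byrow = TRUE)
  Mh <- relu(pre)
  M <- Mh %*% p$W2 + matrix(p$b2, nrow(T1), length(p$b2), byrow = TRUE)
  T2 <- T1 + M
  list(T0 = T0, ln1 = ln1, sa = sa, T1 = T1, ln2 = ln2, pre = pre, Mh = Mh,
       T2 = T2)
}

encoder_backward <- function(dT2, cache, p) {
  # perceptron branch
  dM <- dT2
  dW2 <- t(cache$Mh) %*% dM
  db2 <- colSums(dM)
  dMh <- dM %*% t(p$W2)
  dpre <- dMh * (cache$pre > 0)
  dW1 <- t(cache$ln2$y) %*% dpre
  db1 <- colSums(dpre)
  du2 <- dpre %*% t(p$W1)
  ln2b <- layernorm_backward(du2, cache$ln2, p$ln2_g)
  dT1 <- dT2 + ln2b$dx
  # attention branch
  sab <- sa_core_backward(dT1, cache$sa, p)
  ln1b <- layernorm_backward(sab$du, cache$ln1, p$ln1_g)
  dT0 <- dT1 + ln1b$dx
  list(dT0 = dT0,
       grads = list(Wq = sab$dWq, Wk = sab$dWk, Wv = sab$dWv, Wo = sab$dWo,
                    ln1_g = ln1b$dg, ln1_b = ln1b$db,
                    ln2_g = ln2b$dg, ln2_b = ln2b$db,
                    W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

#' Transformer encoder block (self-attention + two-layer perceptron)
#'
#' Pre-norm residual encoder: tokens + SA(LN(tokens)), then + MLP(LN(.)).
#' With all transform weights at zero the block is the identity map.
#' @inheritParams self_attention
#' @return matrix of transformed tokens
#' @export
encoder_block <- function(tokens, params, norm = c("softmax", "none")) {
  norm <- match.arg(norm)
  encoder_forward(tokens, params, norm)$T2
}

#' Classify a token sequence
#'
#' Mean-pools the tokens and maps the pooled representation through a linear
#' softmax head.
#' @param tokens matrix `[n_tokens, d]`
#' @param head_params as from [init_head_params()]
#' @return probability vector summing to 1
#' @export
classify <- function(tokens, head_params) {
  fbar <- colMeans(tokens)
  logits <- as.vector(fbar %*% head_params$Wc) + head_params$bc
  e <- exp(logits - max(logits))
  e / sum(e)
}
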