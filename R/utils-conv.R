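# Dense 2-D convolution and pooling primitives used by the CssCRBM layers.
#
# Array conventions (R column-major):
#   visible / input maps  v : [H, W, L]   (L input channels)
#   kernels               w : [kh, kw, L, K]
#   hidden / output maps  C : [Hh, Wh, K] with Hh = H + 2*pad - kh + 1
#
# Convolution here is the cross-correlation form used throughout the model
# energy: (v THETA w)_ij = sum_{r,s,l} v[i+r-1, j+s-1, l] * w[r, s, l, k].

#' Precompute gather indices for im2col patch extraction
#'
#' @param H,W,L input height, width, channels (after padding)
#' @param kh,kw kernel height and width
#' @return list with `idx` (integer matrix [kh*kw*L, Hh*Ww]), `Hh`, `Wh`
#' @keywords internal
make_im2col <- function(H, W, L, kh, kw) {
  Hh <- H - kh + 1L
  Wh <- W - kw + 1L
  stopifnot(Hh >= 1L, Wh >= 1L)
  # linear index into [H, W, L] for element (i+r-1, j+s-1, l)
  base <- outer(seq_len(Hh), seq_len(Wh) - 1L, function(i, j) i + j * H) # [Hh, Wh]
  off <- integer(kh * kw * L)
  t <- 1L
  for (l in seq_len(L)) for (s in seq_len(kw)) for (r in seq_len(kh)) {
    off[t] <- (r - 1L) + (s - 1L) * H + (l - 1L) * H * W
    t <- t + 1L
  }
  list(idx = off, base = as.integer(base), Hh = Hh, Wh = Wh,
       H = H, W = W, L = L, kh = kh, kw = kw)
}

#' Extract patches as a matrix (one column per output position)
#' @param x numeric array [H, W, L] (already padded)
#' @param plan result of [make_im2col()]
#' @return matrix [kh*kw*L, Hh*Wh]
#' @keywords internal
im2col <- function(x, plan) {
  n_off <- length(plan$idx)
  n_pos <- length(plan$base)
  # outer sum of offsets and base positions, gathered in one shot
  idx <- rep(plan$idx, times = n_pos) + rep(plan$base, each = n_off)
  matrix(x[idx], nrow = n_off, ncol = n_pos)
}

#' Scatter-add patch gradients back to the input array
#' @param dP matrix [kh*kw*L, Hh*Wh] of patch gradients
#' @return numeric array [H, W, L]
#' @keywords internal
col2im <- function(dP, plan) {
  dx <- numeric(plan$H * plan$W * plan$L)
  for (t in seq_along(plan$idx)) {
    pos <- plan$base + plan$idx[t]
    dx[pos] <- dx[pos] + dP[t, ]
  }
  array(dx, dim = c(plan$H, plan$W, plan$L))
}

pad_array <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

unpad_array <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  x[pad + seq_len(d[1] - 2L * pad), pad + seq_len(d[2] - 2L * pad), , drop = FALSE]
}

# memoized im2col plans keyed by geometry
.plan_cache <- new.env(parent = emptyenv())

get_plan <- function(H, W, L, kh, kw) {
  key <- paste(H, W, L, kh, kw, sep = "x")
  pl <- .plan_cache[[key]]
  if (is.null(pl)) {
    pl <- make_im2col(H, W, L, kh, kw)
    .plan_cache[[key]] <- pl
  }
  pl
}

# column maxima of a small-rowed matrix without apply()
col_max <- function(m) {
  out <- m[1, ]
  nr <- nrow(m)
  if (nr > 1L) for (r in 2:nr) out <- pmax(out, m[r, ])
  out
}

# per-map sums of a [Hh, Wh, K] array
map_sums <- function(x) {
  d <- dim(x)
  colSums(matrix(x, nrow = d[1] * d[2], ncol = d[3]))
}

#' Multi-channel valid convolution (cross-correlation)
#'
#' @param v input array [H, W, L]
#' @param w kernel array [kh, kw, L, K]
#' @param pad zero-padding width applied to both spatial axes
#' @param plan optional precomputed [make_im2col()] plan for the padded size
#' @return array [Hh, Wh, K]
#' @keywords internal
conv_forward <- function(v, w, pad = 0L, plan = NULL) {
  dv <- dim(v); dw <- dim(w)
  stopifnot(length(dv) == 3L, length(dw) == 4L)
  if (dv[3] != dw[3]) stop("conv_forward: channel mismatch between v and w")
  vp <- pad_array(v, pad)
  if (is.null(plan)) plan <- get_plan(dim(vp)[1], dim(vp)[2], dv[3], dw[1], dw[2])
  P <- im2col(vp, plan)
  Wm <- matrix(w, nrow = dw[1] * dw[2] * dw[3], ncol = dw[4]) # [khkwL, K]
  C <- crossprod(P, Wm)                                       # [Hh*Wh, K]
  array(C, dim = c(plan$Hh, plan$Wh, dw[4]))
}

#' Backward pass of [conv_forward()]: gradients w.r.t. kernels and input
#' @param dC gradient array [Hh, Wh, K]
#' @return list(dw = [kh,kw,L,K], dv = [H,W,L])
#' @keywords internal
conv_backward <- function(v, w, dC, pad = 0L, plan = NULL, need_dv = TRUE) {
  dv_dim <- dim(v); dw <- dim(w)
  vp <- pad_array(v, pad)
  if (is.null(plan)) plan <- get_plan(dim(vp)[1], dim(vp)[2], dv_dim[3], dw[1], dw[2])
  P <- im2col(vp, plan)
  Gm <- matrix(dC, nrow = plan$Hh * plan$Wh, ncol = dw[4])
  dwm <- P %*% Gm                                   # [khkwL, K]
  dwa <- array(dwm, dim = dw)
  dv <- NULL
  if (need_dv) {
    Wm <- matrix(w, nrow = dw[1] * dw[2] * dw[3], ncol = dw[4])
    dP <- Wm %*% t(Gm)                              # [khkwL, Hh*Wh]
    dv <- unpad_array(col2im(dP, plan), pad)
  }
  list(dw = dwa, dv = dv)
}

#' Full (transposed) convolution with the flipped kernel
#'
#' Maps hidden-sized maps back to visible-sized maps, as in the visible-unit
#' conditional mean: out_l = sum_k (m_k full-conv flipped w_{l,k}).
#' Inverse operation of the valid convolution in the adjoint sense.
#' @param m array [Hh, Wh, K]
#' @param w kernel array [kh, kw, L, K]
#' @return array [H, W, L] with H = Hh + kh - 1 - 2*pad (the original size)
#' @keywords internal
conv_transpose <- function(m, w, pad = 0L) {
  dm <- dim(m); dw <- dim(w)
  H <- dm[1] + dw[1] - 1L - 2L * pad
  W <- dm[2] + dw[2] - 1L - 2L * pad
  v0 <- array(0, dim = c(H, W, dw[3]))
  conv_backward(v0, w, m, pad = pad, need_dv = TRUE)$dv
}

#' Block max-pooling over the hybrid map (floor division, remainder dropped)
#' @param m array [Hh, Wh, K]
#' @param pool block side length
#' @return list(p = pooled array [Hp, Wp, K], argmax = linear indices into m)
#' @keywords internal
pool_max <- function(m, pool) {
  d <- dim(m)
  Hp <- d[1] %/% pool; Wp <- d[2] %/% pool
  if (pool == 1L) {
    return(list(p = m, argmax = array(seq_along(m), dim = d), Hp = d[1], Wp = d[2]))
  }
  p <- array(-Inf, dim = c(Hp, Wp, d[3]))
  am <- array(NA_integer_, dim = c(Hp, Wp, d[3]))
  for (r in seq_len(pool)) for (s in seq_len(pool)) {
    ii <- (seq_len(Hp) - 1L) * pool + r
    jj <- (seq_len(Wp) - 1L) * pool + s
    sub <- m[ii, jj, , drop = FALSE]
    lin <- linear_index(ii, jj, d)
    upd <- sub > p
    p[upd] <- sub[upd]
    am[upd] <- lin[upd]
  }
  list(p = p, argmax = am, Hp = Hp, Wp = Wp)
}

# linear indices of the [ii, jj, k] grid inside an array of dim d
linear_index <- function(ii, jj, d) {
  a <- outer(ii, (jj - 1L) * d[1], `+`)                    # [Hp, Wp]
  k_off <- (seq_len(d[3]) - 1L) * d[1] * d[2]
  array(rep(a, times = d[3]) + rep(k_off, each = length(a)),
        dim = c(length(ii), length(jj), d[3]))
}

#' Scatter pooled-gradient back through max-pooling
#' @keywords internal
pool_max_backward <- function(dp, pooled, m_dim) {
  dm <- array(0, dim = m_dim)
  dm[as.vector(pooled$argmax)] <- dm[as.vector(pooled$argmax)] + as.vector(dp)
  dm
}

logistic <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

#' Derive a bounded integer sub-seed from a base seed and stream labels
#' @keywords internal
sub_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) h <- (h * 7919 + as.numeric(p) * 104729 + 1299709) %% 2147483629
  as.integer(h)
}
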