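# Contractive spike-and-slab convolutional restricted Boltzmann machine
# (CssCRBM): energy, exact conditional inferences, and dual-variable
# probabilistic max-pooling.
#
# The model couples L-channel real-valued visible maps v to K feature maps of
# binary spike units h and real slab units s through shared convolution
# kernels w. The energy is
#
#   E(v, s, h) = - sum_{l,k,ij} (v^l THETA w^{l,k})_ij h_ij^k s_ij^k
#                - sum_k b^k sum_ij h_ij^k
#                + sum_{l,mn} (v_mn^l - c^l)^2 / (2 sigma^2)
#                + (1/2) sum_{k,ij} a^k (s_ij^k)^2
#
# optionally subject to the pooling constraint sum_{(i,j) in B_a} h_ij^k <= 1
# over non-overlapping pool x pool blocks B_a of each feature map.

#' Construct CssCRBM parameters
#'
#' @param w convolution kernels, array `[kh, kw, L, K]`
#' @param b spike biases, length-`K` vector
#' @param c visible biases, length-`L` vector
#' @param a slab precision penalties (must be positive). Either a length-`K`
#'   vector (one learnable value per feature map, broadcast over positions —
#'   the default, matching the weight-sharing logic of convolution) or a full
#'   per-unit array `[Hh, Wh, K]`.
#' @param sigma visible noise scale (positive scalar)
#' @param pool pooling block side length (`1` disables pooling)
#' @param pad zero-padding applied before convolution
#' @return object of class `csscrbm_params`
#' @export
csscrbm_params <- function(w, b, c, a, sigma = 1, pool = 1L, pad = 0L) {
  w <- as.array(w)
  if (length(dim(w)) != 4L) stop("w must be a 4-d array [kh, kw, L, K]")
  K <- dim(w)[4]; L <- dim(w)[3]
  if (length(b) != K) stop("b must have one entry per feature map (K)")
  if (length(c) != L) stop("c must have one entry per visible channel (L)")
  if (any(!is.finite(a)) || any(a <= 0)) stop("slab penalty a must be positive")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (pool < 1L) stop("pool must be >= 1")
  structure(list(w = w, b = as.numeric(b), c = as.numeric(c), a = a,
                 sigma = sigma, pool = as.integer(pool), pad = as.integer(pad)),
            class = "csscrbm_params")
}

#' Randomly initialized CssCRBM parameters
#'
#' For generative (CD) training, kernels start at N(0, 0.01^2) and spike
#' biases at -1 (sparse start). For discriminative use (`init =
#' "finetune"`), kernels start at He scale sqrt(2 / (kh*kw*L)) and spike
#' biases at 0, so the relu spike maps are active from the start. Visible
#' biases start at 0 and slab penalties at 1 in both cases.
#' @param kh,kw kernel size
#' @param L input channels
#' @param K number of feature maps
#' @inheritParams csscrbm_params
#' @param seed optional RNG seed
#' @param init `"cd"` or `"finetune"`
#' @export
csscrbm_init <- function(kh, kw, L, K, sigma = 1, pool = 1L, pad = 0L,
                         seed = NULL, init = c("cd", "finetune")) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  sd <- if (init == "cd") 0.01 else sqrt(2 / (kh * kw * L))
  b0 <- if (init == "cd") -1 else 0
  w <- array(stats::rnorm(kh * kw * L * K, sd = sd), dim = c(kh, kw, L, K))
  csscrbm_params(w, b = rep(b0, K), c = rep(0, L), a = rep(1, K),
                 sigma = sigma, pool = pool, pad = pad)
}

# broadcast the slab penalty to the hidden-map shape [Hh, Wh, K]
a_broadcast <- function(params, hdim) {
  a <- params$a
  if (any(a <= 0)) stop("slab penalty a must be positive")
  if (is.array(a) && length(dim(a)) == 3L) {
    if (!all(dim(a) == hdim)) stop("per-unit slab penalty a has wrong shape")
    return(a)
  }
  array(rep(a, each = hdim[1] * hdim[2]), dim = hdim)
}

hidden_dim <- function(params, vdim) {
  dw <- dim(params$w)
  c(vdim[1] + 2L * params$pad - dw[1] + 1L,
    vdim[2] + 2L * params$pad - dw[2] + 1L, dw[4])
}

#' Layer state container
#'
#' Holds the visible map, spike/slab maps and their pooled counterparts for
#' one CssCRBM layer. Within every pooling block of `h` at most one unit is
#' active, and `p_h` for a block is 1 iff some unit in the block is.
#' @export
layer_state <- function(v, h, s, p_h = NULL, p_s = NULL) {
  structure(list(v = v, h = h, s = s, p_h = p_h, p_s = p_s),
            class = "layer_state")
}

check_state_shapes <- function(state, params) {
  dv <- dim(state$v)
  if (length(dv) != 3L) stop("state tensor v must be 3-d [H, W, L]")
  if (dv[3] != dim(params$w)[3]) stop("state tensor v: channel count does not match kernels w")
  hd <- hidden_dim(params, dv)
  if (!is.null(state$h) && !all(dim(state$h) == hd))
    stop("state tensor h has shape (", paste(dim(state$h), collapse = "x"),
         "), expected (", paste(hd, collapse = "x"), ")")
  if (!is.null(state$s) && !all(dim(state$s) == hd))
    stop("state tensor s has shape (", paste(dim(state$s), collapse = "x"),
         "), expected (", paste(hd, collapse = "x"), ")")
  invisible(hd)
}

#' CssCRBM energy
#'
#' Evaluates the slab-and-spike energy of a full layer configuration.
#' @param state a [layer_state()] with `v`, `h`, `s`
#' @param params a [csscrbm_params()]
#' @return scalar energy
#' @export
csscrbm_energy <- function(state, params) {
  hd <- check_state_shapes(state, params)
  C <- conv_forward(state$v, params$w, pad = params$pad)
  a <- a_broadcast(params, hd)
  e_int <- -sum(C * state$h * state$s)
  e_spk <- -sum(params$b * apply(state$h, 3, sum))
  cc <- array(rep(params$c, each = dim(state$v)[1] * dim(state$v)[2]),
              dim = dim(state$v))
  e_vis <- sum((state$v - cc)^2) / (2 * params$sigma^2)
  e_slb <- 0.5 * sum(a * state$s^2)
  e <- e_int + e_spk + e_vis + e_slb
  if (!is.finite(e)) stop("non-finite energy")
  e
}

# convolutional response and the spike pre-activation z = C^2/(2a) + b
spike_preactivation <- function(v, params) {
  C <- conv_forward(v, params$w, pad = params$pad)
  hd <- dim(C)
  a <- a_broadcast(params, hd)
  b <- array(rep(params$b, each = hd[1] * hd[2]), dim = hd)
  list(C = C, a = a, z = C^2 / (2 * a) + b)
}

#' Spike conditional p(h = 1 | v) without pooling
#'
#' Each unit's activation probability is the logistic function of
#' z = (1/(2a)) (sum_l v^l THETA w^{l,k})^2 + b^k.
#' @return probability array `[Hh, Wh, K]`
#' @export
spike_given_v <- function(v, params) {
  logistic(spike_preactivation(v, params)$z)
}

# reshape the truncated hidden grid into per-block columns:
# returns matrix [pool^2, n_blocks] plus block geometry
block_view <- function(x, pool) {
  d <- dim(x)
  Hp <- d[1] %/% pool; Wp <- d[2] %/% pool
  xt <- x[seq_len(Hp * pool), seq_len(Wp * pool), , drop = FALSE]
  # [pool, Hp, pool, Wp, K] -> [pool, pool, Hp, Wp, K]
  arr <- array(xt, dim = c(pool, Hp, pool, Wp, d[3]))
  arr <- aperm(arr, c(1, 3, 2, 4, 5))
  list(m = matrix(arr, nrow = pool * pool), Hp = Hp, Wp = Wp, K = d[3])
}

# inverse of block_view: matrix [pool^2, n_blocks] -> array [Hp*pool, Wp*pool, K]
block_unview <- function(m, pool, Hp, Wp, K) {
  arr <- array(m, dim = c(pool, pool, Hp, Wp, K))
  arr <- aperm(arr, c(1, 3, 2, 4, 5))
  array(arr, dim = c(Hp * pool, Wp * pool, K))
}

#' Spike conditionals under dual-variable probabilistic max-pooling
#'
#' Within each pool x pool block at most one spike unit may be active. The
#' block-level conditional is a categorical distribution over the block
#' positions plus an "off" state:
#' P(h_ij = 1 | v) = exp(z_ij) / (1 + sum_block exp(z)),
#' P(p^h = 0 | v)  = 1 / (1 + sum_block exp(z)).
#' When `pool` does not divide the detection grid the trailing remainder is
#' dropped (floor-division pooling).
#' @return list with `p_unit` (array, truncated grid `[Hp*pool, Wp*pool, K]`),
#'   `p_off` (array `[Hp, Wp, K]`), `z` (full pre-activation) and geometry
#' @export
pooled_spike_given_v <- function(v, params) {
  pre <- spike_preactivation(v, params)
  pool <- params$pool
  if (pool == 1L) {
    # singleton blocks: the categorical reduces to the logistic
    p <- logistic(pre$z)
    d <- dim(pre$z)
    return(list(p_unit = p, p_off = 1 - p, z = pre$z, C = pre$C, a = pre$a,
                Hp = d[1], Wp = d[2]))
  }
  bv <- block_view(pre$z, pool)
  m <- pmax(col_max(bv$m), 0)
  e <- exp(sweep(bv$m, 2, m))         # exp(z - m)
  denom <- exp(-m) + colSums(e)
  p_unit <- sweep(e, 2, denom, "/")
  p_off <- exp(-m) / denom
  list(p_unit = block_unview(p_unit, pool, bv$Hp, bv$Wp, bv$K),
       p_off = array(p_off, dim = c(bv$Hp, bv$Wp, bv$K)),
       z = pre$z, C = pre$C, a = pre$a, Hp = bv$Hp, Wp = bv$Wp)
}

#' Slab conditional p(s | v, h): Gaussian per unit
#'
#' mean = (1/a) (sum_l v^l THETA w^{l,k}) h, variance = 1/a (independent of
#' v and h).
#' @return list(mean, var) of arrays `[Hh, Wh, K]`
#' @export
slab_given_vh <- function(v, h, params) {
  pre <- spike_preactivation(v, params)
  list(mean = pre$C * h / pre$a, var = 1 / pre$a)
}

#' Pooled slab conditional: Gaussian per block
#'
#' Block mean is the maximum over the block of the unit-level slab means;
#' variance is 1/a.
#' @return list(mean, var) of arrays `[Hp, Wp, K]`
#' @export
pooled_slab_given_v <- function(v, h, params) {
  sv <- slab_given_vh(v, h, params)
  pool <- params$pool
  if (pool == 1L) return(sv)
  bv <- block_view(sv$mean, pool)
  mx <- col_max(bv$m)
  av <- block_view(1 / sv$var, pool)  # a on the truncated grid
  list(mean = array(mx, dim = c(bv$Hp, bv$Wp, bv$K)),
       var = array(1 / av$m[1, ], dim = c(bv$Hp, bv$Wp, bv$K)))
}

#' Visible conditional p(v | s, h): Gaussian per visible unit
#'
#' mean = sigma^2 * sum_k (h*s full-convolved with the flipped kernel) + c^l,
#' variance = sigma^2.
#' @return list(mean, var)
#' @export
visible_given_sh <- function(s, h, params) {
  if (!all(dim(s) == dim(h))) stop("shape mismatch between tensors s and h")
  top <- conv_transpose(h * s, params$w, pad = params$pad)
  d <- dim(top)
  cc <- array(rep(params$c, each = d[1] * d[2]), dim = d)
  list(mean = params$sigma^2 * top + cc, var = params$sigma^2)
}

#' Sample a full pooled layer state given the visible layer
#'
#' Draws the spike configuration block-wise from the pooled categorical
#' (never more than one active unit per block), the slab units from their
#' Gaussian conditional, and forms the pooled outputs: p_h as the block
#' indicator and p_s as a draw from the pooled slab conditional. The pooled
#' hybrid output is the elementwise product p_h * p_s.
#' @param v visible array `[H, W, L]`
#' @param params a [csscrbm_params()]
#' @param seed optional seed for reproducible draws
#' @return a [layer_state()] with an extra `pooled` element (p_h * p_s)
#' @export
sample_pooled_state <- function(v, params, seed = NULL, ps = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ps)) ps <- pooled_spike_given_v(v, params)
  pool <- params$pool
  hd <- dim(ps$z)
  if (pool == 1L) {
    # singleton blocks: independent Bernoulli spikes
    h <- array(as.numeric(stats::runif(length(ps$p_unit)) < ps$p_unit),
               dim = hd)
    smean <- ps$C * h / ps$a
    s <- smean + stats::rnorm(length(smean)) / sqrt(ps$a)
    p_s <- smean + stats::rnorm(length(smean)) / sqrt(ps$a)
    st <- layer_state(v = v, h = h, s = s, p_h = h, p_s = p_s)
    st$pooled <- h * p_s
    return(st)
  }
  # per-block categorical draw over pool^2 positions + off state
  pu <- block_view(ps$p_unit, pool)$m              # [pool^2, nblocks]
  np <- nrow(pu)
  cum <- pu
  if (np > 1L) for (r in 2:np) cum[r, ] <- cum[r - 1L, ] + pu[r, ]
  u <- stats::runif(ncol(pu))
  pick <- colSums(cum < rep(u, each = np)) + 1L    # np + 1 == off state
  hm <- matrix(0, nrow = np, ncol = ncol(pu))
  on <- which(pick <= np)
  hm[cbind(pick[on], on)] <- 1
  h <- array(0, dim = hd)
  h[seq_len(ps$Hp * pool), seq_len(ps$Wp * pool), ] <-
    block_unview(hm, pool, ps$Hp, ps$Wp, hd[3])
  # slab draw: mean C h / a, variance 1/a (no extra convolution needed)
  smean <- ps$C * h / ps$a
  s <- smean + stats::rnorm(length(smean)) / sqrt(ps$a)
  dim(s) <- hd
  # pooled variables
  p_h <- array(colSums(hm), dim = c(ps$Hp, ps$Wp, hd[3]))
  bmean <- block_view(smean, pool)
  pmean <- apply(bmean$m, 2, max)
  bva <- block_view(ps$a, pool)
  p_s <- pmean + stats::rnorm(length(pmean)) / sqrt(bva$m[1, ])
  p_s <- array(p_s, dim = c(ps$Hp, ps$Wp, hd[3]))
  st <- layer_state(v = v, h = h, s = s, p_h = p_h, p_s = p_s)
  st$pooled <- p_h * p_s
  st
}
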