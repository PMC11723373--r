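# Tiny CssCRBM instances with exact-enumeration oracles.
#
# For models with few spike units the slab units can be integrated out
# analytically (they are conditionally Gaussian) and the spike configurations
# enumerated, giving exact conditionals p(h | v), exact marginals p(h), and
# the exact log-likelihood gradient. These serve as independent references
# for the closed-form inference rules and for contrastive-divergence
# training, and are only feasible at toy scale.

#' Generate a tiny CssCRBM instance for oracle testing
#'
#' One visible channel, 3x3 visible map, `K` 2x2 kernels with randomized
#' small parameters, plus a set of random visible samples.
#' @param seed RNG seed
#' @param K number of feature maps (1 or 2 keep enumeration cheap)
#' @param pool pooling block side (1 = no pooling; 2 pools the 2x2 hidden grid)
#' @param n_samples number of random visible samples to attach
#' @return list(params, v_samples) where `v_samples` is a list of 3x3x1 arrays
#' @export
gen_tiny_rbm <- function(seed = 1L, K = 1L, pool = 1L, n_samples = 5L) {
  set.seed(seed)
  w <- array(stats::rnorm(2 * 2 * 1 * K, sd = 0.4), dim = c(2, 2, 1, K))
  a <- stats::runif(K, 0.8, 1.5)
  params <- csscrbm_params(w, b = stats::rnorm(K, sd = 0.3),
                           c = stats::rnorm(1, sd = 0.2),
                           a = a,
                           sigma = 1, pool = pool, pad = 0L)
  # the joint density is normalizable only when the slab precision dominates
  # the spike-slab/visible coupling; rescale kernels to guarantee it (checked
  # at the worst case, all spikes active)
  M <- conv_matrix(params, c(3L, 3L, 1L))
  A_diag <- as.vector(a_broadcast(params, hidden_dim(params, c(3L, 3L, 1L))))
  emin <- min(eigen(diag(A_diag) - params$sigma^2 * M %*% t(M),
                    symmetric = TRUE, only.values = TRUE)$values)
  if (emin < 0.2) {
    shrink <- sqrt((min(A_diag) - 0.2) / (min(A_diag) - emin))
    params$w <- params$w * shrink
  }
  v_samples <- lapply(seq_len(n_samples), function(i)
    array(stats::rnorm(9, sd = 1), dim = c(3, 3, 1)))
  list(params = params, v_samples = v_samples)
}

# all spike configurations respecting the block constraint, as a matrix with
# one configuration per row (columns = hidden units in array order)
enumerate_h_configs <- function(hd, pool) {
  nh <- prod(hd)
  if (pool == 1L) {
    cfg <- as.matrix(expand.grid(rep(list(0:1), nh)))
    colnames(cfg) <- NULL
    return(cfg)
  }
  Hp <- hd[1] %/% pool; Wp <- hd[2] %/% pool
  if (Hp * pool != hd[1] || Wp * pool != hd[2])
    stop("enumeration requires pool to divide the hidden grid")
  # block membership of each unit, in array order
  blk <- block_membership(hd, pool)
  n_blocks <- max(blk)
  per_block <- split(seq_len(nh), blk)
  states <- lapply(per_block, function(units) c(list(integer(0)), as.list(units)))
  grid <- expand.grid(states, KEEP.OUT.ATTRS = FALSE)
  cfg <- matrix(0L, nrow = nrow(grid), ncol = nh)
  for (r in seq_len(nrow(grid))) {
    on <- unlist(grid[r, ])
    if (length(on)) cfg[r, on] <- 1L
  }
  cfg
}

block_membership <- function(hd, pool) {
  Hp <- hd[1] %/% pool; Wp <- hd[2] %/% pool
  blk <- integer(prod(hd))
  t <- 0L
  for (k in seq_len(hd[3])) for (j in seq_len(hd[2])) for (i in seq_len(hd[1])) {
    t <- t + 1L
    bi <- (i - 1L) %/% pool; bj <- (j - 1L) %/% pool
    blk[t] <- 1L + bi + bj * Hp + (k - 1L) * Hp * Wp
  }
  blk
}

#' Exact spike conditional by enumeration
#'
#' Integrates the slab units out of exp(-E) analytically for fixed `v` and
#' sums over all admissible spike configurations. Independent of the
#' closed-form logistic/softmax inference rules.
#' @param v visible array `[3, 3, 1]` (any small map works)
#' @param params tiny [csscrbm_params()]
#' @return list(configs, probs, marginal) where `marginal` is the array of
#'   per-unit activation probabilities p(h_ij = 1 | v)
#' @export
enumerate_spike_conditional <- function(v, params) {
  pre <- spike_preactivation(v, params)
  z <- as.vector(pre$z)
  cfg <- enumerate_h_configs(dim(pre$z), params$pool)
  logw <- as.vector(cfg %*% z)
  logw <- logw - max(logw)
  p <- exp(logw) / sum(exp(logw))
  marg <- as.vector(t(cfg) %*% p)
  list(configs = cfg, probs = p,
       marginal = array(marg, dim = dim(pre$z)))
}

# patch-position matrix: row for hidden unit (i,j,k), giving linear visible
# indices and kernel values so that (M %*% v_vec) = conv responses
conv_matrix <- function(params, vdim) {
  hd <- hidden_dim(params, vdim)
  if (params$pad != 0L) stop("oracle supports pad = 0 only")
  if (vdim[3] != 1L) stop("oracle supports a single visible channel")
  dw <- dim(params$w)
  nv <- vdim[1] * vdim[2]
  nh <- prod(hd)
  M <- matrix(0, nrow = nh, ncol = nv)
  t <- 0L
  for (k in seq_len(hd[3])) for (j in seq_len(hd[2])) for (i in seq_len(hd[1])) {
    t <- t + 1L
    for (s in seq_len(dw[2])) for (r in seq_len(dw[1])) {
      pos <- (i + r - 1L) + (j + s - 2L) * vdim[1]
      M[t, pos] <- M[t, pos] + params$w[r, s, 1, k]
    }
  }
  M
}

# exact joint treatment of one spike configuration: p(v, s | h) is Gaussian
# with precision P = [[I/sigma^2, -M' diag(h)], [-diag(h) M, A]] and linear
# term l = (c/sigma^2, 0)
config_gaussian <- function(h_vec, M, A_diag, params, vdim) {
  nv <- ncol(M); nh <- nrow(M)
  P <- matrix(0, nv + nh, nv + nh)
  P[seq_len(nv), seq_len(nv)] <- diag(nv) / params$sigma^2
  Mh <- M * h_vec
  P[nv + seq_len(nh), seq_len(nv)] <- -Mh
  P[seq_len(nv), nv + seq_len(nh)] <- -t(Mh)
  P[nv + seq_len(nh), nv + seq_len(nh)] <- diag(A_diag, nh)
  l <- c(rep(params$c[1] / params$sigma^2, nv), rep(0, nh))
  ch <- tryCatch(chol(P), error = function(e) NULL)
  if (is.null(ch)) stop("configuration precision not positive definite")
  Sigma <- chol2inv(ch)
  mu <- Sigma %*% l
  logdet <- 2 * sum(log(diag(ch)))
  # log of the h-dependent part of the marginal weight
  b_full <- rep(params$b, each = nh / length(params$b))
  logw <- sum(b_full * h_vec) - 0.5 * logdet + 0.5 * sum(l * mu)
  list(mu = as.vector(mu), Sigma = Sigma, logw = logw, nv = nv, nh = nh)
}

#' Exact marginal p(h) of a tiny CssCRBM by enumeration
#'
#' Integrates (v, s) jointly (Gaussian given h) for every admissible spike
#' configuration.
#' @return list(configs, probs, marginal)
#' @export
enumerate_spike_marginal <- function(params, vdim = c(3L, 3L, 1L)) {
  hd <- hidden_dim(params, vdim)
  cfg <- enumerate_h_configs(hd, params$pool)
  M <- conv_matrix(params, vdim)
  A_diag <- as.vector(a_broadcast(params, hd))
  logw <- apply(cfg, 1, function(h)
    config_gaussian(h, M, A_diag, params, vdim)$logw)
  logw <- logw - max(logw)
  p <- exp(logw) / sum(exp(logw))
  list(configs = cfg, probs = p,
       marginal = array(as.vector(t(cfg) %*% p), dim = hd))
}

#' Exact log-likelihood gradient for a tiny CssCRBM
#'
#' Returns the gradient of the negative log-likelihood of `v` with respect to
#' (w, b, c, a): the difference between the data-phase and model-phase
#' expectations of the energy gradient, both computed exactly (enumeration
#' over spike configurations; slab and visible units handled analytically).
#' @param v visible array (single channel, no padding)
#' @param params tiny [csscrbm_params()]
#' @return list(dw, db, dc, da) matching the parameter shapes (`da` per map)
#' @export
exact_nll_grad <- function(v, params) {
  vdim <- dim(v)
  hd <- hidden_dim(params, vdim)
  nh <- prod(hd); nv <- vdim[1] * vdim[2]
  K <- hd[3]; per_map <- hd[1] * hd[2]
  map_of <- rep(seq_len(K), each = per_map)
  M <- conv_matrix(params, vdim)
  A_diag <- as.vector(a_broadcast(params, hd))

  # --- data phase: expectations given v (enumeration over h, Gaussian s)
  cond <- enumerate_spike_conditional(v, params)
  pre <- spike_preactivation(v, params)
  Cv <- as.vector(pre$C)
  ph <- as.vector(cond$marginal)
  Ehs <- ph * Cv / A_diag                       # E[h s] given v
  dat_dw <- grad_w_from_stats(v, array(Ehs, dim = hd), params)
  dat_db <- -tapply(ph, map_of, sum)
  dat_dc <- -sum(v - params$c[1]) / params$sigma^2
  Es2 <- 1 / A_diag + ph * Cv^2 / A_diag^2      # E[s^2] given v
  dat_da <- 0.5 * tapply(Es2, map_of, sum)

  # --- model phase: expectations under the joint model
  cfg <- enumerate_h_configs(hd, params$pool)
  gs <- apply(cfg, 1, function(h)
    config_gaussian(h, M, A_diag, params, vdim), simplify = FALSE)
  logw <- vapply(gs, function(g) g$logw, 0)
  logw <- logw - max(logw)
  pcfg <- exp(logw) / sum(exp(logw))

  mod_dw <- array(0, dim = dim(params$w))
  mod_db <- rep(0, K)
  mod_dc <- 0
  mod_da <- rep(0, K)
  dw <- dim(params$w)
  for (r in seq_along(gs)) {
    g <- gs[[r]]; h <- cfg[r, ]
    mu_v <- g$mu[seq_len(nv)]; mu_s <- g$mu[nv + seq_len(nh)]
    # E[v_pos s_ij] = Sigma[pos, nv+ij] + mu_v mu_s
    for (t in which(h == 1)) {
      k <- map_of[t]
      within <- t - (k - 1L) * per_map
      i <- (within - 1L) %% hd[1] + 1L
      j <- (within - 1L) %/% hd[1] + 1L
      for (s2 in seq_len(dw[2])) for (r2 in seq_len(dw[1])) {
        pos <- (i + r2 - 1L) + (j + s2 - 2L) * vdim[1]
        Evs <- g$Sigma[pos, nv + t] + mu_v[pos] * mu_s[t]
        mod_dw[r2, s2, 1, k] <- mod_dw[r2, s2, 1, k] - pcfg[r] * Evs
      }
    }
    mod_db <- mod_db - pcfg[r] * tapply(h, map_of, sum)
    mod_dc <- mod_dc - pcfg[r] * (sum(mu_v) - nv * params$c[1]) / params$sigma^2
    Es2m <- diag(g$Sigma)[nv + seq_len(nh)] + mu_s^2
    mod_da <- mod_da + pcfg[r] * 0.5 * tapply(Es2m, map_of, sum)
  }
  list(dw = dat_dw - mod_dw,
       db = unname(as.numeric(dat_db) - mod_db),
       dc = unname(dat_dc - mod_dc),
       da = unname(as.numeric(dat_da) - mod_da))
}

# dE/dw as the (negative) correlation of v with a hidden-sized map g:
# dE/dw[r,s,l,k] = - sum_ij v[i+r-1, j+s-1, l] g[i,j,k]
grad_w_from_stats <- function(v, g, params) {
  -conv_backward(v, params$w, g, pad = params$pad, need_dv = FALSE)$dw
}
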