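# Contrastive-divergence training of a CssCRBM with a contractive penalty.
#
# CD-k alternates Gibbs sweeps v -> (h, s) -> v using the pooled conditionals,
# and estimates the likelihood gradient as the difference between data-phase
# and model-phase expected energy gradients. The data phase and the final
# model-phase step use expected sufficient statistics (spike probabilities
# and conditional slab means) rather than raw samples, which reduces
# estimator variance; intermediate sweeps are sampled.
#
# The contractive penalty is the squared Frobenius norm of the Jacobian of
# the spike activation probabilities with respect to the visible input,
# summed over units, and is applied to the kernels only.

#' Training configuration for CD
#'
#' @param eta learning rate
#' @param lambda contractive penalty coefficient
#' @param cd_steps number of Gibbs sweeps (CD-k)
#' @param batchsize minibatch size
#' @param epochs passes over the data
#' @param seed RNG seed for shuffling and Gibbs sampling
#' @param max_w_norm per-feature-map cap on the kernel L2 norm, projected
#'   after each update. The joint density is normalizable (and the Gibbs
#'   chain stable) only while the spike-slab/visible coupling stays below
#'   the slab precision; the cap keeps training inside that region.
#'   `Inf` disables the projection.
#' @param sparsity_target optional target mean activation per feature map;
#'   when set, spike biases are nudged toward it each update (sparse-coding
#'   drive that also keeps feature maps from collapsing onto one pattern)
#' @param sparsity_cost strength of the sparsity drive
#' @export
train_config <- function(eta = 0.01, lambda = 0.01, cd_steps = 5L,
                         batchsize = 20L, epochs = 1L, seed = 1L,
                         max_w_norm = 0.3, sparsity_target = NULL,
                         sparsity_cost = 5) {
  stopifnot(eta >= 0, lambda >= 0, cd_steps >= 1L, batchsize >= 1L)
  list(eta = eta, lambda = lambda, cd_steps = as.integer(cd_steps),
       batchsize = as.integer(batchsize), epochs = as.integer(epochs),
       seed = as.integer(seed), max_w_norm = max_w_norm,
       sparsity_target = sparsity_target, sparsity_cost = sparsity_cost)
}

# expected sufficient statistics of the energy gradient given v:
# list(dw, db, dc, da) of E[dE/dtheta | v] under the pooled conditionals
expected_energy_stats <- function(v, params) {
  ps <- pooled_spike_given_v(v, params)
  hd <- dim(ps$z)
  pool <- params$pool
  # activation probabilities on the full grid; remainder units are never
  # active under floor-division pooling
  if (pool == 1L) {
    p <- ps$p_unit
  } else {
    p <- array(0, dim = hd)
    p[seq_len(ps$Hp * pool), seq_len(ps$Wp * pool), ] <- ps$p_unit
  }
  C <- ps$C; a <- ps$a
  Ehs <- p * C / a
  dw <- grad_w_from_stats(v, Ehs, params)
  db <- -map_sums(p)
  dc <- -(map_sums(v) - params$c * dim(v)[1] * dim(v)[2]) / params$sigma^2
  Es2 <- 1 / a + p * C^2 / a^2
  da <- 0.5 * map_sums(Es2)
  list(dw = dw, db = db, dc = dc, da = da,
       pbar = -db / (hd[1] * hd[2]))
}

# one Gibbs sweep starting from v: sample (h, s), then sample v'
gibbs_sweep <- function(v, params) {
  st <- sample_pooled_state(v, params)
  vm <- visible_given_sh(st$s, st$h, params)
  v1 <- vm$mean + stats::rnorm(length(vm$mean)) * sqrt(vm$var)
  dim(v1) <- dim(vm$mean)
  v1
}

#' CD gradient estimate for one visible sample
#'
#' @param v visible array
#' @param params a [csscrbm_params()]
#' @param cd_steps number of Gibbs sweeps
#' @return list(dw, db, dc, da): estimate of the negative log-likelihood
#'   gradient (data-phase minus model-phase expected energy gradients)
#' @export
cd_gradient <- function(v, params, cd_steps = 5L) {
  dat <- expected_energy_stats(v, params)
  vk <- v
  for (k in seq_len(cd_steps)) vk <- gibbs_sweep(vk, params)
  mod <- expected_energy_stats(vk, params)
  list(dw = dat$dw - mod$dw, db = dat$db - mod$db,
       dc = dat$dc - mod$dc, da = dat$da - mod$da, v_model = vk,
       pbar = dat$pbar)
}

#' Contractive penalty of the spike activation map
#'
#' Squared Frobenius norm of the Jacobian of the spike probabilities
#' p = logistic(z), z = C^2/(2a) + b, with respect to the visible input:
#' ||J||_F^2 = sum_k ||w_k||_F^2 * sum_ij (p'(z_ij) C_ij / a)^2.
#' @return scalar penalty
#' @export
contractive_penalty <- function(v, params) {
  pre <- spike_preactivation(v, params)
  p <- logistic(pre$z)
  g <- p * (1 - p) * pre$C / pre$a
  K <- dim(pre$z)[3]
  wn <- vapply(seq_len(K), function(k) sum(params$w[, , , k]^2), 0)
  g2 <- apply(g^2, 3, sum)
  sum(wn * g2)
}

#' Gradient of the contractive penalty with respect to the kernels
#'
#' Analytic gradient of [contractive_penalty()]; the penalty is applied to
#' the kernels only.
#' @return list(dw) matching the kernel shape
#' @export
contractive_grad <- function(v, params) {
  pre <- spike_preactivation(v, params)
  p <- logistic(pre$z)
  sp <- p * (1 - p)            # sigma'
  spp <- sp * (1 - 2 * p)      # sigma''
  C <- pre$C; a <- pre$a
  g <- sp * C / a
  K <- dim(C)[3]
  wn <- vapply(seq_len(K), function(k) sum(params$w[, , , k]^2), 0)
  g2sum <- apply(g^2, 3, sum)
  # term 1: 2 w_k * sum_ij g^2
  dw <- params$w
  for (k in seq_len(K)) dw[, , , k] <- 2 * params$w[, , , k] * g2sum[k]
  # term 2: ||w_k||^2 * corr(v, 2 g (sigma'' C^2/a^2 + sigma'/a))
  G <- 2 * g * (spp * C^2 / a^2 + sp / a)
  for (k in seq_len(K)) G[, , k] <- G[, , k] * wn[k]
  dw2 <- conv_backward(v, params$w, G, pad = params$pad, need_dv = FALSE)$dw
  list(dw = dw + dw2)
}

#' One CD parameter update on a minibatch
#'
#' Averages the CD gradient over the batch, adds `lambda` times the
#' contractive-penalty gradient (kernels only), and applies
#' theta <- theta - eta * (grad_cd + lambda * grad_contractive).
#' The slab penalty `a` is updated in log-space to preserve positivity;
#' `sigma` is fixed.
#' @param batch list of visible arrays, or a 4-d array `[H, W, L, N]`
#' @param params a [csscrbm_params()]
#' @param config a [train_config()]
#' @param seed optional seed for the Gibbs chains
#' @return updated [csscrbm_params()]
#' @export
cd_update <- function(batch, params, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.array(batch) && length(dim(batch)) == 4L)
    batch <- lapply(seq_len(dim(batch)[4]), function(i) batch[, , , i, drop = FALSE][, , , 1])
  n <- length(batch)
  if (n == 0L) stop("empty batch")
  acc <- NULL
  for (v in batch) {
    if (length(dim(v)) != 3L) stop("batch elements must be [H, W, L] arrays")
    g <- cd_gradient(v, params, config$cd_steps)
    if (config$lambda > 0) {
      cg <- contractive_grad(v, params)
      g$dw <- g$dw + config$lambda * cg$dw
    }
    if (is.null(acc)) acc <- g else {
      acc$dw <- acc$dw + g$dw; acc$db <- acc$db + g$db
      acc$dc <- acc$dc + g$dc; acc$da <- acc$da + g$da
      acc$pbar <- acc$pbar + g$pbar
    }
  }
  # per-unit gradient normalization: each parameter's gradient is summed
  # over its contributing units (hidden positions for w, b, a; visible
  # pixels for c), so divide by those counts to keep the step size
  # comparable across parameters and input sizes
  hd <- hidden_dim(params, dim(batch[[1]]))
  n_hid <- hd[1] * hd[2]
  n_vis <- dim(batch[[1]])[1] * dim(batch[[1]])[2]
  eta <- config$eta / n
  w <- params$w - (eta / n_hid) * acc$dw
  b <- params$b - (eta / n_hid) * acc$db
  # sparsity drive: pull each map's mean data-phase activation toward the
  # target (keeps feature maps from collapsing onto one pattern)
  if (!is.null(config$sparsity_target))
    b <- b - config$eta * config$sparsity_cost *
      (acc$pbar / n - config$sparsity_target)
  cbias <- params$c - (eta / n_vis) * acc$dc
  log_a <- log(params$a) - (eta / n_hid) * (acc$da * params$a)
  a <- exp(log_a)
  # stability projection: cap each feature map's kernel norm
  if (is.finite(config$max_w_norm) && config$eta > 0) {
    K <- dim(w)[4]
    for (k in seq_len(K)) {
      nrm <- sqrt(sum(w[, , , k]^2))
      if (nrm > config$max_w_norm)
        w[, , , k] <- w[, , , k] * (config$max_w_norm / nrm)
    }
  }
  if (any(!is.finite(w)) || any(!is.finite(b)) || any(!is.finite(cbias)) ||
      any(!is.finite(a)))
    stop("divergent parameters after CD update (non-finite values)")
  out <- params
  out$w <- w; out$b <- b; out$c <- cbias; out$a <- a
  out
}

#' Train a CssCRBM by CD-k over several epochs
#'
#' @param data list of visible arrays (or 4-d array `[H, W, L, N]`)
#' @param params initial [csscrbm_params()]
#' @param config a [train_config()]
#' @param verbose print per-epoch mean reconstruction error
#' @return list(params, history) where history is a data.frame with one row
#'   per epoch (mean squared one-step reconstruction error)
#' @export
train_csscrbm <- function(data, params, config, verbose = FALSE) {
  if (is.array(data) && length(dim(data)) == 4L)
    data <- lapply(seq_len(dim(data)[4]), function(i) data[, , , i, drop = FALSE][, , , 1])
  n <- length(data)
  if (n == 0L) stop("empty training set")
  set.seed(config$seed)
  hist <- data.frame(epoch = integer(0), recon_mse = numeric(0))
  if (config$epochs == 0L) return(list(params = params, history = hist))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    nb <- max(1L, n %/% config$batchsize)
    err <- 0
    for (jb in seq_len(nb)) {
      idx <- ord[((jb - 1L) * config$batchsize + 1L):min(jb * config$batchsize, n)]
      params <- cd_update(data[idx], params, config)
    }
    # one-step reconstruction error on a fixed subset
    sub <- data[seq_len(min(32L, n))]
    err <- mean(vapply(sub, function(v) {
      st <- sample_pooled_state(v, params)
      vm <- visible_given_sh(st$s, st$h, params)
      mean((vm$mean - v)^2)
    }, 0))
    hist <- rbind(hist, data.frame(epoch = ep, recon_mse = err))
    if (verbose) message(sprintf("epoch %d: recon MSE %.5f", ep, err))
  }
  list(params = params, history = hist)
}
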