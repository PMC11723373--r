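# Stacking CssCRBMs into a deep belief network: greedy layer-wise
# pretraining and the deterministic fine-tuning forward pass.
#
# After pretraining, the stack is treated as a special CNN: spike maps come
# from relu(z) with z = (1/(2a)) C^2 + b (replacing the logistic), slab maps
# from s = (C h + noise)/a, and the hybrid map h*s is max-pooled per block.
# The additive noise is included only in training mode.

#' Stack configuration
#'
#' One entry per layer (bottom to top): number of kernels `K`, kernel side
#' `k`, zero-padding `pad`, pooling block side `pool`, and the per-layer
#' contractive-penalty coefficient `lambda`.
#' @param layers list of lists with elements `K`, `k`, `pad`, `pool`,
#'   `lambda`
#' @export
stack_config <- function(layers) {
  for (ly in layers)
    stopifnot(all(c("K", "k", "pad", "pool") %in% names(ly)))
  structure(list(layers = layers), class = "stack_config")
}

#' Default 4-layer stack configuration
#'
#' 36, 64, 128, 128 kernels of size 3x3 with 2x2 pooling throughout; no
#' padding in the first layer, padding 1 afterwards. On 3x64x64 input the
#' spatial sizes after pooling are 31, 15, 7, 3. Contractive coefficients
#' are 0.1, 0.1, 0.2, 0.2 from the first to the fourth layer.
#' @export
default_stack_config <- function() {
  stack_config(list(
    list(K = 36L, k = 3L, pad = 0L, pool = 2L, lambda = 0.1),
    list(K = 64L, k = 3L, pad = 1L, pool = 2L, lambda = 0.1),
    list(K = 128L, k = 3L, pad = 1L, pool = 2L, lambda = 0.2),
    list(K = 128L, k = 3L, pad = 1L, pool = 2L, lambda = 0.2)))
}

#' Shape chain of a stack configuration
#'
#' @param cfg a [stack_config()]
#' @param input_dim input array dimensions `[H, W, L]`
#' @return data.frame with per-layer input channels and spatial sizes after
#'   convolution and after pooling
#' @export
stack_shapes <- function(cfg, input_dim = c(64L, 64L, 3L)) {
  H <- input_dim[1]; W <- input_dim[2]; L <- input_dim[3]
  out <- NULL
  for (i in seq_along(cfg$layers)) {
    ly <- cfg$layers[[i]]
    Hh <- H + 2L * ly$pad - ly$k + 1L
    Wh <- W + 2L * ly$pad - ly$k + 1L
    if (Hh < 1L || Wh < 1L)
      stop(sprintf("layer %d: kernel larger than its input (%dx%d)", i, H, W))
    Hp <- Hh %/% ly$pool; Wp <- Wh %/% ly$pool
    out <- rbind(out, data.frame(layer = i, in_channels = L, K = ly$K,
                                 conv_h = Hh, conv_w = Wh,
                                 pooled_h = Hp, pooled_w = Wp))
    H <- Hp; W <- Wp; L <- ly$K
  }
  out
}

#' Initialize all layers of a stack
#' @param init `"cd"` (generative pretraining start) or `"finetune"`
#'   (active relu start for purely discriminative training)
#' @export
init_stack <- function(cfg, input_dim = c(64L, 64L, 3L), seed = 1L,
                       init = "cd") {
  shapes <- stack_shapes(cfg, input_dim)
  lapply(seq_along(cfg$layers), function(i) {
    ly <- cfg$layers[[i]]
    csscrbm_init(ly$k, ly$k, shapes$in_channels[i], ly$K, sigma = 1,
                 pool = ly$pool, pad = ly$pad, seed = sub_seed(seed, 77L, i),
                 init = init)
  })
}

#' Greedy layer-wise pretraining of a CssCDBN
#'
#' Trains the bottom CssCRBM by contrastive divergence, then feeds its
#' deterministic pooled hybrid feature maps (evaluation-mode forward) to the
#' next layer, and so on. Each layer uses its configured contractive
#' coefficient.
#' @param data list of input arrays `[H, W, L]`
#' @param cfg a [stack_config()]
#' @param train_cfg a [train_config()]; `epochs = 0` returns the initialized,
#'   untrained parameters
#' @param verbose print layer progress
#' @param scale_inputs standardize each layer's training input to unit scale
#'   before CD (the Gaussian visible units assume unit noise scale); the
#'   scale is absorbed into the layer's kernels afterwards, so the stack
#'   still operates on raw inputs
#' @param recalibrate_bias after CD, shift each feature map's spike bias so
#'   that the median spike pre-activation over the training data is zero.
#'   CD's sparse bias keeps the logistic spike probabilities low; the
#'   fine-tuning forward replaces the logistic with a relu, which would be
#'   inactive everywhere under that bias. The shift makes roughly half the
#'   relu units active without changing the learned filters.
#' @return list of trained [csscrbm_params()], bottom to top
#' @export
pretrain_stack <- function(data, cfg, train_cfg, verbose = FALSE,
                           scale_inputs = TRUE, recalibrate_bias = TRUE) {
  if (length(data) == 0L) stop("empty training set")
  input_dim <- dim(data[[1]])
  shapes <- stack_shapes(cfg, input_dim)   # errors early on a bad chain
  params <- init_stack(cfg, input_dim, seed = train_cfg$seed)
  x <- data
  for (i in seq_along(cfg$layers)) {
    ly <- cfg$layers[[i]]
    tc <- train_cfg
    if (!is.null(ly$lambda)) tc$lambda <- ly$lambda
    tc$seed <- sub_seed(train_cfg$seed, 91L, i)
    sc <- 1
    if (scale_inputs) {
      sc <- stats::sd(unlist(lapply(x[seq_len(min(64L, length(x)))],
                                    as.vector)))
      if (!is.finite(sc) || sc < 1e-12) sc <- 1
    }
    if (tc$epochs > 0L) {
      if (verbose) message(sprintf("pretraining layer %d (%d kernels)", i, ly$K))
      xs <- if (sc != 1) lapply(x, function(v) v / sc) else x
      fit <- train_csscrbm(xs, params[[i]], tc, verbose = verbose)
      params[[i]] <- fit$params
    }
    if (tc$epochs > 0L)
      params[[i]]$w <- params[[i]]$w / sc  # absorb the input scale
    if (recalibrate_bias && tc$epochs > 0L) {
      zs <- lapply(x[seq_len(min(32L, length(x)))], function(v)
        spike_preactivation(v, params[[i]])$z)
      K <- dim(zs[[1]])[3]
      med <- vapply(seq_len(K), function(k)
        stats::median(unlist(lapply(zs, function(z) z[, , k]))), 0)
      params[[i]]$b <- params[[i]]$b - med
    }
    if (i < length(cfg$layers)) {
      x <- lapply(x, function(v)
        layer_forward_det(v, params[[i]], mode = "eval")$pooled)
    }
  }
  params
}

# deterministic forward through one layer (Eqs. relu-spike / linear-slab),
# returning all intermediates needed for backpropagation
layer_forward_det <- function(v, params, mode = "eval",
                              noise_scale = "inv_a", eps = NULL) {
  pre <- spike_preactivation(v, params)
  h <- relu(pre$z)
  if (mode == "train") {
    if (is.null(eps)) eps <- array(stats::rnorm(length(h)), dim = dim(h))
    noise <- if (noise_scale == "inv_a") eps / pre$a else eps / sqrt(pre$a)
  } else {
    eps <- NULL
    noise <- 0
  }
  s <- pre$C * h / pre$a + noise
  m <- h * s
  pl <- pool_max(m, params$pool)
  list(v = v, C = pre$C, z = pre$z, a = pre$a, h = h, s = s, m = m,
       eps = eps, pool = pl, pooled = pl$p)
}

# backward through one deterministic layer: given dm on the pre-pooling
# hybrid map, return gradients for (w, b, log_a) and the input
layer_backward_det <- function(cache, params, dpooled, noise_scale = "inv_a",
                               need_dv = TRUE) {
  dm <- pool_max_backward(dpooled, cache$pool, dim(cache$m))
  C <- cache$C; a <- cache$a; h <- cache$h; s <- cache$s; z <- cache$z
  # m = h * s with s = (C h + eps)/a (eps absent in eval mode)
  ds <- dm * h
  dh <- dm * s + ds * C / a
  dC <- ds * h / a
  # ds/da: slab is (C h)/a plus eps/a (inv_a) or eps/sqrt(a) (inv_sqrt_a)
  da <- -ds * C * h / a^2
  if (!is.null(cache$eps)) {
    da <- da - ds * (if (noise_scale == "inv_a") cache$eps / a^2
                     else 0.5 * cache$eps * a^(-1.5))
  }
  # h = relu(z), z = C^2/(2a) + b
  dz <- dh * (z > 0)
  dC <- dC + dz * C / a
  da <- da - dz * C^2 / (2 * a^2)
  db <- apply(dz, 3, sum)
  bk <- conv_backward(cache$v, params$w, dC, pad = params$pad,
                      need_dv = need_dv)
  da_map <- apply(da, 3, sum)          # per-feature-map (broadcast) penalty
  list(dw = bk$dw, db = db, dlog_a = da_map * params$a, dv = bk$dv)
}

#' Deterministic fine-tuning forward pass through a stack
#'
#' Spike maps via relu of the spike pre-activation, slab maps via the linear
#' rule with additive noise in training mode only, hybrid maps as their
#' elementwise product, block-max pooling between layers.
#' @param v input array `[H, W, L]`
#' @param stack list of [csscrbm_params()]
#' @param mode `"eval"` (deterministic) or `"train"` (adds the slab noise)
#' @param noise_scale `"inv_a"` (noise sd 1/a, the model's stated fine-tuning rule) or `"inv_sqrt_a"`
#'   (noise sd 1/sqrt(a), matching the probabilistic conditional)
#' @param seed optional seed for the training-mode noise
#' @return list with per-layer intermediates (`layers`) and the final pooled
#'   hybrid map (`final`)
#' @export
forward_deterministic <- function(v, stack, mode = c("eval", "train"),
                                  noise_scale = c("inv_a", "inv_sqrt_a"), seed = NULL) {
  mode <- match.arg(mode)
  noise_scale <- match.arg(noise_scale)
  if (!is.null(seed)) set.seed(seed)
  layers <- vector("list", length(stack))
  x <- v
  for (i in seq_along(stack)) {
    layers[[i]] <- layer_forward_det(x, stack[[i]], mode = mode,
                                     noise_scale = noise_scale)
    x <- layers[[i]]$pooled
    if (any(!is.finite(x)))
      stop("non-finite activations in layer ", i)
  }
  list(layers = layers, final = x)
}
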