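# The full discriminative model: CssCDBN feature extractor plus attention
# head plus softmax classifier, with hand-derived backpropagation through
# every stage for the fine-tuning phase.

#' Construct a seizure classification model
#'
#' @param cfg a [stack_config()] (default: the 4-layer configuration)
#' @param input_dim input image dimensions `[H, W, L]`
#' @param n_classes 2 (prediction) or 4 (detection)
#' @param attention include the transformer-encoder head
#' @param norm attention-weight normalization (`"softmax"` or `"none"`)
#' @param noise_scale slab-noise scale during training mode (`"inv_a"` or
#'   `"inv_sqrt_a"`)
#' @param seed initialization seed
#' @return object of class `seizcast_model`
#' @export
seizcast_model <- function(cfg = default_stack_config(),
                           input_dim = c(64L, 64L, 3L), n_classes = 2L,
                           attention = TRUE, norm = "softmax",
                           noise_scale = "inv_a", seed = 1L) {
  shapes <- stack_shapes(cfg, input_dim)
  nl <- nrow(shapes)
  d <- shapes$K[nl]
  n_tokens <- shapes$pooled_h[nl] * shapes$pooled_w[nl]
  structure(list(
    cfg = cfg, input_dim = input_dim, n_classes = as.integer(n_classes),
    stack = init_stack(cfg, input_dim, seed = seed, init = "finetune"),
    attention = attention, norm = norm, noise_scale = noise_scale,
    d = d, n_tokens = n_tokens,
    hp = shapes$pooled_h[nl], wp = shapes$pooled_w[nl],
    attn = if (attention) init_attention_params(d, n_tokens,
                                                seed = sub_seed(seed, 5L)),
    head = init_head_params(d, n_classes)),
    class = "seizcast_model")
}

#' @export
print.seizcast_model <- function(x, ...) {
  cat(sprintf("<seizcast_model> %d-layer CssCDBN, %d tokens x %d, %d classes%s\n",
              length(x$stack), x$n_tokens, x$d, x$n_classes,
              if (x$attention) ", attention head" else ""))
  invisible(x)
}

# forward pass with full cache (single image)
model_forward <- function(model, v, mode = "eval") {
  fs <- forward_deterministic(v, model$stack, mode = mode,
                              noise_scale = model$noise_scale)
  if (model$attention) {
    T0 <- tokenize(fs$final, model$attn$pos)
    enc <- encoder_forward(T0, model$attn, model$norm)
    Tn <- enc$T2
  } else {
    T0 <- tokenize(fs$final)
    enc <- NULL
    Tn <- T0
  }
  fbar <- colMeans(Tn)
  logits <- as.vector(fbar %*% model$head$Wc) + model$head$bc
  e <- exp(logits - max(logits))
  probs <- e / sum(e)
  list(fs = fs, T0 = T0, enc = enc, Tn = Tn, fbar = fbar, probs = probs)
}

# backward pass: dlogits is the gradient at the logits; dfbar_extra is an
# optional additional gradient on the pooled feature (verification branch)
model_backward <- function(model, cache, dlogits, dfbar_extra = NULL) {
  n <- nrow(cache$Tn)
  gh <- list(Wc = outer(cache$fbar, dlogits), bc = dlogits)
  dfbar <- as.vector(model$head$Wc %*% dlogits)
  if (!is.null(dfbar_extra)) dfbar <- dfbar + dfbar_extra
  dTn <- matrix(dfbar, n, length(dfbar), byrow = TRUE) / n
  ga <- NULL
  if (model$attention) {
    eb <- encoder_backward(dTn, cache$enc, model$attn)
    dT0 <- eb$dT0
    ga <- eb$grads
    ga$pos <- dT0
  } else {
    dT0 <- dTn
  }
  dfinal <- untokenize(dT0, model$hp, model$wp)
  gs <- vector("list", length(model$stack))
  dpooled <- dfinal
  for (i in rev(seq_along(model$stack))) {
    lb <- layer_backward_det(cache$fs$layers[[i]], model$stack[[i]], dpooled,
                             noise_scale = model$noise_scale,
                             need_dv = i > 1L)
    gs[[i]] <- list(w = lb$dw, b = lb$db, log_a = lb$dlog_a)
    dpooled <- lb$dv
  }
  list(stack = gs, attn = ga, head = gh)
}

#' Class probabilities for a batch of spectral images
#'
#' @param object a [seizcast_model()]
#' @param pixels array `[H, W, 3, N]` (or a [spectral_dataset()])
#' @param ... unused
#' @return matrix `[N, n_classes]` of probabilities
#' @export
predict.seizcast_model <- function(object, pixels, ...) {
  if (inherits(pixels, "spectral_dataset")) pixels <- pixels$pixels
  if (length(dim(pixels)) == 3L) dim(pixels) <- c(dim(pixels), 1L)
  N <- dim(pixels)[4]
  out <- matrix(0, N, object$n_classes)
  for (i in seq_len(N))
    out[i, ] <- model_forward(object, pixels[, , , i], mode = "eval")$probs
  out
}

# ---- flat parameter access for the optimizer ------------------------------

model_param_list <- function(model) {
  out <- list()
  for (i in seq_along(model$stack)) {
    out[[paste0("stack", i, ".w")]] <- model$stack[[i]]$w
    out[[paste0("stack", i, ".b")]] <- model$stack[[i]]$b
    out[[paste0("stack", i, ".log_a")]] <- log(model$stack[[i]]$a)
  }
  if (model$attention)
    for (nm in names(model$attn))
      out[[paste0("attn.", nm)]] <- model$attn[[nm]]
  out[["head.Wc"]] <- model$head$Wc
  out[["head.bc"]] <- model$head$bc
  out
}

model_set_params <- function(model, plist) {
  for (i in seq_along(model$stack)) {
    model$stack[[i]]$w <- plist[[paste0("stack", i, ".w")]]
    model$stack[[i]]$b <- plist[[paste0("stack", i, ".b")]]
    model$stack[[i]]$a <- exp(plist[[paste0("stack", i, ".log_a")]])
  }
  if (model$attention)
    for (nm in names(model$attn))
      model$attn[[nm]] <- plist[[paste0("attn.", nm)]]
  model$head$Wc <- plist[["head.Wc"]]
  model$head$bc <- plist[["head.bc"]]
  model
}

grads_to_list <- function(model, g) {
  out <- list()
  for (i in seq_along(g$stack)) {
    out[[paste0("stack", i, ".w")]] <- g$stack[[i]]$w
    out[[paste0("stack", i, ".b")]] <- g$stack[[i]]$b
    out[[paste0("stack", i, ".log_a")]] <- g$stack[[i]]$log_a
  }
  if (model$attention)
    for (nm in names(g$attn))
      out[[paste0("attn.", nm)]] <- g$attn[[nm]]
  out[["head.Wc"]] <- g$head$Wc
  out[["head.bc"]] <- g$head$bc
  out
}

add_grad_lists <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}
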