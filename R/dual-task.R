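# Dual-task fine-tuning: classification (cross-entropy) plus Siamese
# verification (contrastive loss with margin), optimized jointly with Adam.
#
# Each minibatch is split into two halves; images are paired by index and a
# verification label marks whether the pair shares a class. Both Siamese
# branches are the same network (shared weights), so each image contributes
# its classification loss and its pair contributes c_ver times the
# verification loss.

#' Classification loss (cross-entropy)
#'
#' Binary cross-entropy for a probability vector, or its categorical
#' generalization when `y_hat` is a probability matrix (reducing exactly to
#' the binary form at 2 classes). Probabilities at 0 or 1 are clamped at
#' 1e-12 with a warning.
#' @param y_true integer labels (0/1 for the binary form; 0-based class
#'   indices for the categorical form)
#' @param y_hat numeric vector of positive-class probabilities, or matrix
#'   `[N, n_classes]`
#' @return mean loss (scalar)
#' @export
main_loss <- function(y_true, y_hat) {
  clamp <- function(p) {
    if (any(p <= 0 | p >= 1)) {
      warning("probabilities clamped away from {0, 1}")
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    }
    p
  }
  if (is.matrix(y_hat)) {
    if (length(y_true) != nrow(y_hat)) stop("length mismatch")
    p <- clamp(y_hat[cbind(seq_len(nrow(y_hat)), y_true + 1L)])
    return(mean(-log(p)))
  }
  if (length(y_true) != length(y_hat)) stop("length mismatch")
  y_hat <- clamp(y_hat)
  mean(-y_true * log(y_hat) - (1 - y_true) * log(1 - y_hat))
}

#' Euclidean distance between feature vectors
#' @export
feature_distance <- function(f1, f2) {
  if (length(f1) != length(f2)) stop("feature length mismatch")
  sqrt(sum((f1 - f2)^2))
}

#' Contrastive verification loss
#'
#' Same-class pairs (`y_ver = 1`) pay half the squared distance; different-
#' class pairs pay half the squared hinge `max(0, delta - D)^2`, zero once
#' the features are at least `delta` apart.
#' @param f1,f2 feature vectors
#' @param y_ver 1 = same class, 0 = different
#' @param delta margin (> 0)
#' @export
verification_loss <- function(f1, f2, y_ver, delta = 1) {
  stopifnot(delta > 0, y_ver %in% c(0, 1))
  D <- feature_distance(f1, f2)
  if (y_ver == 1) 0.5 * D^2 else 0.5 * max(0, delta - D)^2
}

# gradient of the verification loss with respect to f1 (negate for f2)
verification_grad <- function(f1, f2, y_ver, delta = 1) {
  diff <- f1 - f2
  D <- sqrt(sum(diff^2))
  if (y_ver == 1) return(diff)
  if (D >= delta || D < 1e-12) return(0 * diff)
  -(delta - D) * diff / D
}

#' Combined dual-task loss over a batch of pairs
#'
#' Mean over pairs of both members' classification losses plus `c_ver`
#' times the pair's verification loss.
#' @param y1,y2 labels of the two pair members (0-based)
#' @param p1,p2 probability matrices `[n_pairs, n_classes]`
#' @param f1,f2 feature matrices `[n_pairs, d]`
#' @param y_ver verification labels
#' @param c_ver verification weight
#' @param delta margin
#' @export
total_loss <- function(y1, y2, p1, p2, f1, f2, y_ver, c_ver = 0.11,
                       delta = 1) {
  n <- length(y_ver)
  lm <- vapply(seq_len(n), function(i)
    main_loss(y1[i], p1[i, , drop = FALSE]) +
    main_loss(y2[i], p2[i, , drop = FALSE]), 0)
  lv <- vapply(seq_len(n), function(i)
    verification_loss(f1[i, ], f2[i, ], y_ver[i], delta), 0)
  mean(lm + c_ver * lv)
}

#' Split a batch into Siamese verification pairs
#'
#' Shuffles the batch (seeded), splits it into two equal groups and pairs
#' them by index; the verification label is 1 when the two labels agree.
#' @param labels integer label vector (even length)
#' @param seed RNG seed
#' @return data.frame with columns `i`, `j`, `y_ver`
#' @export
make_pairs <- function(labels, seed = NULL) {
  n <- length(labels)
  if (n %% 2L != 0L) stop("batch size must be even for pairing")
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(n)
  i <- ord[seq_len(n / 2)]
  j <- ord[n / 2 + seq_len(n / 2)]
  data.frame(i = i, j = j, y_ver = as.integer(labels[i] == labels[j]))
}

#' Fine-tuning configuration
#'
#' @param eta Adam learning rate
#' @param epochs training epochs (0 = no-op)
#' @param batchsize images per minibatch (even; paired in halves)
#' @param c_ver verification-loss weight
#' @param delta contrastive margin on unit-normalized features
#' @param seed RNG seed
#' @param beta1,beta2,adam_eps Adam moment parameters
#' @param mode forward pass used during optimization: `"eval"` (the default;
#'   the same deterministic pass used at prediction time) or `"train"`
#'   (adds the slab noise term to every pass, making the forward stochastic)
#' @export
finetune_config <- function(eta = 0.01, epochs = 10L, batchsize = 20L,
                            c_ver = 0.11, delta = 1, seed = 1L,
                            beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                            mode = c("eval", "train")) {
  stopifnot(c_ver >= 0, delta > 0, batchsize %% 2L == 0L)
  mode <- match.arg(mode)
  list(eta = eta, epochs = as.integer(epochs), batchsize = as.integer(batchsize),
       c_ver = c_ver, delta = delta, seed = as.integer(seed),
       beta1 = beta1, beta2 = beta2, adam_eps = adam_eps, mode = mode)
}

# l2-normalize a feature vector, with the Jacobian-vector product helper
l2n <- function(f) {
  r <- sqrt(sum(f^2))
  if (r < 1e-8) list(fn = f * 0, r = 1e-8, f = f)
  else list(fn = f / r, r = r, f = f)
}

l2n_backward <- function(dfn, cache) {
  (dfn - cache$fn * sum(dfn * cache$fn)) / cache$r
}

#' Fine-tune a model with the dual-task objective
#'
#' Siamese weight-shared forward through the stack and attention head;
#' per-batch gradient combines classification cross-entropy and `c_ver`
#' times the contrastive verification loss (on the L2-normalized pooled
#' token representation), applied with Adam.
#' @param model a [seizcast_model()] (typically with a pretrained stack)
#' @param pixels array `[H, W, 3, N]`
#' @param labels integer labels (0-based)
#' @param config a [finetune_config()]
#' @param verbose print per-epoch losses
#' @return list(model, history); history has per-epoch mean losses and
#'   training accuracy
#' @export
finetune <- function(model, pixels, labels, config = finetune_config(),
                     verbose = FALSE) {
  if (inherits(pixels, "spectral_dataset")) {
    labels <- pixels$meta$y
    pixels <- pixels$pixels
  }
  N <- dim(pixels)[4]
  stopifnot(length(labels) == N)
  hist <- data.frame(epoch = integer(0), loss_main = numeric(0),
                     loss_ver = numeric(0), total = numeric(0),
                     accuracy = numeric(0))
  if (config$epochs == 0L) return(list(model = model, history = hist))
  set.seed(config$seed)
  plist <- model_param_list(model)
  m1 <- lapply(plist, function(p) p * 0)
  m2 <- m1
  tstep <- 0L
  last_good <- model
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(N)
    bs <- config$batchsize
    nb <- N %/% bs
    ep_main <- 0; ep_ver <- 0; ep_correct <- 0; ep_n <- 0
    for (jb in seq_len(nb)) {
      idx <- ord[(jb - 1L) * bs + seq_len(bs)]
      pairs <- make_pairs(labels[idx])
      gacc <- NULL
      bl_main <- 0; bl_ver <- 0
      np <- nrow(pairs)
      for (r in seq_len(np)) {
        ia <- idx[pairs$i[r]]; ib <- idx[pairs$j[r]]
        ca <- model_forward(model, pixels[, , , ia], mode = config$mode)
        cb <- model_forward(model, pixels[, , , ib], mode = config$mode)
        na <- l2n(ca$fbar); nb2 <- l2n(cb$fbar)
        yv <- pairs$y_ver[r]
        bl_main <- bl_main - log(max(ca$probs[labels[ia] + 1L], 1e-12)) -
          log(max(cb$probs[labels[ib] + 1L], 1e-12))
        bl_ver <- bl_ver + verification_loss(na$fn, nb2$fn, yv, config$delta)
        ep_correct <- ep_correct + (which.max(ca$probs) - 1L == labels[ia]) +
          (which.max(cb$probs) - 1L == labels[ib])
        ep_n <- ep_n + 2L
        # gradients (mean over pairs)
        one_a <- rep(0, model$n_classes); one_a[labels[ia] + 1L] <- 1
        one_b <- rep(0, model$n_classes); one_b[labels[ib] + 1L] <- 1
        dga <- verification_grad(na$fn, nb2$fn, yv, config$delta)
        dgb <- -dga
        dfa <- l2n_backward(config$c_ver * dga, na) / np
        dfb <- l2n_backward(config$c_ver * dgb, nb2) / np
        gb_a <- model_backward(model, ca, (ca$probs - one_a) / np, dfa)
        gb_b <- model_backward(model, cb, (cb$probs - one_b) / np, dfb)
        gacc <- add_grad_lists(gacc, grads_to_list(model, gb_a))
        gacc <- add_grad_lists(gacc, grads_to_list(model, gb_b))
      }
      total <- bl_main / np + config$c_ver * bl_ver / np
      if (!is.finite(total)) {
        warning("non-finite loss; stopping at last good checkpoint")
        return(list(model = last_good, history = hist))
      }
      # Adam step
      tstep <- tstep + 1L
      for (nm in names(plist)) {
        g <- gacc[[nm]]
        m1[[nm]] <- config$beta1 * m1[[nm]] + (1 - config$beta1) * g
        m2[[nm]] <- config$beta2 * m2[[nm]] + (1 - config$beta2) * g^2
        mh <- m1[[nm]] / (1 - config$beta1^tstep)
        vh <- m2[[nm]] / (1 - config$beta2^tstep)
        plist[[nm]] <- plist[[nm]] - config$eta * mh / (sqrt(vh) + config$adam_eps)
      }
      model <- model_set_params(model, plist)
      ep_main <- ep_main + bl_main / np
      ep_ver <- ep_ver + bl_ver / np
    }
    last_good <- model
    hist <- rbind(hist, data.frame(
      epoch = ep, loss_main = ep_main / nb, loss_ver = ep_ver / nb,
      total = (ep_main + config$c_ver * ep_ver) / nb,
      accuracy = ep_correct / ep_n))
    if (verbose)
      message(sprintf("epoch %d: main %.4f ver %.4f acc %.3f", ep,
                      ep_main / nb, ep_ver / nb, ep_correct / ep_n))
  }
  list(model = model, history = hist)
}
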