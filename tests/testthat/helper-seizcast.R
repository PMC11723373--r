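# Shared fixtures: all built in code at test time.

# two orthogonal 3x3 edge filters and images composed from sparse
# activations of both, used for the filter-recovery checks
make_filter_pair <- function() {
  f1 <- matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3)
  f1 <- f1 / sqrt(sum(f1^2))
  list(f1 = f1, f2 = t(f1))
}

# each image carries sparse activations of one of the two filters
# (alternating), at amplitudes well above the noise floor
gen_filter_images <- function(n, seed, size = 12L, density = 0.06,
                              amp = c(3, 6), noise_sd = 0.05) {
  set.seed(seed)
  fp <- make_filter_pair()
  hs <- size - 2L
  imgs <- lapply(seq_len(n), function(i) {
    img <- matrix(0, size, size)
    f <- list(fp$f1, fp$f2)[[1L + (i %% 2L)]]
    sp <- matrix(stats::rbinom(hs * hs, 1, density) *
                   stats::runif(hs * hs, amp[1], amp[2]), hs, hs)
    for (ii in seq_len(hs)) for (jj in seq_len(hs)) if (sp[ii, jj] > 0)
      img[ii:(ii + 2), jj:(jj + 2)] <-
        img[ii:(ii + 2), jj:(jj + 2)] + sp[ii, jj] * f
    array(img + matrix(stats::rnorm(size * size, sd = noise_sd), size, size),
          dim = c(size, size, 1))
  })
  c(fp, list(imgs = imgs))
}

# best absolute cosine similarity between each reference filter and the
# closest learned kernel
best_abs_cosine <- function(w, filters) {
  K <- dim(w)[4]
  vapply(filters, function(f) {
    max(vapply(seq_len(K), function(k) {
      wk <- as.vector(w[, , 1, k])
      abs(sum(wk * as.vector(f))) / sqrt(sum(wk^2) * sum(f^2))
    }, 0))
  }, 0)
}

# a pure-R sinusoid segment builder (channels x samples)
sinusoid_segment <- function(freqs, fs = 256, dur_s = 2, amp = 1) {
  tt <- seq_len(fs * dur_s) / fs
  do.call(rbind, lapply(freqs, function(f) amp * sin(2 * pi * f * tt)))
}

# small random multichannel images for model-level tests
rand_images <- function(n, h = 12L, w = 12L, l = 3L, seed = 1L, sd = 1) {
  set.seed(seed)
  array(stats::rnorm(h * w * l * n, sd = sd), dim = c(h, w, l, n))
}

# tiny two-class image set that is linearly separable through band means
separable_images <- function(n_per_class, h = 12L, seed = 1L, shift = 1.2) {
  set.seed(seed)
  N <- 2L * n_per_class
  px <- array(stats::rnorm(h * h * 3L * N, sd = 0.3), dim = c(h, h, 3L, N))
  y <- rep(0:1, each = n_per_class)
  for (i in which(y == 1L)) px[, , 1, i] <- px[, , 1, i] + shift
  list(pixels = px, labels = y)
}

# exact negative log-likelihood of a tiny CssCRBM (enumeration + Gaussian
# integrals), independent of the package's gradient code
tiny_nll <- function(v, params) {
  pre <- seizcast:::spike_preactivation(v, params)
  z <- as.vector(pre$z)
  hd <- dim(pre$z)
  cfg <- seizcast:::enumerate_h_configs(hd, params$pool)
  A <- as.vector(seizcast:::a_broadcast(params, hd))
  nv <- length(v)
  lognum <- -sum((v - params$c[1])^2) / (2 * params$sigma^2) +
    log(sum(exp(cfg %*% z))) - 0.5 * sum(log(A)) -
    nv * 0 # (2 pi) constants cancel against the partition function
  M <- seizcast:::conv_matrix(params, dim(v))
  lw <- apply(cfg, 1, function(h)
    seizcast:::config_gaussian(h, M, A, params, dim(v))$logw)
  logZ <- log(sum(exp(lw - max(lw)))) + max(lw) -
    nv * params$c[1]^2 / (2 * params$sigma^2)
  -(lognum - logZ)
}
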