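test_that("energy evaluates term by term", {
  # single 1x1 interaction: E = -2 + 2 + 0.5 = 0.5
  p <- csscrbm_params(array(1, c(1, 1, 1, 1)), b = 0, c = 0, a = 1)
  st <- layer_state(v = array(2, c(1, 1, 1)), h = array(1, c(1, 1, 1)),
                    s = array(1, c(1, 1, 1)))
  expect_equal(csscrbm_energy(st, p), 0.5)
  # zero parameters and hidden state: only the quadratic visible term
  set.seed(1)
  v <- array(rnorm(18), c(3, 3, 2))
  p0 <- csscrbm_params(array(0, c(2, 2, 2, 3)), b = rep(0, 3), c = rep(0, 2),
                       a = rep(1, 3))
  z4 <- array(0, c(2, 2, 3))
  expect_equal(csscrbm_energy(layer_state(v, z4, z4), p0), sum(v^2) / 2)
  # permuting feature maps together with their parameters leaves E unchanged
  tiny <- gen_tiny_rbm(3L, K = 2L)
  pp <- tiny$params
  v1 <- tiny$v_samples[[1]]
  set.seed(2)
  h <- array(rbinom(8, 1, 0.5), c(2, 2, 2))
  s <- array(rnorm(8), c(2, 2, 2))
  e1 <- csscrbm_energy(layer_state(v1, h, s), pp)
  perm <- pp
  perm$w <- pp$w[, , , 2:1, drop = FALSE]
  perm$b <- pp$b[2:1]; perm$a <- pp$a[2:1]
  e2 <- csscrbm_energy(layer_state(v1, h[, , 2:1], s[, , 2:1]), perm)
  expect_equal(e1, e2)
  # shape mismatch names the offending tensor
  expect_error(csscrbm_energy(layer_state(v1, array(0, c(3, 3, 2)), s), pp),
               "tensor h")
})

test_that("spike conditional follows the logistic closed form", {
  p0 <- csscrbm_params(array(0, c(2, 2, 1, 1)), b = 0, c = 0, a = 1)
  v <- array(rnorm(9), c(3, 3, 1))
  expect_true(all(spike_given_v(v, p0) == 0.5))
  # 1x1 kernel w = 1, v = 2, a = 1, b = 0: z = 4/2 = 2
  p1 <- csscrbm_params(array(1, c(1, 1, 1, 1)), b = 0, c = 0, a = 1)
  pr <- spike_given_v(array(2, c(1, 1, 1)), p1)
  expect_equal(as.numeric(pr), 1 / (1 + exp(-2)), tolerance = 1e-12)
  # strictly increasing in the spike bias
  tiny <- gen_tiny_rbm(4L)
  p_lo <- tiny$params; p_hi <- tiny$params
  p_hi$b <- p_hi$b + 0.7
  expect_true(all(spike_given_v(tiny$v_samples[[1]], p_hi) >
                  spike_given_v(tiny$v_samples[[1]], p_lo)))
  bad <- tiny$params; bad$a <- -1
  expect_error(spike_given_v(tiny$v_samples[[1]], bad), "positive")
})

test_that("pooled spike conditional is a normalized block categorical", {
  # all-zero pre-activations: 2x2 block gives 1/5 per position and off-state
  p0 <- csscrbm_params(array(0, c(2, 2, 1, 1)), b = 0, c = 0, a = 1, pool = 2L)
  ps <- pooled_spike_given_v(array(0, c(3, 3, 1)), p0)
  expect_true(all(abs(ps$p_unit - 0.2) < 1e-12))
  expect_true(all(abs(ps$p_off - 0.2) < 1e-12))
  # normalization to 1e-12 on random instances
  tiny <- gen_tiny_rbm(6L, K = 2L, pool = 2L)
  ps2 <- pooled_spike_given_v(tiny$v_samples[[1]], tiny$params)
  bl <- seizcast:::block_view(ps2$p_unit, 2L)
  expect_true(all(abs(colSums(bl$m) + as.vector(ps2$p_off) - 1) < 1e-12))
  # a dominant pre-activation takes the whole block
  p1 <- csscrbm_params(array(10, c(1, 1, 1, 1)), b = 0, c = 0, a = 1, pool = 2L)
  v <- array(0, c(2, 2, 1)); v[1, 1, 1] <- 1
  ps3 <- pooled_spike_given_v(v, p1)
  expect_gt(ps3$p_unit[1, 1, 1], 1 - 1e-9)
  expect_lt(ps3$p_off[1, 1, 1], 1e-9)
})

test_that("slab conditionals are Gaussian with v-independent variance", {
  tiny <- gen_tiny_rbm(8L)
  v <- tiny$v_samples[[1]]
  pp <- tiny$params
  h0 <- array(0, c(2, 2, 1))
  sv0 <- slab_given_vh(v, h0, pp)
  expect_true(all(sv0$mean == 0))
  expect_equal(unique(as.vector(sv0$var)), 1 / pp$a)
  # direct substitution: a = 1, conv response 2, h = 1
  p1 <- csscrbm_params(array(1, c(1, 1, 1, 1)), b = 0, c = 0, a = 1)
  sv1 <- slab_given_vh(array(2, c(1, 1, 1)), array(1, c(1, 1, 1)), p1)
  expect_equal(as.numeric(sv1$mean), 2)
  expect_equal(as.numeric(sv1$var), 1)
  # pooled slab: block mean is the max of unit means
  p2 <- csscrbm_params(array(1, c(1, 1, 1, 1)), b = 0, c = 0, a = 1, pool = 2L)
  v2 <- array(c(1, 3, 2, 0), c(2, 2, 1))
  h2 <- array(1, c(2, 2, 1))
  psl <- pooled_slab_given_v(v2, h2, p2)
  expect_equal(as.numeric(psl$mean), 3)
  # all h = 0 in the block
  psl0 <- pooled_slab_given_v(v2, array(0, c(2, 2, 1)), p2)
  expect_equal(as.numeric(psl0$mean), 0)
  # block of size 1 reduces to the unpooled conditional
  p3 <- csscrbm_params(tiny$params$w, tiny$params$b, tiny$params$c,
                       tiny$params$a, pool = 1L)
  h <- array(rbinom(4, 1, 0.5), c(2, 2, 1))
  expect_equal(pooled_slab_given_v(v, h, p3)$mean,
               slab_given_vh(v, h, p3)$mean)
})

test_that("visible conditional matches the transposed convolution", {
  tiny <- gen_tiny_rbm(2L)
  pp <- tiny$params
  h0 <- array(0, c(2, 2, 1)); s0 <- array(0, c(2, 2, 1))
  vm <- visible_given_sh(s0, h0, pp)
  expect_true(all(abs(vm$mean - pp$c[1]) < 1e-12))
  expect_equal(vm$var, pp$sigma^2)
  # single active unit through a 1x1 kernel places its slab value
  p1 <- csscrbm_params(array(1, c(1, 1, 1, 1)), b = 0, c = 0, a = 1)
  vm1 <- visible_given_sh(array(3, c(1, 1, 1)), array(1, c(1, 1, 1)), p1)
  expect_equal(as.numeric(vm1$mean), 3)
  # linearity in s
  s <- array(rnorm(4), c(2, 2, 1)); h <- array(1, c(2, 2, 1))
  m1 <- visible_given_sh(s, h, pp)$mean
  m2 <- visible_given_sh(2 * s, h, pp)$mean
  expect_equal(m2 - pp$c[1], 2 * (m1 - pp$c[1]), tolerance = 1e-12)
})

test_that("closed-form conditionals equal exact enumeration", {
  for (K in 1:2) for (pool in 1:2) {
    tiny <- gen_tiny_rbm(10L + K, K = K, pool = pool)
    for (v in tiny$v_samples[1:3]) {
      en <- enumerate_spike_conditional(v, tiny$params)
      cf <- if (pool == 1L) spike_given_v(v, tiny$params)
            else pooled_spike_given_v(v, tiny$params)$p_unit
      expect_lt(max(abs(cf - en$marginal)), 1e-8)
    }
  }
})

test_that("sampled configurations respect the block constraint and match the categorical", {
  tiny <- gen_tiny_rbm(12L, K = 1L, pool = 2L)
  v <- tiny$v_samples[[1]]
  ps <- pooled_spike_given_v(v, tiny$params)
  set.seed(99)
  n <- 20000L
  counts <- numeric(5)   # 4 positions + off
  for (i in seq_len(n)) {
    st <- sample_pooled_state(v, tiny$params)
    hm <- as.vector(st$h)
    expect_lte(sum(hm), 1L)
    k <- which(hm == 1)
    counts[if (length(k)) k else 5L] <- counts[if (length(k)) k else 5L] + 1
  }
  probs <- c(as.vector(ps$p_unit), as.vector(ps$p_off))
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(counts / n - probs) < 3.5 * se + 1e-4))
  # determinism under a fixed seed
  expect_identical(sample_pooled_state(v, tiny$params, seed = 5),
                   sample_pooled_state(v, tiny$params, seed = 5))
})

test_that("long Gibbs chains reproduce the enumerated spike marginal", {
  tiny <- gen_tiny_rbm(15L, K = 1L, pool = 1L)
  pp <- tiny$params
  ex <- enumerate_spike_marginal(pp)
  set.seed(42)
  n_chain <- 400L; burn <- 60L; keep <- 40L
  acc <- numeric(4)
  total <- 0L
  for (cix in seq_len(n_chain %/% 40L)) {
    vs <- lapply(1:40, function(i) array(rnorm(9), c(3, 3, 1)))
    for (sw in seq_len(burn + keep)) {
      for (j in seq_along(vs)) {
        st <- sample_pooled_state(vs[[j]], pp)
        vm <- visible_given_sh(st$s, st$h, pp)
        vs[[j]] <- array(vm$mean + rnorm(9) * sqrt(vm$var), c(3, 3, 1))
        if (sw > burn && sw %% 8L == 0L) {
          acc <- acc + as.vector(st$h)
          total <- total + 1L
        }
      }
    }
  }
  freq <- acc / total
  marg <- as.vector(ex$marginal)
  se <- sqrt(marg * (1 - marg) / total)
  expect_true(all(abs(freq - marg) < 3.5 * se + 0.01))
})
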