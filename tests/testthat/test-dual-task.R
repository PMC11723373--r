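test_that("classification loss matches its closed forms", {
  expect_equal(main_loss(1L, 0.25), -log(0.25), tolerance = 1e-12)
  expect_equal(main_loss(c(1L, 0L), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_lt(main_loss(c(1L, 0L), c(1 - 1e-9, 1e-9)), 1e-8)
  # categorical form reduces to the binary form at two classes
  y <- c(1L, 0L, 1L)
  p_pos <- c(0.7, 0.2, 0.9)
  expect_equal(main_loss(y, cbind(1 - p_pos, p_pos)), main_loss(y, p_pos),
               tolerance = 1e-12)
  expect_warning(main_loss(1L, 1), "clamp")
  expect_error(main_loss(c(1L, 0L), 0.5), "mismatch")
})

test_that("feature distance is a Euclidean metric", {
  expect_equal(feature_distance(c(0, 0), c(3, 4)), 5)
  f <- rnorm(6); g <- rnorm(6)
  expect_equal(feature_distance(f, g), feature_distance(g, f))
  expect_equal(feature_distance(f, f), 0)
  expect_error(feature_distance(1:3, 1:4), "mismatch")
})

test_that("verification loss follows the contrastive hinge form", {
  f <- rnorm(4)
  expect_equal(verification_loss(f, f, 1), 0)
  expect_equal(verification_loss(c(0, 0), c(3, 4), 0, delta = 2), 0)
  f1 <- c(1, 0); f2 <- c(0, 0)   # D = 1, delta = 2
  expect_equal(verification_loss(f1, f2, 0, delta = 2), 0.5)
  expect_equal(verification_loss(f1, f2, 1), 0.5)
  # every component is non-negative on random inputs
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    expect_gte(verification_loss(a, b, rbinom(1, 1, 0.5), delta = 1.5), 0)
  }
})

test_that("verification gradients match finite differences away from the hinge", {
  set.seed(9)
  eps <- 1e-7
  for (y_ver in c(0, 1)) {
    f1 <- rnorm(5); f2 <- rnorm(5)
    if (y_ver == 0 && abs(feature_distance(f1, f2) - 1) < 0.2) f2 <- f2 * 2
    g <- seizcast:::verification_grad(f1, f2, y_ver, delta = 1)
    for (i in 1:5) {
      fp <- f1; fp[i] <- fp[i] + eps
      fm <- f1; fm[i] <- fm[i] - eps
      fd <- (verification_loss(fp, f2, y_ver, 1) -
             verification_loss(fm, f2, y_ver, 1)) / (2 * eps)
      expect_equal(g[i], fd, tolerance = 1e-5)
    }
  }
})

test_that("the combined loss is linear in the verification weight", {
  set.seed(4)
  n <- 6L
  y1 <- rbinom(n, 1, 0.5); y2 <- rbinom(n, 1, 0.5)
  p1 <- matrix(runif(2 * n, 0.1, 0.9), n); p1 <- p1 / rowSums(p1)
  p2 <- matrix(runif(2 * n, 0.1, 0.9), n); p2 <- p2 / rowSums(p2)
  f1 <- matrix(rnorm(3 * n), n); f2 <- matrix(rnorm(3 * n), n)
  yv <- as.integer(y1 == y2)
  l0 <- total_loss(y1, y2, p1, p2, f1, f2, yv, c_ver = 0)
  l1 <- total_loss(y1, y2, p1, p2, f1, f2, yv, c_ver = 0.11)
  l2 <- total_loss(y1, y2, p1, p2, f1, f2, yv, c_ver = 0.22)
  # c_ver = 0 leaves only the classification terms
  lm <- mean(vapply(seq_len(n), function(i)
    main_loss(y1[i], p1[i, , drop = FALSE]) +
    main_loss(y2[i], p2[i, , drop = FALSE]), 0))
  expect_equal(l0, lm, tolerance = 1e-12)
  # doubling c_ver adds exactly the verification component again
  expect_equal(l2 - l1, l1 - l0, tolerance = 1e-12)
  # perfect predictions with identical features: zero loss
  ident <- matrix(rnorm(3 * n), n)
  perfect <- cbind(1 - y1, y1) * (1 - 1e-15) + 0.5e-15
  expect_lt(total_loss(y1, y1, perfect, perfect, ident, ident,
                       rep(1L, n)), 1e-10)
})

test_that("pairing halves the batch with consistent verification labels", {
  labels <- rep(c(0L, 1L), each = 10L)
  pr <- make_pairs(labels, seed = 2L)
  expect_equal(nrow(pr), 10L)
  expect_setequal(c(pr$i, pr$j), 1:20)
  expect_equal(pr$y_ver, as.integer(labels[pr$i] == labels[pr$j]))
  expect_identical(make_pairs(labels, seed = 2L), pr)
  expect_true(all(make_pairs(rep(1L, 8L), seed = 1L)$y_ver == 1L))
  expect_error(make_pairs(rep(0L, 7L)), "even")
})

test_that("fine-tuning learns a separable task and shapes the feature space", {
  sep <- separable_images(30L, seed = 7L)
  cfg <- stack_config(list(list(K = 6L, k = 3L, pad = 0L, pool = 2L,
                                lambda = 0.1)))
  mdl <- seizcast_model(cfg, input_dim = c(12L, 12L, 3L), n_classes = 2L,
                        seed = 2L)
  # 0 epochs: untouched model
  ft0 <- finetune(mdl, sep$pixels, sep$labels, finetune_config(epochs = 0L))
  expect_identical(ft0$model, mdl)
  feats <- function(m) t(vapply(seq_len(60), function(i) {
    f <- model_forward(m, sep$pixels[, , , i], mode = "eval")$fbar
    f / max(sqrt(sum(f^2)), 1e-8)
  }, numeric(mdl$d)))
  mean_dists <- function(Fm) {
    D <- as.matrix(stats::dist(Fm))
    same <- outer(sep$labels, sep$labels, "==")
    diag(same) <- NA
    c(intra = mean(D[which(same)]), inter = mean(D[which(!same)]))
  }
  d0 <- mean_dists(feats(mdl))
  ft <- finetune(mdl, sep$pixels, sep$labels,
                 finetune_config(epochs = 25L, batchsize = 20L, seed = 5L))
  expect_gte(utils::tail(ft$history$accuracy, 1), 0.95)
  d1 <- mean_dists(feats(ft$model))
  expect_lt(d1["intra"], d0["intra"])
  expect_gt(d1["inter"] - d1["intra"], d0["inter"] - d0["intra"])
  # per-epoch history is recorded
  expect_equal(nrow(ft$history), 25L)
  expect_true(all(ft$history$loss_main >= 0 & ft$history$loss_ver >= 0))
})

test_that("both Siamese branches share one parameter set", {
  sep <- separable_images(10L, seed = 3L)
  cfg <- stack_config(list(list(K = 4L, k = 3L, pad = 0L, pool = 2L,
                                lambda = 0.1)))
  mdl <- seizcast_model(cfg, input_dim = c(12L, 12L, 3L), n_classes = 2L,
                        seed = 4L)
  ft <- finetune(mdl, sep$pixels, sep$labels,
                 finetune_config(epochs = 2L, batchsize = 10L, seed = 1L))
  # the same image fed through either branch position yields identical
  # features before and after updates (single weight-shared network)
  v <- sep$pixels[, , , 1]
  fa <- model_forward(ft$model, v, mode = "eval")$fbar
  fb <- model_forward(ft$model, v, mode = "eval")$fbar
  expect_identical(fa, fb)
  expect_false(identical(model_forward(mdl, v, mode = "eval")$fbar, fa))
})
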