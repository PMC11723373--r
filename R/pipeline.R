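# End-to-end orchestration: synthetic cohort -> spectral images ->
# normalization + ZCA -> layer-wise pretraining -> dual-task fine-tuning ->
# evaluation.

#' Whiten a spectral dataset
#'
#' Fits per-pixel standardization and ZCA whitening on the training indices
#' and applies them to the whole dataset.
#' @param dataset a [spectral_dataset()] with pixels
#' @param train_idx indices used to fit the transforms
#' @param epsilon ZCA eigenvalue regularization
#' @return list(pixels, normalizer, zca): whitened pixel array and the
#'   fitted transforms
#' @export
whiten_dataset <- function(dataset, train_idx = NULL, epsilon = 1e-5) {
  px <- dataset$pixels
  if (is.null(px)) stop("dataset has no pixels")
  d <- dim(px)
  N <- d[4]
  if (is.null(train_idx)) train_idx <- seq_len(N)
  X <- t(matrix(px, nrow = prod(d[1:3]), ncol = N))   # [N, D]
  nrm <- fit_normalizer(X[train_idx, , drop = FALSE])
  Xs <- predict(nrm, X)
  zca <- fit_zca(Xs[train_idx, , drop = FALSE], epsilon = epsilon)
  Xw <- predict(zca, Xs)
  list(pixels = array(t(Xw), dim = d), normalizer = nrm, zca = zca)
}

#' Run the reduced synthetic pipeline
#'
#' Simulates a small cohort, builds binary-task spectral images, whitens
#' them, pretrains a reduced one-layer CssCRBM stack by CD, fine-tunes with
#' the dual-task objective and the attention head, and evaluates on a held
#' out split. Sized to run on one CPU in minutes.
#' @param seed master seed for every stage
#' @param n_images total images (balanced classes) drawn from the cohort
#' @param minutes_per_class synthetic recording minutes per class
#' @param pretrain_epochs CD epochs for the reduced stack
#' @param finetune_epochs dual-task epochs
#' @param K kernels in the reduced layer
#' @param pool pooling block of the reduced layer
#' @param test_frac held-out fraction
#' @param spec optional [synth_spec()] override
#' @param verbose print progress
#' @return list(report, history, model, n_train, n_test)
#' @export
run_synthetic_pipeline <- function(seed = 1L, n_images = 200L,
                                   minutes_per_class = 5,
                                   pretrain_epochs = 3L,
                                   finetune_epochs = 10L,
                                   K = 8L, pool = 8L, test_frac = 0.3,
                                   spec = NULL, verbose = FALSE) {
  if (is.null(spec)) spec <- synth_spec(seed = sub_seed(seed, 11L))
  cohort <- gen_cohort(spec, n_patients = 1L, database = "I",
                       minutes = list(preictal = minutes_per_class,
                                      interictal = minutes_per_class))
  db <- build_database_one(cohort, minutes_per_class = minutes_per_class)
  # balanced subsample
  set.seed(sub_seed(seed, 21L))
  per_class <- n_images %/% 2L
  idx <- c(sample(which(db$meta$y == 0L), per_class),
           sample(which(db$meta$y == 1L), per_class))
  meta <- db$meta[idx, , drop = FALSE]
  px <- db$pixels[, , , idx, drop = FALSE]
  sub <- spectral_dataset(px, meta, db$classes, db$window_s)
  # stratified train/test split
  n <- nrow(meta)
  test_idx <- unlist(lapply(split(seq_len(n), meta$y), function(ii)
    sample(ii, max(1L, round(length(ii) * test_frac)))))
  train_idx <- setdiff(seq_len(n), test_idx)
  wh <- whiten_dataset(sub, train_idx)
  sub$pixels <- wh$pixels
  if (verbose) message("whitened ", n, " images; pretraining")
  cfg <- stack_config(list(list(K = K, k = 3L, pad = 0L, pool = pool,
                                lambda = 0.1)))
  tc <- train_config(eta = 0.01, lambda = 0.1, cd_steps = 5L,
                     batchsize = 20L, epochs = pretrain_epochs,
                     seed = sub_seed(seed, 31L))
  train_imgs <- lapply(train_idx, function(i) sub$pixels[, , , i])
  stack <- pretrain_stack(train_imgs, cfg, tc, verbose = verbose)
  model <- seizcast_model(cfg, input_dim = dim(sub$pixels)[1:3],
                          n_classes = 2L, seed = sub_seed(seed, 41L))
  model$stack <- stack
  if (verbose) message("fine-tuning")
  ft <- finetune(model, sub$pixels[, , , train_idx, drop = FALSE],
                 meta$y[train_idx],
                 finetune_config(epochs = finetune_epochs,
                                 seed = sub_seed(seed, 51L)),
                 verbose = verbose)
  report <- evaluate_model(ft$model, sub, idx = test_idx)
  list(report = report, history = ft$history, model = ft$model,
       n_train = length(train_idx), n_test = length(test_idx))
}
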