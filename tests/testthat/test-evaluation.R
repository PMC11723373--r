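test_that("sensitivity follows TP/(TP+FN)", {
  cc <- confusion_counts(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
                         c(1, 1, 1, 1, 1, 1, 1, 1, 1, 0))
  expect_equal(sensitivity(cc), 0.9)
  cc2 <- confusion_counts(rep(1L, 5), rep(1L, 5))
  expect_equal(sensitivity(cc2), 1)
  cc3 <- list(TP = 197, FN = 1)
  expect_equal(sensitivity(cc3), 197 / 198, tolerance = 1e-12)
  expect_error(sensitivity(list(TP = 0, FN = 0)), "undefined")
})

test_that("false-positive rate covers per-sample and per-hour semantics", {
  truth <- c(rep(0L, 100), rep(1L, 10))
  pred <- c(rep(1L, 4), rep(0L, 96), rep(1L, 10))
  cc <- confusion_counts(truth, pred)
  fpr <- false_positive_rate(cc)
  expect_equal(fpr$per_sample, 0.04)
  # zero false positives
  cc0 <- confusion_counts(rep(0L, 50), rep(0L, 50))
  expect_equal(false_positive_rate(cc0)$per_sample, 0)
  # 3 isolated false-alarm events over 60 monitored hours
  times <- c(10, 5000, 20000)
  f <- false_positive_rate(list(TN = 96, FP = 3), hours = 60, times_s = times)
  expect_equal(f$n_events, 3L)
  expect_equal(f$per_hour, 0.05)
  # consecutive positives within the refractory window merge into one event
  f2 <- false_positive_rate(list(TN = 90, FP = 5), hours = 10,
                            times_s = c(0, 30, 60, 5000, 5060))
  expect_equal(f2$n_events, 2L)
  expect_error(false_positive_rate(list(TN = 0, FP = 0)), "undefined")
})

test_that("accuracy equals correct over total, including multiclass", {
  cc <- confusion_counts(rep(c(0L, 1L), each = 50),
                         c(rep(0L, 45), rep(1L, 5), rep(1L, 45), rep(0L, 5)))
  expect_equal(accuracy(cc), 0.9)
  perfect <- confusion_counts(rep(0:3, 25), rep(0:3, 25), n_classes = 4L)
  expect_equal(accuracy(perfect), 1)
  # binary identity: accuracy = (sens*P + spec*N) / (P + N)
  sens <- sensitivity(cc)
  spec <- cc$TN / (cc$TN + cc$FP)
  expect_equal(accuracy(cc), (sens * 50 + spec * 50) / 100)
  # uniform random four-class predictions on balanced labels: ~0.25
  set.seed(10)
  n <- 4000L
  truth <- rep(0:3, n / 4)
  rand_pred <- sample(0:3, n, replace = TRUE)
  acc <- accuracy(confusion_counts(truth, rand_pred, n_classes = 4L))
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(acc - 0.25), 3 * se)
})

test_that("prediction time runs from the first positive sample to onset", {
  # 60-minute window sampled every 2 s; first positive at minute 10
  times <- seq(0, 3600 - 2, by = 2)
  scores <- rep(0, length(times))
  scores[times >= 600] <- 1
  pt <- prediction_time(scores, times, onset_s = 3600)
  expect_true(pt$predicted)
  expect_equal(pt$time_min, 50)
  # first sample positive: full window
  pt2 <- prediction_time(rep(1, length(times)), times, onset_s = 3600)
  expect_equal(pt2$time_min, 60)
  # no positive: missed event, undefined time
  pt3 <- prediction_time(rep(0, length(times)), times, onset_s = 3600)
  expect_false(pt3$predicted)
  expect_true(is.na(pt3$time_min))
  expect_error(prediction_time(1, 3601, onset_s = 3600), "precede")
})

test_that("stratified folds are disjoint, covering, and seeded", {
  labels <- rep(c("a", "b"), each = 50)
  folds <- kfold_split(labels, k = 10L, seed = 3L)
  expect_length(folds, 10L)
  expect_true(all(lengths(folds) == 10L))
  expect_setequal(unlist(folds), 1:100)
  expect_equal(sum(duplicated(unlist(folds))), 0L)
  # stratification: every fold holds both classes evenly
  for (f in folds) expect_equal(sum(labels[f] == "a"), 5L)
  expect_identical(kfold_split(labels, 10L, seed = 3L), folds)
  expect_error(kfold_split(rep(c("a", "b"), c(95, 5)), k = 10L),
               "fewer than k")
})

test_that("model evaluation reports confusion-derived metrics and times", {
  # deterministic stand-in scores: build a dataset-like object and a
  # trivially perfect model via direct probability injection
  sep <- separable_images(20L, seed = 5L)
  meta <- data.frame(patient = "p1", class = rep(c("interictal", "preictal"),
                                                 each = 20L),
                     y = rep(0:1, each = 20L),
                     t_start_s = c(seq(0, 38, by = 2), seq(0, 38, by = 2)),
                     event = 1L, onset_s = 40,
                     pix_mean = 0)
  ds <- spectral_dataset(sep$pixels, meta, c("interictal", "preictal"))
  cfg <- stack_config(list(list(K = 4L, k = 3L, pad = 0L, pool = 2L,
                                lambda = 0.1)))
  mdl <- seizcast_model(cfg, input_dim = c(12L, 12L, 3L), n_classes = 2L,
                        seed = 2L)
  ft <- finetune(mdl, sep$pixels, sep$labels,
                 finetune_config(epochs = 15L, batchsize = 20L, seed = 4L))
  rep <- evaluate_model(ft$model, ds)
  expect_s3_class(rep, "eval_report")
  expect_gte(rep$accuracy, 0.9)
  expect_gte(rep$sensitivity, 0.9)
  expect_equal(rep$fpr_per_sample, rep$confusion$FP /
                 (rep$confusion$FP + rep$confusion$TN))
  expect_length(rep$prediction_times_min, 1L)
  expect_identical(evaluate_model(ft$model, ds), rep)
})
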