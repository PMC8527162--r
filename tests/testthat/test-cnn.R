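test_that("backpropagation matches finite-difference gradients", {
  cfg <- cnn_config(filters = c(2L, 3L), kernel = 3L, fc_width = 5L,
                    input_len = 16L, seed = 7)
  params <- dotprops:::cnn_init_params(cfg)
  state <- dotprops:::cnn_init_state(cfg)
  set.seed(42)
  B <- 4
  X <- matrix(rnorm(B * 16), B)
  Y <- matrix(rnorm(B * 4), B)
  lossfn <- function(p)
    mean((dotprops:::cnn_forward(p, cfg, state, X, train = TRUE)$out - Y)^2)
  fw <- dotprops:::cnn_forward(params, cfg, state, X, train = TRUE)
  grads <- dotprops:::cnn_backward(params, cfg, fw$cache,
                                   2 * (fw$out - Y) / length(Y))
  eps <- 1e-5
  # conv biases sit directly before batch norm, whose mean subtraction
  # makes the loss exactly flat in them; check every other group
  for (nm in setdiff(names(grads), c("conv1_b", "conv2_b"))) {
    p <- params[[nm]]
    for (i in sample(seq_along(p), min(5, length(p)))) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("the network can memorize a small training set", {
  ds <- fx_small_dataset()
  sel <- which(ds$split == "train")[1:50]
  small <- list(features = ds$features[sel, ], labels = ds$labels[sel, ])
  # full-data batches (batch norm statistics then coincide with the
  # population statistics used at inference) and a constant learning rate:
  # the stepwise decay schedule would freeze the net before it memorizes
  cfg <- cnn_config(epochs = 500L, patience = 0L, lr_decay_every = 500L,
                    batch_size = 50L, seed = 21)
  est <- cnn_train(small, cfg, min_examples = 10L)
  expect_lt(utils::tail(est$history$train_loss, 1), 1e-3)
  # training examples are reproduced within 5% after the overfit run
  pred <- predict(est, small$features)
  expect_lt(max(abs(pred / small$labels - 1)), 0.05)
})

test_that("training is deterministic given the seed", {
  ds <- fx_small_dataset()
  cfg <- cnn_config(epochs = 4L, patience = 0L, seed = 33)
  e1 <- cnn_train(ds, cfg)
  e2 <- cnn_train(ds, cfg)
  expect_identical(e1$params, e2$params)
  expect_identical(e1$history, e2$history)
  # and prediction is deterministic on identical inputs
  fv <- ds$features[1, ]
  expect_identical(predict(e1, fv), predict(e1, fv))
})

test_that("non-finite losses abort with history attached", {
  ds <- fx_small_dataset()
  # batch norm keeps activations bounded for any finite weights, so true
  # divergence needs an overflow-scale learning rate
  cfg <- cnn_config(epochs = 30L, lr = 1e300, patience = 0L, seed = 2)
  err <- tryCatch(cnn_train(ds, cfg), error = function(e) e)
  expect_match(conditionMessage(err), "diverged")
  expect_s3_class(err$history, "data.frame")
})

test_that("zero-epoch fine-tuning returns the estimator unchanged", {
  est <- fx_small_cnn()
  expect_identical(cnn_fine_tune(est, fx_small_dataset(), epochs = 0L), est)
})

test_that("fine-tuning on the training data itself does not degrade it", {
  est <- fx_small_cnn()
  ds <- fx_small_dataset()
  tuned <- cnn_fine_tune(est, ds, lr = 1e-4, epochs = 15L, seed = 5)
  base_err <- evaluate_cnn(est, ds, "test")
  tuned_err <- evaluate_cnn(tuned, ds, "test")
  expect_lt(mean(tuned_err), mean(base_err) * 1.10)
  # stats are frozen, not recomputed
  expect_identical(tuned$stats, est$stats)
})

test_that("prediction validates the feature length and clips to positive", {
  est <- fx_small_cnn()
  expect_error(predict(est, rnorm(100)), "feature length")
  # absurd far-out-of-range input still yields positive estimates
  pred <- predict(est, rep(-50, 256))
  expect_true(all(pred > 0))
})

test_that("estimators survive a save/load round trip", {
  est <- fx_small_cnn()
  dir <- withr::local_tempdir()
  save_estimator(est, dir)
  est2 <- load_estimator(dir)
  ds <- fx_small_dataset()
  expect_equal(predict(est2, ds$features[1:5, ]),
               predict(est, ds$features[1:5, ]), tolerance = 1e-12)
})

test_that("the k-fold harness partitions the data and reports per-fold errors", {
  ds <- fx_small_dataset()
  cfg <- cnn_config(filters = c(4L, 6L), fc_width = 16L, epochs = 6L,
                    patience = 0L, seed = 3)
  cv <- cnn_cross_validate(ds, cfg, folds = 3L)
  expect_length(cv$estimators, 3L)
  expect_equal(dim(cv$fold_errors), c(3L, 4L))
  expect_true(all(is.finite(cv$fold_errors)))
  # fold models differ (different data and seeds)
  expect_false(identical(cv$estimators[[1]]$params,
                         cv$estimators[[2]]$params))
})
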