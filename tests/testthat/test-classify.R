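make_blobs <- function(n = 400, p = 10, seed = 0, sep = 3) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n) + sep * y %o% rep(c(1, -1), length.out = p) / 2
  colnames(x) <- paste0("f", seq_len(p))
  feature_matrix(x, y)
}

test_that("pooling matches hand-evaluated windows", {
  expect_equal(max_pool(c(1, 3, 2, 5)), c(3, 3, 5))
  expect_equal(avg_pool(c(1, 3, 2, 5)), c(2, 2.5, 3.5))
  expect_equal(max_pool(rep(7, 5)), rep(7, 4))
  expect_equal(avg_pool(rep(7, 5)), rep(7, 4))
  expect_equal(max_pool(1:6, size = 3, stride = 2), c(3, 5))
  expect_error(max_pool(1:3, size = 4), "larger than input")
})

test_that("the committed architecture walks 10 -> 9 -> 8 -> 7 -> 6 -> 192", {
  spec <- cnn_spec()
  expect_equal(unname(spec$shape_walk),
               c(10, 9, 8, 7, 6, 192))
  # pooling an input of 2 through both blocks collapses below length 1
  expect_error(cnn_spec(input_len = 2), "collapse")
})

test_that("an untrained forward pass is a seeded softmax", {
  m1 <- build_cnn(cnn_spec(), seed = 123)
  m2 <- build_cnn(cnn_spec(), seed = 123)
  X <- matrix(rnorm(50), 5, 10)
  p1 <- predict(m1, X)$probs
  p2 <- predict(m2, X)$probs
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0))
  expect_equal(rowSums(p1), rep(1, 5), tolerance = 1e-6)
  m3 <- build_cnn(cnn_spec(), seed = 124)
  expect_false(identical(predict(m3, X)$probs, p1))
})

test_that("the first convolution equals the naive loop oracle", {
  model <- build_cnn(cnn_spec(), seed = 1)
  set.seed(2)
  X <- matrix(rnorm(40), 4, 10)
  Z <- eegseize:::.conv1_forward(X, model$params$W1, model$params$b1,
                                 model$spec)
  expect_equal(Z, conv1_oracle(X, model$params$W1, model$params$b1),
               tolerance = 1e-12)
})

test_that("backprop gradients match finite differences", {
  spec <- cnn_spec(input_len = 6, filters = c(3, 4), fc_hidden = 5)
  model <- build_cnn(spec, seed = 5)
  set.seed(6)
  X <- matrix(rnorm(4 * 6), 4, 6)
  y <- c(0L, 1L, 1L, 0L)
  lg <- eegseize:::.cnn_loss_grads(model, X, y, training = TRUE)
  eps <- 1e-5
  for (nm in names(model$params)) {
    theta <- model$params[[nm]]
    # probe a handful of coordinates per tensor
    idx <- seq_len(min(4, length(theta)))
    for (i in idx) {
      mp <- model; mp$params[[nm]][i] <- theta[i] + eps
      mm <- model; mm$params[[nm]][i] <- theta[i] - eps
      num <- (eegseize:::.cnn_loss_grads(mp, X, y, TRUE)$loss -
              eegseize:::.cnn_loss_grads(mm, X, y, TRUE)$loss) / (2 * eps)
      expect_lt(abs(lg$grads[[nm]][i] - num) / max(1, abs(num)), 1e-4,
                label = sprintf("gradient mismatch d%s[%d]", nm, i))
    }
  }
})

test_that("training separates Gaussian blobs and rejects degenerate folds", {
  fm <- make_blobs(n = 400, seed = 0)
  fit <- train_model(build_cnn(cnn_spec(), seed = 0), fm,
                     train_config(epochs = 100, seed = 0))
  expect_length(intersect(fit$train_idx, fit$test_idx), 0)
  expect_equal(sort(c(fit$train_idx, fit$test_idx)), 1:400)
  # stratification: both folds carry both classes at ~3:1
  expect_equal(sum(fm$labels[fit$train_idx] == 1), 150)
  expect_equal(sum(fm$labels[fit$test_idx] == 1), 50)

  pred <- predict(fit$model, fm$values[fit$test_idx, ])
  acc_test <- mean(pred$labels == fm$labels[fit$test_idx])
  expect_gte(acc_test, 0.95)

  # train-set fit is at least as good, within slack
  pred_tr <- predict(fit$model, fm$values[fit$train_idx, ])
  acc_train <- mean(pred_tr$labels == fm$labels[fit$train_idx])
  expect_gte(acc_train, acc_test - 0.05)

  # loss decreases over training
  expect_lt(tail(fit$model$history, 1), fit$model$history[1])

  # determinism of prediction
  expect_identical(predict(fit$model, fm$values[1:7, ]),
                   predict(fit$model, fm$values[1:7, ]))

  expect_error(train_model(build_cnn(cnn_spec(), 0), fm,
                           train_config(epochs = 0)), "epochs")
  one_class <- feature_matrix(fm$values[fm$labels == 1, ],
                              fm$labels[fm$labels == 1])
  expect_error(train_model(build_cnn(cnn_spec(), 0), one_class,
                           train_config(epochs = 1)),
               "fewer than 2|single class")
  expect_error(predict(fit$model, fm$values[, 1:7]), "input_len")
})

test_that("shuffled labels train to chance level", {
  fm <- make_blobs(n = 400, seed = 0)
  set.seed(99)
  fm$labels <- sample(fm$labels)
  fit <- train_model(build_cnn(cnn_spec(), seed = 0), fm,
                     train_config(epochs = 100, seed = 0))
  pred <- predict(fit$model, fm$values[fit$test_idx, ])
  acc <- mean(pred$labels == fm$labels[fit$test_idx])
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("the SVM adapter honors the same contract", {
  fm <- make_blobs(n = 200, seed = 1)
  fit <- train_model(build_svm(), fm, train_config(seed = 0))
  pred <- predict(fit$model, fm$values[fit$test_idx, ])
  expect_gte(mean(pred$labels == fm$labels[fit$test_idx]), 0.9)
})
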