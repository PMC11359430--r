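# BiLSTM classifier: softmax contract, determinism, gradient correctness,
# schedule arithmetic, learning-rate range test, and training on separable
# data.

test_that("softmax outputs are normalized probabilities for any input", {
  m <- build_bilstm(3L, hidden_units = 4L, fc_units = 3L, seed = 7)
  set.seed(1)
  X <- lapply(1:5, function(i) matrix(runif(6 * 3, -1, 2), 6, 3))
  probs <- ppgaf:::network_forward(m$params, X, 4L)$probs
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-6)
})

test_that("weight initialization is seed-deterministic and sized correctly", {
  a <- build_bilstm(10L, 16L, 8L, seed = 3)
  b <- build_bilstm(10L, 16L, 8L, seed = 3)
  expect_identical(a$params, b$params)
  c2 <- build_bilstm(10L, 16L, 8L, seed = 4)
  expect_false(identical(a$params, c2$params))
  expect_gt(count_params(build_bilstm(10L, 32L, 8L)), count_params(a))
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(1)
  X <- lapply(1:4, function(i) matrix(runif(5 * 3), 5, 3))
  y01 <- c(0L, 1L, 0L, 1L)
  m <- build_bilstm(3L, hidden_units = 4L, fc_units = 3L, seed = 7)
  gr <- ppgaf:::network_gradients(m$params, X, y01, 4L)
  gv <- ppgaf:::flatten_params(gr$grads)
  pv <- ppgaf:::flatten_params(m$params)
  expect_gt(sqrt(sum(gv^2)), 1e-4)  # net is alive
  eps <- 1e-6
  idx <- sample(length(pv), 60)
  num <- vapply(idx, function(i) {
    p1 <- pv; p1[i] <- p1[i] + eps
    p2 <- pv; p2[i] <- p2[i] - eps
    (ppgaf:::network_gradients(ppgaf:::relist_params(p1, m$params), X, y01, 4L)$loss -
     ppgaf:::network_gradients(ppgaf:::relist_params(p2, m$params), X, y01, 4L)$loss) /
      (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - gv[idx])), 1e-7)
})

test_that("learning-rate schedule matches its closed form", {
  expect_equal(lr_at_epoch(1), 0.01525)
  expect_equal(lr_at_epoch(10), 0.01525)
  expect_equal(lr_at_epoch(11), 0.01525 * 0.5)
  expect_equal(lr_at_epoch(25, 0.02, 0.5, 5L), 0.02 * 0.5^4)
  toy <- toy_features(4, frames = 6, bands = 3)
  fit <- af_bilstm(toy$x, toy$y, hidden_units = 4L, fc_units = 4L,
                   max_epochs = 12L, decay_period = 5L, seed = 2)
  expect_equal(fit$history$lr,
               lr_at_epoch(1:12, 0.01525, 0.5, 5L))
  expect_true(all(is.finite(fit$history$loss)))
})

test_that("training separates linearly separable classes", {
  toy <- toy_features(20, frames = 10, bands = 4)
  fit <- af_bilstm(toy$x, toy$y, hidden_units = 8L, fc_units = 8L,
                   max_epochs = 40L, seed = 5)
  expect_gte(tail(fit$history$accuracy, 1), 0.95)
  pred <- predict(fit, toy$x)
  expect_gte(mean(pred$label == toy$y), 0.95)
})

test_that("training and prediction are reproducible and batch-order invariant", {
  toy <- toy_features(6, frames = 6, bands = 3)
  fit1 <- af_bilstm(toy$x, toy$y, hidden_units = 4L, fc_units = 4L,
                    max_epochs = 8L, seed = 9)
  fit2 <- af_bilstm(toy$x, toy$y, hidden_units = 4L, fc_units = 4L,
                    max_epochs = 8L, seed = 9)
  expect_identical(predict(fit1, toy$x), predict(fit2, toy$x))

  p_all <- predict(fit1, toy$x, type = "prob")
  perm <- rev(seq_along(toy$x))
  p_perm <- predict(fit1, toy$x[perm], type = "prob")
  expect_equal(p_perm, p_all[perm, ], tolerance = 1e-12)
})

test_that("degenerate training sets and shape mismatches are rejected", {
  toy <- toy_features(4, frames = 6, bands = 3)
  one_class <- rep("AF", length(toy$x))
  expect_error(af_bilstm(toy$x, one_class, max_epochs = 1L), "each class")
  fit <- af_bilstm(toy$x, toy$y, hidden_units = 4L, fc_units = 4L,
                   max_epochs = 2L, seed = 1)
  wrong <- list(matrix(0, 6, 5))
  expect_error(predict(fit, wrong), "dimension")
  expect_error(predict(build_bilstm(3L), toy$x), "trained")
})

test_that("lr range test returns a monotone grid and sane suggestions", {
  toy <- toy_features(8, frames = 6, bands = 3)
  m <- build_bilstm(3L, 4L, 4L, seed = 1)
  out <- lr_range_test(m, toy$x, toy$y, lr_start = 1e-4, lr_end = 0.5,
                       n_steps = 20L, seed = 2)
  expect_length(out$lr, 20L)
  expect_true(all(diff(out$lr) > 0))
  expect_true(out$suggested_lr >= 1e-4 && out$suggested_lr <= 0.5)

  # all-constant loss: documented tie-break to lr_start
  flat <- suggest_lr(c(0.01, 0.02, 0.04), rep(1.5, 3))
  expect_equal(flat$suggested_lr, 0.01)

  # divergence truncates the curve; suggestion comes from the valid prefix
  div <- suggest_lr(c(0.01, 0.02, 0.04, 0.08, 0.16, 0.32),
                    c(2, 1.5, 1.0, 0.6, NaN, NaN))
  expect_equal(div$suggested_lr, 0.08)
  expect_identical(div$valid, 1:4)
})

test_that("suggested lr falls in the stable step-size interval of a quadratic", {
  # gradient descent on f(x) = a/2 x^2 from x0: one step multiplies x by
  # (1 - a*lr); the loss-vs-lr curve over a geometric grid has its
  # descending-branch minimum near lr = 1/a, and diverges past 2/a
  a <- 20
  x0 <- 1
  lrs <- exp(seq(log(1e-4), log(1), length.out = 60))
  losses <- 0.5 * a * (x0 * (1 - a * lrs))^2
  sug <- suggest_lr(lrs, losses)$suggested_lr
  expect_gt(sug, 0)
  expect_lt(sug, 2 / a)
  expect_lt(abs(log(sug / (1 / a))), log(1.6))  # within ~60% of 1/a
})
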