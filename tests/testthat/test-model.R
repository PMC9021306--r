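# CNN regressor: architecture arithmetic, gradient correctness, training
# behavior, determinism, and replicate aggregation.

test_that("the full-scale paired architecture has ~100M parameters", {
  full <- model_config(channels = 2)
  expect_lt(abs(count_params(full) / 100800000 - 1), 0.15)
  # scaling down divides filter counts and dense width
  desk <- model_config(channels = 2, scale = 32)
  expect_equal(desk$filters_eff, c(8, 8, 16, 32, 64))
  expect_equal(desk$dense_eff, 128)
})

test_that("five pooling stages reduce 406 steps to 12", {
  lens <- Reduce(function(l, i) l %/% 2, 1:5, accumulate = TRUE, init = 406)
  expect_equal(lens, c(406, 203, 101, 50, 25, 12))
  # and the network's flatten size reflects it
  cfg <- tiny_model_cfg(channels = 1)
  net <- build_network(cfg)
  s <- random_samples(3, channels = 1, seed = 1)
  fw <- glucopair:::.nn_forward(net, array(s$x_now, c(3, 406, 1)))
  expect_equal(fw$flat_dim[2], 12)
  expect_equal(fw$flat_dim[3], cfg$filters_eff[5])
})

test_that("parameter counting matches hand arithmetic on a small config", {
  cfg <- model_config(channels = 2, conv_filters = c(4, 6, 8, 8, 8),
                      dense_width = 10, input_len = 406)
  # conv: 3*2*4+4, 3*4*6+6, 3*6*8+8, 3*8*8+8, 3*8*8+8
  conv <- (3 * 2 * 4 + 4) + (3 * 4 * 6 + 6) + (3 * 6 * 8 + 8) +
    (3 * 8 * 8 + 8) + (3 * 8 * 8 + 8)
  flat <- 12 * 8 + 1
  expect_equal(count_params(cfg),
               conv + 2 * flat + flat * 10 + 10 + 10 + 1)
})

test_that("a 1-channel configuration omits the baseline merge", {
  cfg <- tiny_model_cfg(channels = 1)
  expect_false(cfg$use_baseline_bgl)
  net <- build_network(cfg)
  s <- random_samples(4, channels = 1, seed = 2)
  expect_length(predict_model(net, s), 4)
  expect_error(model_config(channels = 1, use_baseline_bgl = TRUE),
               "two-channel")
  # 2-channel model refuses unpaired samples
  net2 <- build_network(tiny_model_cfg(channels = 2))
  expect_error(predict_model(net2, s), "paired")
})

test_that("backpropagation matches numerical gradients", {
  cfg <- model_config(channels = 2, conv_filters = c(4, 4, 6, 6, 8),
                      dense_width = 10, input_len = 40, epochs = 1,
                      seed = 2)
  net <- build_network(cfg)
  set.seed(5)
  n <- 4
  x <- array(rnorm(n * 40 * 2), c(n, 40, 2))
  bl <- runif(n, 100, 200)
  y <- runif(n, 100, 200)
  loss_at <- function(net) {
    fw <- glucopair:::.nn_forward(net, x, bl, training = TRUE)
    mean((fw$pred - y)^2)
  }
  fw <- glucopair:::.nn_forward(net, x, bl, training = TRUE)
  grads <- glucopair:::.nn_backward(net, fw, 2 * (fw$pred - y) / n)
  eps <- 1e-6
  for (u in seq_along(grads)) {
    for (p in names(grads[[u]])) {
      g <- grads[[u]][[p]]
      idx <- sample(length(g), min(4, length(g)))
      for (i in idx) {
        up <- net; up$layers[[u]][[p]][i] <- up$layers[[u]][[p]][i] + eps
        dn <- net; dn$layers[[u]][[p]][i] <- dn$layers[[u]][[p]][i] - eps
        num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
        expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), 1e-4)
      }
    }
  }
})

test_that("training reduces the loss on learnable synthetic data", {
  set.seed(3)
  n <- 60
  x <- matrix(rnorm(n * 406), n, 406)
  y <- 150 + 40 * x[, 5] + 5 * rnorm(n)     # target depends on one feature
  s <- structure(list(x_now = x, x_prev = NULL, baseline = NULL,
                      target = y, round = rep(1, n),
                      replicate = rep(1, n)), class = "sample_set")
  cfg <- model_config(channels = 1, scale = 64, epochs = 25,
                      batch_size = 16, learning_rate = 3e-3, seed = 8)
  net <- train_model(build_network(cfg), s)
  h <- net$history$train_loss
  expect_lt(h[length(h)], h[1])
  expect_true(all(is.finite(predict_model(net, s))))
})

test_that("a single sample with target 120 is memorized", {
  s <- random_samples(1, channels = 1, targets = 120, seed = 4)
  cfg <- model_config(channels = 1, scale = 64, epochs = 40,
                      batch_size = 1, learning_rate = 1e-2, seed = 5)
  net <- train_model(build_network(cfg), s)
  expect_lt(abs(predict_model(net, s) - 120), 5)
})

test_that("constant targets are learned regardless of channel count", {
  for (ch in 1:2) {
    s <- random_samples(6, channels = ch, targets = rep(130, 6), seed = 6)
    cfg <- model_config(channels = ch, scale = 64, epochs = 50,
                        batch_size = 6, learning_rate = 1e-2, seed = 6)
    net <- train_model(build_network(cfg), s)
    expect_true(all(abs(predict_model(net, s) - 130) < 5))
  }
})

test_that("identical seeds give identical trained predictions", {
  s <- random_samples(20, channels = 2, seed = 7)
  cfg <- model_config(channels = 2, scale = 64, epochs = 8,
                      batch_size = 8, learning_rate = 3e-3, seed = 9)
  n1 <- train_model(build_network(cfg), s)
  n2 <- train_model(build_network(cfg), s)
  expect_identical(predict_model(n1, s), predict_model(n2, s))
  cfg2 <- cfg; cfg2$seed <- 10L
  n3 <- train_model(build_network(cfg2), s)
  expect_false(identical(predict_model(n1, s), predict_model(n3, s)))
})

test_that("replicate aggregation is the order-invariant window median", {
  s <- random_samples(11, channels = 1, seed = 8)
  net <- build_network(tiny_model_cfg(channels = 1))
  expect_equal(predict_replicate(net, s),
               stats::median(predict_model(net, s)))
  perm <- sample(11)
  sp <- s
  sp$x_now <- s$x_now[perm, ]
  sp$target <- s$target[perm]
  expect_equal(predict_replicate(net, sp), predict_replicate(net, s),
               tolerance = 1e-12)
  empty <- s; empty$x_now <- s$x_now[0, , drop = FALSE]
  empty$target <- numeric(0)
  expect_error(predict_replicate(net, empty))
})
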