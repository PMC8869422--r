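test_that("parameter count matches the closed form for any configuration", {
  # default architecture: 2650 + 2010 + 410 + 2200 + 201 = 7471 weights
  expect_equal(n_trainable_params(model_config()), 7471L)
  cfgs <- list(model_config(),
               model_config(filters = c(4, 8, 16), kernels = c(9, 5, 3),
                            fc = 32),
               model_config(filters = c(2, 2, 2), kernels = c(3, 3, 2),
                            fc = 5))
  for (cfg in cfgs) {
    C <- cfg$n_channels; f <- cfg$filters; k <- cfg$kernels; fc <- cfg$fc
    closed <- (C * k[1] + 1) * f[1] + (f[1] * k[2] + 1) * f[2] +
      (f[2] * k[3] + 1) * f[3] + (f[3] + 1) * fc + fc + 1
    built <- build_model(cfg, n_samples = 600, seed = 1)
    expect_equal(sum(lengths(built$params)), closed)
    expect_equal(n_trainable_params(built), closed)
  }
})

test_that("global pooling makes the parameter count window-length invariant", {
  m1 <- build_model(model_config(), window_samples(1), seed = 1)
  m15 <- build_model(model_config(), window_samples(15), seed = 1)
  expect_equal(n_trainable_params(m1), n_trainable_params(m15))
  # architecture builds across the whole supported window range at 15 Hz
  for (W in c(7.5 / 60, 0.5, 1, 4, 6, 15))
    expect_s3_class(build_model(model_config(), window_samples(W), seed = 1),
                    "window_classifier")
  expect_error(build_model(model_config(), 50), "minimum is 94")
})

test_that("untrained outputs are probabilities and batching is consistent", {
  m <- build_model(model_config(), 450, seed = 3)
  x <- withr::with_seed(4, array(rnorm(450 * 6 * 50), dim = c(450, 6, 50)))
  p_batch <- predict_windows(m, x)
  expect_true(all(p_batch >= 0 & p_batch <= 1))
  p_single <- vapply(1:50, function(i)
    predict_windows(m, x[, , i, drop = FALSE]), numeric(1))
  expect_equal(p_batch, p_single, tolerance = 1e-6)
  expect_error(predict_windows(m, x[1:100, , ]), "does not match")
})

test_that("backpropagation matches finite-difference gradients", {
  cfg <- model_config(filters = c(3, 3, 3), kernels = c(5, 4, 3), fc = 7,
                      l1_penalty = 1e-3)
  m <- build_model(cfg, 40, seed = 2)
  withr::with_seed(42, {
    x <- array(rnorm(40 * 6 * 4), dim = c(40, 6, 4))
    y <- c(1, 0, 1, 0)
    fw <- eatseg:::model_forward(m, x, cache = TRUE)
    gr <- eatseg:::model_gradients(m, fw, y)
    loss_at <- function(mm) eatseg:::bce_loss(
      eatseg:::model_forward(mm, x), y, mm)
    eps <- 1e-6
    for (nm in names(m$params)) {
      for (i in sample(length(m$params[[nm]]),
                       min(5, length(m$params[[nm]])))) {
        up <- m; up$params[[nm]][i] <- up$params[[nm]][i] + eps
        dn <- m; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
        num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
        expect_equal(gr[[nm]][i], num, tolerance = 1e-5)
      }
    }
  })
})

test_that("training learns separable data and the loss decreases", {
  d <- separable_windows(100, seed = 5)
  m <- build_model(model_config(kernels = c(20, 10, 4)), 120, seed = 1)
  tc <- train_config(learning_rate = 1e-3, epochs = 40, seed = 3)
  m <- train_model(m, d$x, d$y, tc)
  expect_true(all(is.finite(m$history$loss)))
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])
  expect_gt(tail(m$history$accuracy, 1), 0.95)
  # held-out windows from the same generating process
  held <- separable_windows(50, seed = 6)
  expect_gt(window_accuracy(predict_windows(m, held$x), held$y), 0.9)
  expect_error(train_model(build_model(model_config(kernels = c(20, 10, 4)),
                                       120, seed = 1),
                           d$x, rep(1, length(d$y)), tc), "single class")
})

test_that("training is deterministic given the seed", {
  d <- separable_windows(20, seed = 7)
  tc <- train_config(learning_rate = 1e-3, epochs = 3, seed = 9)
  m1 <- train_model(build_model(model_config(kernels = c(20, 10, 4)), 120,
                                seed = 9), d$x, d$y, tc)
  m2 <- train_model(build_model(model_config(kernels = c(20, 10, 4)), 120,
                                seed = 9), d$x, d$y, tc)
  expect_identical(m1$params, m2$params)
  tc2 <- tc; tc2$seed <- 10L
  m3 <- train_model(build_model(model_config(kernels = c(20, 10, 4)), 120,
                                seed = 10), d$x, d$y, tc2)
  expect_false(identical(m1$params, m3$params))
})

test_that("window accuracy counts thresholded agreement", {
  expect_equal(window_accuracy(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(window_accuracy(c(0.9, 0.2, 0.6, 0.4), c(1, 0, 0, 0)), 0.75)
  withr::with_seed(12, {
    p <- runif(2000); y <- rep(0:1, 1000)
    expect_lt(abs(window_accuracy(p, y) - 0.5), 0.05)   # chance level
  })
  expect_error(window_accuracy(numeric(), numeric()), "empty")
})

test_that("model checkpoints round trip", {
  m <- build_model(model_config(), 450, seed = 8)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- load_model(f)
  expect_identical(back$params, m$params)
})
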