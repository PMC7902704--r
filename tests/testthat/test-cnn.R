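test_that("the model summary matches the published layer plan", {
  m <- build_model(cnn_config())
  smry <- m$summary
  expect_equal(sum(smry$type == "conv2d"), 4)
  expect_equal(sum(smry$type == "maxpool2d"), 4)
  expect_equal(sum(smry$type == "dropout"), 2)
  expect_equal(sum(smry$type == "dense"), 2)
  last <- smry[nrow(smry), ]
  expect_equal(last$output_shape, "7")
  expect_match(last$detail, "softmax")
  expect_equal(smry$detail[smry$type == "dense"][1], "128 units, relu")
})

test_that("reported parameter counts equal independent shape arithmetic", {
  expect_equal(n_parameters(build_model(cnn_config())),
               oracle_param_count(c(150, 100, 1)))
  expect_equal(n_parameters(build_model(cnn_config(input_shape = c(32, 32, 1)))),
               oracle_param_count(c(32, 32, 1)))
  expect_equal(n_parameters(build_model(cnn_config(input_shape = c(64, 48, 1),
                                                   conv_filters = c(4, 8, 8, 16),
                                                   dense_units = 32, n_classes = 3))),
               oracle_param_count(c(64, 48, 1), c(4, 8, 8, 16), dense = 32, classes = 3))
})

test_that("configs that cannot survive four pooling stages are refused", {
  expect_error(build_model(cnn_config(input_shape = c(8, 8, 1))), "too small")
  expect_error(cnn_config(n_classes = 1), "n_classes")
  expect_error(cnn_config(kernel_size = 4), "odd")
  expect_error(cnn_config(dropout_conv = 1), "Dropout")
})

test_that("softmax outputs form a probability simplex for random weights", {
  withr::with_seed(5, {
    for (s in 1:4) {
      m <- build_model(cnn_config(input_shape = c(32, 32, 1), n_classes = 5, seed = s))
      imgs <- lapply(1:6, function(i) {
        gray_image(matrix(sample(0:255, 32 * 32, TRUE), 32, 32))
      })
      p <- predict(m, imgs)
      probs <- as.matrix(p[paste0("class_", 1:5)])
      expect_true(all(probs >= 0))
      expect_lt(max(abs(rowSums(probs) - 1)), 1e-5)
    }
  })
})

test_that("prediction is stable across repeated calls and argmax breaks ties low", {
  m <- build_model(cnn_config(input_shape = c(32, 32, 1), n_classes = 3,
                              dropout_conv = 0, dropout_dense = 0, seed = 2))
  img <- list(gray_image(matrix(77L, 32, 32)))
  p1 <- predict(m, img); p2 <- predict(m, img)
  expect_identical(p1, p2)

  labs <- c("a", "b", "c")
  expect_equal(tlsimage:::argmax_label(matrix(c(0.2, 0.2, 0.6), 1), labs), "c")
  expect_equal(tlsimage:::argmax_label(matrix(c(0.5, 0.5, 0.0), 1), labs), "a")
})

test_that("wrong image shapes and unknown labels are refused", {
  m <- build_model(cnn_config(input_shape = c(32, 32, 1), n_classes = 2))
  expect_error(predict(m, list(gray_image(matrix(0L, 16, 16)))), "expects 32x32")
  toy <- toy_image_set(n_per_class = 2)
  expect_error(cnn_train(m, toy, labels = c("c0", "zz")), "outside the label set")
  expect_error(cnn_train(m, toy, labels = c("c0", "c1", "c2")), "output units")
})

test_that("zero training epochs leave the model untouched with empty history", {
  toy <- toy_image_set(n_per_class = 3)
  m <- build_model(cnn_config(input_shape = c(32, 32, 1), n_classes = 2, seed = 4))
  fit <- cnn_train(m, toy, epochs = 0)
  expect_equal(nrow(fit$history), 0)
  expect_identical(fit$model$weights, m$weights)
})

test_that("the network overfits a separable toy set and the loss descends", {
  toy <- toy_image_set(n_per_class = 10, seed = 8)
  cfg <- cnn_config(input_shape = c(32, 32, 1), n_classes = 2,
                    dropout_conv = 0, dropout_dense = 0, epochs = 30, seed = 3)
  fit <- cnn_train(build_model(cfg), toy)
  expect_equal(fit$history$accuracy[30], 1.0)
  expect_lte(fit$history$loss[30], fit$history$loss[1])

  # training with a fixed seed is reproducible
  fit2 <- cnn_train(build_model(cfg), toy)
  expect_equal(fit$history$loss, fit2$history$loss, tolerance = 1e-12)

  # and the fitted model separates what it saw
  p <- predict(fit, toy)
  expect_equal(p$.pred, as.character(toy$species))

  g <- glance(fit)
  expect_equal(g$epochs, 30L)
  expect_equal(nrow(tidy(fit)), 30)
})
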