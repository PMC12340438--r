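test_that("ablation flags add and remove exactly the right parameter groups", {
  full <- build_model(tiny_model_config())
  nm <- names(full$params)
  expect_true(all(c("dfs_W1", "attn_lambda", "attn_W_qkv", "mcpa_W_b",
                    "mcpa_alpha", "ph_W1", "head_W_y") %in% nm))
  ab1 <- build_model(ablation_config(tiny_model_config(), "AB1"))
  expect_false(any(startsWith(names(ab1$params), "dfs_")))
  ab2 <- build_model(ablation_config(tiny_model_config(), "AB2"))
  expect_equal(ab2$scales, 32L)                     # single full-length branch
  expect_equal(sum(startsWith(names(ab2$params), "emb_w")), 1L)
  ab3 <- build_model(ablation_config(tiny_model_config(), "AB3"))
  expect_false(any(startsWith(names(ab3$params), c("mcpa_", "ph_", "align_"))))
  # every ablation is strictly smaller than the full model
  for (m in list(ab1, ab2, ab3)) expect_lt(n_params(m), n_params(full))
  expect_error(model_config(use_dfs = FALSE, use_mcpa = FALSE),
               "one module")
})

test_that("forward pass is deterministic and produces probability rows", {
  model <- build_model(tiny_model_config())
  x <- tiny_batch(B = 4)
  p1 <- predict(model, x)
  p2 <- predict(model, x)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), rep(1, 4), tolerance = 1e-9, ignore_attr = TRUE)
  cls <- predict(model, x, type = "class")
  expect_true(all(cls %in% 0:1))
  expect_error(predict(model, tiny_batch(L = 16)), "length")
})

test_that("every learnable parameter group receives finite nonzero gradients", {
  set.seed(50)
  model <- build_model(tiny_model_config(seed = 2))
  x <- tiny_batch(B = 6, seed = 51)
  y <- c(0L, 1L, 0L, 1L, 1L, 0L)
  fw <- seizenet:::model_forward(model, x, training = FALSE)
  gr <- seizenet:::model_backward(model, fw$cache,
                                  seizenet:::cross_entropy_grad(fw$prob, y))
  expect_setequal(names(gr), names(model$params))
  for (nm in names(gr)) {
    expect_true(all(is.finite(gr[[nm]])), label = paste("finite grad", nm))
    expect_gt(max(abs(gr[[nm]])), 0, label = paste("nonzero grad", nm))
  }
})

test_that("analytic gradients match finite differences through all modules", {
  model <- build_model(tiny_model_config(seed = 3))
  x <- tiny_batch(B = 3, seed = 52)
  y <- c(0L, 1L, 1L)
  fw <- seizenet:::model_forward(model, x, training = FALSE)
  gr <- seizenet:::model_backward(model, fw$cache,
                                  seizenet:::cross_entropy_grad(fw$prob, y))
  set.seed(53)
  for (nm in c("dfs_W2", "emb_w_2", "attn_W_qkv", "attn_lambda", "attn_W_o",
               "mcpa_W_b", "mcpa_alpha", "align_w_1", "ph_W1", "ph_W2",
               "head_W_y")) {
    for (j in sample(length(model$params[[nm]]), min(2, length(model$params[[nm]])))) {
      num <- fd_grad(model, x, y, nm, j)
      expect_equal(gr[[nm]][j], num, tolerance = 5e-3 * max(1, abs(num)) + 1e-9,
                   label = sprintf("grad %s[%d]", nm, j))
    }
  }
})

test_that("training is reproducible, inert at zero learning rate, and able to fit", {
  cfg <- tiny_model_config(epochs = 1)
  model <- build_model(cfg)
  set.seed(60)
  x <- tiny_batch(B = 16, seed = 60)
  y <- rep(0:1, 8)
  # lr = 0: parameters unchanged
  fit0 <- train_model(model, x, y, learning_rate = 0, seed = 1)
  expect_equal(fit0$model$params, model$params, tolerance = 0)
  # same seed twice: identical history and parameters
  fa <- train_model(model, x, y, epochs = 2, seed = 5)
  fb <- train_model(model, x, y, epochs = 2, seed = 5)
  expect_identical(fa$history, fb$history)
  expect_identical(fa$model$params, fb$model$params)
  expect_false(identical(fa$history,
                         train_model(model, x, y, epochs = 2, seed = 6)$history))
  # a linearly separable toy (class shifts the signal mean) is fit to
  # high training accuracy
  set.seed(61)
  n <- 40
  yl <- rep(0:1, each = n / 2)
  xl <- matrix(rnorm(n * 32, sd = 0.3), n, 32) + outer(yl, rep(2, 32))
  fit <- train_model(build_model(tiny_model_config(seed = 9)), xl, yl,
                     epochs = 30, learning_rate = 5e-3, seed = 9)
  acc <- mean(predict(fit, xl, type = "class") == yl)
  expect_gte(acc, 0.95)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
})

test_that("fit accessors expose history and summary", {
  model <- build_model(tiny_model_config())
  x <- tiny_batch(B = 8)
  y <- rep(0:1, 4)
  fit <- train_model(model, x, y, epochs = 3, seed = 2,
                     validation = list(x = x, y = y))
  h <- tidy(fit)
  expect_equal(nrow(h), 3L)
  expect_true(all(c("epoch", "loss", "val_acc", "val_f1") %in% names(h)))
  g <- glance(fit)
  expect_equal(g$epochs, 3L)
  expect_equal(g$n_params, n_params(model))
  expect_match(g$config_hash, "^[0-9a-f]+$")
})

test_that("labeled eeg_batch objects feed training directly", {
  cfg <- tiny_model_config()
  b <- eeg_batch(tiny_batch(B = 8), sampling_rate = 32, labels = rep(0:1, 4))
  fit <- train_model(build_model(cfg), b, epochs = 1, seed = 1)
  expect_s3_class(fit, "seizenet_fit")
  expect_error(train_model(build_model(cfg), tiny_batch(B = 4)), "labels")
})
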