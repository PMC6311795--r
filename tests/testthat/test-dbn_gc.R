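test_that("a 128/100/80/45 stack pretrains and emits 45-wide abstractions", {
  withr::with_seed(17, data <- matrix(rnorm(200 * 128), 200, 128))
  dbn <- dbn_new(c(128, 100, 80, 45), seed = 1)
  fit <- pretrain(dbn, data, rbm_hyperparams(epochs = 2, seed = 2),
                  glia_params = list(alpha = 0.8, beta = 0.4, theta = 0.75,
                                     T_refractory = 5))
  a <- abstraction(fit, data[1:5, ])
  expect_equal(dim(a), c(5, 45))
  expect_true(all(a > 0 & a < 1))
  expect_error(pretrain(dbn, data[, 1:100], rbm_hyperparams(epochs = 1)),
               "v1")
})

test_that("layer-wise pretraining is greedy: later layers never touch earlier ones", {
  withr::with_seed(23, data <- matrix(rnorm(80 * 20), 80, 20))
  hp <- rbm_hyperparams(epochs = 3, seed = 9)
  dbn <- dbn_new(c(20, 12, 6), seed = 4)
  full <- pretrain(dbn, data, hp)
  # layer 1 trained alone with the same derived seed gives identical weights
  hp1 <- hp; hp1$seed <- hp$seed + 131 * 1
  solo <- train_rbm_gc(dbn$layers[[1]], data, hp1, chain = NULL)
  expect_identical(full$layers[[1]]$W, solo$rbm$W)
})

test_that("layer-1 reconstruction error decreases over pretraining epochs", {
  d <- eeg_feature_dataset(effect_size = 3, seed = 1)
  X <- standardize_features(d$features)$x[, 1:128]
  dbn <- dbn_new(c(128, 32), seed = 3)
  fit <- pretrain(dbn, X, rbm_hyperparams(epochs = 15, seed = 5))
  rec <- fit$pretrain_history[[1]]$recon_error
  expect_lt(rec[length(rec)], rec[1])
})

test_that("pretraining with alpha = 0 reproduces the plain DBN bit-for-bit", {
  withr::with_seed(29, data <- matrix(rnorm(100 * 24), 100, 24))
  hp <- rbm_hyperparams(epochs = 3, seed = 6)
  plain <- pretrain(dbn_new(c(24, 16, 8), seed = 11), data, hp)
  glia0 <- pretrain(dbn_new(c(24, 16, 8), seed = 11), data, hp,
                    glia_params = list(alpha = 0, beta = 0.4, theta = 0.75,
                                       T_refractory = 5))
  for (k in 1:2) {
    expect_identical(plain$layers[[k]]$W, glia0$layers[[k]]$W)
    expect_identical(plain$layers[[k]]$c, glia0$layers[[k]]$c)
  }
})

test_that("fine-tuning fits separable data and a zero learning rate is a no-op", {
  toy <- separable_toy(n = 60, seed = 19)
  X <- cbind(toy$x, matrix(rnorm(60 * 4), 60, 4))
  dbn <- dbn_new(c(6, 8, 4), seed = 21)
  dbn <- pretrain(dbn, X, rbm_hyperparams(epochs = 5, seed = 22))
  tuned <- finetune(dbn, X, toy$y, epochs = 60, seed = 23)
  expect_gte(mean(predict(tuned, X)$labels == toy$y), 0.95)
  frozen <- finetune(dbn, X, toy$y, lr = 0, epochs = 5, seed = 23)
  expect_identical(frozen$layers[[1]]$W, dbn$layers[[1]]$W)
  expect_identical(frozen$layers[[2]]$W, dbn$layers[[2]]$W)
  expect_error(finetune(dbn, X, rep(1, 60)), "single class")
})

test_that("stack+head gradients match finite differences", {
  withr::with_seed(5, { X <- matrix(rnorm(5 * 6), 5, 6); y <- c(0, 1, 0, 1, 1) })
  dbn <- dbn_new(c(6, 4, 3), seed = 2)
  dbn <- finetune(dbn, X, y, lr = 0, epochs = 1, seed = 3)  # head init only
  g <- gliadbn:::dbn_loss_grad(dbn, X, y)
  h <- 1e-6
  rel_err <- function(ana, perturb) {
    num <- ana * 0
    for (i in seq_along(num)) {
      lp <- gliadbn:::dbn_loss_grad(perturb(dbn, i, h), X, y)$loss
      lm <- gliadbn:::dbn_loss_grad(perturb(dbn, i, -h), X, y)$loss
      num[i] <- (lp - lm) / (2 * h)
    }
    max(abs(num - ana)) / max(abs(ana))
  }
  expect_lt(rel_err(g$gW[[1]], function(d, i, e) { d$layers[[1]]$W[i] <- d$layers[[1]]$W[i] + e; d }), 1e-4)
  expect_lt(rel_err(g$gW[[2]], function(d, i, e) { d$layers[[2]]$W[i] <- d$layers[[2]]$W[i] + e; d }), 1e-4)
  expect_lt(rel_err(g$gW_head, function(d, i, e) { d$head$W[i] <- d$head$W[i] + e; d }), 1e-4)
  expect_lt(rel_err(g$gc[[1]], function(d, i, e) { d$layers[[1]]$c[i] <- d$layers[[1]]$c[i] + e; d }), 1e-4)
})

test_that("abstractions are deterministic sigmoid outputs of the stated width", {
  dbn <- dbn_new(c(128, 110, 105, 90), seed = 13)
  x <- withr::with_seed(14, rnorm(128))
  a <- abstraction(dbn, x)
  expect_length(a, 90)
  expect_true(all(a > 0 & a < 1))
  expect_identical(a, abstraction(dbn, x))
  expect_error(abstraction(dbn, rnorm(64)), "mismatch")
})

test_that("seeded pretraining plus fine-tuning is bit-reproducible", {
  withr::with_seed(37, { X <- matrix(rnorm(40 * 10), 40, 10)
                         y <- rep(c(0, 1), 20) })
  run <- function() {
    dbn <- dbn_new(c(10, 6, 4), seed = 8)
    dbn <- pretrain(dbn, X, rbm_hyperparams(epochs = 3, seed = 9),
                    glia_params = list(alpha = 0.8, beta = 0.4, theta = 0.75,
                                       T_refractory = 5))
    finetune(dbn, X, y, epochs = 10, seed = 10)
  }
  a <- run(); b <- run()
  expect_identical(a$layers, b$layers)
  expect_identical(a$head, b$head)
})
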