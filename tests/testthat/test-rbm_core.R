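test_that("hidden pre-activations and probabilities follow the energy model", {
  r <- rbm_new(2, 1, visible_type = "binary")
  r$W <- matrix(c(0.5, -0.5), 2, 1); r$c <- 0.25
  expect_equal(hidden_preactivation(r, c(1, 0)), 0.75)
  r0 <- rbm_new(3, 2, visible_type = "binary"); r0$W[] <- 0
  expect_equal(hidden_preactivation(r0, c(1, 1, 0)), c(0, 0))
  # linearity in v with zero bias
  r$c <- 0
  expect_equal(hidden_preactivation(r, 3 * c(1, 0)),
               3 * hidden_preactivation(r, c(1, 0)))
  expect_error(hidden_preactivation(r, c(1, 0, 1)), "mismatch")
  expect_equal(hidden_probability(0), 0.5)
  expect_equal(hidden_probability(1), 1 / (1 + exp(-1)))
  expect_true(all(diff(hidden_probability(seq(-5, 5, 0.5))) > 0))
})

test_that("exact enumeration gives the normalized Boltzmann distribution", {
  r0 <- rbm_new(2, 2, visible_type = "binary"); r0$W[] <- 0
  for (v in list(c(0, 0), c(0, 1), c(1, 1)))
    expect_equal(exact_log_likelihood(r0, v), -log(4))
  withr::with_seed(8, {
    r <- rbm_new(3, 2, visible_type = "binary")
    r$W <- matrix(rnorm(6, 0, 1), 3, 2); r$b <- rnorm(3, 0, 0.5); r$c <- rnorm(2, 0, 0.5)
  })
  d <- exact_visible_distribution(r)
  expect_equal(sum(d$prob), 1, tolerance = 1e-10)
  big <- rbm_new(15, 10, visible_type = "binary")
  expect_error(exact_log_likelihood(big, rep(0, 15)), "too large")
})

test_that("analytic likelihood gradient matches central finite differences", {
  withr::with_seed(42, {
    r <- rbm_new(4, 3, visible_type = "binary")
    r$W <- matrix(rnorm(12, 0, 0.5), 4, 3)
    r$b <- rnorm(4, 0, 0.3); r$c <- rnorm(3, 0, 0.3)
  })
  v <- c(1, 0, 1, 1)
  g <- exact_ll_gradient(r, v)
  h <- 1e-5
  fd <- function(set, get) {
    ana <- get(g)
    num <- ana * 0
    for (i in seq_along(num)) {
      rp <- set(r, i, h); rm_ <- set(r, i, -h)
      num[i] <- (exact_log_likelihood(rp, v) - exact_log_likelihood(rm_, v)) / (2 * h)
    }
    max(abs(num - ana)) / max(abs(ana))
  }
  expect_lt(fd(function(r, i, e) { r$W[i] <- r$W[i] + e; r }, function(g) g$dW), 1e-5)
  expect_lt(fd(function(r, i, e) { r$b[i] <- r$b[i] + e; r }, function(g) g$db), 1e-5)
  expect_lt(fd(function(r, i, e) { r$c[i] <- r$c[i] + e; r }, function(g) g$dc), 1e-5)
})

test_that("Gibbs sampling converges to the enumerated distribution", {
  withr::with_seed(5, {
    r <- rbm_new(3, 2, visible_type = "binary")
    r$W <- matrix(rnorm(6, 0, 1), 3, 2); r$b <- rnorm(3, 0, 0.5); r$c <- rnorm(2, 0, 0.5)
  })
  emp <- rbm_gibbs_distribution(r, n_sweeps = 1e5, seed = 9)
  ex <- exact_visible_distribution(r)
  tv <- 0.5 * sum(abs(emp - ex$prob))
  expect_lt(tv, 0.02)
})

test_that("CD-1 raises the exact likelihood of a repeated pattern", {
  pattern <- c(1, 0, 1)
  data <- matrix(rep(pattern, 20), ncol = 3, byrow = TRUE)
  r <- rbm_new(3, 2, visible_type = "binary", seed = 1)
  ll0 <- exact_log_likelihood(r, pattern)
  fit <- train_rbm(r, data, rbm_hyperparams(lr = 0.1, epochs = 200,
                                            batch_size = 5, seed = 2))
  expect_gt(exact_log_likelihood(fit$rbm, pattern), ll0)
})

test_that("CD-1 decreases KL(data || model) on enumerable RBMs", {
  data <- matrix(c(1, 0, 1,
                   0, 1, 0), ncol = 3, byrow = TRUE)[rep(1:2, 10), ]
  emp <- rep(0, 8)
  codes <- data %*% c(4, 2, 1) + 1
  for (cd in codes) emp[cd] <- emp[cd] + 1 / length(codes)
  kl <- function(r) {
    d <- exact_visible_distribution(r)
    p_model <- d$prob[order(d$configs %*% c(4, 2, 1))]
    sel <- emp > 0
    sum(emp[sel] * log(emp[sel] / p_model[sel]))
  }
  for (s in 1:5) {
    r <- rbm_new(3, 2, visible_type = "binary", seed = s)
    fit <- train_rbm(r, data, rbm_hyperparams(lr = 0.05, epochs = 150,
                                              batch_size = 4, seed = s + 10))
    expect_lt(kl(fit$rbm), kl(r))
  }
})

test_that("mean-gradient convention makes duplicated rows equivalent to one row", {
  # saturate hidden biases so the Gibbs step is deterministic and the CD
  # delta can be compared exactly
  r <- rbm_new(3, 2, visible_type = "binary", seed = 3)
  r$c <- c(40, -40)
  v <- c(1, 0, 1)
  withr::with_seed(1, u1 <- cd_update(r, matrix(v, 1), lr = 0.1))
  withr::with_seed(1, u2 <- cd_update(r, rbind(v, v), lr = 0.1))
  expect_equal(u1$dW, u2$dW, tolerance = 1e-12)
  expect_equal(u1$db, u2$db, tolerance = 1e-12)
  u0 <- withr::with_seed(1, cd_update(r, rbind(v, v), lr = 0))
  expect_true(all(u0$dW == 0) && all(u0$db == 0) && all(u0$dc == 0))
  expect_error(cd_update(r, matrix(numeric(0), 0, 3)), "non-empty")
})

test_that("the discriminative RBM computes exact normalized posteriors", {
  m0 <- drbm_new(2, 4, init = "zero")
  p <- predict(m0, matrix(rnorm(10), 5, 2))
  expect_true(all(abs(p$prob - 0.5) < 1e-12))       # symmetric untrained model
  toy <- separable_toy()
  m <- train_drbm(toy$x, toy$y, n_hidden = 8, epochs = 60, seed = 2)
  pr <- predict(m, toy$x)
  expect_true(all(abs(rowSums(pr$prob) - 1) < 1e-10))
  expect_gte(mean(pr$labels == toy$y), 0.95)
  expect_error(train_drbm(toy$x, rep(1, nrow(toy$x)), n_hidden = 4),
               "single class")
  expect_error(predict(m, matrix(0, 2, 5)), "mismatch")
})

test_that("the trained discriminative RBM agrees with a logistic oracle on separable data", {
  toy <- separable_toy(n = 80, seed = 11)
  oracle <- suppressWarnings(stats::glm(toy$y ~ toy$x, family = binomial()))
  oracle_pred <- as.integer(stats::predict(oracle) > 0)
  expect_gte(mean(oracle_pred == toy$y), 0.95)       # set verified separable
  m <- train_drbm(toy$x, toy$y, n_hidden = 8, epochs = 60, seed = 3)
  expect_gte(mean(predict(m, toy$x)$labels == oracle_pred), 0.95)
})
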