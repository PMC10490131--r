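test_that("network forward pass composes affine maps with tanh on hidden layers", {
  # hand-computed 2-2-1 net
  net <- list(W = list(matrix(c(1, 0.5, -1, 2), 2, 2),
                       matrix(c(0.3, -0.7), 2, 1)),
              b = list(c(0.1, -0.2), 0.05))
  x <- c(0.4, -0.6)
  h <- tanh(c(1 * 0.4 + 0.5 * (-0.6) + 0.1, -1 * 0.4 + 2 * (-0.6) - 0.2))
  expect_equal(as.numeric(net_forward(net, matrix(x, 1))),
               0.3 * h[1] - 0.7 * h[2] + 0.05, tolerance = 1e-14)
  # all-zero weights: output equals the final bias, whatever the input
  net0 <- list(W = list(matrix(0, 2, 3), matrix(0, 3, 1)),
               b = list(rep(0, 3), 0.77))
  X <- matrix(rnorm(10), 5, 2)
  expect_equal(as.numeric(net_forward(net0, X)), rep(0.77, 5))
  expect_error(net_forward(net0, matrix(0, 2, 3)), "dimension mismatch")
})

test_that("loss is MSE plus an exact L2 penalty on weights only", {
  net <- list(W = list(matrix(c(0.5, -0.25), 1, 2), matrix(c(2, -1), 2, 1)),
              b = list(c(10, -10), 3))  # large biases must not be penalised
  X <- matrix(c(0.1, 0.2, 0.3), 3, 1)
  Y <- net_forward(net, X)  # perfect predictions by construction
  expect_identical(surrogate_loss(net, X, Y, l2_rate = 0), 0)
  w2 <- 0.5^2 + 0.25^2 + 2^2 + 1^2
  expect_equal(surrogate_loss(net, X, Y, l2_rate = 0.3), 0.3 * w2)
  # single sample, scalar output, error e: loss is e^2
  Ybad <- Y[1, , drop = FALSE] + 0.37
  expect_equal(surrogate_loss(net, X[1, , drop = FALSE], Ybad, 0), 0.37^2)
})

test_that("R backprop gradients match finite differences", {
  set.seed(8)
  net <- list(W = list(matrix(rnorm(12) / 3, 4, 3), matrix(rnorm(6) / 3, 3, 2)),
              b = list(rnorm(3) / 3, rnorm(2) / 3))
  X <- matrix(rnorm(20), 5, 4)
  Y <- matrix(rnorm(10), 5, 2)
  H <- rpinverse:::mlp_forward_cache(net, X)
  resid <- H[[3]] - Y
  g <- rpinverse:::mlp_backward(net, H, 2 * resid / length(resid),
                                input_grad = TRUE)
  lossf <- function(net) mean((net_forward(net, X) - Y)^2)
  h <- 1e-6
  for (k in 1:2) for (idx in c(1, length(net$W[[k]]))) {
    np <- net; np$W[[k]][idx] <- np$W[[k]][idx] + h
    nm <- net; nm$W[[k]][idx] <- nm$W[[k]][idx] - h
    expect_equal(g$gW[[k]][idx], (lossf(np) - lossf(nm)) / (2 * h),
                 tolerance = 1e-6)
  }
  np <- net; np$b[[1]][2] <- np$b[[1]][2] + h
  nm <- net; nm$b[[1]][2] <- nm$b[[1]][2] - h
  expect_equal(g$gb[[1]][2], (lossf(np) - lossf(nm)) / (2 * h),
               tolerance = 1e-6)
  # input gradient
  lossx <- function(X) mean((net_forward(net, X) - Y)^2)
  Xp <- X; Xp[2, 3] <- Xp[2, 3] + h
  Xm <- X; Xm[2, 3] <- Xm[2, 3] - h
  expect_equal(g$dX[2, 3], (lossx(Xp) - lossx(Xm)) / (2 * h),
               tolerance = 1e-6)
})

test_that("training memorises a trivially small dataset", {
  # universal-approximation sanity check: 10 rows, no regularisation
  b <- default_parameter_bounds()
  ds <- generate_dataset(b, 10, rates = 1, seed = 12,
                         split_fractions = c(train = 1, validation = 0,
                                             test = 0))
  ds$split <- "train"
  ds2 <- ds
  ds2$split <- "validation"
  ds <- rbind(ds, ds2)  # validate on the training rows: memorisation test
  class(ds) <- c("stress_dataset", "data.frame")
  net <- train_surrogate(ds, net_config(2, 32),
                         training_config(learning_rate = 5e-3,
                                         n_epochs = 4000, batch_size = 10,
                                         l2_rate = 0, n_repeats = 1,
                                         patience = 4000, lr_decay = 0.5,
                                         lr_decay_every = 800, seed = 13))
  expect_lt(evaluate_relative_error(net, ds, "validation"), 0.1)  # %
})

test_that("dominant regularisation shrinks weights toward zero", {
  ds <- tiny_dataset()
  cfg <- training_config(learning_rate = 0.01, n_epochs = 100,
                         batch_size = 256, n_repeats = 1,
                         patience = 100, restore_best = FALSE, seed = 5)
  cfg_big <- cfg
  cfg_big$l2_rate <- 1e3
  net_free <- train_surrogate(ds, net_config(2, 16), cfg)
  net_reg <- train_surrogate(ds, net_config(2, 16), cfg_big)
  w2 <- function(n) sum(vapply(n$W, function(w) sum(w^2), numeric(1)))
  expect_lt(w2(net_reg), 0.01 * w2(net_free))
})

test_that("relative-error metric is exact on a constant predictor", {
  # an all-zero net predicts 10^out_mean for both components; the metric
  # is then hand-computable from the dataset
  ds <- tiny_dataset()
  net <- tiny_surrogate()
  zero <- net
  for (k in seq_along(zero$W)) {
    zero$W[[k]][] <- 0
    zero$b[[k]][] <- 0
  }
  te <- ds[ds$split == "test", ]
  const <- 10^net$scalers$out_mean
  expected <- 100 * mean(cbind(abs(const[1] - te$sigma_xy) / te$sigma_xy,
                               abs(const[2] - te$N1) / te$N1))
  expect_equal(evaluate_relative_error(zero, ds, "test"), expected,
               tolerance = 1e-12)
  # scale-freeness: scaling stresses and labels jointly leaves it unchanged
  ds10 <- ds
  ds10$sigma_xy <- ds10$sigma_xy * 10
  ds10$N1 <- ds10$N1 * 10
  net10 <- net
  net10$scalers$out_mean <- net$scalers$out_mean + 1  # predictions x10
  expect_equal(evaluate_relative_error(net10, ds10, "test"),
               evaluate_relative_error(net, ds, "test"), tolerance = 1e-10)
})

test_that("surrogate checkpoints round-trip through JSON", {
  net <- tiny_surrogate()
  tmp <- tempfile(fileext = ".json")
  save_surrogate(net, tmp)
  net2 <- load_surrogate(tmp)
  p <- fix_params()
  rates <- c(0.01, 1, 100)
  expect_equal(predict_stress(net2, p, rates), predict_stress(net, p, rates),
               tolerance = 1e-12)
  expect_equal(net2$net_config$n_hidden_layers, net$net_config$n_hidden_layers)
})

test_that("trained surrogate beats the constant predictor and is reproducible", {
  ds <- tiny_dataset()
  net <- tiny_surrogate()
  err <- evaluate_relative_error(net, ds, "test")
  zero <- net
  for (k in seq_along(zero$W)) { zero$W[[k]][] <- 0; zero$b[[k]][] <- 0 }
  expect_lt(err, evaluate_relative_error(zero, ds, "test") / 2)
  # same seeds, same net
  cfg <- training_config(n_epochs = 10, batch_size = 256, n_repeats = 1,
                         patience = 10, seed = 77)
  n1 <- train_surrogate(ds, net_config(2, 8), cfg)
  n2 <- train_surrogate(ds, net_config(2, 8), cfg)
  expect_identical(n1$W, n2$W)
})

test_that("architecture scan tabulates one error per grid cell", {
  ds <- tiny_dataset()
  cfg <- training_config(n_epochs = 8, batch_size = 256, n_repeats = 1,
                         patience = 8, seed = 3)
  grid <- architecture_scan(ds, hidden_layers = c(1, 2), neurons = 8,
                            train_cfg = cfg)
  expect_equal(nrow(grid), 2)
  expect_true(all(is.finite(grid$test_rel_err)))
})
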