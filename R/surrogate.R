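#' Network architecture configuration
#'
#' A fully-connected feed-forward network mapping the six inputs (five
#' molecular parameters plus the shear rate) to the two steady stresses
#' (shear stress and first normal stress difference). Hidden layers use
#' the hyperbolic tangent; the final transformation is affine (no
#' nonlinearity on the output layer).
#'
#' @param n_hidden_layers Number of hidden layers (default 5).
#' @param neurons_per_layer Width of every hidden layer (default 192).
#' @param input_dim,output_dim Input and output dimensions.
#' @return A `net_config` list.
#' @export
net_config <- function(n_hidden_layers = 5, neurons_per_layer = 192,
                       input_dim = 6, output_dim = 2) {
  stopifnot(n_hidden_layers >= 1, neurons_per_layer >= 1,
            input_dim >= 1, output_dim >= 1)
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 neurons_per_layer = as.integer(neurons_per_layer),
                 input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim),
                 activation = "tanh"),
            class = "net_config")
}

#' Training configuration for the surrogate
#'
#' @param learning_rate ADAM step size (around 1e-3).
#' @param l2_rate L2 regularisation weight \eqn{\xi} on the connection
#'   weights (biases excluded).
#' @param n_epochs Epoch cap.
#' @param batch_size Minibatch size.
#' @param n_repeats Independent training runs; the net with the lowest
#'   validation relative error is kept (default 3).
#' @param patience Early-stopping patience in epochs on the validation
#'   relative error.
#' @param beta1,beta2 ADAM moment decays.
#' @param lr_decay,lr_decay_every Step-decay schedule: the learning rate
#'   is multiplied by `lr_decay` every `lr_decay_every` epochs (defaults
#'   halve it every 40 epochs; set `lr_decay = 1` for a constant rate).
#' @param seed RNG seed for initialisation and shuffling.
#' @param restore_best Return the weights of the epoch with the lowest
#'   validation relative error (default) rather than the final epoch.
#' @param verbose Print per-epoch progress.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-3, l2_rate = 1e-6,
                            n_epochs = 200, batch_size = 1024,
                            n_repeats = 3, patience = 50,
                            beta1 = 0.9, beta2 = 0.999,
                            lr_decay = 0.5, lr_decay_every = 40,
                            seed = NULL, restore_best = TRUE,
                            verbose = FALSE) {
  stopifnot(learning_rate > 0, l2_rate >= 0, n_epochs >= 1,
            batch_size >= 1, n_repeats >= 1, lr_decay > 0, lr_decay <= 1,
            lr_decay_every >= 1)
  structure(list(learning_rate = learning_rate, l2_rate = l2_rate,
                 n_epochs = as.integer(n_epochs),
                 batch_size = as.integer(batch_size),
                 n_repeats = as.integer(n_repeats),
                 patience = as.integer(patience),
                 beta1 = beta1, beta2 = beta2,
                 lr_decay = lr_decay,
                 lr_decay_every = as.integer(lr_decay_every),
                 seed = seed, restore_best = isTRUE(restore_best),
                 verbose = isTRUE(verbose)),
            class = "training_config")
}

# ---- feature scaling ------------------------------------------------------
# Inputs: eta_p, tau_D, tau_R and the shear rate enter as log10 (they span
# 3-8 decades), chi_max and beta linearly; all are then mapped affinely to
# [-1, 1] over the parameter bounds / observed rate range.  Outputs are
# log10-transformed and standardised with train-split moments.  The
# relative-error metric is always evaluated back in raw stress space.

make_scalers <- function(dataset, bounds) {
  tr <- dataset[dataset$split == "train", ]
  if (!nrow(tr)) tr <- dataset
  in_log <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)  # 5 params + rate
  lo <- c(ifelse(bounds$scale == "log", log10(bounds$min), bounds$min),
          log10(min(tr$shear_rate)))
  hi <- c(ifelse(bounds$scale == "log", log10(bounds$max), bounds$max),
          log10(max(tr$shear_rate)))
  hi <- ifelse(hi > lo, hi, lo + 1)   # guard degenerate feature ranges
  ylog <- cbind(log10(tr$sigma_xy), log10(tr$N1))
  osd <- apply(ylog, 2, sd)
  osd[!is.finite(osd) | osd <= 0] <- 1
  list(in_log = in_log, in_lo = lo, in_hi = hi,
       out_mean = colMeans(ylog), out_sd = osd)
}

scale_inputs <- function(sc, raw) {
  # raw: n x 6 matrix (eta_p, tau_D, tau_R, chi_max, beta, shear_rate)
  t <- raw
  t[, sc$in_log] <- log10(raw[, sc$in_log, drop = FALSE])
  sweep(sweep(t, 2, (sc$in_lo + sc$in_hi) / 2), 2, (sc$in_hi - sc$in_lo) / 2, "/")
}

scale_outputs <- function(sc, raw) {
  sweep(sweep(log10(raw), 2, sc$out_mean), 2, sc$out_sd, "/")
}

unscale_outputs <- function(sc, y) {
  10^sweep(sweep(y, 2, sc$out_sd, "*"), 2, sc$out_mean, "+")
}

dataset_matrices <- function(dataset, split, sc) {
  d <- dataset[dataset$split == split, ]
  raw <- as.matrix(d[, c(.RP_FREE_PARAMS, "shear_rate")])
  list(X = scale_inputs(sc, raw), Y = scale_outputs(sc, cbind(d$sigma_xy, d$N1)),
       raw_Y = cbind(d$sigma_xy, d$N1))
}

# ---- network core ---------------------------------------------------------

init_layers <- function(cfg) {
  sizes <- c(cfg$input_dim,
             rep(cfg$neurons_per_layer, cfg$n_hidden_layers),
             cfg$output_dim)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (k in seq_along(W)) {
    lim <- sqrt(6 / (sizes[k] + sizes[k + 1]))  # Glorot uniform
    W[[k]] <- matrix(runif(sizes[k] * sizes[k + 1], -lim, lim),
                     sizes[k], sizes[k + 1])
    b[[k]] <- numeric(sizes[k + 1])
  }
  list(W = W, b = b, sizes = sizes)
}

#' Forward pass through a surrogate network (scaled space)
#'
#' Composes the layer maps \eqn{y^k = \alpha_k(W_k x^{k-1} + b_k)} with
#' tanh on hidden layers and identity on the output layer. Operates on
#' scaled inputs/outputs; [predict_stress()] is the raw-space interface.
#'
#' @param net A `surrogate_net` (or a bare layer list with `W` and `b`).
#' @param X Matrix of scaled inputs, one row per sample.
#' @return Matrix of scaled outputs.
#' @export
net_forward <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != nrow(net$W[[1]]))
    stop("input dimension mismatch: expected ", nrow(net$W[[1]]), " features")
  H <- X
  L <- length(net$W)
  for (k in seq_len(L)) {
    H <- sweep(H %*% net$W[[k]], 2, net$b[[k]], "+")
    if (k < L) H <- tanh(H)
  }
  H
}

# forward with cached activations (H[[1]] = input, H[[k+1]] = layer k output)
mlp_forward_cache <- function(net, X) {
  L <- length(net$W)
  H <- vector("list", L + 1L)
  H[[1]] <- X
  for (k in seq_len(L)) {
    Z <- sweep(H[[k]] %*% net$W[[k]], 2, net$b[[k]], "+")
    H[[k + 1L]] <- if (k < L) tanh(Z) else Z
  }
  H
}

# backprop: given dLoss/dY (n x out), return weight/bias gradients and,
# if requested, the gradient w.r.t. the input rows
mlp_backward <- function(net, H, dY, input_grad = FALSE) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dY
  for (k in rev(seq_len(L))) {
    gW[[k]] <- crossprod(H[[k]], delta)
    gb[[k]] <- colSums(delta)
    if (k > 1L) {
      delta <- (delta %*% t(net$W[[k]])) * (1 - H[[k]]^2)
    } else if (input_grad) {
      delta <- delta %*% t(net$W[[1]])
    }
  }
  list(gW = gW, gb = gb, dX = if (input_grad) delta else NULL)
}

#' Training loss: mean squared error plus L2 weight penalty
#'
#' \eqn{Loss = \frac{1}{M}\sum_j (\sigma_j - \hat\sigma_j)^2 +
#' \xi \sum_w w^2}, with the first mean taken over all entries of the
#' batch (rows and stress components) in scaled space, and the penalty
#' over connection weights only (biases excluded).
#'
#' @param net A `surrogate_net` or layer list.
#' @param X,Y Scaled input and target matrices (a batch).
#' @param l2_rate Regularisation weight \eqn{\xi}.
#' @return Scalar loss.
#' @export
surrogate_loss <- function(net, X, Y, l2_rate = 0) {
  pred <- net_forward(net, X)
  mse <- mean((pred - Y)^2)
  if (l2_rate > 0)
    mse <- mse + l2_rate * sum(vapply(net$W, function(w) sum(w^2), numeric(1)))
  mse
}

adam_init <- function(layers) {
  list(mW = lapply(layers$W, function(w) w * 0),
       vW = lapply(layers$W, function(w) w * 0),
       mb = lapply(layers$b, function(b) b * 0),
       vb = lapply(layers$b, function(b) b * 0), t = 0L)
}

adam_update <- function(layers, g, st, lr, beta1, beta2, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (k in seq_along(layers$W)) {
    st$mW[[k]] <- beta1 * st$mW[[k]] + (1 - beta1) * g$gW[[k]]
    st$vW[[k]] <- beta2 * st$vW[[k]] + (1 - beta2) * g$gW[[k]]^2
    layers$W[[k]] <- layers$W[[k]] -
      lr * (st$mW[[k]] / c1) / (sqrt(st$vW[[k]] / c2) + eps)
    st$mb[[k]] <- beta1 * st$mb[[k]] + (1 - beta1) * g$gb[[k]]
    st$vb[[k]] <- beta2 * st$vb[[k]] + (1 - beta2) * g$gb[[k]]^2
    layers$b[[k]] <- layers$b[[k]] -
      lr * (st$mb[[k]] / c1) / (sqrt(st$vb[[k]] / c2) + eps)
  }
  list(layers = layers, st = st)
}

#' Train the neural-network surrogate of the constitutive map
#'
#' Fits the fully-connected network to forward-model stresses by ADAM
#' minimisation of the regularised mean-squared-error loss
#' [surrogate_loss()] in scaled space. Training is repeated
#' `n_repeats` times from independent initialisations and the network
#' with the lowest validation relative error (raw stress space) is
#' returned. Early stopping monitors the validation relative error with
#' the configured patience; the best-epoch weights are restored.
#'
#' @param dataset A `stress_dataset` from [generate_dataset()] with all
#'   three splits.
#' @param net_cfg A [net_config()].
#' @param train_cfg A [training_config()].
#' @param bounds The [param_bounds] the dataset was sampled from (fixes
#'   the input scaling).
#' @return A `surrogate_net`: layer weights/biases, scalers, configs and
#'   per-epoch validation history of the selected repeat.
#' @export
train_surrogate <- function(dataset, net_cfg = net_config(),
                            train_cfg = training_config(),
                            bounds = default_parameter_bounds()) {
  stopifnot(inherits(dataset, "stress_dataset") || is.data.frame(dataset))
  splits <- unique(dataset$split)
  if (!all(c("train", "validation") %in% splits))
    stop("dataset must contain 'train' and 'validation' splits")
  sc <- make_scalers(dataset, bounds)
  tr <- dataset_matrices(dataset, "train", sc)
  va <- dataset_matrices(dataset, "validation", sc)
  if (!is.null(train_cfg$seed)) set.seed(train_cfg$seed)
  best_net <- NULL
  best_val <- Inf
  for (rep_i in seq_len(train_cfg$n_repeats)) {
    fit <- .train_once(tr, va, sc, net_cfg, train_cfg)
    if (train_cfg$verbose)
      message(sprintf("repeat %d: validation relative error %.3f%%",
                      rep_i, fit$val_err))
    if (is.finite(fit$val_err) && fit$val_err < best_val) {
      best_val <- fit$val_err
      best_net <- fit
    }
  }
  if (is.null(best_net))
    stop("all training repeats diverged (loss became non-finite)")
  structure(list(W = best_net$layers$W, b = best_net$layers$b,
                 scalers = sc, net_config = net_cfg,
                 training_config = train_cfg,
                 history = best_net$history,
                 validation_error = best_val,
                 format_version = 1L),
            class = "surrogate_net")
}

# One training run: R initialises the layers (R RNG, reproducible under
# set.seed) and delegates the minibatch ADAM loop to the compiled core.
.train_once <- function(tr, va, sc, net_cfg, train_cfg) {
  layers <- init_layers(net_cfg)
  shuffle_seed <- sample.int(.Machine$integer.max, 1L)
  fit <- .rp_mlp_train_cpp(tr$X, tr$Y, va$X, va$raw_Y,
                           sc$out_mean, sc$out_sd,
                           layers$W, layers$b,
                           train_cfg$learning_rate, train_cfg$l2_rate,
                           train_cfg$n_epochs,
                           min(train_cfg$batch_size, nrow(tr$X)),
                           train_cfg$beta1, train_cfg$beta2,
                           train_cfg$lr_decay, train_cfg$lr_decay_every,
                           train_cfg$patience, shuffle_seed,
                           isTRUE(train_cfg$restore_best),
                           train_cfg$verbose)
  if (isTRUE(fit$diverged)) return(list(val_err = Inf))
  history <- data.frame(epoch = seq_along(fit$loss_history),
                        loss = fit$loss_history,
                        val_rel_err = fit$val_history)
  val_err <- if (isTRUE(train_cfg$restore_best)) fit$val_err else
    history$val_rel_err[nrow(history)]
  list(layers = list(W = fit$W, b = lapply(fit$b, as.numeric)),
       val_err = val_err, history = history)
}

# mean relative error (%) of a layer list on pre-scaled matrices
.rel_err_scaled <- function(layers, mats, sc) {
  pred <- unscale_outputs(sc, net_forward(layers, mats$X))
  100 * mean(abs(pred - mats$raw_Y) / abs(mats$raw_Y))
}

#' Predict steady stresses with the surrogate (raw space)
#'
#' @param net A trained `surrogate_net`.
#' @param params A [rolie_poly_params()] object.
#' @param rates Shear rates, 1/s, all `> 0`.
#' @return Data frame with columns `shear_rate`, `sigma_xy`, `N1` (Pa).
#' @export
predict_stress <- function(net, params, rates) {
  stopifnot(inherits(net, "surrogate_net"), all(rates > 0))
  raw <- cbind(matrix(unlist(params[.RP_FREE_PARAMS]), length(rates), 5,
                      byrow = TRUE), rates)
  Y <- unscale_outputs(net$scalers, net_forward(net, scale_inputs(net$scalers, raw)))
  data.frame(shear_rate = rates, sigma_xy = Y[, 1], N1 = Y[, 2])
}

#' Mean relative error of a surrogate on a dataset split
#'
#' The surrogate-quality metric: the arithmetic mean over rows and over
#' the two stress components of `|predicted - true| / |true|`, as a
#' percentage, evaluated in raw stress space.
#'
#' @param net A trained `surrogate_net`.
#' @param dataset A `stress_dataset`.
#' @param split Which split to score (default `"test"`).
#' @return Percentage (scalar).
#' @export
evaluate_relative_error <- function(net, dataset, split = "test") {
  mats <- dataset_matrices(dataset, split, net$scalers)
  if (!nrow(mats$X)) stop("split '", split, "' is empty")
  .rel_err_scaled(net, mats, net$scalers)
}

#' Objective and gradient of the surrogate-backed inverse problem
#'
#' Evaluates the relative-error objective at `bounded_map(omega)` through
#' the surrogate and its exact gradient with respect to the trial vector
#' by backpropagation through the network, the feature scaling and the
#' sigmoid bound map (automatic differentiation of the full chain).
#'
#' @param net A trained `surrogate_net`.
#' @param omega Trial vector (length 5).
#' @param bounds A [param_bounds] table.
#' @param data Observed `steady_shear_curve`.
#' @param eta_s,delta Fixed constants.
#' @return List with `error` (scalar) and `grad` (length-5 vector).
#' @export
surrogate_error_grad <- function(net, omega, bounds, data,
                                 eta_s = 1e-3, delta = -0.5) {
  theta <- bounded_map(omega, bounds, eta_s, delta)
  th <- unlist(theta[.RP_FREE_PARAMS])
  rates <- data$shear_rate
  M <- length(rates)
  raw <- cbind(matrix(th, M, 5, byrow = TRUE), rates)
  sc <- net$scalers
  X <- scale_inputs(sc, raw)
  H <- mlp_forward_cache(net, X)
  ys <- H[[length(H)]]
  pred <- unscale_outputs(sc, ys)
  obs <- cbind(data$sigma_xy, data$N1)
  err <- mean(abs(pred - obs) / obs)
  # dE/dys = sign(pred-obs)/obs * pred * ln10 * out_sd / (2M)
  dY <- sweep(sign(pred - obs) / obs * pred * log(10), 2, sc$out_sd, "*") /
    length(obs)
  dX <- mlp_backward(net, H, dY, input_grad = TRUE)$dX
  dpar <- colSums(dX)[1:5]                      # d err / d scaled input
  half_range <- (sc$in_hi[1:5] - sc$in_lo[1:5]) / 2
  dx_dth <- ifelse(sc$in_log[1:5], 1 / (th * log(10)), 1) / half_range
  g <- 1 / (1 + exp(-omega))
  dth_dom <- (bounds$max - bounds$min) * g * (1 - g)
  list(error = err, grad = as.numeric(dpar * dx_dth * dth_dom))
}

#' Save/load a surrogate checkpoint (portable JSON)
#'
#' The checkpoint stores layer sizes, activation, weights, biases and
#' scaler constants with a format-version field, as plain JSON.
#'
#' @param net A `surrogate_net`.
#' @param path File path.
#' @return `load_surrogate` returns the `surrogate_net`.
#' @export
save_surrogate <- function(net, path) {
  stopifnot(inherits(net, "surrogate_net"))
  obj <- list(format_version = net$format_version,
              activation = "tanh",
              sizes = c(net$net_config$input_dim,
                        rep(net$net_config$neurons_per_layer,
                            net$net_config$n_hidden_layers),
                        net$net_config$output_dim),
              W = lapply(net$W, function(w) as.numeric(w)),
              b = net$b,
              scalers = net$scalers,
              validation_error = net$validation_error)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(obj$sizes)
  L <- length(sizes) - 1L
  W <- lapply(seq_len(L), function(k)
    matrix(obj$W[[k]], sizes[k], sizes[k + 1]))
  sc <- obj$scalers
  sc$in_log <- as.logical(sc$in_log)
  cfg <- net_config(n_hidden_layers = L - 1L,
                    neurons_per_layer = if (L > 1L) sizes[2] else sizes[1],
                    input_dim = sizes[1], output_dim = sizes[L + 1L])
  structure(list(W = W, b = lapply(obj$b, as.numeric), scalers = sc,
                 net_config = cfg, training_config = NULL,
                 history = NULL,
                 validation_error = obj$validation_error,
                 format_version = obj$format_version),
            class = "surrogate_net")
}

#' Scan network sizes and report test relative errors
#'
#' Trains one surrogate per (hidden layers, neurons) grid cell and
#' tabulates the test-split relative error, to locate the architecture
#' with the lowest overall error.
#'
#' @param dataset A `stress_dataset`.
#' @param hidden_layers,neurons Grid axes.
#' @param train_cfg A [training_config()].
#' @param bounds The sampling bounds.
#' @return Data frame with columns `hidden_layers`, `neurons`,
#'   `test_rel_err` (%).
#' @export
architecture_scan <- function(dataset, hidden_layers = 2:6,
                              neurons = c(64, 128, 192, 256),
                              train_cfg = training_config(),
                              bounds = default_parameter_bounds()) {
  grid <- expand.grid(hidden_layers = hidden_layers, neurons = neurons)
  grid$test_rel_err <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- net_config(grid$hidden_layers[i], grid$neurons[i])
    net <- train_surrogate(dataset, cfg, train_cfg, bounds)
    grid$test_rel_err[i] <- evaluate_relative_error(net, dataset, "test")
  }
  grid
}
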