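#' Sample molecular parameter sets from a bounds table
#'
#' Draws each parameter independently and uniformly on its declared
#' sampling scale: uniform in `log10` for log-scaled parameters
#' (viscosity and relaxation times, whose ranges span 3--4 decades),
#' uniform in value for linear ones (`chi_max`, `beta`).
#'
#' @param bounds A [param_bounds] table.
#' @param n Number of parameter sets.
#' @param seed Optional RNG seed (same seed, same draws).
#' @return A data frame with columns `eta_p`, `tau_D`, `tau_R`,
#'   `chi_max`, `beta`, one row per set.
#' @export
sample_parameters <- function(bounds, n, seed = NULL) {
  stopifnot(inherits(bounds, "param_bounds"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  cols <- lapply(seq_len(nrow(bounds)), function(i) {
    if (bounds$scale[i] == "log") {
      10^runif(n, log10(bounds$min[i]), log10(bounds$max[i]))
    } else {
      runif(n, bounds$min[i], bounds$max[i])
    }
  })
  names(cols) <- bounds$param
  as.data.frame(cols)
}

#' Generate a forward-model stress dataset for surrogate training
#'
#' Samples `n_param_sets` molecular parameter sets, evaluates the steady
#' flow curve of each over the rate grid with the forward model, and
#' assigns each parameter set wholly to the train, validation or test
#' split (splitting by fluid rather than by row prevents leakage between
#' rates of the same fluid). Parameter sets on which the forward solver
#' fails are resampled (with a message).
#'
#' @param bounds A [param_bounds] table.
#' @param n_param_sets Number of fluids to sample (default 15000).
#' @param rates Shear-rate grid shared by all sets.
#' @param seed RNG seed for sampling.
#' @param split_fractions Train/validation/test fractions of the
#'   parameter sets; the default reproduces the 10000/3000/2000 split of
#'   a 15000-set run.
#' @param eta_s,delta Fixed constants of every sampled fluid.
#' @return A `stress_dataset` data frame with columns `set_id`, `eta_p`,
#'   `tau_D`, `tau_R`, `chi_max`, `beta`, `shear_rate`, `sigma_xy`, `N1`,
#'   `split`.
#' @export
generate_dataset <- function(bounds, n_param_sets = 15000,
                             rates = shear_rate_grid(), seed = NULL,
                             split_fractions = c(train = 10, validation = 3,
                                                 test = 2) / 15,
                             eta_s = 1e-3, delta = -0.5) {
  stopifnot(abs(sum(split_fractions) - 1) < 1e-8, all(rates > 0))
  if (!is.null(seed)) set.seed(seed)
  theta <- sample_parameters(bounds, n_param_sets)
  n_rate <- length(rates)
  blocks <- vector("list", n_param_sets)
  for (i in seq_len(n_param_sets)) {
    repeat {
      s <- .rp_steady_sweep_cpp(rates, theta$eta_p[i], theta$tau_D[i],
                                theta$tau_R[i], theta$chi_max[i],
                                theta$beta[i], eta_s, delta)
      if (all(s$converged)) break
      message(sprintf("forward solver failed for sampled set %d; resampling", i))
      theta[i, ] <- sample_parameters(bounds, 1)
    }
    blocks[[i]] <- data.frame(
      set_id = i,
      eta_p = theta$eta_p[i], tau_D = theta$tau_D[i], tau_R = theta$tau_R[i],
      chi_max = theta$chi_max[i], beta = theta$beta[i],
      shear_rate = rates, sigma_xy = s$sigma_xy, N1 = s$N1)
  }
  out <- do.call(rbind, blocks)
  n_train <- round(split_fractions[[1]] * n_param_sets)
  n_val <- round(split_fractions[[2]] * n_param_sets)
  lab <- rep("test", n_param_sets)
  lab[seq_len(n_train)] <- "train"
  if (n_val > 0) lab[n_train + seq_len(min(n_val, n_param_sets - n_train))] <- "validation"
  out$split <- lab[out$set_id]
  class(out) <- c("stress_dataset", "data.frame")
  attr(out, "rates") <- rates
  attr(out, "seed") <- seed
  out
}

#' Read/write a stress dataset as CSV
#'
#' Plain-text columnar round trip of the training dataset, with `'#'`
#' comment lines tolerated on reading.
#'
#' @param dataset A `stress_dataset` data frame.
#' @param path File path.
#' @return `read_dataset_csv` returns the `stress_dataset`.
#' @export
write_dataset_csv <- function(dataset, path) {
  write.csv(as.data.frame(dataset), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  out <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("eta_p", "tau_D", "tau_R", "chi_max", "beta",
            "shear_rate", "sigma_xy", "N1", "split")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("dataset file is missing columns: ", paste(miss, collapse = ", "))
  class(out) <- c("stress_dataset", "data.frame")
  out
}
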