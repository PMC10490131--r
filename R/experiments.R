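#' Add multiplicative white noise to a flow curve
#'
#' Each stress value (both shear stress and first normal stress
#' difference, independently at every rate) is multiplied by
#' \eqn{(1 + u)} with `u` i.i.d. noise bounded by the given maximum
#' fractional level; shear rates are untouched. The default noise is
#' uniform on `[-level, +level]` (the level is a hard bound); a
#' truncated-Gaussian option (`level` = 2 standard deviations, clipped
#' at `level`) is available since "white noise of a maximum percentage"
#' admits either reading.
#'
#' @param curve A `steady_shear_curve`.
#' @param level Maximum fractional deviation, `>= 0` (e.g. 0.03 = 3%).
#' @param seed Optional RNG seed (same seed, same noisy curve).
#' @param dist `"uniform"` (default) or `"gaussian"`.
#' @return The noisy curve; bit-identical to the input when `level = 0`.
#' @export
add_noise <- function(curve, level, seed = NULL,
                      dist = c("uniform", "gaussian")) {
  dist <- match.arg(dist)
  stopifnot(level >= 0)
  if (level == 0) return(curve)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(curve)
  u <- if (dist == "uniform") {
    runif(2 * n, -level, level)
  } else {
    pmin(pmax(stats::rnorm(2 * n, 0, level / 2), -level), level)
  }
  curve$sigma_xy <- curve$sigma_xy * (1 + u[seq_len(n)])
  curve$N1 <- curve$N1 * (1 + u[n + seq_len(n)])
  curve
}

#' Noise-study design
#'
#' @param n_realizations Independent noisy curves per level (default 8).
#' @param n_restarts_per_realization Inverse-solver restarts per noisy
#'   curve (default 10).
#' @param seed Master seed of the study.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(n_realizations = 8, n_restarts_per_realization = 10,
                       seed = NULL) {
  stopifnot(n_realizations >= 1, n_restarts_per_realization >= 1)
  structure(list(n_realizations = as.integer(n_realizations),
                 n_restarts = as.integer(n_restarts_per_realization),
                 seed = seed),
            class = "noise_spec")
}

#' Robustness of the inverse solution to stress-data noise
#'
#' For each noise level: generates `n_realizations` noisy copies of the
#' noise-free curve of `truth`, solves each with
#' `n_restarts_per_realization` random restarts, pools the per-restart
#' estimates, and reports the pooled mean and standard deviation of each
#' parameter normalised by the noise-free (level-0) solution. At level 0
#' the normalised means are exactly 1 by construction and the SDs
#' reflect restart scatter only.
#'
#' @param truth A [rolie_poly_params()] object generating the data.
#' @param levels Noise levels; must include 0 (the normaliser).
#' @param spec A [noise_spec()].
#' @param bounds Search box for the inversions.
#' @param config An [inverse_config()] (its `n_restarts`/`seed` are
#'   overridden by the study design).
#' @param backend Prediction backend for the inversions.
#' @param rates Shear-rate grid of the input curves.
#' @param dist Noise distribution, see [add_noise()].
#' @return A tidy data frame, one row per level and parameter:
#'   `level`, `param`, `norm_mean`, `norm_sd`, `n_pooled`.
#' @export
noise_study <- function(truth, levels, spec = noise_spec(),
                        bounds = default_parameter_bounds(),
                        config = inverse_config(),
                        backend = direct_backend(),
                        rates = shear_rate_grid(),
                        dist = "uniform") {
  if (!any(levels == 0))
    stop("levels must include 0 (the normalising noise-free case)")
  base <- steady_curve(truth, rates)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max / 2L,
                      length(levels) * spec$n_realizations + length(levels))
  cfg <- config
  cfg$n_restarts <- spec$n_restarts
  rows <- list()
  normalizer <- NULL
  pooled <- list()
  for (li in seq_along(levels)) {
    lev <- levels[li]
    ests <- list()
    for (k in seq_len(spec$n_realizations)) {
      sidx <- (li - 1L) * spec$n_realizations + k
      noisy <- add_noise(base, lev, seed = seeds[sidx], dist = dist)
      cfg$seed <- seeds[length(levels) * spec$n_realizations + li] + k
      res <- try(solve_inverse(noisy, bounds, cfg, backend), silent = TRUE)
      if (inherits(res, "try-error")) {
        message(sprintf("inversion failed at level %g, realization %d", lev, k))
        next
      }
      ests[[length(ests) + 1L]] <- res$estimates[res$used, , drop = FALSE]
    }
    est <- do.call(rbind, ests)
    pooled[[li]] <- est
  }
  normalizer <- colMeans(pooled[[which(levels == 0)[1]]])
  for (li in seq_along(levels)) {
    est <- pooled[[li]]
    rows[[li]] <- data.frame(
      level = levels[li],
      param = .RP_FREE_PARAMS,
      norm_mean = colMeans(est) / normalizer,
      norm_sd = apply(est, 2, sd) / normalizer,
      n_pooled = nrow(est),
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- spec$seed
  out
}

#' Power-law fit of a parameter against concentration
#'
#' Ordinary least squares of `ln(value)` on `ln(concentration)`; the
#' slope is the power-law exponent and `exp(intercept)` the prefactor.
#'
#' @param concentrations Positive concentrations (e.g. mg/mL), length
#'   `>= 3`.
#' @param values Positive parameter values, same length.
#' @return A `power_law_fit` list: `exponent`, `prefactor`, `r_squared`,
#'   and the input data.
#' @examples
#' power_law_fit(c(1, 2, 4), c(3, 12, 48))$exponent  # exactly 2
#' @export
power_law_fit <- function(concentrations, values) {
  if (length(concentrations) < 3 || length(values) != length(concentrations))
    stop("need at least 3 (concentration, value) pairs of equal length")
  if (any(concentrations <= 0) || any(values <= 0))
    stop("power-law fit requires strictly positive inputs")
  fit <- lm(log(values) ~ log(concentrations))
  structure(list(exponent = unname(coef(fit)[2]),
                 prefactor = unname(exp(coef(fit)[1])),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 concentrations = concentrations, values = values),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power law: value = %.4g * c^%.4g  (R^2 = %.5f, n = %d)\n",
              x$prefactor, x$exponent, x$r_squared, length(x$values)))
  invisible(x)
}

#' Lambda-DNA validation study
#'
#' For each concentration's extracted parameter set: generates the
#' noise-free steady flow curve over the rate grid, recovers the
#' parameters by multi-restart inversion, tabulates the mean and SD of
#' each parameter over converged restarts, recomputes the flow curve
#' from the mean solution with the forward model, and reports the mean
#' relative errors of the shear stress and of the first normal stress
#' difference between the recomputed and input curves. Concludes with
#' power-law concentration fits of the recovered `eta_p` and `tau_D`.
#'
#' @param extracted Named list of per-concentration
#'   [rolie_poly_params()] (default: [lambda_dna_params()]), each
#'   carrying a `concentration` attribute in mg/mL.
#' @param bounds Search box.
#' @param config An [inverse_config()].
#' @param backend Prediction backend for the inversions.
#' @param rates Shear-rate grid.
#' @return A `dna_validation` list: `table` (one row per concentration
#'   and parameter: mean, sd, extracted value), `stress_errors` (mean
#'   relative sigma and N1 errors per concentration), `scaling`
#'   (power-law fits for `eta_p` and `tau_D`), `curves` (input and
#'   reconstructed curve per concentration), and `results` (the raw
#'   [solve_inverse()] objects).
#' @export
run_dna_validation <- function(extracted = lambda_dna_params(),
                               bounds = default_parameter_bounds(),
                               config = inverse_config(),
                               backend = direct_backend(),
                               rates = shear_rate_grid()) {
  concs <- vapply(extracted, function(p) attr(p, "concentration"), numeric(1))
  tab <- list()
  errs <- list()
  curves <- list()
  results <- list()
  for (i in seq_along(extracted)) {
    truth <- extracted[[i]]
    input <- steady_curve(truth, rates,
                          metadata = list(concentration = concs[i]))
    res <- solve_inverse(input, bounds, config, backend)
    mean_par <- setNames(res$summary$mean, res$summary$param)
    theta_hat <- rolie_poly_params(mean_par["eta_p"], mean_par["tau_D"],
                                   mean_par["tau_R"], mean_par["chi_max"],
                                   mean_par["beta"],
                                   eta_s = truth$eta_s, delta = truth$delta)
    recon <- steady_curve(theta_hat, rates)
    tab[[i]] <- data.frame(concentration = concs[i],
                           param = res$summary$param,
                           mean = res$summary$mean, sd = res$summary$sd,
                           extracted = unlist(truth[.RP_FREE_PARAMS]),
                           row.names = NULL)
    errs[[i]] <- data.frame(
      concentration = concs[i],
      sigma_rel_err = mean(abs(recon$sigma_xy - input$sigma_xy) / input$sigma_xy),
      N1_rel_err = mean(abs(recon$N1 - input$N1) / input$N1))
    curves[[i]] <- list(input = input, reconstructed = recon)
    results[[i]] <- res
  }
  table <- do.call(rbind, tab)
  pick <- function(p) table$mean[table$param == p]
  structure(list(table = table,
                 stress_errors = do.call(rbind, errs),
                 scaling = list(eta_p = power_law_fit(concs, pick("eta_p")),
                                tau_D = power_law_fit(concs, pick("tau_D"))),
                 curves = curves, results = results),
            class = "dna_validation")
}

#' @export
print.dna_validation <- function(x, ...) {
  cat("Lambda-DNA validation\n")
  print(x$table, digits = 5)
  cat("\nreconstruction errors:\n")
  print(x$stress_errors, digits = 3)
  cat(sprintf("\nconcentration scaling: eta_p ~ c^%.3f, tau_D ~ c^%.3f\n",
              x$scaling$eta_p$exponent, x$scaling$tau_D$exponent))
  invisible(x)
}

#' Convergence benchmark of the inverse solver
#'
#' Samples `n_cases` target parameter sets from the search box, generates
#' their stress data either with the surrogate itself or with the exact
#' forward model, inverts each through the chosen backend, and returns
#' the per-iteration objective and per-parameter relative-error
#' trajectories. Inverting surrogate-generated data through the
#' surrogate drives parameter errors toward zero; inverting exact model
#' data through an imperfect surrogate leaves residual errors set by the
#' surrogate's bias at the solution. The objective valley of a
#' surrogate-mediated inversion is flattest along the wide-range
#' parameters `eta_p` and `tau_D`, so under-iterated or
#' unpreconditioned runs scatter most along them.
#'
#' @param n_cases Number of target parameter sets (default 3).
#' @param bounds Search box (targets are sampled from it, shrunk 10%
#'   on each parameter's sampling scale so targets are identifiable
#'   strictly inside the box).
#' @param config An [inverse_config()].
#' @param backend Backend used for the inversions.
#' @param data_source `"surrogate"` or `"direct"`: how the input stress
#'   data are generated. `"surrogate"` requires a surrogate backend (or
#'   `net`).
#' @param net Surrogate used to generate data when
#'   `data_source = "surrogate"` and the backend is direct.
#' @param rates Shear-rate grid.
#' @param seed RNG seed for the target draws.
#' @return List of cases, each with `truth`, `result` (an
#'   `inverse_result` whose restarts carry error and parameter
#'   trajectories), `final_param_rel_err` (per parameter, best restart
#'   by final objective — the multi-restart estimate) and
#'   `mean_param_rel_err` (per parameter, the mean over used restarts of
#'   the per-run relative error — what a single run of the solver
#'   typically achieves).
#' @export
convergence_benchmark <- function(n_cases = 3,
                                  bounds = default_parameter_bounds(),
                                  config = inverse_config(),
                                  backend = direct_backend(),
                                  data_source = c("direct", "surrogate"),
                                  net = NULL, rates = shear_rate_grid(),
                                  seed = NULL) {
  data_source <- match.arg(data_source)
  if (data_source == "surrogate" && is.null(net)) {
    if (!inherits(backend, "rp_backend_surrogate"))
      stop("surrogate data source needs 'net' or a surrogate backend")
    net <- backend$net
  }
  if (!is.null(seed)) set.seed(seed)
  inner <- bounds
  for (i in seq_len(nrow(inner))) {   # shrink 10% per side on sampling scale
    if (inner$scale[i] == "log") {
      lo <- log10(inner$min[i]); hi <- log10(inner$max[i])
      inner$min[i] <- 10^(lo + 0.1 * (hi - lo))
      inner$max[i] <- 10^(hi - 0.1 * (hi - lo))
    } else {
      w <- inner$max[i] - inner$min[i]
      inner$min[i] <- inner$min[i] + 0.1 * w
      inner$max[i] <- inner$max[i] - 0.1 * w
    }
  }
  targets <- sample_parameters(inner, n_cases)
  out <- vector("list", n_cases)
  for (ci in seq_len(n_cases)) {
    truth <- rolie_poly_params(targets$eta_p[ci], targets$tau_D[ci],
                               targets$tau_R[ci], targets$chi_max[ci],
                               targets$beta[ci])
    data <- if (data_source == "surrogate") {
      pr <- predict_stress(net, truth, rates)
      structure(pr, class = c("steady_shear_curve", "data.frame"))
    } else {
      steady_curve(truth, rates)
    }
    res <- solve_inverse(data, bounds, config, backend, truth = truth)
    finals <- vapply(res$restarts, `[[`, numeric(1), "error")
    best <- which.min(replace(finals, !is.finite(finals), Inf))
    ptraj <- res$restarts[[best]]$param_error_trajectory
    tv <- unlist(truth[.RP_FREE_PARAMS])
    per_run <- abs(sweep(res$estimates, 2, tv)) / rep(tv, each = nrow(res$estimates))
    out[[ci]] <- list(truth = truth, result = res,
                      final_param_rel_err = ptraj[nrow(ptraj), ],
                      mean_param_rel_err = colMeans(
                        per_run[res$used, , drop = FALSE]))
  }
  out
}
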