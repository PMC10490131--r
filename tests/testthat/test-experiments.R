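test_that("noise injection is bounded, seeded and exact at level zero", {
  cv <- steady_curve(fix_params(), fix_rates())
  expect_identical(add_noise(cv, 0, seed = 1), cv)
  lv <- 0.04
  noisy <- add_noise(cv, lv, seed = 9)
  expect_identical(noisy$shear_rate, cv$shear_rate)
  rels <- abs(c(noisy$sigma_xy / cv$sigma_xy, noisy$N1 / cv$N1) - 1)
  expect_true(all(rels <= lv * (1 + 1e-12)))
  expect_gt(max(rels), lv / 2)  # noise actually present, near its bound
  expect_identical(add_noise(cv, lv, seed = 9), noisy)
  # sigma and N1 perturbed independently
  expect_false(isTRUE(all.equal(noisy$sigma_xy / cv$sigma_xy,
                                noisy$N1 / cv$N1)))
  # truncated-gaussian option respects the same hard bound
  ng <- add_noise(cv, lv, seed = 10, dist = "gaussian")
  expect_true(all(abs(c(ng$sigma_xy / cv$sigma_xy, ng$N1 / cv$N1) - 1) <=
                    lv * (1 + 1e-12)))
})

test_that("power-law fits recover planted exponents exactly", {
  cc <- c(0.5, 1, 2, 4, 8)
  fit <- power_law_fit(cc, 3 * cc^2)
  expect_equal(fit$exponent, 2, tolerance = 1e-12)
  expect_equal(fit$prefactor, 3, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  f2 <- power_law_fit(cc, 0.7 * cc^-1.5)
  expect_equal(f2$exponent, -1.5, tolerance = 1e-12)
  # multiplicative noise: OLS still close to the planted slope
  set.seed(4)
  f3 <- power_law_fit(cc, 2 * cc^3.3 * exp(rnorm(5, 0, 0.02)))
  expect_equal(f3$exponent, 3.3, tolerance = 0.05)
  expect_error(power_law_fit(c(1, 2), c(1, 4)), "at least 3")
  expect_error(power_law_fit(c(1, 2, -3), c(1, 4, 9)), "positive")
})

test_that("noise study normalises level zero to exactly one", {
  truth <- fix_params()
  cfg <- inverse_config(max_iters = 1500, seed = 1)
  out <- noise_study(truth, levels = c(0, 0.02),
                     spec = noise_spec(n_realizations = 2,
                                       n_restarts_per_realization = 2,
                                       seed = 33),
                     config = cfg, rates = fix_rates())
  expect_equal(nrow(out), 10)  # 2 levels x 5 parameters
  lvl0 <- out[out$level == 0, ]
  expect_equal(lvl0$norm_mean, rep(1, 5))
  expect_true(all(out$norm_sd >= 0))
  expect_true(all(out$n_pooled >= 2))
  # noisy level estimates stay in the right neighbourhood
  lvl2 <- out[out$level == 0.02, ]
  expect_true(all(abs(lvl2$norm_mean - 1) < 0.5))
  expect_error(noise_study(truth, levels = c(0.01, 0.02)), "include 0")
})

test_that("single-restart direct validation recovers an extracted DNA set", {
  pl <- lambda_dna_params()
  rep1 <- run_dna_validation(
    extracted = pl[c("1.01", "0.82", "2.06")],
    config = inverse_config(n_restarts = 1, seed = 21, max_iters = 5000),
    rates = fix_rates())
  tab <- rep1$table
  expect_equal(nrow(tab), 15)
  expect_true(all(abs(tab$mean - tab$extracted) / tab$extracted < 0.01))
  expect_true(all(rep1$stress_errors$sigma_rel_err < 0.01))
  expect_length(rep1$scaling, 2)
  expect_equal(length(rep1$curves), 3)
})

test_that("error trajectories decay in the convergence benchmark", {
  out <- convergence_benchmark(
    n_cases = 1, config = inverse_config(n_restarts = 2, seed = 3,
                                         max_iters = 1200),
    data_source = "direct", rates = fix_rates(), seed = 14)
  res <- out[[1]]$result
  expect_length(res$restarts, 2)
  tr <- res$restarts[[1]]$error_trajectory
  expect_gt(length(tr), 10)
  # late-stage objective far below the starting objective
  expect_lt(min(tail(tr, 50)), 0.01 * max(tr[1:10]))
  # parameter trajectories recorded against the known truth
  pt <- res$restarts[[1]]$param_error_trajectory
  expect_equal(ncol(pt), 5)
  expect_lt(max(pt[nrow(pt), ]), 0.05)
})
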