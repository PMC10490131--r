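test_that("sigmoid bound map hits midpoints, limits and exact values", {
  b <- default_parameter_bounds()
  mid <- bounded_map(rep(0, 5), b)
  expect_equal(unlist(mid[c("eta_p", "tau_D", "tau_R", "chi_max", "beta")]),
               c(eta_p = 3000.5, tau_D = 2500.5, tau_R = 25.5,
                 chi_max = 17.5, beta = 13))
  # saturation toward the box edges
  hi <- bounded_map(rep(40, 5), b)
  lo <- bounded_map(rep(-40, 5), b)
  expect_equal(hi$eta_p, 6000, tolerance = 1e-12)
  expect_equal(lo$eta_p, 1, tolerance = 1e-12)
  # strict interiority for any finite omega
  set.seed(2)
  for (i in 1:20) {
    th <- bounded_map(rnorm(5, 0, 8), b)
    v <- unlist(th[c("eta_p", "tau_D", "tau_R", "chi_max", "beta")])
    expect_true(all(v > b$min & v < b$max))
  }
  # g(ln 3) = 0.75, so bounds (0, 4) map to exactly 3 (beta slot)
  b2 <- param_bounds(
    min = c(eta_p = 1, tau_D = 1, tau_R = 1, chi_max = 15, beta = 0),
    max = c(eta_p = 10, tau_D = 10, tau_R = 10, chi_max = 20, beta = 4),
    scale = c(eta_p = "log", tau_D = "log", tau_R = "log",
              chi_max = "linear", beta = "linear"))
  expect_equal(bounded_map(c(0, 0, 0, 0, log(3)), b2)$beta, 3,
               tolerance = 1e-14)
  # unbounded_map inverts bounded_map
  om <- c(-1.2, 0.3, 2.5, -0.7, 1.1)
  expect_equal(unbounded_map(bounded_map(om, b), b), om, tolerance = 1e-10)
})

test_that("relative-error objective is zero at truth and scale-free", {
  truth <- fix_params()
  cv <- steady_curve(truth, fix_rates())
  expect_equal(inverse_error(truth, cv), 0, tolerance = 1e-9)
  # uniform 10% inflation of the observations gives exactly 0.1/1.1
  cv2 <- cv
  cv2$sigma_xy <- cv$sigma_xy * 1.1
  cv2$N1 <- cv$N1 * 1.1
  expect_equal(inverse_error(truth, cv2), 0.1 / 1.1, tolerance = 1e-9)
  expect_gt(inverse_error(rolie_poly_params(100, 500, 5, 16, 5), cv), 0.1)
  cvbad <- cv
  cvbad$N1[3] <- -1
  expect_error(inverse_error(truth, cvbad), "positive")
})

test_that("surrogate-path gradient matches central finite differences", {
  net <- tiny_surrogate()
  b <- default_parameter_bounds()
  cv <- steady_curve(fix_params(), fix_rates(13))
  be <- surrogate_backend(net)
  set.seed(31)
  for (rep in 1:3) {
    om <- rnorm(5)
    sg <- surrogate_error_grad(net, om, b, cv)
    fd <- numeric(5)
    h <- 1e-6
    for (i in 1:5) {
      op <- om; op[i] <- op[i] + h
      omm <- om; omm[i] <- omm[i] - h
      fd[i] <- (inverse_error(bounded_map(op, b), cv, be) -
                inverse_error(bounded_map(omm, b), cv, be)) / (2 * h)
    }
    expect_equal(sg$grad, fd, tolerance = 1e-4)
  }
})

test_that("a plain gradient step leaves a minimum fixed and descends a slope", {
  b <- default_parameter_bounds()
  truth <- fix_params()
  cv <- steady_curve(truth, fix_rates())
  om0 <- unbounded_map(truth, b)
  # at (numerically) zero gradient the update is the identity
  st <- gradient_step(om0, cv, rho = 0.5, bounds = b)
  expect_equal(as.numeric(st), om0, tolerance = 1e-5)
  # one step from a perturbed start reduces the objective
  om1 <- om0 + c(0.3, 0, 0, 0, 0)
  st1 <- gradient_step(om1, cv, rho = 0.1, bounds = b)
  e_before <- inverse_error(bounded_map(om1, b), cv)
  e_after <- inverse_error(bounded_map(as.numeric(st1), b), cv)
  expect_lt(e_after, e_before)
  expect_equal(attr(st1, "error"), e_before, tolerance = 1e-12)
})

test_that("direct-backend inversion recovers known parameters from noise-free data", {
  b <- default_parameter_bounds()
  truth <- fix_params()
  cv <- steady_curve(truth, fix_rates())
  res <- solve_inverse(cv, b, inverse_config(n_restarts = 3, seed = 5,
                                             max_iters = 4000))
  expect_s3_class(res, "inverse_result")
  expect_gt(res$n_converged, 0)
  tv <- unlist(truth[c("eta_p", "tau_D", "tau_R", "chi_max", "beta")])
  # every converged restart within 1% per parameter
  conv <- vapply(res$restarts, `[[`, logical(1), "converged")
  for (r in which(conv)) {
    th <- unlist(res$restarts[[r]]$theta[names(tv)])
    expect_lt(max(abs(th - tv) / tv), 0.01)
  }
  # restart independence: per-parameter SD below 1% of the mean
  expect_true(all(res$summary$sd < 0.01 * abs(res$summary$mean)))
  # reproducibility under the seed
  res2 <- solve_inverse(cv, b, inverse_config(n_restarts = 3, seed = 5,
                                              max_iters = 4000))
  expect_equal(res2$estimates, res$estimates)
})

test_that("inversion warns on sparse curves and flags total failure honestly", {
  b <- default_parameter_bounds()
  cv <- steady_curve(fix_params(), shear_rate_grid(5, -1, 1))
  expect_warning(
    res <- solve_inverse(cv, b, inverse_config(n_restarts = 1, seed = 1,
                                               max_iters = 5)),
    "fewer than 10")
  expect_false(res$restarts[[1]]$converged)  # 5 iterations cannot converge
  expect_true(res$all_failed)
  expect_equal(nrow(res$summary), 5)  # aggregate still reported, flagged
})
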