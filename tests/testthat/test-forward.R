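test_that("spring coefficient is 1 at equilibrium and diverges at full stretch", {
  expect_identical(spring_coefficient(1, 18), 1)
  # frozen high-precision evaluation of the FENE factor at lam = 2, chi = 18
  expect_equal(spring_coefficient(2, 18), 1.0062564366632338, tolerance = 1e-14)
  # strictly increasing on (1, chi_max)
  lam <- seq(1, 17.9, length.out = 200)
  expect_true(all(diff(spring_coefficient(lam, 18)) > 0))
  # pole at the extensibility limit
  expect_gt(spring_coefficient(18 * (1 - 1e-10), 18), 1e8)
  expect_error(spring_coefficient(18, 18), "finite extensibility")
  expect_error(spring_coefficient(19, 18), "finite extensibility")
})

test_that("relaxation term vanishes at equilibrium and preserves symmetry", {
  p <- fix_params()
  expect_equal(relaxation_term(diag(3), p), matrix(0, 3, 3))
  # symmetric in, symmetric out
  A <- matrix(c(1.4, 0.3, 0.1, 0.3, 1.1, -0.05, 0.1, -0.05, 0.9), 3, 3)
  f <- relaxation_term(A, p)
  expect_equal(f, t(f))
  expect_error(relaxation_term(diag(c(900, 40, 40)), p),
               "finite extensibility")
})

test_that("relaxation term matches an independent scalar evaluation", {
  # term-by-term scalar arithmetic, written out independently of the
  # package's tensor code
  p <- rolie_poly_params(eta_p = 1, tau_D = 1, tau_R = 0.1, chi_max = 18,
                         beta = 1, delta = -0.5)
  A <- diag(c(1.5, 1.0, 0.8))
  trA <- 3.3
  lam <- sqrt(trA / 3)
  ks <- ((3 - lam^2 / 324) * (1 - 1 / 324)) / ((1 - lam^2 / 324) * (3 - 1 / 324))
  pref <- (2 / 0.1) * ks * (1 - sqrt(3 / trA))
  ccr <- 1 * (trA / 3)^(-0.5)
  expected <- diag(c(
    -(1.5 - 1) / 1 - pref * (1.5 + ccr * (1.5 - 1)),
    -(1.0 - 1) / 1 - pref * (1.0 + ccr * (1.0 - 1)),
    -(0.8 - 1) / 1 - pref * (0.8 + ccr * (0.8 - 1))))
  expect_equal(relaxation_term(A, p), expected, tolerance = 1e-14)
  # and the degenerate trace-3 case where only reptation survives
  A2 <- diag(c(1.2, 0.9, 0.9))
  expect_equal(relaxation_term(A2, p), -(A2 - diag(3)) / p$tau_D,
               tolerance = 1e-14)
})

test_that("shear RHS has the advective structure of simple shear", {
  p <- fix_params()
  expect_equal(shear_rhs(diag(3), 0, p), matrix(0, 3, 3))
  # at A = I the only non-zero entry is the xy advection, = gamma_dot
  r <- shear_rhs(diag(3), 2.5, p)
  expect_equal(r[1, 2], 2.5)
  expect_equal(r[2, 1], 2.5)
  expect_equal(r[c(1, 5, 6, 9)], rep(0, 4))
  # shear-reversal symmetry: flipping Axy and gamma_dot negates the xy
  # component and fixes the diagonal
  A <- matrix(c(1.8, 0.4, 0, 0.4, 1.05, 0, 0, 0, 0.95), 3, 3)
  Am <- A; Am[1, 2] <- Am[2, 1] <- -0.4
  r1 <- shear_rhs(A, 1.3, p)
  r2 <- shear_rhs(Am, -1.3, p)
  expect_equal(r2[1, 1], r1[1, 1], tolerance = 1e-14)
  expect_equal(r2[2, 2], r1[2, 2], tolerance = 1e-14)
  expect_equal(r2[1, 2], -r1[1, 2], tolerance = 1e-14)
})

test_that("steady conformation solves the steady equation on the physical branch", {
  p <- fix_params()
  expect_equal(steady_conformation(p, 0), diag(3))
  for (gd in c(1e-3, 0.5, 200)) {
    A <- steady_conformation(p, gd)
    expect_equal(A[2, 2], A[3, 3])  # yy/zz symmetry observed, not imposed
    expect_equal(max(abs(shear_rhs(A, gd, p))), 0,
                 tolerance = 1e-8 * max(gd, 1 / p$tau_D))
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
    expect_lt(sum(diag(A)), 3 * p$chi_max^2)
    expect_gte(sum(diag(A)), 3)
  }
})

test_that("Newton/continuation agrees with time integration on random draws", {
  set.seed(91)
  bounds <- default_parameter_bounds()
  draws <- sample_parameters(bounds, 6)
  rates <- 10^runif(6, -3, 2)
  for (i in seq_len(6)) {
    p <- rolie_poly_params(draws$eta_p[i], draws$tau_D[i], draws$tau_R[i],
                           draws$chi_max[i], draws$beta[i])
    A1 <- steady_conformation(p, rates[i])
    A2 <- integrate_conformation(p, rates[i])
    expect_equal(A1, A2, tolerance = 1e-6)
  }
})

test_that("zero-shear limits recover the linear viscoelastic coefficients", {
  set.seed(17)
  draws <- sample_parameters(default_parameter_bounds(), 5)
  for (i in seq_len(5)) {
    p <- rolie_poly_params(draws$eta_p[i], draws$tau_D[i], draws$tau_R[i],
                           draws$chi_max[i], draws$beta[i])
    gd <- 1e-6 / p$tau_D
    s <- total_steady_stress(p, gd)
    expect_equal(s[["sigma_xy"]] / gd, p$eta_s + p$eta_p, tolerance = 1e-3)
    expect_equal(s[["N1"]] / gd^2, 2 * p$eta_p * p$tau_D, tolerance = 5e-3)
  }
})

test_that("steady curves are valid, stateless and bounded by extensibility", {
  p <- fix_params()
  rates <- shear_rate_grid(91)
  cv <- steady_curve(p, rates)
  expect_s3_class(cv, "steady_shear_curve")
  expect_equal(nrow(cv), 91)
  expect_true(all(diff(cv$shear_rate) > 0))
  expect_true(all(cv$sigma_xy > 0))
  expect_true(all(cv$N1 >= 0))
  # statelessness: splitting the sweep changes nothing
  cv1 <- steady_curve(p, rates[1:40])
  cv2 <- steady_curve(p, rates[41:91])
  expect_equal(rbind(as.data.frame(cv1), as.data.frame(cv2)),
               as.data.frame(cv), ignore_attr = TRUE)
  # gamma_dot = 0 gives the trivial record
  z <- steady_curve(p, 0)
  expect_equal(unlist(z), c(shear_rate = 0, sigma_xy = 0, N1 = 0))
  # finite extensibility along the whole sweep, up to 1e4 1/s
  s <- rpinverse:::.rp_steady_sweep_cpp(rates, p$eta_p, p$tau_D, p$tau_R,
                                        p$chi_max, p$beta, p$eta_s, p$delta)
  expect_true(all(s$trA < 3 * p$chi_max^2))
  expect_error(steady_curve(p, c(2, 1)), "increasing")
  expect_error(steady_curve(p, -1), "non-negative")
})
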