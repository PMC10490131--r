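#' FENE nonlinear spring coefficient
#'
#' The finite-extensibility correction to the entropic spring force of a
#' stretched chain,
#' \deqn{k_s(\lambda) = \frac{(3 - \lambda^2/\chi_{max}^2)\,(1 - 1/\chi_{max}^2)}
#'                           {(1 - \lambda^2/\chi_{max}^2)\,(3 - 1/\chi_{max}^2)},}
#' where \eqn{\lambda = \sqrt{\mathrm{tr}A/3}} is the chain stretch ratio.
#' It equals 1 at equilibrium (\eqn{\lambda = 1}), increases monotonically,
#' and diverges as \eqn{\lambda \to \chi_{max}}.
#'
#' @param lam Stretch ratio(s), `0 < lam < chi_max`.
#' @param chi_max Maximum stretch ratio, `> 1`.
#' @return Dimensionless spring factor, vectorised over `lam`.
#' @examples
#' spring_coefficient(1, 18)   # exactly 1
#' spring_coefficient(17.9, 18)  # large: near full extension
#' @export
spring_coefficient <- function(lam, chi_max) {
  stopifnot(chi_max > 1)
  if (any(lam <= 0)) stop("stretch ratio must be positive")
  if (any(lam >= chi_max))
    stop("finite extensibility violated: lam >= chi_max")
  r <- (lam / chi_max)^2
  ((3 - r) * (1 - 1 / chi_max^2)) / ((1 - r) * (3 - 1 / chi_max^2))
}

#' Rolie-Poly relaxation term f(A)
#'
#' The relaxation part of the conformation-tensor evolution equation:
#' reptation drives `A` back to the identity on the timescale `tau_D`,
#' while chain stretch relaxes on `tau_R` with the FENE spring factor and a
#' convective-constraint-release contribution of strength `beta`,
#' \deqn{f(A) = -\frac{1}{\tau_D}(A - I)
#'   - \frac{2}{\tau_R} k_s(\lambda)\left(1 - \sqrt{3/\mathrm{tr}A}\right)
#'     \left[A + \beta\,(\mathrm{tr}A/3)^{\delta}(A - I)\right].}
#'
#' @param A 3x3 symmetric positive-definite conformation tensor with
#'   `tr(A) < 3 * chi_max^2`.
#' @param p A [rolie_poly_params()] object.
#' @return A 3x3 symmetric matrix, the relaxation rate of `A` (1/s).
#'   `f(I)` is exactly zero.
#' @export
relaxation_term <- function(A, p) {
  stopifnot(is.matrix(A), all(dim(A) == c(3L, 3L)))
  if (max(abs(A - t(A))) > 1e-12 * max(1, max(abs(A))))
    stop("conformation tensor must be symmetric")
  trA <- sum(diag(A))
  if (trA >= 3 * p$chi_max^2)
    stop("finite extensibility violated: tr(A) >= 3 * chi_max^2")
  I3 <- diag(3)
  lam <- sqrt(trA / 3)
  ks <- spring_coefficient(lam, p$chi_max)
  stretch <- 1 - sqrt(3 / trA)
  ccr <- p$beta * (trA / 3)^p$delta
  -(A - I3) / p$tau_D -
    (2 / p$tau_R) * ks * stretch * (A + ccr * (A - I3))
}

#' Conformation evolution rate under simple shear
#'
#' Right-hand side of the evolution equation
#' \eqn{dA/dt = L A + A L^T + f(A)} for homogeneous simple shear with
#' velocity \eqn{u = (\dot\gamma y, 0, 0)}: the velocity-gradient tensor
#' `L` has \eqn{\dot\gamma} in its (x, y) slot and zeros elsewhere
#' (convention `L_ij = du_i/dx_j`).
#'
#' @inheritParams relaxation_term
#' @param gamma_dot Shear rate, 1/s.
#' @return The 3x3 symmetric tensor `dA/dt`; zero at a steady state.
#' @export
shear_rhs <- function(A, gamma_dot, p) {
  L <- matrix(0, 3, 3)
  L[1, 2] <- gamma_dot
  L %*% A + A %*% t(L) + relaxation_term(A, p)
}

#' Steady-state conformation tensor
#'
#' Solves \eqn{L A + A L^T + f(A) = 0} for the physical steady state at a
#' given shear rate, by damped Newton iteration with continuation in
#' log shear rate from the equilibrium solution `A = I` (with an
#' implicit-Euler pseudo-time fallback when Newton stalls). The physical
#' branch is the one connected to equilibrium by continuation.
#'
#' @param p A [rolie_poly_params()] object.
#' @param gamma_dot Single shear rate, 1/s, `>= 0`.
#' @return A 3x3 symmetric positive-definite matrix `A*` with
#'   `tr(A*) < 3 * chi_max^2` and residual max-norm below the scaled
#'   tolerance `1e-10`.
#' @export
steady_conformation <- function(p, gamma_dot) {
  stopifnot(length(gamma_dot) == 1L, gamma_dot >= 0)
  s <- .rp_steady_sweep_cpp(gamma_dot, p$eta_p, p$tau_D, p$tau_R,
                            p$chi_max, p$beta, p$eta_s, p$delta)
  if (!s$converged[1])
    stop(sprintf(paste0("steady-state solver failed at gamma_dot = %g ",
                        "(tau_D = %g, tau_R = %g, chi_max = %g, beta = %g)"),
                 gamma_dot, p$tau_D, p$tau_R, p$chi_max, p$beta))
  A <- diag(3)
  A[1, 1] <- 1 + s$Bxx[1]
  A[1, 2] <- A[2, 1] <- s$Bxy[1]
  A[2, 2] <- 1 + s$Byy[1]
  A[3, 3] <- 1 + s$Byy[1]   # yy and zz equations coincide in planar shear
  A
}

#' Steady total stress under simple shear
#'
#' Total shear stress and first normal stress difference at steady state:
#' the polymeric stress is \eqn{\sigma_p = G\,k_s(\lambda)(A - I)} with
#' plateau modulus \eqn{G = \eta_p/\tau_D}, and the solvent adds
#' \eqn{2\eta_s D}, so
#' \eqn{\sigma_{xy} = \eta_s\dot\gamma + G k_s A^*_{xy}} and
#' \eqn{N_1 = \sigma_{xx}-\sigma_{yy} = G k_s (A^*_{xx} - A^*_{yy})}
#' (the solvent contributes nothing to \eqn{N_1}).
#'
#' @inheritParams steady_conformation
#' @return Named numeric vector `c(sigma_xy = , N1 = )`, Pa.
#' @examples
#' p <- rolie_poly_params(22.6, 109, 14, 18, 13)
#' total_steady_stress(p, 1e-3)
#' @export
total_steady_stress <- function(p, gamma_dot) {
  cv <- steady_curve(p, gamma_dot)
  c(sigma_xy = cv$sigma_xy[1], N1 = cv$N1[1])
}

#' Logarithmic shear-rate grid
#'
#' @param n Number of rates (default 91).
#' @param log10_min,log10_max Decade limits (defaults -4 and 4, i.e.
#'   `1e-4` to `1e4` 1/s).
#' @return Strictly increasing numeric vector of shear rates, 1/s.
#' @export
shear_rate_grid <- function(n = 91, log10_min = -4, log10_max = 4) {
  stopifnot(n >= 1, log10_min < log10_max)
  10^seq(log10_min, log10_max, length.out = n)
}

#' Steady flow curve over a shear-rate sweep
#'
#' Computes the steady shear stress and first normal stress difference at
#' each requested rate, warm-starting the Newton solver by continuation
#' from the previous rate. Stateless: splitting a sweep into several calls
#' yields identical values.
#'
#' @param p A [rolie_poly_params()] object.
#' @param rates Shear rates, 1/s, sorted ascending, all `>= 0`.
#' @param metadata Optional named list attached as an attribute (e.g. a
#'   concentration label).
#' @return A data frame of class `steady_shear_curve` with columns
#'   `shear_rate` (1/s), `sigma_xy` (Pa) and `N1` (Pa).
#' @examples
#' p <- rolie_poly_params(12.4, 87, 11, 18, 20)
#' head(steady_curve(p, shear_rate_grid(11)))
#' @export
steady_curve <- function(p, rates, metadata = NULL) {
  stopifnot(inherits(p, "rolie_poly_params"), length(rates) >= 1)
  if (any(rates < 0)) stop("shear rates must be non-negative")
  if (is.unsorted(rates, strictly = TRUE) && length(rates) > 1)
    stop("shear rates must be strictly increasing")
  s <- .rp_steady_sweep_cpp(as.numeric(rates), p$eta_p, p$tau_D, p$tau_R,
                            p$chi_max, p$beta, p$eta_s, p$delta)
  if (!all(s$converged))
    stop(sprintf("steady-state solver failed at %d of %d rates (first: %g 1/s)",
                 sum(!s$converged), length(rates),
                 rates[which(!s$converged)[1]]))
  out <- data.frame(shear_rate = as.numeric(rates),
                    sigma_xy = s$sigma_xy, N1 = s$N1)
  class(out) <- c("steady_shear_curve", "data.frame")
  attr(out, "params") <- p
  if (!is.null(metadata)) attr(out, "metadata") <- metadata
  out
}

#' Time integration of the conformation equation (independent oracle)
#'
#' Integrates \eqn{dA/dt = L A + A L^T + f(A)} from equilibrium `A = I`
#' with `deSolve::lsoda`, carrying all four in-plane components
#' (`Axx`, `Axy`, `Ayy`, `Azz`) so that the `Ayy = Azz` steady symmetry is
#' observed rather than imposed. Serves as the independent long-time
#' oracle for the Newton/continuation steady solver; transient output is
#' not a user-facing feature.
#'
#' @inheritParams steady_conformation
#' @param t_end Integration horizon, s; default `60 * max(tau_D, tau_R)`,
#'   long enough that the slowest mode has decayed far below the solver
#'   tolerance.
#' @param rtol,atol Integrator tolerances.
#' @return The 3x3 conformation tensor at `t_end`.
#' @export
integrate_conformation <- function(p, gamma_dot,
                                   t_end = 60 * max(p$tau_D, p$tau_R),
                                   rtol = 1e-10, atol = 1e-12) {
  deriv <- function(t, y, parms) {
    A <- diag(c(y[1], y[3], y[4]))
    A[1, 2] <- A[2, 1] <- y[2]
    dA <- shear_rhs(A, gamma_dot, p)
    list(c(dA[1, 1], dA[1, 2], dA[2, 2], dA[3, 3]))
  }
  y0 <- c(Axx = 1, Axy = 0, Ayy = 1, Azz = 1)
  sol <- deSolve::lsoda(y0, times = c(0, t_end), func = deriv,
                        rtol = rtol, atol = atol, maxsteps = 500000)
  y <- sol[nrow(sol), -1]
  A <- diag(c(y[["Axx"]], y[["Ayy"]], y[["Azz"]]))
  A[1, 2] <- A[2, 1] <- y[["Axy"]]
  A
}
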