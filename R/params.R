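#' Rolie-Poly molecular parameter set
#'
#' Bundles the molecular parameters of the single-mode non-Gaussian
#' Rolie-Poly constitutive model for an entangled linear polymer solution.
#' The plateau modulus is the derived quantity `G = eta_p / tau_D`.
#'
#' @param eta_p Zero-shear polymer viscosity, Pa s. Strictly positive.
#' @param tau_D Reptation (disengagement) time, s. Strictly positive.
#' @param tau_R Rouse (stretch) time, s. Strictly positive. `tau_R <= tau_D`
#'   is *not* enforced: the sampling ranges used for surrogate training
#'   permit either order.
#' @param chi_max Maximum chain stretch ratio (finite extensibility),
#'   dimensionless, `> 1`.
#' @param beta Convective-constraint-release (CCR) coefficient,
#'   dimensionless, `>= 0`.
#' @param eta_s Solvent viscosity, Pa s. Treated as a fixed constant;
#'   defaults to the viscosity of water, 1.0e-3 Pa s.
#' @param delta CCR stretch exponent, dimensionless. Fixed constant,
#'   default -1/2 (the standard Rolie-Poly choice).
#'
#' @return An object of class `rolie_poly_params` (a named list).
#' @examples
#' p <- rolie_poly_params(eta_p = 12.4, tau_D = 87, tau_R = 11,
#'                        chi_max = 18, beta = 20)
#' p$eta_p / p$tau_D  # plateau modulus G, Pa
#' @export
rolie_poly_params <- function(eta_p, tau_D, tau_R, chi_max, beta,
                              eta_s = 1e-3, delta = -0.5) {
  stopifnot(is.numeric(eta_p), is.numeric(tau_D), is.numeric(tau_R),
            is.numeric(chi_max), is.numeric(beta),
            length(eta_p) == 1L, length(tau_D) == 1L, length(tau_R) == 1L,
            length(chi_max) == 1L, length(beta) == 1L)
  if (!(eta_p > 0 && tau_D > 0 && tau_R > 0 && eta_s > 0))
    stop("eta_p, tau_D, tau_R and eta_s must be strictly positive")
  if (!(chi_max > 1)) stop("chi_max must exceed 1")
  if (beta < 0) stop("beta must be non-negative")
  structure(list(eta_p = eta_p, tau_D = tau_D, tau_R = tau_R,
                 chi_max = chi_max, beta = beta,
                 eta_s = eta_s, delta = delta),
            class = "rolie_poly_params")
}

#' @export
print.rolie_poly_params <- function(x, ...) {
  cat("Rolie-Poly parameters\n")
  cat(sprintf("  eta_p   = %g Pa s   (zero-shear polymer viscosity)\n", x$eta_p))
  cat(sprintf("  tau_D   = %g s      (reptation time)\n", x$tau_D))
  cat(sprintf("  tau_R   = %g s      (Rouse time)\n", x$tau_R))
  cat(sprintf("  chi_max = %g        (max stretch ratio)\n", x$chi_max))
  cat(sprintf("  beta    = %g        (CCR coefficient)\n", x$beta))
  cat(sprintf("  eta_s   = %g Pa s, delta = %g,  G = %g Pa\n",
              x$eta_s, x$delta, x$eta_p / x$tau_D))
  invisible(x)
}

#' Bounds of the molecular-parameter space
#'
#' A bounds table declares, for each free Rolie-Poly parameter, the
#' admissible range and the scale (linear or logarithmic) on which it is
#' sampled and searched. The default ranges span the entangled polymer
#' solutions the surrogate is trained for.
#'
#' @param min,max Named numeric vectors (names `eta_p`, `tau_D`, `tau_R`,
#'   `chi_max`, `beta`), SI units.
#' @param scale Named character vector, each `"log"` or `"linear"`.
#' @return A `param_bounds` data frame with columns `param`, `min`, `max`,
#'   `scale`.
#' @export
param_bounds <- function(min, max, scale) {
  p <- .RP_FREE_PARAMS
  stopifnot(all(p %in% names(min)), all(p %in% names(max)),
            all(p %in% names(scale)))
  min <- as.numeric(min[p]); max <- as.numeric(max[p])
  scale <- as.character(scale[p])
  if (any(min >= max)) stop("each parameter needs min < max")
  if (!all(scale %in% c("log", "linear")))
    stop("scale must be 'log' or 'linear'")
  if (any(scale == "log" & min <= 0))
    stop("log-scaled parameters need strictly positive bounds")
  structure(data.frame(param = p, min = min, max = max, scale = scale,
                       stringsAsFactors = FALSE),
            class = c("param_bounds", "data.frame"))
}

#' @describeIn param_bounds The default parameter-variation ranges:
#'   eta_p 1--6000 Pa s (log), tau_D 1--5000 s (log), tau_R 1--50 s (log),
#'   chi_max 15--20 (linear), beta 1--25 (linear).
#' @export
default_parameter_bounds <- function() {
  param_bounds(
    min   = c(eta_p = 1,    tau_D = 1,    tau_R = 1,  chi_max = 15, beta = 1),
    max   = c(eta_p = 6000, tau_D = 5000, tau_R = 50, chi_max = 20, beta = 25),
    scale = c(eta_p = "log", tau_D = "log", tau_R = "log",
              chi_max = "linear", beta = "linear"))
}

#' Read a parameter-bounds table from YAML
#'
#' The file maps each parameter name to `min`, `max` and `scale` keys; see
#' `system.file("extdata", "parameter_bounds.yaml", package = "rpinverse")`
#' for the packaged default.
#'
#' @param path Path to a YAML file.
#' @return A [param_bounds] object.
#' @export
read_bounds_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  miss <- setdiff(.RP_FREE_PARAMS, names(y))
  if (length(miss))
    stop("bounds file is missing parameters: ", paste(miss, collapse = ", "))
  param_bounds(
    min   = vapply(y, function(e) as.numeric(e$min), numeric(1)),
    max   = vapply(y, function(e) as.numeric(e$max), numeric(1)),
    scale = vapply(y, function(e) as.character(e$scale), character(1)))
}

#' Extracted molecular parameters of entangled lambda-DNA solutions
#'
#' Molecular parameter sets for completely monodisperse linear lambda-DNA
#' solutions at four entangled concentrations, as extracted from linear
#' viscoelastic measurements. These are the ground-truth inputs of the
#' concentration-scaling validation study.
#'
#' @param eta_s,delta Fixed constants passed to [rolie_poly_params()].
#' @return A named list of [rolie_poly_params()] objects, one per
#'   concentration; names are the concentrations in mg/mL and each element
#'   carries a `concentration` attribute (mg/mL).
#' @examples
#' pl <- lambda_dna_params()
#' names(pl)
#' @export
lambda_dna_params <- function(eta_s = 1e-3, delta = -0.5) {
  path <- system.file("extdata", "lambda_dna_params.csv",
                      package = "rpinverse", mustWork = TRUE)
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    p <- rolie_poly_params(eta_p = tab$eta_p[i], tau_D = tab$tau_D[i],
                           tau_R = tab$tau_R[i], chi_max = tab$chi_max[i],
                           beta = tab$beta[i], eta_s = eta_s, delta = delta)
    attr(p, "concentration") <- tab$concentration[i]
    p
  })
  names(out) <- format(tab$concentration)
  out
}
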