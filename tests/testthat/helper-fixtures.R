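# Shared fixtures, built in code at test time.

# a cheap mid-range parameter set
fix_params <- function() rolie_poly_params(eta_p = 22.6, tau_D = 109,
                                           tau_R = 14, chi_max = 18,
                                           beta = 13)

# short rate grid spanning the shear-thinning transition
fix_rates <- function(n = 21) shear_rate_grid(n, -3, 3)

# memoised expensive objects, shared across test files in one run
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# a small trained surrogate for unit tests of the surrogate-backed paths
# (coarse net and data: quality is not the point here)
tiny_surrogate <- function() {
  memo("tiny_net", {
    b <- default_parameter_bounds()
    ds <- generate_dataset(b, 120, shear_rate_grid(13, -3, 3), seed = 420)
    train_surrogate(ds, net_config(2, 24),
                    training_config(n_epochs = 120, batch_size = 256,
                                    n_repeats = 1, patience = 120,
                                    lr_decay = 0.5, lr_decay_every = 60,
                                    seed = 421))
  })
}

tiny_dataset <- function() {
  memo("tiny_ds", {
    generate_dataset(default_parameter_bounds(), 120,
                     shear_rate_grid(13, -3, 3), seed = 420)
  })
}
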