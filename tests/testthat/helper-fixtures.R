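# Shared fixtures, memoised so expensive objects (smoothed profiles, fitted
# models) are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

fixture_dataset <- function(seed = 7, noise_cv = 0) {
  memo(sprintf("ds_%d_%g", seed, noise_cv),
       generate_tcell_dataset(seed = seed, noise_cv = noise_cv))
}

fixture_profiles <- function(seed = 7, noise_cv = 0) {
  memo(sprintf("profs_%d_%g", seed, noise_cv),
       smooth_all(fixture_dataset(seed, noise_cv)$series))
}

fixture_bounds <- function(seed = 7, noise_cv = 0) {
  memo(sprintf("bounds_%d_%g", seed, noise_cv),
       derive_notch_bounds("6d", fixture_profiles(seed, noise_cv),
                           seed = 1, n_samples = 4000))
}

# the noiseless parameter-recovery fit (the most expensive shared fixture)
fixture_noiseless_fit <- function() {
  memo("fit_noiseless", {
    ds <- fixture_dataset(7, 0)
    fit_tgb("6d", ds$series, fixture_bounds(7, 0), seed = 11)
  })
}

# a minimal model with all production weights zero: pure exponential decay
decay_only_spec <- function(gamma = c(T = 1, G = 2, B = 0.5, P = 1.5)) {
  params <- model_parameters(
    eta = rep(0, 4), delta = rep(0, 3), kappa = rep(0, 3), rho = rep(0, 4),
    f = c(T = 1, G = 1, B = 1, P = 1), gamma = gamma)
  model_spec("1a", params, notch_spec())
}

# a full four-gene model with genuine stable-stable bistability: PU.1
# self-activation plus mutual repression with TCF-1/GATA-3 forms a toggle
# (the TGB subsystem alone, with its linear activation numerators and
# slaved BCL11B, cannot hold two stable states)
toggle_spec <- function() {
  base <- reference_spec()
  params <- model_parameters(
    eta = c(3, 0.010, 0.005, 0.050),   # strong PU.1 repression of TCF-1
    delta = c(1, 0.010, 0.100),        # and of GATA-3
    kappa = base$params$kappa,
    rho = c(0.100, 0.020, 0.020, 0.003),
    f = base$params$f, gamma = base$params$gamma)
  model_spec(base$logic, params, base$notch)
}

# random small model specs for property tests (seeded by caller)
random_spec <- function() {
  id <- sample(names(enumerate_configurations()), 1)
  k <- n_kappa(compile_rate_law(logic_config(id)))
  params <- model_parameters(
    eta = c(runif(1, 0, 5), runif(3, 0, 0.05)),
    delta = c(runif(1, 0, 5), runif(2, 0, 0.05)),
    kappa = 10 ^ runif(k, -8, -2),
    rho = runif(4, 0, 0.05),
    f = c(T = runif(1, 50, 500), G = runif(1, 50, 500),
          B = runif(1, 50, 500), P = runif(1, 50, 500)),
    gamma = c(T = runif(1, 0.5, 4), G = runif(1, 0.5, 4),
              B = runif(1, 0.5, 4), P = runif(1, 0.5, 4)))
  model_spec(id, params, notch_spec(alpha = runif(1, 0.2, 1),
                                    t_half = runif(1, 0.5, 3)))
}
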