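# Two-leg calibration: Notch-constraint bounds, subsystem fitting,
# half-lives, selection filters, PU.1 estimation.

truth_tgb <- function() {
  spec <- reference_spec()
  c(eta1N = spec$params$eta[1], eta2 = spec$params$eta[2],
    eta3 = spec$params$eta[3], eta4 = spec$params$eta[4],
    f_T = unname(spec$params$f[["T"]]),
    gamma_T = unname(spec$params$gamma[["T"]]),
    delta1N = spec$params$delta[1], delta2 = spec$params$delta[2],
    delta3 = spec$params$delta[3],
    f_G = unname(spec$params$f[["G"]]),
    gamma_G = unname(spec$params$gamma[["G"]]),
    kappa1 = spec$params$kappa[1], kappa2 = spec$params$kappa[2],
    f_B = unname(spec$params$f[["B"]]),
    gamma_B = unname(spec$params$gamma[["B"]]))
}

# hand-built evaluated-fit shell around an arbitrary model spec
fit_shell <- function(spec, data) {
  p_prof <- smooth_series(data$P)
  structure(list(config = spec$logic, params = spec$params,
                 notch = spec$notch, spec = spec,
                 objective = NA, notch_fold = notch_fold(spec$notch),
                 p_clamp = p_prof$value, data_times = data$T$times,
                 ci_pass = NULL, half_lives = NULL, accepted = NA,
                 converged = TRUE, seed = 0L),
            class = "fit_result")
}

test_that("derived Notch bounds contain the generating parameters", {
  b <- fixture_bounds(7, 0)
  tr <- truth_tgb()
  expect_identical(names(b$lower), names(tr))
  expect_true(all(tr >= b$lower & tr <= b$upper))
})

test_that("relaxing the fold cap weakly widens every bound", {
  profs <- fixture_profiles(7, 0)
  b1 <- derive_notch_bounds("6d", profs, fold_cap = 3.5, seed = 2,
                            n_samples = 1500)
  b2 <- derive_notch_bounds("6d", profs, fold_cap = Inf, seed = 2,
                            n_samples = 1500)
  expect_true(all(b2$lower <= b1$lower + 1e-15))
  expect_true(all(b2$upper >= b1$upper - 1e-15))
})

test_that("a profile implying negative Notch reports infeasibility", {
  profs <- fixture_profiles(7, 0)
  # TCF-1 collapsing at 30/day: faster than any admissible decay rate, so
  # the implied Notch contribution is negative at every grid point
  bad <- profs
  bad$T <- structure(list(
    gene = "T", value = function(t) 100 * exp(-30 * t),
    derivative = function(t) -3000 * exp(-30 * t), par = NULL, rss = 0),
    class = "smooth_profile")
  expect_error(derive_notch_bounds("6d", bad, seed = 3, n_samples = 500),
               "T equation")
})

test_that("half-life modes follow their definitions", {
  spec <- decay_only_spec(gamma = c(T = log(2), G = 1, B = 1, P = 1))
  # gamma = ln2 per day -> intrinsic half-life exactly one day
  expect_equal(compute_half_life(spec, "T", "intrinsic"), 24)
  # with zero production weights the Jacobian diagonal of production is 0
  st <- c(T = 5, G = 5, B = 5, P = 5)
  for (g in c("T", "G", "B", "P"))
    expect_equal(compute_half_life(spec, g, "effective", state = st),
                 compute_half_life(spec, g, "intrinsic"), tolerance = 1e-6)
  # at the committed state of the reference model all are finite positive
  ref <- reference_spec()
  ss <- steady_state(ref, ref$notch$n_max, etp_initial_state(ref))
  for (g in c("T", "G", "B")) {
    hl <- compute_half_life(ref, g, "effective", state = ss$state)
    expect_true(is.finite(hl) && hl > 0)
  }
  expect_error(compute_half_life(ref, "T", "effective"), "reference state")
})

test_that("the generating model passes the selection filters exactly", {
  ds <- fixture_dataset(7, 0)
  fit <- evaluate_fit(fit_shell(ds$truth, ds$series), ds$series)
  expect_true(all(fit$ci_pass))
  expect_true(fit$accepted)
  expect_lt(sum(fit$objective), 1e-3)
  # a x2 distortion at one point breaks the 95% interval (2 > 1.49)
  bad <- ds$series
  bad$B$values[4] <- bad$B$values[4] / 2  # band centre moves, sim does not
  fit_bad <- evaluate_fit(fit_shell(ds$truth, ds$series), bad)
  expect_false(fit_bad$ci_pass[["B"]])
  expect_false(fit_bad$accepted)
})

test_that("filtering is monotone in cv and half-life window", {
  ds <- fixture_dataset(7, 0)
  fits <- list(evaluate_fit(fit_shell(ds$truth, ds$series), ds$series))
  acc_tight <- filter_fits(fits, ds$series, cv = 0.25,
                           hl_window = c(1, 48))
  acc_wide <- filter_fits(fits, ds$series, cv = 0.4,
                          hl_window = c(0.5, 100))
  expect_gte(length(acc_wide), length(acc_tight))
  expect_equal(length(acc_tight), 1)
  # an implausibly slow decay (half-life of weeks) is rejected
  acc_narrow <- filter_fits(fits, ds$series, cv = 0.25,
                            hl_window = c(1, 2))
  expect_equal(length(acc_narrow), 0)
})

test_that("noiseless fitting recovers the generating configuration", {
  fit <- fixture_noiseless_fit()
  expect_true(fit$converged)
  expect_true(fit$accepted)
  expect_true(all(fit$ci_pass))
  expect_lt(sum(fit$objective), 0.01)
  expect_lte(fit$notch_fold, 3.5)
  # residual distortion: re-scoring the same model against outlier data
  # strictly increases the objective
  ds <- fixture_dataset(7, 0)
  outlier <- ds$series
  outlier$G$values[3] <- outlier$G$values[3] * 10
  refit <- evaluate_fit(fit, outlier, cv = 0.25)
  expect_gt(sum(refit$objective), sum(fit$objective))
})

test_that("PU.1 bounds derive from BCL11B positivity and contain truth", {
  profs <- fixture_profiles(7, 0)
  b <- derive_pu1_bounds(profs, n_mc = 2000, seed = 5)
  spec <- reference_spec()
  tr <- c(rho1 = spec$params$rho[1], rho2 = spec$params$rho[2],
          rho3 = spec$params$rho[3], rho4 = spec$params$rho[4],
          f_P = unname(spec$params$f[["P"]]),
          gamma_P = unname(spec$params$gamma[["P"]]))
  expect_true(all(tr >= b$lower & tr <= b$upper))
  expect_error(derive_pu1_bounds(profs, n_mc = 0), "positive")
  # refining the positivity grid only adds constraints: bounds tighten
  b_coarse <- derive_pu1_bounds(profs, n_mc = 800, seed = 6,
                                grid_step = 0.5)
  b_fine <- derive_pu1_bounds(profs, n_mc = 800, seed = 6,
                              grid_step = 0.1)
  expect_true(all(b_fine$lower >= b_coarse$lower - 1e-15))
  expect_true(all(b_fine$upper <= b_coarse$upper + 1e-15))
})

test_that("constrained annealing yields CI-passing PU.1 sets", {
  ds <- fixture_dataset(7, 0)
  profs <- fixture_profiles(7, 0)
  b <- derive_pu1_bounds(profs, n_mc = 2000, seed = 5)
  sets <- fit_pu1(ds$series, b, n_starts = 4, seed = 5)
  expect_gt(length(sets), 0)
  for (s in sets) {
    expect_lt(s$rho[4], min(s$rho[2], s$rho[3]))
    expect_true(s$ci_pass)
  }
  best <- sets[[which.min(vapply(sets, `[[`, numeric(1), "objective"))]]
  # the best survivor reproduces the noiseless PU.1 series closely
  expect_lt(best$objective, 5e-3)
  # f_P/gamma_P is the least-constrained feature; the best fit pins it to
  # within a factor of 2
  expect_lt(abs(log((best$f_P / best$gamma_P) / (150 / 4))), log(2))
})
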