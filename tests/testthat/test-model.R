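# ODE model: Notch signal, right-hand side, simulation, steady states.

test_that("Notch signal has logistic midpoint, saturation and monotonicity", {
  ns <- notch_spec(n_max = 2, alpha = 0.4, t_half = 1.5, floor = 0.5)
  expect_equal(notch_signal(1.5, ns), (0.5 + 2) / 2)
  expect_equal(notch_signal(1e6, ns), 2, tolerance = 1e-12)
  tt <- seq(-5, 10, by = 0.05)
  expect_false(is.unsorted(notch_signal(tt, ns)))
  expect_true(all(notch_signal(tt, ns) >= 0.5 &
                    notch_signal(tt, ns) <= 2))
  expect_error(notch_spec(alpha = 0), "alpha")
  expect_error(notch_spec(floor = 2, n_max = 1), "floor")
})

test_that("zero-state algebra of the right-hand side", {
  spec <- reference_spec()  # 1a-like check needs an OR gate with pure Notch
  spec_or <- model_spec("1a", model_parameters(
    eta = spec$params$eta, delta = spec$params$delta,
    kappa = c(0.5, 1e-3, 1e-3), rho = spec$params$rho,
    f = spec$params$f, gamma = spec$params$gamma), spec$notch)
  st <- c(T = 0, G = 0, B = 0, P = 0)
  r <- grn_rates(st, t = 2, spec_or)
  expect_equal(r[["P"]], 0)  # PU.1 has no regulated positive input
  sig <- notch_signal(2, spec_or$notch) / spec_or$notch$n_max
  expect_equal(r[["B"]],
               spec_or$params$f[["B"]] * 0.5 * sig / (1 + 0.5 * sig))
  expect_error(grn_rates(c(T = -1, G = 0, B = 0, P = 0), 0, spec_or),
               "nonnegative")
})

test_that("PU.1 repression of TCF-1 acts through the denominator only", {
  spec <- reference_spec()
  st <- c(T = 50, G = 50, B = 10, P = 30)
  base <- grn_rates(st, 2, spec)[["T"]]
  p2 <- spec$params
  stronger <- model_parameters(
    eta = c(p2$eta[1:3], p2$eta[4] * 10), delta = p2$delta,
    kappa = p2$kappa, rho = p2$rho, f = p2$f, gamma = p2$gamma)
  expect_lt(grn_rates(st, 2, model_spec(spec$logic, stronger,
                                        spec$notch))[["T"]], base)
})

test_that("pure decay integrates to the exponential closed form", {
  spec <- decay_only_spec()
  tt <- seq(0, 4, by = 0.5)
  traj <- simulate_grn(spec, c(T = 10, G = 5, B = 2, P = 8), tt)
  expect_equal(traj$T, 10 * exp(-1 * tt), tolerance = 1e-6)
  expect_equal(traj$G, 5 * exp(-2 * tt), tolerance = 1e-6)
})

test_that("clamped genes follow their profiles exactly", {
  spec <- reference_spec()
  tt <- 0:4
  traj <- simulate_grn(spec, c(), tt,
                       clamps = list(T = 10, G = function(t) 5 + t,
                                     B = 1, P = 2))
  expect_equal(traj$T, rep(10, 5))
  expect_equal(traj$G, 5 + tt)
  expect_equal(traj$P, rep(2, 5))
  expect_error(simulate_grn(spec, c(), tt, clamps = list(X = 1)),
               "unknown clamp")
  expect_error(simulate_grn(spec, c(T = 1, G = 1, B = 1, P = 1), c(1, 1)),
               "increasing")
})

test_that("long-time simulation agrees with the steady-state root", {
  spec <- reference_spec()
  init <- etp_initial_state(spec)
  ss <- steady_state(spec, spec$notch$n_max, init)
  t_end <- 60 / min(spec$params$gamma)
  traj <- simulate_grn(spec, init, c(0, t_end), notch_scale = 1)
  endpoint <- unlist(traj[2, c("T", "G", "B", "P")])
  scale <- pmax(abs(ss$state), 1e-8)
  expect_lt(max(abs(endpoint - ss$state) / scale), 1e-6)
  # residual of the polished root is essentially zero
  resid <- grn_rates(ss$state, 0, spec, notch_scale = 1)
  expect_lt(max(abs(resid) / (spec$params$f)), 1e-9)
})

test_that("trajectories stay nonnegative and below their ceilings", {
  set.seed(202)
  for (i in 1:15) {
    spec <- random_spec()
    ceil <- spec$params$f / spec$params$gamma
    init <- c(T = runif(1, 0, ceil[["T"]]), G = runif(1, 0, ceil[["G"]]),
              B = runif(1, 0, ceil[["B"]]), P = runif(1, 0, ceil[["P"]]))
    traj <- simulate_grn(spec, init, seq(0, 4, by = 0.2))
    for (g in c("T", "G", "B", "P")) {
      expect_true(all(traj[[g]] >= 0))
      expect_true(all(traj[[g]] <= max(ceil[[g]], init[[g]]) * (1 + 1e-6)))
    }
  }
})

test_that("P = 0 is an invariant manifold when runx_input = 0", {
  spec <- reference_spec()
  traj <- simulate_grn(spec, c(T = 5, G = 5, B = 5, P = 0), seq(0, 4, 0.5))
  expect_true(all(traj$P == 0))
  ss <- steady_state(spec, 0.7, c(T = 5, G = 5, B = 5, P = 0))
  expect_equal(ss$state[["P"]], 0)
})

test_that("stability flags agree with perturb-and-reintegrate", {
  set.seed(303)
  checked <- 0
  while (checked < 20) {
    spec <- random_spec()
    ceil <- spec$params$f / spec$params$gamma
    init <- c(T = runif(1, 0, ceil[["T"]]), G = runif(1, 0, ceil[["G"]]),
              B = runif(1, 0, ceil[["B"]]), P = runif(1, 0, ceil[["P"]]))
    ss <- tryCatch(steady_state(spec, spec$notch$n_max, init),
                   error = function(e) NULL)
    if (is.null(ss)) next
    checked <- checked + 1
    # a state reached by relaxation must be flagged stable, and a +-1% kick
    # must relax back to it
    expect_true(ss$stable)
    kick <- ss$state * (1 + 0.01 * sample(c(-1, 1), 4, replace = TRUE))
    t_end <- 30 / min(spec$params$gamma)
    back <- simulate_grn(spec, kick, c(0, t_end), notch_scale = 1)
    endpoint <- unlist(back[2, c("T", "G", "B", "P")])
    expect_lt(max(abs(endpoint - ss$state) / pmax(abs(ss$state), 1e-6)),
              1e-3)
  }
})

test_that("model_spec validates the kappa/minterm contract", {
  p <- reference_spec()$params
  expect_error(
    model_spec("8b", model_parameters(
      eta = p$eta, delta = p$delta, kappa = c(1e-5, 1e-9), rho = p$rho,
      f = p$f, gamma = p$gamma)),
    "compiles to 1 minterm")
})
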