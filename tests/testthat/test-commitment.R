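# Commitment analysis: steady-state selection, bifurcation sweeps,
# reversible/irreversible classification.

committed_start <- function(spec) {
  ceil <- spec$params$f / spec$params$gamma
  c(T = ceil[["T"]], G = ceil[["G"]], B = ceil[["B"]], P = 0)
}

test_that("the all-AND configuration shuts BCL11B off without Notch", {
  spec <- winning_model("8b")
  committed <- steady_state(spec, spec$notch$n_max, committed_start(spec),
                            clamp_pu1 = TRUE)$state
  expect_gt(committed[["B"]], 0)
  # with Notch in the only minterm, production is identically 0 at s = 0
  off <- steady_state(spec, 0, committed, clamp_pu1 = TRUE)$state
  expect_equal(off[["B"]], 0, tolerance = 1e-8)
})

test_that("winning-model sweeps classify 3 irreversible and 8b reversible", {
  expected <- c(`6d` = "irreversible", `7b` = "irreversible",
                `7d` = "irreversible", `8b` = "reversible")
  for (id in names(expected)) {
    spec <- winning_model(id)
    committed <- steady_state(spec, spec$notch$n_max,
                              committed_start(spec),
                              clamp_pu1 = TRUE)$state
    down <- bifurcation_scan(spec, committed, "down", n_points = 21,
                             clamp_pu1 = TRUE, root_starts = 0)
    cls <- classify_commitment(down)
    expect_equal(unname(cls$classification[["B"]]), expected[[id]],
                 info = id)
    # TCF-1 and GATA-3 sustain themselves without Notch in all four models
    expect_equal(unname(cls$classification[["T"]]), "irreversible")
  }
})

test_that("continuation and multi-start roots agree on the stable branch", {
  spec <- winning_model("6d")
  committed <- steady_state(spec, spec$notch$n_max, committed_start(spec),
                            clamp_pu1 = TRUE)$state
  down <- bifurcation_scan(spec, committed, "down", n_points = 11,
                           clamp_pu1 = TRUE, root_starts = 15, seed = 4)
  ceil <- spec$params$f / spec$params$gamma
  for (i in seq_along(down$s)) {
    br <- down$branches[down$branches$s == down$s[i] &
                          down$branches$stable, ]
    cont_B <- down$continuation$B[i]
    match_branch <- any(abs(br$value[br$gene == "B"] - cont_B) <=
                          1e-4 * (1 + ceil[["B"]]))
    expect_true(match_branch, info = paste("s =", down$s[i]))
  }
})

test_that("hysteresis implies a separating unstable steady state", {
  # full four-gene toggle: PU.1-high and committed states coexist without
  # Notch (the PU.1-clamped subsystem, with its linear activation
  # numerators and slaved BCL11B, cannot hold two stable states, so the
  # hysteresis check needs the complete network)
  spec <- toggle_spec()
  ceil <- spec$params$f / spec$params$gamma
  committed <- steady_state(spec, spec$notch$n_max, committed_start(spec))
  p_high <- steady_state(spec, 0, c(T = 0, G = 0, B = 0,
                                    P = ceil[["P"]] / 2))
  down <- bifurcation_scan(spec, committed$state, "down", n_points = 11,
                           root_starts = 0)
  up <- bifurcation_scan(spec, p_high$state, "up", n_points = 11,
                         root_starts = 0)
  # the sweeps separate (hysteresis) on part of the grid
  up_rev <- rev(up$continuation$B)
  sep <- which(abs(down$continuation$B - up_rev) >
                 0.05 * pmax(down$continuation$B, up_rev, 1e-12))
  expect_gt(length(sep), 0)
  # at a grid point where both branch endpoints are stable states, root
  # finding from bridge starts locates an unstable state strictly between
  i <- sep[which(down$continuation$stable[sep] &
                   rev(up$continuation$stable)[sep])][1]
  expect_false(is.na(i))
  s_i <- down$s[i]
  a <- unlist(down$continuation[i, c("T", "G", "B", "P")])
  b <- unlist(up$continuation[nrow(up$continuation) + 1 - i,
                              c("T", "G", "B", "P")])
  lo <- min(a[["B"]], b[["B"]]); hi <- max(a[["B"]], b[["B"]])
  found_unstable <- FALSE
  for (lam in seq(0.1, 0.9, by = 0.1)) {
    r <- find_root(spec, s_i * spec$notch$n_max, lam * a + (1 - lam) * b)
    if (r$converged && !r$stable && r$state[["B"]] > lo &&
          r$state[["B"]] < hi)
      found_unstable <- TRUE
  }
  expect_true(found_unstable)
})

test_that("PU.1 never reactivates from the committed state", {
  # full four-gene dynamics with a realistic PU.1 leg, P committed to 0
  for (id in winning_configurations()) {
    spec <- winning_model(id)
    spec <- set_pu1_parameters(spec, rho = c(0.1, 0.004, 0.008, 0.003),
                               f_P = 150, gamma_P = 4)
    committed <- steady_state(spec, spec$notch$n_max,
                              committed_start(spec))$state
    expect_equal(committed[["P"]], 0)
    down <- bifurcation_scan(spec, committed, "down", n_points = 11,
                             root_starts = 0)
    expect_true(all(down$continuation$P == 0))
    cls <- classify_commitment(down)
    expect_equal(unname(cls$classification[["P"]]), "irreversible-off")
  }
})

test_that("zero-production models collapse to a single origin branch", {
  spec <- decay_only_spec()
  down <- bifurcation_scan(spec, c(T = 1, G = 1, B = 1, P = 1), "down",
                           n_points = 11, root_starts = 5, seed = 2)
  for (g in c("T", "G", "B", "P"))
    expect_true(all(abs(down$continuation[[g]]) < 1e-8))
  expect_true(all(down$continuation$stable))
  expect_error(bifurcation_scan(spec, c(T = 0, G = 0, B = 0, P = 0),
                                "down", n_points = 5), "at least 10")
})

test_that("steady-state selection separates committed from uncommitted", {
  spec <- reference_spec()
  day0 <- etp_initial_state(spec)
  ss <- steady_state(spec, spec$notch$n_max, day0)
  day4 <- list(T = ss$state[["T"]], G = ss$state[["G"]],
               B = ss$state[["B"]])
  # enormous TCF-1 repression and a tiny production ceiling: P collapses
  commit_set <- list(rho = c(0.01, 5, 0.01, 0.005), f_P = 20,
                     gamma_P = 4)
  # no repression and a huge production ceiling: P stays high
  high_set <- list(rho = c(0.5, 1e-9, 1e-9, 1e-10), f_P = 5000,
                   gamma_P = 1)
  res <- select_steady_sets(spec, list(commit_set, high_set), day0, day4)
  expect_length(res, 1)
  expect_equal(res[[1]]$f_P, 20)
  expect_length(attr(res, "rejected"), 1)
  expect_length(select_steady_sets(spec, list(), day0, day4), 0)
})

test_that("a constant positive PU.1 input does not rescue PU.1", {
  # robustness variant: adding a RUNX1-like constant drive to PU.1 leaves
  # the committed pattern intact (P stays far below its ceiling, BCL11B
  # stays high along the downward sweep)
  spec <- set_pu1_parameters(winning_model("6d"),
                             rho = c(0.1, 0.004, 0.008, 0.003),
                             f_P = 150, gamma_P = 4, runx_input = 0.3)
  ceil <- spec$params$f / spec$params$gamma
  committed <- steady_state(spec, spec$notch$n_max,
                            committed_start(spec))$state
  expect_lt(committed[["P"]], 0.01 * ceil[["P"]])
  down <- bifurcation_scan(spec, committed, "down", n_points = 11,
                           root_starts = 0)
  expect_true(all(down$continuation$P < 0.01 * ceil[["P"]]))
  expect_true(all(down$continuation$B > 0.5 * down$continuation$B[1]))
})
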