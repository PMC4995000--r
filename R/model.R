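# Four-gene ODE model: Shea-Ackers production minus linear decay, driven by
# a sigmoidal Notch signal. Genes: T = TCF-1, G = GATA-3, B = BCL11B,
# P = PU.1. Time unit: days on the developmental window [0, 4].

.genes <- c("T", "G", "B", "P")

#' Sigmoidal Notch signal specification
#'
#' Notch signalling activity is modelled as a rising logistic in time:
#' `signal(t) = floor + (n_max - floor) / (1 + exp(-(t - t_half)/alpha))`.
#' The floor bounds the fold increase `signal(4)/signal(0)` from above by
#' roughly `n_max/floor`; the default floor `n_max/3.5` makes the maximal
#' admissible fold (3.5 between the ETP and DN3a stages) attainable.
#'
#' @param n_max Maximum signal (arbitrary units).
#' @param alpha Sigmoid steepness (days).
#' @param t_half Sigmoid midpoint (days).
#' @param floor Signal at `t -> -Inf`; nonnegative, `< n_max`.
#' @return Object of class `notch_spec`.
#' @export
notch_spec <- function(n_max = 1, alpha = 0.5, t_half = 1.5,
                       floor = n_max / 3.5) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be positive")
  if (n_max <= 0) stop("n_max must be positive")
  if (floor < 0 || floor >= n_max) stop("floor must be in [0, n_max)")
  structure(list(n_max = n_max, alpha = alpha, t_half = t_half,
                 floor = floor), class = "notch_spec")
}

#' Evaluate the Notch signal
#'
#' @param t Time(s) in days.
#' @param notch A [notch_spec()].
#' @return Signal value(s); nondecreasing in `t`, within `[floor, n_max]`.
#' @export
notch_signal <- function(t, notch) {
  stopifnot(inherits(notch, "notch_spec"))
  notch$floor + (notch$n_max - notch$floor) *
    stats::plogis((t - notch$t_half) / notch$alpha)
}

#' Fold increase of the Notch signal between two times
#' @param notch A [notch_spec()].
#' @param t1,t2 Times in days (defaults: the ETP and DN3a days, 0 and 4).
#' @return `signal(t2) / signal(t1)`.
#' @export
notch_fold <- function(notch, t1 = 0, t2 = 4) {
  notch_signal(t2, notch) / notch_signal(t1, notch)
}

#' Kinetic parameters of the four-gene model
#'
#' Notch-coupled weights (`eta[1]`, `delta[1]`, and every kappa weighting a
#' Notch-containing minterm) are stored as products with the maximum signal
#' `n_max` — the two factors are not separately identifiable — and are
#' rescaled by `signal(t)/n_max` during evaluation.
#'
#' @param eta Length-4 weights of the TCF-1 equation: Notch product
#'   (`eta1*N`), TCF-1 self-activation, GATA-3 activation, PU.1 repression.
#' @param delta Length-3 weights of the GATA-3 equation: Notch product,
#'   TCF-1 activation, PU.1 repression.
#' @param kappa Kinetic weights of the compiled BCL11B rate law, one per
#'   minterm (Notch-containing weights as products with `n_max`).
#' @param rho Length-4 weights of the PU.1 equation: self-activation, and
#'   repression by TCF-1, GATA-3, BCL11B.
#' @param f Named maximal production rates `c(T=, G=, B=, P=)` (units/day).
#' @param gamma Named decay rates `c(T=, G=, B=, P=)` (per day).
#' @param runx_input Optional constant positive input to PU.1 (e.g. a
#'   RUNX1-like activator); default 0.
#' @return Object of class `model_parameters`.
#' @export
model_parameters <- function(eta, delta, kappa, rho = rep(0, 4),
                             f, gamma, runx_input = 0) {
  stopifnot(length(eta) == 4, length(delta) == 3, length(rho) == 4)
  f <- f[.genes]; gamma <- gamma[.genes]
  vals <- c(eta, delta, kappa, rho, f, gamma, runx_input)
  if (anyNA(vals) || any(vals < 0))
    stop("all parameters must be nonnegative and non-missing")
  if (any(gamma <= 0)) stop("decay rates gamma must be positive")
  structure(list(eta = unname(eta), delta = unname(delta),
                 kappa = unname(kappa), rho = unname(rho),
                 f = f, gamma = gamma, runx_input = runx_input),
            class = "model_parameters")
}

#' Full model specification
#'
#' Couples a BCL11B logic configuration, kinetic parameters and a Notch
#' signal into one simulatable ODE system.
#'
#' @param logic A [logic_config()] (or variant id string).
#' @param params A [model_parameters()]; `kappa` length must equal the
#'   compiled rate law's minterm count.
#' @param notch A [notch_spec()].
#' @return Object of class `model_spec` (fields `logic`, `rate_law`,
#'   `params`, `notch`).
#' @export
model_spec <- function(logic, params, notch = notch_spec()) {
  if (is.character(logic)) logic <- logic_config(logic)
  stopifnot(inherits(logic, "logic_config"),
            inherits(params, "model_parameters"),
            inherits(notch, "notch_spec"))
  rl <- compile_rate_law(logic)
  if (length(params$kappa) != n_kappa(rl))
    stop("kappa has length ", length(params$kappa), " but configuration ",
         logic$variant_id, " compiles to ", n_kappa(rl), " minterm(s)")
  structure(list(logic = logic, rate_law = rl, params = params,
                 notch = notch), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> configuration %s: %s\n", x$logic$variant_id,
              x$logic$gate))
  cat("  BCL11B rate law: S =", format(x$rate_law), "\n")
  cat(sprintf("  ceilings f/gamma: T=%.3g G=%.3g B=%.3g P=%.3g\n",
              x$params$f["T"] / x$params$gamma["T"],
              x$params$f["G"] / x$params$gamma["G"],
              x$params$f["B"] / x$params$gamma["B"],
              x$params$f["P"] / x$params$gamma["P"]))
  invisible(x)
}

#' Model right-hand side (production minus decay rates)
#'
#' Evaluates the four time-derivatives at a state. Each gene's production is
#' a Shea-Ackers occupancy ratio times a maximal rate, minus linear decay:
#' \itemize{
#' \item TCF-1: activators Notch, TCF-1 (self), GATA-3; repressor PU.1.
#' \item GATA-3: activators Notch, TCF-1; repressor PU.1 (regulators act as
#'   monomers; BCL11B absent — it is not expressed when these genes first
#'   activate).
#' \item BCL11B: the compiled combinatorial rate law over Notch, TCF-1 (Hill
#'   exponent `n_T`), GATA-3 (`n_G`).
#' \item PU.1: self-activation plus optional constant input in the
#'   numerator; TCF-1, GATA-3, BCL11B as pure denominator repressors
#'   (6 free parameters, no regulated positive input).
#' }
#'
#' @param state Named nonnegative vector `c(T=, G=, B=, P=)`.
#' @param t Time in days (used to evaluate the Notch signal).
#' @param spec A [model_spec()].
#' @param notch_scale If non-NULL, freeze the relative Notch signal at this
#'   value in `[0, 1]` (scale factor `s` applied to all Notch-coupled
#'   products) instead of evaluating the sigmoid at `t`.
#' @return Named numeric vector of the four rates.
#' @export
grn_rates <- function(state, t, spec, notch_scale = NULL) {
  if (any(state < 0)) stop("state components must be nonnegative")
  p <- spec$params
  s_rel <- if (is.null(notch_scale)) {
    notch_signal(t, spec$notch) / spec$notch$n_max
  } else notch_scale
  T <- state[["T"]]; G <- state[["G"]]; B <- state[["B"]]; P <- state[["P"]]
  numT <- p$eta[1] * s_rel + p$eta[2] * T + p$eta[3] * G
  dT <- p$f[["T"]] * numT / (1 + numT + p$eta[4] * P) - p$gamma[["T"]] * T
  numG <- p$delta[1] * s_rel + p$delta[2] * T
  dG <- p$f[["G"]] * numG / (1 + numG + p$delta[3] * P) - p$gamma[["G"]] * G
  conc <- c(Notch = s_rel, `TCF-1` = T, `GATA-3` = G)
  SB <- minterm_sum(spec$rate_law, p$kappa, conc)
  dB <- p$f[["B"]] * SB / (1 + SB) - p$gamma[["B"]] * B
  numP <- p$rho[1] * P + p$runx_input
  denP <- 1 + numP + p$rho[2] * T + p$rho[3] * G + p$rho[4] * B
  dP <- p$f[["P"]] * numP / denP - p$gamma[["P"]] * P
  c(T = unname(dT), G = unname(dG), B = unname(dB), P = unname(dP))
}

# resolve a clamp entry (constant or function of t) at times tt
.clamp_at <- function(clamp, tt) {
  if (is.function(clamp)) vapply(tt, clamp, numeric(1)) else
    rep_len(as.numeric(clamp), length(tt))
}

#' Simulate the model
#'
#' Integrates the ODE system with a stiff-capable solver (`deSolve::lsoda`,
#' relative tolerance 1e-8). Genes named in `clamps` follow their supplied
#' profiles exactly and their equations are not integrated (the "forcing
#' function" device used during fitting). Positivity is a model property,
#' not an integrator guarantee: undershoots smaller than a tiny
#' scale-relative tolerance are clipped to zero, larger ones raise an error.
#'
#' @param spec A [model_spec()].
#' @param init Named initial state `c(T=, G=, B=, P=)` (clamped genes may be
#'   omitted).
#' @param times Increasing vector of output times (days).
#' @param clamps Named list mapping gene names to constants or functions of
#'   time.
#' @param notch_scale Optional frozen relative Notch level (see
#'   [grn_rates()]).
#' @return Object of class `grn_trajectory`: a data.frame with column
#'   `time_days` and one column per gene.
#' @export
simulate_grn <- function(spec, init, times, clamps = list(),
                         notch_scale = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  clamped <- names(clamps)
  if (!all(clamped %in% .genes))
    stop("unknown clamp gene(s): ",
         paste(setdiff(clamped, .genes), collapse = ", "))
  free <- setdiff(.genes, clamped)
  ceil <- spec$params$f / spec$params$gamma
  if (length(free) == 0L) {
    out <- data.frame(time_days = times)
    for (g in .genes) out[[g]] <- .clamp_at(clamps[[g]], times)
    return(structure(out, class = c("grn_trajectory", "data.frame")))
  }
  y0 <- vapply(free, function(g) init[[g]], numeric(1))
  if (anyNA(y0) || any(y0 < 0)) stop("init must be nonnegative for ",
                                     paste(free, collapse = ", "))
  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    full <- numeric(4); names(full) <- .genes
    full[free] <- y
    for (g in clamped) full[g] <- .clamp_at(clamps[[g]], t)
    list(grn_rates(full, t, spec, notch_scale)[free])
  }
  atol <- pmax(1e-10, 1e-12 * ceil[free])
  sol <- deSolve::lsoda(y = y0, times = times, func = deriv, parms = NULL,
                        rtol = 1e-8, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failed; last valid time ", max(sol[, "time"]))
  out <- data.frame(time_days = sol[, "time"])
  for (g in .genes) {
    if (g %in% clamped) out[[g]] <- .clamp_at(clamps[[g]], out$time_days)
    else {
      v <- sol[, g]
      under <- -1e-9 * (1 + ceil[[g]])
      if (any(v < under))
        stop("negative undershoot beyond tolerance for gene ", g)
      out[[g]] <- pmax(v, 0)
    }
  }
  structure(out, class = c("grn_trajectory", "data.frame"))
}

# damped Newton root finder for rhs = 0 on the free genes (internal)
.newton_steady <- function(fn, x0, scale, max_iter = 60, tol = 1e-10) {
  x <- pmax(x0, 0)
  for (it in seq_len(max_iter)) {
    r <- fn(x)
    if (max(abs(r) / scale) < tol) return(list(x = x, converged = TRUE))
    J <- .num_jacobian(fn, x, scale)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) return(list(x = x, converged = FALSE))
    lam <- 1
    f0 <- sum((r / scale)^2)
    repeat {
      xn <- pmax(x + lam * step, 0)
      rn <- fn(xn)
      if (sum((rn / scale)^2) < f0 || lam < 1e-6) break
      lam <- lam / 2
    }
    if (max(abs(xn - x) / (scale + abs(x))) < 1e-14) {
      x <- xn
      break
    }
    x <- xn
  }
  r <- fn(x)
  list(x = x, converged = max(abs(r) / scale) < tol * 100)
}

# central-difference Jacobian of fn at x (internal)
.num_jacobian <- function(fn, x, scale = rep(1, length(x))) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-6 * (abs(x[j]) + 1e-3 * scale[j])
    xp <- x; xm <- x
    xp[j] <- x[j] + h
    xm[j] <- max(x[j] - h, 0)
    J[, j] <- (fn(xp) - fn(xm)) / (xp[j] - xm[j])
  }
  J
}

#' Locate a steady state at a fixed Notch level
#'
#' Freezes the Notch signal at `notch_level` (making the system autonomous),
#' integrates from `init` over several decay timescales, then polishes the
#' endpoint by damped Newton iteration on the right-hand side. Stability is
#' read from the sign of the dominant eigenvalue of the numerically
#' differentiated Jacobian.
#'
#' @param spec A [model_spec()].
#' @param notch_level Absolute Notch level (same units as the spec's
#'   `n_max`); the internal scale factor is `notch_level / n_max`.
#' @param init Named initial state.
#' @param clamp_pu1 If TRUE, PU.1 is held at `init[["P"]]` and excluded from
#'   the root problem (used when only TCF-1/GATA-3/BCL11B parameters are
#'   trusted).
#' @param relax_factor Integration horizon in units of the slowest decay
#'   time `1/min(gamma)`; default 40.
#' @return List with `state` (named 4-vector), `stable` (logical),
#'   `eigenvalues` (of the free-gene Jacobian) and `converged`.
#' @export
steady_state <- function(spec, notch_level, init, clamp_pu1 = FALSE,
                         relax_factor = 40) {
  stopifnot(inherits(spec, "model_spec"), notch_level >= 0)
  s <- notch_level / spec$notch$n_max
  free <- if (clamp_pu1) c("T", "G", "B") else .genes
  p_fixed <- if (clamp_pu1) init[["P"]] else NA_real_
  fn <- function(x) {
    full <- numeric(4); names(full) <- .genes
    full[free] <- pmax(x, 0)
    if (clamp_pu1) full["P"] <- p_fixed
    grn_rates(full, 0, spec, notch_scale = s)[free]
  }
  ceil <- (spec$params$f / spec$params$gamma)[free]
  scale <- pmax(ceil, 1e-6)
  # relaxation
  t_end <- relax_factor / min(spec$params$gamma[free])
  tt <- c(0, t_end / 100, t_end / 10, t_end / 3, t_end)
  clamps <- if (clamp_pu1) list(P = p_fixed) else list()
  traj <- simulate_grn(spec, init, tt, clamps = clamps, notch_scale = s)
  x_relaxed <- vapply(free, function(g) traj[[g]][nrow(traj)], numeric(1))
  ns <- .newton_steady(fn, x_relaxed, scale)
  if (!ns$converged)
    stop("steady_state did not converge at notch level ", notch_level)
  state <- numeric(4); names(state) <- .genes
  state[free] <- ns$x
  if (clamp_pu1) state["P"] <- p_fixed
  J <- .num_jacobian(fn, ns$x, scale)
  ev <- eigen(J, only.values = TRUE)$values
  list(state = state, stable = max(Re(ev)) < 0, eigenvalues = ev,
       converged = TRUE)
}

#' Solve the steady-state equations from a given start (no relaxation)
#'
#' Newton iteration only; used for multi-start searches for coexisting
#' (including unstable) steady states.
#'
#' @inheritParams steady_state
#' @param start Named start state for the free genes.
#' @return As [steady_state()], plus `converged` possibly FALSE.
#' @export
find_root <- function(spec, notch_level, start, clamp_pu1 = FALSE) {
  s <- notch_level / spec$notch$n_max
  free <- if (clamp_pu1) c("T", "G", "B") else .genes
  p_fixed <- if (clamp_pu1) start[["P"]] else NA_real_
  fn <- function(x) {
    full <- numeric(4); names(full) <- .genes
    full[free] <- pmax(x, 0)
    if (clamp_pu1) full["P"] <- p_fixed
    grn_rates(full, 0, spec, notch_scale = s)[free]
  }
  ceil <- (spec$params$f / spec$params$gamma)[free]
  scale <- pmax(ceil, 1e-6)
  ns <- .newton_steady(fn, vapply(free, function(g) start[[g]], numeric(1)),
                       scale)
  state <- numeric(4); names(state) <- .genes
  state[free] <- ns$x
  if (clamp_pu1) state["P"] <- p_fixed
  ev <- eigen(.num_jacobian(fn, ns$x, scale), only.values = TRUE)$values
  list(state = state, stable = max(Re(ev)) < 0, eigenvalues = ev,
       converged = ns$converged)
}
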