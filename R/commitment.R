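# Full-network steady-state selection and bifurcation analysis over the
# maximum Notch level: bistability, hysteresis and the reversible vs
# irreversible classification of lineage commitment.

#' Select PU.1 parameter sets by full-network steady state
#'
#' For each candidate PU.1 set, the full four-gene network (TGB parameters
#' fixed to their best values in `spec`) is integrated to steady state from
#' a day-0-like initial condition at full Notch. A set is accepted iff the
#' steady state is committed-like: TCF-1, GATA-3 and BCL11B at or above
#' `high_frac` of their reference day-4 values and PU.1 at or below
#' `low_frac` of its day-0 value.
#'
#' @param spec A [model_spec()] with trusted TGB parameters.
#' @param pu1_sets List of PU.1 parameter sets (as from [fit_pu1()]).
#' @param init Day-0-like initial state.
#' @param day4_values Named reference values for T, G, B (fitted day-4
#'   levels).
#' @param high_frac,low_frac Acceptance thresholds; defaults 0.5 and 0.1.
#' @return The accepted subset of `pu1_sets`; rejected sets are recorded in
#'   attribute `"rejected"` with a diagnostic.
#' @export
select_steady_sets <- function(spec, pu1_sets, init, day4_values,
                               high_frac = 0.5, low_frac = 0.1) {
  accepted <- list(); rejected <- list()
  for (i in seq_along(pu1_sets)) {
    set <- pu1_sets[[i]]
    full <- set_pu1_parameters(spec, rho = set$rho, f_P = set$f_P,
                               gamma_P = set$gamma_P)
    ss <- tryCatch(steady_state(full, full$notch$n_max, init),
                   error = function(e) e)
    if (inherits(ss, "error")) {
      rejected[[length(rejected) + 1]] <-
        c(set, list(reason = conditionMessage(ss)))
      next
    }
    high_ok <- all(ss$state[c("T", "G", "B")] >=
                     high_frac * unlist(day4_values)[c("T", "G", "B")])
    low_ok <- ss$state[["P"]] <= low_frac * init[["P"]]
    if (high_ok && low_ok) accepted[[length(accepted) + 1]] <- set
    else rejected[[length(rejected) + 1]] <-
        c(set, list(reason = sprintf("steady state not committed-like (high=%s, low=%s)",
                                     high_ok, low_ok)))
  }
  attr(accepted, "rejected") <- rejected
  accepted
}

#' Bifurcation scan over the maximum Notch level
#'
#' Sweeps the Notch scale factor `s` (the frozen relative signal level,
#' `s = 1` at full Notch) across `[0, 1]` in `n_points` steps. Along the
#' sweep, the stable branch is tracked by simulation-based continuation:
#' at each `s` the system is relaxed to steady state starting from the
#' previous point's state. Additionally, coexisting steady states (stable
#' and unstable) are charted at each `s` by multi-start damped-Newton root
#' finding from `root_starts` random states inside the box
#' `[0, f/gamma]` per gene; stability labels come from the Jacobian
#' eigenvalues.
#'
#' @param spec A [model_spec()].
#' @param start_state Named state from which the sweep starts (e.g. the
#'   committed state for a downward sweep).
#' @param direction `"down"` (s: 1 -> 0) or `"up"` (s: 0 -> 1).
#' @param n_points Number of sweep points (>= 10); default 101.
#' @param clamp_pu1 Hold PU.1 at `start_state[["P"]]` (used when only TGB
#'   parameters are trusted).
#' @param root_starts Random root-finding starts per sweep point; 0 skips
#'   the coexisting-state search. Default 20.
#' @param seed RNG seed for the random starts.
#' @return Object of class `bifurcation_diagram`: list with `variant_id`,
#'   `direction`, `s` (sweep grid), `continuation` (data.frame: s, T, G, B,
#'   P, stable), `branches` (data.frame: s, branch_id, gene, value, stable),
#'   `committed` (the state at the sweep start).
#' @export
bifurcation_scan <- function(spec, start_state, direction = c("down", "up"),
                             n_points = 101, clamp_pu1 = FALSE,
                             root_starts = 20, seed = 1) {
  direction <- match.arg(direction)
  if (n_points < 10) stop("n_points must be at least 10")
  s_grid <- if (direction == "down") seq(1, 0, length.out = n_points)
            else seq(0, 1, length.out = n_points)
  genes <- .genes
  ceil <- spec$params$f / spec$params$gamma
  cont <- matrix(NA_real_, n_points, 4, dimnames = list(NULL, genes))
  stable <- logical(n_points)
  state <- start_state
  for (i in seq_along(s_grid)) {
    ss <- steady_state(spec, s_grid[i] * spec$notch$n_max, state,
                       clamp_pu1 = clamp_pu1)
    state <- ss$state
    cont[i, ] <- state[genes]
    stable[i] <- ss$stable
  }
  branches <- NULL
  if (root_starts > 0) {
    set.seed(as.integer(seed))
    free <- if (clamp_pu1) c("T", "G", "B") else genes
    rows <- list()
    for (i in seq_along(s_grid)) {
      roots <- list(list(state = cont[i, ], stable = stable[i]))
      for (k in seq_len(root_starts)) {
        # alternate uniform and log-uniform starts: saddles often sit
        # orders of magnitude below the attractors
        x0 <- vapply(genes, function(g) {
          if (k %% 2 == 0) stats::runif(1, 0, ceil[[g]])
          else ceil[[g]] * 10 ^ stats::runif(1, -6, 0)
        }, numeric(1))
        if (clamp_pu1) x0["P"] <- start_state[["P"]]
        r <- find_root(spec, s_grid[i] * spec$notch$n_max, x0,
                       clamp_pu1 = clamp_pu1)
        if (!r$converged || any(r$state < -1e-9)) next
        dup <- any(vapply(roots, function(rt) {
          all(abs(rt$state - r$state) <= 1e-4 * (1 + ceil)) }, logical(1)))
        if (!dup)
          roots[[length(roots) + 1]] <- list(state = pmax(r$state, 0),
                                             stable = r$stable)
      }
      ord <- order(vapply(roots, function(rt) rt$state[["B"]], numeric(1)))
      roots <- roots[ord]
      for (b in seq_along(roots)) for (g in genes)
        rows[[length(rows) + 1]] <- data.frame(
          s = s_grid[i], branch_id = b, gene = g,
          value = roots[[b]]$state[[g]], stable = roots[[b]]$stable)
    }
    branches <- do.call(rbind, rows)
  }
  structure(list(
    variant_id = spec$logic$variant_id, direction = direction, s = s_grid,
    continuation = data.frame(s = s_grid, cont, stable = stable),
    branches = branches,
    committed = start_state), class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf(
    "<bifurcation_diagram %s, %s sweep> %d points; B: %.3g at s=%.2f -> %.3g at s=%.2f\n",
    x$variant_id, x$direction, length(x$s),
    x$continuation$B[1], x$s[1],
    x$continuation$B[length(x$s)], x$s[length(x$s)]))
  invisible(x)
}

#' Write a bifurcation diagram as CSV (s, gene, branch_id, value, stable)
#' @param diagram A `bifurcation_diagram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diagram_csv <- function(diagram, path) {
  df <- diagram$branches
  if (is.null(df)) {
    cont <- diagram$continuation
    df <- do.call(rbind, lapply(.genes, function(g)
      data.frame(s = cont$s, branch_id = 1L, gene = g, value = cont[[g]],
                 stable = cont$stable)))
  }
  utils::write.csv(df[order(df$s, df$branch_id, df$gene), ], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify per-gene commitment behaviour from sweep diagrams
#'
#' A gene is classified from the downward continuation branch (started at
#' the committed state) and, when available, the upward branch:
#' \itemize{
#' \item `"irreversible"` — the downward branch at `s = 0` stays within 50\%
#'   (by default) of the committed value: removing Notch does not undo
#'   commitment.
#' \item `"irreversible-off"` — committed value is (numerically) zero and
#'   the gene never reactivates along the sweep (the PU.1 case).
#' \item `"reversible"` — the downward branch collapses to the low branch
#'   when Notch is removed.
#' \item `"monostable"` — upward and downward branches coincide everywhere
#'   (within the bistability tolerance); no hysteresis.
#' }
#' The bistable region (sweep values where the branches differ by more than
#' `bistable_tol` relative) is reported per gene when both sweeps are given.
#'
#' @param diagram_down Downward-sweep `bifurcation_diagram`.
#' @param diagram_up Optional upward-sweep diagram on the same grid
#'   (reversed); NULL restricts the classification to the 50\% rule.
#' @param committed_frac Fraction of the committed value that must persist
#'   at `s = 0` for irreversibility; default 0.5.
#' @param bistable_tol Relative branch-separation threshold; default 0.05.
#' @return Object of class `commitment_classification`: list with
#'   `classification` (named character per gene) and `bistable_region`
#'   (named list of s-ranges or NULL).
#' @export
classify_commitment <- function(diagram_down, diagram_up = NULL,
                                committed_frac = 0.5, bistable_tol = 0.05) {
  stopifnot(inherits(diagram_down, "bifurcation_diagram"),
            diagram_down$direction == "down")
  cont_d <- diagram_down$continuation
  n <- nrow(cont_d)
  cls <- character(0); bist <- list()
  for (g in .genes) {
    down <- cont_d[[g]]
    committed <- down[1]
    end0 <- down[n]  # value at s = 0
    scale_g <- max(abs(down), 1e-12)
    bist_region <- NULL
    if (!is.null(diagram_up)) {
      stopifnot(diagram_up$direction == "up",
                length(diagram_up$s) == length(diagram_down$s))
      up <- rev(diagram_up$continuation[[g]])  # align to the down grid
      rel <- abs(down - up) / pmax(abs(down), abs(up), 1e-12)
      sep <- rel > bistable_tol
      if (any(sep)) bist_region <- range(diagram_down$s[sep])
    }
    if (committed <= 1e-9 * scale_g || committed < 1e-12) {
      cls[g] <- if (max(down) <= 1e-6 * max(scale_g, 1)) "irreversible-off"
                else "reversible"
    } else if (end0 >= committed_frac * committed) {
      cls[g] <- "irreversible"
    } else if (!is.null(diagram_up) && is.null(bist_region)) {
      cls[g] <- "monostable"
    } else {
      cls[g] <- "reversible"
    }
    bist[[g]] <- bist_region
  }
  structure(list(classification = cls, bistable_region = bist,
                 variant_id = diagram_down$variant_id),
            class = "commitment_classification")
}

#' @export
print.commitment_classification <- function(x, ...) {
  cat(sprintf("<commitment_classification %s>\n", x$variant_id))
  for (g in names(x$classification)) {
    br <- x$bistable_region[[g]]
    cat(sprintf("  %s: %s%s\n", g, x$classification[[g]],
                if (is.null(br)) "" else
                  sprintf(" (bistable for s in [%.2f, %.2f])", br[1], br[2])))
  }
  invisible(x)
}

#' Headline irreversibility count over the winning configurations
#'
#' Instantiates each winning configuration from the packaged parameter
#' table, relaxes to the committed state at full Notch from a
#' committed-like start (T, G, B at their production ceilings) with PU.1
#' clamped at 0, sweeps the Notch scale factor down to zero by
#' simulation-based continuation, and classifies BCL11B. Returns the
#' per-configuration classification and the number classified irreversible.
#'
#' @param configs Variant ids; default [winning_configurations()].
#' @param n_points Sweep resolution; default 101.
#' @param root_starts Coexisting-state search starts per point; default 0
#'   (the headline count needs only the continuation branch).
#' @return List with `classifications` (named character) and
#'   `n_irreversible`.
#' @export
irreversibility_headline <- function(configs = winning_configurations(),
                                     n_points = 101, root_starts = 0) {
  cls <- character(0)
  for (id in configs) {
    spec <- winning_model(id)
    ceil <- spec$params$f / spec$params$gamma
    start <- c(T = ceil[["T"]], G = ceil[["G"]], B = ceil[["B"]], P = 0)
    committed <- steady_state(spec, spec$notch$n_max, start,
                              clamp_pu1 = TRUE)$state
    down <- bifurcation_scan(spec, committed, "down", n_points = n_points,
                             clamp_pu1 = TRUE, root_starts = root_starts)
    cls[id] <- classify_commitment(down)$classification[["B"]]
  }
  list(classifications = cls,
       n_irreversible = sum(cls == "irreversible"))
}
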