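# Packaged parameter fixture: published mean/SD kinetic parameters for the
# four winning BCL11B configurations (6d, 7b, 7d, 8b), keyed by variant id.

#' Winning-model parameter table
#'
#' Published mean and standard deviation of the fitted kinetic parameters of
#' the TCF-1/GATA-3/BCL11B subsystem (plus the Notch sigmoid steepness
#' `alpha` and the reported half-lives) for the four configurations that
#' survived model selection: 6d, 7b, 7d and 8b. Notch-coupled weights are
#' products with the maximum signal (`eta1N`, `delta1N`, `kappa1N`).
#'
#' @return Data frame with columns `parameter`, `config`, `mean`, `sd`.
#' @export
winning_parameter_table <- function() {
  path <- system.file("extdata", "winning_parameters.csv",
                      package = "tcellcommit", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Instantiate a winning model from the packaged parameter table
#'
#' Builds a [model_spec()] for one of the four winning configurations using
#' the published mean parameters. The printed table covers only the
#' TCF-1/GATA-3/BCL11B + Notch subsystem; PU.1 is given an inert default
#' (no production, unit decay) suitable for analyses where PU.1 is clamped —
#' supply fitted PU.1 parameters with [set_pu1_parameters()] for full
#' four-gene dynamics.
#'
#' @param variant_id One of `"6d"`, `"7b"`, `"7d"`, `"8b"`.
#' @param notch Optional [notch_spec()]; by default `n_max = 1`, midpoint at
#'   day 2, floor `1/3.5`, and the published `alpha` for this configuration.
#' @return A [model_spec()].
#' @export
winning_model <- function(variant_id, notch = NULL) {
  variant_id <- match.arg(variant_id, c("6d", "7b", "7d", "8b"))
  tab <- winning_parameter_table()
  val <- function(p) {
    v <- tab$mean[tab$parameter == p & tab$config == variant_id]
    if (length(v) != 1L) stop("fixture lookup failed for ", p)
    v
  }
  kap <- val("kappa1N")
  k2 <- val("kappa2")
  if (!is.na(k2)) kap <- c(kap, k2)
  if (is.null(notch))
    notch <- notch_spec(n_max = 1, alpha = val("alpha"), t_half = 2,
                        floor = 1 / 3.5)
  params <- model_parameters(
    eta = c(val("eta1N"), val("eta2"), val("eta3"), val("eta4")),
    delta = c(val("delta1N"), val("delta2"), val("delta3")),
    kappa = kap,
    rho = rep(0, 4),
    f = c(T = val("f_T"), G = val("f_G"), B = val("f_B"), P = 0),
    gamma = c(T = val("gamma_T"), G = val("gamma_G"), B = val("gamma_B"),
              P = 1))
  model_spec(variant_id, params, notch)
}

#' Ids of the four winning configurations
#' @return Character vector `c("6d", "7b", "7d", "8b")`.
#' @export
winning_configurations <- function() c("6d", "7b", "7d", "8b")

#' Replace the PU.1 parameters of a model
#'
#' @param spec A [model_spec()].
#' @param rho Length-4 PU.1 weights (self-activation; repression by TCF-1,
#'   GATA-3, BCL11B).
#' @param f_P,gamma_P Maximal production and decay rate of PU.1.
#' @param runx_input Optional constant positive input; default unchanged.
#' @return The updated [model_spec()].
#' @export
set_pu1_parameters <- function(spec, rho, f_P, gamma_P,
                               runx_input = spec$params$runx_input) {
  p <- spec$params
  f <- p$f; f["P"] <- f_P
  g <- p$gamma; g["P"] <- gamma_P
  params <- model_parameters(eta = p$eta, delta = p$delta, kappa = p$kappa,
                             rho = rho, f = f, gamma = g,
                             runx_input = runx_input)
  model_spec(spec$logic, params, spec$notch)
}

#' Count free kinetic parameters of the model
#'
#' The TCF-1/GATA-3/BCL11B + Notch subsystem has 4 eta + 2 (f, gamma for
#' TCF-1) + 3 delta + 2 (GATA-3) + k kappa + 2 (BCL11B) + 1 (alpha) = 14 + k
#' parameters, i.e. 15 to 17 for k = 1..3 minterms; the PU.1 equation has 6
#' (4 rho + f + gamma).
#'
#' @param spec A [model_spec()] (or a [logic_config()] / variant id for the
#'   TGB count).
#' @param subsystem `"tgb"` or `"pu1"`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(spec, subsystem = c("tgb", "pu1")) {
  subsystem <- match.arg(subsystem)
  if (subsystem == "pu1") return(6L)
  if (is.character(spec)) spec <- logic_config(spec)
  if (inherits(spec, "model_spec")) spec <- spec$logic
  k <- n_kappa(compile_rate_law(spec))
  14L + k
}
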