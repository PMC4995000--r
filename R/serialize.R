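# Structured serialisation of model specifications and analysis summaries.

#' Write a model specification to YAML
#'
#' Schema: `variant_id` (BCL11B configuration label), `parameters` (lists
#' `eta`, `delta`, `kappa`, `rho`, `f`, `gamma`, scalar `runx_input`), and
#' `notch` (`n_max`, `alpha`, `t_half`, `floor`).
#'
#' @param spec A [model_spec()].
#' @param path Output path (.yaml).
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  p <- spec$params
  yaml::write_yaml(list(
    variant_id = spec$logic$variant_id,
    parameters = list(eta = p$eta, delta = p$delta, kappa = p$kappa,
                      rho = p$rho, f = as.list(p$f),
                      gamma = as.list(p$gamma),
                      runx_input = p$runx_input),
    notch = list(n_max = spec$notch$n_max, alpha = spec$notch$alpha,
                 t_half = spec$notch$t_half, floor = spec$notch$floor)),
    path, precision = 17L)
  invisible(path)
}

#' Read a model specification from YAML
#' @param path A file written by [write_model_spec()].
#' @return A [model_spec()].
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path)
  x <- yaml::read_yaml(path)
  p <- x$parameters
  params <- model_parameters(
    eta = unlist(p$eta), delta = unlist(p$delta), kappa = unlist(p$kappa),
    rho = unlist(p$rho), f = unlist(p$f), gamma = unlist(p$gamma),
    runx_input = p$runx_input)
  model_spec(x$variant_id, params,
             notch_spec(n_max = x$notch$n_max, alpha = x$notch$alpha,
                        t_half = x$notch$t_half, floor = x$notch$floor))
}

#' Smoother-parameter report for a set of profiles
#' @param profiles Named list of [smooth_series()] results.
#' @return Data frame with one row per gene: baseline `b`, amplitude `a`,
#'   midpoint `t0`, width `w`, relative residual sum of squares.
#' @export
smoother_report <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p)
    data.frame(gene = p$gene, b = p$par[["b"]], a = p$par[["a"]],
               t0 = p$par[["t0"]], w = p$par[["w"]], rss = p$rss,
               row.names = NULL)))
}

#' Selection summary grid over fitted configurations
#'
#' One row per fit: configuration id, whether the simulated trajectories of
#' all three fitted genes stay within the 95\% confidence intervals,
#' whether every half-life is plausible, and the overall acceptance flag.
#'
#' @param fits List of evaluated `fit_result` objects.
#' @param hl_window Half-life window in hours; default `c(1, 48)`.
#' @return Data frame with columns `variant_id`, `ci_pass`, `hl_pass`,
#'   `accepted`.
#' @export
selection_grid <- function(fits, hl_window = c(1, 48)) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(
      variant_id = f$config$variant_id,
      ci_pass = all(f$ci_pass),
      hl_pass = all(is.finite(f$half_lives)) &&
        all(f$half_lives >= hl_window[1] & f$half_lives <= hl_window[2]),
      accepted = isTRUE(f$accepted), row.names = NULL)))
}

#' Write a commitment classification as JSON
#' @param classification A [classify_commitment()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification_json <- function(classification, path) {
  stopifnot(inherits(classification, "commitment_classification"))
  jsonlite::write_json(list(
    variant_id = classification$variant_id,
    classification = as.list(classification$classification),
    bistable_region = classification$bistable_region),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
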