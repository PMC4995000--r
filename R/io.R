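# Plain-text interchange: staged-expression CSV, tidy trajectory CSV,
# YAML/JSON run configuration, JSON fit reports.

#' Write a staged dataset as CSV (columns: stage, gene, value)
#'
#' One row per gene-stage combination; stages are written as labels
#' (ETP ... DN3a) using the package's stage/day mapping.
#'
#' @param series_list Named list of [expression_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stage_csv <- function(series_list, path) {
  rows <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(stage = time_to_stage(s$times), gene = s$gene,
               value = s$values, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a staged dataset from CSV (columns: stage, gene, value)
#'
#' @param path CSV path.
#' @param cv Coefficient of variation attached to each series; default 0.25.
#' @return Named list of [expression_series()], one per gene.
#' @export
read_stage_csv <- function(path, cv = 0.25) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stage", "gene", "value")
  if (!all(need %in% names(df)))
    stop("staged CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$gene), function(d) {
    tt <- stage_to_time(d$stage)
    o <- order(tt)
    expression_series(d$gene[1], tt[o], d$value[o], cv = cv)
  })
  out[order(match(names(out), c("T", "G", "B", "P")))]
}

#' Write a trajectory as tidy CSV (columns: time_days, gene, value)
#' @param traj A `grn_trajectory` from [simulate_grn()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  genes <- setdiff(names(traj), "time_days")
  rows <- do.call(rbind, lapply(genes, function(g) {
    data.frame(time_days = traj$time_days, gene = g, value = traj[[g]],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy trajectory CSV back into wide form
#' @param path CSV with columns time_days, gene, value.
#' @return A `grn_trajectory` data.frame.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  wide <- stats::reshape(df, idvar = "time_days", timevar = "gene",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[order(wide$time_days), , drop = FALSE]
  rownames(wide) <- NULL
  structure(wide, class = c("grn_trajectory", "data.frame"))
}

#' Default run configuration
#'
#' Defaults follow the pinned analysis conditions: measurement CV 0.25,
#' Notch fold cap 3.5, half-life plausibility window (1, 48) hours, 101-point
#' bifurcation sweeps.
#'
#' @param ... Overrides for individual fields.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(seed = 1L, cv = 0.25, fold_cap = 3.5,
              hl_window = c(1, 48), sann_iter = 1500L, polish_iter = 200L,
              n_starts = 8L, n_mc = 2000L, sweep_points = 101L,
              out_dir = ".")
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown run_config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = c("run_config", "list"))
}

#' Read a run configuration from YAML or JSON
#' @param path File ending in .yaml/.yml or .json.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#' @param cfg A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write a JSON fit report
#'
#' Serialises a list of fit results (see [fit_tgb()]) with per-configuration
#' parameters, objectives and pass flags.
#'
#' @param fits List of `fit_result` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fits, path) {
  rep <- lapply(fits, function(f) {
    list(variant_id = f$config$variant_id,
         objective = f$objective,
         notch_fold = f$notch_fold,
         ci_pass = as.list(f$ci_pass),
         half_lives = as.list(f$half_lives),
         accepted = f$accepted,
         parameters = list(eta = f$params$eta, delta = f$params$delta,
                           kappa = f$params$kappa,
                           f = as.list(f$params$f),
                           gamma = as.list(f$params$gamma)))
  })
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
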