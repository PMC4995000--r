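# Stage-indexed expression data -> time series: stage/day mapping,
# parametric smoothing with analytic derivatives, confidence intervals.

.stage_days <- c("ETP" = 0, "ETP-DN2a" = 1, "DN2a" = 2, "DN2b" = 3,
                 "DN3a" = 4)

#' Developmental stage to calendar day
#'
#' Maps the five double-negative stages of early T-cell development to days,
#' using mean-transit-time-derived spacing: ETP = day 0, ETP-DN2a = 1,
#' DN2a = 2, DN2b = 3, DN3a = 4.
#'
#' @param stage Stage label(s).
#' @return Numeric day(s).
#' @export
stage_to_time <- function(stage) {
  bad <- setdiff(stage, names(.stage_days))
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         "; valid labels are: ", paste(names(.stage_days), collapse = ", "))
  unname(.stage_days[stage])
}

#' Calendar day to developmental stage
#' @param day Day value(s) in 0:4.
#' @return Stage label(s).
#' @export
time_to_stage <- function(day) {
  idx <- match(day, .stage_days)
  if (anyNA(idx))
    stop("no stage is assigned to day(s): ",
         paste(day[is.na(idx)], collapse = ", "))
  names(.stage_days)[idx]
}

#' Time-stamped expression series for one gene
#'
#' @param gene Gene name (one of "T", "G", "B", "P" or a free label).
#' @param times Strictly increasing times in days.
#' @param values Positive expression values (arbitrary units).
#' @param cv Coefficient of variation of the measurements; default 0.25.
#' @return Object of class `expression_series`.
#' @export
expression_series <- function(gene, times, values, cv = 0.25) {
  stopifnot(length(times) == length(values))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(values <= 0)) stop("values must be positive")
  if (cv <= 0 || cv >= 1) stop("cv must be in (0, 1)")
  structure(list(gene = gene, times = as.numeric(times),
                 values = as.numeric(values), cv = cv),
            class = "expression_series")
}

#' @export
print.expression_series <- function(x, ...) {
  cat(sprintf("<expression_series %s> %d points on days [%g, %g], cv = %g\n",
              x$gene, length(x$times), min(x$times), max(x$times), x$cv))
  invisible(x)
}

#' 95\% confidence interval from a coefficient of variation
#'
#' Normal-approximation interval `value * (1 -/+ 1.96 cv)` on the linear
#' scale (lower bound clipped at 0), or `value * exp(-/+ 1.96 cv)` with
#' `scale = "log"` (measurement errors of relative-expression data are often
#' estimated on the log scale).
#'
#' @param value Positive measurement value(s).
#' @param cv Coefficient of variation, in (0, 1) for the linear scale.
#' @param scale `"linear"` (default) or `"log"`.
#' @return Matrix with columns `lo`, `hi`.
#' @export
confidence_interval <- function(value, cv, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (!is.numeric(cv) || length(cv) != 1L || cv <= 0)
    stop("cv must be a positive scalar")
  if (any(value <= 0)) stop("value must be positive")
  z <- stats::qnorm(0.975)
  if (scale == "linear") {
    lo <- pmax(value * (1 - z * cv), 0)
    hi <- value * (1 + z * cv)
  } else {
    lo <- value * exp(-z * cv)
    hi <- value * exp(z * cv)
  }
  cbind(lo = lo, hi = hi)
}

# four-parameter smoother: baseline + logistic transition
.smooth_value <- function(t, par) {
  par[["b"]] + par[["a"]] * stats::plogis((t - par[["t0"]]) / par[["w"]])
}
.smooth_deriv <- function(t, par) {
  l <- stats::plogis((t - par[["t0"]]) / par[["w"]])
  par[["a"]] / par[["w"]] * l * (1 - l)
}

#' Parametric smoothing of an expression series
#'
#' Fits a positive four-parameter curve — a baseline plus one logistic
#' transition, `v(t) = b + a * logistic((t - t0)/w)` — by relative-error
#' (1/v^2-weighted) least squares, matching the constant-CV multiplicative
#' error structure of the measurements.
#' The family covers the monotone rising/saturating and monotone declining
#' profiles seen across early T-cell stages; the analytic derivative is
#' returned alongside the value.
#'
#' @param series An [expression_series()] with at least 4 points.
#' @return Object of class `smooth_profile`: list with functions `value(t)`
#'   and `derivative(t)`, the fitted `par`, the residual sum of squares
#'   `rss`, and the source `series`.
#' @export
smooth_series <- function(series) {
  stopifnot(inherits(series, "expression_series"))
  tt <- series$times; vv <- series$values
  if (length(tt) < 4L) stop("need at least 4 points to smooth")
  rng <- diff(range(vv))
  if (rng < 1e-12 * max(vv)) {
    # constant series: degenerate but well-defined limit of the family
    par <- c(b = mean(vv), a = 0, t0 = mean(tt), w = 1)
    return(.make_profile(series, par, rss = 0))
  }
  span <- diff(range(tt))
  starts <- expand.grid(
    t0 = unname(stats::quantile(tt, c(0.25, 0.5, 0.75))),
    w = span * c(0.08, 0.2, 0.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(b = min(vv), a = vv[which.max(tt)] - vv[which.min(tt)],
               t0 = starts$t0[i], w = starts$w[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ b + a * plogis((t - t0) / w),
        data = data.frame(t = tt, v = vv), start = st,
        # 1/v^2 weights: residuals are relative, matching constant-CV
        # multiplicative measurement noise
        weights = 1 / vv^2,
        # transitions sharper than ~1/25 of the window are not resolvable
        # at 1-day stage spacing
        lower = c(b = 0, a = -max(vv) * 2, t0 = min(tt) - span,
                  w = span * 0.04),
        upper = c(b = max(vv) * 2, a = max(vv) * 2, t0 = max(tt) + span,
                  w = span * 5),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum((stats::resid(fit) / vv)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = stats::coef(fit), rss = rss)
  }
  if (is.null(best) || anyNA(best$par) || any(!is.finite(best$par)))
    stop("degenerate smoother fit for gene ", series$gene)
  par <- best$par
  grid <- seq(min(tt), max(tt), length.out = 101)
  if (any(.smooth_value(grid, par) <= 0))
    stop("smoother for gene ", series$gene,
         " is not positive on the fitting window")
  .make_profile(series, par, best$rss)
}

.make_profile <- function(series, par, rss) {
  force(par)
  structure(list(
    gene = series$gene,
    value = function(t) .smooth_value(t, par),
    derivative = function(t) .smooth_deriv(t, par),
    par = par, rss = rss, series = series),
    class = "smooth_profile")
}

#' @export
print.smooth_profile <- function(x, ...) {
  cat(sprintf(
    "<smooth_profile %s> v(t) = %.4g + %.4g * logistic((t - %.3g)/%.3g)\n",
    x$gene, x$par[["b"]], x$par[["a"]], x$par[["t0"]], x$par[["w"]]))
  invisible(x)
}

#' Smooth every series of a staged dataset
#' @param series_list Named list of [expression_series()] (names "T", "G",
#'   "B", "P").
#' @return Named list of `smooth_profile` objects.
#' @export
smooth_all <- function(series_list) lapply(series_list, smooth_series)
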