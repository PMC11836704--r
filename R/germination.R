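#' Fit a three-parameter log-logistic germination time course
#'
#' Fits cumulative germination percentage over time with
#' \deqn{f(t) = \frac{d}{1 + \exp\{b (\log t - \log e)\}},}
#' the three-parameter log-logistic curve standard in germination and
#' dose-response analysis: `d` is the upper asymptote (final germination
#' percentage), `e` the inflection time and `b` the (negative, for
#' increasing curves) slope parameter. The time to 50% germination,
#' `t50`, is defined relative to the fitted asymptote — the time at which
#' the curve reaches `d/2` — which for this parameterization equals `e`
#' exactly. The relative convention matters whenever `d < 100`: an
#' absolute definition (50% of all sown seeds) would be undefined for any
#' species whose final germination falls below 50%.
#'
#' Least squares is solved by Levenberg–Marquardt
#' ([minpack.lm::nlsLM()]) with starts `d0 = max(observed)`,
#' `e0` = time nearest half the maximum, `b0 = -2`, and `d` bounded at
#' 100. Time points at or below zero are dropped (the curve passes
#' through zero there in the limit).
#'
#' @param time_days Observation times (days), at least 4 positive values.
#' @param cum_germ_pct Cumulative germination (%) at each time; expected
#'   non-decreasing (a warning is issued otherwise and the fit proceeds).
#' @return An object of class `germination_fit`: list with `b`, `d`, `e`,
#'   `t50`, `gmax_observed`, `converged`, `fitted`, `data`.
#' @export
fit_germination <- function(time_days, cum_germ_pct) {
  stopifnot(length(time_days) == length(cum_germ_pct))
  keep <- time_days > 0 & !is.na(cum_germ_pct)
  t <- time_days[keep]
  y <- cum_germ_pct[keep]
  if (length(t) < 4) {
    stop("need at least 4 positive-time observations", call. = FALSE)
  }
  if (all(y == 0)) {
    stop("no germination observed; curve cannot be fitted", call. = FALSE)
  }
  if (any(diff(y) < 0)) {
    warning("cumulative germination is not non-decreasing", call. = FALSE)
  }
  d0 <- max(y)
  e0 <- t[which.min(abs(y - d0 / 2))]
  start <- list(b = -2, d = d0, e = max(e0, min(t)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ d / (1 + exp(b * (log(t) - log(e)))),
      start = start,
      lower = c(b = -Inf, d = 1e-8, e = 1e-8),
      upper = c(b = Inf, d = 100, e = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(b = NA_real_, d = NA_real_, e = NA_real_, t50 = NA_real_,
                gmax_observed = max(y), converged = FALSE, fitted = NULL,
                data = data.frame(time_days = t, cum_germ_pct = y))
    class(out) <- "germination_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  out <- list(b = unname(cf["b"]), d = unname(cf["d"]), e = unname(cf["e"]),
              t50 = unname(cf["e"]), gmax_observed = max(y),
              converged = fit$convInfo$isConv, fitted = fit,
              data = data.frame(time_days = t, cum_germ_pct = y))
  class(out) <- "germination_fit"
  out
}

#' @export
print.germination_fit <- function(x, ...) {
  cat("Three-parameter log-logistic germination fit\n")
  if (!x$converged) cat("  (did not converge)\n")
  cat(sprintf("  b = %.4g  d = %.4g %%  e = %.4g d\n", x$b, x$d, x$e))
  cat(sprintf("  T50 (time to half the fitted asymptote) = %.4g days\n",
              x$t50))
  invisible(x)
}

#' @export
coef.germination_fit <- function(object, ...) {
  c(b = object$b, d = object$d, e = object$e)
}

#' @export
predict.germination_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_days else newdata
  object$d / (1 + exp(object$b * (log(t) - log(object$e))))
}

#' Maximum germination percentage of viable seeds
#'
#' Final germination success as a percentage of viable seeds: seeds found
#' dead by cut-test at the end of the trial are removed from the
#' denominator, since they could never have contributed.
#'
#' @param germinated Seeds germinated by the end of the trial.
#' @param n_sown Seeds sown.
#' @param n_dead Seeds found non-viable by cut-test (default 0).
#' @return Percentage in [0, 100], or `NA` (with a warning) when no
#'   viable seeds remain.
#' @export
compute_gmax <- function(germinated, n_sown, n_dead = 0) {
  n_viable <- n_sown - n_dead
  if (any(n_viable <= 0)) {
    warning("no viable seeds; gmax undefined", call. = FALSE)
    return(NA_real_)
  }
  if (any(germinated < 0) || any(germinated > n_viable)) {
    stop("germinated count outside [0, viable]", call. = FALSE)
  }
  100 * germinated / n_viable
}

#' Germination metrics for every species in a count table
#'
#' @param germ A data.frame with columns `species`, `time_days` and either
#'   `cum_germ_pct` or (`germinated_count`, `n_sown`, optionally
#'   `n_dead`). Counts are converted to percentages of viable seeds via
#'   [compute_gmax()]'s denominator rule before fitting.
#' @return A data.frame: `species`, `gmax`, `t50`, `converged`.
#' @export
germination_metrics <- function(germ) {
  stopifnot(all(c("species", "time_days") %in% names(germ)))
  out <- lapply(split(germ, germ$species), function(g) {
    g <- g[order(g$time_days), , drop = FALSE]
    if ("cum_germ_pct" %in% names(g)) {
      pct <- g$cum_germ_pct
      gmax <- max(pct)
    } else {
      n_dead <- if ("n_dead" %in% names(g)) g$n_dead[1] else 0
      pct <- compute_gmax(g$germinated_count, g$n_sown[1], n_dead)
      gmax <- max(pct)
    }
    fit <- tryCatch(fit_germination(g$time_days, pct),
                    error = function(e) NULL)
    data.frame(species = g$species[1], gmax = gmax,
               t50 = if (is.null(fit)) NA_real_ else fit$t50,
               converged = !is.null(fit) && isTRUE(fit$converged))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
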