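#' Power-law allometry of seed metabolic rate, by OLS or PGLS
#'
#' Fits the metabolic scaling model `MR = a * M^b` on log10 scale,
#' `log10(SMR) = log10(a) + b * log10(mass)`, either by ordinary least
#' squares or by phylogenetic generalized least squares with error
#' covariance `sigma^2 * V(lambda)`, where `V(lambda)` is the Pagel
#' transformation of the Brownian covariance of `tree` (see
#' [lambda_transform()]). For PGLS, `lambda` is either a fixed value in
#' [0, 1] or estimated by profiling the restricted likelihood over [0, 1]
#' (`lambda = "REML"`, the default) or the full likelihood
#' (`lambda = "ML"`). Coefficient standard errors use the REML variance
#' estimate; the stored log-likelihood and AIC are always the full
#' (ML) Gaussian log-likelihood at the fitted parameters, so that OLS and
#' PGLS fits are comparable with [compare_allometry()]. The AIC includes
#' the n*log(2*pi)/2 constant; only differences are meaningful across
#' software.
#'
#' Residuals are ordinary vertical deviations `y - X beta` in log10
#' units — the quantity used for downstream correlate analysis — not
#' phylogenetically whitened residuals (available from
#' [residuals.allometry()] with `type = "normalized"` for diagnostics).
#'
#' @param mass Seed dry mass (mg), positive; named by species or
#'   accompanied by `species`.
#' @param smr Standard metabolic rate (ul O2 per seed per hour, typically
#'   Q10-standardized to 20 degrees), positive.
#' @param species Species labels (defaults to `names(mass)`).
#' @param tree A `phylo` object covering all species (PGLS only).
#' @param method `"OLS"` or `"PGLS"`.
#' @param lambda `"REML"`, `"ML"`, or a fixed numeric in [0, 1]
#'   (PGLS only).
#' @return An object of class `allometry` with components `coefficients`
#'   (log10 intercept and slope), `se`, `t`, `df`, `lambda`,
#'   `lambda_mode`, `loglik` (ML), `aic`, `r2`, `residuals`, `fitted`,
#'   `sigma2`, `vcov`, `n`, `method`, `data`, `tree`.
#' @examples
#' set.seed(1)
#' mass <- 10^runif(40, -1, 2)
#' smr <- 0.08 * mass^0.75 * 10^rnorm(40, 0, 0.2)
#' fit <- fit_allometry(mass, smr)
#' summary(fit)
#' @export
fit_allometry <- function(mass, smr, species = names(mass), tree = NULL,
                          method = c("OLS", "PGLS"), lambda = "REML") {
  method <- match.arg(method)
  stopifnot(length(mass) == length(smr))
  if (any(!is.finite(mass)) || any(!is.finite(smr))) {
    stop("mass and smr must be finite", call. = FALSE)
  }
  if (any(mass <= 0) || any(smr <= 0)) {
    stop("mass and smr must be positive (log-log model)", call. = FALSE)
  }
  n <- length(mass)
  if (n < 3) stop("need at least 3 species", call. = FALSE)
  if (is.null(species)) species <- paste0("sp", seq_len(n))
  x <- log10(mass)
  y <- log10(smr)
  names(x) <- names(y) <- species
  if (stats::var(x) == 0) {
    stop("zero variance in log mass", call. = FALSE)
  }
  if (method == "OLS") {
    out <- allometry_ols(x, y)
  } else {
    if (is.null(tree)) stop("PGLS requires a tree", call. = FALSE)
    out <- allometry_pgls(x, y, tree, lambda)
  }
  out$data <- data.frame(species = names(out$residuals),
                         log10_mass = x[names(out$residuals)],
                         log10_smr = y[names(out$residuals)])
  out$tree <- if (method == "PGLS") tree else NULL
  class(out) <- "allometry"
  out
}

allometry_ols <- function(x, y) {
  n <- length(x)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # exact data fit perfectly
  co <- sm$coefficients
  ll <- as.numeric(stats::logLik(fit))
  list(method = "OLS",
       coefficients = c(intercept = unname(co[1, 1]),
                        slope = unname(co[2, 1])),
       se = c(intercept = unname(co[1, 2]), slope = unname(co[2, 2])),
       t = c(intercept = unname(co[1, 3]), slope = unname(co[2, 3])),
       df = n - 2,
       lambda = NA_real_, lambda_mode = "none",
       loglik = ll, aic = -2 * ll + 2 * 3,
       n_par = 3,
       r2 = sm$adj.r.squared,
       residuals = stats::setNames(stats::residuals(fit), names(x)),
       fitted = stats::setNames(stats::fitted(fit), names(x)),
       sigma2 = sum(stats::residuals(fit)^2) / n,
       vcov = stats::vcov(fit),
       n = n)
}

# Generalized least squares of y on X for a fixed covariance V (up to a
# scalar).  Returns both ML and REML variance estimates and likelihoods.
gls_core <- function(y, X, V) {
  n <- length(y)
  p <- ncol(X)
  R <- tryCatch(chol(V), error = function(e)
    stop("singular phylogenetic covariance", call. = FALSE))
  logdet <- 2 * sum(log(diag(R)))
  yw <- backsolve(R, y, transpose = TRUE)
  Xw <- backsolve(R, X, transpose = TRUE)
  XtX <- crossprod(Xw)
  XtXinv <- solve(XtX)
  beta <- drop(XtXinv %*% crossprod(Xw, yw))
  e <- drop(y - X %*% beta)
  ew <- yw - Xw %*% beta
  q <- sum(ew^2)
  s2_ml <- q / n
  s2_reml <- q / (n - p)
  ll_ml <- -0.5 * (n * log(2 * pi * s2_ml) + logdet + n)
  ll_reml <- -0.5 * ((n - p) * log(2 * pi * s2_reml) + logdet +
                       determinant(XtX, logarithm = TRUE)$modulus + (n - p))
  list(beta = beta, resid = e, resid_white = drop(ew), q = q,
       s2_ml = s2_ml, s2_reml = s2_reml,
       loglik_ml = ll_ml, loglik_reml = as.numeric(ll_reml),
       XtXinv = XtXinv, logdet = logdet)
}

allometry_pgls <- function(x, y, tree, lambda) {
  validate_phylogeny(tree)
  sp <- names(x)
  missing <- setdiff(sp, tree$tip.label)
  if (length(missing) > 0) {
    stop("species absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (ape::Ntip(tree) > length(sp)) {
    tree <- ape::keep.tip(tree, sp)
  }
  C <- phylo_vcv(tree)
  ord <- tree$tip.label
  x <- x[ord]; y <- y[ord]
  X <- cbind(intercept = 1, slope = x)
  n <- length(y)
  if (is.numeric(lambda)) {
    lam_hat <- lambda
    lambda_mode <- "fixed"
    if (lam_hat < 0 || lam_hat > 1) {
      stop("fixed lambda must be in [0, 1]", call. = FALSE)
    }
  } else {
    lambda_mode <- match.arg(lambda, c("REML", "ML"))
    crit <- if (lambda_mode == "REML") "loglik_reml" else "loglik_ml"
    obj <- function(l) gls_core(y, X, lambda_transform(C, l))[[crit]]
    opt <- stats::optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- rbind(c(opt$maximum, opt$objective), c(0, obj(0)), c(1, obj(1)))
    lam_hat <- cand[which.max(cand[, 2]), 1]
  }
  V <- lambda_transform(C, lam_hat)
  g <- gls_core(y, X, V)
  se <- sqrt(g$s2_reml * diag(g$XtXinv))
  beta <- g$beta
  # residual R^2 against the phylogenetic mean-only null with the same V
  g0 <- gls_core(y, matrix(1, n, 1), V)
  r2 <- 1 - g$q / g0$q
  n_par <- 3 + (lambda_mode != "fixed")
  list(method = "PGLS",
       coefficients = c(intercept = beta[1], slope = beta[2]),
       se = c(intercept = se[1], slope = se[2]),
       t = c(intercept = beta[1] / se[1], slope = beta[2] / se[2]),
       df = n - 2,
       lambda = lam_hat, lambda_mode = lambda_mode,
       loglik = g$loglik_ml, loglik_reml = g$loglik_reml,
       aic = -2 * g$loglik_ml + 2 * n_par,
       n_par = n_par,
       r2 = r2,
       residuals = stats::setNames(g$resid, ord),
       residuals_normalized = stats::setNames(g$resid_white, ord),
       fitted = stats::setNames(drop(X %*% beta), ord),
       sigma2 = g$s2_reml,
       vcov = g$s2_reml * g$XtXinv,
       n = n)
}

#' @export
print.allometry <- function(x, digits = 4, ...) {
  a <- 10^x$coefficients["intercept"]
  cat(sprintf("%s allometry: SMR = %.4g * M^%.3f  (n = %d)\n",
              x$method, a, x$coefficients["slope"], x$n))
  if (x$method == "PGLS") {
    cat(sprintf("  Pagel's lambda = %.3f (%s)\n", x$lambda, x$lambda_mode))
  }
  cat(sprintf("  log-likelihood = %.3f, AIC = %.2f, R2 = %.3f\n",
              x$loglik, x$aic, x$r2))
  invisible(x)
}

#' @export
summary.allometry <- function(object, ...) {
  ct <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
              `t value` = object$t,
              `Pr(>|t|)` = 2 * stats::pt(abs(object$t), object$df,
                                         lower.tail = FALSE))
  out <- list(fit = object, coef_table = ct)
  class(out) <- "summary.allometry"
  out
}

#' @export
print.summary.allometry <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (log10 scale):\n")
  stats::printCoefmat(x$coef_table, digits = 4)
  invisible(x)
}

#' @export
coef.allometry <- function(object, ...) object$coefficients

#' @export
vcov.allometry <- function(object, ...) object$vcov

#' @export
logLik.allometry <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n,
            class = "logLik")
}

#' Residuals of an allometry fit
#'
#' @param object An `allometry` fit.
#' @param type `"response"` (default): ordinary vertical deviations in
#'   log10 units, the definition used for correlate analysis;
#'   `"normalized"`: phylogenetically whitened residuals (PGLS only),
#'   for diagnostics.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
residuals.allometry <- function(object, type = c("response", "normalized"),
                                ...) {
  type <- match.arg(type)
  if (type == "response") return(object$residuals)
  if (object$method != "PGLS") {
    stop("normalized residuals are defined for PGLS fits only",
         call. = FALSE)
  }
  object$residuals_normalized
}

#' Predict SMR from mass under a fitted allometry
#'
#' @param object An `allometry` fit.
#' @param newdata Numeric vector of masses (mg); defaults to the training
#'   masses.
#' @param scale `"response"` for SMR in original units, `"log10"` for the
#'   linear predictor.
#' @param ... Unused.
#' @export
predict.allometry <- function(object, newdata = NULL,
                              scale = c("response", "log10"), ...) {
  scale <- match.arg(scale)
  lx <- if (is.null(newdata)) object$data$log10_mass else log10(newdata)
  eta <- object$coefficients["intercept"] + object$coefficients["slope"] * lx
  if (scale == "log10") unname(eta) else unname(10^eta)
}

#' Simulate response data from a fitted allometry
#'
#' Draws log10 SMR vectors from the fitted Gaussian model (multivariate
#' normal with covariance `sigma2 * V(lambda)` for PGLS, iid for OLS).
#'
#' @param object An `allometry` fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A matrix, `n` rows by `nsim` columns, of log10 SMR values.
#' @export
simulate.allometry <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  mu <- object$fitted
  if (object$method == "PGLS") {
    C <- phylo_vcv(object$tree)[names(mu), names(mu)]
    V <- object$sigma2 * lambda_transform(C, object$lambda)
    R <- chol(V)
    eps <- t(R) %*% matrix(stats::rnorm(n * nsim), n, nsim)
  } else {
    eps <- matrix(stats::rnorm(n * nsim, sd = sqrt(object$sigma2)), n, nsim)
  }
  out <- matrix(mu, n, nsim) + eps
  rownames(out) <- names(mu)
  out
}

#' Diagnostic log-log plot of an allometry fit
#'
#' @param x An `allometry` fit.
#' @param ... Passed to [plot()].
#' @export
plot.allometry <- function(x, ...) {
  d <- x$data
  plot(d$log10_mass, d$log10_smr,
       xlab = "log10 seed dry mass (mg)",
       ylab = "log10 SMR (ul O2 / seed / h)",
       pch = 19, col = "grey30", ...)
  graphics::abline(x$coefficients["intercept"], x$coefficients["slope"],
                   col = if (x$method == "PGLS") "red" else "blue", lwd = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("%s: b = %.3f", x$method,
                                    x$coefficients["slope"]))
  invisible(x)
}

#' Single-sample t-test of the scaling exponent against a null slope
#'
#' Tests whether the fitted mass-scaling exponent differs from
#' `null_slope` (1 by default: isometry) with `t = (null - b) / SE(b)` in
#' magnitude on `n - 2` degrees of freedom, two-sided.
#'
#' @param fit An `allometry` fit.
#' @param null_slope Null value of the exponent, default 1.
#' @return List: `t`, `df`, `p`, `slope`, `se`, `null_slope`.
#' @export
isometry_test <- function(fit, null_slope = 1) {
  b <- fit$coefficients["slope"]
  se <- fit$se["slope"]
  if (!is.finite(se) || se <= 0) {
    stop("slope standard error unavailable", call. = FALSE)
  }
  t <- abs(null_slope - b) / se
  list(t = unname(t), df = fit$df,
       p = unname(2 * stats::pt(t, fit$df, lower.tail = FALSE)),
       slope = unname(b), se = unname(se), null_slope = null_slope)
}

#' Compare two allometry fits by AIC and likelihood ratio
#'
#' Both fits must model the same response; full (ML) log-likelihoods are
#' used even when lambda was chosen by REML, so OLS and PGLS fits are on
#' a common footing. `fit_b` is taken as the richer model for the
#' likelihood-ratio test; with equal parameter counts the chi-squared
#' p-value is computed on one degree of freedom.
#'
#' @param fit_a,fit_b `allometry` fits on the same data.
#' @return List: `delta_aic` (`AIC_a - AIC_b`), `lr` (`2 * (llb - lla)`),
#'   `df`, `p`.
#' @export
compare_allometry <- function(fit_a, fit_b) {
  if (fit_a$n != fit_b$n) {
    stop("fits have different sample sizes", call. = FALSE)
  }
  lr <- 2 * (fit_b$loglik - fit_a$loglik)
  df <- fit_b$n_par - fit_a$n_par
  p <- stats::pchisq(max(lr, 0), max(df, 1), lower.tail = FALSE)
  list(delta_aic = fit_a$aic - fit_b$aic, lr = lr, df = df, p = p)
}
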