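#' Brownian-motion covariance matrix of a phylogeny
#'
#' Under Brownian motion the expected trait covariance of two tips is
#' proportional to the shared path length from the root to their most
#' recent common ancestor; the diagonal holds root-to-tip depths.
#'
#' @param tree A `phylo` object with non-negative branch lengths.
#' @return An n x n symmetric positive semi-definite matrix in tip order,
#'   with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_phylogeny(tree)
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transformation of a phylogenetic covariance
#'
#' Multiplies the off-diagonal (shared-history) entries by `lambda`,
#' leaving tip variances unchanged: `lambda = 1` is Brownian motion,
#' `lambda = 0` a star phylogeny (independent tips).
#'
#' @param C Phylogenetic covariance matrix (see [phylo_vcv()]).
#' @param lambda Value in [0, 1]; no extrapolation beyond 1 is allowed.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (lambda < 0 || lambda > 1) {
    stop("lambda must be in [0, 1]", call. = FALSE)
  }
  out <- C * lambda
  diag(out) <- diag(C)
  out
}

# Align a named trait vector with the tree's tips.
align_trait <- function(trait, tree) {
  if (is.null(names(trait))) {
    if (length(trait) != ape::Ntip(tree)) {
      stop("unnamed trait vector of wrong length", call. = FALSE)
    }
    names(trait) <- tree$tip.label
    return(trait)
  }
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing) > 0) {
    stop("trait missing for tip(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  trait[tree$tip.label]
}

# Profiled multivariate-normal log-likelihood of x with mean mu*1 and
# covariance sigma2 * V, maximized analytically over mu and sigma2.
# Returns the log-likelihood along with the profiled estimates.
profile_mvn_loglik <- function(x, V) {
  n <- length(x)
  R <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix is not positive definite", call. = FALSE))
  logdet <- 2 * sum(log(diag(R)))
  z <- backsolve(R, x, transpose = TRUE)
  one <- backsolve(R, rep(1, n), transpose = TRUE)
  mu <- sum(one * z) / sum(one * one)
  q <- sum((z - mu * one)^2)
  sigma2 <- q / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(loglik = ll, mu = mu, sigma2 = sigma2)
}

#' Maximum-likelihood estimate of Pagel's lambda for a trait
#'
#' Profiles the multivariate-normal log-likelihood of the trait (mean and
#' rate profiled out analytically) over the lambda transformation of the
#' Brownian covariance, searching [0, 1] by bounded scalar optimization
#' (tolerance 1e-6) with both boundaries checked explicitly. Likelihood
#' ratio tests against `lambda = 0` (no signal) and `lambda = 1`
#' (Brownian motion) are reported; because the null values sit on the
#' boundary of the parameter space, p-values use the 50:50 mixture of
#' chi-squared(0) and chi-squared(1).
#'
#' @param trait Named numeric vector keyed by tip label (or unnamed, in
#'   tip order).
#' @param tree A `phylo` object.
#' @return List: `lambda`, `loglik`, `loglik0`, `loglik1`, `p_vs_0`,
#'   `p_vs_1`, `sigma2`, `mu`.
#' @export
pagel_lambda <- function(trait, tree) {
  trait <- align_trait(trait, tree)
  if (stats::var(trait) == 0) {
    stop("trait has zero variance; lambda undefined", call. = FALSE)
  }
  C <- phylo_vcv(tree)
  obj <- function(lam) profile_mvn_loglik(trait, lambda_transform(C, lam))$loglik
  opt <- stats::optimize(obj, interval = c(0, 1), maximum = TRUE,
                         tol = 1e-6)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(0, obj(0)), c(1, obj(1)))
  best <- cand[which.max(cand[, 2]), ]
  lam_hat <- best[1]
  prof <- profile_mvn_loglik(trait, lambda_transform(C, lam_hat))
  boundary_lrt_p <- function(lr) {
    if (lr <= 0) return(1)
    0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  }
  list(lambda = lam_hat,
       loglik = prof$loglik,
       loglik0 = cand[2, 2],
       loglik1 = cand[3, 2],
       p_vs_0 = boundary_lrt_p(2 * (prof$loglik - cand[2, 2])),
       p_vs_1 = boundary_lrt_p(2 * (prof$loglik - cand[3, 2])),
       sigma2 = prof$sigma2, mu = prof$mu)
}

# Observed MSE0/MSE ratio underlying Blomberg's K: mean squared deviation
# from the phylogenetically corrected mean over the GLS mean squared error.
k_ratio <- function(x, Cinv, ones_Cinv) {
  a_hat <- sum(ones_Cinv * x) / sum(ones_Cinv)
  dev <- x - a_hat
  mse0 <- sum(dev^2) / (length(x) - 1)
  mse <- as.numeric(dev %*% Cinv %*% dev) / (length(x) - 1)
  mse0 / mse
}

#' Blomberg's K with a permutation test
#'
#' K compares the observed ratio of the trait's mean squared deviation
#' from the phylogenetically corrected mean (MSE0) to its generalized
#' least-squares mean squared error (MSE) against the value of that ratio
#' expected under Brownian motion,
#' \deqn{K = \frac{(MSE_0/MSE)_{obs}}
#'   {[\mathrm{tr}(C) - n / \sum_{ij} (C^{-1})_{ij}] / (n - 1)}.}
#' K has expectation close to 1 under Brownian motion; values below 1
#' indicate less resemblance among relatives than Brownian motion
#' predicts. Significance is assessed one-sided by random tip-label
#' permutation of the trait: the p-value is the +1-smoothed proportion of
#' permutations whose MSE0/MSE ratio is at least the observed one.
#'
#' @param trait Named numeric vector keyed by tip label.
#' @param tree A `phylo` object with at least 4 tips.
#' @param n_perm Number of permutations for the test (default 999); set
#'   to 0 to skip the test.
#' @param seed Optional integer seed for the permutations.
#' @return List: `K`, `p` (or `NA` when `n_perm = 0`), `n_perm`.
#' @export
blomberg_k <- function(trait, tree, n_perm = 999, seed = NULL) {
  if (ape::Ntip(tree) < 4) {
    stop("need at least 4 tips", call. = FALSE)
  }
  trait <- align_trait(trait, tree)
  C <- phylo_vcv(tree)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance; check for zero-length ",
         "terminal branches or duplicate tips", call. = FALSE))
  n <- length(trait)
  ones_Cinv <- colSums(Cinv)
  expected_ratio <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  obs <- k_ratio(trait, Cinv, ones_Cinv)
  K <- obs / expected_ratio
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      if (k_ratio(sample(trait), Cinv, ones_Cinv) >= obs) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  list(K = K, p = p, n_perm = n_perm)
}

#' Phylogenetic signal summary for one trait
#'
#' Convenience wrapper combining [pagel_lambda()] and [blomberg_k()].
#'
#' @inheritParams blomberg_k
#' @param trait_name Label used by the print method.
#' @return Object of class `phylo_signal`.
#' @export
phylo_signal <- function(trait, tree, n_perm = 999, seed = NULL,
                         trait_name = deparse(substitute(trait))) {
  lam <- pagel_lambda(trait, tree)
  k <- blomberg_k(trait, tree, n_perm = n_perm, seed = seed)
  out <- list(trait = trait_name, lambda = lam$lambda,
              lambda_loglik = lam$loglik,
              lambda_p_vs_0 = lam$p_vs_0, lambda_p_vs_1 = lam$p_vs_1,
              K = k$K, K_p = k$p, n = ape::Ntip(tree), n_perm = n_perm)
  class(out) <- "phylo_signal"
  out
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat("Phylogenetic signal:", x$trait, sprintf("(n = %d)\n", x$n))
  cat(sprintf("  Pagel's lambda = %.3f  (LRT vs 0: p = %.4g; vs 1: p = %.4g)\n",
              x$lambda, x$lambda_p_vs_0, x$lambda_p_vs_1))
  cat(sprintf("  Blomberg's K   = %.3f  (permutation p = %.4g, %d perms)\n",
              x$K, x$K_p, x$n_perm))
  invisible(x)
}
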