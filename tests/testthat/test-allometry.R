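test_that("OLS reproduces exact linear relationships", {
  mass <- 10^c(0, 1, 2, 3)
  smr <- 10^(1 + 2 * log10(mass))        # y = 2x + 1 on log10 scale
  fit <- fit_allometry(mass, smr, species = letters[1:4])
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(sum(residuals(fit)), 0, tolerance = 1e-9)
})

test_that("inputs are validated", {
  expect_error(fit_allometry(c(1, 2, -3), c(1, 1, 1)), "positive")
  expect_error(fit_allometry(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(fit_allometry(1:3, 1:3, species = letters[1:3],
                             method = "PGLS"), "tree")
})

test_that("PGLS with lambda = 0 equals OLS on an ultrametric tree", {
  set.seed(20)
  tr <- rcoal_unit(25)
  mass <- 10^rnorm(25, 1)
  smr <- 10^(-1 + 0.75 * log10(mass) + rnorm(25, 0, 0.3))
  names(mass) <- names(smr) <- tr$tip.label
  ols <- fit_allometry(mass, smr)
  pgls0 <- fit_allometry(mass, smr, tree = tr, method = "PGLS", lambda = 0)
  expect_equal(unname(coef(pgls0)), unname(coef(ols)), tolerance = 1e-8)
})

test_that("PGLS equals OLS on Cholesky-whitened variables", {
  set.seed(21)
  for (i in 1:5) {
    tr <- rcoal_unit(20)
    lam <- runif(1)
    C <- phylo_vcv(tr)
    x <- rnorm(20)
    y <- 0.5 + 0.8 * x + rmvn1(lambda_transform(C, lam))
    names(x) <- names(y) <- tr$tip.label
    fit <- fit_allometry(10^x, 10^y, tree = tr, method = "PGLS",
                         lambda = lam)
    L <- t(chol(lambda_transform(C, lam)))
    yw <- solve(L, y[tr$tip.label])
    Xw <- solve(L, cbind(1, x[tr$tip.label]))
    beta <- qr.solve(Xw, yw)
    expect_equal(unname(coef(fit)), unname(beta), tolerance = 1e-8)
  }
})

test_that("PGLS matches the independent nlme corPagel implementation", {
  set.seed(22)
  tr <- rcoal_unit(40)
  x <- rnorm(40)
  y <- -1 + 0.7 * x + rmvn1(lambda_transform(phylo_vcv(tr), 0.5))
  names(x) <- names(y) <- tr$tip.label
  fit <- fit_allometry(10^x, 10^y, tree = tr, method = "PGLS", lambda = 0.5)
  d <- data.frame(x = x, y = y, sp = tr$tip.label)
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corPagel(0.5, tr, form = ~sp,
                                               fixed = TRUE))
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(ref$varBeta))),
               tolerance = 1e-6)
})

test_that("PGLS residuals are vertical deviations with GLS orthogonality", {
  set.seed(23)
  tr <- rcoal_unit(30)
  x <- rnorm(30)
  y <- 1 + x + rmvn1(lambda_transform(phylo_vcv(tr), 0.6))
  names(x) <- names(y) <- tr$tip.label
  fit <- fit_allometry(10^x, 10^y, tree = tr, method = "PGLS")
  e <- residuals(fit)
  # response-scale definition
  expect_equal(unname(e),
               unname(y[names(e)] - fit$fitted[names(e)]),
               tolerance = 1e-10)
  # generalized orthogonality X' V^-1 e = 0
  V <- lambda_transform(phylo_vcv(tr), fit$lambda)[names(e), names(e)]
  X <- cbind(1, x[names(e)])
  expect_lt(max(abs(crossprod(X, solve(V, e)))), 1e-6)
  # perfectly collinear data: all residuals zero
  yy <- 2 + 0.5 * x
  fit2 <- fit_allometry(10^x, 10^yy, tree = tr, method = "PGLS", lambda = 0.3)
  expect_lt(max(abs(residuals(fit2))), 1e-10)
})

test_that("freeing lambda never lowers the REML criterion", {
  set.seed(24)
  tr <- rcoal_unit(30)
  x <- rnorm(30)
  y <- 1 + 0.6 * x + rmvn1(lambda_transform(phylo_vcv(tr), 0.4))
  names(x) <- names(y) <- tr$tip.label
  free <- fit_allometry(10^x, 10^y, tree = tr, method = "PGLS")
  for (lam in c(0, 0.25, 0.5, 0.75, 1)) {
    fixed <- fit_allometry(10^x, 10^y, tree = tr, method = "PGLS",
                           lambda = lam)
    expect_gte(free$loglik_reml + 1e-6, fixed$loglik_reml)
  }
})

test_that("isometry test follows the t distribution arithmetic", {
  # exact slope 1: t = 0, p = 1
  mass <- 10^c(0, 1, 2, 3)
  fit <- fit_allometry(mass, 10 * mass, species = letters[1:4])
  iso <- isometry_test(fit)
  expect_equal(iso$t, 0, tolerance = 1e-9)
  expect_equal(iso$p, 1, tolerance = 1e-9)

  # arbitrary null slope
  iso2 <- isometry_test(fit, null_slope = 0.75)
  expect_gt(iso2$t, 0)
})

test_that("model comparison is null for identical fits", {
  set.seed(25)
  mass <- 10^rnorm(20, 1)
  smr <- 10^(0.5 * log10(mass) + rnorm(20, 0, 0.2))
  f <- fit_allometry(mass, smr, species = paste0("s", 1:20))
  cmp <- compare_allometry(f, f)
  expect_equal(cmp$delta_aic, 0)
  expect_equal(cmp$lr, 0)
  expect_equal(cmp$p, 1)
  f2 <- fit_allometry(mass[1:10], smr[1:10], species = paste0("s", 1:10))
  expect_error(compare_allometry(f, f2), "sample sizes")
})

test_that("allometry methods are coherent", {
  set.seed(26)
  tr <- rcoal_unit(20)
  mass <- setNames(10^rnorm(20, 1), tr$tip.label)
  smr <- setNames(0.08 * mass^0.75 * 10^rnorm(20, 0, 0.3), tr$tip.label)
  fit <- fit_allometry(mass, smr, tree = tr, method = "PGLS")
  expect_s3_class(fit, "allometry")
  expect_output(print(fit), "PGLS allometry")
  expect_output(print(summary(fit)), "Coefficients")
  expect_equal(AIC(fit), fit$aic)
  # predict: log10 scale is the linear predictor
  expect_equal(predict(fit, newdata = 10, scale = "log10"),
               unname(coef(fit)["intercept"] + coef(fit)["slope"]),
               tolerance = 1e-12)
  expect_equal(predict(fit, newdata = 10),
               10^predict(fit, newdata = 10, scale = "log10"))
  # simulate: reproducible and of the right shape
  s1 <- simulate(fit, nsim = 3, seed = 1)
  s2 <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(20, 3))
})
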