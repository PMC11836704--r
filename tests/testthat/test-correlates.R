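test_that("simple regression reports slope, F = t^2 and exact fits", {
  x <- 1:10
  y <- 2 * x + 3
  r <- simple_regression(y, x)
  expect_equal(r$slope, 2, tolerance = 1e-10)
  expect_lt(r$p, 1e-12)

  set.seed(30)
  y2 <- rnorm(20); x2 <- rnorm(20)
  r2 <- simple_regression(y2, x2)
  tt <- summary(lm(y2 ~ x2))$coefficients["x2", "t value"]
  expect_equal(r2$F, tt^2, tolerance = 1e-10)

  # two-level factors are coded 0/1
  g <- rep(c("crop", "wild"), each = 10)
  r3 <- simple_regression(c(rnorm(10, 1), rnorm(10)), factor(g))
  expect_equal(r3$df2, 18)
  expect_error(simple_regression(y2, rep(1, 20)), "constant")
})

test_that("Welch t matches the closed-form Satterthwaite computation", {
  x <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6)
  y <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2)
  w <- welch_t(x, y)
  sx2 <- var(x) / length(x); sy2 <- var(y) / length(y)
  t_hand <- (mean(x) - mean(y)) / sqrt(sx2 + sy2)
  df_hand <- (sx2 + sy2)^2 /
    (sx2^2 / (length(x) - 1) + sy2^2 / (length(y) - 1))
  expect_equal(w$t, t_hand, tolerance = 1e-10)
  expect_equal(w$df, df_hand, tolerance = 1e-10)
  expect_equal(w$p, 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE),
               tolerance = 1e-10)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
})

test_that("Welch type-I error is near nominal with unequal variances", {
  set.seed(31)
  rej <- replicate(1000, {
    welch_t(rnorm(8, 0, 3), rnorm(40, 0, 0.5))$p < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("climate ANOVA drops singletons and reduces to pooled t^2", {
  set.seed(32)
  y <- c(rnorm(10), rnorm(12, 0.5))
  g <- rep(c("Csa", "BWh"), c(10, 12))
  a <- climate_anova(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)$statistic
  expect_equal(a$F, unname(tt^2), tolerance = 1e-10)
  expect_equal(a$df1, 1)
  expect_equal(a$df2, 20)

  # singleton class removed and reported
  y2 <- c(y, 5); g2 <- c(g, "BSk")
  a2 <- climate_anova(y2, g2)
  expect_equal(a2$dropped, "BSk")
  expect_equal(a2$n, 22)

  # invariance to label renaming
  a3 <- climate_anova(y, c(Csa = "zz", BWh = "aa")[g])
  expect_equal(a3$F, a$F, tolerance = 1e-12)
})

test_that("ordered contrast detects monotone trends and is calibrated", {
  g <- rep(c("Csa", "BSh", "BWh"), c(30, 10, 20))
  means <- c(Csa = 0, BSh = 0.5, BWh = 1)
  y <- means[g] + rnorm(60, 0, 1e-6)
  ct <- ordered_contrast(y, g)
  expect_lt(ct$p, 1e-10)
  expect_equal(ct$df1, 1)
  expect_equal(ct$df2, 60 - 3)

  # null calibration by label permutation
  set.seed(33)
  y0 <- rnorm(60)
  rej <- replicate(600, ordered_contrast(y0, sample(g))$p < 0.05)
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)

  expect_error(ordered_contrast(y, g, ordered_levels = c("Csa", "BWh")),
               "3 ordered")
})

test_that("type-III F of a single retained covariate equals its squared t", {
  set.seed(34)
  y <- rnorm(40)
  x <- rnorm(40)
  y <- y + 0.9 * x
  sw <- backward_stepwise(y, data.frame(only_var = x))
  expect_equal(nrow(sw$retained), 1)
  r <- simple_regression(y, x)
  expect_equal(sw$retained$F, r$F, tolerance = 1e-8)
  expect_equal(sw$retained$slope, r$slope, tolerance = 1e-10)
})

test_that("backward stepwise retains a real effect among null covariates", {
  set.seed(35)
  hit <- 0
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    n <- 86
    X <- as.data.frame(matrix(rnorm(n * 15), n, 15))
    names(X) <- bioclim_vars()
    y <- scale(X$annual_mean_temp)[, 1] + rnorm(n)   # 1-SD effect
    sw <- backward_stepwise(y, X)
    if ("annual_mean_temp" %in% sw$retained$term) hit <- hit + 1
  }
  expect_gte(hit / n_rep, 0.9)
})

test_that("stepwise under the global null rarely keeps noise covariates", {
  set.seed(36)
  kept <- replicate(30, {
    n <- 86
    X <- as.data.frame(matrix(rnorm(n * 15), n, 15))
    names(X) <- bioclim_vars()
    sw <- backward_stepwise(rnorm(n), X)
    if (is.null(sw$retained)) 0L else nrow(sw$retained)
  })
  # expected roughly 15 * alpha under independence; allow slack for the
  # greedy selection
  expect_lt(mean(kept), 3)
})

test_that("stepwise rejects aliased designs and reports removal order", {
  set.seed(37)
  n <- 30
  X <- data.frame(a = rnorm(n))
  X$b <- 2 * X$a
  expect_error(backward_stepwise(rnorm(n), X), "aliased")

  X2 <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  sw <- backward_stepwise(rnorm(n), X2)
  expect_true(length(sw$dropped) + NROW(sw$retained) == 3)
  expect_output(print(sw), "dropped")
})

test_that("residual_correlates assembles the full summary table", {
  set.seed(38)
  cfg <- sim_config(n_species = 60, seed = 8)
  st <- simulate_seed_study(cfg, traces = FALSE)
  fit <- fit_allometry(st$traits$dry_mass_mg, st$traits$smr20_true,
                       species = st$traits$species, tree = st$tree,
                       method = "PGLS")
  res <- residual_correlates(residuals(fit), st$traits)
  expect_true(all(c("gmax", "t50", "crop_vs_wild", "climate_anova",
                    "aridity_contrast", "stepwise") %in% names(res)))
  expect_s3_class(res$table, "data.frame")
  expect_gte(nrow(res$table), 5)
  # crop species were generated with elevated residuals
  expect_gt(res$crop_vs_wild$slope, 0)
})
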