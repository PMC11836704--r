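#' Univariate regression of allometric residuals on a covariate
#'
#' Ordinary least-squares regression of residual SMR (log10 units) on a
#' single numeric or two-level covariate, reporting the slope, its
#' standard error and the single-factor ANOVA F (`= t^2`).
#'
#' @param residuals Numeric residual vector.
#' @param covariate Numeric vector, or a factor/character/logical with
#'   two levels (coded 0/1 in level order).
#' @return List: `slope`, `se`, `F`, `df1`, `df2`, `p`, `n`.
#' @export
simple_regression <- function(residuals, covariate) {
  if (is.character(covariate)) covariate <- factor(covariate)
  if (is.factor(covariate)) {
    if (nlevels(droplevels(covariate)) != 2) {
      stop("factor covariates must have exactly two levels", call. = FALSE)
    }
    covariate <- as.numeric(droplevels(covariate)) - 1
  }
  if (is.logical(covariate)) covariate <- as.numeric(covariate)
  keep <- is.finite(residuals) & is.finite(covariate)
  y <- residuals[keep]; x <- covariate[keep]
  if (length(y) < 3) stop("fewer than 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0) stop("constant covariate", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- suppressWarnings(summary(fit))$coefficients
  tval <- co["x", "t value"]
  list(slope = unname(co["x", "Estimate"]), se = unname(co["x", "Std. Error"]),
       F = unname(tval^2), df1 = 1, df2 = length(y) - 2,
       p = unname(co["x", "Pr(>|t|)"]), n = length(y))
}

#' Welch two-sample comparison of residuals between groups
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom,
#' appropriate when group sizes and spreads differ strongly (e.g. 14 crop
#' cultivars against ~94 wild species).
#'
#' @param x,y Numeric vectors for the two groups, each of length >= 2.
#' @return List: `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  mean_x = mean(x), mean_y = mean(y)))
    }
    stop("zero variance in both groups", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' One-way ANOVA of residuals across climate classes
#'
#' Classes with fewer than `min_n` species are dropped first (singleton
#' classes carry no within-group information), and the dropped classes
#' are reported.
#'
#' @param residuals Numeric residual vector.
#' @param climate_class Factor or character vector of class labels.
#' @param min_n Minimum class size retained, default 2.
#' @return List: `F`, `df1`, `df2`, `p`, `n`, `dropped`,
#'   `group_means`.
#' @export
climate_anova <- function(residuals, climate_class, min_n = 2) {
  keep <- is.finite(residuals) & !is.na(climate_class)
  y <- residuals[keep]
  g <- factor(as.character(climate_class[keep]))
  sizes <- table(g)
  dropped <- names(sizes)[sizes < min_n]
  ok <- !(g %in% dropped)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("fewer than 2 usable classes", call. = FALSE)
  av <- summary(stats::aov(y ~ g))[[1]]
  list(F = av[1, "F value"], df1 = av[1, "Df"], df2 = av[2, "Df"],
       p = av[1, "Pr(>F)"], n = length(y), dropped = dropped,
       group_means = tapply(y, g, mean))
}

#' Ordered (aridity-trend) contrast across climate classes
#'
#' Single-degree-of-freedom F-test for a monotone trend in group means
#' across classes ranked a priori (e.g. by increasing aridity,
#' Csa < BSh < BWh), using linear polynomial contrast coefficients on the
#' group means with the one-way ANOVA error term:
#' \deqn{F_1 = \frac{(\sum_i c_i \bar{y}_i)^2}
#'   {MSE \sum_i c_i^2 / n_i}.}
#' With `type = "successive"` the two successive-difference contrasts are
#' tested instead and the larger F reported with its class pair.
#'
#' @param residuals Numeric residual vector.
#' @param climate_class Class labels.
#' @param ordered_levels Class labels in increasing rank order (length
#'   >= 3); classes absent from this vector are dropped.
#' @param type `"linear"` (default) for the single ordered trend
#'   contrast, `"successive"` for successive differences.
#' @return List: `F`, `df1`, `df2`, `p`, `n`, `contrast`.
#' @export
ordered_contrast <- function(residuals, climate_class,
                             ordered_levels = c("Csa", "BSh", "BWh"),
                             type = c("linear", "successive")) {
  type <- match.arg(type)
  if (length(ordered_levels) < 3) {
    stop("need at least 3 ordered classes", call. = FALSE)
  }
  keep <- is.finite(residuals) & as.character(climate_class) %in% ordered_levels
  y <- residuals[keep]
  g <- factor(as.character(climate_class[keep]), levels = ordered_levels)
  sizes <- table(g)
  if (any(sizes == 0)) {
    stop("empty class(es): ",
         paste(names(sizes)[sizes == 0], collapse = ", "), call. = FALSE)
  }
  k <- nlevels(g)
  n <- length(y)
  means <- tapply(y, g, mean)
  mse <- sum((y - means[g])^2) / (n - k)
  f_for <- function(cc) {
    est <- sum(cc * means)
    est^2 / (mse * sum(cc^2 / sizes))
  }
  if (type == "linear") {
    cc <- stats::poly(seq_len(k), 1)[, 1]  # normalized linear coefficients
    F <- f_for(cc)
    contrast <- stats::setNames(cc, ordered_levels)
  } else {
    Fs <- vapply(seq_len(k - 1), function(i) {
      cc <- rep(0, k); cc[i] <- -1; cc[i + 1] <- 1
      f_for(cc)
    }, numeric(1))
    F <- max(Fs)
    i <- which.max(Fs)
    cc <- rep(0, k); cc[i] <- -1; cc[i + 1] <- 1
    contrast <- stats::setNames(cc, ordered_levels)
  }
  list(F = unname(F), df1 = 1, df2 = n - k,
       p = stats::pf(F, 1, n - k, lower.tail = FALSE),
       n = n, contrast = contrast)
}

#' Backward stepwise regression of residuals on bioclim covariates
#'
#' Starts from the full main-effects model over all supplied covariates
#' and repeatedly removes the single term with the largest type-III
#' p-value above `alpha_stay`, refitting after each removal, until every
#' retained term satisfies `p <= alpha_stay`. Ties are broken
#' alphabetically by variable name, so the removal path is deterministic.
#' No interaction terms are considered. Strongly co-correlated covariates
#' are permitted (the design may be ill-conditioned); the condition
#' number of the standardized design is reported, and exactly aliased
#' columns are an error.
#'
#' @param residuals Numeric residual vector.
#' @param covariates Data.frame of numeric covariates (e.g. the
#'   [bioclim_vars()] columns).
#' @param alpha_stay Retention threshold for type-III p-values,
#'   default 0.05.
#' @return Object of class `stepwise_fit`: `retained` (data.frame with
#'   term, slope, se, F, df1, df2, p), `dropped` (removal order), `n`,
#'   `model` (the final `lm`), `condition_number`.
#' @export
backward_stepwise <- function(residuals, covariates, alpha_stay = 0.05) {
  stopifnot(is.data.frame(covariates))
  covariates <- covariates[, order(names(covariates)), drop = FALSE]
  keep <- is.finite(residuals) & stats::complete.cases(covariates)
  y <- residuals[keep]
  X <- covariates[keep, , drop = FALSE]
  n <- length(y)
  if (n <= ncol(X) + 1) {
    stop("need more observations than parameters (n = ", n,
         ", p = ", ncol(X), ")", call. = FALSE)
  }
  d <- data.frame(.y = y, X, check.names = FALSE)
  full <- stats::lm(.y ~ ., data = d)
  if (any(is.na(stats::coef(full)))) {
    stop("aliased (exactly collinear) covariate(s): ",
         paste(names(stats::coef(full))[is.na(stats::coef(full))],
               collapse = ", "), call. = FALSE)
  }
  cond <- kappa(scale(as.matrix(X)), exact = TRUE)
  type3_p <- function(fit) {
    a3 <- car::Anova(fit, type = 3)
    p <- a3[, "Pr(>F)"]
    names(p) <- gsub("`", "", rownames(a3))
    p[!names(p) %in% c("(Intercept)", "Residuals")]
  }
  terms_now <- names(X)
  dropped <- character(0)
  fit <- full
  repeat {
    if (length(terms_now) == 0) break
    p <- type3_p(fit)
    p <- p[order(names(p))]             # alphabetical tie-break
    worst <- names(p)[order(-p, names(p))][1]
    if (p[worst] <= alpha_stay) break
    dropped <- c(dropped, worst)
    terms_now <- setdiff(terms_now, worst)
    if (length(terms_now) == 0) {
      fit <- stats::lm(.y ~ 1, data = d)
      break
    }
    fml <- stats::reformulate(sprintf("`%s`", terms_now), response = ".y")
    fit <- stats::lm(fml, data = d)
  }
  retained <- NULL
  if (length(terms_now) > 0) {
    a3 <- car::Anova(fit, type = 3)
    co <- summary(fit)$coefficients
    rows <- rownames(a3)[!rownames(a3) %in% c("(Intercept)", "Residuals")]
    co_names <- rownames(co)
    strip <- function(s) gsub("`", "", s)
    idx <- match(rows, strip(co_names))
    retained <- data.frame(
      term = rows,
      slope = co[idx, "Estimate"],
      se = co[idx, "Std. Error"],
      F = a3[rows, "F value"],
      df1 = a3[rows, "Df"],
      df2 = a3["Residuals", "Df"],
      p = a3[rows, "Pr(>F)"],
      row.names = NULL)
  }
  out <- list(retained = retained, dropped = dropped, n = n,
              model = fit, condition_number = cond,
              alpha_stay = alpha_stay)
  class(out) <- "stepwise_fit"
  out
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("Backward stepwise regression (n = %d, alpha_stay = %g)\n",
              x$n, x$alpha_stay))
  cat(sprintf("  dropped (in order): %s\n",
              if (length(x$dropped)) paste(x$dropped, collapse = ", ")
              else "none"))
  if (is.null(x$retained)) {
    cat("  no terms retained\n")
  } else {
    cat("  retained terms:\n")
    print(x$retained, digits = 4, row.names = FALSE)
  }
  cat(sprintf("  design condition number: %.3g\n", x$condition_number))
  invisible(x)
}

#' Full correlate analysis of allometric residuals
#'
#' Reproduces the residual-correlate layer of the seed SMR analysis:
#' univariate regressions of residuals on maximum germination and
#' germination speed, the crop-vs-wild comparison (all species), then —
#' on native species only, after removing crops (selectively bred, higher
#' residuals) and weeds (uncertain provenance) — climate-class ANOVA with
#' singleton classes dropped, the a priori ordered aridity contrast, and
#' backward stepwise regression over the bioclim covariates.
#'
#' @param residuals Named residual vector (species names).
#' @param traits Trait table with `species`, `status`, `climate_class`,
#'   `gmax`, `t50` and [bioclim_vars()] columns (missing columns skip the
#'   corresponding analyses).
#' @param ordered_levels Climate classes in increasing aridity order.
#' @param alpha_stay Stepwise retention threshold.
#' @return List of results with a `table` element mirroring a
#'   factor/slope/F/p summary table.
#' @export
residual_correlates <- function(residuals, traits,
                                ordered_levels = c("Csa", "BSh", "BWh"),
                                alpha_stay = 0.05) {
  stopifnot(!is.null(names(residuals)))
  traits <- traits[match(names(residuals), traits$species), , drop = FALSE]
  out <- list()
  rows <- list()
  add_row <- function(factor, slope, se, F, df1, df2, p, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      factor = factor, slope = slope, se = se, F = F,
      df = sprintf("%d,%d", df1, df2), p = p, n = n)
  }
  if ("gmax" %in% names(traits)) {
    r <- simple_regression(residuals, traits$gmax)
    out$gmax <- r
    add_row("maximum germination (Gmax) %", r$slope, r$se, r$F,
            r$df1, r$df2, r$p, r$n)
  }
  if ("t50" %in% names(traits)) {
    r <- simple_regression(residuals, traits$t50)
    out$t50 <- r
    add_row("germination speed (T50) days", r$slope, r$se, r$F,
            r$df1, r$df2, r$p, r$n)
  }
  native <- NULL
  if ("status" %in% names(traits)) {
    crop <- traits$status == "crop"
    r <- simple_regression(residuals, crop)
    out$crop_vs_wild <- r
    add_row("crop vs wild", r$slope, r$se, r$F, r$df1, r$df2, r$p, r$n)
    out$crop_welch <- welch_t(residuals[crop], residuals[!crop])
    native <- traits$status == "native"
  }
  if (!is.null(native) && "climate_class" %in% names(traits)) {
    rn <- residuals[native]
    cn <- traits$climate_class[native]
    av <- climate_anova(rn, cn)
    out$climate_anova <- av
    add_row("Koppen-Geiger climate class", NA, NA, av$F, av$df1, av$df2,
            av$p, av$n)
    ct <- ordered_contrast(rn, cn, ordered_levels = ordered_levels)
    out$aridity_contrast <- ct
    add_row("ordered aridity contrast", NA, NA, ct$F, ct$df1, ct$df2,
            ct$p, ct$n)
    bc <- intersect(bioclim_vars(), names(traits))
    n_usable <- if (length(bc) > 0) {
      sum(is.finite(rn) & stats::complete.cases(traits[native, bc]))
    } else 0
    if (length(bc) > 0 && n_usable > length(bc) + 1) {
      sw <- backward_stepwise(rn, traits[native, bc, drop = FALSE],
                              alpha_stay = alpha_stay)
      out$stepwise <- sw
      if (!is.null(sw$retained)) {
        for (i in seq_len(nrow(sw$retained))) {
          add_row(sw$retained$term[i], sw$retained$slope[i],
                  sw$retained$se[i], sw$retained$F[i], sw$retained$df1[i],
                  sw$retained$df2[i], sw$retained$p[i], sw$n)
        }
      }
    }
  }
  out$table <- do.call(rbind, rows)
  out
}
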