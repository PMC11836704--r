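#' Run the full seed-energetics analysis pipeline
#'
#' Orchestrates every stage end-to-end: read and validate the tree and
#' trait table, process raw respirometry traces into a Q10-standardized
#' SMR table (or take `smr_t`/`t_measure_c` from the trait table when no
#' traces are supplied), fit germination curves when germination counts
#' are given, fit OLS and PGLS allometries with the isometry test and
#' model comparison, compute phylogenetic signal for log10 mass and
#' log10 SMR, extract PGLS residuals, and run the correlate analysis.
#' Results are returned as a list and, when `out_dir` is given, written
#' as `smr_table.csv`, `allometry_report.json`, `signal_stats.json`,
#' `residuals.csv` and `correlates.csv`.
#'
#' @param config A named list (or path to a YAML/JSON file naming one)
#'   with elements: `tree` (path or `phylo`), `traits` (path or
#'   data.frame), optionally `traces` (path or data.frame),
#'   `germination` (path or data.frame), `q10` (default 2.5), `t_ref`
#'   (20), `lambda_mode` ("REML"), `alpha_stay` (0.05), `n_perm` (999),
#'   `seed` (1), `out_dir`.
#' @return A list with elements `smr`, `germination`, `ols`, `pgls`,
#'   `comparison`, `isometry`, `signal_mass`, `signal_smr`, `residuals`,
#'   `correlates`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- read_pipeline_config(config)
  }
  defaults <- list(q10 = 2.5, t_ref = 20, lambda_mode = "REML",
                   alpha_stay = 0.05, n_perm = 999, seed = 1,
                   out_dir = NULL)
  config <- utils::modifyList(defaults, config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tree <- stage("tree", {
    if (inherits(config$tree, "phylo")) validate_phylogeny(config$tree)
    else read_phylogeny(config$tree)
  })
  if (ape::Ntip(tree) - 1L > tree$Nnode) {
    tree <- resolve_polytomies(tree, offset_myr = 1)
  }
  traits <- stage("traits", {
    if (is.data.frame(config$traits)) validate_trait_table(config$traits,
                                                           tree = tree)
    else read_trait_table(config$traits, tree = tree)
  })
  smr <- stage("respirometry", {
    if (!is.null(config$traces)) {
      tr <- if (is.data.frame(config$traces)) validate_traces(config$traces)
            else read_traces(config$traces)
      process_respirometry(tr, q10 = config$q10, t_ref = config$t_ref)
    } else {
      if (!all(c("smr_t", "t_measure_c") %in% names(traits))) {
        stop("no traces given and trait table lacks smr_t/t_measure_c")
      }
      data.frame(species = traits$species, smr_t = traits$smr_t,
                 t_measure_c = traits$t_measure_c,
                 smr20 = q10_correct(traits$smr_t, traits$t_measure_c,
                                     t_ref = config$t_ref, q10 = config$q10),
                 n_replicates = NA_integer_,
                 n_replicates_kept = NA_integer_)
    }
  })
  germ <- NULL
  if (!is.null(config$germination)) {
    germ <- stage("germination", {
      g <- if (is.data.frame(config$germination)) config$germination
           else utils::read.csv(config$germination)
      germination_metrics(g)
    })
    traits$gmax <- germ$gmax[match(traits$species, germ$species)]
    traits$t50 <- germ$t50[match(traits$species, germ$species)]
  }
  m <- match(smr$species, traits$species)
  dat <- data.frame(species = smr$species,
                    mass = traits$dry_mass_mg[m], smr20 = smr$smr20)
  dat <- dat[stats::complete.cases(dat) & dat$smr20 > 0, , drop = FALSE]
  n_dropped <- nrow(smr) - nrow(dat)
  if (n_dropped > 0) {
    message(n_dropped, " species dropped for missing mass or SMR")
  }
  ols <- stage("allometry", {
    fit_allometry(dat$mass, dat$smr20, species = dat$species,
                  method = "OLS")
  })
  pgls <- stage("allometry", {
    fit_allometry(dat$mass, dat$smr20, species = dat$species, tree = tree,
                  method = "PGLS", lambda = config$lambda_mode)
  })
  comparison <- compare_allometry(ols, pgls)
  iso <- isometry_test(ols)
  lm10 <- stats::setNames(log10(dat$mass), dat$species)
  ls10 <- stats::setNames(log10(dat$smr20), dat$species)
  keep_tree <- ape::keep.tip(tree, dat$species)
  sig_mass <- stage("signal", {
    phylo_signal(lm10, keep_tree, n_perm = config$n_perm,
                 seed = config$seed, trait_name = "log10 mass")
  })
  sig_smr <- stage("signal", {
    phylo_signal(ls10, keep_tree, n_perm = config$n_perm,
                 seed = config$seed, trait_name = "log10 SMR20")
  })
  res <- residuals(pgls)
  correlates <- stage("correlates", {
    tr2 <- traits[match(names(res), traits$species), , drop = FALSE]
    if (any(c("status", "gmax", "t50") %in% names(tr2))) {
      residual_correlates(res, tr2, alpha_stay = config$alpha_stay)
    } else NULL
  })
  out <- list(smr = smr, germination = germ, ols = ols, pgls = pgls,
              comparison = comparison, isometry = iso,
              signal_mass = sig_mass, signal_smr = sig_smr,
              residuals = res, correlates = correlates,
              config = config)
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(out, config$out_dir)
  }
  invisible(out)
}

read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop("YAML configs require the 'yaml' package", call. = FALSE)
  }
}

fit_json <- function(fit) {
  list(method = fit$method,
       intercept_log10 = unname(fit$coefficients["intercept"]),
       a = unname(10^fit$coefficients["intercept"]),
       slope = unname(fit$coefficients["slope"]),
       se_intercept = unname(fit$se["intercept"]),
       se_slope = unname(fit$se["slope"]),
       lambda = fit$lambda, loglik = fit$loglik, aic = fit$aic,
       r2 = fit$r2, n = fit$n)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$smr, file.path(out_dir, "smr_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(ols = fit_json(result$ols), pgls = fit_json(result$pgls),
         comparison = result$comparison, isometry = result$isometry),
    file.path(out_dir, "allometry_report.json"),
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(log10_mass = unclass(result$signal_mass),
         log10_smr = unclass(result$signal_smr)),
    file.path(out_dir, "signal_stats.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(species = names(result$residuals),
               residual = unname(result$residuals)),
    file.path(out_dir, "residuals.csv"), row.names = FALSE)
  if (!is.null(result$correlates) && !is.null(result$correlates$table)) {
    utils::write.csv(result$correlates$table,
                     file.path(out_dir, "correlates.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}
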