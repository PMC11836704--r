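#' Configuration for the synthetic seed-energetics study generator
#'
#' Bundles every parameter of the synthetic data generator. Defaults
#' emulate the structure and scale of a comparative seed SMR study: 108
#' species (87 native, 7 naturalized weeds, 14 crop cultivars) on an
#' ultrametric birth-death tree of height 160.5 Myr; a power-law
#' mass-SMR relationship `SMR = a * M^b` with `a = 0.057`, `b = 0.75`
#' and lognormal residual scatter of 0.5 log10 units carrying
#' phylogenetic signal `lambda = 0.6`; species-specific measurement
#' temperatures of 18-30 degrees (so the pipeline must Q10-standardize,
#' Q10 = 2.5); 10 replicate chambers per species sampled every 30 min
#' over 48 h with 0.05 kPa white noise on pO2 and a 20% chance per
#' replicate of microbial contamination multiplying the depletion slope
#' by 5; binomial cumulative germination counts from a log-logistic truth
#' (50 seeds sown); native species spread over three Koppen-Geiger
#' classes of increasing aridity (Csa, BSh, BWh, plus one BSk singleton)
#' with ordered shifts 0 / 0.25 / 0.5 log10 units added to residual SMR;
#' and 15 block-correlated bioclim covariates (within-block correlation
#' 0.7) whose temperature and precipitation levels track the climate
#' class.
#'
#' @param n_species Number of tips / species.
#' @param seed Integer seed; mandatory for all stochastic operations.
#' @param birth,death Birth-death rates for the tree shape.
#' @param tree_height Tree height in Myr.
#' @param true_a,true_b Allometry intercept (original scale) and exponent.
#' @param sigma_resid Residual SD in log10 units.
#' @param true_lambda Pagel's lambda of the residual covariance, [0, 1].
#' @param mass_log10_mean,mass_log10_sd Mean and SD of log10 dry mass
#'   (mg) across tips (Brownian motion scaled to this marginal SD).
#' @param q10 Q10 used to de-standardize SMR to measurement temperature.
#' @param temp_range Range of species measurement temperatures, degrees C.
#' @param n_replicates Chambers per species.
#' @param sample_interval_h,duration_h Trace sampling design.
#' @param trace_noise_kpa White-noise SD added to pO2 samples.
#' @param p_contam Probability a replicate is contaminated.
#' @param contam_factor Slope multiplier for contaminated replicates.
#' @param po2_init_kpa Initial chamber pO2.
#' @param pressure_kpa Ambient pressure.
#' @param n_status Named counts for native/weed/crop species.
#' @param crop_effect Log10 shift added to crop species' SMR.
#' @param climate_n Named counts of native species per climate class.
#' @param climate_effects Named ordered log10 shifts per climate class.
#' @param germ_b_range,germ_d_range,germ_e_range Ranges for the
#'   log-logistic germination truth (slope, asymptote %, inflection days).
#' @param germ_n_sown Seeds sown per species in the germination trial.
#' @param germ_score_days Scoring days for cumulative counts.
#' @param bioclim_rho Within-block correlation of the bioclim covariates.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 108,
                       seed = 1,
                       birth = 0.1, death = 0.05,
                       tree_height = 160.5,
                       true_a = 0.057, true_b = 0.75,
                       sigma_resid = 0.5,
                       true_lambda = 0.6,
                       mass_log10_mean = 0.7, mass_log10_sd = 0.8,
                       q10 = 2.5,
                       temp_range = c(18, 30),
                       n_replicates = 10,
                       sample_interval_h = 0.5, duration_h = 48,
                       trace_noise_kpa = 0.05,
                       p_contam = 0.2, contam_factor = 5,
                       po2_init_kpa = 20.6, pressure_kpa = 101.325,
                       n_status = c(native = 87, weed = 7, crop = 14),
                       crop_effect = 0.5,
                       climate_n = c(Csa = 60, BSh = 6, BWh = 20, BSk = 1),
                       climate_effects = c(Csa = 0, BSh = 0.25, BWh = 0.5,
                                           BSk = 0),
                       germ_b_range = c(-8, -2),
                       germ_d_range = c(30, 100),
                       germ_e_range = c(2, 15),
                       germ_n_sown = 50,
                       germ_score_days = seq(3, 56, by = 3),
                       bioclim_rho = 0.7) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_species >= 3, cfg$birth >= 0, cfg$death >= 0,
            cfg$true_lambda >= 0, cfg$true_lambda <= 1,
            is.numeric(cfg$seed), length(cfg$seed) == 1)
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic per-stage seeding: every generator op reseeds from
# (config$seed, stage), so each op is reproducible on its own.
stage_seed <- function(config, stage) {
  set.seed((config$seed * 97L + stage) %% .Machine$integer.max)
}

# Allocate n items over named groups proportionally to `counts`
# (largest-remainder rounding), so configured group proportions hold at
# any n_species.
alloc_counts <- function(counts, n) {
  counts <- counts[counts > 0]
  raw <- counts / sum(counts) * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  rep(names(base), base)
}

#' Simulate an ultrametric birth-death phylogeny
#'
#' Conditioned on the tip count via [ape::rphylo()] and rescaled to
#' `tree_height`. Tips are labelled `sp001`, `sp002`, ...
#'
#' @param config A [sim_config()].
#' @return A `phylo` object.
#' @export
simulate_tree <- function(config) {
  stage_seed(config, 1L)
  tree <- ape::rphylo(config$n_species, birth = config$birth,
                      death = config$death)
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * config$tree_height / h
  tree$tip.label <- sprintf("sp%03d", seq_len(config$n_species))
  tree
}

# Draw one multivariate-normal vector with covariance V via Cholesky.
rmvn_chol <- function(V) {
  drop(t(chol(V)) %*% stats::rnorm(nrow(V)))
}

#' Simulate allometric mass and SMR traits on a tree
#'
#' log10 dry mass evolves by Brownian motion on the tree, scaled so its
#' marginal SD matches `mass_log10_sd`; log10 SMR at 20 degrees is
#' `log10(true_a) + true_b * log10(mass)` plus multivariate-normal
#' residuals with covariance `sigma_resid^2` times the
#' lambda-transformed Brownian correlation. Species are assigned a
#' status (native/weed/crop, crop species receiving `crop_effect` extra
#' log10 SMR) and a measurement temperature from `temp_range`; the
#' reported `smr_t` is back-transformed through the inverse Q10 rule so
#' the analysis pipeline must re-standardize it.
#'
#' @param tree A `phylo` from [simulate_tree()].
#' @param config A [sim_config()].
#' @return A trait `data.frame` (species, dry_mass_mg, smr_t,
#'   t_measure_c, status, smr20_true, resid_true).
#' @export
simulate_allometric_traits <- function(tree, config) {
  stage_seed(config, 2L)
  C <- phylo_vcv(tree)
  n <- nrow(C)
  Ccor <- C / config$tree_height          # unit-diagonal BM correlation
  log_mass <- config$mass_log10_mean +
    config$mass_log10_sd * rmvn_chol(Ccor)
  resid <- config$sigma_resid *
    rmvn_chol(lambda_transform(Ccor, config$true_lambda))
  status <- sample(alloc_counts(config$n_status, n))
  eff <- ifelse(status == "crop", config$crop_effect, 0)
  log_smr20 <- log10(config$true_a) + config$true_b * log_mass + resid + eff
  t_meas <- sample(seq(config$temp_range[1], config$temp_range[2]),
                   n, replace = TRUE)
  smr20 <- 10^log_smr20
  smr_t <- smr20 * config$q10 ^ ((t_meas - 20) / 10)
  data.frame(species = rownames(C), dry_mass_mg = 10^log_mass,
             smr_t = smr_t, t_measure_c = t_meas, status = status,
             smr20_true = smr20, resid_true = resid + eff,
             row.names = NULL)
}

#' Simulate raw respirometry traces for every species
#'
#' Inverts the trace-processing chain: each species' true per-seed
#' oxygen consumption at its measurement temperature is converted to a
#' pO2 depletion slope through the inverse of [slope_to_vo2()] (seed
#' count chosen so the chamber depletes a few kPa over the run, clamped
#' to 2-150 seeds), sampled every `sample_interval_h` hours over
#' `duration_h` with Gaussian noise, and with probability `p_contam` a
#' replicate's slope is multiplied by `contam_factor`, emulating
#' microbial contamination.
#'
#' @param traits A trait table from [simulate_allometric_traits()].
#' @param config A [sim_config()].
#' @return A trace `data.frame` in [read_traces()] layout, with the true
#'   contamination flags attached as attribute `"contaminated"`.
#' @export
simulate_traces <- function(traits, config) {
  stage_seed(config, 3L)
  times <- seq(0, config$duration_h, by = config$sample_interval_h)
  out <- vector("list", nrow(traits) * config$n_replicates)
  contam_log <- list()
  k <- 0L
  for (i in seq_len(nrow(traits))) {
    sp <- traits$species[i]
    tc <- traits$t_measure_c[i]
    p_dry <- config$pressure_kpa - svp_buck(tc)
    stp <- 273.15 / (273.15 + tc)
    volume <- 1500
    # per-seed slope magnitude; target ~3 kPa total depletion
    slope_per_seed <- traits$smr_t[i] * p_dry / (volume * stp)
    n_seeds <- round(3 / (config$duration_h * slope_per_seed))
    n_seeds <- min(max(n_seeds, 2), 150)
    slope <- -slope_per_seed * n_seeds
    for (r in seq_len(config$n_replicates)) {
      k <- k + 1L
      contam <- stats::runif(1) < config$p_contam
      s <- if (contam) slope * config$contam_factor else slope
      po2 <- config$po2_init_kpa + s * times +
        stats::rnorm(length(times), sd = config$trace_noise_kpa)
      # fully depleted chambers read a small positive floor; everything
      # below 0.8 of initial is discarded upstream of analysis anyway
      po2 <- pmax(po2, 1e-3)
      id <- sprintf("%s_r%02d", sp, r)
      out[[k]] <- data.frame(chamber_id = id, species = sp,
                             time_h = times, po2_kpa = po2,
                             volume_ul = volume, n_seeds = n_seeds,
                             temp_c = tc,
                             pressure_kpa = config$pressure_kpa)
      contam_log[[k]] <- data.frame(chamber_id = id, species = sp,
                                    contaminated = contam)
    }
  }
  traces <- do.call(rbind, out)
  attr(traces, "contaminated") <- do.call(rbind, contam_log)
  traces
}

#' Simulate germination counts and climate structure
#'
#' Adds to the trait table: (i) cumulative binomial germination counts
#' from a per-species three-parameter log-logistic truth (each sown seed
#' germinates with probability `d/100`, with a log-logistic germination
#' time), crop species drawn from the fast/high end of the parameter
#' ranges; (ii) a climate class for native species with the configured
#' ordered aridity shifts added to true SMR (and propagated to `smr_t`);
#' and (iii) 15 block-correlated bioclim covariates whose temperature
#' block increases, and precipitation block decreases, with aridity.
#'
#' @param traits A trait table from [simulate_allometric_traits()].
#' @param config A [sim_config()].
#' @return List: `traits` (augmented; SMR columns updated), `germination`
#'   (long count table: species, time_days, germinated_count, n_sown),
#'   `germ_truth` (per-species b, d, e).
#' @export
simulate_germination_and_climate <- function(traits, config) {
  stage_seed(config, 4L)
  n <- nrow(traits)
  crop <- traits$status == "crop"
  # germination truth; crops fast (small e) and successful (high d)
  b <- stats::runif(n, config$germ_b_range[1], config$germ_b_range[2])
  d <- stats::runif(n, config$germ_d_range[1], config$germ_d_range[2])
  e <- stats::runif(n, config$germ_e_range[1], config$germ_e_range[2])
  d[crop] <- stats::runif(sum(crop), 80, 100)
  e[crop] <- stats::runif(sum(crop), 1.5, 5)
  germ <- vector("list", n)
  for (i in seq_len(n)) {
    n_sown <- config$germ_n_sown
    will <- stats::runif(n_sown) < d[i] / 100
    # log-logistic germination times: F(t) = 1/(1 + (t/e)^b), b < 0
    u <- stats::runif(n_sown)
    t_germ <- e[i] * (1 / u - 1)^(1 / b[i])
    t_germ[!will] <- Inf
    counts <- vapply(config$germ_score_days,
                     function(td) sum(t_germ <= td), integer(1))
    germ[[i]] <- data.frame(species = traits$species[i],
                            time_days = config$germ_score_days,
                            germinated_count = counts, n_sown = n_sown)
  }
  germination <- do.call(rbind, germ)
  gmax_true <- vapply(split(germination, germination$species),
                      function(g) 100 * max(g$germinated_count) / g$n_sown[1],
                      numeric(1))
  traits$gmax <- gmax_true[traits$species]
  traits$t50 <- e
  # climate classes for native species, ordered aridity shifts on SMR
  native <- traits$status == "native"
  cls <- rep(NA_character_, n)
  cls[native] <- sample(alloc_counts(config$climate_n, sum(native)))
  traits$climate_class <- cls
  shift <- ifelse(is.na(cls), 0, config$climate_effects[cls])
  traits$smr20_true <- traits$smr20_true * 10^shift
  traits$resid_true <- traits$resid_true + shift
  traits$smr_t <- traits$smr20_true *
    config$q10 ^ ((traits$t_measure_c - 20) / 10)
  # bioclim covariates: class-dependent means, block-correlated noise
  arid_rank <- c(Csa = 0, BSh = 1, BWh = 2, BSk = 1)
  rank <- ifelse(is.na(cls), 1, arid_rank[cls])
  vars <- bioclim_vars()
  temp_block <- vars[1:9]
  prec_block <- vars[10:15]
  blk <- function(p, rho, nobs) {
    S <- matrix(rho, p, p); diag(S) <- 1
    t(t(chol(S)) %*% matrix(stats::rnorm(p * nobs), p, nobs))
  }
  zt <- blk(length(temp_block), config$bioclim_rho, n)
  zp <- blk(length(prec_block), config$bioclim_rho, n)
  base_t <- c(annual_mean_temp = 18, diurnal_range = 12, isothermality = 0.5,
              temp_seasonality = 400, annual_temp_range = 28,
              temp_wettest_q = 14, temp_driest_q = 24,
              temp_warmest_q = 26, temp_coldest_q = 11)
  sd_t <- c(2, 1.5, 0.05, 60, 2.5, 3, 3, 3, 2)
  gain_t <- c(3, 1.5, 0.04, 50, 2, 6, 3, 3, 3)
  base_p <- c(annual_precip = 600, precip_seasonality = 40,
              precip_wettest_q = 280, precip_driest_q = 30,
              precip_warmest_q = 60, precip_coldest_q = 250)
  sd_p <- c(80, 8, 45, 10, 25, 45)
  gain_p <- c(-180, 25, -90, 5, 60, -100)
  for (j in seq_along(temp_block)) {
    traits[[temp_block[j]]] <- base_t[j] + gain_t[j] * rank +
      sd_t[j] * zt[, j]
  }
  for (j in seq_along(prec_block)) {
    traits[[prec_block[j]]] <- pmax(base_p[j] + gain_p[j] * rank +
                                      sd_p[j] * zp[, j], 0)
  }
  list(traits = traits, germination = germination,
       germ_truth = data.frame(species = traits$species, b = b, d = d, e = e))
}

#' Generate a complete synthetic seed-energetics study
#'
#' Runs all generator stages and optionally writes the study to disk as
#' `tree.nwk`, `traits.csv`, `traces.csv`, `germination.csv` and a
#' `truth.json` manifest of the generating parameters.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory (created if needed).
#' @param traces Logical; simulate raw respirometry traces (the slowest
#'   stage). When `FALSE`, analyses start from the trait table's `smr_t`.
#' @return List: `tree`, `traits`, `traces` (or `NULL`), `germination`,
#'   `truth`.
#' @export
simulate_seed_study <- function(config = sim_config(), dir = NULL,
                                traces = TRUE) {
  tree <- simulate_tree(config)
  traits <- simulate_allometric_traits(tree, config)
  gc <- simulate_germination_and_climate(traits, config)
  traits <- gc$traits
  tr <- if (traces) simulate_traces(traits, config) else NULL
  truth <- list(n_species = config$n_species, true_a = config$true_a,
                true_b = config$true_b, true_lambda = config$true_lambda,
                sigma_resid = config$sigma_resid, q10 = config$q10,
                crop_effect = config$crop_effect,
                climate_effects = as.list(config$climate_effects),
                seed = config$seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_phylogeny(tree, file.path(dir, "tree.nwk"))
    utils::write.csv(traits, file.path(dir, "traits.csv"),
                     row.names = FALSE)
    if (!is.null(tr)) {
      utils::write.csv(tr, file.path(dir, "traces.csv"), row.names = FALSE)
    }
    utils::write.csv(gc$germination, file.path(dir, "germination.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(tree = tree, traits = traits, traces = tr,
       germination = gc$germination, truth = truth)
}
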