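test_that("tree simulation is ultrametric, scaled and reproducible", {
  cfg <- sim_config(n_species = 30, seed = 4)
  tr <- simulate_tree(cfg)
  expect_equal(ape::Ntip(tr), 30)
  depths <- ape::node.depth.edgelength(tr)[1:30]
  expect_equal(unname(depths), rep(160.5, 30), tolerance = 1e-8)
  # byte-identical rerun from the same config
  expect_identical(ape::write.tree(simulate_tree(cfg)), ape::write.tree(tr))
  # a different seed gives a different tree
  cfg2 <- sim_config(n_species = 30, seed = 5)
  expect_false(identical(ape::write.tree(simulate_tree(cfg2)),
                         ape::write.tree(tr)))
})

test_that("noise-free allometric traits sit exactly on the power law", {
  cfg <- sim_config(n_species = 20, seed = 6, sigma_resid = 0,
                    n_status = c(native = 20, weed = 0, crop = 0))
  tr <- simulate_tree(cfg)
  tra <- simulate_allometric_traits(tr, cfg)
  fit <- fit_allometry(tra$dry_mass_mg, tra$smr20_true,
                       species = tra$species)
  expect_equal(unname(coef(fit)["slope"]), cfg$true_b, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["intercept"]), log10(cfg$true_a),
               tolerance = 1e-8)
  # smr_t is the inverse-Q10 image of smr20
  expect_equal(q10_correct(tra$smr_t, tra$t_measure_c), tra$smr20_true,
               tolerance = 1e-10)
})

test_that("trait simulation is reproducible and statuses respect counts", {
  cfg <- sim_config(n_species = 40, seed = 7,
                    n_status = c(native = 30, weed = 4, crop = 6))
  tr <- simulate_tree(cfg)
  t1 <- simulate_allometric_traits(tr, cfg)
  t2 <- simulate_allometric_traits(tr, cfg)
  expect_identical(t1, t2)
  expect_equal(sum(t1$status == "crop"), 6)
  expect_equal(sum(t1$status == "native"), 30)
})

test_that("simulated traces invert exactly through the pipeline", {
  cfg <- sim_config(n_species = 6, seed = 9, trace_noise_kpa = 0,
                    p_contam = 0, n_replicates = 3, duration_h = 24,
                    n_status = c(native = 6, weed = 0, crop = 0))
  tr <- simulate_tree(cfg)
  tra <- simulate_allometric_traits(tr, cfg)
  trc <- simulate_traces(tra, cfg)
  smr <- process_respirometry(trc)
  m <- match(smr$species, tra$species)
  expect_equal(smr$smr_t, tra$smr_t[m], tolerance = 1e-8)
  expect_equal(smr$smr20, tra$smr20_true[m], tolerance = 1e-8)
  # reproducible
  expect_identical(simulate_traces(tra, cfg), trc)
})

test_that("germination and climate layers carry the configured structure", {
  cfg <- sim_config(n_species = 60, seed = 10)
  tr <- simulate_tree(cfg)
  tra <- simulate_allometric_traits(tr, cfg)
  gc <- simulate_germination_and_climate(tra, cfg)
  tt <- gc$traits
  expect_true(all(bioclim_vars() %in% names(tt)))
  expect_true(all(!is.na(tt$climate_class[tt$status == "native"])))
  expect_true(all(is.na(tt$climate_class[tt$status != "native"])))
  # cumulative counts are non-decreasing per species
  nd <- tapply(gc$germination$germinated_count, gc$germination$species,
               function(x) all(diff(x) >= 0))
  expect_true(all(nd))
  # ordered aridity shifts show up in the residual truth
  mn <- tapply(tt$resid_true, tt$climate_class, mean)
  expect_gt(mn["BWh"], mn["Csa"])
  # temperature covariates track aridity rank
  expect_gt(mean(tt$annual_mean_temp[tt$climate_class == "BWh"], na.rm = TRUE),
            mean(tt$annual_mean_temp[tt$climate_class == "Csa"], na.rm = TRUE))
})

test_that("study bundles round-trip through the file formats", {
  cfg <- sim_config(n_species = 12, seed = 11, n_replicates = 3,
                    duration_h = 12)
  dir <- withr::local_tempdir()
  st <- simulate_seed_study(cfg, dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("tree.nwk", "traits.csv", "traces.csv", "germination.csv",
           "truth.json")))))
  tr2 <- read_phylogeny(file.path(dir, "tree.nwk"))
  expect_setequal(tr2$tip.label, st$tree$tip.label)
  tab <- read_trait_table(file.path(dir, "traits.csv"), tree = tr2)
  expect_equal(nrow(tab), 12)
  expect_equal(sort(tab$dry_mass_mg), sort(st$traits$dry_mass_mg),
               tolerance = 1e-8)
  trc <- read_traces(file.path(dir, "traces.csv"))
  expect_equal(nrow(trc), nrow(st$traces))
})
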