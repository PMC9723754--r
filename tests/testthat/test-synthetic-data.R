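test_that("design generation covers the default layout and degenerate cases", {
  d <- generate_design(design_config())
  expect_identical(nrow(d), 150L)
  expect_identical(length(unique(d$plot)), 52L)
  expect_true(all(d$richness %in% c(1, 2, 4, 8, 16, 24)))
  # every plot carries exactly one richness level
  expect_true(all(tapply(d$richness, d$plot, function(r)
    length(unique(r))) == 1))

  d1 <- generate_design(design_config(n_plots = 1, n_samples = 1,
                                      richness_levels = 4))
  expect_identical(nrow(d1), 1L)

  # determinism
  expect_identical(generate_design(design_config(seed = 9)),
                   generate_design(design_config(seed = 9)))
  expect_error(design_config(n_plots = 0), "positive integer")
  expect_error(design_config(n_samples = 10, n_plots = 20), "n_samples")
})

test_that("soil chemistry honors its covariance specification and ranges", {
  dsn <- generate_design(design_config(n_plots = 50, n_samples = 10000,
                                       seed = 3))
  p_id <- generator_params(exogenous_covariance = diag(5))
  soil <- generate_soil_chemistry(dsn, p_id, seed = 3)
  lat <- attr(soil, "latents")
  # identity covariance: pairwise latent correlations within +/- 0.05 of 0
  cm <- cor(lat)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)
  # marginal control: latent means ~ 0, SDs ~ 1
  expect_lt(max(abs(colMeans(lat))), 0.05)
  expect_lt(max(abs(apply(lat, 2, sd) - 1)), 0.05)
  # measurement ranges
  expect_true(all(soil$toc > 0 & soil$tn > 0 & soil$tp > 0))
  expect_true(all(soil$ph >= 3 & soil$ph <= 9))
  expect_true(all(soil$humidity > 0 & soil$humidity < 1))

  # zero-noise variant collapses onto the mean vector
  soil0 <- generate_soil_chemistry(dsn[1:10, ],
                                   generator_params(soil_noise_scale = 0),
                                   seed = 1)
  expect_equal(unname(apply(soil0[, -1], 2, sd)), rep(0, 5))

  # non-positive-definite covariance is rejected
  bad <- diag(c(1, 1, 0, 1, 1))
  expect_error(generator_params(exogenous_covariance = bad),
               "positive definite")
})

test_that("latent facets follow the structural equations", {
  dsn <- generate_design(design_config(n_plots = 52, n_samples = 5000,
                                       seed = 5))
  soil <- generate_soil_chemistry(dsn, generator_params(), seed = 5)

  # noiseless limit: facets equal their linear predictors exactly
  fv <- c("total_biomass", "active_biomass", "bf_ratio", "bac_div",
          "fun_div", "cata_score", "fg_evenness", "sir_efficiency",
          "sir_range", "respiration")
  p0 <- generator_params(noise_sd = setNames(rep(0, 10), fv))
  lat0 <- generate_facets(dsn, soil, p0, seed = 5)
  rich_z <- scale(dsn$richness)[, 1]
  hum_z <- scale(soil$humidity)[, 1]
  expect_equal(lat0$total_biomass, 0.173 * rich_z - 0.234 * hum_z,
               tolerance = 1e-12)
  expect_equal(lat0$bac_div, 0.164 * rich_z, tolerance = 1e-12)

  # with noise: 2-SD-standardized regression recovers the tree ->
  # total-biomass coefficient 0.173 within 0.03 at n = 5000
  lat <- generate_facets(dsn, soil, generator_params(), seed = 5)
  fit <- fit_effect_model(lat$total_biomass,
                          data.frame(richness = dsn$richness))
  est <- fit$coefficients$estimate[fit$coefficients$term == "richness"]
  expect_lt(abs(est - 0.173), 0.03)

  # all-zero coefficients: facets independent of the design
  sc0 <- default_structural_coefficients()
  sc0$coefficient <- 0
  latn <- generate_facets(dsn, soil, generator_params(structural_coefficients = sc0),
                          seed = 5)
  fit0 <- fit_effect_model(latn$total_biomass,
                           data.frame(richness = dsn$richness))
  expect_lt(abs(fit0$coefficients$estimate[2]), 0.05)

  # cyclic structural graph rejected
  scc <- rbind(default_structural_coefficients(),
               data.frame(source = "respiration", target = "sir_efficiency",
                          coefficient = 0.1))
  expect_error(generator_params(structural_coefficients = scc), "cycle")
})

test_that("observation battery is deterministic and hits degenerate limits", {
  d1 <- small_dataset(n = 30, seed = 8)
  d2 <- small_dataset(n = 30, seed = 8)
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
  d3 <- small_dataset(n = 30, seed = 9)
  expect_false(identical(d1$asv_bacteria, d3$asv_bacteria))

  # validity of the battery
  expect_true(all(d1$asv_bacteria >= 0))
  expect_true(all(d1$plfa > 0))
  expect_true(all(d1$microresp > 0))
  expect_true(all(d1$respiration > 0))

  # single-taxon concentration limit: Shannon collapses to ~ 0
  pmono <- generator_params(n_taxa_bacteria = 10, n_taxa_fungi = 10,
                            depth_bacteria = 500, depth_fungi = 500,
                            shannon_base = c(bacteria = 0, fungi = 0),
                            shannon_slope = c(bacteria = 0, fungi = 0))
  dm <- simulate_dataset(design_config(n_plots = 5, n_samples = 10),
                         pmono, seed = 2)
  h <- apply(dm$asv_bacteria, 2, shannon_entropy)
  expect_lt(max(h), 0.01)
})

test_that("facet indices recomputed from observations track their latents", {
  d <- small_dataset(n = 400, seed = 12)
  f <- suppressWarnings(compute_facets(
    d, rarefy_depth_bac = 2000, rarefy_depth_fun = 1500, seed = 12))
  lat <- d$latents
  for (v in c("total_biomass", "active_biomass", "bf_ratio", "bac_div",
              "fun_div", "cata_score", "fg_evenness", "sir_efficiency",
              "sir_range", "respiration")) {
    rho <- cor(f[[v]], lat[[v]], method = "spearman", use = "complete.obs")
    expect_gt(rho, 0.8)
  }
})

test_that("datasets round-trip through the delimited-text writers", {
  d <- small_dataset(n = 25, seed = 4)
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_dataset(dir)
  expect_equal(back$design$sample, d$design$sample)
  expect_equal(unname(back$asv_bacteria), unname(d$asv_bacteria))
  expect_equal(back$respiration, d$respiration, tolerance = 1e-8)
  expect_identical(back$catabolic, d$catabolic)
})
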