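test_that("generation is byte-identical under a fixed seed and substreams
           are independent of unrelated config", {
  cfg <- generator_config(seed = 101)
  expect_identical(generate_compound_table(cfg), generate_compound_table(cfg))
  s1 <- generate_expression_and_compounds(cfg, n_units = 50)
  s2 <- generate_expression_and_compounds(cfg, n_units = 50)
  expect_identical(s1, s2)
  # changing the coupling must not perturb the compound-table stream
  cfg2 <- generator_config(seed = 101,
                           coupling = data.frame(gene = "GOT1",
                                                 compound = "Asp",
                                                 rho = 0.5))
  expect_identical(generate_compound_table(cfg), generate_compound_table(cfg2))
})

test_that("zero SD collapses replicates onto the configured mean", {
  cfg <- generator_config(
    compounds = data.frame(species = "A", compound = "GMP",
                           mean = 250, sd = 0),
    seed = 5)
  tab <- generate_compound_table(cfg)
  expect_equal(tab$concentration, rep(250, 10))
})

test_that("lognormal draws are moment-matched at large n", {
  cfg <- generator_config(
    compounds = data.frame(species = "A", compound = c("GMP", "AMP"),
                           mean = c(265.17, 152.49), sd = c(100.1, 66.28)),
    n_replicates = 1e5, seed = 103)
  tab <- generate_compound_table(cfg)
  for (cmp in c("GMP", "AMP")) {
    x <- tab$concentration[tab$compound == cmp]
    target <- cfg$compounds[cfg$compounds$compound == cmp, ]
    expect_lt(abs(mean(x) / target$mean - 1), 0.01)
    expect_lt(abs(sd(x) / target$sd - 1), 0.02)
    expect_true(all(x > 0))
  }
})

test_that("copula calibration recovers the target observed-scale Pearson r", {
  n <- 20000
  # bilognormal pairs have an asymmetric attainable range (negative r is
  # capped harder than positive); CV ~0.25 margins on both sides admit the
  # whole tested set, including -0.9
  means <- c(300, 380, 420, 250, 500, 350)
  compounds <- data.frame(species = sprintf("S%d", 1:6), compound = "Glu",
                          mean = means, sd = 0.1 * means)
  for (rho in c(-0.9, 0, 0.5, 0.9)) {
    cfg <- generator_config(compounds = compounds,
                            coupling = data.frame(gene = "GLUD1",
                                                  compound = "Glu",
                                                  rho = rho),
                            expression_cv = 0.25, seed = 104)
    sim <- generate_expression_and_compounds(cfg, n_units = n)
    r_hat <- cor(sim$latent$expression_fold, sim$latent$concentration)
    expect_lt(abs(r_hat - rho), 3 / sqrt(n))
  }
  # the shipped default coupling (0.90 on the Glu spread) is also recovered
  cfg_default <- generator_config(seed = 104)
  sim_d <- generate_expression_and_compounds(cfg_default, n_units = n)
  expect_lt(abs(cor(sim_d$latent$expression_fold,
                    sim_d$latent$concentration) - 0.9), 3 / sqrt(n))
})

test_that("perfectly coupled matched margins give r = 1 up to noise", {
  # equal log-scale SDs on both margins make rho = 1 attainable exactly
  cv <- 0.5
  means <- c(100, 180, 260, 150, 210, 320)
  cfg <- generator_config(
    compounds = data.frame(species = sprintf("S%d", 1:6), compound = "Glu",
                           mean = means, sd = 0.1 * means),
    coupling = data.frame(gene = "GLUD1", compound = "Glu", rho = 1),
    expression_cv = sd(means) / mean(means), seed = 105)
  # force the compound margin's log-SD to equal the expression margin's
  cfg$expression_cv <- sd(means) / mean(means)
  sim <- generate_expression_and_compounds(cfg, n_units = 500)
  r_hat <- cor(sim$latent$expression_fold, sim$latent$concentration)
  expect_gt(r_hat, 0.999)
})

test_that("unattainable couplings fail loudly at generation", {
  means <- c(100, 101, 102, 103, 99, 98)        # tiny between-species spread
  cfg <- generator_config(
    compounds = data.frame(species = sprintf("S%d", 1:6), compound = "Glu",
                           mean = means, sd = 0.1 * means),
    coupling = data.frame(gene = "GLUD1", compound = "Glu", rho = 0.95),
    expression_cv = 2, seed = 106)
  expect_error(generate_expression_and_compounds(cfg, n_units = 100),
               "not attainable")
  expect_error(generator_config(coupling = data.frame(
    gene = "GLUD1", compound = "Glu", rho = 1.2)), "\\[-1, 1\\]")
})

test_that("derived Ct records carry the latent folds through the ddCt chain", {
  cfg <- generator_config(seed = 107, ct_noise_sd = 0)
  sim <- generate_expression_and_compounds(cfg, n_units = 6)
  expr <- relative_expression(sim$ct, calibrator = "S1", quiet = TRUE)
  merged <- merge(expr, sim$latent, by.x = c("species", "gene"),
                  by.y = c("unit", "gene"))
  # without technical noise the fold ratios are exact
  ratio <- merged$fold / (merged$expression_fold /
                            merged$expression_fold[merged$species == "S1"])
  expect_equal(ratio, rep(1, 6), tolerance = 1e-12)
  expect_true(all(sim$ct$ct_target > 0 & sim$ct$ct_target < 45))
})

test_that("simulated standards behave like the calibration span they mimic", {
  # zero noise: exact recovery of the generating line
  std <- generate_hplc_standards(slope = 120, intercept = 4, noise_sd = 0,
                                 seed = 108)
  curve <- fit_calibration(std)
  expect_equal(curve$slope, 120)
  expect_equal(curve$intercept, 4)
  expect_equal(curve$range, c(0.1, 50))

  # small noise: curve passes the acceptance bound
  std2 <- generate_hplc_standards(slope = 120, intercept = 4, noise_sd = 10,
                                  seed = 109)
  expect_gt(fit_calibration(std2)$r_squared, 0.995)

  # heavy noise: flagged invalid by construction
  std3 <- generate_hplc_standards(slope = 10, intercept = 0, noise_sd = 200,
                                  seed = 110)
  expect_warning(curve3 <- fit_calibration(std3), "invalid")
  expect_false(curve3$valid)

  expect_error(generate_hplc_standards(noise_sd = -1), "noise_sd")
})
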