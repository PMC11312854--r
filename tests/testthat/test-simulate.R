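test_that("marker simulation is deterministic and kinship-ready", {
  cfg <- small_sim_config()
  X1 <- simulate_snps(cfg)
  X2 <- simulate_snps(cfg)
  expect_identical(X1, X2)
  expect_true(all(X1 %in% 0:2))
  # a realistic panel yields a usable (PSD after jitter) kinship matrix
  cfg2 <- simulation_config(n_genotypes = 67, n_markers = 2000, seed = 5)
  G <- vanraden_grm(simulate_snps(cfg2))
  expect_gte(min(eigen(G$values, only.values = TRUE)$values), 0)
})

test_that("simulated networks satisfy their structural contract", {
  cfg <- simulation_config(n_genotypes = 10, n_metabolites = 20,
                           n_reactions = 12, mets_per_reaction = 4,
                           reactions_per_metabolite = 2, seed = 3)
  net <- simulate_network(cfg)
  expect_length(validate_network(net), 0)
  nz <- net$coefficients != 0
  expect_true(all(rowSums(nz) >= 2))
  ach <- network_sparsity(net)
  expect_lte(abs(ach["mets_per_reaction"] - 4), 1)
  expect_lte(abs(ach["reactions_per_metabolite"] - 2), 1)
  # target reaction exists, is irreversible and only consumes
  tj <- net$target_reaction
  expect_false(net$reversible[tj])
  expect_true(all(net$coefficients[, tj] <= 0))
  # infeasible sparsity demand is rejected
  expect_error(
    simulate_network(simulation_config(n_metabolites = 50,
                                       n_reactions = 4,
                                       mets_per_reaction = 4,
                                       reactions_per_metabolite = 2,
                                       seed = 1)),
    "infeasible")
})

test_that("simulated fluxes balance exactly and respect irreversibility", {
  ds <- small_dataset()
  res <- balance_residuals(ds$network, ds$true_fluxes)
  expect_lt(max(abs(res)), 1e-8)
  irrev <- !ds$network$reversible
  expect_gte(min(ds$true_fluxes$values[, irrev]), 0)
})

test_that("zero residual variance makes fluxes equal their genetic values", {
  cfg <- small_sim_config(seed = 21)
  net <- simulate_network(cfg, seed = 4)
  G <- vanraden_grm(simulate_snps(cfg, seed = 5))
  J <- cfg$n_reactions
  par0 <- genetic_params(mu = rep(20, J), sigma2_U = rep(4, J),
                         sigma2_V = rep(0, J))
  sim <- simulate_fluxes(net, G, par0, seed = 6)
  expect_equal(sim$fluxes$values, sim$genetic, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("phenotype noise variance is the configured fraction", {
  # direct arithmetic case plus a Monte-Carlo calibration check
  V <- matrix(c(1, 3, 5, 7), 4, 1)   # var = 20/3
  ph <- simulate_phenotypes(flux_table(V), 1, noise_fraction = 0.25,
                            seed = 1)
  expect_length(ph$values, 4)

  set.seed(9)
  vJ <- rnorm(67, 20, 2)
  V2 <- flux_table(matrix(vJ, 67, 1))
  s2 <- stats::var(vJ)
  ratios <- replicate(10000, {
    y <- simulate_phenotypes(V2, 1, 0.25,
                             seed = sample.int(1e8, 1))$values
    y - vJ
  })
  expect_equal(stats::var(as.vector(ratios)) / s2, 0.25, tolerance = 0.02)
  # degenerate target flux is rejected
  expect_error(simulate_phenotypes(flux_table(matrix(2, 5, 1)), 1, 0.25),
               "variance")
  expect_error(simulate_phenotypes(flux_table(matrix(1:4, 4, 1)), 1, 1.5),
               "noise_fraction")
})

test_that("flux heritability matches the configured ratio at larger n", {
  cfg <- simulation_config(n_genotypes = 200, n_markers = 1000,
                           n_metabolites = 6, n_reactions = 6,
                           mets_per_reaction = 3,
                           reactions_per_metabolite = 3, seed = 31)
  net <- simulate_network(cfg, seed = 1)
  G <- vanraden_grm(simulate_snps(cfg, seed = 2))
  J <- cfg$n_reactions
  par0 <- genetic_params(mu = rep(30, J), sigma2_U = rep(8, J),
                         sigma2_V = rep(2, J))
  sim <- simulate_fluxes(net, G, par0, seed = 3)
  # empirical variance of V - U approximates sigma2_V
  resid_var <- apply(sim$fluxes$values - sim$genetic, 2, stats::var)
  expect_equal(mean(resid_var), 2, tolerance = 0.35)
  h2 <- apply(sim$genetic, 2, stats::var) /
    (apply(sim$genetic, 2, stats::var) + resid_var)
  expect_true(all(abs(h2 - 8 / 10) < 0.2))
})

test_that("dataset generation is deterministic and records sub-seeds", {
  cfg <- small_sim_config(seed = 77)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$true_fluxes$values, d2$true_fluxes$values)
  expect_identical(d1$phenotypes$values, d2$phenotypes$values)
  expect_identical(d1$meta$sub_seeds, d2$meta$sub_seeds)
  # bitwise-identical files on disk
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  save_dataset(d1, dir1); save_dataset(d2, dir2)
  for (f in list.files(dir1))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)

  reps <- generate_replicates(small_sim_config(seed = 5, n = 10), 10)
  expect_length(reps, 10)
  seeds <- vapply(reps, function(d) d$meta$seed, numeric(1))
  expect_length(unique(seeds), 10)
  for (d in reps) {
    expect_length(validate_network(d$network), 0)
    expect_lt(max(abs(balance_residuals(d$network, d$true_fluxes))), 1e-8)
  }
})
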