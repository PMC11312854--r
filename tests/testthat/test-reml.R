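test_that("REML optimum matches the 2-D grid-search oracle", {
  for (seed in 1:5) {
    inst <- make_reml_instance(seed)
    fit <- reml_single_kernel(inst$y, inst$G)
    oracle <- reml_grid_oracle(inst$y, inst$G)
    # the profile optimizer must do at least as well as any grid point
    expect_gte(fit$loglik, oracle$loglik - 1e-6)
    # and the two objective implementations agree where they meet
    expect_equal(fit$loglik,
                 reml_loglik_direct(inst$y, inst$G, fit$sigma2_u,
                                    fit$sigma2_e),
                 tolerance = 1e-8)
  }
})

test_that("constant responses collapse to the boundary gracefully", {
  G <- diag(10)
  fit <- reml_single_kernel(rep(3.5, 10), G)
  expect_equal(fit$mu, 3.5)
  expect_lt(fit$sigma2_u, 1e-6)
  expect_equal(fit$blup, rep(0, 10), tolerance = 1e-6)
})

test_that("identity kinship: likelihood value still matches the oracle", {
  set.seed(4)
  y <- rnorm(25, 2, 1.5)
  G <- diag(25)
  fit <- reml_single_kernel(y, G)
  oracle <- reml_grid_oracle(y, G)
  expect_gte(fit$loglik, oracle$loglik - 1e-6)
})

test_that("GBLUP predictions shift with the training mean and permute with rows", {
  inst <- make_reml_instance(10, n = 40)
  tr <- 1:30; te <- 31:40
  fit <- reml_single_kernel(inst$y[tr], inst$G[tr, tr])
  p0 <- gblup_predict(fit, inst$G, inst$y[tr], tr, te)
  # adding a constant to y shifts predictions by that constant
  fit2 <- reml_single_kernel(inst$y[tr] + 11, inst$G[tr, tr])
  p2 <- gblup_predict(fit2, inst$G, inst$y[tr] + 11, tr, te)
  expect_equal(unname(p2), unname(p0) + 11, tolerance = 1e-6)
  # permuting the test set permutes the output identically
  perm <- c(5, 1, 4, 2, 3, 10, 9, 6, 8, 7)
  p3 <- gblup_predict(fit, inst$G, inst$y[tr], tr, te[perm])
  expect_equal(unname(p3), unname(p0)[perm])
  # overlap between train and test is rejected
  expect_error(gblup_predict(fit, inst$G, inst$y[tr], tr, c(30, 31)),
               "overlap")
})

test_that("zero genetic variance yields constant predictions at the mean", {
  fit <- structure(list(mu = 4.2, sigma2_u = 0, sigma2_e = 1,
                        loglik = 0, blup = rep(0, 5), lambda = 0),
                   class = "reml_fit")
  G <- diag(8)
  p <- gblup_predict(fit, G, rnorm(5), 1:5, 6:8)
  expect_equal(unname(p), rep(4.2, 3))
})

test_that("a duplicated genotype is interpolated when noise vanishes", {
  # interpolation limit of the prediction formula: with a test row that
  # duplicates training genotype 3 and a vanishing residual variance,
  # the prediction must converge to that genotype's phenotype
  set.seed(2)
  n <- 12
  A <- matrix(rnorm(n * n), n)
  Ktt <- crossprod(A) / n + diag(0.1, n)
  K <- rbind(cbind(Ktt, Ktt[, 3]), c(Ktt[3, ], Ktt[3, 3]))
  y <- rnorm(n, 10, 2)
  fit <- structure(list(mu = mean(y), sigma2_u = 1, sigma2_e = 1e-10,
                        loglik = 0, blup = rep(0, n), lambda = 1e10),
                   class = "reml_fit")
  p <- gblup_predict(fit, K, y, 1:n, n + 1)
  expect_equal(unname(p), y[3], tolerance = 1e-4)
})

test_that("cross-validated GBLUP recovers strong signal", {
  # family-structured kinship so relatives carry real information
  # (an unrelated-panel GRM is near-identity and predicts nothing)
  set.seed(6)
  n <- 200
  K <- kronecker(diag(20), matrix(0.6, 10, 10)) + diag(0.4, n)
  u <- sqrt(0.8) * drop(t(chol(K)) %*% rnorm(n))
  y <- u + sqrt(0.2) * rnorm(n)
  lab <- sample(rep(1:3, length.out = n))
  rs <- sapply(1:3, function(f) {
    te <- which(lab == f); tr <- setdiff(1:n, te)
    fit <- reml_single_kernel(y[tr], K[tr, tr])
    cor(gblup_predict(fit, K, y[tr], tr, te), y[te])
  })
  expect_gt(mean(rs), 0.5)
})

test_that("per-reaction parameter estimates recover simulated truth", {
  cfg <- simulation_config(n_genotypes = 200, n_markers = 800,
                           n_metabolites = 6, n_reactions = 8,
                           mets_per_reaction = 3,
                           reactions_per_metabolite = 3, seed = 13)
  net <- simulate_network(cfg, seed = 1)
  G <- vanraden_grm(simulate_snps(cfg, seed = 2))
  set.seed(3)
  par0 <- sample_genetic_params(cfg$n_reactions)
  sim <- simulate_fluxes(net, G, par0, seed = 4)
  est <- estimate_reaction_params(sim$fluxes, G)
  expect_equal(nrow(est), 8)
  expect_identical(est$reaction_id, net$reaction_ids)
  rel_mu <- abs(est$mu - par0$mu) / abs(par0$mu)
  expect_lt(median(rel_mu), 0.1)
  # a constant reaction falls back without failing
  V <- sim$fluxes$values
  V[, 2] <- 7
  est2 <- estimate_reaction_params(V, G)
  expect_equal(est2$mu[2], 7, tolerance = 1e-6)
  expect_gt(est2$sigma2_U[2], 0)
})
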