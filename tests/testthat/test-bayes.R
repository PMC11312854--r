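test_that("log posterior matches a naive triple-loop implementation", {
  fx <- bayes_fixture()
  N <- 12; J <- 6
  irrev <- !fx$ds$network$reversible
  set.seed(33)
  for (rep in 1:10) {
    st <- random_state(N, J, fx$sc$alpha, irrev)
    lp1 <- log_posterior(st, fx$ds, fx$mask, fx$sc, fx$cfg)
    lp2 <- naive_log_posterior(st, fx$ds, fx$mask, fx$sc, fx$cfg)
    expect_equal(lp1, lp2, tolerance = 1e-10)
  }
  # with the simulation jitter attached to the constraint left-hand side
  psi <- matrix(rnorm(N * nrow(fx$ds$network$coefficients), 0, 0.01),
                N, nrow(fx$ds$network$coefficients))
  st <- random_state(N, J, fx$sc$alpha, irrev)
  expect_equal(log_posterior(st, fx$ds, fx$mask, fx$sc, fx$cfg, psi),
               naive_log_posterior(st, fx$ds, fx$mask, fx$sc, fx$cfg, psi),
               tolerance = 1e-10)
})

test_that("the likelihood weight scales the constraint term linearly", {
  fx <- bayes_fixture()
  irrev <- !fx$ds$network$reversible
  set.seed(41)
  st <- random_state(12, 6, fx$sc$alpha, irrev)
  lp_at <- function(w) {
    cfg <- fx$cfg; cfg$weight <- w
    log_posterior(st, fx$ds, fx$mask, fx$sc, cfg)
  }
  lp0 <- lp_at(0)            # constraint contributes exactly nothing
  con32 <- lp_at(0.32) - lp0 # 0.32 x constraint term
  con64 <- lp_at(0.64) - lp0
  expect_equal(con64, 2 * con32, tolerance = 1e-10)
  # doubling the weight adds exactly the lower-weight constraint term
  expect_equal(lp_at(0.64) - lp_at(0.32), con32, tolerance = 1e-10)
  # at full weight the posterior is the plain sum of both terms
  expect_equal(lp_at(1), lp0 + con32 / 0.32, tolerance = 1e-10)
})

test_that("states outside the truncated support have zero density", {
  fx <- bayes_fixture()
  irrev <- !fx$ds$network$reversible
  set.seed(5)
  st <- random_state(12, 6, fx$sc$alpha, irrev)
  j <- which(irrev)[1]
  st$V[3, j] <- fx$sc$alpha[j] - 0.5
  expect_identical(log_posterior(st, fx$ds, fx$mask, fx$sc, fx$cfg), -Inf)
  st$V[3, j] <- fx$sc$alpha[j] + 0.5
  st$sigma2_e <- -1
  expect_identical(log_posterior(st, fx$ds, fx$mask, fx$sc, fx$cfg), -Inf)
})

test_that("compiled evaluator agrees with the R reference density", {
  fx <- bayes_fixture()
  N <- 12; J <- 6
  irrev <- !fx$ds$network$reversible
  md <- fluxgp:::build_model_data(fx$ds, fx$mask, fx$sc, fx$cfg)
  set.seed(71)
  D <- 5 + 2 * J + 2 * N * J
  theta <- rnorm(D, 0, 0.3)
  out <- fluxgp:::flux_lp_grad(theta, md)
  st <- fluxgp:::theta_to_state(theta, N, J, fx$sc$alpha, irrev,
                                md$mU, md$Qg, md$lamg)
  lpR <- log_posterior(st, fx$ds, fx$mask, fx$sc, fx$cfg)
  # correct for the transform Jacobians the sampler works with
  oVp <- 5 + 2 * J + N * J
  jac <- sum(theta[2:5]) + sum(theta[6:(5 + 2 * J)])
  Vr <- matrix(theta[(oVp + 1):(oVp + N * J)], N, J)
  for (j in which(irrev)) jac <- jac + sum(Vr[, j])
  nc <- sum(0.5 * N * theta[(5 + J + 1):(5 + 2 * J)]) +
    J * 0.5 * sum(log(md$lamg))
  expect_equal(lpR, out$lp - jac - nc, tolerance = 1e-8)
  # and its gradient matches central differences
  idx <- sort(sample(D, 25))
  ng <- sapply(idx, function(i) {
    e <- 1e-5; tp <- theta; tm <- theta
    tp[i] <- tp[i] + e; tm[i] <- tm[i] - e
    (fluxgp:::flux_lp_grad(tp, md)$lp -
       fluxgp:::flux_lp_grad(tm, md)$lp) / (2 * e)
  })
  expect_lt(max(abs(ng - out$grad[idx]) / pmax(abs(ng), 1)), 1e-4)
})

tiny_fit <- function() {
  cached("tiny_fit", {
    ds <- generate_dataset(simulation_config(
      n_genotypes = 20, n_markers = 500, n_metabolites = 6,
      n_reactions = 8, mets_per_reaction = 3,
      reactions_per_metabolite = 3, seed = 11))
    tj <- ds$network$target_reaction
    ds$phenotypes$values[] <- ds$true_fluxes$values[, tj]  # noiseless
    mask <- rep(TRUE, 20); mask[c(3, 7, 12, 18)] <- FALSE
    tr <- which(mask)
    sc <- scaling_from_training(ds$true_fluxes$values[tr, ],
                                ds$kinship$values[tr, tr])
    cfg <- model_config(weight = 0.64, iterations = 1000, warmup = 500,
                        simulation_jitter = TRUE, seed = 5)
    fit <- fit_model(ds, mask, sc, cfg,
                     init_fluxes = flux_table(ds$true_fluxes$values[tr, ],
                                              ds$kinship$genotype_ids[tr]))
    list(ds = ds, mask = mask, fit = fit)
  })
}

test_that("a small noiseless fit recovers the training phenotypes", {
  tf <- tiny_fit()
  tr <- which(tf$mask)
  pp <- predict_phenotypes(tf$fit)
  expect_gt(cor(pp$mean[tr], tf$ds$phenotypes$values[tr]), 0.9)
  # held-out genotypes still receive finite predictions
  expect_true(all(is.finite(pp$mean[!tf$mask])))
  expect_true(all(pp$lower <= pp$mean & pp$mean <= pp$upper))
})

test_that("every retained draw respects the truncation", {
  tf <- tiny_fit()
  fit <- tf$fit
  for (j in which(fit$irrev))
    expect_gt(min(fit$V[, , j]), fit$alpha[j])
})

test_that("sampling is deterministic given the seed", {
  ds <- generate_dataset(simulation_config(
    n_genotypes = 10, n_markers = 300, n_metabolites = 4,
    n_reactions = 5, mets_per_reaction = 3,
    reactions_per_metabolite = 3, seed = 23))
  mask <- rep(TRUE, 10); mask[c(2, 8)] <- FALSE
  tr <- which(mask)
  sc <- scaling_from_training(ds$true_fluxes$values[tr, ],
                              ds$kinship$values[tr, tr])
  cfg <- model_config(weight = 0.48, iterations = 400, warmup = 200,
                      simulation_jitter = TRUE, seed = 99)
  f1 <- fit_model(ds, mask, sc, cfg)
  f2 <- fit_model(ds, mask, sc, cfg)
  expect_identical(f1$scalars, f2$scalars)
  expect_identical(f1$V, f2$V)
  expect_identical(f1$U, f2$U)
})

test_that("posterior prediction handles degenerate draws exactly", {
  fake <- structure(list(
    scalars = cbind(a = rep(2, 10), b = rep(3, 10),
                    sigma2_e = rep(1, 10), sigma2_eps = rep(1, 10),
                    S_eps = rep(1, 10)),
    V = array(5, c(10, 2, 3)), U = array(5, c(10, 2, 3)),
    sigma2_V = matrix(1, 10, 3), sigma2_U = matrix(1, 10, 3),
    genotype_ids = c("g1", "g2"), target_reaction = 3L,
    alpha = rep(0, 3), irrev = rep(FALSE, 3),
    scaling = NULL), class = "flux_posterior")
  p <- predict_phenotypes(fake)
  expect_equal(p$mean, rep(2 + 3 * 5, 2))
  expect_equal(p$upper - p$lower, c(0, 0))
  # zero slope: predictions equal the posterior mean intercept
  fake$scalars[, "b"] <- 0
  fake$scalars[, "a"] <- rnorm(10)
  p2 <- predict_phenotypes(fake)
  expect_equal(p2$mean, rep(mean(fake$scalars[, "a"]), 2))
  expect_error(predict_phenotypes(fake, 5), "unknown")
})

test_that("split-chain diagnostics flag separation and pass iid draws", {
  set.seed(12)
  make_fake <- function(x) {
    n <- length(x)
    structure(list(
      scalars = cbind(a = x, b = abs(x) + 1, sigma2_e = abs(x) + 1,
                      sigma2_eps = abs(x) + 1, S_eps = abs(x) + 1),
      V = array(rnorm(n * 2 * 2), c(n, 2, 2)),
      U = array(rnorm(n * 2 * 2), c(n, 2, 2)),
      sigma2_V = matrix(abs(rnorm(n * 2)) + 1, n, 2),
      sigma2_U = matrix(abs(rnorm(n * 2)) + 1, n, 2),
      genotype_ids = c("g1", "g2"), target_reaction = 2L,
      alpha = rep(0, 2), irrev = rep(FALSE, 2), scaling = NULL),
      class = "flux_posterior")
  }
  iid <- make_fake(rnorm(2000))
  rep1 <- convergence_report(iid)
  expect_lt(rep1$rhat[rep1$parameter == "a"], 1.02)
  # two regimes with disjoint means: flagged
  drift <- make_fake(c(rnorm(1000, 0), rnorm(1000, 50)))
  rep2 <- convergence_report(drift)
  expect_gt(rep2$rhat[rep2$parameter == "a"], 1.5)
  expect_true(rep2$flagged[rep2$parameter == "a"])
  # too few draws rejected
  expect_error(convergence_report(make_fake(rnorm(3))), "draws")
})
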