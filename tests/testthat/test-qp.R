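test_that("projection reproduces the hand-derived toy minimizer", {
  # one metabolite, two reactions: balance forces v1 = v2 = v;
  # minimizing (v/2-1)^2 + (v/4-1)^2 gives v = 12/5
  M <- matrix(c(1, -1), 1, 2)
  v <- project_to_balance(c(2, 4), M, irrev = c(TRUE, TRUE))
  expect_equal(v, c(2.4, 2.4), tolerance = 1e-6)
  # an already balanced, sign-feasible input is returned unchanged
  v2 <- project_to_balance(c(3, 3), M, irrev = c(TRUE, TRUE))
  expect_equal(v2, c(3, 3), tolerance = 1e-8)
  # idempotence
  v3 <- project_to_balance(v, M, irrev = c(TRUE, TRUE))
  expect_equal(v3, v, tolerance = 1e-8)
})

test_that("projection matches dense grid oracles on small networks", {
  set.seed(17)
  for (rep in 1:10) {
    J <- sample(4:6, 1)
    K <- J - sample(1:2, 1)
    # build a full-rank stoichiometry with a nonempty feasible cone
    repeat {
      M <- matrix(rnorm(K * J), K, J)
      ns <- MASS::Null(t(M))
      if (qr(M)$rank == K && ncol(ns) >= 1 &&
          any(abs(ns) > 1e-3)) break
    }
    irrev <- rep(FALSE, J)
    u <- runif(J, 0.5, 3) * sample(c(-1, 1), J, replace = TRUE)
    v <- project_to_balance(u, M, irrev)
    oracle <- qp_grid_oracle(u, M, irrev, lim = 4, n_grid = 41)
    expect_lte(sum((v / u - 1)^2), oracle$objective + 1e-4)
    expect_lt(max(abs(M %*% v)), 1e-6)
    # idempotence on the solution
    expect_equal(project_to_balance(v, M, irrev), v, tolerance = 1e-6)
  }
})

test_that("ratio-pair constraints bind at the configured boundary", {
  # reactions: 1 oxygenation, 2 carboxylation, 3 sucrose, 4 starch;
  # two metabolite balances couple all four
  M <- rbind(c(1, -0.2, 1, -1), c(0.5, 1, -1, -0.5))
  st <- qp_settings(use_additional_constraints = TRUE,
                    constraint_reactions = c(1, 2, 3, 4))
  # predicted fluxes demanding a carboxylation/oxygenation ratio far
  # above the upper band limit
  u <- c(0.5, 15, 2, 2.4)
  irrev <- rep(TRUE, 4)
  v_free <- project_to_balance(u, M, irrev)
  expect_gt(v_free[2] / v_free[1], 3.81)   # the band really is binding
  v <- project_to_balance(u, M, irrev, st)
  Ain <- fluxgp:::additional_constraint_rows(st, 4)
  expect_true(all(Ain %*% v <= 1e-6))
  expect_equal(v[2] / v[1], 3.81, tolerance = 1e-4)
  oracle <- qp_grid_oracle(u, M, irrev, lim = 4, n_grid = 41,
                           Ain = Ain, bin = rep(0, 4))
  expect_lte(sum((v / u - 1)^2), oracle$objective + 1e-4)
})

test_that("training-flux estimation anchors at the reference genotype", {
  ds <- small_dataset()
  tr <- which(rep(TRUE, 20))[1:14]
  Vt <- estimate_training_fluxes(ds, tr)
  expect_equal(dim(Vt$values), c(14, 8))
  tj <- ds$network$target_reaction
  y <- ds$phenotypes$values
  ref <- ds$reference_genotype
  vref <- ds$true_fluxes$values[ref, ]
  for (t in seq_along(tr)) {
    if (any(is.na(Vt$values[t, ]))) next
    i <- tr[t]
    # biomass-ratio condition holds as a hard equality
    expect_equal(unname(Vt$values[t, tj]),
                 unname(vref[tj] * y[i] / y[ref]), tolerance = 1e-6)
    # per-genotype steady state
    Mi <- effective_stoichiometry(ds$network, i)
    expect_lt(max(abs(Mi %*% Vt$values[t, ])), 1e-6)
    # irreversible fluxes nonnegative
    expect_gte(min(Vt$values[t, !ds$network$reversible]), -1e-8)
  }
  # the reference genotype itself reproduces its own fluxes
  t_ref <- match(ref, tr)
  if (!is.na(t_ref) && !any(is.na(Vt$values[t_ref, ])))
    expect_equal(unname(sum((Vt$values[t_ref, ] / vref - 1)^2)), 0,
                 tolerance = 1e-6)
})

test_that("per-reaction flux prediction has the right shape and limits", {
  ds <- small_dataset()
  tr <- 1:14; te <- 15:20
  Vt <- estimate_training_fluxes(ds, tr)
  U <- predict_flux_genetics(Vt, ds$kinship, tr, te)
  expect_equal(dim(U), c(6, 8))
  expect_true(all(is.finite(U)))
  # with an identity kinship there is no information to differentiate
  # test genotypes: predictions collapse toward per-reaction means
  ok <- complete.cases(Vt$values)
  I_kin <- diag(20)
  U0 <- predict_flux_genetics(Vt, I_kin, tr, te)
  cm <- colMeans(Vt$values[ok, , drop = FALSE])
  for (j in 1:8)
    expect_lt(max(abs(U0[, j] - cm[j])) /
                max(stats::sd(Vt$values[ok, j]), 1e-8), 0.6)
})

test_that("pipeline predictions are balanced and leak no test phenotypes", {
  ds <- small_dataset()
  folds <- make_cv_folds(20, 3, 1, seed = 4)
  out <- qp_predict_pipeline(ds, folds)
  expect_named(out, c("genotype_id", "fold", "prediction"))
  fl <- attr(out, "flux_tables")
  lab <- fluxgp:::fold_labels(folds, 20)
  for (f in names(fl)) {
    te <- which(lab == as.integer(f))
    V <- fl[[f]]$values
    for (t in seq_along(te)) {
      if (any(is.na(V[t, ]))) next
      Mi <- effective_stoichiometry(ds$network, te[t])
      expect_lt(max(abs(Mi %*% V[t, ])), 1e-6)
    }
  }
  # taint test: perturbing held-out phenotypes leaves predictions
  # bitwise unchanged (the reference genotype stays untouched)
  ds2 <- ds
  lab1 <- which(lab == 1)
  lab1 <- setdiff(lab1, ds$reference_genotype)
  ds2$phenotypes$values[lab1] <- ds2$phenotypes$values[lab1] + 100
  out2 <- qp_predict_pipeline(ds2, folds)
  expect_identical(out$prediction[lab1], out2$prediction[lab1])
})
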