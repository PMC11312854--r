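test_that("well-formed networks validate cleanly and defects are named", {
  net <- tiny_network()
  expect_length(validate_network(net), 0)

  # a metabolite that participates in no reaction
  M <- net$coefficients
  M[2, ] <- 0
  bad <- reaction_network(M, reversible = net$reversible,
                          target_reaction = 3)
  rep <- validate_network(bad)
  expect_length(rep, 1)
  expect_match(rep, "B")

  # undetermined reversibility flag
  bad2 <- net
  bad2$reversible[3] <- NA
  rep2 <- validate_network(bad2)
  expect_true(any(grepl("r3", rep2)))

  # out-of-range target
  bad3 <- net
  bad3$target_reaction <- 9L
  expect_true(any(grepl("target", validate_network(bad3))))
})

test_that("balance residuals compute per-genotype net production", {
  M <- matrix(c(1, -1), 1, 2)
  net <- reaction_network(M, reversible = c(FALSE, FALSE),
                          target_reaction = 2)
  expect_equal(unname(balance_residuals(net, matrix(c(3, 3), 1, 2))[1, 1]), 0)
  expect_equal(unname(balance_residuals(net, matrix(c(3, 1), 1, 2))[1, 1]), 2)
  expect_error(balance_residuals(net, matrix(1, 1, 3)), "reaction")
})

test_that("balance residuals are linear in the fluxes", {
  set.seed(42)
  for (rep in 1:5) {
    K <- sample(3:5, 1); J <- K + sample(2:3, 1); N <- 4
    M <- matrix(rnorm(K * J), K, J)
    net <- reaction_network(M, reversible = rep(TRUE, J))
    V1 <- matrix(rnorm(N * J), N, J)
    V2 <- matrix(rnorm(N * J), N, J)
    a <- rnorm(1); b <- rnorm(1)
    expect_equal(balance_residuals(net, a * V1 + b * V2),
                 a * balance_residuals(net, V1) +
                   b * balance_residuals(net, V2),
                 tolerance = 1e-12)
  }
})

test_that("genotype overrides change only their own genotype's matrix", {
  net <- tiny_network()
  net$overrides <- data.frame(genotype = 2L, metabolite = 1L,
                              reaction = 3L, coefficient = 7)
  expect_equal(effective_stoichiometry(net, 1), net$coefficients)
  M2 <- effective_stoichiometry(net, 2)
  expect_equal(M2[1, 3], 7)
  M2[1, 3] <- net$coefficients[1, 3]
  expect_equal(M2, net$coefficients)
})

test_that("VanRaden kinship matches the hand-computed example", {
  X <- rbind(g1 = c(0, 2), g2 = c(2, 0), g3 = c(1, 1))
  G <- vanraden_grm(X)
  expect_equal(unname(G$values),
               rbind(c(2, -2, 0), c(-2, 2, 0), c(0, 0, 0)),
               tolerance = 1e-12)
  # duplicated genotypes give identical rows/columns
  X2 <- rbind(X, g4 = c(0, 2))
  G2 <- vanraden_grm(X2)$values
  expect_equal(unname(G2[1, ]), unname(G2[4, ]))
  expect_equal(unname(G2[, 1]), unname(G2[, 4]))
  # single genotype (needs a heterozygous marker to be polymorphic):
  # nonnegative 1x1 Gram matrix
  g1 <- vanraden_grm(matrix(c(0, 1, 2, 1), 1, 4))$values
  expect_equal(dim(g1), c(1L, 1L))
  expect_gte(g1[1, 1], 0)
  # monomorphic-only input is rejected
  expect_error(vanraden_grm(matrix(2, 4, 3)), "monomorphic")
})

test_that("VanRaden diagonal is near one under HWE simulation", {
  set.seed(7)
  P <- 2000; N <- 50
  p <- runif(P, 0.1, 0.5)
  X <- matrix(rbinom(N * P, 2, rep(p, each = N)), N, P)
  G <- vanraden_grm(X)
  expect_gt(mean(diag(G$values)), 0.8)
  expect_lt(mean(diag(G$values)), 1.2)
})

test_that("kinship constructor repairs tiny indefiniteness and rejects more", {
  G <- diag(3)
  expect_s3_class(kinship(G), "flux_kinship")
  # slightly indefinite: repaired by jitter
  ev <- eigen(G)$vectors
  G2 <- ev %*% diag(c(1, 1, -5e-9)) %*% t(ev)
  G2 <- (G2 + t(G2)) / 2
  k2 <- kinship(G2)
  expect_gte(min(eigen(k2$values)$values), 0)
  # clearly indefinite: rejected
  G3 <- ev %*% diag(c(1, 1, -1e-3)) %*% t(ev)
  expect_error(kinship((G3 + t(G3)) / 2), "indefinite")
  expect_error(kinship(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
})
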