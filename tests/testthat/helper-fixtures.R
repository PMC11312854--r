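# Shared fixtures: tiny deterministic instances built in code.

tiny_network <- function() {
  # 2 metabolites, 3 reactions; last reaction is the target
  M <- rbind(c(1, -1, -0.5),
             c(0.5, 1, -1))
  rownames(M) <- c("A", "B")
  colnames(M) <- c("r1", "r2", "r3")
  reaction_network(M, reversible = c(TRUE, FALSE, FALSE),
                   target_reaction = 3)
}

small_sim_config <- function(seed = 11, n = 20) {
  simulation_config(n_genotypes = n, n_markers = 500, n_metabolites = 6,
                    n_reactions = 8, mets_per_reaction = 3,
                    reactions_per_metabolite = 3, seed = seed)
}

# cache expensive objects across tests within a session
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

small_dataset <- function() {
  cached("small_dataset", generate_dataset(small_sim_config()))
}

make_reml_instance <- function(seed, n = 30, h2 = 0.5) {
  set.seed(seed)
  X <- matrix(rbinom(n * 400, 2, rep(runif(400, 0.1, 0.5), each = n)),
              n, 400)
  G <- vanraden_grm(X)$values
  L <- t(chol(G + diag(1e-6, n)))
  u <- sqrt(h2) * drop(L %*% rnorm(n))
  y <- 5 + u + sqrt(1 - h2) * rnorm(n)
  list(y = y, G = G)
}

bayes_fixture <- function() {
  cached("bayes_fixture", {
    ds <- generate_dataset(simulation_config(
      n_genotypes = 12, n_markers = 400, n_metabolites = 5,
      n_reactions = 6, mets_per_reaction = 3,
      reactions_per_metabolite = 3, seed = 19))
    # a sample-centered relationship matrix is singular by construction
    # (G %*% 1 = 0); ridge it so the dense-solve oracle is exact
    ds$kinship <- kinship(ds$kinship$values + diag(1e-3, 12),
                          ds$kinship$genotype_ids)
    mask <- rep(TRUE, 12); mask[c(4, 9)] <- FALSE
    tr <- which(mask)
    sc <- scaling_from_training(ds$true_fluxes$values[tr, ],
                                ds$kinship$values[tr, tr])
    list(ds = ds, mask = mask, sc = sc,
         cfg = model_config(weight = 0.64, iterations = 200,
                            warmup = 100, seed = 2))
  })
}
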