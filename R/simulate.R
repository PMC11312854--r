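# Synthetic data generator. Emulates the statistical structure of the
# real benchmark data: a sparse signed stoichiometry matrix, SNP-derived
# kinship, kinship-correlated per-reaction fluxes with nonnegativity for
# irreversible reactions, exact per-genotype flux balance obtained by
# adjusting the last nonzero coefficient of each metabolite row, and a
# phenotype equal to the target-reaction flux plus noise whose variance is
# a fixed fraction (default 25%) of the flux variance.

#' Simulation configuration
#'
#' @param n_genotypes number of genotypes N (default 67, the size of the
#'   motivating Arabidopsis panel).
#' @param n_markers number of SNP markers P for the dosage matrix.
#' @param n_metabolites number of metabolites K.
#' @param n_reactions number of reactions J (the last one is the
#'   biomass-producing target).
#' @param mets_per_reaction target median number of metabolites per
#'   reaction.
#' @param reactions_per_metabolite target median number of reactions per
#'   metabolite.
#' @param frac_irreversible fraction of reactions restricted to
#'   nonnegative flux (the target reaction is always irreversible).
#' @param noise_fraction phenotype noise variance as a fraction of the
#'   target-flux variance (default 0.25).
#' @param maf ancestral minor-allele-frequency bounds for simulated
#'   markers.
#' @param n_families number of subpopulations/families in the marker
#'   simulation; relatedness within them is what makes the kinship
#'   matrix informative.
#' @param fst Balding-Nichols differentiation of family allele
#'   frequencies from the ancestral ones (0 gives an unrelated panel).
#' @param params optional [genetic_params()] (one row per reaction); when
#'   \code{NULL} they are drawn with [sample_genetic_params()].
#' @param seed integer seed; all randomness derives from it.
#' @return object of class \code{sim_config}.
#' @export
simulation_config <- function(n_genotypes = 67, n_markers = 2000,
                              n_metabolites = 20, n_reactions = 12,
                              mets_per_reaction = 4,
                              reactions_per_metabolite = 2,
                              frac_irreversible = 0.5,
                              noise_fraction = 0.25,
                              maf = c(0.05, 0.5),
                              n_families = 10, fst = 0.25,
                              params = NULL, seed = 1L) {
  stopifnot(n_genotypes >= 2, n_markers >= 2, n_metabolites >= 2,
            n_reactions >= 2)
  if (noise_fraction <= 0 || noise_fraction >= 1)
    stop("noise_fraction must be in (0, 1)", call. = FALSE)
  if (maf[1] <= 0 || maf[2] > 0.5 || maf[1] > maf[2])
    stop("maf bounds must satisfy 0 < lower <= upper <= 0.5", call. = FALSE)
  if (fst < 0 || fst >= 1)
    stop("fst must be in [0, 1)", call. = FALSE)
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_markers = as.integer(n_markers),
                 n_metabolites = as.integer(n_metabolites),
                 n_reactions = as.integer(n_reactions),
                 mets_per_reaction = mets_per_reaction,
                 reactions_per_metabolite = reactions_per_metabolite,
                 frac_irreversible = frac_irreversible,
                 noise_fraction = noise_fraction,
                 maf = maf, n_families = as.integer(n_families),
                 fst = fst, params = params, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a structured SNP dosage matrix
#'
#' Markers follow a Balding-Nichols model: each marker gets an ancestral
#' frequency uniform within the configured bounds, each family draws its
#' own frequency from the corresponding Beta distribution (differentiation
#' \code{fst}), and dosages are Binomial(2, p_family). The family
#' structure gives the derived kinship matrix real off-diagonal signal,
#' as in an accession panel; \code{fst = 0} yields an unrelated panel.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to the config seed).
#' @return N x P integer dosage matrix with genotype row names.
#' @export
simulate_snps <- function(config, seed = config$seed) {
  set.seed(seed)
  N <- config$n_genotypes; P <- config$n_markers
  p0 <- stats::runif(P, config$maf[1], config$maf[2])
  fam <- sort(rep_len(seq_len(max(1L, config$n_families)), N))
  fst <- config$fst
  X <- matrix(0L, N, P)
  for (f in unique(fam)) {
    rows <- which(fam == f)
    pf <- if (fst > 0)
      stats::rbeta(P, p0 * (1 - fst) / fst, (1 - p0) * (1 - fst) / fst)
    else p0
    X[rows, ] <- matrix(stats::rbinom(length(rows) * P, 2L,
                                      rep(pf, each = length(rows))),
                        length(rows), P)
  }
  rownames(X) <- sprintf("g%03d", seq_len(N))
  colnames(X) <- sprintf("m%05d", seq_len(P))
  X
}

#' Simulate a sparse signed reaction network
#'
#' Builds a K x J stoichiometry matrix whose per-reaction and per-metabolite
#' nonzero counts have medians close to the configured targets, with every
#' metabolite appearing in at least two reactions (so that the balancing
#' coefficient adjustment is always possible) and at least one producer and
#' one consumer per metabolite. The last reaction is the target: it only
#' consumes metabolites.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to the config seed).
#' @return a [reaction_network()].
#' @export
simulate_network <- function(config, seed = config$seed) {
  set.seed(seed)
  K <- config$n_metabolites; J <- config$n_reactions
  mpr <- config$mets_per_reaction
  for (attempt in 1:50) {
    net <- try(build_network_once(K, J, mpr, config$frac_irreversible),
               silent = TRUE)
    if (inherits(net, "try-error")) {
      if (grepl("infeasible", attr(net, "condition")$message))
        stop(attr(net, "condition")$message, call. = FALSE)
      next
    }
    ach <- network_sparsity(net)
    if (abs(ach["mets_per_reaction"] - mpr) <= 1 &&
        abs(ach["reactions_per_metabolite"] -
            config$reactions_per_metabolite) <= 1)
      return(net)
  }
  stop("could not reach sparsity targets (mets/reaction ", mpr,
       ", reactions/metabolite ", config$reactions_per_metabolite,
       ") for K=", K, ", J=", J, "; targets look infeasible", call. = FALSE)
}

#' Achieved sparsity of a network
#'
#' @param network a [reaction_network()].
#' @return named vector with achieved median metabolites-per-reaction and
#'   reactions-per-metabolite of the base matrix.
#' @export
network_sparsity <- function(network) {
  nz <- network$coefficients != 0
  c(mets_per_reaction = stats::median(colSums(nz)),
    reactions_per_metabolite = stats::median(rowSums(nz)))
}

build_network_once <- function(K, J, mpr, frac_irreversible) {
  # per-reaction metabolite counts, median mpr
  m <- sample(c(mpr - 1, mpr, mpr + 1), J, replace = TRUE,
              prob = c(.25, .5, .25))
  m <- pmin(pmax(m, 2L), K)
  nnz <- sum(m)
  if (nnz < 2 * K)
    stop("infeasible sparsity targets: ", nnz, " nonzeros cannot give every ",
         "metabolite two reactions (need >= ", 2 * K, ")", call. = FALSE)
  # per-metabolite quotas: everyone 2, surplus concentrated on a few hubs
  quota <- rep(2L, K)
  extra <- nnz - 2L * K
  if (extra > 0) {
    hubs <- sample.int(K, max(1L, ceiling(0.3 * K)))
    add <- stats::rmultinom(1, extra, rep(1, length(hubs)))[, 1]
    quota[hubs] <- quota[hubs] + add
    quota <- pmin(quota, J)
  }
  inc <- matrix(FALSE, K, J)
  remaining <- quota
  for (j in sample.int(J)) {
    avail <- which(remaining > 0)
    if (length(avail) < m[j]) avail <- seq_len(K)
    pick <- if (length(avail) == 1) avail else
      sample(avail, m[j], prob = remaining[avail] + 0.1)
    inc[pick, j] <- TRUE
    remaining[pick] <- pmax(remaining[pick] - 1L, 0L)
  }
  # repair metabolites with fewer than two reactions
  for (k in which(rowSums(inc) < 2)) {
    need <- 2 - sum(inc[k, ])
    slots <- which(!inc[k, ])
    inc[k, sample(slots, need)] <- TRUE
  }
  M <- matrix(0.0, K, J)
  M[inc] <- stats::runif(sum(inc), 0.5, 2) * sample(c(-1, 1), sum(inc),
                                                    replace = TRUE)
  M[, J] <- -abs(M[, J])  # target reaction consumes its precursors
  # every metabolite needs a producer and a consumer
  for (k in seq_len(K)) {
    jnz <- which(M[k, ] != 0)
    cand <- setdiff(jnz, J)
    if (all(M[k, jnz] < 0)) M[k, cand[1]] <- abs(M[k, cand[1]])
    if (all(M[k, jnz] > 0)) M[k, jnz[1]] <- -abs(M[k, jnz[1]])
  }
  n_irr <- max(1L, round(frac_irreversible * J))
  irr <- c(J, sample(seq_len(J - 1), n_irr - 1L))
  rev_flag <- !(seq_len(J) %in% irr)
  reaction_network(M, reversible = rev_flag, target_reaction = J)
}

#' Simulate kinship-correlated fluxes with exact balance
#'
#' Draws the genetic flux component U_{,j} from N(1 mu_j, G sigma2_U_j) and
#' the realized fluxes V_{,j} from N(U_{,j}, I sigma2_V_j). For
#' irreversible reactions, U is redrawn as a whole vector and V per
#' genotype until nonnegative. Finally, for every genotype and metabolite
#' the coefficient of the last nonzero reaction of that metabolite row is
#' overridden so the steady-state balance holds exactly:
#' coefficient = (0 - sum over the other reactions of M V) / V_last.
#'
#' @param network a [reaction_network()] (base coefficients are used).
#' @param kin a [kinship()] object.
#' @param params a [genetic_params()] with one row per reaction.
#' @param seed integer seed.
#' @param max_retries retry budget for all-positive redraws and for
#'   genotypes whose balancing denominator is degenerate (|V_last| < 1e-6).
#' @return list with \code{fluxes} (a [flux_table()] of V), \code{genetic}
#'   (matrix of U), and \code{network} (the input network with per-genotype
#'   overrides attached).
#' @export
simulate_fluxes <- function(network, kin, params, seed = 1L,
                            max_retries = 100L) {
  set.seed(seed)
  M <- network$coefficients
  K <- nrow(M); J <- ncol(M); N <- nrow(kin$values)
  stopifnot(nrow(params) == J)
  L <- t(chol(kin$values + diag(1e-8, N)))
  irr <- !network$reversible

  U <- matrix(0.0, N, J)
  for (j in seq_len(J)) {
    sdU <- sqrt(params$sigma2_U[j])
    for (r in seq_len(max_retries)) {
      U[, j] <- params$mu[j] + sdU * as.vector(L %*% stats::rnorm(N))
      if (!irr[j] || all(U[, j] > 0)) break
      if (r == max_retries)
        stop("could not draw an all-positive genetic flux vector for ",
             "irreversible reaction ", network$reaction_ids[j],
             " within ", max_retries, " retries", call. = FALSE)
    }
  }

  draw_V_row <- function(i) {
    v <- stats::rnorm(J, U[i, ], sqrt(params$sigma2_V))
    for (r in seq_len(max_retries)) {
      bad <- irr & v < 0
      if (!any(bad)) return(v)
      v[bad] <- stats::rnorm(sum(bad), U[i, bad],
                             sqrt(params$sigma2_V[bad]))
    }
    stop("could not draw nonnegative fluxes for genotype ", i, call. = FALSE)
  }
  V <- t(vapply(seq_len(N), draw_V_row, numeric(J)))

  # balancing overrides: last nonzero reaction of each metabolite row
  last_j <- unname(apply(M != 0, 1, function(z) max(which(z))))
  ov <- vector("list", K)
  for (i in seq_len(N)) {
    r <- 0L
    while (any(abs(V[i, last_j]) < 1e-6)) {
      r <- r + 1L
      if (r > max_retries)
        stop("degenerate balancing denominator persisted for genotype ", i,
             " after ", max_retries, " redraws", call. = FALSE)
      V[i, ] <- draw_V_row(i)
    }
  }
  rows <- list()
  for (k in seq_len(K)) {
    jl <- last_j[k]
    others <- setdiff(which(M[k, ] != 0), jl)
    coef <- (0 - as.vector(V[, others, drop = FALSE] %*% M[k, others])) /
      V[, jl]
    rows[[k]] <- data.frame(genotype = seq_len(N), metabolite = k,
                            reaction = jl, coefficient = unname(coef))
  }
  net2 <- network
  net2$overrides <- do.call(rbind, rows)
  colnames(V) <- network$reaction_ids
  colnames(U) <- network$reaction_ids
  list(fluxes = flux_table(V, kin$genotype_ids), genetic = U,
       network = net2)
}

#' Simulate phenotypes from the target-reaction flux
#'
#' Y_i = V_{i,J} + e_i with e ~ N(0, noise_fraction * var(V_{,J})).
#'
#' @param fluxes a [flux_table()].
#' @param target_index column index of the target reaction.
#' @param noise_fraction noise variance as a fraction of the target flux
#'   variance (default 0.25).
#' @param seed integer seed.
#' @return a [phenotype_vector()] (all observed).
#' @export
simulate_phenotypes <- function(fluxes, target_index,
                                noise_fraction = 0.25, seed = 1L) {
  if (noise_fraction <= 0 || noise_fraction >= 1)
    stop("noise_fraction must be in (0, 1)", call. = FALSE)
  set.seed(seed)
  vJ <- fluxes$values[, target_index]
  s2 <- stats::var(vJ)
  if (s2 <= 0)
    stop("target-reaction flux has zero variance; cannot scale noise",
         call. = FALSE)
  y <- vJ + stats::rnorm(length(vJ), 0, sqrt(noise_fraction * s2))
  phenotype_vector(y, genotype_ids = fluxes$genotype_ids)
}

#' Generate a complete simulated dataset
#'
#' Orchestrates marker, network, flux and phenotype simulation; all
#' sub-seeds derive from \code{config$seed} and are recorded in the dataset
#' metadata. The first genotype acts as the reference (its true fluxes and
#' phenotype are treated as known side information by the predict-then-
#' project pipeline).
#'
#' @param config a [simulation_config()].
#' @return a [flux_dataset()] with true fluxes stored.
#' @export
generate_dataset <- function(config) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 5L)
  X <- simulate_snps(config, seed = seeds[1])
  G <- vanraden_grm(X)
  net <- simulate_network(config, seed = seeds[2])
  params <- config$params
  if (is.null(params)) {
    set.seed(seeds[3])
    params <- sample_genetic_params(config$n_reactions,
                                    reaction_ids = net$reaction_ids)
  }
  sim <- simulate_fluxes(net, G, params, seed = seeds[4])
  ph <- simulate_phenotypes(sim$fluxes, net$target_reaction,
                            config$noise_fraction, seed = seeds[5])
  flux_dataset(network = sim$network, kinship = G, phenotypes = ph,
               true_fluxes = sim$fluxes, reference_genotype = 1L,
               meta = list(seed = config$seed, sub_seeds = seeds,
                           noise_fraction = config$noise_fraction,
                           params = as.data.frame(params),
                           genetic_values_target =
                             sim$genetic[, net$target_reaction]))
}

#' Generate replicate simulated datasets
#'
#' @param config a [simulation_config()]; each replicate runs with a
#'   distinct sub-seed derived from \code{config$seed}.
#' @param n number of replicates (default 10).
#' @return list of [flux_dataset()].
#' @export
generate_replicates <- function(config, n = 10L) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- s
    generate_dataset(cfg)
  })
}
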