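# Independent oracle implementations used only by tests. These are coded
# naively (explicit loops, dense linear algebra, base distributions) and
# deliberately share no code with the package's vectorized/compiled paths.

# Restricted log-likelihood by the direct dense formula:
# -0.5 [ log|V| + log|X'V^-1 X| + r'V^-1 r + (n-1) log 2pi - log|X'X| ]
reml_loglik_direct <- function(y, K, s2u, s2e) {
  n <- length(y)
  V <- s2u * K + s2e * diag(n)
  Vi <- solve(V)
  X <- matrix(1, n, 1)
  xvx <- drop(t(X) %*% Vi %*% X)
  beta <- drop(t(X) %*% Vi %*% y) / xvx
  r <- y - X %*% beta
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  as.numeric(-0.5 * (ld + log(xvx) + drop(t(r) %*% Vi %*% r) +
                     (n - 1) * log(2 * pi) - log(n)))
}

# 2-D grid search over (sigma2_u, sigma2_e) maximizing the restricted
# likelihood; returns the best grid point and its value
reml_grid_oracle <- function(y, K, n_grid = 20) {
  vy <- stats::var(y)
  s2u_grid <- exp(seq(log(vy * 1e-4), log(vy * 4), length.out = n_grid))
  s2e_grid <- exp(seq(log(vy * 1e-4), log(vy * 4), length.out = n_grid))
  best <- -Inf; arg <- c(NA, NA)
  for (a in s2u_grid) for (b in s2e_grid) {
    ll <- reml_loglik_direct(y, K, a, b)
    if (ll > best) { best <- ll; arg <- c(a, b) }
  }
  list(loglik = best, sigma2_u = arg[1], sigma2_e = arg[2])
}

# Naive triple-loop log posterior of the joint flux model. Matches the
# package's constant conventions: no 2*pi in the observation/constraint
# terms, full densities for priors.
naive_log_posterior <- function(state, dataset, train_mask, scaling,
                                config, psi = NULL) {
  net <- dataset$network
  N <- length(dataset$kinship$genotype_ids)
  K <- nrow(net$coefficients); J <- ncol(net$coefficients)
  delta <- scaling$delta; alpha <- scaling$alpha
  tj <- net$target_reaction
  irrev <- !net$reversible
  y <- dataset$phenotypes$values
  lp <- 0

  # observation term over training genotypes
  ntr <- 0; ss <- 0
  for (i in seq_len(N)) {
    if (!train_mask[i]) next
    ntr <- ntr + 1
    ss <- ss + (y[i] - state$a - state$b * state$V[i, tj])^2
  }
  lp <- lp - ntr / 2 * log(state$sigma2_e) - ss / (2 * state$sigma2_e)

  # weighted constraint term over all genotypes and metabolites
  ssc <- 0
  for (i in seq_len(N)) {
    Mi <- effective_stoichiometry(net, i)
    for (k in seq_len(K)) {
      lhs <- 0; rhs <- 0
      for (j in seq_len(J)) {
        lhs <- lhs + Mi[k, j] * delta[j] * alpha[j]
        rhs <- rhs + Mi[k, j] * delta[j] * state$V[i, j]
      }
      if (!is.null(psi)) lhs <- lhs + psi[i, k]
      ssc <- ssc + (lhs - rhs)^2
    }
  }
  lp <- lp + config$weight *
    (-N * K / 2 * log(state$sigma2_eps) - ssc / (2 * state$sigma2_eps))

  # flux priors (truncated below at alpha_j for irreversible reactions)
  for (j in seq_len(J)) {
    sv <- sqrt(state$sigma2_V[j])
    for (i in seq_len(N)) {
      lp <- lp + stats::dnorm(state$V[i, j], state$U[i, j] + alpha[j], sv,
                              log = TRUE)
      if (irrev[j])
        lp <- lp - stats::pnorm((state$U[i, j] + alpha[j] - alpha[j]) / sv,
                                log.p = TRUE)
    }
  }

  # kinship-structured genetic prior, dense multivariate normal
  G <- dataset$kinship$values
  rough_mu <- attr(scaling, "rough_mu")
  for (j in seq_len(J)) {
    S <- state$sigma2_U[j] * G
    dev <- state$U[, j] - rough_mu[j] / delta[j]
    ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
    lp <- lp - 0.5 * (N * log(2 * pi) + ld +
                      drop(t(dev) %*% solve(S) %*% dev))
  }

  # hyperpriors
  lhc <- function(x, s) log(2) - log(pi * s) - log(1 + (x / s)^2)
  as.numeric(
    lp + stats::dcauchy(state$a, 0, config$hc_scale_ab, log = TRUE) +
      lhc(state$b, config$hc_scale_ab) +
      lhc(state$sigma2_e, config$hc_scale_e) +
      lhc(state$sigma2_eps, state$S_eps) +
      sum(sapply(state$sigma2_V, lhc, s = config$hc_scale_v)) +
      sum(sapply(state$sigma2_U, lhc, s = config$hc_scale_u)) +
      stats::dgamma(state$S_eps, config$gamma_shape, config$gamma_rate,
                    log = TRUE))
}

# random model state in the constrained space
random_state <- function(N, J, alpha, irrev, sd = 0.5) {
  V <- matrix(10 + rnorm(N * J, 0, sd), N, J)
  for (j in which(irrev)) V[, j] <- pmax(V[, j], alpha[j] + 0.1)
  list(a = rnorm(1, 0, 5), b = exp(rnorm(1, 0, 0.5)),
       sigma2_e = exp(rnorm(1, 0, 1)), sigma2_eps = exp(rnorm(1, -2, 1)),
       S_eps = exp(rnorm(1, -2, 0.5)),
       sigma2_V = exp(rnorm(J, 0, 0.5)), sigma2_U = exp(rnorm(J, 0, 0.5)),
       U = matrix(10 + rnorm(N * J, 0, sd), N, J), V = V)
}

# dense grid minimizer of the projection objective on the balance
# nullspace (for J small), with iterative grid refinement;
# parameterizes the feasible set by the nullspace of the equalities
qp_grid_oracle <- function(u, Meq, irrev, lim = 3, n_grid = 41,
                           rounds = 4, Ain = NULL, bin = NULL) {
  ns <- MASS::Null(t(Meq))   # J x d basis of the nullspace
  d <- ncol(ns)
  stopifnot(d >= 1, d <= 2)
  scale <- max(abs(u))
  centers <- rep(0, d); width <- lim
  best <- Inf; varg <- NULL
  for (rd in seq_len(rounds)) {
    grids <- lapply(seq_len(d), function(i)
      seq(centers[i] - width, centers[i] + width, length.out = n_grid))
    pts <- as.matrix(expand.grid(grids))
    bp <- centers
    for (p in seq_len(nrow(pts))) {
      v <- drop(ns %*% pts[p, ]) * scale
      if (any(irrev & v < -1e-12)) next
      if (!is.null(Ain) && any(Ain %*% v > bin + 1e-12)) next
      obj <- sum((v / u - 1)^2)
      if (obj < best) { best <- obj; varg <- v; bp <- pts[p, ] }
    }
    centers <- bp
    width <- width * 4 / (n_grid - 1)   # zoom around the incumbent
  }
  list(objective = best, v = varg)
}
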