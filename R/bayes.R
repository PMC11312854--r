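# The joint Bayesian flux model. All genotypes' standardized fluxes V''
# and genetic components U' are inferred together: the phenotype is
# regressed on the standardized target-reaction flux (observation term,
# training genotypes only), the steady-state balance enters as a weighted
# Gaussian soft constraint over all genotypes, U' carries the kinship
# covariance, and irreversible-reaction fluxes have truncated-normal
# priors. Sampling is by the package's own No-U-Turn Sampler (Rcpp).

#' Model configuration
#'
#' @param weight likelihood weight W in (0, 1] balancing the observation
#'   term against the flux-balance constraint term.
#' @param iterations total NUTS iterations (default 5000).
#' @param warmup adaptation iterations discarded from the posterior
#'   (default 4000).
#' @param thinning keep every \code{thinning}-th post-warmup draw.
#' @param chains number of chains (default 1; split-half diagnostics are
#'   used within chains).
#' @param location_target common location of standardized fluxes
#'   (default 10).
#' @param hc_scale_e half-Cauchy scale of the observation noise variance.
#' @param hc_scale_ab half-Cauchy scale of the regression parameters a', b'.
#' @param hc_scale_v half-Cauchy scale of the standardized flux variances.
#' @param hc_scale_u half-Cauchy scale of the standardized genetic
#'   variances.
#' @param gamma_shape,gamma_rate Gamma hyperprior on the scale of the
#'   constraint-noise variance (defaults 0.1 and 1.0).
#' @param simulation_jitter add a small N(0, jitter_var) jitter to the
#'   constraint left-hand side (used when fitting simulated data whose
#'   balance is exact; off for real-data-style fits).
#' @param jitter_var variance of that jitter (default 1e-4).
#' @param max_treedepth NUTS maximum tree depth.
#' @param adapt_delta dual-averaging target acceptance probability.
#' @param delta_mode scale definition passed to [compute_scaling()].
#' @param seed integer seed for the sampler.
#' @return object of class \code{flux_model_config}.
#' @export
model_config <- function(weight = 0.64, iterations = 5000, warmup = 4000,
                         thinning = 1, chains = 1, location_target = 10,
                         hc_scale_e = 0.1, hc_scale_ab = 10,
                         hc_scale_v = 10, hc_scale_u = 10000,
                         gamma_shape = 0.1, gamma_rate = 1.0,
                         simulation_jitter = FALSE, jitter_var = 1e-4,
                         max_treedepth = 10, adapt_delta = 0.8,
                         delta_mode = "sqrt", seed = 1L) {
  if (weight <= 0 || weight > 1)
    stop("weight must be in (0, 1]", call. = FALSE)
  if (warmup >= iterations)
    stop("warmup must be smaller than iterations", call. = FALSE)
  scales <- c(hc_scale_e, hc_scale_ab, hc_scale_v, hc_scale_u,
              gamma_shape, gamma_rate)
  if (any(scales <= 0)) stop("prior scales must be positive", call. = FALSE)
  structure(list(weight = weight, iterations = as.integer(iterations),
                 warmup = as.integer(warmup), thinning = as.integer(thinning),
                 chains = as.integer(chains),
                 location_target = location_target,
                 hc_scale_e = hc_scale_e, hc_scale_ab = hc_scale_ab,
                 hc_scale_v = hc_scale_v, hc_scale_u = hc_scale_u,
                 gamma_shape = gamma_shape, gamma_rate = gamma_rate,
                 simulation_jitter = simulation_jitter,
                 jitter_var = jitter_var,
                 max_treedepth = as.integer(max_treedepth),
                 adapt_delta = adapt_delta, delta_mode = delta_mode,
                 seed = as.integer(seed)),
            class = "flux_model_config")
}

# Precompute the fixed quantities the C++ evaluator needs.
# psi: optional N x K jitter matrix added to the constraint left-hand side.
build_model_data <- function(dataset, train_mask, scaling, config,
                             psi = NULL) {
  net <- dataset$network
  N <- n_genotypes(dataset)
  K <- nrow(net$coefficients); J <- ncol(net$coefficients)
  delta <- scaling$delta; alpha <- scaling$alpha
  Mdelta <- array(0, c(K, J, N))
  lhs <- matrix(0, N, K)
  for (i in seq_len(N)) {
    Mi <- effective_stoichiometry(net, i)
    Md <- sweep(Mi, 2, delta, "*")
    Mdelta[, , i] <- Md
    lhs[i, ] <- as.vector(Md %*% alpha)
  }
  if (!is.null(psi)) lhs <- lhs + psi
  eg <- eigen(dataset$kinship$values, symmetric = TRUE)
  lamg <- pmax(eg$values, 1e-8)
  y <- dataset$phenotypes$values
  y[is.na(y)] <- 0  # never touched: the sum runs over training indices
  rough_mu <- attr(scaling, "rough_mu")
  if (is.null(rough_mu))
    stop("scaling must carry the rough locations (build it with ",
         "compute_scaling() on estimate_reaction_params() output and keep ",
         "the rough_mu attribute)", call. = FALSE)
  list(Y = y, train = as.integer(which(train_mask) - 1L),
       Mdelta = Mdelta, lhs = lhs, alpha = alpha,
       irrev = as.integer(!net$reversible),
       Qg = eg$vectors, lamg = lamg, mU = rough_mu / delta,
       W = config$weight, hc_e = config$hc_scale_e,
       hc_ab = config$hc_scale_ab, hc_v = config$hc_scale_v,
       hc_u = config$hc_scale_u, g_shape = config$gamma_shape,
       g_rate = config$gamma_rate, tj = net$target_reaction)
}

#' Joint log posterior of the flux model
#'
#' Reference implementation (vectorized R) of the model's log posterior in
#' the standardized flux space, up to an additive constant shared across
#' states: the observation term over training genotypes, the flux-balance
#' constraint term over all genotypes multiplied by the weight W, the
#' truncated/plain normal flux priors, the kinship-structured genetic
#' prior, and all hyperpriors. Used as the sampling target (the C++
#' evaluator mirrors it exactly) and directly testable against naive-loop
#' implementations.
#'
#' @param state named list with elements \code{a}, \code{b} (positive
#'   regression parameters), \code{sigma2_e}, \code{sigma2_eps},
#'   \code{S_eps} (positive variances/scales), \code{sigma2_V},
#'   \code{sigma2_U} (length-J positive vectors), \code{U} and \code{V}
#'   (N x J matrices of standardized genetic values and fluxes).
#' @param dataset a [flux_dataset()].
#' @param train_mask logical vector: which genotypes' phenotypes are
#'   observed.
#' @param scaling a [compute_scaling()] result carrying the rough
#'   locations.
#' @param config a [model_config()].
#' @param psi optional N x K matrix added to the constraint left-hand side
#'   (the simulation-mode jitter).
#' @return scalar log posterior (\code{-Inf} outside the support).
#' @export
log_posterior <- function(state, dataset, train_mask, scaling, config,
                          psi = NULL) {
  net <- dataset$network
  N <- n_genotypes(dataset)
  K <- nrow(net$coefficients); J <- ncol(net$coefficients)
  delta <- scaling$delta; alpha <- scaling$alpha
  V <- state$V; U <- state$U
  irrev <- !net$reversible
  pos <- c(state$b, state$sigma2_e, state$sigma2_eps, state$S_eps,
           state$sigma2_V, state$sigma2_U)
  if (any(pos <= 0)) return(-Inf)
  for (j in which(irrev)) if (any(V[, j] <= alpha[j])) return(-Inf)

  lhc <- function(x, s) log(2 / pi) - log(s) - log1p((x / s)^2)

  ntr <- sum(train_mask)
  yhat <- state$a + state$b * V[, net$target_reaction]
  obs <- -0.5 * ntr * log(state$sigma2_e) -
    sum((dataset$phenotypes$values[train_mask] - yhat[train_mask])^2) /
      (2 * state$sigma2_e)

  ssc <- 0
  for (i in seq_len(N)) {
    Md <- sweep(effective_stoichiometry(net, i), 2, delta, "*")
    lhs_i <- as.vector(Md %*% alpha)
    if (!is.null(psi)) lhs_i <- lhs_i + psi[i, ]
    ssc <- ssc + sum((lhs_i - as.vector(Md %*% V[i, ]))^2)
  }
  con <- -0.5 * N * K * log(state$sigma2_eps) - ssc / (2 * state$sigma2_eps)

  lp <- obs + config$weight * con

  for (j in seq_len(J)) {
    sv <- sqrt(state$sigma2_V[j])
    z <- (V[, j] - U[, j] - alpha[j]) / sv
    lp <- lp - 0.5 * N * log(2 * pi * state$sigma2_V[j]) - 0.5 * sum(z^2)
    if (irrev[j])
      lp <- lp - sum(stats::pnorm(U[, j] / sv, log.p = TRUE))
  }

  eg <- eigen(dataset$kinship$values, symmetric = TRUE)
  lamg <- pmax(eg$values, 1e-8)
  rough_mu <- attr(scaling, "rough_mu")
  for (j in seq_len(J)) {
    dev <- U[, j] - rough_mu[j] / delta[j]
    t2 <- crossprod(eg$vectors, dev)[, 1]
    quad <- sum(t2^2 / lamg)
    lp <- lp - 0.5 * (N * log(2 * pi * state$sigma2_U[j]) +
                      sum(log(lamg)) + quad / state$sigma2_U[j])
  }

  lp + stats::dcauchy(state$a, 0, config$hc_scale_ab, log = TRUE) +
    lhc(state$b, config$hc_scale_ab) +
    lhc(state$sigma2_e, config$hc_scale_e) +
    lhc(state$sigma2_eps, state$S_eps) +
    sum(vapply(state$sigma2_V, lhc, numeric(1), s = config$hc_scale_v)) +
    sum(vapply(state$sigma2_U, lhc, numeric(1), s = config$hc_scale_u)) +
    stats::dgamma(state$S_eps, config$gamma_shape, config$gamma_rate,
                  log = TRUE)
}

#' Rough estimates and scaling from training fluxes
#'
#' Convenience wrapper: per-reaction mixed-model estimates on the training
#' fluxes followed by [compute_scaling()]; the rough locations are kept as
#' an attribute because the genetic prior needs them.
#'
#' @param train_fluxes [flux_table()] or matrix over training genotypes.
#' @param kin_train kinship over the same genotypes.
#' @param location_target,delta_mode passed to [compute_scaling()].
#' @return a \code{flux_scaling} with attributes \code{rough_mu} and
#'   \code{rough} (the full [genetic_params()]).
#' @export
scaling_from_training <- function(train_fluxes, kin_train,
                                  location_target = 10,
                                  delta_mode = "sqrt") {
  rough <- estimate_reaction_params(train_fluxes, kin_train)
  sc <- compute_scaling(rough, location_target, delta_mode)
  attr(sc, "rough_mu") <- rough$mu
  attr(sc, "rough") <- rough
  sc
}

# map an unconstrained sampler vector to the constrained state list;
# the genetic effects are stored non-centered and reconstructed here
theta_to_state <- function(theta, N, J, alpha, irrev, mU, Qg, lamg) {
  oV <- 6; oU <- 6 + J; oUp <- 6 + 2 * J; oVp <- 6 + 2 * J + N * J
  s2U <- exp(theta[oU:(oU + J - 1)])
  Z <- matrix(theta[oUp:(oUp + N * J - 1)], N, J)
  U <- Qg %*% (Z * sqrt(lamg))
  U <- sweep(sweep(U, 2, sqrt(s2U), "*"), 2, mU, "+")
  Vr <- matrix(theta[oVp:(oVp + N * J - 1)], N, J)
  V <- Vr
  for (j in which(irrev)) V[, j] <- alpha[j] + exp(Vr[, j])
  list(a = theta[1], b = exp(theta[2]), sigma2_e = exp(theta[3]),
       sigma2_eps = exp(theta[4]), S_eps = exp(theta[5]),
       sigma2_V = exp(theta[oV:(oV + J - 1)]),
       sigma2_U = s2U, U = U, V = V)
}

#' Fit the joint flux model by NUTS
#'
#' Runs the package's No-U-Turn Sampler on the joint posterior, with
#' dual-averaging step-size adaptation and diagonal mass-matrix estimation
#' during warmup. Standardized fluxes are initialized at the transformed
#' training-flux estimates where available and at the location target
#' (plus small noise) elsewhere; hyperparameters start at their prior
#' medians.
#'
#' @param dataset a [flux_dataset()].
#' @param train_mask logical N-vector; \code{TRUE} for genotypes whose
#'   phenotype is observed during fitting.
#' @param scaling output of [scaling_from_training()] computed from
#'   training data only.
#' @param config a [model_config()].
#' @param init_fluxes optional [flux_table()]/matrix of flux values (raw
#'   scale) used to initialize the standardized fluxes; rows of genotypes
#'   absent from it (e.g. test genotypes) fall back to the default
#'   initialization. Typically the QP-estimated training fluxes.
#' @return object of class \code{flux_posterior}: scalar draws
#'   (\code{a}, \code{b}, \code{sigma2_e}, \code{sigma2_eps},
#'   \code{S_eps}), matrix draws (\code{sigma2_V}, \code{sigma2_U}), flux
#'   draws (\code{V}, \code{U}: draws x N x J arrays), sampler metadata
#'   and the scaling used.
#' @export
fit_model <- function(dataset, train_mask, scaling, config,
                      init_fluxes = NULL) {
  t_start <- Sys.time()
  net <- dataset$network
  N <- n_genotypes(dataset)
  K <- nrow(net$coefficients); J <- ncol(net$coefficients)
  alpha <- scaling$alpha
  irrev <- !net$reversible

  set.seed(config$seed)
  psi <- NULL
  if (config$simulation_jitter)
    psi <- matrix(stats::rnorm(N * K, 0, sqrt(config$jitter_var)), N, K)
  model <- build_model_data(dataset, train_mask, scaling, config, psi)

  # --- initialization ---------------------------------------------------
  Vinit <- matrix(config$location_target + stats::rnorm(N * J, 0, 0.1),
                  N, J)
  if (!is.null(init_fluxes)) {
    Vf <- if (inherits(init_fluxes, "flux_table")) init_fluxes$values
          else as.matrix(init_fluxes)
    ids <- rownames(Vf)
    rows <- match(ids, dataset$kinship$genotype_ids)
    Vt <- transform_fluxes(Vf, scaling, "forward")
    usable <- !is.na(rows) & stats::complete.cases(Vt)
    Vinit[rows[usable], ] <- Vt[usable, , drop = FALSE]
  }
  # keep truncated coordinates strictly inside the support
  for (j in which(irrev))
    Vinit[, j] <- pmax(Vinit[, j], alpha[j] + 0.05)
  Uinit <- sweep(Vinit, 2, alpha)          # U' = V'' - alpha at init
  Vraw <- Vinit
  for (j in which(irrev)) Vraw[, j] <- log(Vinit[, j] - alpha[j])
  # non-centered z reproducing Uinit at the initial sigma2_U
  Zinit <- crossprod(model$Qg, sweep(Uinit, 2, model$mU)) /
    sqrt(model$lamg) / sqrt(config$hc_scale_u)
  S_med <- stats::qgamma(0.5, config$gamma_shape, config$gamma_rate)
  y_tr <- dataset$phenotypes$values[train_mask]
  vJ_init <- Vinit[, net$target_reaction]
  b0 <- stats::sd(y_tr) / max(stats::sd(vJ_init), 1e-3)
  b0 <- max(b0, 1e-3)
  a0 <- mean(y_tr) - b0 * mean(vJ_init)
  s2e0 <- max(0.25 * stats::var(y_tr), 1e-6)
  # start the constraint-noise variance at the scale of the initial
  # residuals (test-genotype fluxes start unbalanced); it tightens during
  # sampling
  r2 <- vapply(seq_len(N), function(i)
    mean((model$lhs[i, ] - model$Mdelta[, , i] %*% Vinit[i, ])^2),
    numeric(1))
  s2eps0 <- max(mean(r2), S_med)
  theta <- c(a0, log(b0), log(s2e0),
             log(s2eps0), log(S_med),
             rep(log(config$hc_scale_v), J), rep(log(config$hc_scale_u), J),
             as.vector(Zinit), as.vector(Vraw))
  D <- length(theta)

  # --- warmup: dual averaging + diagonal mass estimation ----------------
  inv_mass <- rep(1, D)
  eps <- flux_find_epsilon(theta, inv_mass, model)
  mu_da <- log(10 * eps); Hbar <- 0; log_eps_bar <- log(eps)
  gamma_da <- 0.05; t0 <- 10; kappa <- 0.75; m_da <- 0
  win_start <- max(10L, floor(config$warmup * 0.3))
  win_end <- floor(config$warmup * 0.7)
  win <- matrix(NA_real_, max(0, win_end - win_start + 1), D)
  divergences <- 0L; depths <- integer(0)

  for (it in seq_len(config$warmup)) {
    step <- flux_nuts_step(theta, eps, inv_mass, model,
                           config$max_treedepth)
    theta <- as.vector(step$theta)
    if (isTRUE(step$divergent)) divergences <- divergences + 1L
    m_da <- m_da + 1
    Hbar <- (1 - 1 / (m_da + t0)) * Hbar +
      (config$adapt_delta - step$accept_stat) / (m_da + t0)
    log_eps <- mu_da - sqrt(m_da) / gamma_da * Hbar
    eta <- m_da^(-kappa)
    log_eps_bar <- eta * log_eps + (1 - eta) * log_eps_bar
    eps <- exp(log_eps)
    if (it >= win_start && it <= win_end)
      win[it - win_start + 1, ] <- theta
    if (it == win_end && win_end > win_start + 10) {
      v <- apply(win, 2, stats::var)
      n_w <- nrow(win)
      inv_mass <- pmax(v * n_w / (n_w + 5) + 1e-3 * 5 / (n_w + 5), 1e-8)
      eps <- flux_find_epsilon(theta, inv_mass, model)
      mu_da <- log(10 * eps); Hbar <- 0; log_eps_bar <- log(eps); m_da <- 0
    }
  }
  eps <- exp(log_eps_bar)

  # --- sampling ---------------------------------------------------------
  n_keep <- floor((config$iterations - config$warmup) / config$thinning)
  draws_scalar <- matrix(NA_real_, n_keep, 5,
                         dimnames = list(NULL, c("a", "b", "sigma2_e",
                                                 "sigma2_eps", "S_eps")))
  draws_s2V <- matrix(NA_real_, n_keep, J)
  draws_s2U <- matrix(NA_real_, n_keep, J)
  draws_V <- array(NA_real_, c(n_keep, N, J))
  draws_U <- array(NA_real_, c(n_keep, N, J))
  draws_lp <- numeric(n_keep)
  kept <- 0L
  for (it in seq_len(config$iterations - config$warmup)) {
    step <- flux_nuts_step(theta, eps, inv_mass, model,
                           config$max_treedepth)
    theta <- as.vector(step$theta)
    if (isTRUE(step$divergent)) divergences <- divergences + 1L
    depths <- c(depths, step$depth)
    if (it %% config$thinning == 0 && kept < n_keep) {
      kept <- kept + 1L
      st <- theta_to_state(theta, N, J, alpha, irrev, model$mU, model$Qg,
                           model$lamg)
      draws_scalar[kept, ] <- c(st$a, st$b, st$sigma2_e, st$sigma2_eps,
                                st$S_eps)
      draws_s2V[kept, ] <- st$sigma2_V
      draws_s2U[kept, ] <- st$sigma2_U
      draws_V[kept, , ] <- st$V
      draws_U[kept, , ] <- st$U
      draws_lp[kept] <- step$lp
    }
  }
  div_frac <- divergences / config$iterations
  if (!all(is.finite(draws_scalar[seq_len(kept), ])))
    stop("sampler produced non-finite draws", call. = FALSE)
  if (div_frac > 0.5)
    stop(sprintf("divergence fraction %.2f exceeds 0.5; the fit is unusable",
                 div_frac), call. = FALSE)

  structure(list(scalars = draws_scalar[seq_len(kept), , drop = FALSE],
                 sigma2_V = draws_s2V[seq_len(kept), , drop = FALSE],
                 sigma2_U = draws_s2U[seq_len(kept), , drop = FALSE],
                 V = draws_V[seq_len(kept), , , drop = FALSE],
                 U = draws_U[seq_len(kept), , , drop = FALSE],
                 lp = draws_lp[seq_len(kept)],
                 scaling = scaling, train_mask = train_mask,
                 target_reaction = net$target_reaction,
                 genotype_ids = dataset$kinship$genotype_ids,
                 irrev = irrev, alpha = alpha,
                 divergences = divergences, div_frac = div_frac,
                 mean_depth = if (length(depths)) mean(depths) else NA_real_,
                 step_size = eps, seed = config$seed, config = config,
                 runtime_s = as.numeric(difftime(Sys.time(), t_start,
                                                 units = "secs"))),
            class = "flux_posterior")
}

#' @export
print.flux_posterior <- function(x, ...) {
  cat("flux_posterior:", nrow(x$scalars), "draws,",
      length(x$genotype_ids), "genotypes,", length(x$alpha), "reactions\n")
  cat(sprintf("  divergent: %d  mean tree depth: %.1f  step size: %.3g  (%.1fs)\n",
              x$divergences, x$mean_depth, x$step_size, x$runtime_s))
  invisible(x)
}

#' Posterior phenotype predictions
#'
#' Per draw, the predicted phenotype of genotype i is
#' \eqn{\hat Y_i = a' + b' V''_{i,J}}; the function returns the posterior
#' mean and a central 90% credible interval for each requested genotype.
#'
#' @param samples a [fit_model()] result.
#' @param genotype_indices integer indices of genotypes to predict
#'   (default all).
#' @return data frame with \code{genotype_id}, \code{mean}, \code{lower},
#'   \code{upper}.
#' @export
predict_phenotypes <- function(samples,
                               genotype_indices =
                                 seq_along(samples$genotype_ids)) {
  N <- length(samples$genotype_ids)
  if (any(genotype_indices < 1 | genotype_indices > N))
    stop("unknown genotype index: ",
         paste(genotype_indices[genotype_indices < 1 |
                                genotype_indices > N], collapse = ", "),
         call. = FALSE)
  tj <- samples$target_reaction
  out <- lapply(genotype_indices, function(i) {
    yhat <- samples$scalars[, "a"] + samples$scalars[, "b"] *
      samples$V[, i, tj]
    data.frame(genotype_id = samples$genotype_ids[i], mean = mean(yhat),
               lower = unname(stats::quantile(yhat, 0.05)),
               upper = unname(stats::quantile(yhat, 0.95)))
  })
  do.call(rbind, out)
}

# split-half Gelman-Rubin statistic for a single chain (or stacked chains)
split_rhat <- function(x) {
  n <- length(x)
  if (n < 4) return(NA_real_)
  h <- floor(n / 2)
  xs <- list(x[seq_len(h)], x[(n - h + 1):n])
  m <- length(xs)
  means <- vapply(xs, mean, numeric(1))
  vars <- vapply(xs, stats::var, numeric(1))
  Wv <- mean(vars)
  Bv <- h * stats::var(means)
  if (Wv <= 0) return(ifelse(Bv > 0, Inf, 1))
  sqrt(((h - 1) / h * Wv + Bv / h) / Wv)
}

#' Convergence diagnostics
#'
#' Split-half R-hat and a crude effective sample size for every scalar
#' parameter (regression parameters, variances and each flux coordinate),
#' flagging parameters whose R-hat exceeds the threshold.
#'
#' @param samples a [fit_model()] result (or any list with draw matrices).
#' @param threshold R-hat flag threshold (default 1.1, a common
#'   convergence criterion).
#' @return data frame with \code{parameter}, \code{rhat}, \code{flagged};
#'   attribute \code{n_flagged}.
#' @export
convergence_report <- function(samples, threshold = 1.1) {
  if (nrow(samples$scalars) < 4)
    stop("need at least 4 retained draws for diagnostics", call. = FALSE)
  N <- length(samples$genotype_ids); J <- length(samples$alpha)
  mats <- cbind(samples$scalars, samples$sigma2_V, samples$sigma2_U)
  colnames(mats) <- c(colnames(samples$scalars),
                      sprintf("sigma2_V[%d]", seq_len(J)),
                      sprintf("sigma2_U[%d]", seq_len(J)))
  flux_cols <- matrix(samples$V, nrow = nrow(samples$scalars))
  colnames(flux_cols) <- sprintf("V[%d,%d]", rep(seq_len(N), J),
                                 rep(seq_len(J), each = N))
  mats <- cbind(mats, flux_cols)
  rh <- apply(mats, 2, split_rhat)
  out <- data.frame(parameter = colnames(mats), rhat = rh,
                    flagged = !is.na(rh) & rh > threshold,
                    row.names = NULL)
  attr(out, "n_flagged") <- sum(out$flagged)
  out
}

#' Correlation between the two sides of the balance constraint
#'
#' At convergence the posterior fluxes should satisfy the soft steady-state
#' constraint: over all genotype-metabolite pairs, the constraint
#' left-hand side and the fitted right-hand side should be essentially
#' collinear. Returns their Pearson correlation computed at the posterior
#' mean of V''.
#'
#' @param samples a [fit_model()] result.
#' @param dataset the [flux_dataset()] the model was fitted to.
#' @return scalar Pearson correlation.
#' @export
constraint_adherence <- function(samples, dataset) {
  net <- dataset$network
  N <- length(samples$genotype_ids)
  Vbar <- apply(samples$V, c(2, 3), mean)
  delta <- samples$scaling$delta; alpha <- samples$scaling$alpha
  lhs <- rhs <- matrix(0, N, nrow(net$coefficients))
  for (i in seq_len(N)) {
    Md <- sweep(effective_stoichiometry(net, i), 2, delta, "*")
    lhs[i, ] <- as.vector(Md %*% alpha)
    rhs[i, ] <- as.vector(Md %*% Vbar[i, ])
  }
  stats::cor(as.vector(lhs), as.vector(rhs))
}
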