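# Single-kernel REML mixed model y = 1*mu + u + e, u ~ N(0, sigma2_u K),
# fitted by spectral decomposition of K and 1-D profile optimization of
# the variance ratio lambda = sigma2_u / sigma2_e (log-grid scan followed
# by golden-section refinement). Used for GBLUP on phenotypes, for
# per-reaction rough estimates of flux variance components, and inside the
# predict-then-project baseline.

#' Restricted log-likelihood of the single-kernel mixed model
#'
#' Direct evaluation of the REML log-likelihood of y = X beta + u + e with
#' u ~ N(0, sigma2_u K), e ~ N(0, sigma2_e I) and X = 1:
#' \deqn{\ell_R = -\tfrac12[\log|V| + \log|X'V^{-1}X| + r'V^{-1}r +
#'   (n-p)\log 2\pi - \log|X'X|]}
#' with V the marginal covariance and r the GLS residual. Exposed mainly so
#' independent optimizers can be compared on the same objective.
#'
#' @param y numeric response vector.
#' @param K covariance kernel (matrix or [kinship()]).
#' @param sigma2_u genetic variance (>= 0).
#' @param sigma2_e residual variance (> 0).
#' @return restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(y, K, sigma2_u, sigma2_e) {
  if (inherits(K, "flux_kinship")) K <- K$values
  n <- length(y)
  V <- sigma2_u * K + diag(sigma2_e, n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetV <- 2 * sum(log(diag(ch)))
  Vinv_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  xvx <- sum(Vinv_1)            # 1' V^-1 1
  beta <- sum(Vinv_y) / xvx
  r <- y - beta
  Vinv_r <- Vinv_y - beta * Vinv_1
  quad <- sum(r * Vinv_r)
  -0.5 * (logdetV + log(xvx) + quad + (n - 1) * log(2 * pi) - log(n))
}

#' Fit the single-kernel REML mixed model
#'
#' Maximizes the restricted likelihood over (sigma2_u, sigma2_e) by
#' eigendecomposing K once and profiling the residual variance out of a
#' 1-D search over the ratio lambda = sigma2_u/sigma2_e (coarse log grid,
#' then golden-section). Variance components are floored at
#' \code{1e-8 * var(y)} to avoid boundary pathologies in downstream use.
#'
#' @param y numeric vector of observations (training genotypes).
#' @param K kinship restricted to the same genotypes ([kinship()] or
#'   matrix).
#' @return object of class \code{reml_fit}: list with \code{mu},
#'   \code{sigma2_u}, \code{sigma2_e}, \code{loglik} (restricted),
#'   \code{blup} (genetic values of the training genotypes) and
#'   \code{lambda}.
#' @export
reml_single_kernel <- function(y, K) {
  if (inherits(K, "flux_kinship")) K <- K$values
  n <- length(y)
  if (n < 3) stop("need at least 3 observations for REML", call. = FALSE)
  if (!all(dim(K) == c(n, n)))
    stop("kinship dimension does not match y", call. = FALSE)
  vy <- stats::var(y)
  floor_v <- 1e-8 * max(vy, .Machine$double.eps)
  if (vy <= 0) {
    # constant response: no variance to partition
    return(structure(list(mu = y[1], sigma2_u = floor_v, sigma2_e = floor_v,
                          loglik = reml_loglik(y, K, floor_v, floor_v),
                          blup = rep(0, n), lambda = 1),
                     class = "reml_fit"))
  }
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)[, 1]
  xt <- crossprod(eg$vectors, rep(1, n))[, 1]

  # profile REML criterion in lambda (sigma2_e profiled analytically)
  prof <- function(loglam) {
    lam <- exp(loglam)
    w <- lam * d + 1
    xwx <- sum(xt^2 / w)
    beta <- sum(xt * yt / w) / xwx
    rss <- sum((yt - beta * xt)^2 / w)
    s2e <- rss / (n - 1)
    -0.5 * (sum(log(w)) + n * log(s2e) + log(xwx / s2e) + rss / s2e +
            (n - 1) * log(2 * pi) - log(n))
  }
  grid <- seq(log(1e-6), log(1e6), length.out = 41)
  vals <- vapply(grid, prof, numeric(1))
  if (!any(is.finite(vals)))
    stop("restricted likelihood non-finite on the whole search grid",
         call. = FALSE)
  i0 <- which.max(vals)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  # compare against boundary of the grid in case the optimum is extreme
  loglam <- if (opt$objective >= vals[i0]) opt$maximum else grid[i0]
  lam <- exp(loglam)
  w <- lam * d + 1
  xwx <- sum(xt^2 / w)
  beta <- sum(xt * yt / w) / xwx
  rss <- sum((yt - beta * xt)^2 / w)
  s2e <- max(rss / (n - 1), floor_v)
  s2u <- max(lam * s2e, floor_v)
  ll <- reml_loglik(y, K, s2u, s2e)
  if (!is.finite(ll))
    stop("restricted likelihood non-finite at the optimum", call. = FALSE)
  # BLUP of genetic values: u = s2u K (s2u K + s2e I)^-1 (y - mu)
  H <- s2u * K + diag(s2e, n)
  u <- s2u * (K %*% solve(H, y - beta))[, 1]
  structure(list(mu = beta, sigma2_u = s2u, sigma2_e = s2e, loglik = ll,
                 blup = u, lambda = lam),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("reml_fit: mu=%.4g sigma2_u=%.4g sigma2_e=%.4g logLik=%.4f\n",
              x$mu, x$sigma2_u, x$sigma2_e, x$loglik))
  invisible(x)
}

#' GBLUP prediction for held-out genotypes
#'
#' \eqn{\hat y_{test} = \hat\mu + \hat\sigma^2_u K_{test,train}
#' (\hat\sigma^2_u K_{train,train} + \hat\sigma^2_e I)^{-1}
#' (y_{train} - 1\hat\mu)}.
#'
#' @param fit a \code{reml_fit} produced on the training genotypes.
#' @param kin full [kinship()] (or matrix) over all genotypes.
#' @param y_train training observations (order matching \code{train_idx}).
#' @param train_idx,test_idx disjoint genotype index vectors.
#' @return named numeric vector of predictions for \code{test_idx}.
#' @export
gblup_predict <- function(fit, kin, y_train, train_idx, test_idx) {
  if (inherits(kin, "flux_kinship")) kin <- kin$values
  if (length(intersect(train_idx, test_idx)) > 0)
    stop("train and test indices overlap", call. = FALSE)
  Ktt <- kin[train_idx, train_idx, drop = FALSE]
  Kst <- kin[test_idx, train_idx, drop = FALSE]
  H <- fit$sigma2_u * Ktt + diag(fit$sigma2_e, length(train_idx))
  alpha <- solve(H, y_train - fit$mu)
  preds <- fit$mu + fit$sigma2_u * (Kst %*% alpha)[, 1]
  names(preds) <- rownames(kin)[test_idx]
  preds
}

#' Per-reaction rough genetic parameter estimates
#'
#' Fits the single-kernel mixed model to every reaction's training fluxes
#' (V_{t,j} = 1 mu_j + U_{,j} + r_j) and returns the per-reaction
#' location and variance components used to standardize flux scales. A
#' reaction whose REML fit fails (or whose fluxes are constant) falls back
#' to mu = sample mean and sigma2_U = sigma2_V = half the (floored) sample
#' variance; fallbacks are recorded in the \code{fallback} attribute.
#'
#' @param fluxes [flux_table()] (or matrix) over the training genotypes
#'   only; test-genotype fluxes must not be included.
#' @param kin [kinship()] (or matrix) over the same training genotypes.
#' @return a [genetic_params()] with one row per reaction; attribute
#'   \code{fallback} flags reactions that used the fallback.
#' @export
estimate_reaction_params <- function(fluxes, kin) {
  V <- if (inherits(fluxes, "flux_table")) fluxes$values else as.matrix(fluxes)
  if (inherits(kin, "flux_kinship")) kin <- kin$values
  ok <- stats::complete.cases(V)
  if (!all(ok)) {       # genotypes whose flux estimation failed upstream
    V <- V[ok, , drop = FALSE]
    kin <- kin[ok, ok, drop = FALSE]
  }
  J <- ncol(V)
  mu <- s2u <- s2v <- numeric(J)
  fb <- logical(J)
  for (j in seq_len(J)) {
    fit <- tryCatch(reml_single_kernel(V[, j], kin), error = function(e) NULL)
    if (is.null(fit)) {
      vj <- stats::var(V[, j])
      floor_v <- 1e-8 * max(vj, 1)
      mu[j] <- mean(V[, j])
      s2u[j] <- s2v[j] <- max(vj / 2, floor_v)
      fb[j] <- TRUE
    } else {
      mu[j] <- fit$mu; s2u[j] <- fit$sigma2_u; s2v[j] <- fit$sigma2_e
      fb[j] <- FALSE
    }
  }
  out <- genetic_params(mu, s2u, s2v, reaction_ids = colnames(V))
  attr(out, "fallback") <- fb
  out
}
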