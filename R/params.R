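#' Per-reaction genetic parameters
#'
#' Container for per-reaction location and variance components of the flux
#' mixed model V_{,j} = 1 mu_j + U_{,j} + r_j with U kinship-structured:
#' \code{mu} (flux units), genetic variance \code{sigma2_U}, residual
#' variance \code{sigma2_V}. Used both as simulation truth and as the rough
#' estimates that drive the per-reaction scale/location standardization.
#'
#' @param mu numeric vector of per-reaction locations.
#' @param sigma2_U numeric vector of per-reaction genetic variances (>= 0).
#' @param sigma2_V numeric vector of per-reaction residual variances (>= 0).
#' @param reaction_ids optional reaction ids.
#' @return object of class \code{genetic_params} (a data frame).
#' @export
genetic_params <- function(mu, sigma2_U, sigma2_V, reaction_ids = NULL) {
  J <- length(mu)
  stopifnot(length(sigma2_U) == J, length(sigma2_V) == J)
  if (any(sigma2_U < 0) || any(sigma2_V < 0))
    stop("variance components must be nonnegative", call. = FALSE)
  if (is.null(reaction_ids)) reaction_ids <- sprintf("rxn%03d", seq_len(J))
  structure(data.frame(reaction_id = reaction_ids, mu = mu,
                       sigma2_U = sigma2_U, sigma2_V = sigma2_V,
                       stringsAsFactors = FALSE),
            class = c("genetic_params", "data.frame"))
}

#' Sample heterogeneous per-reaction genetic parameters
#'
#' Draws per-reaction locations log-uniformly over two orders of magnitude
#' and genetic / residual coefficients of variation log-uniformly over an
#' order of magnitude each, reproducing the strong between-reaction
#' heterogeneity of scale that motivates the standardization step.
#' Uses the current RNG state.
#'
#' @param J number of reactions.
#' @param mu_range range (log10) of locations, default c(0.5, 2.5).
#' @param cv_U_range range (log10) of genetic coefficient of variation,
#'   default c(-1.3, -0.3) (about 0.05 to 0.5).
#' @param cv_V_range range (log10) of residual coefficient of variation,
#'   default c(-1.8, -0.8).
#' @param reaction_ids optional reaction ids.
#' @return a [genetic_params()] object.
#' @export
sample_genetic_params <- function(J, mu_range = c(0.5, 2.5),
                                  cv_U_range = c(-1.3, -0.3),
                                  cv_V_range = c(-1.8, -0.8),
                                  reaction_ids = NULL) {
  mu <- 10^stats::runif(J, mu_range[1], mu_range[2])
  cv_U <- 10^stats::runif(J, cv_U_range[1], cv_U_range[2])
  cv_V <- 10^stats::runif(J, cv_V_range[1], cv_V_range[2])
  genetic_params(mu, (cv_U * mu)^2, (cv_V * mu)^2, reaction_ids)
}
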