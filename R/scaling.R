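# Per-reaction scale/location standardization. Flux scales differ by
# orders of magnitude between reactions, which cripples joint posterior
# exploration; each reaction is therefore rescaled by delta_j and shifted
# by alpha_j so all standardized fluxes live near a common location.

#' Compute per-reaction scaling parameters
#'
#' From rough per-reaction estimates (location mu_j, genetic variance
#' sigma2_U_j, residual variance sigma2_V_j) computes
#' \deqn{\delta_j = \sqrt{\tilde\sigma^2_{Uj} + \tilde\sigma^2_{Vj}},
#' \qquad \alpha_j = \mathrm{target} - \tilde\mu_j/\delta_j,}
#' so that the standardized flux \eqn{V''_{,j} = V_{,j}/\delta_j + \alpha_j}
#' has location \code{location_target} (default 10) and unit-order scale
#' for every reaction. \code{delta_mode = "literal"} uses the plain sum of
#' the variance components instead of its square root (see the vignette for
#' why the square root is the default).
#'
#' @param rough a [genetic_params()] of rough estimates (from
#'   [estimate_reaction_params()] on training data).
#' @param location_target common location of standardized fluxes
#'   (default 10).
#' @param delta_mode \code{"sqrt"} (default) or \code{"literal"}.
#' @return object of class \code{flux_scaling}: data frame with
#'   \code{reaction_id}, \code{delta}, \code{alpha}.
#' @export
compute_scaling <- function(rough, location_target = 10,
                            delta_mode = c("sqrt", "literal")) {
  delta_mode <- match.arg(delta_mode)
  tot <- rough$sigma2_U + rough$sigma2_V
  delta <- if (delta_mode == "sqrt") sqrt(tot) else tot
  if (any(!is.finite(delta)) || any(delta <= 0))
    stop("nonpositive scale for reaction(s): ",
         paste(rough$reaction_id[!is.finite(delta) | delta <= 0],
               collapse = ", "), call. = FALSE)
  alpha <- location_target - rough$mu / delta
  structure(data.frame(reaction_id = rough$reaction_id, delta = delta,
                       alpha = alpha, stringsAsFactors = FALSE),
            class = c("flux_scaling", "data.frame"))
}

#' Standardize or de-standardize a flux table
#'
#' Forward: \eqn{V''_{,j} = V_{,j}/\delta_j + \alpha_j}; inverse exactly
#' undoes it.
#'
#' @param fluxes a [flux_table()] or numeric matrix (genotypes x reactions).
#' @param scaling a [compute_scaling()] result.
#' @param direction \code{"forward"} or \code{"inverse"}.
#' @return object of the same type as the input.
#' @export
transform_fluxes <- function(fluxes, scaling,
                             direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  is_ft <- inherits(fluxes, "flux_table")
  V <- if (is_ft) fluxes$values else as.matrix(fluxes)
  if (ncol(V) != nrow(scaling))
    stop("scaling has ", nrow(scaling), " reactions but fluxes have ",
         ncol(V), call. = FALSE)
  W <- if (direction == "forward")
    sweep(sweep(V, 2, scaling$delta, "/"), 2, scaling$alpha, "+")
  else
    sweep(sweep(V, 2, scaling$alpha, "-"), 2, scaling$delta, "*")
  if (is_ft) flux_table(W, fluxes$genotype_ids) else W
}
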