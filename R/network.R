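#' Construct a reaction network
#'
#' A reaction network holds the stoichiometry matrix of a metabolic network
#' (metabolites in rows, reactions in columns; positive coefficients produce
#' the metabolite, negative coefficients consume it), the partition of
#' reactions into reversible and irreversible sets, the index of the
#' target (biomass-producing) reaction, and optional genotype-specific
#' coefficient overrides on top of the shared base matrix.
#'
#' Overrides are stored sparsely as a data frame because in practice only a
#' handful of coefficients (the biomass column and the per-metabolite
#' balancing coefficient) differ between genotypes.
#'
#' @param coefficients K x J numeric matrix of stoichiometric coefficients.
#'   Row names are taken as metabolite ids, column names as reaction ids
#'   (generated if absent).
#' @param reversible logical vector of length J; \code{TRUE} for reactions
#'   that may carry flux in either direction. Irreversible reactions are
#'   constrained to nonnegative flux.
#' @param target_reaction integer index (1-based) of the target reaction,
#'   whose flux is proportional to the phenotype. Defaults to the last
#'   column.
#' @param overrides optional data frame with columns \code{genotype},
#'   \code{metabolite}, \code{reaction}, \code{coefficient}; \code{genotype}
#'   is a 1-based genotype index (or genotype id once attached to a
#'   dataset), \code{metabolite}/\code{reaction} are 1-based indices.
#' @return An object of class \code{flux_network}.
#' @seealso [validate_network()], [balance_residuals()]
#' @export
reaction_network <- function(coefficients, reversible,
                             target_reaction = ncol(coefficients),
                             overrides = NULL) {
  coefficients <- as.matrix(coefficients)
  storage.mode(coefficients) <- "double"
  K <- nrow(coefficients); J <- ncol(coefficients)
  if (is.null(rownames(coefficients)))
    rownames(coefficients) <- sprintf("met%03d", seq_len(K))
  if (is.null(colnames(coefficients)))
    colnames(coefficients) <- sprintf("rxn%03d", seq_len(J))
  reversible <- as.logical(reversible)
  if (length(reversible) != J)
    stop("`reversible` must have one entry per reaction (", J, "), got ",
         length(reversible), call. = FALSE)
  if (!is.null(overrides)) {
    overrides <- as.data.frame(overrides)
    need <- c("genotype", "metabolite", "reaction", "coefficient")
    if (!all(need %in% names(overrides)))
      stop("overrides must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
  }
  structure(list(
    metabolite_ids = rownames(coefficients),
    reaction_ids = colnames(coefficients),
    coefficients = coefficients,
    reversible = reversible,
    target_reaction = as.integer(target_reaction),
    overrides = overrides
  ), class = "flux_network")
}

#' @export
print.flux_network <- function(x, ...) {
  K <- nrow(x$coefficients); J <- ncol(x$coefficients)
  cat("flux_network:", K, "metabolites x", J, "reactions\n")
  cat("  irreversible:", sum(!x$reversible), " reversible:", sum(x$reversible), "\n")
  cat("  target reaction:", x$reaction_ids[x$target_reaction],
      sprintf("(column %d)", x$target_reaction), "\n")
  if (!is.null(x$overrides))
    cat("  genotype-specific overrides:", nrow(x$overrides), "\n")
  invisible(x)
}

#' Validate a reaction network
#'
#' Checks the structural invariants of a network: the reversibility flags
#' partition the reaction set, every metabolite participates in at least one
#' reaction, the target reaction index is in range, and overrides (if
#' present) point at existing cells. Returns a character vector of
#' human-readable violations; an empty vector means the network is
#' well-formed.
#'
#' @param network a [reaction_network()] object.
#' @return character vector of violation messages (empty if valid).
#' @export
validate_network <- function(network) {
  rep <- character(0)
  M <- network$coefficients
  K <- nrow(M); J <- ncol(M)
  if (length(network$reversible) != J)
    rep <- c(rep, sprintf("reversibility flags (%d) do not match reaction count (%d)",
                          length(network$reversible), J))
  if (anyNA(network$reversible))
    rep <- c(rep, paste("reactions with undetermined reversibility:",
                        paste(network$reaction_ids[is.na(network$reversible)],
                              collapse = ", ")))
  zero_rows <- which(apply(M != 0, 1, sum) == 0)
  for (k in zero_rows)
    rep <- c(rep, sprintf("metabolite %s (row %d) has no nonzero coefficient",
                          network$metabolite_ids[k], k))
  if (network$target_reaction < 1L || network$target_reaction > J)
    rep <- c(rep, sprintf("target reaction index %d outside 1..%d",
                          network$target_reaction, J))
  if (!all(is.finite(M)))
    rep <- c(rep, "non-finite stoichiometric coefficients present")
  if (!is.null(network$overrides)) {
    ov <- network$overrides
    bad_m <- ov$metabolite < 1 | ov$metabolite > K
    bad_r <- ov$reaction < 1 | ov$reaction > J
    if (any(bad_m | bad_r))
      rep <- c(rep, sprintf("%d override rows point outside the matrix",
                            sum(bad_m | bad_r)))
  }
  rep
}

#' Effective stoichiometry matrix of one genotype
#'
#' The base coefficient matrix with that genotype's sparse overrides
#' applied.
#'
#' @param network a [reaction_network()].
#' @param genotype 1-based genotype index.
#' @return K x J numeric matrix.
#' @export
effective_stoichiometry <- function(network, genotype) {
  M <- network$coefficients
  ov <- network$overrides
  if (!is.null(ov)) {
    ov <- ov[ov$genotype == genotype, , drop = FALSE]
    if (nrow(ov) > 0)
      M[cbind(ov$metabolite, ov$reaction)] <- ov$coefficient
  }
  M
}

#' Steady-state balance residuals
#'
#' For each genotype i and metabolite k computes the net production
#' \eqn{M_{i,k} V_i^T} under genotype i's effective stoichiometry. At exact
#' steady state (production balances consumption for every metabolite) the
#' result is the zero matrix.
#'
#' @param network a [reaction_network()].
#' @param fluxes a [flux_table()] or N x J numeric matrix of fluxes.
#' @return N x K matrix of residuals (rows genotypes, columns metabolites).
#' @export
balance_residuals <- function(network, fluxes) {
  V <- if (inherits(fluxes, "flux_table")) fluxes$values else as.matrix(fluxes)
  J <- ncol(network$coefficients)
  if (ncol(V) != J)
    stop("flux table has ", ncol(V), " reactions but network has ", J,
         " (reaction axis mismatch)", call. = FALSE)
  N <- nrow(V); K <- nrow(network$coefficients)
  R <- matrix(0.0, N, K, dimnames = list(rownames(V), network$metabolite_ids))
  if (is.null(network$overrides)) {
    R[] <- V %*% t(network$coefficients)
  } else {
    for (i in seq_len(N))
      R[i, ] <- effective_stoichiometry(network, i) %*% V[i, ]
  }
  R
}

#' Construct a flux table
#'
#' @param values N x J numeric matrix of reaction fluxes (genotypes in rows).
#' @param genotype_ids character vector of genotype ids (defaults to row
#'   names or generated).
#' @return object of class \code{flux_table}.
#' @export
flux_table <- function(values, genotype_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(genotype_ids))
    genotype_ids <- sprintf("g%03d", seq_len(nrow(values)))
  rownames(values) <- genotype_ids
  structure(list(values = values, genotype_ids = genotype_ids),
            class = "flux_table")
}

#' @export
print.flux_table <- function(x, ...) {
  cat("flux_table:", nrow(x$values), "genotypes x", ncol(x$values), "reactions\n")
  invisible(x)
}
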