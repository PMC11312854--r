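#' Construct a phenotype vector
#'
#' @param values numeric vector of trait values; \code{NA} marks unobserved
#'   (held-out) genotypes, mirrored in \code{mask}.
#' @param mask logical vector, \code{TRUE} where the phenotype is observed.
#'   Defaults to \code{!is.na(values)}.
#' @param genotype_ids genotype ids (default names or generated).
#' @return object of class \code{flux_phenotypes}.
#' @export
phenotype_vector <- function(values, mask = !is.na(values),
                             genotype_ids = names(values)) {
  values <- as.numeric(values)
  if (length(mask) != length(values))
    stop("mask length must match values", call. = FALSE)
  if (is.null(genotype_ids))
    genotype_ids <- sprintf("g%03d", seq_along(values))
  names(values) <- genotype_ids
  structure(list(values = values, mask = as.logical(mask),
                 genotype_ids = genotype_ids),
            class = "flux_phenotypes")
}

#' Assemble a dataset
#'
#' Bundles a network, kinship matrix and phenotypes (plus, for simulated
#' data, the true fluxes) and checks that all components agree on the
#' genotype set and ordering.
#'
#' @param network a [reaction_network()].
#' @param kinship a [kinship()] object.
#' @param phenotypes a [phenotype_vector()].
#' @param true_fluxes optional [flux_table()] of simulated true fluxes.
#' @param reference_genotype optional integer index of the reference
#'   genotype (the one whose fluxes anchor the QP training stage).
#' @param meta optional list of free-form metadata (seeds, config).
#' @return object of class \code{flux_dataset}.
#' @export
flux_dataset <- function(network, kinship, phenotypes, true_fluxes = NULL,
                         reference_genotype = NULL, meta = list()) {
  ids <- kinship$genotype_ids
  if (!identical(phenotypes$genotype_ids, ids))
    stop("phenotype genotype ids do not match kinship: first difference at ",
         which(phenotypes$genotype_ids != ids)[1], call. = FALSE)
  if (!is.null(true_fluxes)) {
    if (!identical(true_fluxes$genotype_ids, ids))
      stop("flux table genotype ids do not match kinship", call. = FALSE)
    if (ncol(true_fluxes$values) != length(network$reaction_ids))
      stop("flux table reaction count does not match network", call. = FALSE)
  }
  if (!is.null(reference_genotype)) {
    reference_genotype <- as.integer(reference_genotype)
    if (reference_genotype < 1L || reference_genotype > length(ids))
      stop("reference genotype index out of range", call. = FALSE)
  }
  structure(list(network = network, kinship = kinship,
                 phenotypes = phenotypes, true_fluxes = true_fluxes,
                 reference_genotype = reference_genotype, meta = meta),
            class = "flux_dataset")
}

#' @export
print.flux_dataset <- function(x, ...) {
  cat("flux_dataset:", length(x$kinship$genotype_ids), "genotypes,",
      nrow(x$network$coefficients), "metabolites,",
      ncol(x$network$coefficients), "reactions\n")
  cat("  observed phenotypes:", sum(x$phenotypes$mask), "\n")
  if (!is.null(x$true_fluxes)) cat("  true fluxes: stored (simulated data)\n")
  invisible(x)
}

n_genotypes <- function(dataset) length(dataset$kinship$genotype_ids)
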