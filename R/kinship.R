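#' Construct a kinship (genomic relationship) object
#'
#' Wraps an N x N genomic relationship matrix, checking symmetry and
#' positive semi-definiteness. Numerically indefinite matrices with smallest
#' eigenvalue in \code{[-1e-8, 0)} are repaired once by adding
#' \code{1e-8} to the diagonal; anything more indefinite is rejected, since
#' a large silent repair would change the model.
#'
#' @param values N x N numeric symmetric matrix.
#' @param genotype_ids genotype ids (default row names or generated).
#' @return object of class \code{flux_kinship}.
#' @export
kinship <- function(values, genotype_ids = rownames(values)) {
  G <- as.matrix(values)
  storage.mode(G) <- "double"
  if (nrow(G) != ncol(G)) stop("kinship matrix must be square", call. = FALSE)
  if (max(abs(G - t(G))) > 1e-10)
    stop("kinship matrix is not symmetric (max asymmetry ",
         format(max(abs(G - t(G)))), ")", call. = FALSE)
  G <- (G + t(G)) / 2
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8)
    stop("kinship matrix is indefinite (min eigenvalue ", format(ev_min),
         " < -1e-8)", call. = FALSE)
  if (ev_min < 0) G <- G + diag(1e-8, nrow(G))
  if (is.null(genotype_ids))
    genotype_ids <- sprintf("g%03d", seq_len(nrow(G)))
  dimnames(G) <- list(genotype_ids, genotype_ids)
  structure(list(values = G, genotype_ids = genotype_ids),
            class = "flux_kinship")
}

#' @export
print.flux_kinship <- function(x, ...) {
  cat("flux_kinship:", nrow(x$values), "genotypes\n")
  invisible(x)
}

#' VanRaden genomic relationship matrix from SNP dosages
#'
#' Computes \eqn{G = Z Z' / (2 \sum_p p(1-p))} where \eqn{Z} is the dosage
#' matrix centred by twice the column allele frequencies. Monomorphic
#' markers contribute nothing to the numerator or denominator; an input
#' consisting only of monomorphic markers is rejected (zero denominator).
#'
#' @param snp_dosages N x P numeric matrix of allele dosages coded 0/1/2;
#'   row names are genotype ids.
#' @return a [kinship()] object.
#' @export
vanraden_grm <- function(snp_dosages) {
  X <- as.matrix(snp_dosages)
  storage.mode(X) <- "double"
  if (ncol(X) < 1) stop("need at least one marker", call. = FALSE)
  p <- colMeans(X) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers are monomorphic; VanRaden denominator is zero",
         call. = FALSE)
  Z <- sweep(X, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  kinship(G, genotype_ids = rownames(X))
}
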