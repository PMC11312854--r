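# Dataset I/O. All files are plain TSV with full-precision numbers
# (%.17g), so save -> load round trips are lossless. Indices are 1-based
# in files; ids are carried verbatim.

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!is.null(required) && !all(required %in% names(df)))
    stop(path, ": missing column(s) ",
         paste(setdiff(required, names(df)), collapse = ", "), call. = FALSE)
  df
}

#' Save a dataset as a directory of TSV files
#'
#' Writes \code{network.tsv} (stoichiometry; column \code{metabolite} plus
#' one column per reaction), \code{reactions.tsv} (\code{reaction_id},
#' \code{reversible}, \code{is_target}), optional \code{overrides.tsv}
#' (genotype-specific coefficients), \code{kinship.tsv} (square matrix with
#' ids), \code{phenotypes.tsv} (\code{genotype_id}, \code{value}; held-out
#' values as NA), optional \code{true_fluxes.tsv}, and \code{metadata.json}.
#'
#' @param dataset a [flux_dataset()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- dataset$network
  ndf <- data.frame(metabolite = net$metabolite_ids, check.names = FALSE)
  for (j in seq_along(net$reaction_ids))
    ndf[[net$reaction_ids[j]]] <- net$coefficients[, j]
  write_tsv(ndf, file.path(dir, "network.tsv"))
  write_tsv(data.frame(reaction_id = net$reaction_ids,
                       reversible = as.integer(net$reversible),
                       is_target = as.integer(seq_along(net$reaction_ids) ==
                                              net$target_reaction)),
            file.path(dir, "reactions.tsv"))
  if (!is.null(net$overrides)) {
    ov <- net$overrides
    write_tsv(data.frame(
      genotype_id = dataset$kinship$genotype_ids[ov$genotype],
      metabolite_id = net$metabolite_ids[ov$metabolite],
      reaction_id = net$reaction_ids[ov$reaction],
      coefficient = ov$coefficient), file.path(dir, "overrides.tsv"))
  }
  G <- dataset$kinship$values
  kdf <- data.frame(genotype_id = rownames(G), check.names = FALSE)
  for (j in seq_len(ncol(G))) kdf[[colnames(G)[j]]] <- G[, j]
  write_tsv(kdf, file.path(dir, "kinship.tsv"))
  ph <- dataset$phenotypes
  vals <- ph$values; vals[!ph$mask] <- NA_real_
  write_tsv(data.frame(genotype_id = ph$genotype_ids, value = vals),
            file.path(dir, "phenotypes.tsv"))
  if (!is.null(dataset$true_fluxes)) {
    V <- dataset$true_fluxes$values
    fdf <- data.frame(genotype_id = rownames(V), check.names = FALSE)
    for (j in seq_len(ncol(V))) fdf[[net$reaction_ids[j]]] <- V[, j]
    write_tsv(fdf, file.path(dir, "true_fluxes.tsv"))
  }
  meta <- dataset$meta
  if (!is.null(dataset$reference_genotype))
    meta$reference_genotype_id <-
      dataset$kinship$genotype_ids[dataset$reference_genotype]
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a dataset saved by [save_dataset()]
#'
#' @param dir directory containing the TSV files.
#' @return a [flux_dataset()].
#' @export
load_dataset <- function(dir) {
  ndf <- read_tsv(file.path(dir, "network.tsv"), required = "metabolite")
  rdf <- read_tsv(file.path(dir, "reactions.tsv"),
                  required = c("reaction_id", "reversible", "is_target"))
  M <- as.matrix(ndf[, -1, drop = FALSE])
  rownames(M) <- ndf$metabolite
  if (!identical(colnames(M), as.character(rdf$reaction_id)))
    stop("network.tsv reaction columns do not match reactions.tsv order",
         call. = FALSE)
  if (!all(rdf$reversible %in% c(0L, 1L)))
    stop("reactions.tsv: `reversible` must be 0/1; offending reaction(s): ",
         paste(rdf$reaction_id[!rdf$reversible %in% c(0L, 1L)],
               collapse = ", "), call. = FALSE)
  if (sum(rdf$is_target) != 1L)
    stop("reactions.tsv must flag exactly one target reaction", call. = FALSE)

  kdf <- read_tsv(file.path(dir, "kinship.tsv"), required = "genotype_id")
  ids <- as.character(kdf$genotype_id)
  G <- as.matrix(kdf[, -1, drop = FALSE])
  if (!identical(colnames(G), ids))
    stop("kinship.tsv header does not match its genotype_id column",
         call. = FALSE)
  rownames(G) <- ids

  pdf <- read_tsv(file.path(dir, "phenotypes.tsv"),
                  required = c("genotype_id", "value"))
  missing_ids <- setdiff(as.character(pdf$genotype_id), ids)
  if (length(missing_ids) > 0)
    stop("phenotypes.tsv: genotype(s) absent from kinship: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  if (!identical(as.character(pdf$genotype_id), ids))
    stop("phenotypes.tsv genotype order must match kinship.tsv", call. = FALSE)
  if (!is.numeric(pdf$value))
    stop("phenotypes.tsv: non-numeric values in `value`", call. = FALSE)

  ov <- NULL
  ov_path <- file.path(dir, "overrides.tsv")
  if (file.exists(ov_path)) {
    odf <- read_tsv(ov_path, required = c("genotype_id", "metabolite_id",
                                          "reaction_id", "coefficient"))
    gi <- match(as.character(odf$genotype_id), ids)
    mi <- match(as.character(odf$metabolite_id), rownames(M))
    ri <- match(as.character(odf$reaction_id), colnames(M))
    if (anyNA(gi) || anyNA(mi) || anyNA(ri))
      stop("overrides.tsv refers to unknown ids (first bad row ",
           which(is.na(gi) | is.na(mi) | is.na(ri))[1], ")", call. = FALSE)
    ov <- data.frame(genotype = gi, metabolite = mi, reaction = ri,
                     coefficient = odf$coefficient)
  }

  net <- reaction_network(M, reversible = rdf$reversible == 1L,
                          target_reaction = which(rdf$is_target == 1L),
                          overrides = ov)

  tf <- NULL
  tf_path <- file.path(dir, "true_fluxes.tsv")
  if (file.exists(tf_path)) {
    fdf <- read_tsv(tf_path, required = "genotype_id")
    V <- as.matrix(fdf[, -1, drop = FALSE])
    rownames(V) <- as.character(fdf$genotype_id)
    tf <- flux_table(V)
  }

  meta <- list()
  meta_path <- file.path(dir, "metadata.json")
  if (file.exists(meta_path))
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  ref <- NULL
  if (!is.null(meta$reference_genotype_id)) {
    ref <- match(meta$reference_genotype_id, ids)
    meta$reference_genotype_id <- NULL
  }

  flux_dataset(network = net, kinship = kinship(G, ids),
               phenotypes = phenotype_vector(pdf$value, genotype_ids = ids),
               true_fluxes = tf, reference_genotype = ref, meta = meta)
}
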