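# Cross-validation harness: fold construction, per-fold Pearson accuracy,
# Mann-Whitney-Wilcoxon method comparisons with Bonferroni correction,
# and the benchmark orchestrator comparing GBLUP, predict-then-project QP
# and the joint Bayesian model over a grid of likelihood weights.

#' Default likelihood-weight grid
#'
#' The six weight values compared in the benchmark.
#' @return numeric vector c(0.16, 0.32, 0.48, 0.64, 0.80, 0.96).
#' @export
default_w_grid <- function() c(0.16, 0.32, 0.48, 0.64, 0.80, 0.96)

#' Random k-fold cross-validation assignments
#'
#' Uniformly random partitions with fold sizes differing by at most one,
#' repeated \code{n_repeats} times; deterministic given the seed.
#'
#' @param n_genotypes number of genotypes.
#' @param k folds per repeat (default 3).
#' @param n_repeats number of repeats (default 1).
#' @param seed integer seed.
#' @return data frame with columns \code{rep}, \code{fold},
#'   \code{genotype} (1-based index); class \code{cv_folds}.
#' @export
make_cv_folds <- function(n_genotypes, k = 3, n_repeats = 1, seed = 1L) {
  if (k > n_genotypes)
    stop("k (", k, ") exceeds the number of genotypes (", n_genotypes, ")",
         call. = FALSE)
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_repeats), function(r) {
    lab <- sample(rep(seq_len(k), length.out = n_genotypes))
    data.frame(rep = r, fold = lab, genotype = seq_len(n_genotypes))
  }))
  structure(out, seed = seed, class = c("cv_folds", "data.frame"))
}

# accepts a cv_folds (one repeat), a data frame, or a plain label vector
fold_labels <- function(folds, n, which_rep = 1) {
  if (is.data.frame(folds)) {
    fr <- folds[folds$rep == which_rep, , drop = FALSE]
    lab <- integer(n)
    lab[fr$genotype] <- fr$fold
    return(lab)
  }
  if (length(folds) != n)
    stop("fold labels must cover all ", n, " genotypes", call. = FALSE)
  as.integer(folds)
}

#' Load fold assignments from a TSV file
#'
#' Expects columns \code{genotype_id}, \code{fold} and optionally
#' \code{rep} (defaults to 1), so published fold divisions can be reused.
#'
#' @param path TSV file.
#' @param genotype_ids genotype ids defining the index order.
#' @return a \code{cv_folds} data frame.
#' @export
load_folds <- function(path, genotype_ids) {
  df <- read_tsv(path, required = c("genotype_id", "fold"))
  if (is.null(df$rep)) df$rep <- 1L
  idx <- match(as.character(df$genotype_id), genotype_ids)
  if (anyNA(idx))
    stop("fold file refers to unknown genotype(s): ",
         paste(unique(df$genotype_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  structure(data.frame(rep = as.integer(df$rep), fold = as.integer(df$fold),
                       genotype = idx),
            class = c("cv_folds", "data.frame"))
}

#' Per-fold Pearson correlation
#'
#' @param y_true,y_pred numeric vectors over all genotypes (predictions
#'   may be NA where a method failed).
#' @param folds fold labels (vector or \code{cv_folds} single repeat).
#' @return named numeric vector of per-fold correlations; folds with zero
#'   variance in either vector give NA with a warning.
#' @export
pearson_by_fold <- function(y_true, y_pred, folds) {
  lab <- fold_labels(folds, length(y_true))
  out <- vapply(sort(unique(lab)), function(f) {
    i <- which(lab == f & !is.na(y_pred) & !is.na(y_true))
    if (length(i) < 3) {
      warning("fold ", f, " has fewer than 3 usable predictions")
      return(NA_real_)
    }
    if (stats::sd(y_true[i]) == 0 || stats::sd(y_pred[i]) == 0) {
      warning("fold ", f, " has zero variance; correlation undefined")
      return(NA_real_)
    }
    stats::cor(y_true[i], y_pred[i])
  }, numeric(1))
  names(out) <- sort(unique(lab))
  out
}

#' Pairwise method comparison
#'
#' Two-sided Mann-Whitney-Wilcoxon tests on the pooled fold-level
#' accuracies of every method pair, Bonferroni-corrected over all pairs,
#' with figure-style significance letters (methods share a letter iff
#' their adjusted p-value is >= alpha).
#'
#' @param result benchmark result data frame with columns \code{method}
#'   and \code{R} (one row per fold; \code{method} should already encode
#'   the weight for weight-dependent methods).
#' @param alpha significance level after correction (default 0.05).
#' @return list with \code{pairs} (data frame: method1, method2, p_value,
#'   p_adjusted, significant) and \code{letters} (named character vector).
#' @export
compare_methods <- function(result, alpha = 0.05) {
  groups <- split(result$R[!is.na(result$R)],
                  result$method[!is.na(result$R)])
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2)
    stop("need at least two methods with accuracies", call. = FALSE)
  if (any(lengths(groups) < 5))
    warning("fewer than 5 fold-level accuracies for: ",
            paste(names(groups)[lengths(groups) < 5], collapse = ", "))
  nm <- names(groups)
  cmb <- utils::combn(length(nm), 2)
  pv <- apply(cmb, 2, function(ij) {
    x <- groups[[ij[1]]]; y <- groups[[ij[2]]]
    exact <- length(x) <= 20 && length(y) <= 20
    suppressWarnings(stats::wilcox.test(x, y, exact = exact)$p.value)
  })
  padj <- pmin(pv * ncol(cmb), 1)
  pairs <- data.frame(method1 = nm[cmb[1, ]], method2 = nm[cmb[2, ]],
                      p_value = pv, p_adjusted = padj,
                      significant = padj < alpha)
  # compact letter display: order methods by median accuracy, then insert
  # each into the first letter class it is compatible with
  ord <- order(-vapply(groups, stats::median, numeric(1)))
  different <- matrix(FALSE, length(nm), length(nm),
                      dimnames = list(nm, nm))
  for (p in seq_len(ncol(cmb)))
    different[nm[cmb[1, p]], nm[cmb[2, p]]] <-
      different[nm[cmb[2, p]], nm[cmb[1, p]]] <- padj[p] < alpha
  classes <- list()
  for (g in nm[ord]) {
    placed <- FALSE
    for (ci in seq_along(classes)) {
      if (!any(different[g, classes[[ci]]])) {
        classes[[ci]] <- c(classes[[ci]], g); placed <- TRUE
      }
    }
    if (!placed) classes[[length(classes) + 1]] <- g
  }
  letters_out <- stats::setNames(rep("", length(nm)), nm)
  for (ci in seq_along(classes))
    for (g in classes[[ci]])
      letters_out[g] <- paste0(letters_out[g], letters[ci])
  list(pairs = pairs, letters = letters_out)
}

#' Benchmark methods across simulated datasets
#'
#' For each dataset: builds a 3-fold cross-validation, estimates training
#' fluxes by QP once per fold, then evaluates the requested methods —
#' GBLUP on the phenotype, the predict-then-project QP pipeline, and the
#' joint Bayesian model for each likelihood weight (scaling recomputed per
#' fold from training data only). Accuracy is the per-fold Pearson
#' correlation between observed and predicted phenotypes of the held-out
#' genotypes.
#'
#' @param datasets a [flux_dataset()] or list of them (replicates).
#' @param methods subset of \code{c("gblup", "qp", "proposed")}.
#' @param weights likelihood-weight grid for the proposed model.
#' @param config a [model_config()] template (weight and seed are set per
#'   fit).
#' @param settings a [qp_settings()].
#' @param k folds (default 3).
#' @param seed master seed (folds and fit seeds derive from it).
#' @param verbose print progress.
#' @return data frame of class \code{benchmark_result} with columns
#'   \code{method} (label incl. weight), \code{base_method}, \code{W},
#'   \code{replicate}, \code{fold}, \code{R}, \code{constraint_cor}.
#' @export
run_benchmark <- function(datasets,
                          methods = c("gblup", "qp", "proposed"),
                          weights = default_w_grid(),
                          config = model_config(iterations = 1000,
                                                warmup = 500,
                                                simulation_jitter = TRUE),
                          settings = qp_settings(), k = 3, seed = 1L,
                          verbose = FALSE) {
  if (inherits(datasets, "flux_dataset")) datasets <- list(datasets)
  methods <- match.arg(methods, several.ok = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, length(datasets))
  rows <- list()
  for (r in seq_along(datasets)) {
    ds <- datasets[[r]]
    N <- n_genotypes(ds)
    y <- ds$phenotypes$values
    folds <- make_cv_folds(N, k, 1, seed = rep_seeds[r])
    lab <- fold_labels(folds, N)
    for (f in seq_len(k)) {
      test_idx <- which(lab == f)
      train_idx <- setdiff(seq_len(N), test_idx)
      need_flux <- any(c("qp", "proposed") %in% methods)
      Vt <- if (need_flux)
        estimate_training_fluxes(ds, train_idx, settings) else NULL

      if ("gblup" %in% methods) {
        fit <- reml_single_kernel(y[train_idx],
                                  ds$kinship$values[train_idx, train_idx])
        pr <- gblup_predict(fit, ds$kinship, y[train_idx], train_idx,
                            test_idx)
        rows[[length(rows) + 1]] <- data.frame(
          method = "GBLUP", base_method = "gblup", W = NA_real_,
          replicate = r, fold = f,
          R = fold_cor(y[test_idx], pr), constraint_cor = NA_real_)
      }
      if ("qp" %in% methods) {
        Uhat <- predict_flux_genetics(Vt, ds$kinship, train_idx, test_idx)
        pr <- rep(NA_real_, length(test_idx))
        for (t in seq_along(test_idx)) {
          v <- tryCatch(project_to_balance(
            Uhat[t, ], effective_stoichiometry(ds$network, test_idx[t]),
            !ds$network$reversible, settings), error = function(e) NULL)
          if (!is.null(v)) pr[t] <- v[ds$network$target_reaction]
        }
        rows[[length(rows) + 1]] <- data.frame(
          method = "QP", base_method = "qp", W = NA_real_,
          replicate = r, fold = f,
          R = fold_cor(y[test_idx], pr), constraint_cor = NA_real_)
      }
      if ("proposed" %in% methods) {
        ok <- stats::complete.cases(Vt$values)
        sc <- scaling_from_training(
          Vt$values[ok, , drop = FALSE],
          ds$kinship$values[train_idx[ok], train_idx[ok]],
          location_target = config$location_target,
          delta_mode = config$delta_mode)
        mask <- rep(FALSE, N); mask[train_idx] <- TRUE
        for (w in weights) {
          cfg <- config
          cfg$weight <- w
          cfg$seed <- (rep_seeds[r] + 7L * f +
                       round(1000 * w)) %% .Machine$integer.max
          fit <- tryCatch(fit_model(ds, mask, sc, cfg, init_fluxes = Vt),
                          error = function(e) e)
          if (inherits(fit, "error")) {
            # individual fold failures are recorded as missing
            warning(sprintf("proposed-model fit failed (rep %d fold %d W=%.2f): %s",
                            r, f, w, conditionMessage(fit)))
            rows[[length(rows) + 1]] <- data.frame(
              method = sprintf("PM-%.2f", w), base_method = "proposed",
              W = w, replicate = r, fold = f,
              R = NA_real_, constraint_cor = NA_real_)
            next
          }
          pr <- predict_phenotypes(fit, test_idx)$mean
          rows[[length(rows) + 1]] <- data.frame(
            method = sprintf("PM-%.2f", w), base_method = "proposed",
            W = w, replicate = r, fold = f,
            R = fold_cor(y[test_idx], pr),
            constraint_cor = constraint_adherence(fit, ds))
          if (verbose)
            message(sprintf("rep %d fold %d W=%.2f R=%.3f div=%d (%.1fs)",
                            r, f, w, rows[[length(rows)]]$R,
                            fit$divergences, fit$runtime_s))
        }
      }
    }
  }
  structure(do.call(rbind, rows),
            class = c("benchmark_result", "data.frame"))
}

fold_cor <- function(y, pred) {
  ok <- !is.na(pred) & !is.na(y)
  if (sum(ok) < 3 || stats::sd(y[ok]) == 0 || stats::sd(pred[ok]) == 0)
    return(NA_real_)
  stats::cor(y[ok], pred[ok])
}

#' Median accuracy by method
#'
#' @param result a [run_benchmark()] output.
#' @return data frame with method, W and median fold-level R.
#' @export
summarize_benchmark <- function(result) {
  agg <- stats::aggregate(R ~ method + base_method,
                          data = result[!is.na(result$R), ],
                          FUN = stats::median)
  agg$W <- result$W[match(agg$method, result$method)]
  agg[order(agg$base_method, agg$W), c("method", "base_method", "W", "R")]
}
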