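# Predict-then-project baseline: (i) per-genotype training fluxes from a
# QP anchored at the reference genotype's fluxes, (ii) per-reaction GBLUP
# prediction of test fluxes, (iii) QP projection of the predicted fluxes
# onto the steady-state polytope. The projected target-reaction flux is
# the phenotype prediction.

#' Settings of the QP stages
#'
#' @param use_additional_constraints impose the physiological box
#'   constraints linking the oxygenation/carboxylation and
#'   sucrose/starch reaction pairs (default off; see the vignette for why
#'   these constraints are pathological).
#' @param oxg_car_bounds lower/upper ratio bounds of carboxylation to
#'   oxygenation flux (defaults 0.94 and 3.81).
#' @param suc_sta_bounds lower/upper ratio bounds of starch synthesis to
#'   sucrose synthesis flux (defaults 0.79 and 3.37).
#' @param constraint_reactions integer vector of the four reaction indices
#'   (oxygenation, carboxylation, sucrose, starch) the bounds apply to;
#'   required when the constraints are on.
#' @param feas_tol solver feasibility tolerance (default 1e-8).
#' @param zero_tol denominators below this magnitude switch the
#'   corresponding objective term from relative to absolute deviation.
#' @return object of class \code{qp_settings}.
#' @export
qp_settings <- function(use_additional_constraints = FALSE,
                        oxg_car_bounds = c(0.94, 3.81),
                        suc_sta_bounds = c(0.79, 3.37),
                        constraint_reactions = NULL,
                        feas_tol = 1e-8, zero_tol = 1e-6) {
  if (use_additional_constraints) {
    if (is.null(constraint_reactions) || length(constraint_reactions) != 4)
      stop("constraint_reactions must give the four reaction indices ",
           "(oxygenation, carboxylation, sucrose, starch)", call. = FALSE)
    if (anyDuplicated(constraint_reactions))
      stop("constraint_reactions must be distinct", call. = FALSE)
  }
  stopifnot(oxg_car_bounds[1] > 0, oxg_car_bounds[1] < oxg_car_bounds[2],
            suc_sta_bounds[1] > 0, suc_sta_bounds[1] < suc_sta_bounds[2])
  structure(list(use_additional_constraints = use_additional_constraints,
                 oxg_car_bounds = oxg_car_bounds,
                 suc_sta_bounds = suc_sta_bounds,
                 constraint_reactions = constraint_reactions,
                 feas_tol = feas_tol, zero_tol = zero_tol),
            class = "qp_settings")
}

# ratio-pair inequalities as A v <= b rows
additional_constraint_rows <- function(settings, J) {
  cr <- settings$constraint_reactions
  A <- matrix(0, 4, J)
  A[1, cr[2]] <- -1; A[1, cr[1]] <- settings$oxg_car_bounds[1]  # car >= lo*oxg
  A[2, cr[2]] <- 1;  A[2, cr[1]] <- -settings$oxg_car_bounds[2] # car <= hi*oxg
  A[3, cr[4]] <- -1; A[3, cr[3]] <- settings$suc_sta_bounds[1]
  A[4, cr[4]] <- 1;  A[4, cr[3]] <- -settings$suc_sta_bounds[2]
  A
}

# Solve min sum_j (v_j/u_j - 1)^2 subject to Meq v = beq, v_j >= 0 for
# irreversible j, optional extra inequalities Ain v <= bin. Terms with
# |u_j| < zero_tol use absolute deviation scaled by the median |u|.
solve_relative_qp <- function(u, Meq, beq, irrev, settings,
                              Ain = NULL, bin = NULL, extra_eq = NULL) {
  J <- length(u)
  small <- abs(u) < settings$zero_tol
  scale_abs <- stats::median(abs(u[!small]))
  if (!is.finite(scale_abs) || scale_abs <= 0) scale_abs <- 1
  wt <- ifelse(small, 1 / scale_abs^2, 1 / u^2)
  C <- diag(2 * wt, J)
  d <- ifelse(small, -2 * u / scale_abs^2, -2 / u)
  if (!is.null(extra_eq)) {
    Meq <- rbind(Meq, extra_eq$A)
    beq <- c(beq, extra_eq$b)
  }
  # drop linearly dependent balance rows (overridden coefficients can make
  # the equality system rank deficient for pathological draws)
  qr_eq <- qr(t(Meq))
  if (qr_eq$rank < nrow(Meq)) {
    keep <- qr_eq$pivot[seq_len(qr_eq$rank)]
    Meq <- Meq[keep, , drop = FALSE]; beq <- beq[keep]
  }
  # nonnegativity of irreversible fluxes as inequality rows (-v_j <= 0)
  if (any(irrev)) {
    nn <- -diag(1, J)[irrev, , drop = FALSE]
    Ain <- rbind(Ain, nn)
    bin <- c(bin, rep(0, sum(irrev)))
  }
  sol <- tryCatch(
    pracma::quadprog(C, d, A = Ain, b = bin, Aeq = Meq, beq = beq),
    error = function(e) e)
  if (inherits(sol, "error") || any(!is.finite(sol$xmin)))
    stop("QP infeasible or solver failure: ",
         if (inherits(sol, "error")) conditionMessage(sol) else "nonfinite",
         call. = FALSE)
  v <- sol$xmin
  viol <- max(abs(Meq %*% v - beq))
  if (any(irrev & v < -settings$feas_tol) ||
      viol > max(1e-6, settings$feas_tol * 100))
    stop(sprintf(paste0("QP solution violates constraints (balance %.2g, ",
                        "min irreversible flux %.2g)"),
                 viol, min(v[irrev], Inf)), call. = FALSE)
  v
}

#' Estimate per-genotype training fluxes
#'
#' For each training genotype solves a QP anchored at the reference
#' genotype's fluxes: minimize the relative deviation
#' \eqn{\sum_j (V_j/V_{ref,j} - 1)^2} subject to that genotype's
#' steady-state balance, nonnegative irreversible fluxes, and the target
#' flux fixed at \eqn{V_{ref,J} \, Y_i / Y_{ref}} (the biomass-ratio
#' condition).
#'
#' @param dataset a [flux_dataset()] (the reference genotype's true fluxes
#'   and phenotype act as known side information).
#' @param train_idx indices of training genotypes.
#' @param settings a [qp_settings()].
#' @param reference_fluxes optional numeric length-J vector overriding the
#'   reference fluxes (defaults to the dataset's stored true fluxes of the
#'   reference genotype).
#' @return a [flux_table()] over \code{train_idx}; failed genotypes get
#'   \code{NA} rows and are listed in the \code{failures} attribute.
#' @export
estimate_training_fluxes <- function(dataset, train_idx, settings =
                                       qp_settings(),
                                     reference_fluxes = NULL) {
  net <- dataset$network
  J <- ncol(net$coefficients)
  ref <- dataset$reference_genotype
  if (is.null(ref)) stop("dataset has no reference genotype", call. = FALSE)
  if (is.null(reference_fluxes)) {
    if (is.null(dataset$true_fluxes))
      stop("no reference fluxes available", call. = FALSE)
    reference_fluxes <- dataset$true_fluxes$values[ref, ]
  }
  y <- dataset$phenotypes$values
  y_ref <- y[ref]
  if (!is.finite(y_ref) || abs(y_ref) < 1e-12)
    stop("reference phenotype unavailable or zero", call. = FALSE)
  irrev <- !net$reversible
  tj <- net$target_reaction
  Ain <- NULL; bin <- NULL
  if (settings$use_additional_constraints) {
    Ain <- additional_constraint_rows(settings, J); bin <- rep(0, 4)
  }
  V <- matrix(NA_real_, length(train_idx), J)
  fails <- character(0)
  for (t in seq_along(train_idx)) {
    i <- train_idx[t]
    Mi <- effective_stoichiometry(net, i)
    target_row <- matrix(0, 1, J); target_row[1, tj] <- 1
    res <- tryCatch(
      solve_relative_qp(reference_fluxes, Mi, rep(0, nrow(Mi)), irrev,
                        settings, Ain, bin,
                        extra_eq = list(A = target_row,
                                        b = reference_fluxes[tj] *
                                            y[i] / y_ref)),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails <- c(fails, sprintf("%s: %s",
                                dataset$kinship$genotype_ids[i],
                                conditionMessage(res)))
    } else V[t, ] <- res
  }
  out <- flux_table(V, dataset$kinship$genotype_ids[train_idx])
  attr(out, "failures") <- fails
  out
}

#' Per-reaction GBLUP prediction of test-genotype fluxes
#'
#' Fits the single-kernel mixed model to each reaction's training fluxes
#' and predicts the genetic flux values of the test genotypes. Reactions
#' whose REML fit fails fall back to the training mean.
#'
#' @param training_fluxes [flux_table()] over the training genotypes (from
#'   [estimate_training_fluxes()]; rows with NA are dropped).
#' @param kin full [kinship()] over all genotypes.
#' @param train_idx,test_idx genotype index vectors.
#' @return |test| x J matrix of predicted fluxes.
#' @export
predict_flux_genetics <- function(training_fluxes, kin, train_idx,
                                  test_idx) {
  Vt <- if (inherits(training_fluxes, "flux_table")) training_fluxes$values
        else as.matrix(training_fluxes)
  ok <- stats::complete.cases(Vt)
  Vt <- Vt[ok, , drop = FALSE]
  train_idx <- train_idx[ok]
  J <- ncol(Vt)
  G <- if (inherits(kin, "flux_kinship")) kin$values else kin
  out <- matrix(NA_real_, length(test_idx), J,
                dimnames = list(rownames(G)[test_idx], colnames(Vt)))
  for (j in seq_len(J)) {
    pred <- tryCatch({
      fit <- reml_single_kernel(Vt[, j], G[train_idx, train_idx])
      gblup_predict(fit, G, Vt[, j], train_idx, test_idx)
    }, error = function(e) NULL)
    if (is.null(pred)) pred <- rep(mean(Vt[, j]), length(test_idx))
    out[, j] <- pred
  }
  out
}

#' Project predicted fluxes onto the steady-state polytope
#'
#' Finds the flux vector minimizing the relative deviation
#' \eqn{\sum_j (V_j/U_j - 1)^2} from the predicted fluxes \code{u_row},
#' subject to the genotype's steady-state balance, nonnegativity of
#' irreversible fluxes, and (optionally) the physiological ratio-pair
#' constraints.
#'
#' @param u_row length-J vector of predicted fluxes.
#' @param M_genotype K x J effective stoichiometry matrix of the genotype.
#' @param irrev logical length-J irreversibility flags.
#' @param settings a [qp_settings()].
#' @return length-J balanced flux vector.
#' @export
project_to_balance <- function(u_row, M_genotype, irrev,
                               settings = qp_settings()) {
  Ain <- NULL; bin <- NULL
  if (settings$use_additional_constraints) {
    Ain <- additional_constraint_rows(settings, length(u_row))
    bin <- rep(0, 4)
  }
  solve_relative_qp(u_row, M_genotype, rep(0, nrow(M_genotype)), irrev,
                    settings, Ain, bin)
}

#' Predict-then-project pipeline over cross-validation folds
#'
#' Chains training-flux estimation, per-reaction GBLUP and steady-state
#' projection for every fold; the prediction for a held-out genotype is
#' its projected target-reaction flux.
#'
#' @param dataset a [flux_dataset()].
#' @param folds a fold assignment from [make_cv_folds()] (single repeat)
#'   or an integer fold-label vector of length N.
#' @param settings a [qp_settings()].
#' @return data frame with \code{genotype_id}, \code{fold},
#'   \code{prediction} (NA where a stage failed), and attribute
#'   \code{flux_tables} (per-fold projected test fluxes).
#' @export
qp_predict_pipeline <- function(dataset, folds, settings = qp_settings()) {
  fold_lab <- fold_labels(folds, n_genotypes(dataset))
  net <- dataset$network
  irrev <- !net$reversible
  tj <- net$target_reaction
  N <- n_genotypes(dataset)
  pred <- rep(NA_real_, N)
  flux_list <- list()
  for (f in sort(unique(fold_lab))) {
    test_idx <- which(fold_lab == f)
    train_idx <- setdiff(seq_len(N), test_idx)
    Vt <- estimate_training_fluxes(dataset, train_idx, settings)
    Uhat <- predict_flux_genetics(Vt, dataset$kinship, train_idx, test_idx)
    Vproj <- matrix(NA_real_, length(test_idx), ncol(Uhat))
    for (t in seq_along(test_idx)) {
      i <- test_idx[t]
      v <- tryCatch(
        project_to_balance(Uhat[t, ], effective_stoichiometry(net, i),
                           irrev, settings),
        error = function(e) NULL)
      if (!is.null(v)) {
        Vproj[t, ] <- v
        pred[i] <- v[tj]
      }
    }
    flux_list[[as.character(f)]] <-
      flux_table(Vproj, dataset$kinship$genotype_ids[test_idx])
  }
  out <- data.frame(genotype_id = dataset$kinship$genotype_ids,
                    fold = fold_lab, prediction = pred)
  attr(out, "flux_tables") <- flux_list
  out
}
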