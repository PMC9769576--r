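# The published 14-gene CRD prognostic risk score, median stratification,
# and an L1-penalized Cox path fitter (IRLS + cyclic coordinate descent)
# for re-deriving such signatures.

#' Construct a risk model
#'
#' @param coefficients Named numeric vector: gene -> coefficient.
#' @param provenance Free-text provenance note.
#' @return Object of class `RiskModel` with `genes`, `coefficients`,
#'   `provenance`.
#' @export
risk_model <- function(coefficients, provenance = "user") {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stop("coefficients must be named by gene symbol")
  if (anyDuplicated(names(coefficients))) stop("duplicate genes in model")
  if (!all(is.finite(coefficients))) stop("coefficients must be finite")
  structure(list(genes = names(coefficients),
                 coefficients = coefficients,
                 provenance = provenance),
            class = "RiskModel")
}

#' @export
print.RiskModel <- function(x, ...) {
  cat(sprintf("RiskModel (%s): %d genes\n", x$provenance, length(x$genes)))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' The published 14-gene liver CRD risk model
#'
#' The linear prognostic signature derived from circadian-rhythm-related
#' genes in liver hepatocellular carcinoma: the CRD risk score of a sample is
#' the sum of these 14 coefficients times the sample's expression of each
#' gene.
#'
#' @return A [risk_model()] with the 14 published (gene, coefficient) pairs.
#' @export
published_livercrd_model <- function() {
  risk_model(c(ENO1 = 0.112, STMN1 = 0.077, SLC1A7 = 0.108, RAB13 = 0.055,
               SRPRB = 0.019, UGDH = 0.019, RCAN2 = -0.039, HILPDA = 0.201,
               WEE1 = 0.042, HSPA8 = 0.159, BAMBI = 0.022, P2RX1 = -0.383,
               UBB = -0.053, MAFG = 0.048),
             provenance = "published 14-gene liver CRD signature")
}

#' Per-sample linear risk score
#'
#' `score_s = sum_g coef_g * expr[g, s]`. All model genes must be present in
#' the matrix; with `impute_zero = TRUE` missing genes contribute 0 and a
#' warning is emitted instead.
#'
#' @param expr An [expression_matrix()].
#' @param model A [risk_model()].
#' @param impute_zero Downgrade missing model genes to a warning.
#' @return Named numeric vector of per-sample risk scores.
#' @export
risk_score <- function(expr, model, impute_zero = FALSE) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(model, "RiskModel"))
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing) == length(model$genes))
    stop("no model gene is present in the expression matrix")
  if (length(missing)) {
    msg <- paste0("model gene(s) missing from the matrix: ",
                  paste(missing, collapse = ", "))
    if (impute_zero) warning(msg, "; treated as zero expression")
    else stop(msg)
  }
  present <- setdiff(model$genes, missing)
  drop(crossprod(unclass(expr)[present, , drop = FALSE],
                 model$coefficients[present]))[colnames(expr)]
}

#' Stratify samples at the median risk score
#'
#' Scores strictly above the (interpolated) median are labelled `"high"`,
#' the rest `"low"`; for an even number of distinct scores this gives an
#' exact half split.
#'
#' @param scores Named numeric vector (>= 2 samples).
#' @return Named character vector of `"high"`/`"low"` labels.
#' @export
stratify_by_median <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 samples to stratify")
  med <- stats::median(scores)
  lab <- ifelse(scores > med, "high", "low")
  if (all(lab == "low"))
    warning("all scores at or below the median (degenerate split); all samples labelled low")
  stats::setNames(lab, names(scores))
}

#' Fit an L1-penalized Cox proportional-hazards path with cross-validation
#'
#' Minimizes `-(1/n) * Breslow partial log-likelihood + lambda * sum(|beta|)`
#' by iteratively reweighted least squares with cyclic coordinate-descent
#' soft-thresholding updates. Predictors are standardized internally (mean 0,
#' sd 1) and coefficients returned on the original scale. The lambda grid
#' runs from `lambda_max` (smallest lambda with the all-zero solution) down
#' `n_lambda` log-spaced steps to `0.01 * lambda_max`. Cross-validated
#' partial-likelihood deviance (Verweij-van Houwelingen) selects
#' `lambda_min` by the minimum criterion; `n_repeats` re-randomizes the folds
#' and averages the deviance curves before selection.
#'
#' @param expr An [expression_matrix()] of candidate genes.
#' @param surv A [survival_table()]; samples are aligned by id with `expr`
#'   columns.
#' @param lambda_grid Optional decreasing lambda grid; auto-generated when
#'   `NULL`.
#' @param n_lambda Grid length for the auto grid (default 100).
#' @param n_folds CV folds (default 10).
#' @param n_repeats CV repetitions with re-randomized folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param standardize Standardize predictors internally (default TRUE).
#' @return Object of class `CoxPath`: `lambda`, `beta` (genes x lambda,
#'   original scale), `df` (nonzero count per lambda), `cv_deviance`,
#'   `cv_se`, `lambda_min`, `selected` ([risk_model()] at `lambda_min`).
#' @export
fit_lasso_cox <- function(expr, surv, lambda_grid = NULL, n_lambda = 100,
                          n_folds = 10, n_repeats = 10, seed = 1L,
                          standardize = TRUE) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(surv, "SurvivalTable"))
  common <- intersect(colnames(expr), surv$sample)
  if (length(common) < n_folds)
    stop("fewer aligned samples than CV folds")
  X0 <- t(unclass(expr)[, common, drop = FALSE])
  st <- surv[match(common, surv$sample), ]
  time <- st$time; event <- st$event
  if (sum(event) < 2) stop("need at least 2 observed events")
  n <- nrow(X0); p <- ncol(X0)
  ctr <- colMeans(X0)
  scl <- if (standardize) apply(X0, 2, stats::sd) else rep(1, p)
  if (any(scl == 0)) stop("constant predictor(s): ",
                          paste(colnames(X0)[scl == 0], collapse = ", "))
  X <- sweep(sweep(X0, 2, ctr), 2, scl, `/`)
  # work in the time-sorted domain throughout (fold subsets stay sorted)
  ord <- order(time)
  X <- X[ord, , drop = FALSE]; time <- time[ord]; event <- event[ord]
  g0 <- cox_derivs_sorted(time, event, rep(0, n))$grad
  lambda_max <- max(abs(crossprod(X, g0))) / n
  if (is.null(lambda_grid)) {
    lambda_grid <- exp(seq(log(lambda_max), log(0.01 * lambda_max),
                           length.out = n_lambda))
    # guard the top of the grid against round-off below lambda_max
    lambda_grid[1] <- lambda_max * (1 + 1e-6)
  } else {
    lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  }
  path_fit <- function(Xtr, ttr, etr, strict = TRUE) {
    # CV folds tolerate a capped fit (quasi-separation at tiny lambda on a
    # fold subset); the full-data path must converge
    cox_lasso_path_cpp(Xtr, ttr, etr, lambda_grid,
                       stop_on_nonconv = strict)$beta
  }
  B_full <- path_fit(X, time, event)
  # cross-validated deviance, averaged over repeats
  cv_mat <- matrix(0, n_repeats, length(lambda_grid))
  cv_se_mat <- matrix(0, n_repeats, length(lambda_grid))
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      folds <- sample(rep_len(seq_len(n_folds), n))
      dev_fold <- matrix(NA_real_, n_folds, length(lambda_grid))
      for (k in seq_len(n_folds)) {
        tr <- folds != k
        if (sum(event[tr]) < 2) next
        Btr <- path_fit(X[tr, , drop = FALSE], time[tr], event[tr],
                        strict = FALSE)
        eta_all <- X %*% Btr
        for (l in seq_along(lambda_grid)) {
          ll_all <- cox_derivs_sorted(time, event, eta_all[, l])$loglik
          ll_tr <- cox_derivs_sorted(time[tr], event[tr], eta_all[tr, l])$loglik
          dev_fold[k, l] <- -2 * (ll_all - ll_tr)
        }
      }
      cv_mat[r, ] <- colMeans(dev_fold, na.rm = TRUE)
      cv_se_mat[r, ] <- apply(dev_fold, 2, function(x)
        stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))))
    }
  })
  cv_dev <- colMeans(cv_mat)
  cv_se <- colMeans(cv_se_mat)
  sel <- which.min(cv_dev)
  beta_orig <- B_full / scl  # back to original predictor scale
  rownames(beta_orig) <- colnames(X0)
  nz <- beta_orig[, sel]
  nz <- nz[nz != 0]
  selected <- if (length(nz))
    risk_model(nz, provenance = sprintf("lasso-cox lambda_min = %.4g", lambda_grid[sel]))
  else NULL
  structure(list(lambda = lambda_grid, beta = beta_orig,
                 df = colSums(beta_orig != 0),
                 cv_deviance = cv_dev, cv_se = cv_se,
                 lambda_max = lambda_max,
                 lambda_min = lambda_grid[sel], selected = selected,
                 center = ctr, scale = scl,
                 n = n, n_events = sum(event)),
            class = "CoxPath")
}

#' @export
print.CoxPath <- function(x, ...) {
  cat(sprintf("CoxPath: %d lambdas, n = %d (%d events), lambda_min = %.4g (df = %d)\n",
              length(x$lambda), x$n, x$n_events, x$lambda_min,
              x$df[match(x$lambda_min, x$lambda)]))
  invisible(x)
}
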