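# Survival machinery from definitions: Kaplan-Meier product-limit estimate,
# log-rank test, Newton-Raphson Cox fits (Breslow ties), and IPCW
# time-dependent cumulative/dynamic AUC.
#
# Convention throughout: a subject censored exactly at an event time remains
# in the risk set for that time's events.

#' Kaplan-Meier product-limit estimate
#'
#' @param surv A [survival_table()].
#' @param group Optional character/factor vector aligned with `surv` rows
#'   (or named by sample id); one estimate per group.
#' @return For no `group`: an object of class `KMEstimate`, a data.frame with
#'   one row per distinct event time (`time`, `n_risk`, `n_event`, `surv`,
#'   `se`) and attribute `n` (subjects). With `group`: named list of
#'   `KMEstimate`s.
#' @export
km_estimate <- function(surv, group = NULL) {
  stopifnot(inherits(surv, "SurvivalTable"))
  if (!is.null(group)) {
    if (!is.null(names(group))) group <- group[surv$sample]
    if (length(group) != nrow(surv))
      stop("group must align with the survival table")
    out <- lapply(split(seq_len(nrow(surv)), group), function(i) {
      if (!length(i)) stop("empty group")
      km_estimate(surv[i, ])
    })
    return(out)
  }
  if (nrow(surv) == 0) stop("empty survival table")
  time <- surv$time; event <- surv$event
  ut <- sort(unique(time[event == 1]))
  if (!length(ut)) {
    km <- data.frame(time = numeric(0), n_risk = numeric(0),
                     n_event = numeric(0), surv = numeric(0), se = numeric(0))
  } else {
    n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
    n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
    s <- cumprod(1 - n_event / n_risk)
    gw <- cumsum(n_event / (n_risk * pmax(n_risk - n_event, 0)))
    se <- s * sqrt(ifelse(is.finite(gw), gw, NA_real_))
    km <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                     surv = s, se = se)
  }
  attr(km, "n") <- nrow(surv)
  class(km) <- c("KMEstimate", "data.frame")
  km
}

#' Median survival time from a KM estimate
#'
#' Smallest event time at which the survival curve drops to 0.5 or below;
#' `NA` ("not reached") when the curve never crosses 0.5.
#'
#' @param km A `KMEstimate` from [km_estimate()].
#' @return Median time, or `NA_real_` when not reached.
#' @export
median_survival <- function(km) {
  stopifnot(inherits(km, "KMEstimate"))
  i <- which(km$surv <= 0.5)
  if (!length(i)) return(NA_real_)
  km$time[min(i)]
}

#' Log-rank test
#'
#' At each distinct event time, observed events per group are compared with
#' their hypergeometric expectation given the risk sets. For two groups the
#' statistic is `(sum(O - E))^2 / sum(V)`; for g groups a quadratic form in
#' the (g-1)-dimensional O - E vector with its covariance. The p-value comes
#' from a chi-square distribution with g - 1 degrees of freedom.
#'
#' @param surv A [survival_table()].
#' @param groups Group label per sample (aligned with rows, or named by
#'   sample id).
#' @return Object of class `LogRankResult`: list with `statistic`, `df`,
#'   `p_value`, `observed`, `expected` per group.
#' @export
logrank_test <- function(surv, groups) {
  stopifnot(inherits(surv, "SurvivalTable"))
  if (!is.null(names(groups))) groups <- groups[surv$sample]
  if (length(groups) != nrow(surv))
    stop("groups must align with the survival table")
  groups <- factor(groups)
  g <- nlevels(groups)
  if (g < 2) stop("need at least 2 non-empty groups")
  if (any(table(groups) == 0)) stop("a group has no at-risk subjects")
  time <- surv$time; event <- surv$event
  ut <- sort(unique(time[event == 1]))
  if (!length(ut)) stop("no events observed")
  O <- E <- stats::setNames(numeric(g), levels(groups))
  V <- matrix(0, g, g, dimnames = list(levels(groups), levels(groups)))
  for (t in ut) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & time == t)
    n_gt <- vapply(levels(groups), function(l) sum(at_risk & groups == l),
                   numeric(1))
    d_gt <- vapply(levels(groups), function(l)
      sum(event == 1 & time == t & groups == l), numeric(1))
    O <- O + d_gt
    E <- E + d_t * n_gt / n_t
    if (n_t > 1) {
      frac <- n_gt / n_t
      Vt <- d_t * (n_t - d_t) / (n_t - 1) * (diag(frac, g) - tcrossprod(frac))
      V <- V + Vt
    }
  }
  u <- (O - E)[-g]
  Vsub <- V[-g, -g, drop = FALSE]
  stat <- if (all(Vsub == 0)) 0 else drop(t(u) %*% solve(Vsub, u))
  structure(list(statistic = stat, df = g - 1,
                 p_value = stats::pchisq(stat, g - 1, lower.tail = FALSE),
                 observed = O, expected = E),
            class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

# gradient, full information matrix and loglik of the Breslow partial
# likelihood at beta (X: n x p)
cox_derivs_full <- function(time, event, X, beta) {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  ord <- order(time)
  t_s <- time[ord]; d_s <- event[ord]
  X_s <- X[ord, , drop = FALSE]; e_s <- exp(eta[ord])
  r0 <- rev(cumsum(rev(e_s)))
  r1 <- apply(e_s * X_s, 2, function(col) rev(cumsum(rev(col))))
  r1 <- matrix(r1, nrow = n)
  # p x p reverse cumulative second moments, stored as n x p^2
  XX <- t(matrix(vapply(seq_len(n), function(i) as.vector(tcrossprod(X_s[i, ])),
                        numeric(p * p)), nrow = p * p))
  r2 <- apply(e_s * XX, 2, function(col) rev(cumsum(rev(col))))
  r2 <- matrix(r2, nrow = n)
  ut <- sort(unique(t_s[d_s == 1]))
  fu <- match(ut, t_s)
  du <- as.vector(table(t_s[d_s == 1]))
  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  for (k in seq_along(ut)) {
    i <- fu[k]
    D0 <- r0[i]; D1 <- r1[i, ]; D2 <- matrix(r2[i, ], p, p)
    ev <- which(d_s == 1 & t_s == ut[k])
    s_e <- colSums(X_s[ev, , drop = FALSE])
    ll <- ll + sum(eta[ord][ev]) - du[k] * log(D0)
    U <- U + s_e - du[k] * D1 / D0
    I <- I + du[k] * (D2 / D0 - tcrossprod(D1 / D0))
  }
  list(loglik = ll, grad = U, info = I)
}

#' Cox proportional-hazards fit (Newton-Raphson, Breslow ties)
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson with step
#' halving. Standard errors come from the inverse observed information;
#' Wald z and p per covariate. Also reports the score test at `beta = 0`
#' (for a single binary covariate this equals the log-rank statistic).
#'
#' @param surv A [survival_table()].
#' @param X Covariate matrix (samples x covariates) aligned with `surv` rows
#'   (or with rownames matching sample ids); a vector is treated as one
#'   covariate.
#' @param max_iter,tol Newton-Raphson controls.
#' @return Object of class `CoxFit`: `coef`, `se`, `hr`, `z`, `p`,
#'   `loglik`, `loglik_null`, `score_test`, `iter`, `converged`.
#' @export
cox_fit <- function(surv, X, max_iter = 25, tol = 1e-9) {
  stopifnot(inherits(surv, "SurvivalTable"))
  if (is.null(dim(X))) X <- matrix(X, ncol = 1,
                                   dimnames = list(NULL, "x"))
  X <- as.matrix(X)
  if (!is.null(rownames(X)) && all(surv$sample %in% rownames(X)))
    X <- X[surv$sample, , drop = FALSE]
  if (nrow(X) != nrow(surv)) stop("covariates must align with the survival table")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (sum(surv$event) < 1) stop("no events observed")
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank-deficient")
  time <- surv$time; event <- surv$event
  p <- ncol(X)
  beta <- rep(0, p)
  d0 <- cox_derivs_full(time, event, X, beta)
  score_stat <- drop(t(d0$grad) %*% solve(d0$info, d0$grad))
  ll_null <- d0$loglik
  ll <- d0$loglik; d <- d0
  converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    step <- solve(d$info, d$grad)
    beta_new <- beta + step
    d_new <- cox_derivs_full(time, event, X, beta_new)
    halvings <- 0
    while ((!is.finite(d_new$loglik) || d_new$loglik < ll - 1e-12) &&
           halvings < 20) {
      beta_new <- (beta + beta_new) / 2
      d_new <- cox_derivs_full(time, event, X, beta_new)
      halvings <- halvings + 1
    }
    if (!is.finite(d_new$loglik))
      stop(sprintf("Cox fit diverged at iteration %d (possible separation)", it))
    delta_ll <- d_new$loglik - ll
    beta <- beta_new; ll <- d_new$loglik; d <- d_new
    if (abs(delta_ll) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("Cox fit did not converge in %d iterations (last loglik change %.3g)",
                 max_iter, abs(ll - ll_null)))
  se <- sqrt(diag(solve(d$info)))
  z <- beta / se
  structure(list(coef = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 hr = stats::setNames(exp(beta), colnames(X)),
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 loglik = ll, loglik_null = ll_null,
                 score_test = score_stat, iter = it, converged = converged),
            class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  df <- data.frame(coef = x$coef, HR = x$hr, se = x$se, z = x$z, p = x$p)
  print(df)
  invisible(x)
}

#' Time-dependent cumulative/dynamic AUC
#'
#' For each horizon t, cases are subjects with an observed event by t and
#' controls are subjects still at risk beyond t. Censoring before t is
#' handled by inverse-probability-of-censoring weights from the KM estimate
#' of the censoring distribution (left limit at each case's event time);
#' score ties count 1/2. With no censoring this reduces to the empirical
#' binary AUC (Mann-Whitney) of event-by-t against the score.
#'
#' @param scores Named numeric risk scores (higher = higher risk).
#' @param surv A [survival_table()].
#' @param horizons Numeric vector of evaluation times (days).
#' @return Object of class `TimeROC`: data.frame with `horizon`, `auc`,
#'   `n_cases`, `n_controls`; `auc` is `NA` (flagged) when a horizon has no
#'   cases or no controls.
#' @export
time_dependent_auc <- function(scores, surv, horizons) {
  stopifnot(inherits(surv, "SurvivalTable"))
  if (!is.null(names(scores))) scores <- scores[surv$sample]
  if (length(scores) != nrow(surv))
    stop("scores must align with the survival table")
  time <- surv$time; event <- surv$event
  # KM of the censoring distribution (censoring is the "event")
  ut <- sort(unique(time[event == 0]))
  G_step <- if (length(ut)) {
    n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
    n_cens <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
    cumprod(1 - n_cens / n_risk)
  } else numeric(0)
  G_at <- function(t) {  # left-continuous G(t-)
    i <- findInterval(t - 1e-12, ut)
    if (i == 0) 1 else G_step[i]
  }
  res <- lapply(horizons, function(h) {
    is_case <- time <= h & event == 1
    is_ctrl <- time > h
    n_ca <- sum(is_case); n_co <- sum(is_ctrl)
    if (n_ca == 0 || n_co == 0)
      return(data.frame(horizon = h, auc = NA_real_,
                        n_cases = n_ca, n_controls = n_co))
    w <- vapply(time[is_case], G_at, numeric(1))
    if (any(w <= 0)) w[w <= 0] <- min(w[w > 0])
    w <- 1 / w
    sc_ca <- scores[is_case]; sc_co <- scores[is_ctrl]
    conc <- vapply(seq_len(n_ca), function(i)
      sum(sc_ca[i] > sc_co) + 0.5 * sum(sc_ca[i] == sc_co), numeric(1))
    data.frame(horizon = h, auc = sum(w * conc) / (sum(w) * n_co),
               n_cases = n_ca, n_controls = n_co)
  })
  out <- do.call(rbind, res)
  class(out) <- c("TimeROC", "data.frame")
  out
}
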