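#' Fit an Aalen additive-hazard model with time-varying coefficients
#'
#' Estimates cumulative regression functions \eqn{B_j(t) = \int_0^t b_j(s) ds}
#' for the additive hazard model
#' \deqn{h(t \mid X) = b_0(t) + b_1(t) x_1 + \dots + b_p(t) x_p,}
#' the model used throughout this package to relate covariates, immune-cell
#' abundances and (predicted) gene expression to overall survival without
#' assuming time-invariant effects.
#'
#' At each distinct event time the least-squares increment
#' \eqn{dB(t) = (X_R^\top X_R)^{-1} X_R^\top dN(t)} is computed over the
#' at-risk set \eqn{R(t)}; tied events are absorbed into one increment.
#' Estimation stops (curves are frozen) at the first event time where the
#' at-risk design loses full column rank. The per-covariate test is the
#' cumulative-effect statistic
#' \eqn{z_j = \hat B_j(\tau) / \widehat{SE}(\hat B_j(\tau))} with a
#' two-sided normal p-value, evaluated at \eqn{\tau} = the `tau_quantile`
#' quantile of the estimable event times. Near the end of follow-up the
#' at-risk count approaches the design dimension and the variance increments
#' (of order 1 / at-risk size) dominate the statistic, so the default
#' evaluates the cumulative effect at the 0.75 quantile; `tau_quantile = 1`
#' gives the literal last-event-time statistic. Variances use the
#' optional-variation estimator
#' \eqn{\sum_t (X^\top X)^{-1} X^\top \mathrm{diag}(dN) X (X^\top X)^{-1}}.
#'
#' @param time numeric vector of follow-up times (> 0).
#' @param event 0/1 event indicator (1 = death).
#' @param design numeric matrix, first column an intercept of ones. Column
#'   names are carried into the result.
#' @param tau_quantile quantile of the estimable event times at which the
#'   per-covariate test is evaluated (default 0.75; 1 = last event time).
#' @param sup_test also compute a supremum-type statistic
#'   \eqn{\max_t |\hat B_j(t)| / \widehat{SE}(\hat B_j(\tau))} per covariate
#'   (reported alongside, no p-value; sensitivity analysis only).
#' @return An object of class `aalen_fit`: list with `times` (event-time
#'   grid), `cumcoef` (steps of \eqn{\hat B}, one column per covariate),
#'   `cumvar` (pointwise variances), `z`, `p` (tests at `tau`), `tau`
#'   (evaluation time), `tau_last` (last estimable event time), `n`,
#'   `n_events`, and `frozen` (TRUE if estimation stopped before the last
#'   event time).
#' @examples
#' t <- c(1, 2, 3); d <- rep(1, 3)
#' f <- fit_additive_hazard(t, d, cbind(intercept = rep(1, 3)))
#' cumsum(1 / (3:1))  # Nelson-Aalen; equals f$cumcoef[, 1]
#' @export
fit_additive_hazard <- function(time, event, design, tau_quantile = 0.75,
                                sup_test = FALSE) {
  stopifnot(tau_quantile > 0, tau_quantile <= 1)
  design <- as.matrix(design)
  n <- length(time)
  stopifnot(length(event) == n, nrow(design) == n)
  if (anyNA(time) || anyNA(event) || anyNA(design)) {
    stop("fit_additive_hazard: missing values in time, event or design")
  }
  if (!all(design[, 1] == 1)) {
    stop("fit_additive_hazard: first design column must be an intercept of ones")
  }
  if (sum(event) == 0) stop("fit_additive_hazard: no events")
  p <- ncol(design)
  if (is.null(colnames(design))) {
    colnames(design) <- c("(intercept)", paste0("x", seq_len(p - 1)))[seq_len(p)]
  }

  ord <- order(time)
  time <- time[ord]; event <- event[ord]; design <- design[ord, , drop = FALSE]
  ev_times <- unique(time[event == 1])

  # At-risk Gram matrix maintained by downdating as subjects leave risk set.
  M <- crossprod(design)
  n_times <- length(ev_times)
  cumcoef <- matrix(0, n_times, p, dimnames = list(NULL, colnames(design)))
  cumvar <- matrix(0, n_times, p, dimnames = list(NULL, colnames(design)))
  B <- numeric(p)
  V <- matrix(0, p, p)
  left <- 0L  # subjects with time < current event time have left the risk set
  frozen <- FALSE
  k_stop <- n_times
  for (k in seq_len(n_times)) {
    tk <- ev_times[k]
    while (left < n && time[left + 1L] < tk) {
      xi <- design[left + 1L, ]
      M <- M - tcrossprod(xi)
      left <- left + 1L
    }
    Minv <- tryCatch(chol2inv(chol(M)), error = function(e) NULL)
    if (is.null(Minv)) { frozen <- TRUE; k_stop <- k - 1L; break }
    idx <- which(time == tk & event == 1)
    dN_X <- colSums(design[idx, , drop = FALSE])
    dB <- drop(Minv %*% dN_X)
    A <- Minv %*% t(design[idx, , drop = FALSE])  # p x d_k
    B <- B + dB
    V <- V + tcrossprod(A)
    cumcoef[k, ] <- B
    cumvar[k, ] <- diag(V)
  }
  if (k_stop == 0L) stop("fit_additive_hazard: design rank-deficient at first event time")
  cumcoef <- cumcoef[seq_len(k_stop), , drop = FALSE]
  cumvar <- cumvar[seq_len(k_stop), , drop = FALSE]
  times <- ev_times[seq_len(k_stop)]
  k_eval <- max(1L, min(k_stop, ceiling(tau_quantile * k_stop)))
  tau <- times[k_eval]
  se_tau <- sqrt(cumvar[k_eval, ])
  z <- ifelse(se_tau > 0, cumcoef[k_eval, ] / se_tau, NA_real_)
  pval <- 2 * stats::pnorm(-abs(z))
  out <- list(
    times = times, cumcoef = cumcoef, cumvar = cumvar,
    z = z, p = pval, tau = tau, tau_last = times[k_stop], k_eval = k_eval,
    n = n, n_events = sum(event), frozen = frozen
  )
  if (sup_test) {
    out$sup_stat <- apply(abs(cumcoef), 2, max) / se_tau
  }
  class(out) <- "aalen_fit"
  out
}

#' @export
print.aalen_fit <- function(x, ...) {
  cat(sprintf("Aalen additive-hazard fit: n = %d, events = %d, tau = %.3g%s\n",
              x$n, x$n_events, x$tau, if (x$frozen) " (frozen early)" else ""))
  tab <- data.frame(
    B_tau = x$cumcoef[x$k_eval, ],
    se = sqrt(x$cumvar[x$k_eval, ]),
    z = x$z, p = x$p
  )
  print(tab, digits = 4)
  invisible(x)
}

#' Fit a Cox proportional hazards model
#'
#' Thin wrapper over [survival::coxph()] with Efron tie handling, returning
#' the quantities the pipeline consumes (log hazard ratios, Wald tests,
#' maximised log partial likelihood). Monotone-likelihood separation is
#' detected and reported as an error naming the offending covariate.
#'
#' @param time,event follow-up time and 0/1 event indicator.
#' @param design numeric covariate matrix (no intercept column).
#' @return list of class `cox_fit`: `coef`, `se`, `p` (Wald), `loglik`
#'   (maximised), `loglik_null`, `n`, `n_events`, `covariates`.
#' @export
fit_cox <- function(time, event, design) {
  design <- as.matrix(design)
  n <- length(time)
  stopifnot(length(event) == n, nrow(design) == n)
  if (anyNA(time) || anyNA(event) || anyNA(design)) {
    stop("fit_cox: missing values")
  }
  if (sum(event) < 1) stop("fit_cox: no events")
  if (n < 2) stop("fit_cox: need at least two subjects")
  if (is.null(colnames(design))) colnames(design) <- paste0("x", seq_len(ncol(design)))
  fit <- survival::coxph(survival::Surv(time, event) ~ design,
                         ties = "efron", control = survival::coxph.control(eps = 1e-9))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  bad <- which(!is.finite(cf) | !is.finite(se) | abs(cf) > 15)
  if (length(bad)) {
    stop("fit_cox: separation / monotone likelihood for covariate(s): ",
         paste(colnames(design)[bad], collapse = ", "))
  }
  structure(list(
    coef = stats::setNames(cf, colnames(design)),
    se = stats::setNames(se, colnames(design)),
    p = stats::setNames(2 * stats::pnorm(-abs(cf / se)), colnames(design)),
    loglik = fit$loglik[2], loglik_null = fit$loglik[1],
    n = n, n_events = sum(event), covariates = colnames(design)
  ), class = "cox_fit")
}

#' Likelihood-ratio test between nested Cox models
#'
#' Compares a full and a reduced Cox fit on the same samples;
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{reduced})} with degrees of freedom
#' equal to the difference in covariate counts.
#'
#' @param full,reduced `cox_fit` objects; the reduced model's covariates must
#'   be a subset of the full model's, fitted on the same samples.
#' @return list with `chi2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "cox_fit"), inherits(reduced, "cox_fit"))
  if (!all(reduced$covariates %in% full$covariates)) {
    stop("likelihood_ratio_test: models are not nested (reduced has covariates absent from full)")
  }
  if (full$n != reduced$n || full$n_events != reduced$n_events) {
    stop("likelihood_ratio_test: models fitted on different samples")
  }
  df <- length(full$covariates) - length(reduced$covariates)
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Kaplan-Meier survival curves with median survival per group
#'
#' Product-limit estimator via [survival::survfit()]. The median is the first
#' time at which the estimated survival drops to 0.5 or below (`NA` if the
#' curve never reaches 0.5).
#'
#' @param time,event follow-up time and 0/1 event indicator.
#' @param group optional grouping factor (single group if omitted).
#' @return list with `curves` (data frame: group, time, surv, n_risk, n_event)
#'   and `median` (named numeric, one entry per group).
#' @export
kaplan_meier <- function(time, event, group = NULL) {
  n <- length(time)
  if (is.null(group)) group <- rep("all", n)
  group <- factor(group)
  if (any(table(group) < 1)) stop("kaplan_meier: empty group")
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  if (is.null(sf$strata)) {
    strata <- rep(levels(group)[1], length(sf$time))
  } else {
    strata <- rep(sub("^group=", "", names(sf$strata)), sf$strata)
  }
  curves <- data.frame(group = strata, time = sf$time, surv = sf$surv,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       stringsAsFactors = FALSE)
  med <- vapply(levels(group), function(g) {
    cg <- curves[curves$group == g, ]
    hit <- which(cg$surv <= 0.5)
    if (length(hit)) cg$time[hit[1]] else NA_real_
  }, numeric(1))
  list(curves = curves, median = med)
}
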