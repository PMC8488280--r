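# Survival statistics used by the signature pipeline. Standard estimators
# (Kaplan-Meier, log-rank, Cox PH, penalized Cox) are delegated to the
# survival and glmnet packages; the time-dependent ROC (nearest-neighbour
# estimator), the correlated concordance comparison (jackknife), restricted
# mean survival time and the model-based RMS curve are implemented here.

check_surv <- function(time, event) {
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (!all(is.finite(time)) || any(time <= 0)) stop("times must be finite and > 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  invisible(NULL)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function; censoring enters by
#' decrementing the risk set without an event.
#'
#' @param time survival times in days (> 0).
#' @param event 0/1 death indicator.
#' @return object of class `km_curve`: data.frame-backed list with event
#'   `time`, `surv`, `n_risk`, `n_event`, `n_censor`.
#' @export
km_fit <- function(time, event) {
  check_surv(time, event)
  if (length(time) == 0L) stop("empty input")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d event time(s), final S = %.3f\n",
              x$n, sum(x$n_event > 0), min(1, utils::tail(x$surv, 1))))
  invisible(x)
}

# S(t) from a km_curve (right-continuous step function).
km_surv_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  c(1, km$surv)[idx + 1L]
}

#' @export
plot.km_curve <- function(x, xlab = "Days", ylab = "Survival probability",
                          ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = xlab, ylab = ylab, ylim = c(0, 1), ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Classic one-degree-of-freedom log-rank chi-square built from the
#' hypergeometric expectation and variance of the group-1 event count at
#' each distinct event time.
#'
#' @param time,event survival outcome.
#' @param group two-level grouping (anything coercible to a factor with
#'   both levels present).
#' @return list of class `logrank_test`: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  g <- factor(group)
  if (nlevels(g) != 2L || any(table(g) == 0L)) {
    stop("`group` must contain exactly two non-empty groups")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  structure(list(chisq = unname(sd$chisq), df = 1L,
                 p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Vectorized log-rank screen over many binary markers
#'
#' Computes the two-group log-rank statistic of every row of a 0/1 marker
#' matrix (e.g. a `pair_matrix`) against one survival outcome in a single
#' pass of matrix products — algebraically identical to calling
#' [logrank_test()] per row, but usable on thousands of gene pairs.
#' Markers that are constant get `chisq = 0`, `p = 1`.
#'
#' @param markers integer 0/1 matrix, markers x samples.
#' @param time,event survival outcome, one entry per sample column.
#' @return data.frame with one row per marker: `chisq`, `p`.
#' @export
logrank_screen <- function(markers, time, event) {
  check_surv(time, event)
  m <- unclass(markers)
  if (ncol(m) != length(time)) stop("markers/sample mismatch")
  ut <- sort(unique(time[event == 1]))
  if (!length(ut)) stop("no events")
  # n x m_t indicator matrices: at risk at each event time; event at it
  at_risk <- outer(time, ut, `>=`) * 1
  died <- outer(time, ut, `==`) * event
  n_i <- colSums(at_risk)
  d_i <- colSums(died)
  n1 <- m %*% at_risk            # markers x event-times: group-1 at risk
  d1 <- m %*% died               # group-1 deaths
  expct <- sweep(n1, 2L, d_i / n_i, `*`)
  p1 <- sweep(n1, 2L, n_i, `/`)
  vmul <- ifelse(n_i > 1, d_i * (n_i - d_i) / (n_i - 1), 0)
  v <- sweep(p1 * (1 - p1), 2L, vmul, `*`)
  o_minus_e <- rowSums(d1 - expct)
  vv <- rowSums(v)
  chisq <- ifelse(vv > 0, o_minus_e^2 / vv, 0)
  data.frame(chisq = as.vector(chisq),
             p = ifelse(vv > 0,
                        stats::pchisq(as.vector(chisq), 1, lower.tail = FALSE),
                        1),
             row.names = rownames(m))
}

#' Cox proportional hazards fit
#'
#' Maximizes the Breslow-tie partial likelihood (Efron available via
#' `ties`) and attaches Wald standard errors, hazard ratios with 95%
#' confidence intervals and the Breslow baseline cumulative hazard.
#' Monotone likelihoods (perfect separation) are detected by a coefficient
#' bound and reported as an error rather than returned as huge hazard
#' ratios.
#'
#' @param time,event survival outcome.
#' @param covariates numeric matrix or data.frame of covariates (columns
#'   named).
#' @param ties "breslow" (default) or "efron".
#' @param beta_cap treat `max |beta| >` this as monotone likelihood.
#' @return object of class `cox_fit` with elements `coef`, `se`, `hr`,
#'   `ci_lower`, `ci_upper`, `p`, `loglik`, `baseline` (data.frame `time`,
#'   `cumhaz`), `n`, `n_event` and the underlying `coxph` fit.
#' @export
cox_fit <- function(time, event, covariates, ties = c("breslow", "efron"),
                    beta_cap = 15) {
  ties <- match.arg(ties)
  check_surv(time, event)
  if (sum(event) < 1) stop("need at least one event")
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  qrx <- qr(cbind(1, scale(x, scale = FALSE)))
  if (qrx$rank < ncol(x) + 1L) stop("covariates are collinear")
  df <- data.frame(time = time, event = event, x, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", colnames(x)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties,
                         control = survival::coxph.control(iter.max = 50,
                                                           eps = 1e-10))
  if (!is.null(fit$fail)) stop("Cox fit failed to converge: ", fit$fail)
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || max(abs(beta)) > beta_cap) {
    stop_pairsurv(
      "monotone partial likelihood (perfect separation); coefficients diverge",
      "pairsurv_monotone_likelihood")
  }
  se <- sqrt(diag(fit$var))
  bh <- survival::basehaz(fit, centered = FALSE)
  names(beta) <- names(se) <- colnames(x)
  structure(list(coef = beta, se = se, hr = exp(beta),
                 ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 loglik = fit$loglik[2L],
                 baseline = data.frame(time = bh$time, cumhaz = bh$hazard),
                 n = length(time), n_event = sum(event), ties = ties,
                 x = x, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_event))
  tab <- data.frame(coef = x$coef, HR = x$hr, lower95 = x$ci_lower,
                    upper95 = x$ci_upper, se = x$se, p = x$p)
  print(round(tab, digits))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$coef

#' LASSO-penalized Cox regression with k-fold cross-validation
#'
#' Fits the L1-penalized Cox partial likelihood over a log-spaced lambda
#' path (coordinate descent, via glmnet) and selects lambda by k-fold
#' cross-validated partial-likelihood deviance. Both the deviance minimum
#' (`lambda_min`) and the one-standard-error choice (`lambda_1se`, the
#' largest lambda whose CV deviance is within one SE of the minimum) are
#' returned. Covariates are not standardized by default so that each
#' coefficient stays interpretable as the log-hazard step of one pair
#' flip.
#'
#' @param x covariate matrix, samples x covariates (columns named).
#' @param time,event survival outcome.
#' Fold assignment is stratified by event status so every fold carries
#' its share of events; with heavy censoring this keeps the fold-level
#' deviance comparable across folds, which the one-standard-error rule
#' relies on.
#'
#' @param nfolds number of CV folds (default 10).
#' @param seed integer seed fixing the fold assignment.
#' @param standardize standardize covariates internally (default FALSE).
#' @param ... further arguments for [glmnet::cv.glmnet()] (e.g.
#'   `lambda.min.ratio` to extend the path toward the unpenalized fit).
#' @return object of class `cox_lasso_cv`: `lambda` grid, `beta`
#'   (covariates x lambda coefficient matrix), `cvm`, `cvsd`,
#'   `lambda_min`, `lambda_1se`, `nfolds`, `seed`, `foldid`.
#' @export
cox_lasso_cv <- function(x, time, event, nfolds = 10L, seed = 1L,
                         standardize = FALSE, ...) {
  check_surv(time, event)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (sum(event) < nfolds) {
    stop(sprintf("only %d events for %d folds; reduce nfolds",
                 sum(event), nfolds))
  }
  foldid <- integer(nrow(x))
  with_seed(seed, for (g in unique(event)) {
    idx <- which(event == g)
    foldid[idx] <- sample(rep(seq_len(nfolds), length.out = length(idx)))
  })
  y <- survival::Surv(time, event)
  cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                          standardize = standardize,
                          type.measure = "deviance", ...)
  beta <- as.matrix(cv$glmnet.fit$beta)
  structure(list(lambda = cv$lambda, beta = beta, cvm = cv$cvm,
                 cvsd = cv$cvsd, lambda_min = cv$lambda.min,
                 lambda_1se = cv$lambda.1se, nfolds = nfolds, seed = seed,
                 foldid = foldid, glmnet_fit = cv$glmnet.fit, cv = cv),
            class = "cox_lasso_cv")
}

#' @export
print.cox_lasso_cv <- function(x, ...) {
  k_min <- sum(coef_at_lambda(x, x$lambda_min) != 0)
  k_1se <- sum(coef_at_lambda(x, x$lambda_1se) != 0)
  cat(sprintf(
    "LASSO-Cox CV (%d folds): lambda_min = %.4g (%d nonzero), lambda_1se = %.4g (%d nonzero)\n",
    x$nfolds, x$lambda_min, k_min, x$lambda_1se, k_1se))
  invisible(x)
}

#' Coefficients of a penalized Cox path at a given lambda
#' @param cvfit a `cox_lasso_cv` object.
#' @param lambda penalty value (interpolated onto the fitted path).
#' @return named coefficient vector.
#' @export
coef_at_lambda <- function(cvfit, lambda) {
  cf <- as.matrix(stats::coef(cvfit$glmnet_fit, s = lambda))
  stats::setNames(as.vector(cf), rownames(cf))
}

#' Time-dependent ROC curve by nearest-neighbour estimation
#'
#' Cumulative-case / dynamic-control ROC at a fixed horizon: cases are
#' subjects failing by the horizon, controls those surviving beyond it.
#' The conditional survival S(horizon | marker) is estimated by a weighted
#' Kaplan-Meier over a nearest-neighbour window in marker percentile
#' (symmetric window of half-width `span`), which handles censoring and
#' guarantees monotone sensitivity/specificity in the threshold. AUC is
#' the trapezoidal area over the curve.
#'
#' @param marker numeric risk marker, higher = riskier.
#' @param time,event survival outcome.
#' @param horizon evaluation time in days, within the observed range.
#' @param span nearest-neighbour half-width in percentile units; default
#'   `0.25 * n^-0.2`, a conventional rate for this smoother.
#' @return object of class `td_roc`: `thresholds`, `sens`, `fpr`, `auc`,
#'   `horizon`, `span`.
#' @export
td_roc <- function(marker, time, event, horizon, span = NULL) {
  check_surv(time, event)
  n <- length(marker)
  if (n != length(time)) stop("marker/outcome length mismatch")
  if (!all(is.finite(marker))) stop("marker must be finite")
  if (horizon <= 0 || horizon > max(time)) {
    stop("horizon must lie within the observed time range")
  }
  span <- span %||% (0.25 * n^(-0.2))
  if (span <= 0 || span >= 1) stop("span must lie in (0,1)")

  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  pct <- (rank(marker, ties.method = "average") - 0.5) / n
  pct_s <- pct[ord]
  grp <- match(t_s, unique(t_s))             # tie groups in time order
  first_of_grp <- !duplicated(grp)
  ug_t <- t_s[first_of_grp]
  use_grp <- which(ug_t <= horizon)

  surv_h <- vapply(seq_len(n), function(i) {
    w <- as.numeric(abs(pct_s - pct_s[i]) <= span)
    at_risk <- rev(cumsum(rev(w)))
    dsum <- rowsum(w * e_s, grp)[, 1L]
    nrisk <- at_risk[first_of_grp]
    keep <- use_grp[dsum[use_grp] > 0 & nrisk[use_grp] > 0]
    if (!length(keep)) return(1)
    prod(1 - dsum[keep] / nrisk[keep])
  }, numeric(1))
  surv_h <- surv_h[order(ord)]               # back to input order

  p_case <- 1 - surv_h
  if (sum(p_case) <= 1e-12) stop("no cases by the horizon")
  if (sum(surv_h) <= 1e-12) stop("no controls beyond the horizon")

  thr <- sort(unique(marker))
  cuts <- c(-Inf, thr)
  above <- outer(marker, cuts, `>`) * 1      # n x thresholds
  sens <- as.vector(crossprod(above, p_case)) / sum(p_case)
  fpr <- as.vector(crossprod(above, surv_h)) / sum(surv_h)
  o <- order(fpr, sens)
  xs <- c(0, fpr[o], 1); ys <- c(0, sens[o], 1)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  structure(list(thresholds = cuts, sens = sens, fpr = fpr, auc = auc,
                 horizon = horizon, span = span, n = n),
            class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("Time-dependent ROC at t = %g days: AUC = %.3f (span %.3f, n = %d)\n",
              x$horizon, x$auc, x$span, x$n))
  invisible(x)
}

#' @export
plot.td_roc <- function(x, ...) {
  o <- order(x$fpr, x$sens)
  graphics::plot(c(0, x$fpr[o], 1), c(0, x$sens[o], 1), type = "l",
                 xlab = "1 - specificity", ylab = "Sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Optimal risk cutoff from a time-dependent ROC curve
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the curve's
#' thresholds; ties are broken toward the smaller threshold.
#'
#' @param roc a `td_roc` object.
#' @return the cutoff (a marker value).
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "td_roc"))
  j <- roc$sens - roc$fpr
  if (diff(range(j)) < 1e-12) stop("flat ROC curve; no informative cutoff")
  finite <- is.finite(roc$thresholds)
  jf <- j[finite]; thrf <- roc$thresholds[finite]
  best <- which(jf == max(jf))
  min(thrf[best])
}

#' Harrell's concordance index
#'
#' Fraction of censoring-admissible ordered pairs in which the subject
#' with the higher marker fails first; tied markers count 0.5. A pair
#' (i, j) is admissible when i fails (event) strictly before j's observed
#' time, or at the same recorded time at which j is censored.
#'
#' @param marker numeric risk score, higher = riskier.
#' @param time,event survival outcome.
#' @param detail also return per-observation numerator/denominator
#'   contributions (used by [compare_concordance()]).
#' @return the C-index, or a list when `detail = TRUE`.
#' @export
harrell_c <- function(marker, time, event, detail = FALSE) {
  check_surv(time, event)
  n <- length(marker)
  if (n != length(time)) stop("marker/outcome length mismatch")
  admissible <- (outer(time, time, `<`) |
                   (outer(time, time, `==`) & outer(event == 1, event == 0))) &
    matrix(event == 1, n, n)
  diag(admissible) <- FALSE
  conc <- (outer(marker, marker, `>`) + 0.5 * outer(marker, marker, `==`)) *
    admissible
  num_tot <- sum(conc)
  den_tot <- sum(admissible)
  if (den_tot == 0) stop("no comparable pairs")
  if (!detail) return(num_tot / den_tot)
  num_i <- rowSums(conc) + colSums(conc)
  den_i <- rowSums(admissible) + colSums(admissible)
  list(c = num_tot / den_tot, num = num_tot, den = den_tot,
       num_i = num_i, den_i = den_i, n = n)
}

#' Compare two correlated concordance indices
#'
#' Estimates C1 - C2 for two markers evaluated on the same subjects, with
#' a leave-one-out jackknife standard error for the paired difference and
#' a two-sided normal p-value.
#'
#' @param m1,m2 numeric markers on the same samples.
#' @param time,event survival outcome.
#' @return object of class `concordance_comparison`: `c1`, `c2`, `diff`,
#'   `se`, `p`.
#' @export
compare_concordance <- function(m1, m2, time, event) {
  if (length(unique(m1)) < 2L || length(unique(m2)) < 2L) {
    stop("degenerate (constant) marker")
  }
  d1 <- harrell_c(m1, time, event, detail = TRUE)
  d2 <- harrell_c(m2, time, event, detail = TRUE)
  n <- d1$n
  # leave-one-out C: remove observation i's pair contributions
  c1_loo <- (d1$num - d1$num_i) / (d1$den - d1$den_i)
  c2_loo <- (d2$num - d2$num_i) / (d2$den - d2$den_i)
  ok <- is.finite(c1_loo) & is.finite(c2_loo)
  di <- c1_loo[ok] - c2_loo[ok]
  m <- length(di)
  se <- sqrt((m - 1) / m * sum((di - mean(di))^2))
  est <- d1$c - d2$c
  p <- if (se == 0) as.numeric(est != 0) * 0 + (est == 0) * 1 else
    2 * stats::pnorm(-abs(est / se))
  structure(list(c1 = d1$c, c2 = d2$c, diff = est, se = se, p = p, n = n),
            class = "concordance_comparison")
}

#' @export
print.concordance_comparison <- function(x, ...) {
  cat(sprintf(
    "C-index comparison: C1 = %.3f, C2 = %.3f, diff = %+.4f (SE %.4f), p = %.4g\n",
    x$c1, x$c2, x$diff, x$se, x$p))
  invisible(x)
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier curve on [0, tau].
#'
#' @param time,event survival outcome.
#' @param tau truncation time, at most the largest observed time.
#' @return object of class `rmst_result`: `tau`, `rmst`.
#' @export
rmst <- function(time, event, tau) {
  check_surv(time, event)
  if (tau <= 0 || tau > max(time)) stop("tau must lie within follow-up")
  km <- km_fit(time, event)
  structure(list(tau = tau, rmst = step_area(km$time, km$surv, tau)),
            class = "rmst_result")
}

# integral over [0, tau] of the right-continuous step function that is 1
# on [0, t[1]) and equals s[k] on [t[k], t[k+1]).
step_area <- function(t, s, tau) {
  keep <- t <= tau
  tt <- c(0, t[keep], tau)
  ss <- c(1, s[keep])
  sum(diff(tt) * ss)
}

#' @export
print.rmst_result <- function(x, ...) {
  cat(sprintf("RMST over [0, %g] = %.2f days\n", x$tau, x$rmst))
  invisible(x)
}

#' Model-based restricted-mean-survival curve over a risk index
#'
#' For a Cox fit on a single continuous index with Breslow baseline
#' cumulative hazard H0, computes RMST(x) = integral over [0, tau] of
#' S0(t)^exp(beta x) for each grid value x. Grid points outside the range
#' of the index used in the fit are flagged as extrapolation with a
#' warning.
#'
#' @param fit a `cox_fit` with exactly one covariate.
#' @param index_grid index values at which to evaluate the curve.
#' @param tau truncation time in days.
#' @return object of class `rms_curve`: data.frame `index`, `rmst`, plus
#'   `tau` and `beta` attributes.
#' @export
rms_curve <- function(fit, index_grid, tau) {
  stopifnot(inherits(fit, "cox_fit"))
  if (length(fit$coef) != 1L) stop("rms_curve needs a single-covariate fit")
  rng <- range(fit$x)
  extrap <- index_grid < rng[1] | index_grid > rng[2]
  if (any(extrap)) {
    warning(sprintf("%d grid value(s) outside the observed index range; extrapolating",
                    sum(extrap)))
  }
  bh <- fit$baseline
  beta <- unname(fit$coef)
  vals <- vapply(index_grid, function(x) {
    s <- exp(-bh$cumhaz * exp(beta * x))
    step_area(bh$time, s, tau)
  }, numeric(1))
  structure(data.frame(index = index_grid, rmst = vals,
                       extrapolated = extrap),
            tau = tau, beta = beta, class = c("rms_curve", "data.frame"))
}

#' @export
plot.rms_curve <- function(x, xlab = "Risk index", ylab = "RMS time (days)",
                           type = "l", ...) {
  graphics::plot(x$index, x$rmst, xlab = xlab, ylab = ylab, type = type, ...)
  invisible(x)
}
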