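# Training pipeline: enumerate pairs -> constancy filter -> per-pair
# log-rank screen -> LASSO-Cox selection at the CV-chosen penalty ->
# unpenalized refit -> time-dependent-ROC cutoff. The fitted object is a
# `pair_signature`, the same class the published model ships as.

#' Fit a gene-pair prognostic signature on training cohorts
#'
#' Runs the full signature-building pipeline on a harmonized multi-cohort
#' training collection: all gene pairs are enumerated and scored, pairs
#' constant within any cohort are dropped, the remainder are screened by a
#' per-pair log-rank test on the dichotomy they induce, and the screened
#' pairs enter a LASSO-penalized Cox model whose penalty is chosen by
#' k-fold cross-validation (one-standard-error rule by default). Weights
#' are, by default, the unpenalized Cox refit on the selected pairs; the
#' risk cutoff maximizes Youden's J on the training time-dependent ROC at
#' a reference horizon.
#'
#' @param train a `cohort_collection` with survival data.
#' @param screen_p log-rank screening threshold (unadjusted p), default
#'   0.05.
#' @param fdr screen on Benjamini-Hochberg adjusted p-values instead
#'   (default FALSE).
#' @param nfolds cross-validation folds for the penalty (default 10).
#' @param seed integer master seed (fold assignment).
#' @param lambda_rule "1se" (default) or "min".
#' @param weights "refit" (unpenalized Cox refit on the selected pairs,
#'   default) or "penalized" (raw LASSO coefficients).
#' @param cutoff_horizon reference horizon in days for the cutoff ROC
#'   (default 1825, i.e. 5 years); clamped to the largest observed event
#'   time when follow-up is shorter.
#' @param span nearest-neighbour span for the cutoff ROC (default
#'   `0.25 n^-0.2`).
#' @param filter_scope constancy-filter scope, see
#'   [filter_informative_pairs()].
#' @param min_freq optional pooled minority-frequency filter (default 0 =
#'   off).
#' @param pairs optional data.frame of pairs (gene1, gene2) to use as-is:
#'   skips enumeration, filtering, screening and LASSO selection, and
#'   fits weights directly on these pairs.
#' @param standardize standardize pair indicators inside the LASSO
#'   (default FALSE).
#' @return a `pair_signature` with provenance "trained" and the pipeline
#'   settings, counts and penalty values in `$meta`.
#' @export
pair_signature <- function(train, screen_p = 0.05, fdr = FALSE,
                           nfolds = 10L, seed = 1L,
                           lambda_rule = c("1se", "min"),
                           weights = c("refit", "penalized"),
                           cutoff_horizon = 1825, span = NULL,
                           filter_scope = c("any", "pooled"), min_freq = 0,
                           pairs = NULL, standardize = FALSE) {
  stopifnot(inherits(train, "cohort_collection"))
  lambda_rule <- match.arg(lambda_rule)
  weights <- match.arg(weights)
  filter_scope <- match.arg(filter_scope)
  cl <- train$clinical
  time <- cl$time_days
  event <- cl$event

  meta <- list(seed = seed, screen_p = screen_p, fdr = fdr,
               nfolds = nfolds, lambda_rule = lambda_rule,
               weights = weights, filter_scope = filter_scope,
               min_freq = min_freq, standardize = standardize)

  if (is.null(pairs)) {
    all_pairs <- enumerate_pairs(rownames(train$cohorts[[1L]]))
    pm <- build_pair_matrix(train, all_pairs)
    informative <- filter_informative_pairs(pm, scope = filter_scope,
                                            min_freq = min_freq)
    pm_inf <- pm[attr(informative, "index"), , drop = FALSE]
    scr <- logrank_screen(pm_inf, time, event)
    pvals <- if (fdr) stats::p.adjust(scr$p, "BH") else scr$p
    keep <- which(pvals < screen_p)
    meta$n_enumerated <- nrow(all_pairs)
    meta$n_informative <- nrow(informative)
    meta$n_screened <- length(keep)
    if (length(keep) < 2L) {
      stop_pairsurv("fewer than 2 pairs survive the log-rank screen",
                    "pairsurv_empty_screen")
    }
    x <- t(unclass(pm_inf)[keep, , drop = FALSE])
    cvfit <- cox_lasso_cv(x, time, event, nfolds = nfolds,
                          seed = derive_seed(seed, "cvfolds"),
                          standardize = standardize)
    lambda <- if (lambda_rule == "1se") cvfit$lambda_1se else
      cvfit$lambda_min
    beta <- coef_at_lambda(cvfit, lambda)
    sel <- names(beta)[beta != 0]
    meta$lambda_min <- cvfit$lambda_min
    meta$lambda_1se <- cvfit$lambda_1se
    meta$lambda_used <- lambda
    meta$n_selected <- length(sel)
    if (!length(sel)) {
      stop_pairsurv(paste(
        "no pair has a nonzero coefficient at the chosen penalty;",
        "consider lambda_rule = \"min\""), "pairsurv_empty_selection")
    }
    sel_pairs <- parse_pair_ids(sel)
    w <- if (weights == "penalized") unname(beta[sel]) else NULL
  } else {
    sel_pairs <- pairs[, c("gene1", "gene2")]
    pm <- build_pair_matrix(train, sel_pairs)
    meta$n_selected <- nrow(sel_pairs)
    w <- NULL
  }

  pm_sel <- build_pair_matrix(train, sel_pairs)
  if (is.null(w)) {
    refit <- cox_fit(time, event, t(unclass(pm_sel)))
    w <- unname(refit$coef)
  }
  model <- new_pair_signature(
    data.frame(sel_pairs, weight = w, stringsAsFactors = FALSE),
    cutoff = NA_real_, provenance = "trained", meta = meta)

  scores <- score_pairs(train, model)
  horizon <- min(cutoff_horizon, max(time[event == 1]))
  roc <- td_roc(scores, time, event, horizon = horizon, span = span)
  model$cutoff <- optimal_cutoff(roc)
  model$meta$cutoff_horizon <- horizon
  model$meta$span <- roc$span
  model
}

#' Combine a trained signature with clinical covariates
#'
#' Fits a multivariate Cox model on (signature score, stage code, age) in
#' the training collection; the fitted coefficients are the clinical-index
#' weights, and the cutoff maximizes Youden's J on the training
#' time-dependent ROC of the combined index at `tau_ref`.
#'
#' @param train a `cohort_collection`.
#' @param model a `pair_signature` scoring every training sample.
#' @param tau_ref reference horizon in days for the cutoff (default 1825);
#'   clamped to the largest observed event time.
#' @param span nearest-neighbour span for the cutoff ROC.
#' @return an `acpi_model` with provenance "trained"; the underlying
#'   `cox_fit` is kept in `$meta$fit`.
#' @export
build_acpi <- function(train, model, tau_ref = 1825, span = NULL) {
  stopifnot(inherits(train, "cohort_collection"),
            inherits(model, "pair_signature"))
  cl <- train$clinical
  sc <- score_pairs(train, model)
  covs <- cbind(atgpi = unname(sc), stage = cl$stage, age = cl$age)
  fit <- cox_fit(cl$time_days, cl$event, covs)
  acpi <- new_acpi(w_atgpi = unname(fit$coef["atgpi"]),
                   w_stage = unname(fit$coef["stage"]),
                   w_age = unname(fit$coef["age"]),
                   cutoff = NA_real_, provenance = "trained",
                   meta = list(fit = fit, tau_ref = tau_ref))
  idx <- score_acpi(sc, cl$stage, cl$age, acpi)
  horizon <- min(tau_ref, max(cl$time_days[cl$event == 1]))
  roc <- td_roc(idx, cl$time_days, cl$event, horizon = horizon, span = span)
  acpi$cutoff <- optimal_cutoff(roc)
  acpi$meta$cutoff_horizon <- horizon
  acpi
}

#' Evaluate a signature on a cohort collection
#'
#' Produces the standard validation report: risk classification at the
#' model cutoff, Kaplan-Meier curves by risk group with a log-rank test,
#' univariate Cox hazard ratios for risk group, sex, age and stage, a
#' multivariate Cox model restricted to variables with univariate
#' p < 0.05, time-dependent AUCs at the requested horizons, and the
#' C-index of the continuous score. When a clinical-combination model is
#' supplied, its index is scored as well and the two C-indices are
#' compared on the same samples.
#'
#' @param model a `pair_signature`.
#' @param cohort a `cohort_collection` with clinical data.
#' @param acpi optional `acpi_model` for the clinical combination.
#' @param horizons AUC horizons in days (default 1, 3, 5 years); horizons
#'   beyond follow-up are skipped.
#' @param span nearest-neighbour span for the ROC estimator.
#' @return object of class `signature_evaluation`.
#' @export
evaluate_signature <- function(model, cohort, acpi = NULL,
                               horizons = c(365, 1095, 1825), span = NULL) {
  stopifnot(inherits(model, "pair_signature"),
            inherits(cohort, "cohort_collection"))
  cl <- cohort$clinical
  need <- c("time_days", "event", "age", "stage", "sex")
  miss <- setdiff(need, colnames(cl))
  if (length(miss)) {
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  }
  time <- cl$time_days; event <- cl$event
  scores <- score_pairs(cohort, model)
  risk <- classify_risk(scores, model$cutoff)

  km <- lapply(split(seq_along(time), risk),
               function(i) km_fit(time[i], event[i]))
  lr <- if (all(table(risk) > 0)) logrank_test(time, event, risk) else NULL

  vars <- list(risk = as.integer(risk == "high"),
               sex = as.integer(tolower(as.character(cl$sex)) == "male"),
               age = cl$age,
               stage = cl$stage)
  uni <- lapply(vars, function(v) {
    if (length(unique(v)) < 2L) return(NULL)
    f <- cox_fit(time, event, matrix(v, ncol = 1,
                                     dimnames = list(NULL, "v")))
    c(hr = unname(f$hr), lower = unname(f$ci_lower),
      upper = unname(f$ci_upper), p = unname(f$p))
  })
  uni_tab <- do.call(rbind, uni[!vapply(uni, is.null, logical(1))])
  uni_tab <- as.data.frame(uni_tab)

  keep <- rownames(uni_tab)[uni_tab$p < 0.05]
  multi_tab <- NULL
  if (length(keep) >= 1L) {
    xm <- do.call(cbind, vars[keep])
    colnames(xm) <- keep
    mf <- cox_fit(time, event, xm)
    multi_tab <- data.frame(hr = mf$hr, lower = mf$ci_lower,
                            upper = mf$ci_upper, p = mf$p)
  }

  horizons <- horizons[horizons <= max(time)]
  aucs <- vapply(horizons, function(h) {
    tryCatch(td_roc(scores, time, event, horizon = h, span = span)$auc,
             error = function(e) NA_real_)
  }, numeric(1))
  names(aucs) <- paste0(horizons, "d")

  cindex <- harrell_c(scores, time, event)
  acpi_part <- NULL
  if (!is.null(acpi)) {
    idx <- score_acpi(scores, cl$stage, cl$age, acpi)
    acpi_risk <- if (is.finite(acpi$cutoff %||% NA_real_)) {
      classify_risk(idx, acpi$cutoff)
    } else NULL
    acpi_part <- list(scores = idx, risk = acpi_risk,
                      cindex = harrell_c(idx, time, event),
                      comparison = compare_concordance(idx, scores, time,
                                                       event))
  }

  structure(list(scores = scores, risk = risk, km = km, logrank = lr,
                 univariate = uni_tab, multivariate = multi_tab,
                 auc = aucs, cindex = cindex, acpi = acpi_part,
                 n = length(time), n_event = sum(event)),
            class = "signature_evaluation")
}

#' @export
print.signature_evaluation <- function(x, digits = 3, ...) {
  cat(sprintf("Signature evaluation: n = %d, events = %d\n", x$n, x$n_event))
  cat(sprintf("  risk groups: low %d / high %d\n",
              sum(x$risk == "low"), sum(x$risk == "high")))
  if (!is.null(x$logrank)) {
    cat(sprintf("  log-rank p = %.3g\n", x$logrank$p))
  }
  cat("  univariate Cox:\n")
  print(round(x$univariate, digits))
  if (!is.null(x$multivariate)) {
    cat("  multivariate Cox (univariate p < 0.05):\n")
    print(round(x$multivariate, digits))
  }
  cat("  time-dependent AUC:",
      paste(sprintf("%s %.3f", names(x$auc), x$auc), collapse = ", "), "\n")
  cat(sprintf("  C-index (score) = %.3f\n", x$cindex))
  if (!is.null(x$acpi)) {
    cat(sprintf("  C-index (clinical index) = %.3f\n", x$acpi$cindex))
    print(x$acpi$comparison)
  }
  invisible(x)
}

#' Write an evaluation report to a directory
#'
#' Emits the hazard-ratio tables and AUC table as TSV, plus a JSON
#' summary; optionally KM and ROC-free plots as PDFs.
#'
#' @param ev a `signature_evaluation`.
#' @param dir output directory (created if absent).
#' @param plots also write KM plot PDFs (default TRUE).
#' @return invisibly, the directory.
#' @export
write_evaluation <- function(ev, dir, plots = TRUE) {
  stopifnot(inherits(ev, "signature_evaluation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(data.frame(variable = rownames(df), df),
                       file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(ev$univariate, "univariate_cox.tsv")
  if (!is.null(ev$multivariate)) tsv(ev$multivariate, "multivariate_cox.tsv")
  utils::write.table(
    data.frame(horizon = names(ev$auc), auc = as.numeric(ev$auc)),
    file.path(dir, "td_auc.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  summ <- list(n = ev$n, n_event = ev$n_event,
               logrank_p = if (!is.null(ev$logrank)) ev$logrank$p else NULL,
               cindex_score = ev$cindex,
               cindex_clinical = if (!is.null(ev$acpi)) ev$acpi$cindex,
               cindex_comparison_p = if (!is.null(ev$acpi))
                 ev$acpi$comparison$p)
  jsonlite::write_json(summ[!vapply(summ, is.null, logical(1))],
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  if (plots) {
    grDevices::pdf(file.path(dir, "km_by_risk.pdf"), width = 6, height = 5)
    cols <- c(low = "steelblue", high = "firebrick")
    first <- TRUE
    for (g in names(ev$km)) {
      km <- ev$km[[g]]
      fn <- stats::stepfun(km$time, c(1, km$surv))
      if (first) {
        graphics::plot(fn, do.points = FALSE, col = cols[[g]],
                       xlab = "Days", ylab = "Survival probability",
                       ylim = c(0, 1), main = "Survival by risk group")
        first <- FALSE
      } else {
        graphics::lines(fn, do.points = FALSE, col = cols[[g]])
      }
    }
    graphics::legend("bottomleft", legend = names(ev$km),
                     col = cols[names(ev$km)], lty = 1, bty = "n")
    grDevices::dev.off()
  }
  invisible(dir)
}
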