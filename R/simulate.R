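# Synthetic multi-cohort expression + survival generator with known
# ground truth. Emulates the study design the signature method targets:
# several microarray-like cohorts on different platform scales, survival
# driven by a handful of true pair indicators plus age and stage effects,
# and uniform right censoring. Every expression value of a cohort passes
# through a cohort-specific strictly increasing transform, so within-
# sample orderings (hence all pair indicators) are preserved while raw
# scales differ arbitrarily.

#' Simulation configuration
#'
#' Defaults describe a desk-scale version of a merged multi-cohort
#' microarray study: 4 cohorts of 200 samples, 30 genes, 5 prognostic
#' pairs with log-hazard ratios of magnitude 0.8-1.0, an age effect of
#' 0.03 per year and a stage effect of 0.65 per step (hazard ratios about
#' 1.03 and 1.9), and a Weibull baseline and uniform censoring bound
#' calibrated so the median observed time is near 1700 days and the event
#' fraction near 0.37 — the figures reported for merged early-stage lung
#' adenocarcinoma cohorts.
#'
#' @param n_cohorts number of cohorts.
#' @param n_per_cohort samples per cohort (recycled to `n_cohorts`).
#' @param n_genes number of genes (gene symbols G001, G002, ...).
#' @param n_true_pairs number of prognostic pairs.
#' @param beta generating log-hazard ratios, one per true pair.
#' @param gamma_age log-hazard per year of age (centred at 65).
#' @param gamma_stage log-hazard per stage step (stage - 1).
#' @param weibull_shape,weibull_scale baseline Weibull parameters (scale
#'   in days).
#' @param censor_max upper bound of the Uniform(0, c) censoring time.
#' @param stage2_prev prevalence of stage II.
#' @param tie_fraction fraction in [0, 1): expression values are rounded
#'   to this coarse a grid to exercise tie handling (0 = continuous).
#' @param distortions list of per-cohort monotone transforms (see
#'   [distort()]); `NULL` picks a default mix of affine, power, logistic
#'   and identity transforms.
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 4L, n_per_cohort = 200L, n_genes = 30L,
                       n_true_pairs = min(5L, n_genes %/% 2L),
                       beta = c(0.9, -0.9, 1.0, -0.8, 0.8)[seq_len(n_true_pairs)],
                       gamma_age = 0.03, gamma_stage = 0.65,
                       weibull_shape = 1.2, weibull_scale = 11000,
                       censor_max = 5500, stage2_prev = 0.25,
                       tie_fraction = 0, distortions = NULL, seed = 1L) {
  stopifnot(n_cohorts >= 1L, n_genes >= 4L, n_true_pairs >= 0L,
            length(beta) == n_true_pairs,
            weibull_shape > 0, weibull_scale > 0, censor_max > 0,
            stage2_prev >= 0, stage2_prev <= 1,
            tie_fraction >= 0, tie_fraction < 1)
  n_per_cohort <- rep_len(as.integer(n_per_cohort), n_cohorts)
  if (any(n_per_cohort < 1L)) stop("zero-sample cohort requested")
  if (2L * n_true_pairs > n_genes) {
    stop("need at least 2 genes per true pair")
  }
  structure(list(n_cohorts = as.integer(n_cohorts),
                 n_per_cohort = n_per_cohort, n_genes = as.integer(n_genes),
                 n_true_pairs = as.integer(n_true_pairs), beta = beta,
                 gamma_age = gamma_age, gamma_stage = gamma_stage,
                 weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale, censor_max = censor_max,
                 stage2_prev = stage2_prev, tie_fraction = tie_fraction,
                 distortions = distortions, seed = as.integer(seed)),
            class = "sim_config")
}

default_distortions <- function(k) {
  base <- list(
    list(type = "affine", a = 2, b = 3),
    list(type = "power", p = 1.7),
    list(type = "loglogistic", scale = 4),
    list(type = "identity"),
    list(type = "affine", a = 0.5, b = 10),
    list(type = "power", p = 0.6))
  base[((seq_len(k) - 1L) %% length(base)) + 1L]
}

apply_transform <- function(x, spec) {
  switch(spec$type,
         identity = x,
         affine = {
           if (spec$a <= 0) stop("affine slope must be positive")
           spec$a * x + spec$b
         },
         power = {
           if (spec$p <= 0) stop("power exponent must be positive")
           if (any(x < 0)) stop("power transform needs non-negative data")
           x^spec$p
         },
         log = {
           if (any(x <= 0)) stop("log transform needs positive data")
           log(x)
         },
         logistic = 1 / (1 + exp(-x / (spec$scale %||% 1))),
         loglogistic = {
           if (any(x <= 0)) stop("loglogistic transform needs positive data")
           1 / (1 + exp(-log(x) / (spec$scale %||% 1)))
         },
         stop("unknown transform type: ", spec$type))
}

#' Apply a strictly increasing transform to a cohort's expression values
#'
#' Models cross-platform scale differences: every value is transformed
#' elementwise by a monotone map (affine with positive slope, power on
#' non-negative data, log on positive data, logistic, or identity), which
#' preserves all within-sample gene orderings.
#'
#' @param expr a `cohort_expr` matrix.
#' @param transform list with `type` and parameters, e.g.
#'   `list(type = "affine", a = 2, b = 3)`.
#' @return the transformed `cohort_expr`.
#' @export
distort <- function(expr, transform) {
  vals <- apply_transform(unclass(expr), transform)
  # strict monotonicity on the values actually present: distinct inputs
  # must map to distinct, order-preserving outputs (this also catches
  # numerically saturating maps that collapse values into ties)
  u <- sort(unique(as.vector(unclass(expr))))
  tu <- apply_transform(u, transform)
  if (length(u) > 1L && any(diff(tu) <= 0)) {
    stop("transform is not strictly increasing on these data")
  }
  expression_matrix(vals, cohort_id = cohort_id(expr))
}

#' Simulate multi-cohort expression and survival data with ground truth
#'
#' Latent expression is log-normal with gene-specific location and scale;
#' the two genes of each true pair share a latent factor and a common
#' location so their 0/1 indicator is non-degenerate (minority frequency
#' roughly 20-50%). Survival times follow a Weibull proportional-hazards
#' model (inverse-transform construction) with linear predictor
#' `sum(beta_j z_j) + gamma_age (age - 65) + gamma_stage (stage - 1)`;
#' censoring is Uniform(0, c). Each cohort's expression is then passed
#' through its own strictly increasing platform transform.
#'
#' @param config a [sim_config()].
#' @return list with `collection` (a `cohort_collection`) and `truth`
#'   (class `ground_truth`: true pairs, generating coefficients, and the
#'   per-sample linear predictor `eta`).
#' @export
simulate_cohorts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohorts_impl(config))
}

simulate_cohorts_impl <- function(config) {
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  k <- config$n_true_pairs
  true_pairs <- if (k > 0) {
    data.frame(gene1 = genes[seq_len(k) * 2 - 1], gene2 = genes[seq_len(k) * 2],
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene1 = character(), gene2 = character())
  }
  # gene-specific log-scale locations; paired genes share a location with
  # a small offset so the indicator frequency stays between ~20 and 50%
  mu <- stats::runif(config$n_genes, 2, 8)
  sdv <- stats::runif(config$n_genes, 0.5, 1.5)
  if (k > 0) {
    for (j in seq_len(k)) {
      i1 <- 2 * j - 1; i2 <- 2 * j
      mu[i2] <- mu[i1] + stats::runif(1, 0, 0.9)
      sdv[i2] <- sdv[i1] <- stats::runif(1, 0.7, 1.2)
    }
  }
  distortions <- config$distortions %||% default_distortions(config$n_cohorts)

  cohorts <- vector("list", config$n_cohorts)
  clin <- vector("list", config$n_cohorts)
  eta_all <- numeric(0)
  offset <- 0L
  for (co in seq_len(config$n_cohorts)) {
    n <- config$n_per_cohort[co]
    sample_ids <- sprintf("C%02dS%04d", co, seq_len(n) + offset)
    latent <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n)
    # shared latent factor per true pair (correlated paired genes)
    if (k > 0) {
      for (j in seq_len(k)) {
        f <- stats::rnorm(n)
        latent[2 * j - 1, ] <- 0.6 * f + 0.8 * latent[2 * j - 1, ]
        latent[2 * j, ] <- 0.6 * f + 0.8 * latent[2 * j, ]
      }
    }
    logexpr <- mu + sdv * latent          # recycles by row
    if (config$tie_fraction > 0) {
      # snap a fraction of log-values to a coarse grid to create ties
      sel <- stats::runif(length(logexpr)) < config$tie_fraction
      logexpr[sel] <- round(logexpr[sel] * 2) / 2
    }
    expr <- exp(logexpr)
    dimnames(expr) <- list(genes, sample_ids)

    z <- if (k > 0) {
      (expr[true_pairs$gene1, , drop = FALSE] <=
         expr[true_pairs$gene2, , drop = FALSE]) * 1
    } else {
      matrix(0, 0, n)
    }
    age <- pmin(pmax(stats::rnorm(n, 65, 8), 35), 90)
    stage <- 1L + stats::rbinom(n, 1L, config$stage2_prev)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    eta <- as.vector(crossprod(z, config$beta)) +
      config$gamma_age * (age - 65) + config$gamma_stage * (stage - 1)
    if (k == 0) eta <- config$gamma_age * (age - 65) +
        config$gamma_stage * (stage - 1)
    # Weibull PH by inverse transform: S(t|x) = exp(-(t/b)^k e^eta)
    u <- stats::runif(n)
    t_event <- config$weibull_scale *
      (-log(u) / exp(eta))^(1 / config$weibull_shape)
    t_cens <- stats::runif(n, 0, config$censor_max)
    time <- pmax(pmin(t_event, t_cens), 0.5)
    event <- as.integer(t_event <= t_cens)

    cid <- sprintf("cohort%02d", co)
    em <- expression_matrix(expr, cohort_id = cid)
    cohorts[[co]] <- distort(em, distortions[[co]])
    clin[[co]] <- data.frame(sample_id = sample_ids, time_days = time,
                             event = event, age = age, stage = stage,
                             sex = sex, cohort_id = cid,
                             stringsAsFactors = FALSE)
    eta_all <- c(eta_all, eta)
    offset <- offset + n
  }
  clinical <- do.call(rbind, clin)
  truth <- structure(list(true_pairs = true_pairs, beta = config$beta,
                          gamma_age = config$gamma_age,
                          gamma_stage = config$gamma_stage,
                          eta = stats::setNames(eta_all,
                                                clinical$sample_id),
                          config = config),
                     class = "ground_truth")
  list(collection = cohort_collection(cohorts, clinical),
       truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d true pair(s); gamma_age = %g, gamma_stage = %g\n",
              nrow(x$true_pairs), x$gamma_age, x$gamma_stage))
  if (nrow(x$true_pairs)) {
    print(data.frame(x$true_pairs, beta = x$beta), row.names = FALSE)
  }
  invisible(x)
}

#' Censoring rate of a collection
#'
#' @param collection a `cohort_collection`.
#' @return fraction of samples with event = 0.
#' @export
censoring_rate <- function(collection) {
  stopifnot(inherits(collection, "cohort_collection"))
  mean(collection$clinical$event == 0)
}

#' Write simulated cohorts and ground truth to disk
#'
#' Expression as per-cohort TSV, clinical table as CSV, ground truth as
#' JSON — the same formats [read_expression()] and [read_clinical()]
#' consume.
#'
#' @param sim result of [simulate_cohorts()].
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (co in sim$collection$cohorts) {
    write_expression(co, file.path(dir, paste0(cohort_id(co), "_expr.tsv")))
  }
  write_clinical(sim$collection$clinical, file.path(dir, "clinical.csv"))
  tr <- sim$truth
  jsonlite::write_json(
    list(true_pairs = tr$true_pairs, beta = tr$beta,
         gamma_age = tr$gamma_age, gamma_stage = tr$gamma_stage,
         eta = as.list(tr$eta)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
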