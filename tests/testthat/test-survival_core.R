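test_that("Kaplan-Meier matches hand product-limit computations", {
  # three events: S = 2/3, 1/3, 0
  km <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0))

  # censoring at 2 shrinks the risk set: risk sets 3 then 1
  km2 <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(pairsurv:::km_surv_at(km2, 1), 2/3)
  expect_equal(pairsurv:::km_surv_at(km2, 3), 0)

  # no events: flat at 1
  km3 <- km_fit(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  expect_error(km_fit(numeric(0), integer(0)), "empty")

  # monotone, in [0, 1], S(0) = 1
  d <- sim_one_cov(100, 0.5, seed = 2)
  km4 <- km_fit(d$time, d$event)
  expect_true(all(diff(km4$surv) <= 0))
  expect_true(all(km4$surv >= 0 & km4$surv <= 1))
  expect_equal(pairsurv:::km_surv_at(km4, 0), 1)
})

test_that("log-rank matches an independent hand oracle", {
  # duplicated data in both groups: no difference
  t0 <- c(2, 4, 6, 8); e0 <- c(1, 0, 1, 1)
  lr0 <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_lt(lr0$chisq, 1e-10)
  expect_equal(lr0$p, 1, tolerance = 1e-6)

  # 6-observation toy against the sum of hypergeometric terms
  ti <- c(1, 3, 4, 5, 8, 9); ev <- c(1, 1, 0, 1, 1, 0)
  gr <- c(0, 1, 0, 1, 0, 1)
  lr <- logrank_test(ti, ev, gr)
  expect_equal(lr$chisq, oracle_logrank(ti, ev, gr), tolerance = 1e-10)
  expect_equal(lr$df, 1L)

  expect_error(logrank_test(ti, ev, rep("a", 6)), "two non-empty")
})

test_that("log-rank asymptotic p agrees with a permutation distribution", {
  d <- sim_one_cov(60, 0, seed = 9)
  grp <- pairsurv:::with_seed(10, rbinom(60, 1, 0.5))
  lr <- logrank_test(d$time, d$event, grp)

  # permutation oracle: 10000 label permutations, statistic recomputed by
  # the vectorised screen (itself checked against survdiff below)
  perms <- pairsurv:::with_seed(11, {
    t(replicate(10000, sample(grp)))
  })
  chis <- logrank_screen(perms, d$time, d$event)$chisq
  p_perm <- mean(chis >= lr$chisq - 1e-12)
  expect_lt(abs(p_perm - lr$p), 0.03)
})

test_that("vectorised screen reproduces survdiff over many binary markers", {
  d <- sim_one_cov(80, 0.4, seed = 3)
  markers <- pairsurv:::with_seed(4, {
    matrix(rbinom(40 * 80, 1, 0.4), 40, 80,
           dimnames = list(paste0("m", 1:40), NULL))
  })
  scr <- logrank_screen(markers, d$time, d$event)
  for (k in seq_len(nrow(markers))) {
    if (length(unique(markers[k, ])) < 2) next
    lr <- logrank_test(d$time, d$event, markers[k, ])
    expect_equal(scr$chisq[k], lr$chisq, tolerance = 1e-8)
    expect_equal(scr$p[k], lr$p, tolerance = 1e-8)
  }
})

test_that("Cox fit maximizes the Breslow partial likelihood", {
  # 8-observation toy vs grid maximization of the hand-coded likelihood
  ti <- c(3, 5, 6, 8, 10, 12, 15, 20)
  ev <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(0.5, -0.2, 1.1, 0.8, -1.0, 0.3, 1.5, -0.7)
  fit <- cox_fit(ti, ev, matrix(x, ncol = 1, dimnames = list(NULL, "x")))
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, oracle_breslow_loglik, numeric(1),
               time = ti, event = ev, x = x)
  expect_lt(abs(unname(fit$coef) - grid[which.max(ll)]), 1e-4)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-6)

  # invariants: HR > 0, CI brackets HR
  expect_true(fit$hr > 0)
  expect_true(fit$ci_lower < fit$hr && fit$hr < fit$ci_upper)
})

test_that("Cox fit recovers null and non-null generating coefficients", {
  # covariate independent of survival
  d0 <- sim_one_cov(500, 0, seed = 21)
  f0 <- cox_fit(d0$time, d0$event, cbind(x = d0$x))
  expect_lt(abs(f0$coef), 3 * f0$se)

  # true log-HR 0.7, averaged over simulations
  betas <- vapply(1:8, function(s) {
    d <- sim_one_cov(1000, 0.7, seed = 100 + s)
    unname(cox_fit(d$time, d$event, cbind(x = d$x))$coef)
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.7), 0.1)
})

test_that("Cox fit rejects degenerate problems", {
  d <- sim_one_cov(50, 0.5, seed = 5)
  expect_error(cox_fit(d$time, d$event, cbind(a = d$x, b = 2 * d$x)),
               "collinear")
  # a covariate that perfectly anti-ranks uncensored times separates
  ti <- 1:20
  expect_error(
    suppressWarnings(cox_fit(ti, rep(1, 20), cbind(x = -ti))),
    class = "pairsurv_monotone_likelihood")
})

test_that("penalized Cox path satisfies soft-threshold bound and KKT", {
  d <- sim_one_cov(200, 0.8, seed = 31)
  xm <- pairsurv:::with_seed(32, {
    cbind(signal = d$x, n1 = rnorm(200), n2 = rnorm(200), n3 = rnorm(200))
  })
  # explicit path reaching the unpenalized end (the automatic path stops
  # early once the deviance saturates)
  lam_seq <- c(exp(seq(log(0.5), log(1e-4), length.out = 40)), 0)
  cv <- cox_lasso_cv(xm, d$time, d$event, nfolds = 5, seed = 7,
                     lambda = lam_seq, thresh = 1e-12)

  # at and above lambda_max every coefficient is exactly zero
  expect_true(all(cv$beta[, 1] == 0))
  expect_true(all(coef_at_lambda(cv, cv$lambda[1] * 2) == 0))
  expect_gte(cv$lambda_1se, cv$lambda_min)

  # KKT at several path points: |(1/n) dll/dbeta_j| <= lambda for zeroed
  # coordinates, = lambda (signed) for active ones
  grad_ll <- function(beta) {
    eta <- as.vector(xm %*% beta); g <- rep(0, ncol(xm))
    for (t in sort(unique(d$time[d$event == 1]))) {
      dd <- which(d$time == t & d$event == 1)
      rs <- which(d$time >= t)
      w <- exp(eta[rs])
      g <- g + colSums(xm[dd, , drop = FALSE]) -
        length(dd) * colSums(xm[rs, , drop = FALSE] * w) / sum(w)
    }
    g
  }
  n <- nrow(xm)
  for (i in unique(pmin(c(5, 15, 30), length(cv$lambda)))) {
    l <- cv$lambda[i]
    b <- cv$beta[, i]
    g <- grad_ll(b) / n
    zero <- b == 0
    if (any(zero)) expect_true(all(abs(g[zero]) <= l * 1.02 + 1e-8))
    if (any(!zero)) {
      expect_equal(unname(g[!zero]), unname(l * sign(b[!zero])),
                   tolerance = 0.05)
    }
  }

  # the path end approaches the unpenalized fit
  b_end <- coef_at_lambda(cv, min(cv$lambda))
  f <- cox_fit(d$time, d$event, xm)
  expect_lt(max(abs(b_end - f$coef)), 1e-3)
})

test_that("penalized Cox selection is reproducible for a fixed seed", {
  d <- sim_one_cov(150, 0.8, seed = 41)
  xm <- pairsurv:::with_seed(42, cbind(s = d$x, matrix(rnorm(150 * 5), 150)))
  colnames(xm) <- paste0("v", 1:6)
  cv1 <- cox_lasso_cv(xm, d$time, d$event, seed = 3)
  cv2 <- cox_lasso_cv(xm, d$time, d$event, seed = 3)
  expect_identical(cv1$foldid, cv2$foldid)
  expect_equal(cv1$lambda_1se, cv2$lambda_1se)
  expect_equal(coef_at_lambda(cv1, cv1$lambda_1se),
               coef_at_lambda(cv2, cv2$lambda_1se))
  expect_error(cox_lasso_cv(xm[1:20, ], d$time[1:20], rep(0, 20)),
               "events")
})

test_that("time-dependent ROC behaves at the null and perfect extremes", {
  # independent marker: AUC near 1/2
  d <- sim_one_cov(1000, 0, seed = 51)
  mk <- pairsurv:::with_seed(52, rnorm(1000))
  roc0 <- td_roc(mk, d$time, d$event, horizon = 1000)
  expect_lt(abs(roc0$auc - 0.5), 0.05)

  # marker = -time with no censoring ranks failures perfectly
  ti <- pairsurv:::with_seed(53, runif(300, 10, 3000))
  roc1 <- td_roc(-ti, ti, rep(1, 300), horizon = 1000)
  expect_gte(roc1$auc, 0.99)

  # flipping the marker flips the curve
  d2 <- sim_one_cov(400, 0.8, seed = 54)
  a <- td_roc(d2$x, d2$time, d2$event, horizon = 800)$auc
  b <- td_roc(-d2$x, d2$time, d2$event, horizon = 800)$auc
  expect_lt(abs(a + b - 1), 0.02)

  # sensitivity and false-positive rate are monotone along thresholds
  expect_true(all(diff(roc0$sens) <= 1e-12))
  expect_true(all(diff(roc0$fpr) <= 1e-12))

  expect_error(td_roc(mk, d$time, d$event, horizon = 1e9), "range")
  expect_error(td_roc(-ti, ti, rep(1, 300), horizon = 1), "cases")
})

test_that("the Youden cutoff matches an exhaustive scan", {
  # hand-built curve: J = (0.2, 0.6, 0.3) picks the middle threshold
  roc <- structure(list(thresholds = c(1, 2, 3),
                        sens = c(0.9, 0.8, 0.4),
                        fpr = c(0.7, 0.2, 0.1),
                        auc = 0.7, horizon = 365, span = 0.1, n = 10),
                   class = "td_roc")
  expect_equal(optimal_cutoff(roc), 2)

  # ties break toward the smaller threshold
  roc$sens <- c(0.8, 0.8, 0.3); roc$fpr <- c(0.2, 0.2, 0.1)
  expect_equal(optimal_cutoff(roc), 1)

  # flat curve is an error
  roc$sens <- c(0.5, 0.5, 0.5); roc$fpr <- c(0.5, 0.5, 0.5)
  expect_error(optimal_cutoff(roc), "flat")

  # exhaustive oracle on simulated data
  d <- sim_one_cov(250, 1.0, seed = 61)
  roc2 <- td_roc(d$x, d$time, d$event, horizon = 900)
  j <- roc2$sens - roc2$fpr
  fin <- is.finite(roc2$thresholds)
  brute <- min(roc2$thresholds[fin][j[fin] == max(j[fin])])
  expect_equal(optimal_cutoff(roc2), brute)

  # separating marker: cutoff between the two groups
  ti <- c(rep(100, 20), rep(2000, 20))
  mk <- c(rep(5, 20), rep(1, 20)) + pairsurv:::with_seed(62, runif(40, 0, 0.5))
  roc3 <- td_roc(mk, ti, rep(1, 40), horizon = 1000)
  cut <- optimal_cutoff(roc3)
  expect_gt(cut, max(mk[21:40]) - 1e-9)
  expect_lt(cut, max(mk[1:20]))
})

test_that("Harrell's C matches brute force and survival::concordance", {
  # perfect anti-ranking, uncensored
  ti <- pairsurv:::with_seed(71, runif(50, 1, 1000))
  expect_equal(harrell_c(-ti, ti, rep(1, 50)), 1.0)

  # censored toy vs O(n^2) brute force, exactly
  d <- sim_one_cov(30, 0.6, seed = 72)
  mk <- pairsurv:::with_seed(73, d$x + rnorm(30, sd = 0.5))
  expect_identical(harrell_c(mk, d$time, d$event),
                   oracle_harrell_c(mk, d$time, d$event))

  # flip symmetry without marker ties
  c1 <- harrell_c(mk, d$time, d$event)
  expect_equal(harrell_c(-mk, d$time, d$event), 1 - c1)

  # independent reference implementation on continuous data
  cref <- survival::concordance(
    survival::Surv(d$time, d$event) ~ mk, reverse = TRUE)$concordance
  expect_equal(c1, cref, tolerance = 1e-12)

  expect_error(harrell_c(mk, rep(1, 30), rep(0, 30)), "comparable")
})

test_that("concordance comparison is calibrated", {
  # self-comparison: zero difference, p = 1
  d <- sim_one_cov(100, 0.7, seed = 81)
  cc0 <- compare_concordance(d$x, d$x, d$time, d$event)
  expect_equal(cc0$diff, 0)
  expect_equal(cc0$p, 1)
  expect_error(compare_concordance(rep(1, 100), d$x, d$time, d$event),
               "degenerate")

  # jackknife SE within 20% of a 1000-rep bootstrap on n = 200
  n <- 200
  dat <- pairsurv:::with_seed(82, {
    eta <- rnorm(n)
    m1 <- eta + rnorm(n, sd = 0.8)
    m2 <- eta + rnorm(n, sd = 0.8)
    tev <- rweibull(n, 1.2, 2000) * exp(-eta / 1.2)
    tc <- runif(n, 0, 4000)
    list(m1 = m1, m2 = m2, time = pmax(pmin(tev, tc), 1e-3),
         event = as.integer(tev <= tc))
  })
  cc <- compare_concordance(dat$m1, dat$m2, dat$time, dat$event)
  boot <- pairsurv:::with_seed(83, {
    replicate(1000, {
      i <- sample.int(n, replace = TRUE)
      harrell_c(dat$m1[i], dat$time[i], dat$event[i]) -
        harrell_c(dat$m2[i], dat$time[i], dat$event[i])
    })
  })
  expect_lt(abs(cc$se - stats::sd(boot)) / stats::sd(boot), 0.2)
})

test_that("concordance comparison holds its nominal type-I error", {
  rejections <- vapply(1:500, function(s) {
    n <- 150
    dat <- pairsurv:::with_seed(9000 + s, {
      eta <- rnorm(n)
      list(m1 = eta + rnorm(n, sd = 0.7), m2 = eta + rnorm(n, sd = 0.7),
           tev = rweibull(n, 1.2, 2000) * exp(-eta / 1.2),
           tc = runif(n, 0, 4000))
    })
    ti <- pmax(pmin(dat$tev, dat$tc), 1e-3)
    ev <- as.integer(dat$tev <= dat$tc)
    compare_concordance(dat$m1, dat$m2, ti, ev)$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.08)
})

test_that("RMST matches closed forms", {
  # uncensored: exactly mean(min(T, tau))
  ti <- pairsurv:::with_seed(91, runif(200, 10, 2000))
  r <- rmst(ti, rep(1, 200), tau = 800)
  expect_equal(r$rmst, mean(pmin(ti, 800)), tolerance = 1e-10)
  expect_lte(r$rmst, 800)

  # exponential: (1 - exp(-l tau)) / l within 2% at n = 5000
  lam <- 0.01
  d <- pairsurv:::with_seed(92, {
    tev <- rexp(5000, lam); tc <- runif(5000, 0, 2000)
    list(time = pmax(pmin(tev, tc), 1e-3), event = as.integer(tev <= tc))
  })
  r2 <- rmst(d$time, d$event, tau = 365)
  expect_lt(abs(r2$rmst - (1 - exp(-lam * 365)) / lam) /
              ((1 - exp(-lam * 365)) / lam), 0.02)

  expect_error(rmst(ti, rep(1, 200), tau = 1e6), "follow-up")
})

test_that("model-based RMS curves respect the proportional-hazards shape", {
  d <- sim_one_cov(400, 0.9, seed = 95)
  fit <- cox_fit(d$time, d$event, cbind(index = d$x))
  grid <- seq(-1.5, 1.5, length.out = 7)
  cur <- rms_curve(fit, grid, tau = 1500)
  expect_true(all(diff(cur$rmst) < 0))          # beta > 0: decreasing
  expect_true(all(cur$rmst > 0 & cur$rmst <= 1500))

  # refinement oracle: trapezoid on a 10x finer time grid within 0.5%
  bh <- fit$baseline
  beta <- unname(fit$coef)
  for (x in c(-1, 0.5)) {
    tt <- seq(0, 1500, length.out = 10 * nrow(bh))
    h <- stats::approx(c(0, bh$time), c(0, bh$cumhaz), xout = tt,
                       method = "constant", rule = 2)$y
    s <- exp(-h * exp(beta * x))
    fine <- sum(diff(tt) * (utils::head(s, -1) + utils::tail(s, -1)) / 2)
    expect_lt(abs(cur$rmst[cur$index == x] - fine) / fine, 0.005)
  }

  # beta = 0 gives a flat curve at the baseline RMST
  fit0 <- fit; fit0$coef[] <- 0
  cur0 <- rms_curve(fit0, grid, tau = 1500)
  expect_lt(diff(range(cur0$rmst)), 1e-9)

  expect_warning(rms_curve(fit, c(grid, 99), tau = 1500), "extrapolat")
})

test_that("estimators are invariant to sample ordering", {
  d <- sim_one_cov(120, 0.8, seed = 97)
  mk <- pairsurv:::with_seed(98, d$x + rnorm(120, sd = 0.3))
  perm <- pairsurv:::with_seed(99, sample.int(120))

  expect_equal(km_fit(d$time, d$event)$surv,
               km_fit(d$time[perm], d$event[perm])$surv)
  expect_equal(harrell_c(mk, d$time, d$event),
               harrell_c(mk[perm], d$time[perm], d$event[perm]))
  expect_equal(unname(cox_fit(d$time, d$event, cbind(x = d$x))$coef),
               unname(cox_fit(d$time[perm], d$event[perm],
                              cbind(x = d$x[perm]))$coef),
               tolerance = 1e-8)
  expect_equal(td_roc(mk, d$time, d$event, horizon = 900)$auc,
               td_roc(mk[perm], d$time[perm], d$event[perm],
                      horizon = 900)$auc)
})

test_that("log-rank direction is consistent with the Cox coefficient sign", {
  for (s in 1:5) {
    d <- sim_one_cov(200, 0.9, seed = 200 + s)
    g <- as.integer(d$x > 0)
    f <- cox_fit(d$time, d$event, cbind(g = g))
    km_hi <- km_fit(d$time[g == 1], d$event[g == 1])
    km_lo <- km_fit(d$time[g == 0], d$event[g == 0])
    # positive beta: group 1 dies faster, its curve sits lower
    s_hi <- pairsurv:::km_surv_at(km_hi, 1000)
    s_lo <- pairsurv:::km_surv_at(km_lo, 1000)
    expect_equal(unname(sign(f$coef)), sign(s_lo - s_hi))
  }
})
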