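# Shared fixtures, all built in code.

# small expression matrix with named genes/samples
toy_expr <- function(genes = c("A", "B", "C"), n = 4, seed = 1,
                     cohort = "toy") {
  m <- pairsurv:::with_seed(seed, {
    matrix(rnorm(length(genes) * n, 5, 2), length(genes), n,
           dimnames = list(genes, paste0(cohort, "_s", seq_len(n))))
  })
  expression_matrix(m, cohort_id = cohort)
}

# clinical table matching a set of expression matrices
toy_clinical <- function(cohorts, seed = 1) {
  ids <- unlist(lapply(cohorts, colnames))
  cid <- rep(vapply(cohorts, function(x) attr(x, "cohort_id"), ""),
             vapply(cohorts, ncol, 1L))
  pairsurv:::with_seed(seed, data.frame(
    sample_id = ids,
    time_days = round(runif(length(ids), 30, 3000), 1),
    event = rbinom(length(ids), 1, 0.5),
    age = round(rnorm(length(ids), 65, 8)),
    stage = sample(1:2, length(ids), replace = TRUE),
    sex = sample(c("female", "male"), length(ids), replace = TRUE),
    cohort_id = cid, stringsAsFactors = FALSE))
}

# the 15 signature genes with values making exactly one pair indicator 1
profile_single_pair <- function(which_pair) {
  g <- list(ARSB = 2, BAK1 = 2, BAX = 2, BCL2 = 2, BIRC5 = 3, CCL2 = 2,
            CCR2 = 2, CDKN2A = 2, FADD = 2, CX3CL1 = 1, SPHK1 = 1,
            MAP2K7 = 1, TSC1 = 1, MAPK9 = 1, HSPB8 = 1)
  if (which_pair == "ARSB|BIRC5") {
    # defaults already have ARSB < BIRC5 and every other pair gene1 > gene2
  } else if (which_pair == "CCR2|SPHK1") {
    g$ARSB <- 2; g$BIRC5 <- 1; g$MAP2K7 <- 0.5; g$TSC1 <- 0.5
    g$CCR2 <- 1; g$SPHK1 <- 2; g$BCL2 <- 3
    g$CX3CL1 <- 0.5; g$MAPK9 <- 0.5; g$HSPB8 <- 0.5
  } else {
    stop("unknown profile")
  }
  v <- unlist(g)
  expression_matrix(cbind(s1 = v, s2 = v + 0.01), cohort_id = "profile")
}

# independent hand implementation of the two-group log-rank statistic
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) - 1L
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# independent Breslow partial log-likelihood (single or multi covariate)
oracle_breslow_loglik <- function(beta, time, event, x) {
  x <- as.matrix(x)
  eta <- as.vector(x %*% beta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- which(time == t & event == 1)
    rs <- which(time >= t)
    ll <- ll + sum(eta[d]) - length(d) * log(sum(exp(eta[rs])))
  }
  ll
}

# brute-force Harrell C by explicit double loop
oracle_harrell_c <- function(marker, time, event) {
  n <- length(marker); num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    adm <- event[i] == 1 &&
      (time[i] < time[j] || (time[i] == time[j] && event[j] == 0))
    if (!adm) next
    den <- den + 1
    if (marker[i] > marker[j]) num <- num + 1
    else if (marker[i] == marker[j]) num <- num + 0.5
  }
  num / den
}

# simulated survival with one continuous covariate and a known log-HR
sim_one_cov <- function(n, beta, seed, censor = 4000) {
  pairsurv:::with_seed(seed, {
    x <- rnorm(n)
    t_ev <- rweibull(n, 1, 2000) * exp(-x * beta)
    t_c <- runif(n, 0, censor)
    list(x = x, time = pmax(pmin(t_ev, t_c), 1e-3),
         event = as.integer(t_ev <= t_c))
  })
}
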