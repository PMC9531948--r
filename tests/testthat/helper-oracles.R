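# Independent brute-force oracles used to check the package's vectorized
# implementations on small fixtures.

# Negative mean Cox partial log-likelihood by explicit risk-set enumeration
# (Breslow handling of ties).
oracle_cox_loss <- function(s, t, e) {
  D <- sum(e == 1)
  stopifnot(D > 0)
  ll <- 0
  for (i in which(e == 1)) {
    rs <- which(t >= t[i])
    ll <- ll + s[i] - log(sum(exp(s[rs])))
  }
  -ll / D
}

# Product-limit estimator over distinct event times.
oracle_km <- function(times, events, at) {
  ev <- sort(unique(times[events == 1]))
  s <- 1
  for (tt in ev[ev <= at]) {
    n_i <- sum(times >= tt)
    d_i <- sum(times == tt & events == 1)
    s <- s * (1 - d_i / n_i)
  }
  s
}

# Two-group log-rank chi-square by O - E / V tabulation.
oracle_logrank <- function(t1, e1, t2, e2) {
  t <- c(t1, t2); e <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  O <- 0; E <- 0; V <- 0
  for (tt in sort(unique(t[e == 1]))) {
    n1 <- sum(t >= tt & grp == 1)
    n <- sum(t >= tt)
    d1 <- sum(t == tt & e == 1 & grp == 1)
    d <- sum(t == tt & e == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# AUC as the fraction of concordant (positive, negative) pairs, ties 1/2.
oracle_auc <- function(risks, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (risks[i] > risks[j]) + 0.5 * (risks[i] == risks[j])
  tot / (length(pos) * length(neg))
}

# Continuous NRI by direct up/down counting.
oracle_nri <- function(old, new, lab) {
  ev <- which(lab == 1); ne <- which(lab == 0)
  up <- function(i) sum(new[i] > old[i]) / length(i)
  dn <- function(i) sum(new[i] < old[i]) / length(i)
  (up(ev) - dn(ev)) + (dn(ne) - up(ne))
}

# IDI as the difference of discrimination slopes.
oracle_idi <- function(old, new, lab) {
  ev <- lab == 1; ne <- lab == 0
  (mean(new[ev]) - mean(new[ne])) - (mean(old[ev]) - mean(old[ne]))
}

# Net benefit from an explicit confusion matrix.
oracle_net_benefit <- function(p, lab, pt) {
  n <- length(lab)
  tp <- sum(p >= pt & lab == 1)
  fp <- sum(p >= pt & lab == 0)
  tp / n - (fp / n) * pt / (1 - pt)
}

# One hand-buildable patient record, with overridable fields.
make_record <- function(id = "A", age = 60, sex = "male",
                        histology = "adenocarcinoma", lobe = "RUL",
                        stage = "IA", os_time = 60, os_event = 0L,
                        rfs_time = 50, rfs_event = 0L, split = "train") {
  data.frame(id = id, age = age, sex = sex, histology = histology,
             lobe = lobe, stage = stage, os_time = os_time,
             os_event = os_event, rfs_time = rfs_time,
             rfs_event = rfs_event, split = split,
             stringsAsFactors = FALSE)
}

# A small random cohort with splits and graph, for model-level tests.
make_test_graph <- function(n = 60, seed = 1, feature_dim = 6,
                            cfg = similarity_config()) {
  coh <- generate_cohort(cohort_spec(n_patients = n, seed = seed,
                                     feature_dim = feature_dim,
                                     n_informative = min(3, feature_dim)))
  rec <- assign_splits(coh$records, seed = seed)
  build_graph(rec, coh$features, cfg)
}

# Random survival fixture for loss/statistics oracles.
random_fixture <- function(n, seed) {
  set.seed(seed)
  list(s = round(rnorm(n), 2),
       t = sample(1:8, n, replace = TRUE),
       e = rbinom(n, 1, 0.6))
}
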