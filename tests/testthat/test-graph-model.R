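test_that("sage_layer aggregates by normalized edge weights", {
  # 3-node path A - B - C with distinct weights; no activation so the
  # identity-block weight matrix returns [h_v ; agg_v] exactly
  g <- structure(list(
    node_ids = c("A", "B", "C"),
    features = matrix(c(1, 0, 2, 0, 0, 3), 3, 2, byrow = TRUE),
    edges = data.frame(i = c(1L, 2L), j = c(2L, 3L), weight = c(1, 3)),
    masks = list(train = rep(TRUE, 3), val = rep(FALSE, 3),
                 test = rep(FALSE, 3)),
    records = NULL), class = "population_graph")
  p <- list(W = diag(4), b = rep(0, 4))
  out <- sage_layer(g, g$features, p, activation = FALSE)
  # A's only neighbour is B; B aggregates (1*A + 3*C)/4; C's is B
  expect_equal(out[1, ], c(1, 0, 2, 0))
  expect_equal(out[2, ], c(2, 0, (1 * 1 + 3 * 0) / 4, (1 * 0 + 3 * 3) / 4))
  expect_equal(out[3, ], c(0, 3, 2, 0))

  # identical neighbour features: agg equals that feature for any weights
  g$features <- matrix(c(5, 5, 5), 3, 1)
  out2 <- sage_layer(g, g$features, list(W = diag(2), b = c(0, 0)),
                     activation = FALSE)
  expect_equal(out2[, 2], c(5, 5, 5))

  # isolated node: aggregation side is zero
  g$edges <- data.frame(i = 1L, j = 2L, weight = 2)
  out3 <- sage_layer(g, g$features, list(W = diag(2), b = c(0, 0)),
                     activation = FALSE)
  expect_equal(out3[3, ], c(5, 0))
})

test_that("sage_layer is invariant to rescaling all edge weights", {
  g <- make_test_graph(n = 30, seed = 2)
  m <- survival_model(ncol(g$features), hidden = c(5L, 4L), seed = 3)
  h1 <- sage_layer(g, g$features, m$layer1)
  g2 <- g; g2$edges$weight <- g$edges$weight * 7.3
  h2 <- sage_layer(g2, g2$features, m$layer1)
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("forward pass is constant for zero parameters", {
  g <- make_test_graph(n = 25, seed = 4)
  m <- survival_model(ncol(g$features), hidden = c(4L, 3L), seed = 1)
  m$layer1$W[] <- 0; m$layer2$W[] <- 0; m$head$w[] <- 0
  m$head$b <- 0.7
  risks <- predict_risk(g, m)
  expect_equal(unname(risks), rep(0.7, 25))
})

test_that("forward pass is equivariant to node permutation", {
  g <- make_test_graph(n = 40, seed = 6)
  m <- survival_model(ncol(g$features), hidden = c(6L, 4L), seed = 2)
  risks <- predict_risk(g, m)

  set.seed(9)
  perm <- sample(40)
  inv <- order(perm)
  gp <- g
  gp$node_ids <- g$node_ids[perm]
  gp$features <- g$features[perm, ]
  gp$edges <- data.frame(i = pmin(inv[g$edges$i], inv[g$edges$j]),
                         j = pmax(inv[g$edges$i], inv[g$edges$j]),
                         weight = g$edges$weight)
  gp$masks <- lapply(g$masks, `[`, perm)
  risks_p <- predict_risk(gp, m)
  expect_equal(unname(risks_p[inv]), unname(risks), tolerance = 1e-10)
})

test_that("a 4-node forward pass matches a per-node hand computation", {
  set.seed(31)
  feats <- matrix(round(rnorm(8), 2), 4, 2)
  g <- structure(list(
    node_ids = c("a", "b", "c", "d"), features = feats,
    edges = data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 4L),
                       weight = c(2, 1, 4)),
    masks = list(train = rep(TRUE, 4), val = rep(FALSE, 4),
                 test = rep(FALSE, 4)),
    records = NULL), class = "population_graph")
  m <- survival_model(2, hidden = c(3L, 2L), seed = 7)
  risks <- predict_risk(g, m)

  # independent loop-based evaluation
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 2; W[1, 3] <- W[3, 1] <- 1; W[2, 4] <- W[4, 2] <- 4
  layer <- function(H, p) {
    out <- matrix(0, 4, length(p$b))
    for (v in 1:4) {
      nb <- which(W[v, ] > 0)
      agg <- if (length(nb))
        colSums(W[v, nb] * H[nb, , drop = FALSE]) / sum(W[v, nb])
      else rep(0, ncol(H))
      out[v, ] <- pmax(drop(c(H[v, ], agg) %*% p$W) + p$b, 0)
    }
    out
  }
  H2 <- layer(layer(feats, m$layer1), m$layer2)
  expected <- drop(H2 %*% m$head$w) + m$head$b
  expect_equal(unname(risks), expected, tolerance = 1e-6)
})

test_that("cox_loss matches closed forms on degenerate fixtures", {
  expect_equal(cox_loss(c(0, 0), c(1, 2), c(1, 0)), log(2),
               tolerance = 1e-12)
  expect_equal(cox_loss(c(3.2), c(5), c(1)), 0, tolerance = 1e-12)
  expect_error(cox_loss(c(1, 2), c(1, 2), c(0, 0)), "no events")
  # mask restricts both the loss and the risk set
  expect_equal(cox_loss(c(0, 0, 99), c(1, 2, 3), c(1, 0, 0),
                        mask = c(TRUE, TRUE, FALSE)), log(2),
               tolerance = 1e-12)
})

test_that("cox_loss equals brute-force risk-set enumeration", {
  for (k in 1:200) {
    fx <- random_fixture(sample(2:8, 1), seed = 1000 + k)
    if (sum(fx$e) == 0) fx$e[1] <- 1L
    expect_equal(cox_loss(fx$s, fx$t, fx$e),
                 oracle_cox_loss(fx$s, fx$t, fx$e), tolerance = 1e-10)
  }
})

test_that("cox_loss is shift invariant and locally monotone", {
  for (k in 1:50) {
    fx <- random_fixture(8, seed = 2000 + k)
    if (sum(fx$e) == 0) fx$e[1] <- 1L
    base <- cox_loss(fx$s, fx$t, fx$e)
    expect_equal(cox_loss(fx$s + 13.7, fx$t, fx$e), base,
                 tolerance = 1e-9)
  }
  # raising the risk of the earliest event above its risk set lowers loss
  s <- c(0, 0, 0); t <- c(1, 2, 3); e <- c(1, 0, 0)
  expect_lt(cox_loss(c(2, 0, 0), t, e), cox_loss(s, t, e))
})

test_that("Efron and Breslow agree without ties and match coxph with them", {
  fx <- list(s = c(0.5, -1, 0.2, 1.1, -0.3), t = c(1, 2, 3, 4, 5),
             e = c(1, 0, 1, 1, 0))
  expect_equal(cox_loss(fx$s, fx$t, fx$e, ties = "efron"),
               cox_loss(fx$s, fx$t, fx$e, ties = "breslow"),
               tolerance = 1e-12)
  # with ties, check both against coxph's partial likelihood at an offset
  s <- c(0.3, -0.5, 0.8, 0.1, -1, 0.6)
  t <- c(2, 2, 2, 5, 5, 7); e <- c(1, 1, 0, 1, 1, 0)
  for (ties in c("breslow", "efron")) {
    fit <- survival::coxph(survival::Surv(t, e) ~ offset(s), ties = ties)
    expect_equal(cox_loss(s, t, e, ties = ties),
                 -fit$loglik[1] / sum(e), tolerance = 1e-9)
  }
})

test_that("analytic gradients match numeric differentiation", {
  g <- make_test_graph(n = 20, seed = 8, feature_dim = 3)
  m <- survival_model(3, hidden = c(3L, 2L), dropout = 0, seed = 5)
  surv <- list(time = g$records$os_time, event = g$records$os_event)
  if (sum(surv$event[g$masks$train]) == 0) surv$event[1] <- 1L
  A <- sagesurv:::normalized_adjacency(g)
  fw <- sagesurv:::forward_pass(g, m, A = A, keep = TRUE)
  cl <- sagesurv:::cox_loss_internal(fw$s, surv$time, surv$event,
                                     g$masks$train, "breslow", TRUE)
  gr <- sagesurv:::backward_pass(m, fw, matrix(cl$grad, ncol = 1))
  f <- function(mm) cox_loss(sagesurv:::forward_pass(g, mm, A = A),
                             surv$time, surv$event, g$masks$train)
  eps <- 1e-6
  set.seed(2)
  for (k in 1:6) {
    i <- sample(length(m$layer1$W), 1)
    m2 <- m; m2$layer1$W[i] <- m2$layer1$W[i] + eps
    expect_equal((f(m2) - f(m)) / eps, gr$layer1$W[i], tolerance = 1e-4)
  }
  m2 <- m; m2$head$b <- m2$head$b + eps
  expect_equal((f(m2) - f(m)) / eps, gr$head$b, tolerance = 1e-4)
})

test_that("training reduces the loss and is reproducible from its seed", {
  coh <- generate_cohort(cohort_spec(n_patients = 150, seed = 42))
  rec <- assign_splits(coh$records, seed = 42)
  g <- build_graph(rec, coh$features)
  cfg <- train_config(epochs = 40L, patience = 40L, seed = 11)
  fit1 <- train_survival_model(g, cfg)
  expect_lt(tail(fit1$log$train_loss, 1), fit1$log$train_loss[1])
  fit2 <- train_survival_model(g, cfg)
  expect_identical(fit1$log, fit2$log)
  expect_identical(fit1$risks, fit2$risks)

  # no events in the training mask is an error before any training
  g2 <- g
  g2$records$os_event[g2$masks$train] <- 0L
  expect_error(train_survival_model(g2, cfg), "no events")
})

test_that("mean-augmented pooling changes risks but stays permutation-safe", {
  g <- make_test_graph(n = 30, seed = 12)
  m0 <- survival_model(ncol(g$features), hidden = c(4L, 3L), seed = 3)
  mp <- survival_model(ncol(g$features), hidden = c(4L, 3L),
                       pooling = "mean_augment", seed = 3)
  r0 <- predict_risk(g, m0)
  rp <- predict_risk(g, mp)
  expect_false(isTRUE(all.equal(unname(r0), unname(rp))))
  expect_length(mp$head$w, 6L)
})

test_that("models round-trip through the flat-text archive", {
  g <- make_test_graph(n = 60, seed = 14)
  coh_fit <- train_survival_model(g, train_config(epochs = 5L,
                                                  patience = 5L, seed = 2))
  prefix <- file.path(tempdir(), "model_rt")
  save_model(coh_fit$model, prefix)
  back <- load_model(prefix)
  expect_equal(predict_risk(g, back), coh_fit$risks, tolerance = 1e-12)
  unlink(paste0(prefix, c(".json", ".txt")))
})

test_that("concordance_index agrees with survival::concordance", {
  set.seed(19)
  for (k in 1:5) {
    n <- 40
    t <- round(rexp(n, 0.02), 1)
    e <- rbinom(n, 1, 0.6)
    r <- rnorm(n)
    ref <- survival::concordance(survival::Surv(t, e) ~ r, reverse = TRUE)
    expect_equal(concordance_index(r, t, e), unname(ref$concordance),
                 tolerance = 1e-12)
  }
})
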