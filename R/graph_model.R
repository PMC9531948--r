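#' Edge-weighted GraphSAGE survival model
#'
#' Constructs an (untrained) two-layer edge-weighted GraphSAGE network with
#' a linear risk head. Each layer updates node v as
#' `h'_v = relu(W [h_v ; agg_v] + b)` where `agg_v` is the edge-weight
#' normalized mean of the neighbours' features (the zero vector for an
#' isolated node), so neighbours contribute in proportion to their clinical
#' similarity. The head maps the final embedding to a scalar log-risk per
#' patient. With `pooling = "mean_augment"` the graph-wide mean embedding is
#' concatenated to every node embedding before the head.
#'
#' @param input_dim node feature dimension.
#' @param hidden integer length-2, widths of the two layers.
#' @param pooling `"none"` (default) or `"mean_augment"`.
#' @param dropout dropout rate applied to each hidden layer during training.
#' @param seed seed for weight initialization.
#' @return object of class `survival_model` with elements `layer1`,
#'   `layer2` (each `list(W, b)`), `head` (`list(w, b)`) and `config`.
#' @export
survival_model <- function(input_dim, hidden = c(128L, 64L),
                           pooling = c("none", "mean_augment"),
                           dropout = 0.1, seed = 1L) {
  pooling <- match.arg(pooling)
  stopifnot(length(hidden) == 2L, all(hidden >= 1L), input_dim >= 1L,
            dropout >= 0, dropout < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  glorot <- function(nin, nout)
    matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
  head_in <- if (pooling == "mean_augment") 2L * hidden[2] else hidden[2]
  structure(list(
    layer1 = list(W = glorot(2L * input_dim, hidden[1]),
                  b = rep(0, hidden[1])),
    layer2 = list(W = glorot(2L * hidden[1], hidden[2]),
                  b = rep(0, hidden[2])),
    head = list(w = glorot(head_in, 1L), b = 0),
    config = list(input_dim = as.integer(input_dim),
                  hidden = as.integer(hidden), pooling = pooling,
                  dropout = dropout, seed = as.integer(seed))),
    class = "survival_model")
}

#' @export
print.survival_model <- function(x, ...) {
  cat(sprintf(
    "GraphSAGE survival model: %d -> %d -> %d -> risk (pooling %s, dropout %g)\n",
    x$config$input_dim, x$config$hidden[1], x$config$hidden[2],
    x$config$pooling, x$config$dropout))
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }

#' One edge-weighted GraphSAGE layer
#'
#' `agg_v = sum_u w_uv h_u / sum_u w_uv` over neighbours u of v (zero for
#' isolated nodes), then `h'_v = sigma(W [h_v ; agg_v] + b)`. The
#' normalization makes the layer invariant to a global rescaling of the
#' edge weights.
#'
#' @param g a population graph.
#' @param H numeric matrix, one row per node.
#' @param params `list(W, b)` with `W` of dimension `2*ncol(H) x d_out`.
#' @param activation apply ReLU (`TRUE`) or return the linear pre-activation.
#' @param A optional precomputed normalized adjacency (internal reuse).
#' @return matrix of updated node embeddings.
#' @export
sage_layer <- function(g, H, params, activation = TRUE, A = NULL) {
  H <- as.matrix(H)
  if (nrow(H) != length(g$node_ids))
    stop("H rows must align with graph nodes")
  if (nrow(params$W) != 2L * ncol(H))
    stop(sprintf("weight matrix expects input width %d, got %d",
                 nrow(params$W) / 2L, ncol(H)))
  if (is.null(A)) A <- normalized_adjacency(g)
  agg <- as.matrix(A %*% H)
  Z <- cbind(H, agg) %*% params$W
  Z <- sweep(Z, 2L, params$b, `+`)
  if (activation) relu(Z) else Z
}

# Full forward pass; keeps intermediates when backprop = TRUE. Dropout masks
# (inverted dropout, already scaled) are applied only when supplied.
forward_pass <- function(g, m, A = NULL, drop1 = NULL, drop2 = NULL,
                         keep = FALSE) {
  if (is.null(A)) A <- normalized_adjacency(g)
  X <- as.matrix(g$features)
  agg1 <- as.matrix(A %*% X)
  Z1 <- sweep(cbind(X, agg1) %*% m$layer1$W, 2L, m$layer1$b, `+`)
  H1 <- relu(Z1)
  H1d <- if (is.null(drop1)) H1 else H1 * drop1
  agg2 <- as.matrix(A %*% H1d)
  Z2 <- sweep(cbind(H1d, agg2) %*% m$layer2$W, 2L, m$layer2$b, `+`)
  H2 <- relu(Z2)
  H2d <- if (is.null(drop2)) H2 else H2 * drop2
  Hin <- if (m$config$pooling == "mean_augment") {
    mu <- colMeans(H2d)
    cbind(H2d, matrix(mu, nrow(H2d), length(mu), byrow = TRUE))
  } else H2d
  s <- drop(Hin %*% m$head$w) + m$head$b
  if (!keep) return(s)
  list(s = s, X = X, A = A, agg1 = agg1, Z1 = Z1, H1d = H1d, agg2 = agg2,
       Z2 = Z2, H2d = H2d, Hin = Hin, drop1 = drop1, drop2 = drop2)
}

#' Per-patient risk scores from a model
#'
#' Deterministic forward pass over the whole population graph (dropout off);
#' returns one log-risk score per node, named by patient id.
#'
#' @param g a population graph.
#' @param m a [survival_model].
#' @return named numeric vector of risk scores.
#' @export
predict_risk <- function(g, m) {
  if (ncol(g$features) != m$config$input_dim)
    stop("feature width does not match the model")
  s <- forward_pass(g, m)
  names(s) <- g$node_ids
  s
}

# Gradient of the training loss with respect to every parameter; ds is the
# gradient of the loss with respect to the risk vector.
backward_pass <- function(m, fw, ds) {
  h2 <- m$config$hidden[2]
  dw_head <- crossprod(fw$Hin, ds)
  db_head <- sum(ds)
  dHin <- ds %*% t(m$head$w)  # n x head_in
  dH2d <- dHin[, seq_len(h2), drop = FALSE]
  if (m$config$pooling == "mean_augment") {
    dmu <- colSums(dHin[, h2 + seq_len(h2), drop = FALSE]) / nrow(dHin)
    dH2d <- sweep(dH2d, 2L, dmu, `+`)
  }
  dH2 <- if (is.null(fw$drop2)) dH2d else dH2d * fw$drop2
  dZ2 <- dH2 * (fw$Z2 > 0)
  dW2 <- crossprod(cbind(fw$H1d, fw$agg2), dZ2)
  db2 <- colSums(dZ2)
  h1 <- m$config$hidden[1]
  dC <- tcrossprod(dZ2, m$layer2$W)
  dH1d <- dC[, seq_len(h1), drop = FALSE] +
    as.matrix(Matrix::crossprod(fw$A, dC[, h1 + seq_len(h1), drop = FALSE]))
  dH1 <- if (is.null(fw$drop1)) dH1d else dH1d * fw$drop1
  dZ1 <- dH1 * (fw$Z1 > 0)
  dW1 <- crossprod(cbind(fw$X, fw$agg1), dZ1)
  db1 <- colSums(dZ1)
  list(layer1 = list(W = dW1, b = db1), layer2 = list(W = dW2, b = db2),
       head = list(w = dw_head, b = db_head))
}

#' Negative Cox partial log-likelihood
#'
#' The training loss: the negative mean partial log-likelihood of the risk
#' scores over the masked patients,
#' `-(1/D) * sum_{i: event} [ s_i - log sum_{j: t_j >= t_i} exp(s_j) ]`,
#' with `D` the number of events and risk sets formed within the mask.
#' Tied event times are handled by the Breslow approximation by default,
#' or Efron's correction with `ties = "efron"`. Adding a constant to all
#' risks leaves the loss unchanged.
#'
#' @param risks numeric vector of log-risk scores.
#' @param times observed times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param mask logical vector restricting loss and risk sets (default all).
#' @param ties `"breslow"` or `"efron"`.
#' @return scalar loss.
#' @export
cox_loss <- function(risks, times, events, mask = NULL,
                     ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  cox_loss_internal(risks, times, events, mask, ties, gradient = FALSE)$loss
}

cox_loss_internal <- function(risks, times, events, mask, ties, gradient) {
  n <- length(risks)
  stopifnot(length(times) == n, length(events) == n)
  if (is.null(mask)) mask <- rep(TRUE, n)
  idx <- which(mask)
  s <- risks[idx]; t <- times[idx]; e <- events[idx]
  D <- sum(e == 1)
  if (D == 0L) stop("no events in the masked set; Cox loss undefined")
  ord <- order(t)
  s <- s[ord]; t <- t[ord]; e <- e[ord]
  m <- length(s)
  smax <- max(s)
  es <- exp(s - smax)                       # stabilized exponentials
  cs <- rev(cumsum(rev(es)))                # sum_{j >= i} exp(s_j - smax)
  grp_first <- match(t, t)
  grp_last <- m + 1L - match(t, rev(t))
  S <- cs[grp_first]                        # risk-set sums (t_j >= t_i)

  grad_s <- NULL
  if (ties == "breslow") {
    loss <- -(sum(s[e == 1]) - sum(log(S[e == 1]) + smax)) / D
    if (gradient) {
      contrib <- ifelse(e == 1, 1 / S, 0)
      cum <- cumsum(contrib)
      B <- cum[grp_last]                    # events with t_i <= t_k
      grad_s <- -(e - es * B) / D
    }
  } else {
    # Efron: per tied event-time group, denominators S - (l/d) * T_tied.
    loss_terms <- sum(s[e == 1])
    logden <- 0
    if (gradient) grad_s <- rep(0, m)
    ev_times <- unique(t[e == 1])
    for (tt in ev_times) {
      tie <- which(t == tt & e == 1)
      d <- length(tie)
      Sg <- S[grp_first[tie[1]]]
      Tg <- sum(es[tie])
      l <- seq_len(d) - 1
      den <- Sg - (l / d) * Tg
      logden <- logden + sum(log(den) + smax)
      if (gradient) {
        inv <- 1 / den
        at_risk <- which(t >= tt)
        grad_s[at_risk] <- grad_s[at_risk] + es[at_risk] * sum(inv)
        grad_s[tie] <- grad_s[tie] - es[tie] * sum(l / d * inv)
      }
    }
    loss <- -(loss_terms - logden) / D
    if (gradient) grad_s <- -(e - grad_s) / D
  }

  out <- list(loss = loss)
  if (gradient) {
    full <- rep(0, n)
    full[idx[ord]] <- grad_s
    out$grad <- full
  }
  out
}

#' Training configuration
#'
#' Optimization settings for [train_survival_model()]. Training is
#' transductive: the whole graph (all nodes and edges) is visible in the
#' forward pass, and the Cox loss is evaluated over the training mask only.
#' Adam with full-graph gradients; early stopping monitors the validation
#' Cox loss and the parameters from the best validation epoch are returned.
#'
#' @param endpoint `"OS"` or `"RFS"`.
#' @param learning_rate Adam step size.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement); must not exceed `epochs`.
#' @param weight_decay L2 penalty coefficient on the weight matrices
#'   (added to their gradient; biases are not penalized). Counters the
#'   rapid overfitting a high-capacity network shows on a few hundred
#'   training patients.
#' @param ties tie handling for the Cox loss.
#' @param hidden widths of the two GraphSAGE layers.
#' @param dropout dropout rate during training.
#' @param pooling `"none"` or `"mean_augment"`.
#' @param seed seed governing initialization and dropout.
#' @param verbose print progress every 50 epochs.
#' @return object of class `train_config`.
#' @export
train_config <- function(endpoint = c("OS", "RFS"), learning_rate = 1e-3,
                         epochs = 300L, patience = 30L,
                         weight_decay = 0.5,
                         ties = c("breslow", "efron"),
                         hidden = c(128L, 64L), dropout = 0.1,
                         pooling = c("none", "mean_augment"),
                         seed = 1L, verbose = FALSE) {
  endpoint <- match.arg(endpoint)
  ties <- match.arg(ties)
  pooling <- match.arg(pooling)
  stopifnot(epochs >= 1L, patience >= 1L, patience <= epochs,
            learning_rate > 0, weight_decay >= 0)
  structure(list(endpoint = endpoint, learning_rate = learning_rate,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 weight_decay = weight_decay,
                 ties = ties, hidden = as.integer(hidden), dropout = dropout,
                 pooling = pooling, seed = as.integer(seed),
                 verbose = verbose),
            class = "train_config")
}

endpoint_columns <- function(records, endpoint) {
  if (endpoint == "OS") list(time = records$os_time, event = records$os_event)
  else list(time = records$rfs_time, event = records$rfs_event)
}

# Flatten/unflatten model parameters for the optimizer and serialization.
param_list <- function(m) list(W1 = m$layer1$W, b1 = m$layer1$b,
                               W2 = m$layer2$W, b2 = m$layer2$b,
                               w = m$head$w, bh = m$head$b)
set_params <- function(m, p) {
  m$layer1$W <- p$W1; m$layer1$b <- p$b1
  m$layer2$W <- p$W2; m$layer2$b <- p$b2
  m$head$w <- p$w; m$head$b <- p$bh
  m
}

#' Train the GraphSAGE survival model
#'
#' Transductive full-graph training with Adam on the negative Cox partial
#' log-likelihood over the training nodes. Early stopping monitors the
#' validation-mask Cox loss (falling back to the training loss when the
#' validation mask has no events); the parameters of the best validation
#' epoch are returned.
#'
#' @param g a population graph with split masks.
#' @param cfg a [train_config()].
#' @return list of class `sage_fit`: `model` (best-validation parameters),
#'   `risks` (per-node scores from the best model), `log` (data.frame
#'   epoch / train_loss / val_loss), `best_epoch`, `config`.
#' @export
train_survival_model <- function(g, cfg = train_config()) {
  surv <- endpoint_columns(g$records, cfg$endpoint)
  if (sum(surv$event[g$masks$train]) == 0L)
    stop("no events among training nodes; cannot fit a Cox-type loss")
  val_ok <- sum(surv$event[g$masks$val]) > 0L
  if (!val_ok)
    warning("no events among validation nodes; early stopping on train loss")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  m <- survival_model(ncol(g$features), hidden = cfg$hidden,
                      pooling = cfg$pooling, dropout = cfg$dropout,
                      seed = cfg$seed)
  A <- normalized_adjacency(g)
  n <- length(g$node_ids)

  p <- param_list(m)
  adam_m <- lapply(p, function(x) x * 0)
  adam_v <- lapply(p, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  keep <- 1 - cfg$dropout

  best_val <- Inf; best_p <- p; best_epoch <- 0L; stall <- 0L
  log_tr <- numeric(cfg$epochs); log_va <- numeric(cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    drop1 <- drop2 <- NULL
    if (cfg$dropout > 0) {
      drop1 <- matrix(stats::rbinom(n * cfg$hidden[1], 1L, keep) / keep,
                      n, cfg$hidden[1])
      drop2 <- matrix(stats::rbinom(n * cfg$hidden[2], 1L, keep) / keep,
                      n, cfg$hidden[2])
    }
    fw <- forward_pass(g, m, A = A, drop1 = drop1, drop2 = drop2, keep = TRUE)
    cl <- cox_loss_internal(fw$s, surv$time, surv$event, g$masks$train,
                            cfg$ties, gradient = TRUE)
    grads <- backward_pass(m, fw, matrix(cl$grad, ncol = 1L))
    gflat <- list(W1 = grads$layer1$W, b1 = grads$layer1$b,
                  W2 = grads$layer2$W, b2 = grads$layer2$b,
                  w = grads$head$w, bh = grads$head$b)
    for (k in names(p)) {
      gk <- gflat[[k]]
      if (cfg$weight_decay > 0 && k %in% c("W1", "W2", "w"))
        gk <- gk + cfg$weight_decay * p[[k]]
      adam_m[[k]] <- b1 * adam_m[[k]] + (1 - b1) * gk
      adam_v[[k]] <- b2 * adam_v[[k]] + (1 - b2) * gk^2
      mhat <- adam_m[[k]] / (1 - b1^epoch)
      vhat <- adam_v[[k]] / (1 - b2^epoch)
      p[[k]] <- p[[k]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
    }
    m <- set_params(m, p)

    s_eval <- forward_pass(g, m, A = A)
    log_tr[epoch] <- cox_loss_internal(s_eval, surv$time, surv$event,
                                       g$masks$train, cfg$ties, FALSE)$loss
    log_va[epoch] <- if (val_ok)
      cox_loss_internal(s_eval, surv$time, surv$event, g$masks$val,
                        cfg$ties, FALSE)$loss
    else log_tr[epoch]
    if (cfg$verbose && epoch %% 50L == 0L)
      message(sprintf("epoch %d  train %.4f  val %.4f",
                      epoch, log_tr[epoch], log_va[epoch]))

    if (log_va[epoch] < best_val - 1e-9) {
      best_val <- log_va[epoch]; best_p <- p; best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  n_run <- epoch
  m <- set_params(m, best_p)
  risks <- predict_risk(g, m)
  structure(list(model = m, risks = risks,
                 log = data.frame(epoch = seq_len(n_run),
                                  train_loss = log_tr[seq_len(n_run)],
                                  val_loss = log_va[seq_len(n_run)]),
                 best_epoch = best_epoch, config = cfg),
            class = "sage_fit")
}

#' @export
print.sage_fit <- function(x, ...) {
  cat(sprintf(
    "GraphSAGE survival fit (%s): %d epochs run, best validation loss %.4f at epoch %d\n",
    x$config$endpoint, nrow(x$log), min(x$log$val_loss), x$best_epoch))
  invisible(x)
}

#' Concordance index of a risk score
#'
#' Harrell's C for right-censored data: over comparable pairs (the earlier
#' time is an observed event), the fraction in which the shorter-lived
#' patient has the higher risk score, counting ties as 1/2.
#'
#' @param risks risk scores (higher = worse prognosis).
#' @param times observed times.
#' @param events event indicators.
#' @return scalar in `[0, 1]` (NA if no comparable pairs).
#' @export
concordance_index <- function(risks, times, events) {
  n <- length(risks)
  stopifnot(length(times) == n, length(events) == n)
  conc <- 0; comp <- 0
  for (i in which(events == 1)) {
    later <- times > times[i]
    comp <- comp + sum(later)
    conc <- conc + sum(risks[i] > risks[later]) +
      0.5 * sum(risks[i] == risks[later])
    # tied times with one censored: the event patient is comparable too
    tied_cens <- times == times[i] & events == 0
    comp <- comp + sum(tied_cens)
    conc <- conc + sum(risks[i] > risks[tied_cens]) +
      0.5 * sum(risks[i] == risks[tied_cens])
  }
  if (comp == 0) return(NA_real_)
  conc / comp
}

#' Save / load a model as plain text
#'
#' Parameters are written as one flat numeric vector (one value per line)
#' next to a JSON sidecar recording shapes and configuration.
#'
#' @param m a [survival_model].
#' @param prefix path prefix; writes `<prefix>.json` and `<prefix>.txt`.
#' @return the prefix (save) or the model (load), invisibly.
#' @export
save_model <- function(m, prefix) {
  p <- param_list(m)
  shapes <- lapply(p, function(x) if (is.matrix(x)) dim(x) else length(x))
  jsonlite::write_json(list(config = m$config, shapes = shapes),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  writeLines(format(unlist(p, use.names = FALSE), digits = 17),
             paste0(prefix, ".txt"))
  invisible(prefix)
}

#' @rdname save_model
#' @export
load_model <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  vals <- as.numeric(readLines(paste0(prefix, ".txt")))
  m <- survival_model(meta$config$input_dim, hidden = meta$config$hidden,
                      pooling = meta$config$pooling,
                      dropout = meta$config$dropout, seed = meta$config$seed)
  p <- param_list(m)
  pos <- 0L
  for (k in names(p)) {
    sh <- meta$shapes[[k]]
    len <- prod(sh)
    chunk <- vals[pos + seq_len(len)]
    p[[k]] <- if (length(sh) == 2L) matrix(chunk, sh[1], sh[2]) else chunk
    pos <- pos + len
  }
  set_params(m, p)
}
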