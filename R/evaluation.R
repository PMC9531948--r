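#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function,
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the observed event times,
#' computed via [survival::survfit()].
#'
#' @param times observed times (months).
#' @param events event indicators (1 = event, 0 = censored).
#' @return object of class `survival_curve`: list with `event_times`
#'   (ascending), `survival`, `at_risk` and `n`.
#' @export
km_curve <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (length(times) == 0L) stop("empty input")
  if (any(times < 0)) stop("times must be non-negative")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(event_times = sf$time, survival = sf$surv,
                 at_risk = sf$n.risk, n = length(times)),
            class = "survival_curve")
}

#' Evaluate a survival curve at arbitrary times
#'
#' @param curve a [km_curve()] result.
#' @param t times at which to read off the step function.
#' @return survival probabilities (1 before the first observed time).
#' @export
km_at <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  vapply(t, function(tt) {
    i <- findInterval(tt, curve$event_times)
    if (i == 0L) 1 else curve$survival[i]
  }, numeric(1))
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d time points, S(last) = %.3f\n",
              x$n, length(x$event_times),
              if (length(x$survival)) x$survival[length(x$survival)] else 1))
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, ..., col = "black", add = FALSE,
                                xlab = "Months", ylab = "Survival") {
  t <- c(0, x$event_times)
  s <- c(1, x$survival)
  if (add) graphics::lines(t, s, type = "s", col = col, ...)
  else graphics::plot(t, s, type = "s", ylim = c(0, 1), col = col,
                      xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square comparing two survival curves,
#' computed via [survival::survdiff()].
#'
#' @param times_a,events_a first group.
#' @param times_b,events_b second group.
#' @return list with `statistic` and `p`.
#' @export
logrank <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    stop("both groups must be non-empty")
  grp <- c(rep(0L, length(times_a)), rep(1L, length(times_b)))
  sd <- survival::survdiff(
    survival::Surv(c(times_a, times_b), c(events_a, events_b)) ~ grp)
  list(statistic = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Stratify patients by the training-median risk
#'
#' The threshold is the median risk over training nodes only; patients with
#' risk strictly above it are labelled `"high"`, all others `"low"`.
#' Evaluation-set risks never influence the threshold.
#'
#' @param risks per-patient risk scores.
#' @param train_mask logical vector marking training patients.
#' @return object of class `risk_groups`: list with `threshold` and
#'   `labels` (character vector aligned with `risks`).
#' @export
risk_stratify <- function(risks, train_mask) {
  stopifnot(length(risks) == length(train_mask))
  if (!any(train_mask)) stop("train_mask selects no patients")
  thr <- stats::median(risks[train_mask])
  structure(list(threshold = thr,
                 labels = ifelse(risks > thr, "high", "low")),
            class = "risk_groups")
}

# Binary survival status at a fixed horizon: 1 if the event occurred by the
# horizon, 0 if followed beyond it, NA (excluded) if censored before it.
horizon_labels <- function(times, events, horizon) {
  ifelse(times <= horizon & events == 1, 1L,
         ifelse(times > horizon, 0L, NA_integer_))
}

# Mann-Whitney AUC: ties in risk count 1/2.
auc_mw <- function(risks, labels) {
  pos <- risks[labels == 1]; neg <- risks[labels == 0]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("need both classes to compute an AUC")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' AUC at a fixed horizon with bootstrap confidence interval
#'
#' Binarizes survival status at `horizon` months (event by the horizon =
#' positive; censored before the horizon excluded), computes the
#' Mann-Whitney AUC of the risk scores against that status, and attaches a
#' seeded percentile bootstrap CI.
#'
#' @param risks risk scores (higher = worse prognosis).
#' @param times,events survival endpoint.
#' @param horizon months (default 60: 5-year status).
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @return list with `auc`, `ci` (length 2), `n_used`, `n_excluded`.
#' @export
auc_ci <- function(risks, times, events, horizon = 60, n_boot = 1000L,
                   conf = 0.95, seed = 1L) {
  if (horizon <= 0) stop("horizon must be positive")
  lab <- horizon_labels(times, events, horizon)
  use <- !is.na(lab)
  r <- risks[use]; l <- lab[use]
  point <- auc_mw(r, l)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(length(r), replace = TRUE)
    if (length(unique(l[i])) < 2L) return(NA_real_)
    auc_mw(r[i], l[i])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  list(auc = point, ci = ci, n_used = sum(use), n_excluded = sum(!use))
}

nri_point <- function(old_r, new_r, labels) {
  ev <- labels == 1; ne <- labels == 0
  up_e <- mean(new_r[ev] > old_r[ev]); dn_e <- mean(new_r[ev] < old_r[ev])
  up_n <- mean(new_r[ne] > old_r[ne]); dn_n <- mean(new_r[ne] < old_r[ne])
  (up_e - dn_e) + (dn_n - up_n)
}

idi_point <- function(old_p, new_p, labels) {
  ev <- labels == 1; ne <- labels == 0
  (mean(new_p[ev]) - mean(old_p[ev])) - (mean(new_p[ne]) - mean(old_p[ne]))
}

boot_ci <- function(stat, n, n_boot, conf, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, replace = TRUE)
    stat(i)
  }, numeric(1))
  alpha <- (1 - conf) / 2
  stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
}

#' Continuous net reclassification improvement
#'
#' Category-free NRI of a new risk score against an old one:
#' `[P(up | event) - P(down | event)] + [P(down | non-event) -
#' P(up | non-event)]`, where up/down mean the new score moved strictly
#' above/below the old. Ranges over `[-2, 2]`; antisymmetric under swapping
#' old and new. The two scores are compared within subject, so they must
#' live on a common scale; map raw scores from different models through
#' [rank_to_probability()] first.
#'
#' @param risks_old,risks_new risk scores under the two models (common
#'   scale).
#' @param labels binary outcome labels (1 = event).
#' @param n_boot,conf,seed percentile bootstrap settings.
#' @return list with `nri` and `ci`.
#' @export
nri <- function(risks_old, risks_new, labels, n_boot = 1000L, conf = 0.95,
                seed = 1L) {
  stopifnot(length(risks_old) == length(risks_new),
            length(risks_old) == length(labels))
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop("labels must contain both events and non-events")
  use <- !is.na(labels)
  ro <- risks_old[use]; rn <- risks_new[use]; l <- labels[use]
  ci <- boot_ci(function(i) {
    if (length(unique(l[i])) < 2L) return(NA_real_)
    nri_point(ro[i], rn[i], l[i])
  }, length(l), n_boot, conf, seed)
  list(nri = nri_point(ro, rn, l), ci = ci)
}

#' Integrated discrimination improvement
#'
#' Difference in discrimination slopes between two probability-scale risk
#' models: `(mean_new - mean_old | events) - (mean_new - mean_old |
#' non-events)`. Inputs must already be probabilities in `[0, 1]`; map raw
#' scores with [rank_to_probability()] first.
#'
#' @param probs_old,probs_new risk probabilities under the two models.
#' @param labels binary outcome labels (1 = event).
#' @param n_boot,conf,seed percentile bootstrap settings.
#' @return list with `idi` and `ci`.
#' @export
idi <- function(probs_old, probs_new, labels, n_boot = 1000L, conf = 0.95,
                seed = 1L) {
  stopifnot(length(probs_old) == length(probs_new),
            length(probs_old) == length(labels))
  if (any(probs_old < 0 | probs_old > 1 | probs_new < 0 | probs_new > 1,
          na.rm = TRUE))
    stop("IDI needs probabilities in [0, 1]; see rank_to_probability()")
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop("labels must contain both events and non-events")
  use <- !is.na(labels)
  po <- probs_old[use]; pn <- probs_new[use]; l <- labels[use]
  ci <- boot_ci(function(i) {
    if (length(unique(l[i])) < 2L) return(NA_real_)
    idi_point(po[i], pn[i], l[i])
  }, length(l), n_boot, conf, seed)
  list(idi = idi_point(po, pn, l), ci = ci)
}

#' Map raw risk scores to the probability scale by rank
#'
#' Within-cohort rank scaling `(rank - 0.5) / n`: a monotone map of raw
#' log-risk scores onto `(0, 1)` so that probability-scale metrics (IDI,
#' decision curves) can be applied to uncalibrated scores. Average ranks are
#' used for ties.
#'
#' @param risks numeric scores.
#' @return probabilities in `(0, 1)` preserving the ordering of `risks`.
#' @export
rank_to_probability <- function(risks) {
  (rank(risks, ties.method = "average") - 0.5) / length(risks)
}

#' Decision curve analysis
#'
#' Net benefit of treating patients whose risk probability reaches each
#' threshold `p_t`: `NB(p_t) = TP/n - FP/n * p_t / (1 - p_t)`, together
#' with the treat-all and treat-none reference policies.
#'
#' @param risk_probs risk probabilities in `[0, 1]`.
#' @param labels binary outcome labels (1 = event).
#' @param thresholds decision thresholds in (0, 1).
#' @return data.frame with `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
dca <- function(risk_probs, labels, thresholds = seq(0.05, 0.6, by = 0.05)) {
  stopifnot(length(risk_probs) == length(labels))
  if (any(risk_probs < 0 | risk_probs > 1))
    stop("risk_probs must lie in [0, 1]")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  use <- !is.na(labels)
  p <- risk_probs[use]; l <- labels[use]
  n <- length(l)
  prev <- mean(l)
  out <- lapply(thresholds, function(pt) {
    pos <- p >= pt
    tp <- sum(pos & l == 1) / n
    fp <- sum(pos & l == 0) / n
    odds <- pt / (1 - pt)
    data.frame(threshold = pt,
               net_benefit = tp - fp * odds,
               treat_all = prev - (1 - prev) * odds,
               treat_none = 0)
  })
  do.call(rbind, out)
}

#' Full model-comparison report for one endpoint
#'
#' Runs the whole evaluation stack on the test set for a proposed risk
#' score against a baseline score (e.g. the stage-ordinal score standing in
#' for TNM staging): horizon AUC with bootstrap CI for both models,
#' training-median stratified KM curves with the log-rank test, continuous
#' NRI and IDI of proposed vs baseline, and decision curves.
#'
#' @param risks_new proposed per-patient risk scores (all patients).
#' @param risks_old baseline risk scores (all patients, aligned).
#' @param times,events the survival endpoint (all patients, aligned).
#' @param train_mask,eval_mask logical vectors: where the stratification
#'   threshold is learned and where metrics are computed.
#' @param endpoint label, `"OS"` or `"RFS"`.
#' @param horizon AUC/DCA status horizon in months.
#' @param n_boot,seed bootstrap settings.
#' @return object of class `eval_report`.
#' @export
evaluate_models <- function(risks_new, risks_old, times, events,
                            train_mask, eval_mask, endpoint = "OS",
                            horizon = 60, n_boot = 1000L, seed = 1L) {
  n <- length(risks_new)
  stopifnot(length(risks_old) == n, length(times) == n, length(events) == n,
            length(train_mask) == n, length(eval_mask) == n)

  auc_new <- auc_ci(risks_new[eval_mask], times[eval_mask],
                    events[eval_mask], horizon, n_boot, seed = seed)
  auc_old <- auc_ci(risks_old[eval_mask], times[eval_mask],
                    events[eval_mask], horizon, n_boot, seed = seed)

  groups <- risk_stratify(risks_new, train_mask)
  lab_eval <- groups$labels[eval_mask]
  hi <- lab_eval == "high"
  km_high <- km_curve(times[eval_mask][hi], events[eval_mask][hi])
  km_low <- km_curve(times[eval_mask][!hi], events[eval_mask][!hi])
  lr <- logrank(times[eval_mask][hi], events[eval_mask][hi],
                times[eval_mask][!hi], events[eval_mask][!hi])

  status <- horizon_labels(times[eval_mask], events[eval_mask], horizon)
  # both scores are rank-calibrated so the within-subject old-vs-new
  # comparisons of NRI/IDI/DCA happen on a common scale
  p_new <- rank_to_probability(risks_new[eval_mask])
  p_old <- rank_to_probability(risks_old[eval_mask])
  nri_res <- nri(p_old, p_new, status, n_boot, seed = seed)
  idi_res <- idi(p_old, p_new, status, n_boot, seed = seed)
  dca_new <- dca(p_new, status)
  dca_old <- dca(p_old, status)

  structure(list(endpoint = endpoint, horizon = horizon,
                 auc = auc_new$auc, auc_ci = auc_new$ci,
                 auc_baseline = auc_old$auc, auc_baseline_ci = auc_old$ci,
                 logrank_p = lr$p, logrank_statistic = lr$statistic,
                 risk_threshold = groups$threshold,
                 km_high = km_high, km_low = km_low,
                 nri = nri_res$nri, nri_ci = nri_res$ci,
                 idi = idi_res$idi, idi_ci = idi_res$ci,
                 dca = dca_new, dca_baseline = dca_old,
                 n_eval = sum(eval_mask), n_excluded = auc_new$n_excluded),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report (%s, %g-month horizon, n = %d):\n",
              x$endpoint, x$horizon, x$n_eval))
  cat(sprintf("  AUC          %.3f (95%% CI %.3f-%.3f)   baseline %.3f (%.3f-%.3f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2],
              x$auc_baseline, x$auc_baseline_ci[1], x$auc_baseline_ci[2]))
  cat(sprintf("  log-rank p   %.4g (high vs low risk)\n", x$logrank_p))
  cat(sprintf("  NRI          %.3f (%.3f-%.3f)\n", x$nri, x$nri_ci[1],
              x$nri_ci[2]))
  cat(sprintf("  IDI          %.3f (%.3f-%.3f)\n", x$idi, x$idi_ci[1],
              x$idi_ci[2]))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an [evaluate_models()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- report
  class(out) <- NULL
  out$km_high <- unclass(out$km_high)
  out$km_low <- unclass(out$km_low)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot stratified KM curves or decision curves from a report
#'
#' @param x an `eval_report`.
#' @param which `"km"` or `"dca"`.
#' @param ... passed to the underlying plot calls.
#' @export
plot.eval_report <- function(x, which = c("km", "dca"), ...) {
  which <- match.arg(which)
  if (which == "km") {
    plot(x$km_low, col = "steelblue",
         main = sprintf("%s: KM by risk group (log-rank p = %.3g)",
                        x$endpoint, x$logrank_p), ...)
    plot(x$km_high, col = "firebrick", add = TRUE)
    graphics::legend("bottomleft", c("low risk", "high risk"),
                     col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  } else {
    d <- x$dca
    graphics::plot(d$threshold, d$net_benefit, type = "l", col = "firebrick",
                   ylim = range(c(d$net_benefit, d$treat_all, 0)),
                   xlab = "Threshold probability", ylab = "Net benefit",
                   main = sprintf("%s: decision curves", x$endpoint), ...)
    graphics::lines(x$dca_baseline$threshold, x$dca_baseline$net_benefit,
                    col = "steelblue")
    graphics::lines(d$threshold, d$treat_all, col = "grey40", lty = 2)
    graphics::abline(h = 0, col = "grey40", lty = 3)
    graphics::legend("topright",
                     c("model", "baseline", "treat all", "treat none"),
                     col = c("firebrick", "steelblue", "grey40", "grey40"),
                     lty = c(1, 1, 2, 3), bty = "n")
  }
  invisible(x)
}
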