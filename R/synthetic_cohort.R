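#' Specification of a synthetic NSCLC cohort
#'
#' Collects the distributional assumptions used by [generate_cohort()].
#' Defaults reproduce the covariate marginals of a large single-centre
#' early stage (I-II) NSCLC surgical cohort: 59.2% male, mean age 60.6
#' (SD 8.7), 72.4% adenocarcinoma, stage distribution IA 46.4% / IB 35.6% /
#' IIA 7.8% / IIB 10.2%, and upper-lobe predominance. Survival is simulated
#' from a Weibull proportional-hazards model whose baseline parameters are
#' calibrated so that, at the default effect sizes, roughly 78% of patients
#' survive 5 years (overall survival) and roughly 74% are recurrence-free.
#'
#' The linear predictor (true log-hazard) is
#' `effect_stage * stage_ordinal + effect_image * z`, where `stage_ordinal`
#' codes IA=0, IB=1, IIA=2, IIB=3 and `z` is a standard-normal latent image
#' score, independent of the clinical covariates. Recurrence shares the same
#' linear predictor with its own baseline scale; recurrence-free survival
#' time is the minimum of the recurrence and death times. Follow-up ends by
#' administrative censoring at `admin_censor_time` months.
#'
#' The image features handed to downstream models are Gaussian noise in
#' which the first `n_informative` columns are mean-shifted by `z`; the
#' remaining columns carry no survival signal.
#'
#' @param n_patients number of patients.
#' @param p_male probability of male sex.
#' @param age_mean,age_sd age distribution in years (normal, truncated at
#'   18 and 95).
#' @param histology_probs named probabilities over
#'   `c("adenocarcinoma", "squamous", "other")`.
#' @param lobe_probs named probabilities over
#'   `c("LUL", "LLL", "RUL", "RML", "RLL")`.
#' @param stage_probs named probabilities over `c("IA", "IB", "IIA", "IIB")`.
#' @param feature_dim length of each per-patient feature vector.
#' @param n_informative number of feature columns carrying the latent image
#'   score; must not exceed `feature_dim`.
#' @param effect_stage log-hazard increment per stage ordinal step.
#' @param effect_image log-hazard increment per SD of the latent image score.
#' @param image_clinical_corr correlation in `[-1, 1]` between the latent
#'   image score and the (standardized) stage ordinal; 0 (the default)
#'   keeps the imaging and clinical channels independent.
#' @param baseline_shape Weibull shape parameter (shared by both endpoints).
#' @param baseline_scale Weibull scale (months) for overall survival.
#' @param recurrence_scale Weibull scale (months) for the recurrence process.
#' @param admin_censor_time administrative censoring time in months.
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_patients = 400,
                        p_male = 0.592,
                        age_mean = 60.6,
                        age_sd = 8.7,
                        histology_probs = c(adenocarcinoma = 0.724,
                                            squamous = 0.229,
                                            other = 0.047),
                        lobe_probs = c(LUL = 0.255, LLL = 0.146, RUL = 0.342,
                                       RML = 0.094, RLL = 0.163),
                        stage_probs = c(IA = 0.464, IB = 0.356,
                                        IIA = 0.078, IIB = 0.102),
                        feature_dim = 32,
                        n_informative = 8,
                        effect_stage = 0.5,
                        effect_image = 1.0,
                        image_clinical_corr = 0,
                        baseline_shape = 1.2,
                        baseline_scale = 375,
                        recurrence_scale = 1130,
                        admin_censor_time = 84,
                        seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients), p_male = p_male,
               age_mean = age_mean, age_sd = age_sd,
               histology_probs = histology_probs, lobe_probs = lobe_probs,
               stage_probs = stage_probs,
               feature_dim = as.integer(feature_dim),
               n_informative = as.integer(n_informative),
               effect_stage = effect_stage, effect_image = effect_image,
               image_clinical_corr = image_clinical_corr,
               baseline_shape = baseline_shape,
               baseline_scale = baseline_scale,
               recurrence_scale = recurrence_scale,
               admin_censor_time = admin_censor_time,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_patients < 1L) stop("n_patients must be positive")
  if (spec$p_male < 0 || spec$p_male > 1) stop("p_male must be in [0, 1]")
  check_probs <- function(p, vocab, what) {
    if (!setequal(names(p), vocab))
      stop(sprintf("%s must be named over {%s}", what,
                   paste(vocab, collapse = ", ")))
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop(sprintf("%s must be non-negative and sum to 1", what))
  }
  check_probs(spec$histology_probs, histology_levels(), "histology_probs")
  check_probs(spec$lobe_probs, lobe_levels(), "lobe_probs")
  check_probs(spec$stage_probs, stage_levels(), "stage_probs")
  if (spec$n_informative < 0L || spec$n_informative > spec$feature_dim)
    stop("n_informative must lie in [0, feature_dim]")
  if (spec$baseline_shape <= 0 || spec$baseline_scale <= 0 ||
      spec$recurrence_scale <= 0)
    stop("Weibull parameters must be positive")
  if (spec$admin_censor_time <= 0) stop("admin_censor_time must be positive")
  if (abs(spec$image_clinical_corr) > 1)
    stop("image_clinical_corr must lie in [-1, 1]")
  invisible(spec)
}

histology_levels <- function() c("adenocarcinoma", "squamous", "other")
lobe_levels <- function() c("LUL", "LLL", "RUL", "RML", "RLL")
stage_levels <- function() c("IA", "IB", "IIA", "IIB")

#' Ordinal coding of pathological sub-stage
#'
#' IA=0, IB=1, IIA=2, IIB=3 -- the natural ordering of the four sub-stages.
#'
#' @param stage character vector of sub-stages.
#' @return integer vector.
#' @export
stage_ordinal <- function(stage) {
  m <- match(stage, stage_levels())
  if (anyNA(m)) stop("unknown stage label(s): ",
                     paste(unique(stage[is.na(m)]), collapse = ", "))
  m - 1L
}

# Inverse-CDF Weibull proportional-hazards sampler: hazard multiplier
# exp(eta) on a Weibull(shape, scale) baseline.
rweibull_ph <- function(n, shape, scale, eta) {
  u <- stats::runif(n)
  scale * (-log(u) / exp(eta))^(1 / shape)
}

#' Generate a synthetic cohort
#'
#' Draws clinical covariates, latent image scores, image feature vectors and
#' survival endpoints (overall and recurrence-free) according to a
#' [cohort_spec()]. Censoring is administrative: the observed time is the
#' minimum of the event time and `spec$admin_censor_time`.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `synthetic_cohort`: a list with
#'   \describe{
#'     \item{records}{data.frame of patient records (clinical table schema,
#'       see [read_clinical()]), without split assignment.}
#'     \item{features}{numeric matrix, one row per patient.}
#'     \item{latent_risk}{true per-patient log-hazard.}
#'     \item{latent_image_score}{the latent standard-normal image score.}
#'     \item{spec}{the generating spec.}
#'   }
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 50, seed = 7))
#' table(coh$records$stage)
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_patients
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  sex <- ifelse(stats::runif(n) < spec$p_male, "male", "female")
  age <- pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd), 18), 95)
  histology <- sample(names(spec$histology_probs), n, replace = TRUE,
                      prob = spec$histology_probs)
  lobe <- sample(names(spec$lobe_probs), n, replace = TRUE,
                 prob = spec$lobe_probs)
  stage <- sample(names(spec$stage_probs), n, replace = TRUE,
                  prob = spec$stage_probs)

  z <- stats::rnorm(n)
  rho <- spec$image_clinical_corr
  if (rho != 0) {
    ord_std <- as.vector(scale(stage_ordinal(stage)))
    if (anyNA(ord_std)) ord_std <- rep(0, n)  # degenerate single-stage cohort
    z <- rho * ord_std + sqrt(1 - rho^2) * z
  }
  eta <- spec$effect_stage * stage_ordinal(stage) + spec$effect_image * z

  t_death <- rweibull_ph(n, spec$baseline_shape, spec$baseline_scale, eta)
  t_recur <- rweibull_ph(n, spec$baseline_shape, spec$recurrence_scale, eta)
  t_rfs <- pmin(t_recur, t_death)

  cens <- spec$admin_censor_time
  os_time <- pmin(t_death, cens)
  os_event <- as.integer(t_death <= cens)
  rfs_time <- pmin(t_rfs, cens)
  rfs_event <- as.integer(t_rfs <= cens)

  features <- matrix(stats::rnorm(n * spec$feature_dim), nrow = n)
  if (spec$n_informative > 0L)
    features[, seq_len(spec$n_informative)] <-
      features[, seq_len(spec$n_informative), drop = FALSE] + z
  colnames(features) <- sprintf("f%03d", seq_len(spec$feature_dim))

  records <- data.frame(
    id = sprintf("P%04d", seq_len(n)),
    age = round(age, 1), sex = sex, histology = histology, lobe = lobe,
    stage = stage,
    os_time = round(os_time, 3), os_event = os_event,
    rfs_time = round(rfs_time, 3), rfs_event = rfs_event,
    stringsAsFactors = FALSE)
  rownames(features) <- records$id

  structure(list(records = records, features = features, latent_risk = eta,
                 latent_image_score = z, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d features (seed %d)\n",
              nrow(x$records), ncol(x$features), x$spec$seed))
  cat(sprintf("  OS events: %d (%.1f%%)  RFS events: %d (%.1f%%)\n",
              sum(x$records$os_event),
              100 * mean(x$records$os_event),
              sum(x$records$rfs_event),
              100 * mean(x$records$rfs_event)))
  invisible(x)
}

# Save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a phantom tumour volume
#'
#' Produces a noisy ellipsoidal phantom on a darker background, as a stand-in
#' input for the image preprocessing path. The ellipsoid has the requested
#' diameter along x and y and 80% of it along z, centred in a field of view
#' of `fov_mm` per side; ellipsoids larger than the field of view are
#' clipped. Foreground voxels take intensity around `fg_hu` HU and
#' background around `bg_hu` HU, with additive Gaussian noise.
#'
#' @param size_mm tumour diameter in millimetres; must be positive.
#' @param seed integer seed.
#' @param voxel_mm isotropic voxel spacing in millimetres.
#' @param fov_mm field of view (one side) in millimetres.
#' @param fg_hu,bg_hu mean foreground/background intensity (HU).
#' @param noise_sd SD of additive Gaussian noise (HU).
#' @return a [tumor_volume()].
#' @export
generate_volume <- function(size_mm, seed = 1L, voxel_mm = 1,
                            fov_mm = 96, fg_hu = 40, bg_hu = -800,
                            noise_sd = 30) {
  if (!is.numeric(size_mm) || length(size_mm) != 1L || size_mm <= 0)
    stop("size_mm must be a positive number")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  npix <- max(4L, as.integer(round(fov_mm / voxel_mm)))
  ax <- (seq_len(npix) - (npix + 1) / 2) * voxel_mm
  r_xy <- size_mm / 2
  r_z <- 0.8 * size_mm / 2
  d2 <- outer(outer((ax / r_xy)^2, (ax / r_xy)^2, `+`), (ax / r_z)^2, `+`)
  vol <- array(bg_hu, dim = c(npix, npix, npix))
  vol[d2 <= 1] <- fg_hu
  vol <- vol + array(stats::rnorm(length(vol), sd = noise_sd), dim = dim(vol))
  tumor_volume(vol, voxel_spacing = rep(voxel_mm, 3))
}
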