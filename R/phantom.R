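## Synthetic DWI/ADC phantom cohorts with known ground truth.
##
## Each subject carries a paired DWI/ADC volume with a single lesion
## (DWI-hyperintense, ADC-hypointense), a true lesion mask, a clinical
## record drawn to match the margins of the study cohort, and a recurrence
## label drawn from a logistic model on a known subset of (standardized)
## radiomic features and clinical covariates. The generator is the ground
## truth against which every downstream stage is tested.

#' Phantom cohort configuration
#'
#' Defaults emulate the study cohort: 1,003 subjects with an 8.5% 1-year
#' recurrence prevalence, lesions of 60--350 voxels (all above the 50-voxel
#' inclusion floor), and a planted logistic dependence of recurrence on
#' three radiomic features (lesion ADC level, texture amplitude, texture
#' smoothness) and six clinical covariates. Effect magnitudes are calibrated
#' once so that each model arm reproduces the discriminative regime the
#' study reports (clinical AUC near 0.68, radiomics near 0.78, combined
#' ceiling near 0.85); signs follow the cohort table (older age, statin and
#' anticoagulant use, atrial fibrillation, hypertension and higher NIHSS
#' all raising recurrence odds).
#'
#' @param n_subjects cohort size.
#' @param prevalence target recurrence probability (0 < p < 1).
#' @param volume_shape integer triple, voxel grid of each volume.
#' @param lesion_volume_range min/max lesion volume in voxels (min >= 50
#'   unless `allow_small` is TRUE, in which case sub-50 lesions are
#'   generated and flagged as designed exclusions downstream).
#' @param lesion_texture_scale range of the intra-lesion texture
#'   correlation length (voxels).
#' @param lesion_texture_amplitude range of the intra-lesion texture
#'   standard deviation (intensity units).
#' @param dwi_contrast,adc_contrast mean/sd of the lesion contrast draw
#'   (DWI positive, ADC negative).
#' @param noise_sd global Gaussian magnitude-noise standard deviation.
#' @param effect_weights named numeric: log-odds of recurrence per SD of
#'   each named radiomic feature (names from [feature_manifest()]).
#' @param clinical_effects named numeric: log-odds per SD (numeric
#'   covariates) or per centred unit (flags) of each clinical covariate.
#' @param exact_count logical; if TRUE labels are assigned so positives =
#'   `round(n_subjects * prevalence)` exactly (probability-weighted draw),
#'   otherwise independent Bernoulli draws.
#' @param allow_small permit lesion_volume_range minima below 50 voxels.
#' @param seed integer master seed; all generator randomness flows from it.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(n_subjects = 1003L,
                           prevalence = 0.085,
                           volume_shape = c(24L, 24L, 16L),
                           lesion_volume_range = c(60L, 350L),
                           lesion_texture_scale = c(0.6, 2.0),
                           lesion_texture_amplitude = c(0.05, 0.25),
                           dwi_contrast = c(0.35, 0.08),
                           adc_contrast = c(-0.30, 0.07),
                           noise_sd = 0.03,
                           effect_weights = c(
                             image_intensity_mean = -1.4,
                             image_intensity_variance = 1.0,
                             image_glcm_correlation = 0.9
                           ),
                           clinical_effects = c(
                             age = 0.60,
                             statins_after_discharge = 0.90,
                             atrial_fibrillation = 0.80,
                             anticoagulants_after_discharge = 0.90,
                             hypertension = 0.35,
                             nihss = 0.30
                           ),
                           exact_count = TRUE,
                           allow_small = FALSE,
                           seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), prevalence = prevalence,
    volume_shape = as.integer(volume_shape),
    lesion_volume_range = as.numeric(lesion_volume_range),
    lesion_texture_scale = as.numeric(lesion_texture_scale),
    lesion_texture_amplitude = as.numeric(lesion_texture_amplitude),
    dwi_contrast = dwi_contrast, adc_contrast = adc_contrast,
    noise_sd = noise_sd,
    effect_weights = effect_weights, clinical_effects = clinical_effects,
    exact_count = isTRUE(exact_count), allow_small = isTRUE(allow_small),
    seed = as.integer(seed)
  )
  if (cfg$n_subjects < 0L) stop("n_subjects must be >= 0")
  if (!(prevalence > 0 && prevalence < 1)) stop("prevalence must lie in (0, 1)")
  if (length(cfg$volume_shape) != 3L || any(cfg$volume_shape < 4L))
    stop("volume_shape must be a triple of dimensions >= 4")
  if (cfg$lesion_volume_range[1] < 50 && !cfg$allow_small)
    stop("lesion_volume_range minimum is below the 50-voxel inclusion floor; set allow_small = TRUE to generate designed exclusions")
  if (cfg$lesion_volume_range[1] < 1) stop("lesion volume must be >= 1 voxel")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(cfg, class = "phantom_config")
}

## Separable Gaussian smoothing of a 3D array (periodic boundary), used to
## turn white noise into a correlated random field.
gaussian_smooth3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  for (axis in 1:3) {
    acc <- array(0, dim(x))
    shifted <- x
    ## accumulate k-weighted circular shifts; shift by s along `axis`
    d <- dim(x)
    for (s in seq(-r, r)) {
      idx <- lapply(d, seq_len)
      idx[[axis]] <- ((seq_len(d[axis]) - 1L + s) %% d[axis]) + 1L
      acc <- acc + k[s + r + 1] * x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    }
    x <- acc
  }
  x
}

## Brain-like background: an ellipsoidal "parenchyma" region on a dark field.
phantom_brain_mask <- function(shape) {
  ctr <- (shape + 1) / 2
  ax <- shape * 0.45
  g <- expand_grid_coords(shape)
  r2 <- ((g[, 1] - ctr[1]) / ax[1])^2 + ((g[, 2] - ctr[2]) / ax[2])^2 +
    ((g[, 3] - ctr[3]) / ax[3])^2
  array(r2 <= 1, shape)
}

phantom_background <- function(shape, inside_value) {
  brain <- phantom_brain_mask(shape)
  array(ifelse(brain, inside_value, 0.05), shape)
}

expand_grid_coords <- function(shape) {
  cbind(
    rep(seq_len(shape[1]), times = shape[2] * shape[3]),
    rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
    rep(seq_len(shape[3]), each = shape[1] * shape[2])
  )
}

## Rasterise a union of ellipsoids into a logical mask.
ellipsoid_union_mask <- function(shape, centers, radii) {
  g <- expand_grid_coords(shape)
  inside <- rep(FALSE, nrow(g))
  for (b in seq_len(nrow(centers))) {
    r2 <- ((g[, 1] - centers[b, 1]) / radii[b, 1])^2 +
      ((g[, 2] - centers[b, 2]) / radii[b, 2])^2 +
      ((g[, 3] - centers[b, 3]) / radii[b, 3])^2
    inside <- inside | (r2 <= 1)
  }
  array(inside, shape)
}

#' Synthesize a paired DWI/ADC lesion phantom
#'
#' Generates one subject's DWI and ADC volumes plus the true lesion mask.
#' The lesion is a union of 1--3 overlapping ellipsoids (a single
#' 26-connected component) whose total volume is calibrated to
#' `lesion_volume` within a few percent. The lesion is hyperintense on DWI
#' and hypointense on ADC, and its interior carries a spatially correlated
#' Gaussian random-field texture with the requested correlation length.
#'
#' @param volume_shape integer triple.
#' @param lesion_volume target lesion volume in voxels (>= 1; must fit).
#' @param texture_scale correlation length of the intra-lesion texture
#'   (voxels); 0 disables smoothing.
#' @param texture_amplitude SD of the texture field (0 = constant interior).
#' @param dwi_contrast,adc_contrast additive lesion contrast on each
#'   modality (DWI positive, ADC negative).
#' @param noise_sd global Gaussian noise SD (0 = noiseless).
#' @param n_blobs number of overlapping ellipsoids (1--3).
#' @param seed optional integer seed for this subject.
#' @return list with 3D arrays `dwi`, `adc`, integer `mask` and the logical
#'   `brain` parenchyma mask (the reference region for lesion contrast).
#' @export
synthesize_lesion_pair <- function(volume_shape = c(24L, 24L, 16L),
                                   lesion_volume = 150,
                                   texture_scale = 1.0,
                                   texture_amplitude = 0.12,
                                   dwi_contrast = 0.35,
                                   adc_contrast = -0.30,
                                   noise_sd = 0.03,
                                   n_blobs = NULL,
                                   seed = NULL) {
  with_seed(seed, {
    shape <- as.integer(volume_shape)
    if (lesion_volume < 1) stop("requested lesion volume must be >= 1 voxel")
    ## geometric feasibility: the equivalent sphere must fit in the volume
    r_eq <- (3 * lesion_volume / (4 * pi))^(1 / 3)
    if (2 * (r_eq * 1.4) + 2 > min(shape)) {
      stop(sprintf("lesion of %g voxels does not fit inside a %s volume",
                   lesion_volume, paste(shape, collapse = "x")))
    }
    if (is.null(n_blobs)) n_blobs <- sample.int(3L, 1L)
    ctr <- (shape + 1) / 2
    ## center within the inner half of the brain ellipsoid
    center0 <- ctr + runif(3, -0.15, 0.15) * shape
    anis <- runif(3, 0.75, 1.3)
    anis <- anis / prod(anis)^(1 / 3)
    build <- function(scale) {
      centers <- matrix(center0, 1L, 3L)
      radii <- matrix(r_eq * scale * anis, 1L, 3L)
      if (n_blobs > 1L) {
        for (b in 2:n_blobs) {
          dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
          centers <- rbind(centers, center0 + dir * r_eq * scale * 0.8)
          radii <- rbind(radii, r_eq * scale * 0.55 * runif(3, 0.8, 1.2))
        }
      }
      ellipsoid_union_mask(shape, centers, radii)
    }
    ## calibrate the radius scale so the voxel count lands near target
    scale <- 1.0
    mask <- build(scale)
    for (it in 1:3) {
      cnt <- sum(mask)
      if (cnt == 0) { scale <- scale * 1.5; mask <- build(scale); next }
      if (abs(cnt - lesion_volume) / lesion_volume <= 0.05) break
      scale <- scale * (lesion_volume / cnt)^(1 / 3)
      mask <- build(scale)
    }
    storage.mode(mask) <- "integer"

    dwi <- phantom_background(shape, 0.55)
    adc <- phantom_background(shape, 0.70)
    les <- mask > 0
    dwi[les] <- dwi[les] + dwi_contrast
    adc[les] <- adc[les] + adc_contrast
    if (texture_amplitude > 0) {
      field <- gaussian_smooth3(array(rnorm(prod(shape)), shape), texture_scale)
      fv <- field[les]
      if (length(fv) > 1L && sd(fv) > 0) {
        fv <- (fv - mean(fv)) / sd(fv)
        dwi[les] <- dwi[les] + texture_amplitude * fv
        adc[les] <- adc[les] + texture_amplitude * fv
      }
    }
    if (noise_sd > 0) {
      dwi <- dwi + array(rnorm(prod(shape), 0, noise_sd), shape)
      adc <- adc + array(rnorm(prod(shape), 0, noise_sd), shape)
    }
    list(dwi = dwi, adc = adc, mask = mask, brain = phantom_brain_mask(shape))
  })
}

#' Assign recurrence labels from planted feature and clinical effects
#'
#' Computes each subject's true recurrence probability as
#' `plogis(intercept + sum(w_f * z(feature_f)) + sum(w_c * z(covariate_c)))`
#' where `z()` standardizes within the cohort (numeric covariates are
#' z-scored, flags are centred 0/1), then calibrates the intercept by 1-D
#' root finding so the mean probability equals the target prevalence.
#' Labels are drawn independently per subject, or as an exact-count
#' probability-weighted draw when `exact_count = TRUE`.
#'
#' @param features numeric matrix (subjects x features) with column names.
#' @param clinical data.frame of clinical covariates (may be NULL when no
#'   clinical effects are configured).
#' @param config a [phantom_config()].
#' @param seed optional integer seed for the label draw.
#' @return list with `labels` (integer 0/1), `probabilities`, `intercept`
#'   and the linear predictor `lp`.
#' @export
assign_labels <- function(features, clinical = NULL, config, seed = NULL) {
  n <- if (!is.null(features)) nrow(features) else nrow(clinical)
  lp <- rep(0, n)
  ew <- config$effect_weights
  if (length(ew)) {
    missing_f <- setdiff(names(ew), colnames(features))
    if (length(missing_f)) {
      stop("effect_weights reference unknown feature(s): ",
           paste(missing_f, collapse = ", "))
    }
    for (f in names(ew)) {
      x <- features[, f]
      s <- sd(x)
      z <- if (!is.na(s) && s > 0) (x - mean(x)) / s else rep(0, n)
      lp <- lp + ew[[f]] * z
    }
  }
  ce <- config$clinical_effects
  if (length(ce)) {
    missing_c <- setdiff(names(ce), colnames(clinical))
    if (length(missing_c)) {
      stop("clinical_effects reference unknown covariate(s): ",
           paste(missing_c, collapse = ", "))
    }
    for (cv in names(ce)) {
      x <- clinical[[cv]]
      if (is.logical(x) || all(x %in% c(0, 1))) {
        z <- as.numeric(x) - mean(as.numeric(x))
      } else {
        s <- sd(x)
        z <- if (!is.na(s) && s > 0) (x - mean(x)) / s else rep(0, n)
      }
      lp <- lp + ce[[cv]] * z
    }
  }
  target <- config$prevalence
  if (all(lp == 0)) {
    intercept <- qlogis(target)
  } else {
    intercept <- uniroot(function(a) mean(plogis(a + lp)) - target,
                         interval = c(-30, 30), tol = 1e-10)$root
  }
  prob <- plogis(intercept + lp)
  labels <- with_seed(seed, {
    if (config$exact_count) {
      k <- round(n * target)
      pos <- sample.int(n, size = min(k, n), prob = prob)
      lab <- integer(n); lab[pos] <- 1L
      lab
    } else {
      rbinom(n, 1L, prob)
    }
  })
  list(labels = labels, probabilities = prob, intercept = intercept, lp = lp)
}

## Clinical covariate margins of the study cohort (counts out of 1,003).
clinical_margins <- function() {
  list(
    age = c(mean = 65.90, sd = 12.44),
    male = 682 / 1003,
    smoking = 378 / 1003,
    drinking = 134 / 1003,
    hypertension = 676 / 1003,
    hyperlipidemia = 277 / 1003,
    diabetes = 350 / 1003,
    atrial_fibrillation = 113 / 1003,
    toast = c(LAA = 544, cardioembolic = 80, SAO = 298,
              other = 13, undetermined = 68) / 1003,
    circulation = c(anterior = 688, posterior = 285, both = 30) / 1003,
    statins_after_discharge = 634 / 1003,
    antiplatelets_after_discharge = 897 / 1003,
    anticoagulants_after_discharge = 45 / 1003,
    nihss_lambda = 3,
    mrs90_lambda = 1.2,
    days_to_recurrence = c(mean = 167.11, sd = 100.08)
  )
}

sample_clinical <- function(n) {
  m <- clinical_margins()
  data.frame(
    age = round(pmax(18, rnorm(n, m$age["mean"], m$age["sd"])), 1),
    sex = ifelse(rbinom(n, 1, m$male) == 1, "male", "female"),
    smoking = rbinom(n, 1, m$smoking),
    drinking = rbinom(n, 1, m$drinking),
    hypertension = rbinom(n, 1, m$hypertension),
    hyperlipidemia = rbinom(n, 1, m$hyperlipidemia),
    diabetes = rbinom(n, 1, m$diabetes),
    atrial_fibrillation = rbinom(n, 1, m$atrial_fibrillation),
    toast_subtype = sample(names(m$toast), n, replace = TRUE, prob = m$toast),
    circulation = sample(names(m$circulation), n, replace = TRUE, prob = m$circulation),
    statins_after_discharge = rbinom(n, 1, m$statins_after_discharge),
    antiplatelets_after_discharge = rbinom(n, 1, m$antiplatelets_after_discharge),
    anticoagulants_after_discharge = rbinom(n, 1, m$anticoagulants_after_discharge),
    nihss = rpois(n, m$nihss_lambda),
    mrs90 = rpois(n, m$mrs90_lambda),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic phantom cohort
#'
#' Draws per-subject lesion geometry and texture parameters, synthesizes the
#' DWI/ADC/mask triplets, extracts the 513-feature radiomic vector from the
#' ADC volume under the true mask, samples clinical covariates matching the
#' study cohort margins, and assigns recurrence labels from the configured
#' planted effects. All randomness flows from `config$seed`.
#'
#' @param config a [phantom_config()].
#' @param out_dir optional directory; when given, per-subject NIfTI volumes
#'   (`sub-XXXX_dwi.nii.gz`, `_adc`, `_mask`) and `cohort.csv` are written.
#' @param keep_volumes retain the per-subject volumes in the returned
#'   object (memory-heavy for large cohorts; default FALSE).
#' @param extract compute the radiomic feature matrix (default TRUE;
#'   required when `effect_weights` is non-empty).
#' @return object of class `phantom_cohort`: list with `clinical`
#'   (data.frame incl. `id`, `recurrence`, `days_to_recurrence`,
#'   `true_probability`), `features` (n x 513 matrix), `lesion_params`,
#'   optionally `subjects` (volumes), and `config`.
#' @export
generate_cohort <- function(config = phantom_config(), out_dir = NULL,
                            keep_volumes = FALSE, extract = TRUE) {
  n <- config$n_subjects
  if (!extract && length(config$effect_weights))
    stop("effect_weights are configured: feature extraction cannot be skipped")
  set.seed(config$seed)
  ## per-subject generative draws
  vol <- runif(n, config$lesion_volume_range[1], config$lesion_volume_range[2])
  tsc <- runif(n, config$lesion_texture_scale[1], config$lesion_texture_scale[2])
  tam <- runif(n, config$lesion_texture_amplitude[1], config$lesion_texture_amplitude[2])
  dwc <- pmax(0.10, rnorm(n, config$dwi_contrast[1], config$dwi_contrast[2]))
  adcc <- pmin(-0.10, rnorm(n, config$adc_contrast[1], config$adc_contrast[2]))
  nblob <- if (n > 0) sample.int(3L, n, replace = TRUE) else integer(0)
  subj_seeds <- if (n > 0) sample.int(2147480000L, n) else integer(0)
  clinical <- sample_clinical(n)
  label_seed <- sample.int(2147480000L, 1L)

  features <- if (extract) matrix(NA_real_, n, 513L) else NULL
  subjects <- if (keep_volumes) vector("list", n) else NULL
  masks_n <- integer(n)
  for (i in seq_len(n)) {
    sp <- synthesize_lesion_pair(
      volume_shape = config$volume_shape, lesion_volume = vol[i],
      texture_scale = tsc[i], texture_amplitude = tam[i],
      dwi_contrast = dwc[i], adc_contrast = adcc[i],
      noise_sd = config$noise_sd, n_blobs = nblob[i], seed = subj_seeds[i]
    )
    masks_n[i] <- sum(sp$mask)
    if (extract) {
      features[i, ] <- extract_features(sp$adc, sp$mask,
                                        min_voxels = if (config$allow_small) 1L else 50L)
    }
    if (keep_volumes) subjects[[i]] <- sp
    if (!is.null(out_dir)) write_subject_nifti(sp, i, out_dir)
  }
  if (extract) colnames(features) <- feature_manifest()$name

  al <- if (n > 0) {
    assign_labels(features, clinical, config, seed = label_seed)
  } else list(labels = integer(0), probabilities = numeric(0), intercept = NA_real_)
  m <- clinical_margins()
  days <- ifelse(
    al$labels == 1L,
    pmax(1, round(rnorm(n, m$days_to_recurrence["mean"], m$days_to_recurrence["sd"]))),
    NA_real_
  )
  clinical <- cbind(
    data.frame(id = sprintf("sub-%04d", seq_len(n)), stringsAsFactors = FALSE),
    clinical,
    data.frame(recurrence = al$labels, days_to_recurrence = days,
               true_probability = al$probabilities)
  )
  cohort <- structure(
    list(clinical = clinical, features = features,
         lesion_params = data.frame(lesion_volume = vol, texture_scale = tsc,
                                    texture_amplitude = tam, dwi_contrast = dwc,
                                    adc_contrast = adcc, n_blobs = nblob,
                                    mask_voxels = masks_n),
         subjects = subjects, config = config),
    class = "phantom_cohort"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(clinical, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  }
  cohort
}

write_subject_nifti <- function(sp, i, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  id <- sprintf("sub-%04d", i)
  RNifti::writeNifti(RNifti::asNifti(sp$dwi), file.path(out_dir, paste0(id, "_dwi.nii.gz")))
  RNifti::writeNifti(RNifti::asNifti(sp$adc), file.path(out_dir, paste0(id, "_adc.nii.gz")))
  RNifti::writeNifti(RNifti::asNifti(sp$mask), file.path(out_dir, paste0(id, "_mask.nii.gz")))
  invisible(NULL)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom cohort: %d subjects, %d recurrences (%.1f%%)\n",
              nrow(x$clinical), sum(x$clinical$recurrence),
              100 * mean(x$clinical$recurrence)))
  invisible(x)
}
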