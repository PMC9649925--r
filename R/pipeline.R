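## End-to-end experiment: phantom cohort -> (optional trained segmentation)
## -> feature extraction -> sparse selection -> three classifier arms
## (clinical / radiomics / combined) -> statistical evaluation.

## clinical covariates entering the selection pool and the clinical arm
CLINICAL_MODEL_COVARIATES <- c("age", "statins_after_discharge",
                               "atrial_fibrillation",
                               "anticoagulants_after_discharge",
                               "hypertension", "nihss")

#' Experiment configuration
#'
#' Bundles the per-stage configurations. The defaults reproduce the study
#' design: a 1,003-subject cohort at 8.5% recurrence, an under-sampled
#' 57/100 training cohort (leaving a test cohort of 846 with 28
#' recurrences), selection of 100 features from the 519 candidate columns
#' (513 radiomic + 6 clinical), and all three model arms. The master seed
#' fans out to fixed per-stage seeds so stages can be rerun in isolation.
#'
#' @param phantom a [phantom_config()].
#' @param quantization a [quantization_spec()].
#' @param selection_k number of features to select (default 100).
#' @param n_pos_train,n_neg_train under-sampled training counts (57/100).
#' @param rnn an [rnn_config()].
#' @param arms model arms to run, subset of
#'   `c("clinical", "radiomics", "combined")`.
#' @param clinical_covariates covariates used by the clinical arm and
#'   appended to the selection pool.
#' @param combined_mode how the combined arm fuses modalities:
#'   `"late_fusion"` (default) stacks the radiomics-GRU and
#'   clinical-logistic scores with a logistic meta-learner fitted on the
#'   training cohort; `"timestep"` appends the clinical block as a
#'   zero-padded 10th GRU timestep and trains a single network.
#' @param use_trained_seg replace the true phantom masks by a trained
#'   U-Net's predictions before feature extraction (slower; small cohorts).
#' @param seg a [seg_config()] (only used with `use_trained_seg`).
#' @param seed master seed.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_config(),
                              quantization = quantization_spec(),
                              selection_k = 100L,
                              n_pos_train = 57L, n_neg_train = 100L,
                              rnn = rnn_config(),
                              arms = c("clinical", "radiomics", "combined"),
                              clinical_covariates = CLINICAL_MODEL_COVARIATES,
                              combined_mode = c("late_fusion", "timestep"),
                              use_trained_seg = FALSE,
                              seg = seg_config(),
                              seed = 1L) {
  structure(list(phantom = phantom, quantization = quantization,
                 selection_k = as.integer(selection_k),
                 n_pos_train = as.integer(n_pos_train),
                 n_neg_train = as.integer(n_neg_train),
                 rnn = rnn, arms = arms,
                 clinical_covariates = clinical_covariates,
                 combined_mode = match.arg(combined_mode),
                 use_trained_seg = isTRUE(use_trained_seg), seg = seg,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Validate and normalize an experiment configuration
#'
#' Fills defaults and checks cross-field consistency (split counts vs the
#' cohort size and prevalence, selection budget vs candidate columns,
#' non-empty arms). Returns the normalized config or stops with the full
#' list of violations, each naming the offending field.
#'
#' @param config an [experiment_config()].
#' @return the validated config (invisibly usable downstream).
#' @export
validate_config <- function(config) {
  errors <- character(0)
  if (!inherits(config, "experiment_config"))
    stop("config must be an experiment_config")
  ph <- config$phantom
  n_pos_avail <- round(ph$n_subjects * ph$prevalence)
  if (config$n_pos_train > n_pos_avail)
    errors <- c(errors, sprintf(
      "split: insufficient positives (n_pos_train = %d, expected positives = %d)",
      config$n_pos_train, n_pos_avail))
  if (config$n_neg_train > ph$n_subjects - n_pos_avail)
    errors <- c(errors, sprintf(
      "split: insufficient negatives (n_neg_train = %d, expected negatives = %d)",
      config$n_neg_train, ph$n_subjects - n_pos_avail))
  n_candidates <- 513L + length(config$clinical_covariates)
  if (config$selection_k > n_candidates)
    errors <- c(errors, sprintf(
      "selection_k: %d exceeds the %d candidate columns",
      config$selection_k, n_candidates))
  if (!length(config$arms))
    errors <- c(errors, "arms: at least one model arm is required")
  if (!all(config$arms %in% c("clinical", "radiomics", "combined")))
    errors <- c(errors, "arms: unknown arm name")
  if (length(errors)) stop(paste(errors, collapse = "\n"))
  config
}

clinical_block <- function(clinical, covariates) {
  out <- lapply(covariates, function(v) as.numeric(clinical[[v]]))
  names(out) <- covariates
  as.matrix(as.data.frame(out))
}

#' Run the full experiment
#'
#' Executes every stage in order: cohort generation (features extracted
#' under the true masks, or under trained-U-Net masks with
#' `use_trained_seg`), table-one summary, under-sampled split, sparse
#' selection on the training cohort (513 radiomic + clinical columns,
#' standardized), the requested model arms, and evaluation (AUC with 95%
#' CI, pairwise DeLong tests, confusion metrics at the training-cohort
#' Youden threshold, decision curves). Fully reproducible from the config.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory for JSON/CSV artifacts.
#' @return object of class `experiment_report`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  config <- validate_config(config)
  ph <- config$phantom
  ph$seed <- stage_seed(config$seed, 1L)
  cohort <- generate_cohort(ph, keep_volumes = config$use_trained_seg)
  labels <- cohort$clinical$recurrence
  features <- cohort$features

  if (config$use_trained_seg) {
    seg <- train_segmenter_on_cohort(cohort, config$seg)
    features <- refeature_with_segmenter(cohort, seg, config$quantization)
    keep <- !is.na(features[, 1])
    cohort$clinical <- cohort$clinical[keep, , drop = FALSE]
    features <- features[keep, , drop = FALSE]
    labels <- labels[keep]
  }

  tone <- table_one(cohort$clinical)
  split <- build_split(labels, config$n_pos_train, config$n_neg_train,
                       seed = stage_seed(config$seed, 3L))
  tr <- split$train; te <- split$test

  clin_block <- clinical_block(cohort$clinical, config$clinical_covariates)
  pool <- cbind(features, clin_block)
  pool_tr <- standardize_features(pool[tr, , drop = FALSE])
  sel_fit <- solve_sparse(pool_tr, labels[tr], k = config$selection_k)
  sel <- select_top_k(sel_fit$w, config$selection_k)
  sel_radiomic <- sel$selected[sel$selected <= 513L]
  sel_clinical <- sel$selected[sel$selected > 513L] - 513L

  arms <- list()
  preds_train <- list()
  preds_test <- list()
  if ("clinical" %in% config$arms) {
    cl_df <- as.data.frame(clin_block)
    fit <- train_clinical_logistic(cl_df[tr, , drop = FALSE], labels[tr])
    preds_train$clinical <- predict(fit, cl_df[tr, , drop = FALSE])
    preds_test$clinical <- predict(fit, cl_df[te, , drop = FALSE])
    arms$clinical <- fit
  }
  if ("radiomics" %in% config$arms) {
    cfg <- config$rnn; cfg$seed <- stage_seed(config$seed, 4L)
    fit <- train_rnn_ensemble(features[tr, , drop = FALSE], labels[tr], cfg,
                              selected = sel_radiomic)
    preds_train$radiomics <- predict(fit, features[tr, , drop = FALSE])
    preds_test$radiomics <- predict(fit, features[te, , drop = FALSE])
    arms$radiomics <- fit
  }
  if ("combined" %in% config$arms) {
    if (identical(config$combined_mode, "late_fusion")) {
      ## stack the radiomics GRU and the clinical logistic on the training
      ## cohort; reuses the single-modality fits where those arms ran
      rad_fit <- arms$radiomics %||% {
        cfg <- config$rnn; cfg$seed <- stage_seed(config$seed, 4L)
        train_rnn_ensemble(features[tr, , drop = FALSE], labels[tr], cfg,
                           selected = sel_radiomic)
      }
      cl_df <- as.data.frame(clin_block)
      cl_fit <- arms$clinical %||% train_clinical_logistic(cl_df[tr, , drop = FALSE],
                                                           labels[tr])
      p_rad_tr <- preds_train$radiomics %||% predict(rad_fit, features[tr, , drop = FALSE])
      p_rad_te <- preds_test$radiomics %||% predict(rad_fit, features[te, , drop = FALSE])
      p_cl_tr <- preds_train$clinical %||% predict(cl_fit, cl_df[tr, , drop = FALSE])
      p_cl_te <- preds_test$clinical %||% predict(cl_fit, cl_df[te, , drop = FALSE])
      lg <- function(p) qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6))
      stack <- suppressWarnings(
        glm.fit(cbind(1, lg(p_rad_tr), lg(p_cl_tr)), labels[tr],
                family = binomial()))
      fuse <- function(pr, pc) drop(plogis(cbind(1, lg(pr), lg(pc)) %*%
                                             stack$coefficients))
      preds_train$combined <- fuse(p_rad_tr, p_cl_tr)
      preds_test$combined <- fuse(p_rad_te, p_cl_te)
      arms$combined <- structure(list(stack = stack$coefficients,
                                      radiomics = rad_fit, clinical = cl_fit),
                                 class = "late_fusion_classifier")
    } else {
      cfg <- config$rnn; cfg$seed <- stage_seed(config$seed, 5L)
      fit <- train_rnn_ensemble(features[tr, , drop = FALSE], labels[tr], cfg,
                                clinical = clin_block[tr, , drop = FALSE],
                                selected = sel_radiomic)
      preds_train$combined <- predict(fit, features[tr, , drop = FALSE],
                                      clinical = clin_block[tr, , drop = FALSE])
      preds_test$combined <- predict(fit, features[te, , drop = FALSE],
                                     clinical = clin_block[te, , drop = FALSE])
      arms$combined <- fit
    }
  }

  roc <- lapply(preds_test, roc_auc, labels = labels[te])
  thresholds <- lapply(preds_train, youden_threshold, labels = labels[tr])
  confusion <- Map(function(p, t) confusion_metrics(p, labels[te], t),
                   preds_test, thresholds)
  dca <- lapply(preds_test, decision_curve, labels = labels[te])
  arm_names <- names(preds_test)
  delong <- list()
  if (length(arm_names) >= 2L) {
    for (i in seq_along(arm_names)) for (j in seq_along(arm_names)) {
      if (i < j) {
        key <- paste0(arm_names[i], "_vs_", arm_names[j])
        delong[[key]] <- delong_test(preds_test[[arm_names[i]]],
                                     preds_test[[arm_names[j]]], labels[te])
      }
    }
  }

  report <- structure(list(
    roc = roc, confusion = confusion, thresholds = thresholds,
    delong = delong, dca = dca, table_one = tone,
    split_counts = split$counts,
    selection = list(
      n_selected = length(sel$selected),
      n_radiomic = length(sel_radiomic),
      n_clinical = length(sel_clinical),
      radiomic_indices = sel_radiomic,
      clinical_names = config$clinical_covariates[sel_clinical]
    ),
    predictions = list(test = preds_test, labels_test = labels[te]),
    provenance = list(seed = config$seed,
                      n_subjects = ph$n_subjects,
                      prevalence = ph$prevalence,
                      arms = arm_names,
                      combined_mode = config$combined_mode,
                      package_version = as.character(utils::packageVersion("strokerad")))
  ), class = "experiment_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

## Train the U-Net on the first cohort subjects' DWI slices (needs
## keep_volumes = TRUE cohorts; intended for small segmentation studies).
train_segmenter_on_cohort <- function(cohort, seg_cfg, n_train = 10L) {
  subs <- cohort$subjects
  if (is.null(subs)) stop("cohort was generated without volumes")
  n_train <- min(n_train, length(subs))
  slices <- list()
  for (i in seq_len(n_train)) {
    sp <- subs[[i]]
    wl <- robust_window(sp$dwi)
    nv <- normalize_intensity(sp$dwi, wl$level, wl$width)
    zs <- which(apply(sp$mask, 3, sum) > 0)
    for (z in zs) slices[[length(slices) + 1L]] <- list(image = nv[, , z],
                                                       mask = sp$mask[, , z])
    ez <- setdiff(seq_len(dim(sp$mask)[3]), zs)
    if (length(ez)) slices[[length(slices) + 1L]] <-
        list(image = nv[, , ez[1]], mask = sp$mask[, , ez[1]])
  }
  train_unet(slices, seg_cfg)
}

refeature_with_segmenter <- function(cohort, seg, q) {
  subs <- cohort$subjects
  out <- matrix(NA_real_, length(subs), 513L)
  for (i in seq_along(subs)) {
    sp <- subs[[i]]
    wl <- robust_window(sp$dwi)
    pred <- segment_volume(seg, normalize_intensity(sp$dwi, wl$level, wl$width))
    pp <- postprocess_mask(pred)
    if (!pp$excluded) out[i, ] <- extract_features(sp$adc, pp$mask, q)
  }
  colnames(out) <- feature_manifest()$name
  out
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment report\n")
  cat(sprintf("  test cohort: %d subjects (%d recurrences)\n",
              x$split_counts$test_pos + x$split_counts$test_neg,
              x$split_counts$test_pos))
  for (arm in names(x$roc)) {
    r <- x$roc[[arm]]
    cm <- x$confusion[[arm]]
    cat(sprintf("  %-10s AUC %.3f (%.3f-%.3f)  acc %.3f sens %.3f spec %.3f\n",
                arm, r$auc, r$ci_low, r$ci_high,
                cm$accuracy, cm$sensitivity, cm$specificity))
  }
  for (key in names(x$delong)) {
    cat(sprintf("  DeLong %s: p = %s\n", key,
                format_pvalue(x$delong[[key]]$p_value)))
  }
  invisible(x)
}

## Serialise the report (minus model objects) as JSON + the DCA grid as CSV.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  slim <- list(
    roc = lapply(report$roc, function(r) r[c("auc", "ci_low", "ci_high",
                                             "n_pos", "n_neg")]),
    confusion = report$confusion,
    thresholds = report$thresholds,
    delong = lapply(report$delong, function(d) d[c("auc_a", "auc_b",
                                                   "difference", "p_value")]),
    split_counts = report$split_counts,
    selection = report$selection[c("n_selected", "n_radiomic", "n_clinical",
                                   "clinical_names")],
    provenance = report$provenance
  )
  jsonlite::write_json(slim, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (arm in names(report$dca)) {
    write.csv(report$dca[[arm]], file.path(out_dir, paste0("dca_", arm, ".csv")),
              row.names = FALSE)
  }
  write.csv(report$table_one, file.path(out_dir, "table1.csv"), row.names = FALSE)
  invisible(NULL)
}
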