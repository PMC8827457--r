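#' Leave-one-out fold specification
#'
#' One fold per patient: fold i tests patient i and trains on all others.
#'
#' @param patient_ids vector of unique patient identifiers (>= 2).
#' @return list of folds: list(fold_index, test_patient_id,
#'   training_patient_ids).
#' @export
make_folds <- function(patient_ids) {
  if (anyDuplicated(patient_ids)) stop("duplicate patient ids", call. = FALSE)
  if (length(patient_ids) < 2) stop("need at least 2 patients", call. = FALSE)
  lapply(seq_along(patient_ids), function(i)
    list(fold_index = i, test_patient_id = patient_ids[i],
         training_patient_ids = patient_ids[-i]))
}

frame_keys <- function(dataset, idx = seq_along(dataset$frames)) {
  sprintf("p%s:%s:%d", dataset$patient[idx], dataset$sweep_id[idx],
          dataset$frame_index[idx])
}

#' Leave-one-out cross-validation of the segmenter
#'
#' Trains one model per fold on all other patients (optionally rebalanced),
#' evaluates on the held-out patient's frames, and selects the best fold by
#' mean rank over the seven evaluation metrics. Per-fold seeds derive from
#' the config seed plus the fold index, so folds are independent but the
#' whole run is reproducible.
#'
#' @param dataset a `vsi_dataset` with a `patient` column.
#' @param structure `"head"` or `"placenta"`.
#' @param config a [unet_config()].
#' @param rebalance optional `c(pos, neg)` ratio applied to each fold's
#'   training frames (head 1:2 and placenta 1:1 are the conventional
#'   choices), or NULL.
#' @param threshold binarization threshold for evaluation.
#' @param train_fn training function `(dataset, config, structure) ->
#'   segmenter`; defaults to [train_segmenter()]. Any object satisfying the
#'   [predict_mask()] contract may be returned (e.g. a perfect reference
#'   segmenter in pipeline tests).
#' @param verbose print per-fold progress.
#' @return A `loocv_record`: list(metrics data.frame, models, selected_fold,
#'   assignments (train/val/test frame keys per fold), skipped).
#' @export
run_loocv <- function(dataset, structure = c("head", "placenta"), config,
                      rebalance = NULL, threshold = 0.5,
                      train_fn = train_segmenter, verbose = FALSE) {
  structure <- match.arg(structure)
  patients <- unique(dataset$patient)
  folds <- make_folds(patients)
  present_field <- paste0(structure, "_present")
  masks_field <- paste0(structure, "_masks")
  metrics <- NULL; models <- list(); assignments <- list(); skipped <- integer(0)
  for (f in folds) {
    train_idx <- which(dataset$patient %in% f$training_patient_ids)
    test_idx <- which(dataset$patient == f$test_patient_id)
    train_ds <- dataset_subset(dataset, train_idx)
    if (!any(train_ds[[present_field]])) {
      warning(sprintf("fold %d skipped: no structure-present training frame",
                      f$fold_index))
      skipped <- c(skipped, f$fold_index)
      next
    }
    fold_seed <- derive_seed(config$seed, f$fold_index)
    if (!is.null(rebalance))
      train_ds <- rebalance_frames(train_ds, structure, rebalance,
                                   seed = fold_seed)
    fold_config <- config
    fold_config$seed <- fold_seed
    model <- train_fn(train_ds, fold_config, structure)
    pred <- lapply(test_idx, function(i)
      predict_mask(model, dataset$frames[[i]], threshold = threshold)$mask)
    truth <- dataset[[masks_field]][test_idx]
    m <- segmentation_metrics(pred, truth)
    metrics <- rbind(metrics, data.frame(
      fold = f$fold_index, test_patient = f$test_patient_id,
      sensitivity = m$sensitivity, specificity = m$specificity,
      ppv = m$ppv, npv = m$npv, jaccard = m$jaccard,
      pixel_accuracy = m$pixel_accuracy, area_error_pct = m$area_error_pct))
    models[[as.character(f$fold_index)]] <- model
    assignments[[as.character(f$fold_index)]] <- list(
      train = frame_keys(train_ds, model$split$train %||% seq_along(train_ds$frames)),
      val = frame_keys(train_ds, model$split$val %||% integer(0)),
      test = frame_keys(dataset, test_idx))
    if (verbose)
      message(sprintf("fold %d: jaccard %.3f", f$fold_index, m$jaccard))
  }
  if (is.null(metrics)) stop("all folds were skipped", call. = FALSE)
  structure(list(metrics = metrics, models = models,
                 selected_fold = select_best(metrics),
                 assignments = assignments, skipped = skipped,
                 structure = structure),
            class = "loocv_record")
}

#' Select the best fold by mean rank over the evaluation metrics
#'
#' Sensitivity, specificity, PPV, NPV, Jaccard and pixel accuracy are
#' ranked descending, the segmentation area error ascending; the fold with
#' the lowest mean rank wins (ties: lowest fold index). Rank aggregation is
#' scale-free across the seven metrics.
#'
#' @param records data.frame with columns `fold`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `jaccard`, `pixel_accuracy`,
#'   `area_error_pct` (one row per fold).
#' @return The winning `fold` value.
#' @export
select_best <- function(records) {
  if (!nrow(records)) stop("no records", call. = FALSE)
  up <- c("sensitivity", "specificity", "ppv", "npv", "jaccard", "pixel_accuracy")
  rks <- sapply(up, function(m) rank(-records[[m]], ties.method = "average",
                                     na.last = "keep"))
  rks <- cbind(rks, area = rank(records$area_error_pct, ties.method = "average",
                                na.last = "keep"))
  score <- rowMeans(rks, na.rm = TRUE)
  records$fold[order(score, records$fold)][1]
}

#' Audit a LOOCV record for test-frame leakage
#'
#' @param record a `loocv_record`.
#' @return Number of test-frame keys that also appear in the same fold's
#'   training or validation split (0 means no leakage).
#' @export
audit_folds <- function(record) {
  sum(vapply(record$assignments, function(a)
    length(intersect(a$test, union(a$train, a$val))), integer(1)))
}

#' Evaluate trained (or oracle) segmenters on a hold-out set
#'
#' Runs the full diagnosis on each hold-out exam and compares labels and
#' biometry against the reference reads. Reference entries recorded as NA
#' ("unable to report") are excluded from the corresponding comparison and
#' counted.
#'
#' @param head_segmenter,placenta_segmenter segmenter per structure; a
#'   function(exam) returning a segmenter may be given instead (used for
#'   per-exam oracle segmenters).
#' @param holdout_exams list of `vsi_exam`s.
#' @param references data.frame with one row per exam: `presentation`,
#'   `placenta_location`, `bpd_mm`, `hc_mm` (NAs allowed).
#' @param registry,params,... passed to [diagnose_exam()].
#' @return list(presentation, placenta, placenta_no_fundal
#'   (agreement_reports), biometry (icc/bland-altman/relative error per
#'   measure), per_exam (data.frame), n_unreportable.
#' @export
evaluate_holdout <- function(head_segmenter, placenta_segmenter, holdout_exams,
                             references, registry = default_registry(),
                             params = classifier_params(), ...) {
  if (!length(holdout_exams)) stop("empty hold-out set", call. = FALSE)
  if (nrow(references) != length(holdout_exams))
    stop("one reference row per exam required", call. = FALSE)
  get_seg <- function(s, exam) if (is.function(s)) s(exam) else s
  rows <- NULL
  for (i in seq_along(holdout_exams)) {
    ex <- holdout_exams[[i]]
    dg <- diagnose_exam(ex, get_seg(head_segmenter, ex),
                        get_seg(placenta_segmenter, ex),
                        registry = registry, params = params, ...)
    rows <- rbind(rows, data.frame(
      exam = i,
      presentation = dg$presentation,
      placenta_location = dg$placenta_location,
      bpd_mm = if (is.null(dg$biometry)) NA_real_ else dg$biometry$bpd_mm,
      hc_mm = if (is.null(dg$biometry)) NA_real_ else dg$biometry$hc_mm,
      low_placenta_flag = dg$low_placenta_flag))
  }
  ok_pres <- !is.na(references$presentation)
  ok_plac <- !is.na(references$placenta_location)
  pres_rep <- agreement_report(references$presentation[ok_pres],
                               rows$presentation[ok_pres],
                               positive_label = "cephalic")
  plac_rep <- agreement_report(references$placenta_location[ok_plac],
                               rows$placenta_location[ok_plac],
                               positive_label = "anterior")
  plac_nf <- tryCatch(
    agreement_report(references$placenta_location[ok_plac],
                     rows$placenta_location[ok_plac],
                     positive_label = "anterior", exclude = "fundal"),
    error = function(e) NULL)
  bio <- list()
  for (m in c("bpd_mm", "hc_mm")) {
    ok <- !is.na(references[[m]]) & !is.na(rows[[m]])
    if (sum(ok) >= 3) {
      bio[[m]] <- list(
        icc = icc_absolute(rows[[m]][ok], references[[m]][ok]),
        bland_altman = bland_altman(rows[[m]][ok], references[[m]][ok]),
        relative_error_pct = relative_error(rows[[m]][ok], references[[m]][ok]))
    }
  }
  list(presentation = pres_rep, placenta = plac_rep,
       placenta_no_fundal = plac_nf, biometry = bio, per_exam = rows,
       n_unreportable = sum(!ok_pres) + sum(!ok_plac))
}
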