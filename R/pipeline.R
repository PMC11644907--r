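stratified_split <- function(y, train_frac, seed) {
  with_seed(seed, {
    tr <- logical(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      n_tr <- max(1L, round(train_frac * length(idx)))
      if (length(idx) < 2L) stopf("class '%s' has too few epochs to split", cl)
      n_tr <- min(n_tr, length(idx) - 1L)   # keep at least one test epoch
      tr[sample(idx, n_tr)] <- TRUE
    }
    tr
  })
}

correct_epoch <- function(epoch, params) {
  r1 <- reshape1(epoch$eeg)
  e_total <- predict_condition_error(params, epoch$meta)$e_total
  corrected <- apply_correction(r1$avg, e_total)
  epoch$corrected_avg <- corrected
  epoch$eeg <- reshape2(corrected, r1$weights)   # restore 8-channel layout
  epoch$e_total <- e_total
  epoch
}

pipeline_core <- function(epochs, params, cfg, seed, n_subwindows,
                          overlap_fraction, split) {
  use_corr <- !is.null(params)
  if (use_corr) epochs <- lapply(epochs, correct_epoch, params = params)
  src <- if (use_corr) "corrected_avg" else "raw_avg"
  mats <- lapply(epochs, build_feature_matrix, n_subwindows = n_subwindows,
                 overlap_fraction = overlap_fraction, source = src)
  y <- labels_of(mats)
  tr <- stratified_split(y, split, seed)
  stats <- compute_feature_stats(mats[tr])
  mats_std <- standardize_features(mats, stats)
  classes <- sort(unique(y))
  model <- build_model(
    model_config(architecture = cfg$architecture, n_classes = length(classes),
                 conv_activation = cfg$conv_activation,
                 dense_activation = cfg$dense_activation,
                 dense_units = cfg$dense_units, dropout_rate = cfg$dropout_rate,
                 batch_norm = cfg$batch_norm, conv_filters = cfg$conv_filters,
                 optimizer = cfg$optimizer, batch_size = cfg$batch_size,
                 epochs = cfg$epochs, seed = seed),
    input_shape = dim(mats_std[[1]]), class_labels = classes)
  model$feature_stats <- stats
  model <- train(model, mats_std[tr], y[tr])
  metrics <- evaluate(model, mats_std[!tr], y[!tr])
  list(classifier = model, metrics = metrics, n_train = sum(tr),
       n_test = sum(!tr))
}

#' Run the end-to-end pipeline on a set of recordings
#'
#' Segments all recordings into cue epochs, optionally calibrates the
#' empirical error model on the stationary reference and applies the RMS
#' correction to every epoch's averaged series (restoring the 8-channel
#' layout via the channel weights), builds standardized feature grids,
#' splits 80:20 stratified by class, trains the configured classifier and
#' evaluates it on the held-out epochs. Fully reproducible from `seed`.
#'
#' @param recordings List of [bci_recording()]s; must include the stationary
#'   reference when `use_empirical_model` is `TRUE`.
#' @param use_empirical_model Apply calibration + correction before feature
#'   extraction.
#' @param cfg A [model_config()].
#' @param seed Seed for the split and training.
#' @param n_subwindows,overlap_fraction Feature-grid geometry (default 8
#'   windows, 50% overlap).
#' @param split Training fraction (default 0.8).
#' @param include_labels Cue labels kept as classification classes.
#' @param params Optional pre-fitted `error_model_params`; when supplied
#'   with `use_empirical_model = TRUE` the internal calibration is skipped
#'   (useful when the model was calibrated on a wider condition grid than
#'   the recordings being classified).
#' @return List with `classifier`, `metrics`, `params` (the fitted error
#'   model or `NULL`) and a `report` fragment (config snapshot, seed, sizes).
#' @export
run_pipeline <- function(recordings, use_empirical_model = FALSE,
                         cfg = model_config(), seed = 1L,
                         n_subwindows = 8L, overlap_fraction = 0.5,
                         split = 0.8,
                         include_labels = c("RELAX", "LEFT", "RIGHT"),
                         params = NULL) {
  if (!length(recordings)) stopf("empty recording list")
  is_ref <- vapply(recordings, function(r) isTRUE(r$meta$is_reference), logical(1))
  motion <- recordings[!is_ref]
  if (use_empirical_model) {
    if (is.null(params)) {
      if (!any(is_ref)) stopf("missing reference recording for empirical correction")
      params <- calibrate(recordings[is_ref][[1]], motion,
                          include_labels = include_labels)
    }
  } else {
    params <- NULL
  }
  epochs <- unlist(lapply(motion, segment_by_cues,
                          include_labels = include_labels),
                   recursive = FALSE)
  res <- pipeline_core(epochs, params, cfg, seed, n_subwindows,
                       overlap_fraction, split)
  res$params <- params
  res$report <- list(use_empirical_model = use_empirical_model,
                     seed = seed, split = split,
                     n_epochs = length(epochs),
                     n_train = res$n_train, n_test = res$n_test,
                     architecture = cfg$architecture)
  res
}

case_axis <- function(case_id) {
  switch(case_id,
         a = list(axis = "surface", correction = FALSE),
         b = list(axis = "wheelchair", correction = FALSE),
         c = list(axis = "surface", correction = TRUE),
         d = list(axis = "wheelchair", correction = TRUE),
         stopf("unknown case id '%s' (expected a, b, c or d)", case_id))
}

#' Run one validation case (a-d)
#'
#' The four validation scenarios: one subject on a single wheelchair across
#' the surfaces (a without, c with the empirical model) and one subject on
#' a single surface across the wheelchairs (b without, d with). The error
#' model is calibrated once on the full dataset; metrics are then reported
#' per condition level, mirroring a per-surface/per-wheelchair comparison.
#'
#' @param case_id `"a"`, `"b"`, `"c"` or `"d"`.
#' @param dataset Output of [generate_condition_grid()] (or a list with
#'   `reference` and `recordings`).
#' @param cfg A [model_config()].
#' @param seed Seed.
#' @param ... Passed to the core pipeline (sub-window geometry, split).
#' @return A `case_report`: list with `case_id`, `correction`, per-condition
#'   `metrics`, `config` snapshot and `seed`.
#' @export
run_validation_case <- function(case_id, dataset, cfg = model_config(),
                                seed = 1L, n_subwindows = 8L,
                                overlap_fraction = 0.5, split = 0.8) {
  ax <- case_axis(case_id)
  recs <- dataset$recordings
  metas <- lapply(recs, function(r) r$meta)
  base <- dataset$reference$meta
  # fix the off-axis condition at the baseline levels
  keep <- vapply(metas, function(m) {
    m$subject_id == base$subject_id &&
      (if (ax$axis == "surface") m$wheelchair_id == base$wheelchair_id
       else m$surface_id == base$surface_id)
  }, logical(1))
  recs <- recs[keep]
  levels_ <- vapply(recs, function(r)
    if (ax$axis == "surface") r$meta$surface_id else r$meta$wheelchair_id,
    character(1))
  ulev <- unique(levels_)
  need <- if (ax$axis == "surface") 2L else 2L
  if (length(ulev) < need) {
    stopf("dataset lacks required conditions: case %s needs multiple %ss, found %d",
          case_id, ax$axis, length(ulev))
  }
  params <- NULL
  if (ax$correction) {
    params <- calibrate(dataset$reference, dataset$recordings)
  }
  per_level <- list()
  for (lv in ulev) {
    epochs <- unlist(lapply(recs[levels_ == lv], segment_by_cues),
                     recursive = FALSE)
    res <- pipeline_core(epochs, params, cfg, seed, n_subwindows,
                         overlap_fraction, split)
    per_level[[lv]] <- res$metrics
  }
  structure(
    list(case_id = case_id, correction = ax$correction, axis = ax$axis,
         metrics = per_level, seed = seed, split = split,
         config = list(architecture = cfg$architecture,
                       batch_size = cfg$batch_size, epochs = cfg$epochs)),
    class = "case_report"
  )
}

#' Serialize a case report to canonical JSON
#'
#' @param report A `case_report` from [run_validation_case()].
#' @param path Optional file to write to.
#' @return The JSON string (invisibly when written to file).
#' @export
case_report_json <- function(report, path = NULL) {
  payload <- report
  payload$metrics <- lapply(report$metrics, function(m) {
    list(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
         f1 = m$f1, confusion = unclass(m$confusion), n = m$n)
  })
  js <- jsonlite::toJSON(unclass(payload), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
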