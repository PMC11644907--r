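MODALITIES <- c("accel_x", "accel_y", "accel_z", "eeg_avg")
FACTORS <- c("surface", "subject", "wheelchair")

modality_signal <- function(epoch, modality) {
  switch(modality,
         accel_x = epoch$accel["ax", ],
         accel_y = epoch$accel["ay", ],
         accel_z = epoch$accel["az", ],
         eeg_avg = reshape1(epoch$eeg)$avg,
         stopf("unknown modality '%s'", modality))
}

#' Measure the motion error of one epoch against the stationary reference
#'
#' The "error" is the RMS amplitude difference between the motion epoch and
#' the paired reference epoch, per modality (one accelerometer axis, or the
#' 8-channel EEG average from [reshape1()]). RMS is computed about the
#' window mean, so DC components (gravity, electrode offset) do not enter.
#' Negative values (motion quieter than reference) are kept as-is.
#'
#' @param motion,reference Two [bci_epoch()] objects with equal `fs` and
#'   length; `reference$meta$is_reference` must be `TRUE`.
#' @param modality One of `"accel_x"`, `"accel_y"`, `"accel_z"`, `"eeg_avg"`.
#' @param epoch_id Optional identifier stored for traceability.
#' @return An `error_measurement`: list with `value`, `modality`,
#'   `condition`, `epoch_id`.
#' @export
measure_window_error <- function(motion, reference, modality,
                                 epoch_id = NA_integer_) {
  stopifnot(inherits(motion, "bci_epoch"), inherits(reference, "bci_epoch"))
  if (!isTRUE(reference$meta$is_reference)) {
    stopf("reference epoch must come from the stationary reference recording")
  }
  if (motion$fs != reference$fs) stopf("fs mismatch between epochs")
  if (ncol(motion$eeg) != ncol(reference$eeg)) stopf("length mismatch between epochs")
  val <- rms(modality_signal(motion, modality)) -
         rms(modality_signal(reference, modality))
  structure(list(value = val, modality = modality, condition = motion$meta,
                 epoch_id = epoch_id),
            class = "error_measurement")
}

as_error_value <- function(x) {
  if (inherits(x, "error_measurement")) x$value else as.numeric(x)
}

#' Fit one per-condition weight factor
#'
#' Solves `E_n = ratio * Wf * E_1` for `Wf`, where `ratio` is the
#' friction or weight ratio of the condition relative to the reference
#' condition (e.g. `mu_s1 / mu_sn`) and `E_1` the error measured at the
#' reference condition.
#'
#' @param measured_n Error at condition n (`error_measurement` or numeric).
#' @param reference_1 Error at the reference condition; must be nonzero.
#' @param ratio Dimensionless ratio (> 0).
#' @return The weight factor `E_n / (ratio * E_1)`.
#' @export
fit_weight_factor <- function(measured_n, reference_1, ratio) {
  e_n <- as_error_value(measured_n); e_1 <- as_error_value(reference_1)
  if (ratio <= 0) stopf("ratio must be > 0")
  if (e_1 == 0) stopf("calibration error: zero reference error, cannot normalize")
  e_n / (ratio * e_1)
}

#' Average per-condition weight factors into the general model's Wf
#'
#' @param factors Non-empty numeric vector of positive weight factors.
#' @return Their arithmetic mean.
#' @export
average_weight_factors <- function(factors) {
  factors <- as.numeric(factors)
  if (length(factors) == 0L) stopf("empty weight-factor list")
  mean(factors)
}

#' Fit the second-level correction factor from hold-out conditions
#'
#' `Cf` is the mean residual (measured minus predicted) over the designated
#' hold-out conditions; the model's prediction for those conditions then
#' has zero mean residual by construction.
#'
#' @param measured_holdout,predicted_holdout Named numeric vectors sharing
#'   exactly the same condition keys.
#' @return The correction factor.
#' @export
fit_correction_factor <- function(measured_holdout, predicted_holdout) {
  if (is.null(names(measured_holdout)) || is.null(names(predicted_holdout)) ||
      !setequal(names(measured_holdout), names(predicted_holdout))) {
    stopf("measured and predicted hold-out condition keys do not match")
  }
  predicted_holdout <- predicted_holdout[names(measured_holdout)]
  mean(measured_holdout - predicted_holdout)
}

#' Predict the error at a condition from the fitted factor model
#'
#' The general per-factor form: `ratio * wf * reference_error + cf`.
#'
#' @param reference_error Error at the reference condition.
#' @param ratio Friction or weight ratio (> 0) of the target condition.
#' @param wf Averaged weight factor.
#' @param cf Correction factor.
#' @return Predicted error.
#' @export
predict_factor_error <- function(reference_error, ratio, wf, cf) {
  if (ratio <= 0) stopf("ratio must be > 0")
  ratio * wf * reference_error + cf
}

#' Combine the three accelerometer axis errors (Euclidean norm)
#'
#' @param ex,ey,ez Finite per-axis errors.
#' @return `sqrt(ex^2 + ey^2 + ez^2)`.
#' @export
combine_axes <- function(ex, ey, ez) {
  assert_finite(c(ex, ey, ez), "axis errors")
  sqrt(ex^2 + ey^2 + ez^2)
}

#' Total accelerometer error across the three factors
#'
#' @param e_surface,e_subject,e_wheelchair Combined-axis errors for the
#'   surface, subject-weight and wheelchair-weight factors.
#' @return Their average (symbolically, `Ea`).
#' @export
accel_error <- function(e_surface, e_subject, e_wheelchair) {
  (e_surface + e_subject + e_wheelchair) / 3
}

#' Overall error combining the EEG factors and the accelerometer error
#'
#' @param esn,epn,ewn EEG errors for surface, subject and wheelchair factors.
#' @param ea_normalized Accelerometer error already rescaled to EEG units
#'   (microvolts) via the model's normalization constant.
#' @return The average of the four terms.
#' @export
total_error <- function(esn, epn, ewn, ea_normalized) {
  (esn + epn + ewn + ea_normalized) / 4
}

mean_condition_error <- function(recs, ref_epochs, modality, include_labels) {
  vals <- unlist(lapply(recs, function(r) {
    eps <- segment_by_cues(r, include_labels)
    k <- min(length(eps), length(ref_epochs))
    vapply(seq_len(k), function(i) {
      measure_window_error(eps[[i]], ref_epochs[[i]], modality, i)$value
    }, numeric(1))
  }))
  if (!length(vals)) stopf("no epochs available for a calibration condition")
  mean(vals)
}

#' Calibrate the empirical error model from a recording set
#'
#' Expects the stationary reference recording plus motion recordings that
#' sweep one factor at a time while the other two stay at their reference
#' levels (the first surface/subject/wheelchair). For each modality (three
#' accelerometer axes and the averaged EEG) and each factor it:
#' measures the mean per-epoch RMS error per condition, fits one weight
#' factor per non-reference condition and averages them, and fits the
#' correction factor as the mean hold-out residual. Default hold-outs: the
#' last two surfaces, the last two subjects, and both non-reference
#' wheelchairs.
#'
#' @param reference_rec The stationary reference [bci_recording()]
#'   (`meta$is_reference` must be `TRUE`).
#' @param motion_recs List of motion [bci_recording()]s covering the three
#'   one-factor sweeps (a full condition grid works: only the one-factor
#'   cells are used).
#' @param holdout Named list of hold-out condition ids per factor; `NULL`
#'   picks the defaults described above.
#' @param wf_conditions `"all"` (default) fits and averages a weight factor
#'   on every non-reference condition of the sweep; `"non_holdout"`
#'   restricts the average to conditions outside the hold-out set (falling
#'   back to all when none remain).
#' @param include_labels Cue labels used for error epochs (default all).
#' @return An object of class `error_model_params`.
#' @export
calibrate <- function(reference_rec, motion_recs, holdout = NULL,
                      wf_conditions = c("all", "non_holdout"),
                      include_labels = c("RELAX", "LEFT", "RIGHT")) {
  wf_conditions <- match.arg(wf_conditions)
  if (missing(reference_rec) || !inherits(reference_rec, "bci_recording") ||
      !isTRUE(reference_rec$meta$is_reference)) {
    stopf("calibration error: missing stationary reference recording")
  }
  if (!length(motion_recs)) stopf("calibration error: no motion recordings")
  ref_epochs <- segment_by_cues(reference_rec, include_labels)

  base <- reference_rec$meta
  metas <- lapply(motion_recs, function(r) r$meta)
  at_base <- function(m, f) switch(f,
    surface = m$surface_id == base$surface_id,
    subject = m$subject_id == base$subject_id,
    wheelchair = m$wheelchair_id == base$wheelchair_id)
  level_id <- function(m, f) switch(f,
    surface = m$surface_id, subject = m$subject_id, wheelchair = m$wheelchair_id)
  level_val <- function(m, f) switch(f,
    surface = m$friction, subject = m$subject_weight,
    wheelchair = m$wheelchair_weight)

  # baseline motion cell: all three factors at reference levels
  idx_base <- which(vapply(metas, function(m)
    at_base(m, "surface") && at_base(m, "subject") && at_base(m, "wheelchair"),
    logical(1)))
  if (!length(idx_base)) {
    stopf("calibration error: no motion recording at the baseline condition")
  }

  ref_err <- matrix(NA_real_, 4, 3, dimnames = list(MODALITIES, FACTORS))
  wf <- ref_err; cf <- ref_err
  tables <- list()

  for (f in FACTORS) {
    # sweep: vary factor f, others at baseline
    others <- setdiff(FACTORS, f)
    idx <- which(vapply(metas, function(m)
      all(vapply(others, function(o) at_base(m, o), logical(1))), logical(1)))
    ids <- vapply(metas[idx], level_id, character(1), f = f)
    tab <- vapply(split(vapply(metas[idx], level_val, numeric(1), f = f), ids),
                  unique, numeric(1))
    base_id <- level_id(base, f)
    non_ref <- setdiff(names(tab), base_id)
    if (length(non_ref) < 2L) {
      stopf("calibration error: factor '%s' needs at least 2 non-reference conditions", f)
    }
    # order: reference level first, then the sweep order of appearance
    tab <- tab[c(base_id, ids[!duplicated(ids)][ids[!duplicated(ids)] != base_id])]
    non_ref <- setdiff(names(tab), base_id)
    hold <- if (!is.null(holdout[[f]])) holdout[[f]] else {
      if (f == "wheelchair") non_ref else utils::tail(non_ref, 2)
    }
    if (!all(hold %in% non_ref)) {
      stopf("calibration error: hold-out condition(s) %s absent for factor '%s'",
            paste(setdiff(hold, non_ref), collapse = ", "), f)
    }
    nh <- setdiff(non_ref, hold)
    # the surface/subject designs keep the hold-outs out of the main fit,
    # so at least two non-hold-out conditions must remain; the wheelchair
    # factor has only two non-reference chairs and reuses both
    if (f != "wheelchair" && length(nh) < 2L) {
      stopf("calibration error: factor '%s' has fewer than 2 non-hold-out conditions", f)
    }
    wf_ids <- if (wf_conditions == "non_holdout") {
      if (length(nh)) nh else non_ref
    } else non_ref
    tables[[f]] <- tab

    for (m_ in MODALITIES) {
      e1 <- mean_condition_error(motion_recs[idx_base], ref_epochs, m_,
                                 include_labels)
      if (e1 == 0) stopf("calibration error: zero reference error for %s", m_)
      e_cond <- vapply(non_ref, function(id) {
        mean_condition_error(motion_recs[idx][ids == id], ref_epochs, m_,
                             include_labels)
      }, numeric(1))
      ratio <- tab[[base_id]] / tab[non_ref]   # mu1/mun, W1/Wn, U1/Un
      names(ratio) <- non_ref
      wfs <- vapply(wf_ids, function(id)
        fit_weight_factor(e_cond[[id]], e1, ratio[[id]]), numeric(1))
      wf_avg <- average_weight_factors(wfs)
      pred_hold <- vapply(hold, function(id)
        predict_factor_error(e1, ratio[[id]], wf_avg, 0), numeric(1))
      ref_err[m_, f] <- e1
      wf[m_, f] <- wf_avg
      cf[m_, f] <- fit_correction_factor(e_cond[hold], pred_hold)
    }
  }

  # scale merging accelerometer (g) into EEG (microvolt) units
  ea_ref <- accel_error(
    combine_axes(ref_err["accel_x", "surface"], ref_err["accel_y", "surface"],
                 ref_err["accel_z", "surface"]),
    combine_axes(ref_err["accel_x", "subject"], ref_err["accel_y", "subject"],
                 ref_err["accel_z", "subject"]),
    combine_axes(ref_err["accel_x", "wheelchair"], ref_err["accel_y", "wheelchair"],
                 ref_err["accel_z", "wheelchair"]))
  eeg_ref <- mean(ref_err["eeg_avg", ])
  normalization <- if (ea_ref > 0) eeg_ref / ea_ref else 0

  structure(
    list(reference_errors = ref_err, weight_factors = wf,
         correction_factors = cf,
         friction_table = tables$surface,
         subject_weights = tables$subject,
         wheelchair_weights = tables$wheelchair,
         normalization = normalization,
         baseline = base[c("surface_id", "subject_id", "wheelchair_id")]),
    class = "error_model_params"
  )
}

#' @export
print.error_model_params <- function(x, ...) {
  cat("<error_model_params>\n  weight factors:\n")
  print(round(x$weight_factors, 4))
  cat("  correction factors:\n")
  print(round(x$correction_factors, 4))
  cat(sprintf("  accel->EEG normalization: %.4g\n", x$normalization))
  invisible(x)
}

factor_ratio <- function(params, condition, f) {
  switch(f,
    surface = params$friction_table[[1]] / condition$friction,
    subject = params$subject_weights[[1]] / condition$subject_weight,
    wheelchair = params$wheelchair_weights[[1]] / condition$wheelchair_weight)
}

#' Predict the total EEG error for a motion condition
#'
#' Evaluates the fitted model at a condition: per-factor EEG errors
#' (`Esn`, `Epn`, `Ewn`), per-factor accelerometer errors combined across
#' axes, their three-factor average `Ea` rescaled to EEG units, and the
#' overall error `E` (the average of the four terms) that
#' [apply_correction()] removes from the averaged EEG.
#'
#' @param params An `error_model_params` from [calibrate()].
#' @param condition A [recording_meta()] describing the motion condition.
#' @return List with `e_total`, the per-factor EEG errors, and `ea`.
#' @export
predict_condition_error <- function(params, condition) {
  stopifnot(inherits(params, "error_model_params"))
  eeg <- numeric(3); names(eeg) <- FACTORS
  ea_f <- numeric(3); names(ea_f) <- FACTORS
  for (f in FACTORS) {
    ratio <- factor_ratio(params, condition, f)
    eeg[f] <- predict_factor_error(params$reference_errors["eeg_avg", f],
                                   ratio, params$weight_factors["eeg_avg", f],
                                   params$correction_factors["eeg_avg", f])
    ax <- vapply(c("accel_x", "accel_y", "accel_z"), function(m_)
      predict_factor_error(params$reference_errors[m_, f], ratio,
                           params$weight_factors[m_, f],
                           params$correction_factors[m_, f]), numeric(1))
    ea_f[f] <- combine_axes(ax[1], ax[2], ax[3])
  }
  ea <- accel_error(ea_f["surface"], ea_f["subject"], ea_f["wheelchair"])
  e_total <- total_error(eeg["surface"], eeg["subject"], eeg["wheelchair"],
                         ea * params$normalization)
  list(e_total = unname(e_total), eeg_factor_errors = eeg,
       accel_factor_errors = ea_f, ea = unname(ea))
}

#' Remove the predicted artifact amplitude from the averaged EEG
#'
#' Shrinks the series' RMS by the predicted total error: if
#' `RMS(avg) > e_total > 0` the series is scaled by
#' `(RMS - e_total)/RMS` so its RMS drops by exactly `e_total`; a
#' non-positive error leaves the series untouched; an error at or above the
#' series RMS floors the output at zero.
#'
#' @param avg Averaged (single-channel) EEG series.
#' @param e_total Predicted total error in the same units (microvolts).
#' @return The corrected series.
#' @export
apply_correction <- function(avg, e_total) {
  if (!is.finite(e_total)) stopf("e_total must be finite")
  if (e_total <= 0) return(avg)
  r <- rms(avg)
  if (e_total >= r) return(avg * 0)
  avg * ((r - e_total) / r)
}

#' Save / load fitted error-model parameters as JSON
#'
#' @param params An `error_model_params` object.
#' @param path Output/input JSON path.
#' @return `load_error_model` returns the restored `error_model_params`.
#' @export
save_error_model <- function(params, path) {
  stopifnot(inherits(params, "error_model_params"))
  payload <- list(
    reference_errors = as.data.frame(params$reference_errors),
    weight_factors = as.data.frame(params$weight_factors),
    correction_factors = as.data.frame(params$correction_factors),
    friction_table = as.list(params$friction_table),
    subject_weights = as.list(params$subject_weights),
    wheelchair_weights = as.list(params$wheelchair_weights),
    normalization = params$normalization,
    baseline = params$baseline
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_error_model
#' @export
load_error_model <- function(path) {
  p <- jsonlite::fromJSON(path)
  as_mat <- function(df) {
    m <- as.matrix(df)
    rownames(m) <- MODALITIES
    m[, FACTORS, drop = FALSE]
  }
  structure(
    list(reference_errors = as_mat(p$reference_errors),
         weight_factors = as_mat(p$weight_factors),
         correction_factors = as_mat(p$correction_factors),
         friction_table = unlist(p$friction_table),
         subject_weights = unlist(p$subject_weights),
         wheelchair_weights = unlist(p$wheelchair_weights),
         normalization = p$normalization,
         baseline = p$baseline),
    class = "error_model_params"
  )
}
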