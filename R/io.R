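#' Read a recording from OpenBCI-GUI-style delimited text
#'
#' The data file is delimited text (comma by default) with columns
#' `sample_index`, the 8 EEG channels in montage order (microvolts) and the
#' 3 accelerometer axes (g). Lines starting with `%` are comments and are
#' skipped, as in OpenBCI GUI exports. Metadata and the cue schedule live in
#' a JSON sidecar (`<path>.json` by default) with fields `subject_weight`,
#' `wheelchair_weight`, `surface_id`, `friction`, `wheelchair_id`,
#' `subject_id`, `is_reference`, `fs` and `cues`.
#'
#' @param path Path to the data file.
#' @param sidecar Path to the metadata JSON; default `paste0(path, ".json")`.
#' @param sep Field separator, default `","`.
#' @param montage Expected channel names, default [default_montage()].
#' @return A [bci_recording()].
#' @seealso [write_recording()], [segment_by_cues()]
#' @export
read_recording <- function(path, sidecar = paste0(path, ".json"),
                           sep = ",", montage = default_montage()) {
  if (!file.exists(path)) stopf("recording file not found: %s", path)
  if (!file.exists(sidecar)) stopf("metadata sidecar not found: %s", sidecar)

  side <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  need <- c("subject_weight", "wheelchair_weight", "surface_id", "friction",
            "fs", "cues")
  miss <- setdiff(need, names(side))
  if (length(miss)) stopf("sidecar missing field(s): %s", paste(miss, collapse = ", "))
  meta <- recording_meta(
    subject_weight = side$subject_weight,
    wheelchair_weight = side$wheelchair_weight,
    surface_id = side$surface_id, friction = side$friction,
    wheelchair_id = side$wheelchair_id %||% "u1",
    subject_id = side$subject_id %||% "w1",
    is_reference = isTRUE(side$is_reference)
  )
  cue_df <- as.data.frame(side$cues)
  cues <- cue_schedule(cue_df$label, cue_df$start_s, cue_df$duration_s)

  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "%") & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) stopf("no data rows in %s", path)
  header <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  header <- trimws(header)
  want <- c("sample_index", montage, "ax", "ay", "az")
  miss <- setdiff(want, header)
  if (length(setdiff(montage, header)) > 0L &&
      sum(header %in% montage) < 8L) {
    stopf("montage error: fewer than 8 EEG columns present (missing: %s)",
          paste(setdiff(montage, header), collapse = ", "))
  }
  if (length(miss)) stopf("format error: missing column(s): %s",
                          paste(miss, collapse = ", "))

  body <- lines[-1]
  n <- length(body)
  m <- matrix(NA_real_, nrow = n, ncol = length(header))
  if (n > 0L) {
    cells <- strsplit(body, sep, fixed = TRUE)
    for (i in seq_len(n)) {
      v <- suppressWarnings(as.numeric(cells[[i]]))
      if (length(v) != length(header) || anyNA(v)) {
        stopf("parse error: non-numeric or malformed row at data line %d", i)
      }
      m[i, ] <- v
    }
  }
  colnames(m) <- header
  eeg <- t(m[, montage, drop = FALSE])
  accel <- t(m[, c("ax", "ay", "az"), drop = FALSE])
  bci_recording(eeg, accel, fs = side$fs, cues = cues, meta = meta,
                channel_names = montage)
}

#' Write a recording (data file + JSON sidecar)
#'
#' Inverse of [read_recording()]: writes the delimited data file and the
#' metadata/cue sidecar so that reading the pair back reproduces the
#' recording to floating round-trip precision.
#'
#' @param rec A valid [bci_recording()].
#' @param path Output data file path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param sep Field separator, default `","`.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "bci_recording"))
  if (ncol(rec$eeg) > 0L) {
    assert_finite(rec$eeg, "eeg"); assert_finite(rec$accel, "accel")
  }
  header <- c("sample_index", rec$channel_names, "ax", "ay", "az")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%OpenBCI-style recording export",
               sprintf("%%fs=%g", rec$fs),
               paste(header, collapse = sep)), con)
  n <- ncol(rec$eeg)
  if (n > 0L) {
    m <- cbind(seq_len(n) - 1L, t(rec$eeg), t(rec$accel))
    rows <- apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                  scientific = TRUE),
                                           collapse = sep))
    writeLines(rows, con)
  }
  side <- c(rec$meta[c("subject_weight", "wheelchair_weight", "surface_id",
                       "friction", "wheelchair_id", "subject_id",
                       "is_reference")],
            list(fs = rec$fs,
                 cues = as.data.frame(unclass(rec$cues))))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Cut a recording into labeled cue-aligned epochs
#'
#' Each schedule entry whose label is in `include_labels` yields one epoch
#' starting exactly at cue onset with `round(duration_s * fs)` samples; no
#' pre/post padding is added and entries extending past the end of the
#' recording are an error, not truncated.
#'
#' @param rec A [bci_recording()].
#' @param include_labels Labels to keep; default all three cue labels.
#' @return A list of [bci_epoch()] objects carrying `rec$meta`.
#' @export
segment_by_cues <- function(rec,
                            include_labels = c("RELAX", "LEFT", "RIGHT")) {
  stopifnot(inherits(rec, "bci_recording"))
  n <- ncol(rec$eeg)
  out <- list()
  gt <- rec$ground_truth
  for (i in seq_len(nrow(rec$cues))) {
    lab <- rec$cues$label[i]
    if (!lab %in% include_labels) next
    a <- round(rec$cues$start_s[i] * rec$fs) + 1L
    len <- round(rec$cues$duration_s[i] * rec$fs)
    b <- a + len - 1L
    if (a < 1L || b > n) {
      stopf("bounds error: cue entry %d (%s @ %gs) exceeds recording of %d samples",
            i, lab, rec$cues$start_s[i], n)
    }
    egt <- NULL
    if (!is.null(gt) && !is.null(gt$eeg_artifact)) {
      egt <- list(
        eeg_artifact = gt$eeg_artifact[a:b],
        accel_artifact = gt$accel_artifact[, a:b, drop = FALSE],
        true_weight_factors = gt$true_weight_factors,
        artifact_multiplier = gt$artifact_multiplier
      )
    }
    out[[length(out) + 1L]] <- bci_epoch(
      rec$eeg[, a:b, drop = FALSE], rec$accel[, a:b, drop = FALSE],
      label = lab, fs = rec$fs, meta = rec$meta, ground_truth = egt
    )
  }
  out
}
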