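#' Construct a synchronized two-channel signal record
#'
#' Holds one ECG lead and the dorso-ventral SCG acceleration on a common
#' time base.  Times are implicit: sample `k` is at `(k - 1) / sampling_rate`
#' seconds from record start.
#'
#' @param ecg,scg numeric sample vectors of equal length.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param patient_id identifier string.
#' @param metadata named list; when present, `diagnosis` must be one of
#'   `"MI"`, `"HF"`, `"TX"`.
#' @return object of class `scg_record`.
#' @examples
#' rec <- signal_record(rnorm(100), rnorm(100), 200)
#' @export
signal_record <- function(ecg, scg, sampling_rate, patient_id = "", metadata = list()) {
  if (length(ecg) != length(scg)) {
    stopf("`ecg` and `scg` must have equal length (%d vs %d)", length(ecg), length(scg))
  }
  if (!is_scalar_number(sampling_rate) || sampling_rate <= 0) {
    stopf("`sampling_rate` must be a positive number")
  }
  if (!is.null(metadata$diagnosis) && !metadata$diagnosis %in% c("MI", "HF", "TX")) {
    stopf("metadata field `diagnosis` must be one of MI, HF, TX (got %s)", metadata$diagnosis)
  }
  structure(list(
    ecg = as.numeric(ecg), scg = as.numeric(scg),
    sampling_rate = sampling_rate,
    patient_id = as.character(patient_id), metadata = metadata
  ), class = "scg_record")
}

#' @export
print.scg_record <- function(x, ...) {
  cat(sprintf("<scg_record> %s: %d samples @ %g Hz (%.1f s)\n",
              if (nzchar(x$patient_id)) x$patient_id else "(unnamed)",
              length(x$ecg), x$sampling_rate, length(x$ecg) / x$sampling_rate))
  if (!is.null(x$metadata$diagnosis)) {
    cat(sprintf("  diagnosis: %s  EF: %s\n", x$metadata$diagnosis,
                if (is.null(x$metadata$ejection_fraction) ||
                    is.na(x$metadata$ejection_fraction)) "n/a"
                else sprintf("%.0f%%", x$metadata$ejection_fraction)))
  }
  invisible(x)
}

#' Construct a sonogram valve-event annotation
#'
#' One M-mode ultrasound image annotated for a single valve event: the RR
#' intervals of the displayed beats (used for synchronization against the
#' device ECG) and the event time measured from each beat's R peak.
#'
#' @param patient_id identifier string.
#' @param event one of `"MC"`, `"AO"`, `"AC"`, `"MO"`.
#' @param rr_sequence displayed RR intervals in ms (length >= 2).
#' @param event_times_from_r event times in ms from R, one per displayed
#'   beat (at most `length(rr_sequence) + 1`).
#' @param image_id identifier of the source image.
#' @return object of class `echo_annotation`.
#' @export
echo_annotation <- function(patient_id, event, rr_sequence, event_times_from_r,
                            image_id = "") {
  if (!event %in% FP_EVENTS) {
    stopf("unknown valve event code '%s' (must be one of %s)",
          event, paste(FP_EVENTS, collapse = ", "))
  }
  if (length(rr_sequence) < 2) stopf("`rr_sequence` must contain at least 2 intervals")
  if (!all(is.finite(rr_sequence)) || !all(is.finite(event_times_from_r))) {
    stopf("annotation times must all be finite")
  }
  if (length(event_times_from_r) > length(rr_sequence) + 1) {
    stopf("more event times (%d) than displayed beats (%d)",
          length(event_times_from_r), length(rr_sequence) + 1)
  }
  structure(list(
    patient_id = as.character(patient_id), event = event,
    rr_sequence = as.numeric(rr_sequence),
    event_times_from_r = as.numeric(event_times_from_r),
    image_id = as.character(image_id)
  ), class = "echo_annotation")
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write / read a signal record (CSV samples + JSON sidecar)
#'
#' The on-disk format is a CSV with columns `time_s`, `ecg`, `scg_z`
#' accompanied by a JSON sidecar (same path with extension `.json`)
#' holding `sampling_rate`, `patient_id` and `metadata`.
#'
#' @param record an [signal_record()].
#' @param path CSV file path (the sidecar path is derived from it).
#' @return `write_record` returns `path` invisibly; `read_record` returns
#'   the reconstructed [signal_record()].
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "scg_record"))
  n <- length(record$ecg)
  df <- data.frame(
    time_s = (seq_len(n) - 1) / record$sampling_rate,
    ecg = record$ecg, scg_z = record$scg
  )
  write.csv(df, path, row.names = FALSE)
  side <- list(sampling_rate = record$sampling_rate,
               patient_id = record$patient_id,
               metadata = record$metadata)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  if (!file.exists(path)) stopf("record file not found: %s", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stopf("missing JSON sidecar for %s (expected %s)", path, sp)
  df <- read.csv(path)
  for (col in c("time_s", "ecg", "scg_z")) {
    if (!col %in% names(df)) stopf("record CSV %s lacks required column `%s`", path, col)
  }
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(side$sampling_rate)) stopf("sidecar %s lacks field `sampling_rate`", sp)
  md <- side$metadata
  if (is.null(md)) md <- list()
  if (!is.null(md$ejection_fraction) && !length(md$ejection_fraction)) {
    md$ejection_fraction <- NA_real_
  }
  signal_record(df$ecg, df$scg_z, side$sampling_rate,
                patient_id = if (is.null(side$patient_id)) "" else side$patient_id,
                metadata = as.list(md))
}

#' Write / read valve-event annotations (JSON)
#'
#' Annotations are stored as a JSON array of objects with fields
#' `patient_id`, `event`, `rr_sequence`, `event_times_from_r`, `image_id`.
#'
#' @param annotations list of [echo_annotation()] objects.
#' @param path JSON file path.
#' @return `write_annotations` returns `path` invisibly;
#'   `read_annotations` returns a list of [echo_annotation()].
#' @export
write_annotations <- function(annotations, path) {
  payload <- lapply(annotations, function(a) {
    stopifnot(inherits(a, "echo_annotation"))
    list(patient_id = a$patient_id, event = a$event,
         rr_sequence = a$rr_sequence,
         event_times_from_r = a$event_times_from_r,
         image_id = a$image_id)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(a) {
    echo_annotation(
      patient_id = a$patient_id %||% "", event = a$event %||% "",
      rr_sequence = unlist(a$rr_sequence),
      event_times_from_r = unlist(a$event_times_from_r),
      image_id = a$image_id %||% ""
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
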