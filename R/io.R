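# Recording containers and the plain on-disk dialect: a channels x samples
# numeric matrix (TSV, one row per channel) next to a JSON sidecar holding
# {sfreq, channel_labels, condition, participant}.

#' Construct a raw (continuous) recording
#'
#' @param data numeric channels x samples matrix, microvolts.
#' @param sfreq sampling rate in Hz.
#' @param channel_labels one label per row of `data`.
#' @param condition condition label (e.g. `"comfort"`, `"fatigue"`).
#' @param participant participant identifier.
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(data, sfreq, channel_labels,
                          condition = NA_character_,
                          participant = NA_character_) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("raw_recording: data contains NA")
  if (nrow(data) != length(channel_labels)) {
    stop("raw_recording: nrow(data) != length(channel_labels)")
  }
  if (sfreq <= 0) stop("raw_recording: sfreq must be positive")
  rownames(data) <- channel_labels
  structure(list(data = data, sfreq = sfreq,
                 channel_labels = channel_labels,
                 condition = condition, participant = participant),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: %d channels x %d samples @ %g Hz (%.1f s)",
              nrow(x$data), ncol(x$data), x$sfreq,
              ncol(x$data) / x$sfreq))
  if (!is.na(x$participant)) cat(" |", x$participant, x$condition)
  cat("\n")
  invisible(x)
}

#' Construct an epoched recording
#'
#' @param data numeric epochs x channels x samples array, microvolts.
#' @param sfreq sampling rate in Hz.
#' @param channel_labels one label per channel.
#' @param epoch_length_s epoch length in seconds.
#' @param band band label or `"broadband"`.
#' @param condition,participant carried metadata.
#' @return object of class `epoched_recording`.
#' @export
epoched_recording <- function(data, sfreq, channel_labels,
                              epoch_length_s,
                              band = "broadband",
                              condition = NA_character_,
                              participant = NA_character_) {
  if (length(dim(data)) != 3) {
    stop("epoched_recording: data must be epochs x channels x samples")
  }
  if (dim(data)[2] != length(channel_labels)) {
    stop("epoched_recording: channel dimension mismatch")
  }
  if (dim(data)[3] != round(sfreq * epoch_length_s)) {
    stop("epoched_recording: samples != sfreq * epoch_length")
  }
  if (dim(data)[1] < 1) stop("epoched_recording: needs at least one epoch")
  structure(list(data = data, sfreq = sfreq,
                 channel_labels = channel_labels,
                 epoch_length_s = epoch_length_s, band = band,
                 condition = condition, participant = participant),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "epoched_recording: %d epochs x %d channels x %d samples @ %g Hz [%s]",
    d[1], d[2], d[3], x$sfreq, x$band))
  if (!is.na(x$participant)) cat(" |", x$participant, x$condition)
  cat("\n")
  invisible(x)
}

#' Write / read a recording in the plain matrix + JSON sidecar dialect
#'
#' `<stem>.tsv` holds the channels x samples matrix (no header); the sidecar
#' `<stem>.json` holds sampling rate, channel labels and metadata.
#'
#' @param rec a [raw_recording()].
#' @param path path of the `.tsv` matrix file.
#' @return `write_recording` the path, invisibly; `read_recording` a
#'   [raw_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  utils::write.table(format(rec$data, digits = 8, trim = TRUE,
                            scientific = TRUE),
                     path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  sidecar <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(
    list(sfreq = rec$sfreq, channel_labels = rec$channel_labels,
         condition = rec$condition, participant = rec$participant),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording not found: ", path)
  sidecar <- sub("\\.tsv$", ".json", path)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  vals <- scan(path, what = numeric(), sep = "\t", quiet = TRUE)
  n_ch <- length(meta$channel_labels)
  if (length(vals) %% n_ch != 0) {
    stop("read_recording: matrix shape inconsistent with sidecar: ", path)
  }
  mat <- matrix(vals, nrow = n_ch, byrow = TRUE)
  raw_recording(mat, meta$sfreq, meta$channel_labels,
                condition = meta$condition %||% NA_character_,
                participant = meta$participant %||% NA_character_)
}

#' Read a study manifest
#'
#' @param path `manifest.csv` with columns participant, condition, path
#'   (paths relative to the manifest's directory).
#' @return data.frame with an extra `abs_path` column.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "condition", "path")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  m$abs_path <- file.path(dirname(path), m$path)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
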