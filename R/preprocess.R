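# Preprocessing: broadband filtering, resampling, epoching, amplitude-based
# artifact rejection, common average referencing and band filtering.
# Pipeline order is fixed (preprocess_recording): broadband filter ->
# resample -> epoch -> amplitude rejection -> common average reference ->
# band filter. All filters are zero phase (forward-backward biquads) so the
# downstream phase estimates are unbiased in time.

#' Band definitions
#'
#' @return data.frame of the three analysis bands: delta 0.5-4, theta 4-8,
#'   alpha 8-13 Hz.
#' @export
band_specs <- function() {
  data.frame(name = c("delta", "theta", "alpha"),
             low = c(0.5, 4, 8), high = c(4, 8, 13),
             stringsAsFactors = FALSE)
}

check_band <- function(low, high, sfreq) {
  if (!(low > 0 && low < high && high <= sfreq / 2)) {
    stop(sprintf("band [%g, %g] Hz invalid for sfreq %g", low, high, sfreq))
  }
}

#' Broadband filter: 0.5-30 Hz band-pass plus 50 Hz notch
#'
#' Zero-phase 4th-order Butterworth band-pass and a Q = 30 notch biquad,
#' applied per channel on the continuous recording.
#'
#' @param raw a [raw_recording()].
#' @param low,high band-pass edges in Hz.
#' @param notch powerline frequency in Hz; `NA` disables the notch (e.g.
#'   when it exceeds Nyquist after decimation).
#' @return filtered [raw_recording()].
#' @export
broadband_filter <- function(raw, low = 0.5, high = 30, notch = 50) {
  stopifnot(inherits(raw, "raw_recording"))
  check_band(low, high, raw$sfreq)
  sos <- butter_sos(4, c(low, high), raw$sfreq, "pass")
  use_notch <- !is.na(notch)
  if (use_notch && notch >= raw$sfreq / 2) {
    stop("notch frequency at or above Nyquist")
  }
  nsos <- if (use_notch) notch_sos(notch, raw$sfreq) else NULL
  out <- raw
  for (c in seq_len(nrow(raw$data))) {
    x <- sos_filtfilt(sos, raw$data[c, ])
    if (use_notch) x <- sos_filtfilt(nsos, x)
    out$data[c, ] <- x
  }
  out
}

#' Downsample a recording
#'
#' Fourier-domain resampling (inherently anti-aliased when decimating).
#' Upsampling is rejected: the pipeline only ever reduces the rate.
#'
#' @param raw a [raw_recording()].
#' @param target_sfreq target rate in Hz (default 250).
#' @return resampled [raw_recording()].
#' @export
resample_recording <- function(raw, target_sfreq = 250) {
  stopifnot(inherits(raw, "raw_recording"))
  if (target_sfreq > raw$sfreq) {
    stop("resample_recording: upsampling not supported")
  }
  if (target_sfreq == raw$sfreq) return(raw)
  n_out <- round(ncol(raw$data) * target_sfreq / raw$sfreq)
  data <- t(apply(raw$data, 1, fft_resample, n_out = n_out))
  raw_recording(data, target_sfreq, raw$channel_labels,
                raw$condition, raw$participant)
}

#' Cut a continuous recording into non-overlapping epochs
#'
#' The trailing remainder shorter than one epoch is discarded; sample `i` of
#' epoch `k` is raw sample `(k-1) * L + i`.
#'
#' @param raw a [raw_recording()].
#' @param length_s epoch length in seconds (default 2).
#' @return an [epoched_recording()] with band `"broadband"`.
#' @export
epoch_recording <- function(raw, length_s = 2) {
  stopifnot(inherits(raw, "raw_recording"))
  ep_len <- round(length_s * raw$sfreq)
  n_ep <- floor(ncol(raw$data) / ep_len)
  if (n_ep < 1) stop("epoch_recording: recording shorter than one epoch")
  n_ch <- nrow(raw$data)
  data <- array(0, dim = c(n_ep, n_ch, ep_len))
  for (e in seq_len(n_ep)) {
    data[e, , ] <- raw$data[, ((e - 1) * ep_len + 1):(e * ep_len)]
  }
  epoched_recording(data, raw$sfreq, raw$channel_labels, length_s,
                    band = "broadband", condition = raw$condition,
                    participant = raw$participant)
}

#' Drop epochs whose amplitude exceeds a limit
#'
#' An epoch is rejected when any sample on any channel satisfies
#' `|value| > limit_uv` (strict inequality: samples at exactly the limit are
#' kept). Idempotent.
#'
#' @param ep an [epoched_recording()].
#' @param limit_uv rejection limit in microvolts (default 100).
#' @return list with `epochs` (the cleaned [epoched_recording()]) and
#'   `rejected` (indices of dropped epochs in the input).
#' @export
reject_amplitude <- function(ep, limit_uv = 100) {
  stopifnot(inherits(ep, "epoched_recording"))
  if (limit_uv <= 0) stop("reject_amplitude: limit must be positive")
  peak <- apply(abs(ep$data), 1, max)
  rejected <- which(peak > limit_uv)
  if (length(rejected) == dim(ep$data)[1]) {
    stop("reject_amplitude: all epochs rejected")
  }
  out <- ep
  if (length(rejected)) {
    out$data <- ep$data[-rejected, , , drop = FALSE]
  }
  list(epochs = out, rejected = rejected)
}

#' Common average reference
#'
#' Subtracts the across-channel mean at every time point; the across-channel
#' mean of the output is identically zero. Works on epoched and continuous
#' recordings (the operation is instantaneous, so it commutes with epoching
#' and with linear filtering).
#'
#' @param ep an [epoched_recording()] or [raw_recording()] with at least 2
#'   channels.
#' @return referenced recording of the same class.
#' @export
common_average_reference <- function(ep) {
  if (inherits(ep, "raw_recording")) {
    if (nrow(ep$data) < 2) {
      stop("common_average_reference: needs at least 2 channels")
    }
    out <- ep
    out$data <- sweep(ep$data, 2, colMeans(ep$data))
    return(out)
  }
  stopifnot(inherits(ep, "epoched_recording"))
  if (dim(ep$data)[2] < 2) {
    stop("common_average_reference: needs at least 2 channels")
  }
  out <- ep
  m <- apply(ep$data, c(1, 3), mean)           # epochs x samples
  out$data <- ep$data - aperm(
    array(m, dim = c(dim(m), dim(ep$data)[2])), c(1, 3, 2))
  out
}

#' Band-pass filter an epoched (or continuous) recording
#'
#' Zero-phase 4th-order Butterworth per trace. Epoched data are filtered per
#' epoch with odd-reflection padding to tame edge transients.
#'
#' @param ep an [epoched_recording()] or [raw_recording()].
#' @param low,high band edges in Hz, or
#' @param band a band name from [band_specs()] (overrides `low`/`high`).
#' @return same class as the input, band label attached when epoched.
#' @export
band_filter <- function(ep, low = NULL, high = NULL, band = NULL) {
  if (!is.null(band)) {
    bs <- band_specs()
    i <- match(band, bs$name)
    if (is.na(i)) stop("unknown band: ", band)
    low <- bs$low[i]; high <- bs$high[i]
  } else if (is.null(low) || is.null(high)) {
    stop("band_filter: give either band= or low=/high=")
  }
  check_band(low, high, ep$sfreq)
  sos <- butter_sos(4, c(low, high), ep$sfreq, "pass")
  if (inherits(ep, "raw_recording")) {
    out <- ep
    for (c in seq_len(nrow(ep$data))) {
      out$data[c, ] <- sos_filtfilt(sos, ep$data[c, ])
    }
    return(out)
  }
  stopifnot(inherits(ep, "epoched_recording"))
  out <- ep
  d <- dim(ep$data)
  for (e in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      out$data[e, c, ] <- sos_filtfilt(sos, ep$data[e, c, ],
                                       padlen = d[3] - 1L)
    }
  }
  out$band <- if (!is.null(band)) band else sprintf("%g-%g", low, high)
  out
}

#' Full preprocessing chain for one recording
#'
#' broadband filter -> resample -> epoch -> amplitude rejection ->
#' common average reference (optional) -> band filter.
#'
#' @param raw a [raw_recording()].
#' @param band band name from [band_specs()], or `NULL` to stop after
#'   referencing (broadband epochs).
#' @param target_sfreq resampling target in Hz.
#' @param epoch_length_s epoch length in seconds.
#' @param limit_uv amplitude rejection limit in microvolts.
#' @param car apply common average referencing (default TRUE).
#' @param notch powerline notch frequency, `NA` to disable.
#' @return list with `epochs` (an [epoched_recording()]) and `rejected`
#'   (dropped epoch indices).
#' @export
preprocess_recording <- function(raw, band = NULL, target_sfreq = 250,
                                 epoch_length_s = 2, limit_uv = 100,
                                 car = TRUE, notch = 50) {
  x <- broadband_filter(raw, notch = notch)
  x <- resample_recording(x, target_sfreq)
  ep <- epoch_recording(x, epoch_length_s)
  rej <- reject_amplitude(ep, limit_uv)
  ep <- rej$epochs
  if (car) ep <- common_average_reference(ep)
  if (!is.null(band)) ep <- band_filter(ep, band = band)
  list(epochs = ep, rejected = rej$rejected)
}
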