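# Phase-locking value connectivity. Instantaneous phases come from the
# analytic signal computed per 2-s epoch; the PLV between two channels is
#
#   PLV_e = | (1/S) * sum_t exp(i * (phi_x(t) - phi_y(t))) |   per epoch,
#   PLV   = mean over epochs of PLV_e                           ("epoch")
#
# or, in pooled mode, the modulus of the single mean phasor over all samples
# of all epochs ("pooled"). The epoch-averaged form is the conventional
# estimator; the pooled form is consistent with much smaller finite-sample
# modulus bias when the phase difference is autocorrelated (see the methods
# vignette), which matters when absolute PLV levels are compared against a
# threshold grid.

#' Construct a phase array
#'
#' @param phases numeric epochs x channels x samples array of instantaneous
#'   phases in radians; stored wrapped to (-pi, pi].
#' @param channel_labels one label per channel.
#' @return object of class `phase_array`.
#' @export
phase_array <- function(phases, channel_labels) {
  if (length(dim(phases)) != 3) {
    stop("phase_array: phases must be epochs x channels x samples")
  }
  if (dim(phases)[2] != length(channel_labels)) {
    stop("phase_array: channel dimension mismatch")
  }
  if (!all(is.finite(phases))) stop("phase_array: non-finite phases")
  ph <- (phases + pi) %% (2 * pi) - pi
  ph[ph <= -pi] <- pi   # principal interval (-pi, pi]
  structure(list(phases = ph, channel_labels = channel_labels),
            class = "phase_array")
}

#' Instantaneous phase of every epoch-channel trace
#'
#' Argument of the FFT analytic signal, computed independently per epoch and
#' channel. The input should be band limited (narrowband assumption of the
#' analytic-signal method).
#'
#' @param ep an [epoched_recording()].
#' @return a [phase_array()].
#' @export
instantaneous_phase <- function(ep) {
  stopifnot(inherits(ep, "epoched_recording"))
  d <- dim(ep$data)
  ph <- array(0, d)
  for (e in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      x <- ep$data[e, c, ]
      if (stats::sd(x) == 0) {
        stop(sprintf(
          "instantaneous_phase: zero-variance trace (epoch %d, channel %s)",
          e, ep$channel_labels[c]))
      }
      ph[e, c, ] <- Arg(analytic_signal(x))
    }
  }
  phase_array(ph, ep$channel_labels)
}

#' Preprocess one recording straight to band-limited phases
#'
#' Convenience wrapper around the preprocessing chain and
#' [instantaneous_phase()], with a choice of where the analytic signal is
#' computed:
#'
#' * `"epoch"` (default): band filter and Hilbert per 2-s epoch, the
#'   conventional route;
#' * `"continuous"`: band filter and Hilbert on the continuous recording,
#'   then cut the phase traces into epochs. Avoids short-window edge bias,
#'   which matters for the delta band (~4 carrier cycles per 2-s epoch).
#'
#' Amplitude rejection indices are always computed on the broadband epochs;
#' both routes drop the same epochs.
#'
#' @param raw a [raw_recording()].
#' @param band band name from [band_specs()].
#' @param analytic `"epoch"` or `"continuous"`.
#' @param target_sfreq,epoch_length_s,limit_uv,car,notch passed to the
#'   preprocessing steps, see [preprocess_recording()].
#' @return list with `phases` (a [phase_array()]) and `rejected` (dropped
#'   epoch indices).
#' @export
preprocess_phases <- function(raw, band, analytic = c("epoch", "continuous"),
                              target_sfreq = 250, epoch_length_s = 2,
                              limit_uv = 100, car = TRUE, notch = 50) {
  res <- multi_band_phases(raw, band, analytic = analytic,
                           target_sfreq = target_sfreq,
                           epoch_length_s = epoch_length_s,
                           limit_uv = limit_uv, car = car, notch = notch)
  list(phases = res$phases[[band]], rejected = res$rejected)
}

#' @rdname preprocess_phases
#' @param bands character vector of band names; the broadband stages
#'   (filtering, resampling, rejection, referencing) run once and only the
#'   band filter and analytic signal are repeated per band.
#' @return `multi_band_phases`: list with `phases` (named list of
#'   [phase_array()], one per band) and `rejected`.
#' @export
multi_band_phases <- function(raw, bands,
                              analytic = c("epoch", "continuous"),
                              target_sfreq = 250, epoch_length_s = 2,
                              limit_uv = 100, car = TRUE, notch = 50) {
  analytic <- match.arg(analytic)
  x <- broadband_filter(raw, notch = notch)
  x <- resample_recording(x, target_sfreq)
  ep_broad <- epoch_recording(x, epoch_length_s)
  rejected <- reject_amplitude(ep_broad, limit_uv)$rejected
  phases <- vector("list", length(bands))
  names(phases) <- bands

  if (analytic == "epoch") {
    ep <- ep_broad
    if (length(rejected)) {
      ep$data <- ep$data[-rejected, , , drop = FALSE]
    }
    if (car) ep <- common_average_reference(ep)
    for (band in bands) {
      phases[[band]] <- instantaneous_phase(band_filter(ep, band = band))
    }
    return(list(phases = phases, rejected = rejected))
  }

  if (car) x <- common_average_reference(x)
  n_ch <- nrow(x$data)
  ep_len <- round(epoch_length_s * x$sfreq)
  n_ep <- floor(ncol(x$data) / ep_len)
  keep <- setdiff(seq_len(n_ep), rejected)
  if (!length(keep)) stop("preprocess_phases: all epochs rejected")
  for (band in bands) {
    xb <- band_filter(x, band = band)
    pha <- array(0, c(n_ep, n_ch, ep_len))
    for (c in seq_len(n_ch)) {
      xc <- xb$data[c, ]
      if (stats::sd(xc) == 0) {
        stop("preprocess_phases: zero-variance channel ",
             xb$channel_labels[c])
      }
      ph_c <- Arg(analytic_signal(xc))[seq_len(n_ep * ep_len)]
      pha[, c, ] <- matrix(ph_c, n_ep, ep_len, byrow = TRUE)
    }
    phases[[band]] <- phase_array(pha[keep, , , drop = FALSE],
                                  xb$channel_labels)
  }
  list(phases = phases, rejected = rejected)
}

plv_poolings <- c("epoch", "pooled")

#' PLV between two phase traces
#'
#' @param phix,phiy numeric arrays of identical shape: epochs x samples
#'   matrices (or vectors, treated as one epoch) of phases in radians.
#' @param pooling `"epoch"` (mean over epochs of per-epoch moduli, default)
#'   or `"pooled"` (modulus of the grand mean phasor).
#' @return PLV in `[0, 1]`.
#' @export
#' @examples
#' plv_pair(c(0, 1, 2), c(0, 1, 2))               # identical phases -> 1
#' plv_pair(c(0, pi / 2, pi, 3 * pi / 2), rep(0, 4))  # balanced -> 0
plv_pair <- function(phix, phiy, pooling = "epoch") {
  pooling <- match.arg(pooling, plv_poolings)
  if (!identical(dim(phix), dim(phiy)) || length(phix) != length(phiy)) {
    stop("plv_pair: phase arrays must have identical shape")
  }
  z <- exp(1i * (phix - phiy))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (pooling == "pooled") return(Mod(mean(z)))
  mean(Mod(rowMeans(z)))
}

#' PLV matrix over all channel pairs
#'
#' @param ph a [phase_array()].
#' @param pooling see [plv_pair()].
#' @param band,condition,participant metadata carried into the result.
#' @return object of class `plv_matrix`: list with `values` (symmetric
#'   channel x channel matrix, unit diagonal), `channel_labels`, `band`,
#'   `condition`, `participant`, `n_epochs`, `pooling`.
#' @export
plv_matrix <- function(ph, pooling = "epoch", band = NA_character_,
                       condition = NA_character_,
                       participant = NA_character_) {
  stopifnot(inherits(ph, "phase_array"))
  pooling <- match.arg(pooling, plv_poolings)
  d <- dim(ph$phases)
  n_ep <- d[1]; n_ch <- d[2]; n_s <- d[3]
  if (n_ch < 2) stop("plv_matrix: needs at least 2 channels")
  acc <- matrix(0, n_ch, n_ch)
  if (pooling == "epoch") {
    for (e in seq_len(n_ep)) {
      z <- exp(1i * matrix(ph$phases[e, , ], n_ch, n_s))
      acc <- acc + Mod(z %*% Conj(t(z))) / n_s
    }
    vals <- acc / n_ep
  } else {
    accc <- matrix(0 + 0i, n_ch, n_ch)
    for (e in seq_len(n_ep)) {
      z <- exp(1i * matrix(ph$phases[e, , ], n_ch, n_s))
      accc <- accc + z %*% Conj(t(z)) / n_s
    }
    vals <- Mod(accc) / n_ep
  }
  vals <- (vals + t(vals)) / 2
  vals <- pmin(vals, 1)
  diag(vals) <- 1
  dimnames(vals) <- list(ph$channel_labels, ph$channel_labels)
  structure(list(values = vals, channel_labels = ph$channel_labels,
                 band = band, condition = condition,
                 participant = participant, n_epochs = n_ep,
                 pooling = pooling),
            class = "plv_matrix")
}

#' @export
print.plv_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf(
    "plv_matrix: %d channels [%s/%s/%s], %d epochs (%s pooling), mean %.3f\n",
    length(x$channel_labels), x$participant, x$condition, x$band,
    x$n_epochs, x$pooling, mean(off)))
  invisible(x)
}

#' Entrywise mean and SD of PLV matrices across participants
#'
#' @param matrices list of [plv_matrix()] objects with matching labels and
#'   band/condition.
#' @return list with `mean` (a `plv_matrix` whose `participant` is
#'   `"group"`), `sd` (plain matrix), `n`.
#' @export
group_mean_plv <- function(matrices) {
  if (!length(matrices)) stop("group_mean_plv: empty list")
  ref <- matrices[[1]]
  for (m in matrices) {
    stopifnot(inherits(m, "plv_matrix"))
    if (!identical(m$channel_labels, ref$channel_labels) ||
        !identical(m$band, ref$band) ||
        !identical(m$condition, ref$condition)) {
      stop("group_mean_plv: label/band/condition mismatch across matrices")
    }
  }
  stack <- vapply(matrices, function(m) m$values,
                  matrix(0, nrow(ref$values), ncol(ref$values)))
  mu <- apply(stack, c(1, 2), mean)
  sdm <- if (length(matrices) > 1) apply(stack, c(1, 2), stats::sd) else
    matrix(0, nrow(mu), ncol(mu))
  out <- ref
  out$values <- mu
  out$participant <- "group"
  dimnames(sdm) <- dimnames(mu)
  list(mean = out, sd = sdm, n = length(matrices))
}

#' Long-format table of a PLV matrix
#'
#' @param plv a [plv_matrix()].
#' @return data.frame `chan_a, chan_b, band, condition, participant, plv`
#'   with one row per unordered pair.
#' @export
plv_long <- function(plv) {
  stopifnot(inherits(plv, "plv_matrix"))
  idx <- which(upper.tri(plv$values), arr.ind = TRUE)
  data.frame(chan_a = plv$channel_labels[idx[, 1]],
             chan_b = plv$channel_labels[idx[, 2]],
             band = plv$band, condition = plv$condition,
             participant = plv$participant,
             plv = plv$values[idx],
             stringsAsFactors = FALSE)
}
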