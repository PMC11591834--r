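# Signal-processing primitives: IIR design, zero-phase filtering, analytic
# signal, Fourier resampling. Filters are built as cascaded biquads (second-
# order sections) for numerical stability at low normalized cutoffs
# (0.5 Hz at fs = 1000 puts poles very close to the unit circle; a direct-form
# order-8 polynomial is unusable there in double precision).

#' Design a Butterworth filter as second-order sections
#'
#' Standard analog-prototype design: Butterworth poles, lowpass/highpass/
#' bandpass frequency transform with bilinear prewarping, then grouping of
#' conjugate pole pairs into biquads. Only even orders are supported, so
#' every section holds one conjugate pole pair.
#'
#' @param order filter order of the prototype (even). A bandpass design has
#'   `2 * order` poles.
#' @param freq cutoff in Hz: one value for `"low"`/`"high"`, `c(low, high)`
#'   for `"pass"`.
#' @param fs sampling rate in Hz.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return matrix with one row per biquad, columns `b0 b1 b2 a0 a1 a2`
#'   (`a0` is always 1).
#' @keywords internal
butter_sos <- function(order, freq, fs, type = c("pass", "low", "high")) {
  type <- match.arg(type)
  if (order %% 2L != 0L || order < 2L) {
    stop("butter_sos: 'order' must be a positive even integer")
  }
  nyq <- fs / 2
  if (any(freq <= 0) || any(freq >= nyq)) {
    stop("butter_sos: cutoff frequencies must lie strictly inside (0, fs/2)")
  }
  if (type == "pass" && (length(freq) != 2L || freq[1] >= freq[2])) {
    stop("butter_sos: bandpass needs freq = c(low, high) with low < high")
  }

  # analog Butterworth prototype poles (unit cutoff, gain 1, no zeros)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))

  fs2 <- 2 * fs
  warp <- function(f) fs2 * tan(pi * f / fs)  # bilinear prewarp

  if (type == "low") {
    wc <- warp(freq[1])
    poles <- proto * wc
    zeros <- complex(0)
    gain <- wc^order
  } else if (type == "high") {
    wc <- warp(freq[1])
    poles <- wc / proto
    zeros <- rep(0 + 0i, order)
    # k_hp = 1 at s -> Inf: prod(-p_proto) = 1 for Butterworth
    gain <- 1
  } else {
    w1 <- warp(freq[1]); w2 <- warp(freq[2])
    bw <- w2 - w1
    w0 <- sqrt(w1 * w2)
    s <- proto * bw / 2
    disc <- sqrt(s^2 - w0^2)
    poles <- c(s + disc, s - disc)
    zeros <- rep(0 + 0i, order)
    gain <- bw^order
  }

  # bilinear transform to z-plane
  zp <- (fs2 + poles) / (fs2 - poles)
  zz <- (fs2 + zeros) / (fs2 - zeros)
  gain <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  deficit <- length(zp) - length(zz)
  zz <- c(zz, rep(-1 + 0i, deficit))  # zeros at Nyquist fill the degree

  # group poles into conjugate pairs (sorted toward the unit circle last so
  # the hardest section sees an already-smoothed signal)
  up <- zp[Im(zp) > 0]
  up <- up[order(Mod(up))]
  if (length(up) * 2L != length(zp)) {
    stop("butter_sos: expected strictly complex conjugate pole pairs")
  }
  nsec <- length(up)

  # zeros are all real (+1 / -1 mixtures); hand one of each kind per section
  pos <- sum(Re(zz) > 0)
  neg <- length(zz) - pos
  secgain <- gain^(1 / nsec)
  sos <- matrix(0, nsec, 6)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  for (i in seq_len(nsec)) {
    p <- up[i]
    a1 <- -2 * Re(p)
    a2 <- Mod(p)^2
    if (pos > 0 && neg > 0) {
      bq <- c(1, 0, -1); pos <- pos - 1L; neg <- neg - 1L
    } else if (neg > 0) {
      bq <- c(1, 2, 1); neg <- neg - 2L
    } else {
      bq <- c(1, -2, 1); pos <- pos - 2L
    }
    sos[i, ] <- c(bq * secgain, 1, a1, a2)
  }
  sos
}

#' 50/60 Hz notch biquad (RBJ cookbook design)
#'
#' @param f0 notch frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param Q quality factor; bandwidth is roughly `f0 / Q`.
#' @return a 1-row SOS matrix.
#' @keywords internal
notch_sos <- function(f0, fs, Q = 30) {
  if (f0 <= 0 || f0 >= fs / 2) stop("notch_sos: f0 outside (0, fs/2)")
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  a0 <- 1 + alpha
  matrix(c(1 / a0, -2 * cos(w0) / a0, 1 / a0,
           1, -2 * cos(w0) / a0, (1 - alpha) / a0),
         1, 6, dimnames = list(NULL, c("b0", "b1", "b2", "a0", "a1", "a2")))
}

# one biquad, zero initial conditions; AR recursion runs in C via stats::filter
biquad_apply <- function(b, a, x) {
  n <- length(x)
  xp <- c(0, 0, x)
  ma <- b[1] * xp[3:(n + 2)] + b[2] * xp[2:(n + 1)] + b[3] * xp[1:n]
  as.numeric(stats::filter(ma, -a[2:3], method = "recursive"))
}

sos_filter <- function(sos, x) {
  for (i in seq_len(nrow(sos))) {
    x <- biquad_apply(sos[i, 1:3], sos[i, 4:6], x)
  }
  x
}

#' Zero-phase filtering of a vector through an SOS cascade
#'
#' Forward-backward application with odd-reflection padding at both ends,
#' giving zero phase distortion and squared magnitude response.
#'
#' @param sos SOS matrix from [butter_sos()] / [notch_sos()] (rows may be
#'   concatenated with `rbind`).
#' @param x numeric vector.
#' @param padlen reflection pad length in samples; defaults to a short
#'   multiple of the section count. Pass something like `3 * fs / f_low`
#'   when the filter has a slow low-frequency edge.
#' @return filtered vector, same length as `x`.
#' @keywords internal
sos_filtfilt <- function(sos, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) {
    # ~9 time constants of the slowest pole so zero-initial-condition
    # transients decay below 1e-4 before the retained segment starts
    pr <- max(sqrt(sos[, 6]))
    tau <- if (pr >= 1) n else 1 / (1 - pr)
    padlen <- ceiling(9 * tau)
  }
  padlen <- min(as.integer(padlen), n - 1L)
  if (padlen > 0) {
    head_pad <- 2 * x[1] - x[(padlen + 1):2]
    tail_pad <- 2 * x[n] - x[(n - 1):(n - padlen)]
    xe <- c(head_pad, x, tail_pad)
  } else {
    xe <- x
  }
  y <- sos_filter(sos, xe)
  y <- rev(sos_filter(sos, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Instantaneous phase via the FFT analytic signal
#'
#' Single-sided spectrum doubling (the discrete analytic signal): for a
#' narrowband real input the argument of the result is the instantaneous
#' phase and its modulus the instantaneous amplitude.
#'
#' @param x numeric vector (one narrowband trace).
#' @return complex vector, the analytic signal.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Fourier-domain resampling of a uniformly sampled vector
#'
#' Truncates the spectrum to the target bandwidth, which is inherently
#' anti-aliased for downsampling.
#'
#' @param x numeric vector.
#' @param n_out target number of samples.
#' @return numeric vector of length `n_out`.
#' @keywords internal
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  m <- min(n, n_out)
  half <- floor((m - 1) / 2)
  Y[1] <- X[1]
  if (half >= 1) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(n_out - half + 1):n_out] <- X[(n - half + 1):n]
  }
  if (m %% 2 == 0) {
    # shared Nyquist bin: split so the result stays real
    if (n_out < n) {
      Y[m / 2 + 1] <- X[m / 2 + 1] + X[n - m / 2 + 1]
    } else {
      Y[m / 2 + 1] <- X[m / 2 + 1] / 2
      Y[n_out - m / 2 + 1] <- X[m / 2 + 1] / 2
    }
  }
  # ifft(Y)/n_out times amplitude correction n_out/n collapses to 1/n
  Re(stats::fft(Y, inverse = TRUE)) / n
}
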