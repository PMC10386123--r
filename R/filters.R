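# Butterworth bandpass design and zero-phase filtering.
#
# No signal-processing package is assumed: the digital filter is designed
# from the analog Butterworth prototype (poles on the unit half-circle),
# transformed lowpass -> bandpass, then discretised with the bilinear
# transform with frequency prewarping. Forward-backward application gives
# zero phase; the effective magnitude response is therefore the square of
# the one-pass response (attenuation in dB doubles).

butter_bandpass <- function(low, high, order = 4, fs = 51.2) {
  if (!(low > 0 && high > low && high < fs / 2))
    cogload_error("cogload_parameter_error",
                  sprintf("invalid band (%g, %g) Hz for fs = %g Hz", low, high, fs))
  # analog prototype poles (Butterworth, cutoff 1 rad/s)
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order) + pi / 2
  p <- complex(modulus = 1, argument = theta)
  # prewarped band edges
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # lowpass -> bandpass: each pole maps to a conjugate-free pair
  pb <- bw * p / 2
  disc <- sqrt(pb^2 - w0^2)
  poles <- c(pb + disc, pb - disc)
  zeros <- rep(0 + 0i, order)
  gain <- bw^order
  # bilinear transform z = (2fs + s) / (2fs - s)
  fs2 <- 2 * fs
  zd <- (fs2 + zeros) / (fs2 - zeros)
  pd <- (fs2 + poles) / (fs2 - poles)
  gain <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  # pad zeros at z = -1 for the order difference
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  b <- Re(gain * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# steady-state initial conditions (direct form II transposed)
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[2:n]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(1, n - 1) - t(comp), B)
}

filt_filt <- function(b, a, x) {
  n <- length(x)
  nf <- max(length(a), length(b))
  pad <- 3 * nf            # scipy-compatible default edge padding
  if (n <= pad)
    cogload_error("cogload_parameter_error",
                  "signal too short for zero-phase filtering")
  # odd extension at both ends (mirrors scipy's default padding)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  zi <- lfilter_zi(b, a)
  y <- .iir_filter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- .iir_filter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth bandpass filter
#'
#' Filters a signal with a Butterworth bandpass of the given order applied
#' forward and backward (zero phase). Used with (0.5, 8) Hz for the pulse
#' waveform and (0.5, 6) Hz for the accelerometer axes, both at order 4.
#'
#' @param x numeric signal.
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param order filter order of the one-pass filter (default 4). Because
#'   the filter is applied twice, stopband attenuation in dB doubles.
#' @param fs sampling rate in Hz.
#' @return Filtered signal, same length as `x`.
#' @export
#' @examples
#' x <- sin(2 * pi * 2 * seq(0, 10, by = 1 / 51.2))
#' y <- bandpass(x, 0.5, 8, fs = 51.2)
bandpass <- function(x, low, high, order = 4, fs = 51.2) {
  if (all(x == 0)) return(x * 0)
  ba <- butter_bandpass(low, high, order, fs)
  filt_filt(ba$b, ba$a, x)
}

#' Euclidean magnitude of the three accelerometer axes
#'
#' @param ax,ay,az equal-length numeric vectors (typically the bandpassed
#'   accelerometer axes, m/s^2).
#' @return Elementwise `sqrt(ax^2 + ay^2 + az^2)`.
#' @export
accel_magnitude <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ay) != length(az))
    cogload_error("cogload_parameter_error", "accelerometer axes differ in length")
  sqrt(ax^2 + ay^2 + az^2)
}

# simple Welch power spectral density (Hann window, 50 % overlap)
welch_psd <- function(x, fs, nperseg = min(length(x), 256)) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1, floor(nperseg / 2))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  starts <- seq(1, n - nperseg + 1, by = step)
  scale <- fs * sum(win^2)
  acc <- numeric(floor(nperseg / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(fft(seg))^2 / scale
    half <- sp[seq_len(length(acc))]
    if (nperseg %% 2 == 0) {
      half[2:(length(half) - 1)] <- 2 * half[2:(length(half) - 1)]
    } else {
      half[2:length(half)] <- 2 * half[2:length(half)]
    }
    acc <- acc + half
  }
  list(freq = (seq_along(acc) - 1) * fs / nperseg, power = acc / length(starts))
}

# local maxima with a minimum separation, greedy by amplitude
find_peaks <- function(x, min_dist = 1, min_height = -Inf) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(-x[cand])]
  keep <- logical(n)
  blocked <- logical(n)
  for (i in ord) {
    if (blocked[i]) next
    keep[i] <- TRUE
    lo <- max(1, i - min_dist)
    hi <- min(n, i + min_dist)
    blocked[lo:hi] <- TRUE
  }
  sort(which(keep))
}
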