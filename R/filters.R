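#' Zero-phase FIR bandpass filter
#'
#' Designs a Hamming-windowed FIR bandpass (`signal::fir1`) and applies it
#' forward and backward (via FFT convolution) so the net phase response is
#' zero: event onsets and peaks are not shifted in time, which matters
#' because detected event timing feeds density and time-locked averaging.
#' Edges are padded by reflection (3 x the filter length) before filtering
#' and trimmed afterwards, so output length equals input length.
#'
#' Note the effective magnitude response is the square of the single-pass
#' response, and the transition width scales as `fs / order`: a 300th-order
#' filter at 250 Hz cannot attenuate sharply below ~1 Hz. Pass a larger
#' `order` when a steep low-frequency stopband is required.
#'
#' @param x numeric signal (microvolts).
#' @param fs sampling rate, Hz.
#' @param lo,hi band edges, Hz; `0 < lo < hi < fs/2`.
#' @param order filter order (number of taps minus one), default 300.
#' @return Filtered signal, same length as `x`.
#' @export
fir_bandpass <- function(x, fs, lo, hi, order = 300L) {
  stopifnot(is.numeric(x), fs > 0, order >= 2)
  if (!(lo > 0 && lo < hi && hi < fs / 2))
    stop("band edges must satisfy 0 < lo < hi < fs/2")
  ntap <- order + 1L
  npad <- 3L * ntap
  if (length(x) <= npad + 1L)
    stop("signal too short to filter: need more than 3x the filter length (",
         npad + 1L, " samples)")
  b <- as.numeric(signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass"))
  n <- length(x)
  xp <- c(2 * x[1] - rev(x[2:(npad + 1L)]),
          x,
          2 * x[n] - rev(x[(n - npad):(n - 1L)]))
  # forward-backward: group delays cancel, magnitude response squared
  y <- rev(signal::fftfilt(b, rev(signal::fftfilt(b, xp))))
  y[(npad + 1L):(npad + n)]
}

#' Instantaneous amplitude envelope via the analytic signal
#'
#' Magnitude of the Hilbert analytic signal, computed in the frequency
#' domain. Used for the sigma-band (11-16 Hz) envelope in spindle
#' detection and amplitude summaries.
#'
#' @param x numeric signal (typically already narrowband-filtered).
#' @return Non-negative numeric vector, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' 1/f ("pink") background noise
#'
#' Gaussian noise shaped in the frequency domain to a power spectrum
#' proportional to `1/f^exponent` above `f_floor` (flat-to-zero below it,
#' so the variance does not diverge at DC), then rescaled to the requested
#' RMS amplitude. This is the background against which synthetic sleep
#' events are injected.
#'
#' @param n number of samples.
#' @param fs sampling rate, Hz.
#' @param exponent spectral exponent (1 = pink).
#' @param rms target RMS amplitude, microvolts.
#' @param f_floor low-frequency cutoff, Hz.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs, exponent = 1, rms = 15, f_floor = 0.3) {
  stopifnot(n > 3, fs > 0, rms >= 0)
  nf <- n %/% 2 + 1
  f <- seq(0, fs / 2, length.out = nf)
  amp <- ifelse(f < f_floor, 0, pmax(f, f_floor) ^ (-exponent / 2))
  spec <- complex(modulus = amp, argument = runif(nf, 0, 2 * pi))
  spec[1] <- 0
  full <- c(spec, Conj(rev(spec[2:(n - nf + 1)])))
  x <- Re(fft(full, inverse = TRUE))
  if (rms == 0) return(numeric(n))
  x * rms / sd(x)
}
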