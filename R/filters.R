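#' Butterworth filter design (second-order sections)
#'
#' Designs an even-order digital Butterworth filter by bilinear transform of
#' the analog prototype and returns it as a cascade of biquads (second-order
#' sections, SOS). SOS form is used throughout the package because the
#' envelope bands of interest (e.g. theta at 4--8 Hz on a 1 kHz envelope)
#' sit at very low normalized frequencies where a single transfer-function
#' polynomial of order 8 is numerically fragile.
#'
#' @param n filter order (even, >= 2); for band-pass this is the prototype
#'   order, i.e. a "four-pole" band-pass is `n = 4` and yields 4 biquads.
#' @param fc cutoff frequency in Hz: a single value for `type = "low"`, a
#'   length-2 vector `c(lo, hi)` for `type = "pass"`.
#' @param fs sampling rate in Hz.
#' @param type `"low"` or `"pass"`.
#' @return numeric matrix with one row per section, columns
#'   `b0, b1, b2, a0, a1, a2` (`a0 = 1`).
#' @export
butter_sos <- function(n, fc, fs, type = c("pass", "low")) {
  type <- match.arg(type)
  if (n < 2L || n %% 2L != 0L) stop("filter order must be even and >= 2")
  if (fs <= 0) stop("fs must be positive")
  fs2 <- 2 * fs
  # analog lowpass prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))

  if (type == "low") {
    if (length(fc) != 1L || fc <= 0 || fc >= fs / 2)
      stop("lowpass cutoff must be a single value in (0, fs/2)")
    w <- fs2 * tan(pi * fc / fs)          # pre-warped analog cutoff
    pa <- proto * w
    pd <- (fs2 + pa) / (fs2 - pa)
    # n zeros at z = -1 (analog zeros at infinity)
    gain <- Re(w^n / prod(fs2 - pa))
    zd <- rep(-1 + 0i, n)
  } else {
    if (length(fc) != 2L || fc[1] <= 0 || fc[2] <= fc[1] || fc[2] >= fs / 2)
      stop("bandpass edges must satisfy 0 < lo < hi < fs/2")
    w1 <- fs2 * tan(pi * fc[1] / fs)
    w2 <- fs2 * tan(pi * fc[2] / fs)
    w0 <- sqrt(w1 * w2)
    bw <- w2 - w1
    # lowpass -> bandpass: each prototype pole spawns a conjugate-symmetric pair
    pa <- c((proto * bw + sqrt((proto * bw)^2 - 4 * w0^2)) / 2,
            (proto * bw - sqrt((proto * bw)^2 - 4 * w0^2)) / 2)
    pd <- (fs2 + pa) / (fs2 - pa)
    # n analog zeros at s = 0 -> z = +1, n at infinity -> z = -1
    gain <- Re(bw^n * fs2^n / prod(fs2 - pa))
    zd <- c(rep(1 + 0i, n), rep(-1 + 0i, n))
  }

  # group poles into conjugate pairs (positive-imaginary representative)
  pu <- pd[Im(pd) > 0]
  if (length(pu) * 2L != length(pd)) {
    # fall back: sort by imaginary part magnitude and pair sequentially
    pd <- pd[order(Re(pd), abs(Im(pd)))]
    pu <- pd[seq(1, length(pd), by = 2)]
  }
  nsec <- length(pu)
  g <- abs(gain)^(1 / nsec)       # spread gain across sections
  sgn <- sign(gain)
  sos <- matrix(0, nsec, 6, dimnames = list(NULL, c("b0", "b1", "b2", "a0", "a1", "a2")))
  for (s in seq_len(nsec)) {
    p <- pu[s]
    a1 <- -2 * Re(p)
    a2 <- Re(p * Conj(p))
    if (type == "low") {
      b <- g * c(1, 2, 1)          # zeros at z = -1, -1
    } else {
      b <- g * c(1, 0, -1)         # zeros at z = +1 and z = -1
    }
    if (s == 1L) b <- b * sgn
    sos[s, ] <- c(b, 1, a1, a2)
  }
  sos
}

#' Zero-phase filtering with a SOS cascade
#'
#' Applies the filter forward and backward (`filtfilt`) so pass-band group
#' delay cancels, with odd-reflection padding at both ends to absorb the
#' start-up transient.
#'
#' @param sos SOS matrix from [butter_sos()].
#' @param x numeric signal.
#' @param padlen number of samples of odd reflection prepended/appended;
#'   capped at `length(x) - 1`.
#' @return filtered signal, same length as `x`.
#' @export
filtfilt_sos <- function(sos, x, padlen = 1000L) {
  n <- length(x)
  if (n < 2L) stop("signal too short to filter")
  padlen <- min(as.integer(padlen), n - 1L)
  if (padlen > 0L) {
    head_ext <- 2 * x[1] - x[(padlen + 1L):2L]
    tail_ext <- 2 * x[n] - x[(n - 1L):(n - padlen)]
    xp <- c(head_ext, x, tail_ext)
  } else {
    xp <- x
  }
  y <- .sosfilt_cpp(sos, xp)
  y <- rev(.sosfilt_cpp(sos, rev(y)))
  if (padlen > 0L) y <- y[(padlen + 1L):(padlen + n)]
  y
}

#' Anti-aliased integer-factor decimation
#'
#' Low-passes with a zero-phase order-4 Butterworth at 80% of the target
#' Nyquist, then keeps every q-th sample. Used to bring rectified envelopes
#' from acquisition rate (tens of kHz) down to ~1 kHz before spectral
#' analysis; the analysis range tops out at 200 Hz so nothing of interest is
#' lost.
#'
#' @param x numeric signal.
#' @param fs sampling rate of `x` in Hz.
#' @param target_fs desired rate; the actual factor is `round(fs/target_fs)`.
#' @return list with `samples` and the achieved `fs`.
#' @export
decimate_envelope <- function(x, fs, target_fs = 1000) {
  q <- max(1L, as.integer(round(fs / target_fs)))
  if (q == 1L) return(list(samples = x, fs = fs))
  new_fs <- fs / q
  sos <- butter_sos(4L, 0.8 * new_fs / 2, fs, type = "low")
  y <- filtfilt_sos(sos, x, padlen = min(length(x) - 1L, 3L * q * 10L))
  list(samples = y[seq(1L, length(y), by = q)], fs = new_fs)
}
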