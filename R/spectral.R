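#' Full-wave rectified, demeaned envelope
#'
#' Rectification of the multi-unit signal followed by mean subtraction
#' exposes the low-frequency envelope that carries the band structure of
#' interest: `|x| - mean(|x|)`.
#'
#' @param samples numeric signal.
#' @return zero-mean envelope, same length.
#' @export
rectify_demean <- function(samples) {
  if (!length(samples)) stop("samples must be nonempty")
  if (!all(is.finite(samples))) stop("non-finite sample in input")
  a <- abs(samples)
  a - mean(a)
}

#' Welch power spectral density at 1/3 Hz resolution
#'
#' Welch's method with Hamming-windowed segments of `window_s` seconds
#' (default 3 s, fixing the frequency spacing at exactly 1/3 Hz) and 50%
#' overlap; segments are demeaned before windowing. One-sided density
#' scaling, so `sum(power) * df` estimates the signal variance.
#'
#' @param envelope numeric signal (typically from [rectify_demean()], after
#'   decimation).
#' @param fs sampling rate in Hz; `window_s * fs` must be an integer.
#' @param window_s window length in seconds.
#' @return object of class `mer_psd`: list with `freqs`, `power`, `df`.
#' @export
estimate_psd <- function(envelope, fs, window_s = 3) {
  n <- length(envelope)
  if (n / fs < window_s)
    stop(sprintf("envelope duration %.3f s < PSD window %g s", n / fs, window_s))
  nper <- window_s * fs
  if (abs(nper - round(nper)) > 1e-8)
    stop("window_s * fs must be an integer number of samples; resample first")
  nper <- as.integer(round(nper))
  step <- nper %/% 2L
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))
  u <- sum(w^2)
  nf <- nper %/% 2L + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- envelope[s0:(s0 + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nf)])^2
    acc <- acc + sp
  }
  pxx <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC and (for even nper) Nyquist
  sc <- rep(2, nf); sc[1] <- 1
  if (nper %% 2L == 0L) sc[nf] <- 1
  pxx <- pxx * sc
  structure(list(freqs = seq(0, nf - 1) * fs / nper, power = pxx, df = fs / nper),
            class = "mer_psd")
}

#' @export
print.mer_psd <- function(x, ...) {
  cat(sprintf("<mer_psd> %d bins, %g-%g Hz, df = %g Hz, integral = %.4g\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$df,
              sum(x$power) * x$df))
  invisible(x)
}

#' Restrict and unit-normalize a PSD
#'
#' Keeps the bins inside the analysis range and rescales so the integral
#' `sum(power) * df` equals 1. Normalizing to total analysis-range power
#' removes the influence of varying absolute RMS across recordings and
#' patients.
#'
#' @param psd a `mer_psd`.
#' @param lo,hi analysis range edges in Hz (default 2 and 200).
#' @return a `mer_psd` restricted to `[lo, hi]` with unit integral.
#' @export
normalize_psd <- function(psd, lo = 2, hi = 200) {
  if (min(psd$freqs) > lo + 1e-9 || max(psd$freqs) < hi - 1e-9)
    stop(sprintf("PSD grid [%g, %g] does not cover [%g, %g] Hz",
                 min(psd$freqs), max(psd$freqs), lo, hi))
  keep <- psd$freqs >= lo - 1e-9 & psd$freqs <= hi + 1e-9
  p <- psd$power[keep]
  tot <- sum(p) * psd$df
  if (tot <= 0) stop("zero total power in analysis range")
  structure(list(freqs = psd$freqs[keep], power = p / tot, df = psd$df),
            class = "mer_psd")
}

# internal: edge-trimmed variance after zero-phase band-pass filtering.
# The start-up transient of an order-4 band-pass decays with time constant
# ~ 1/(pi * bandwidth); three time constants are dropped from each end
# (capped at 10% of the signal per end so short epochs keep some support).
bandpass_var <- function(x, fs, lo, hi) {
  sos <- butter_sos(4L, c(lo, hi), fs, type = "pass")
  tau <- 1 / (pi * (hi - lo))
  trim <- min(as.integer(round(3 * tau * fs)), as.integer(length(x) * 0.1))
  y <- filtfilt_sos(sos, x, padlen = min(length(x) - 1L, max(1000L, 3L * trim)))
  if (trim > 0L) y <- y[(trim + 1L):(length(y) - trim)]
  stats::var(y)
}

#' Band power fraction (filter domain)
#'
#' Fraction of envelope power in a band, computed as the ratio of
#' edge-trimmed variances after zero-phase order-4 ("four-pole")
#' Butterworth band-pass filtering: band numerator over the 2--200 Hz
#' analysis-range denominator. Exactly invariant to amplitude scaling.
#'
#' @param envelope numeric signal at rate `fs`.
#' @param fs sampling rate in Hz.
#' @param band length-2 numeric `c(lo, hi)` in Hz, or a name in [GPI_BANDS].
#' @param range analysis range for the denominator.
#' @return scalar fraction in `[0, 1]` (up to filter roll-off tolerance).
#' @export
band_power_fraction <- function(envelope, fs, band, range = GPI_ANALYSIS_RANGE) {
  if (is.character(band)) band <- GPI_BANDS[[match.arg(band, names(GPI_BANDS))]]
  if (length(envelope) / fs < 3) stop("envelope shorter than 3 s")
  denom <- bandpass_var(envelope, fs, range[1], range[2])
  if (denom <= 0) stop("zero variance in analysis range")
  bandpass_var(envelope, fs, band[1], band[2]) / denom
}

#' Band power fraction by PSD bin integration
#'
#' Alternative route to the same quantity: integrate a unit-normalized PSD
#' over the band's bins (half-open `[lo, hi)` so adjacent bands stay
#' disjoint). Used as a cross-method check on the filter-domain default.
#'
#' @param psd_norm a unit-normalized `mer_psd` from [normalize_psd()].
#' @param band length-2 numeric or band name.
#' @export
band_fraction_psd <- function(psd_norm, band) {
  if (is.character(band)) band <- GPI_BANDS[[match.arg(band, names(GPI_BANDS))]]
  sel <- psd_norm$freqs >= band[1] - 1e-9 & psd_norm$freqs < band[2] - 1e-9
  sum(psd_norm$power[sel]) * psd_norm$df
}

#' Band ratios from fractions
#'
#' Quotients of band power fractions: alpha/theta, beta/theta, beta/alpha.
#' A zero denominator yields `NA` for that ratio (row retained).
#'
#' @param fractions named numeric with `theta`, `alpha`, `beta` entries (or
#'   `*_frac` names as produced by [extract_features()]).
#' @return named numeric: `alpha_theta_ratio`, `beta_theta_ratio`,
#'   `beta_alpha_ratio`.
#' @export
band_ratios <- function(fractions) {
  g <- function(nm) {
    v <- fractions[[nm]] %||% fractions[[paste0(nm, "_frac")]]
    if (is.null(v)) stop("missing fraction: ", nm)
    v
  }
  th <- g("theta"); al <- g("alpha"); be <- g("beta")
  safe_div <- function(a, b) if (isTRUE(b > 0)) a / b else NA_real_
  c(alpha_theta_ratio = safe_div(al, th),
    beta_theta_ratio = safe_div(be, th),
    beta_alpha_ratio = safe_div(be, al))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Baseline elevation of a band
#'
#' Mean normalized-PSD bin power within the band divided by the median bin
#' power over the whole spectrum up to 100 Hz (2--100 Hz). The median
#' baseline is robust to narrow elevated bands, so a flat spectrum gives
#' elevation 1 and an elevated band a value > 1.
#'
#' @param psd_norm a unit-normalized `mer_psd`.
#' @param band length-2 numeric or band name.
#' @param baseline_range range over which the median baseline is taken.
#' @export
baseline_elevation <- function(psd_norm, band, baseline_range = c(2, 100)) {
  if (is.character(band)) band <- GPI_BANDS[[match.arg(band, names(GPI_BANDS))]]
  if (min(psd_norm$freqs) > baseline_range[1] + 1e-9 ||
      max(psd_norm$freqs) < baseline_range[2] - 1e-9)
    stop("PSD grid does not cover the baseline range")
  base_sel <- psd_norm$freqs >= baseline_range[1] - 1e-9 &
    psd_norm$freqs <= baseline_range[2] + 1e-9
  base <- stats::median(psd_norm$power[base_sel])
  if (base <= 0) stop("zero median baseline power")
  sel <- psd_norm$freqs >= band[1] - 1e-9 & psd_norm$freqs < band[2] - 1e-9
  mean(psd_norm$power[sel]) / base
}

#' Extract the spectral feature vector of one recording
#'
#' Full per-recording pipeline: stable-epoch detection, full-wave
#' rectification and demeaning, anti-aliased decimation of the envelope to
#' ~1 kHz, band power fractions (filter domain), band ratios, and per-band
#' baseline elevation from the unit-normalized Welch PSD. Deterministic for
#' fixed input.
#'
#' @param rec a [mer_recording()].
#' @param seg_dur,n_sd,min_duration_s stability parameters, see
#'   [detect_stable_epoch()].
#' @param target_fs envelope rate after decimation.
#' @param keep_psd also return the normalized PSD (`$psd`).
#' @return named list of class `spectral_features` with the fractions,
#'   ratios, elevations and `stable_duration_s`.
#' @export
extract_features <- function(rec, seg_dur = 0.050, n_sd = 3, min_duration_s = 3,
                             target_fs = 1000, keep_psd = FALSE) {
  sec <- tryCatch(
    detect_stable_epoch(rec, seg_dur = seg_dur, n_sd = n_sd,
                        min_duration_s = min_duration_s),
    recording_excluded = function(e) {
      stop(structure(class = c("recording_excluded", "error", "condition"),
                     list(message = sprintf("[%s/%s @ %.2f mm] %s",
                                            rec$patient_id, rec$trajectory_id,
                                            rec$depth_mm, conditionMessage(e)),
                          call = NULL)))
    })
  env <- rectify_demean(sec$samples)
  dec <- decimate_envelope(env, rec$fs, target_fs = target_fs)
  fr <- vapply(GPI_BANDS, function(b)
    band_power_fraction(dec$samples, dec$fs, b), numeric(1))
  psd <- normalize_psd(estimate_psd(dec$samples, dec$fs))
  elev <- vapply(GPI_BANDS, function(b) baseline_elevation(psd, b), numeric(1))
  out <- list(theta_frac = fr[["theta"]], alpha_frac = fr[["alpha"]],
              beta_frac = fr[["beta"]], gamma_frac = fr[["gamma"]])
  out <- c(out, as.list(band_ratios(fr)))
  out$theta_elev <- elev[["theta"]]; out$alpha_elev <- elev[["alpha"]]
  out$beta_elev <- elev[["beta"]]; out$gamma_elev <- elev[["gamma"]]
  out$stable_duration_s <- sec$duration_s
  out$envelope_fs <- dec$fs
  if (keep_psd) out$psd <- psd
  structure(out, class = "spectral_features")
}
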