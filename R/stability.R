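#' Segment RMS of a recording
#'
#' Divides the signal into consecutive non-overlapping segments of
#' `seg_dur` seconds (default 50 ms) and returns the root mean square of
#' each full segment; a trailing partial segment is discarded.
#'
#' @param samples numeric signal.
#' @param fs sampling rate in Hz.
#' @param seg_dur segment duration in seconds.
#' @return numeric vector, one RMS per full segment.
#' @export
segment_rms <- function(samples, fs, seg_dur = 0.050) {
  if (seg_dur <= 0) stop("seg_dur must be positive")
  seg_len <- as.integer(floor(seg_dur * fs))
  if (seg_len < 1L) stop("seg_dur * fs must be >= 1 sample")
  nseg <- length(samples) %/% seg_len
  if (nseg < 1L) stop("recording shorter than one segment")
  m <- matrix(samples[seq_len(nseg * seg_len)], nrow = seg_len)
  sqrt(colMeans(m^2))
}

#' Label stable segments
#'
#' A segment is stable when its RMS lies within three standard deviations
#' of the median RMS. The SD is the ordinary (sample, n-1) standard
#' deviation of the full RMS sequence, computed in a single pass with
#' outliers included; if the SD is zero every segment is stable.
#'
#' @param rms RMS sequence from [segment_rms()].
#' @param n_sd outlier threshold in SD units.
#' @param population_sd use the n-denominator SD instead of n-1.
#' @return logical mask, same length as `rms`.
#' @export
label_stable <- function(rms, n_sd = 3, population_sd = FALSE) {
  if (!length(rms)) stop("rms must be nonempty")
  s <- stats::sd(rms)
  if (length(rms) == 1L) s <- 0
  if (population_sd) s <- s * sqrt((length(rms) - 1) / length(rms))
  abs(rms - stats::median(rms)) <= n_sd * s
}

#' Longest stable section
#'
#' Returns the sample span covering the longest run of consecutive stable
#' segments; ties are broken toward the earliest run. Span boundaries
#' always coincide with segment boundaries.
#'
#' @param samples,fs the signal the mask was computed from.
#' @param mask logical stability mask from [label_stable()] on the same
#'   segmentation.
#' @param seg_dur segment duration in seconds (must match [segment_rms()]).
#' @return object of class `stable_section` with fields `start_index`
#'   (0-based inclusive), `end_index` (exclusive), `duration_s` and
#'   `samples` (the extracted span).
#' @export
longest_stable_section <- function(samples, fs, mask, seg_dur = 0.050) {
  seg_len <- as.integer(floor(seg_dur * fs))
  if (length(mask) * seg_len > length(samples))
    stop("mask does not match the segmentation of samples")
  if (!any(mask)) {
    stop(structure(class = c("recording_excluded", "error", "condition"),
                   list(message = "no stable segment (reason: no_stable_segment)",
                        call = sys.call(-1))))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  stable_runs <- which(r$values)
  best <- stable_runs[which.max(r$lengths[stable_runs])]  # which.max -> earliest tie
  seg_start <- starts[best] - 1L                          # 0-based segment index
  seg_end <- ends[best]
  start_index <- seg_start * seg_len
  end_index <- seg_end * seg_len
  structure(list(start_index = start_index, end_index = end_index,
                 duration_s = (end_index - start_index) / fs,
                 samples = samples[(start_index + 1L):end_index]),
            class = "stable_section")
}

#' Stable-epoch detection for one recording
#'
#' Convenience composition of [segment_rms()], [label_stable()] and
#' [longest_stable_section()], enforcing the minimum usable duration (one
#' PSD window, 3 s by default -- shorter spans cannot support the 1/3 Hz
#' spectral resolution and the recording is excluded).
#'
#' @param rec a [mer_recording()].
#' @param seg_dur segment duration in seconds.
#' @param n_sd stability threshold in SD units.
#' @param min_duration_s minimum stable duration in seconds.
#' @return a `stable_section`, or a condition of class `recording_excluded`
#'   is signalled with a reason code (`no_stable_segment` or `too_short`).
#' @export
detect_stable_epoch <- function(rec, seg_dur = 0.050, n_sd = 3, min_duration_s = 3) {
  rms <- segment_rms(rec$samples, rec$fs, seg_dur)
  mask <- label_stable(rms, n_sd)
  sec <- longest_stable_section(rec$samples, rec$fs, mask, seg_dur)
  if (sec$duration_s < min_duration_s) {
    stop(structure(class = c("recording_excluded", "error", "condition"),
                   list(message = sprintf(
                     "stable section %.2f s < %.2f s (reason: too_short)",
                     sec$duration_s, min_duration_s), call = sys.call(-1))))
  }
  sec
}
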