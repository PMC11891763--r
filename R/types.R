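#' MER recording container
#'
#' One depth-labeled single-channel microelectrode recording plus the
#' metadata needed downstream. Validation enforces the analysis-range
#' constraint `fs > 400` Hz: the spectral analysis range tops out at 200 Hz,
#' which must lie below Nyquist.
#'
#' @param patient_id,trajectory_id character identifiers.
#' @param group genetic etiology, one of [GPI_GROUPS].
#' @param depth_mm recording depth along the trajectory in mm (increasing
#'   toward target).
#' @param samples finite numeric vector.
#' @param fs sampling rate in Hz.
#' @return object of class `mer_recording`.
#' @export
mer_recording <- function(patient_id, group, trajectory_id, depth_mm, samples, fs) {
  group <- match.arg(toupper(group), GPI_GROUPS)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 400)
    stop("fs must exceed 400 Hz (2x the 200 Hz analysis-range upper edge)")
  if (length(samples) < 1L) stop("samples must be nonempty")
  if (!all(is.finite(samples)))
    stop("non-finite sample at index ", which(!is.finite(samples))[1])
  if (!is.finite(depth_mm)) stop("depth_mm must be finite")
  structure(list(patient_id = as.character(patient_id), group = group,
                 trajectory_id = as.character(trajectory_id),
                 depth_mm = as.numeric(depth_mm),
                 samples = as.numeric(samples), fs = as.numeric(fs)),
            class = "mer_recording")
}

#' @export
print.mer_recording <- function(x, ...) {
  cat(sprintf("<mer_recording> %s/%s depth %.2f mm: %d samples @ %g Hz (%.2f s)\n",
              x$patient_id, x$trajectory_id, x$depth_mm,
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Trajectory metadata
#'
#' GPi entry/exit anchors for one trajectory and the recordings made along
#' it. Entry and exit are expressed in the same depth frame as the
#' recordings; only their difference (the GPi span) and the affine map they
#' induce matter downstream.
#'
#' @param trajectory_id character identifier.
#' @param gpi_entry_mm,gpi_exit_mm GPi border depths in mm, `entry != exit`.
#' @param recordings list of [mer_recording()] objects sharing `trajectory_id`.
#' @export
trajectory_meta <- function(trajectory_id, gpi_entry_mm, gpi_exit_mm,
                            recordings = list()) {
  if (gpi_entry_mm == gpi_exit_mm)
    stop("degenerate trajectory: gpi_entry_mm == gpi_exit_mm")
  for (r in recordings) {
    if (!identical(r$trajectory_id, as.character(trajectory_id)))
      stop("recording trajectory_id mismatch: ", r$trajectory_id)
  }
  structure(list(trajectory_id = as.character(trajectory_id),
                 gpi_entry_mm = as.numeric(gpi_entry_mm),
                 gpi_exit_mm = as.numeric(gpi_exit_mm),
                 recordings = recordings),
            class = "trajectory_meta")
}

#' Patient clinical scores
#'
#' Motor BFMDRS (Burke-Fahn-Marsden Dystonia Rating Scale, motor part) at
#' baseline and 1-year follow-up. `percent_change` is always derived as
#' `100 * (pre - post) / pre`, so improvement is positive and worsening
#' negative; it is never stored independently.
#'
#' @param patient_id character identifier.
#' @param bfmdrs_pre,bfmdrs_post_1y nonnegative scores.
#' @export
patient_clinical <- function(patient_id, bfmdrs_pre, bfmdrs_post_1y) {
  if (bfmdrs_pre < 0 || bfmdrs_post_1y < 0) stop("BFMDRS scores must be >= 0")
  structure(list(patient_id = as.character(patient_id),
                 bfmdrs_pre = as.numeric(bfmdrs_pre),
                 bfmdrs_post_1y = as.numeric(bfmdrs_post_1y),
                 percent_change = 100 * (bfmdrs_pre - bfmdrs_post_1y) / bfmdrs_pre),
            class = "patient_clinical")
}

#' Names of the spectral feature family
#'
#' The default family entering the group-comparison battery: the four band
#' power fractions plus the three band ratios.
#' @export
feature_names <- function() {
  c("theta_frac", "alpha_frac", "beta_frac", "gamma_frac",
    "alpha_theta_ratio", "beta_theta_ratio", "beta_alpha_ratio")
}

# internal: validate a feature table data.frame
check_feature_table <- function(tab) {
  req <- c("patient_id", "group", "trajectory_id", "depth_mm", feature_names(),
           "normalized_depth", "stable_duration_s")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("feature table missing columns: ", paste(miss, collapse = ", "))
  fr <- as.matrix(tab[, c("theta_frac", "alpha_frac", "beta_frac", "gamma_frac")])
  if (any(fr < 0 | fr > 1, na.rm = TRUE)) stop("band fractions must lie in [0, 1]")
  if (any(rowSums(fr) > 1 + 1e-9, na.rm = TRUE))
    stop("band fractions must sum to <= 1 (disjoint sub-bands of 2-200 Hz)")
  invisible(tab)
}
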