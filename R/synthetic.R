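#' Synthetic MER cohort specification
#'
#' Describes a cohort for the seeded generator. The default scale mirrors
#' the dystonia GPi surgical cohort the pipeline targets: 30 patients in
#' seven etiology groups, 70 trajectories, 597 recordings. Per-group
#' envelope modulation depths encode the programmed electrophysiological
#' contrasts: every group carries theta/alpha-dominant envelope modulation
#' (the low-frequency signature of dystonia), the SGCE group carries half
#' the theta and alpha modulation of the others, and the VPS16 group
#' carries extra gamma modulation and a beta depth gradient.
#'
#' @param patients_per_group named integer vector over [GPI_GROUPS].
#' @param n_trajectories total trajectories, allocated round-robin over
#'   patients.
#' @param n_recordings total recordings, allocated round-robin over
#'   trajectories.
#' @param fs sampling rate in Hz (MER acquisition rate).
#' @param duration_s recording duration in seconds.
#' @param group_modulation groups x bands matrix of envelope modulation
#'   depths in `[0, 1]`.
#' @param depth_gradient groups x bands matrix of modulation-depth change
#'   per unit normalized depth.
#' @param artifact_rate expected transient artifacts per recording.
#' @param artifact_mult artifact amplitude as a multiple of background RMS.
#' @param span_range_mm range for the uniform GPi span draw.
#' @param clinical_coupling coupling of the baseline clinical score to the
#'   patient's low-frequency modulation (0 = none, as observed).
#' @param seed master seed; every child seed derives from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(patients_per_group = c(GNAL = 2L, KMT2B = 2L, SGCE = 2L,
                                               THAP1 = 4L, TOR1A = 8L,
                                               VPS16 = 3L, IDIOPATHIC = 9L),
                        n_trajectories = 70L, n_recordings = 597L,
                        fs = 24000, duration_s = 10,
                        group_modulation = default_group_modulation(),
                        depth_gradient = default_depth_gradient(),
                        artifact_rate = 0.5, artifact_mult = 10,
                        span_range_mm = c(3, 6),
                        clinical_coupling = 0, seed = 20250310L) {
  stopifnot(all(patients_per_group >= 1L), n_trajectories >= sum(patients_per_group),
            n_recordings >= n_trajectories, fs > 400, duration_s > 0,
            artifact_rate >= 0)
  if (any(group_modulation < 0 | group_modulation > 1))
    stop("modulation depths must lie in [0, 1]")
  if (artifact_rate > 0 && artifact_mult <= 3)
    stop("artifact_mult must exceed 3 to guarantee detectability")
  structure(list(patients_per_group = patients_per_group,
                 n_trajectories = as.integer(n_trajectories),
                 n_recordings = as.integer(n_recordings),
                 fs = fs, duration_s = duration_s,
                 group_modulation = group_modulation,
                 depth_gradient = depth_gradient,
                 artifact_rate = artifact_rate, artifact_mult = artifact_mult,
                 span_range_mm = span_range_mm,
                 clinical_coupling = clinical_coupling,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_group_modulation <- function() {
  m <- matrix(rep(c(theta = 0.30, alpha = 0.25, beta = 0.20, gamma = 0.15),
                  each = length(GPI_GROUPS)),
              nrow = length(GPI_GROUPS),
              dimnames = list(GPI_GROUPS, names(GPI_BANDS)))
  m["SGCE", c("theta", "alpha")] <- m["SGCE", c("theta", "alpha")] / 2
  m["VPS16", "gamma"] <- 0.30
  m
}

#' @rdname cohort_spec
#' @export
default_depth_gradient <- function() {
  g <- matrix(0, length(GPI_GROUPS), length(GPI_BANDS),
              dimnames = list(GPI_GROUPS, names(GPI_BANDS)))
  g["VPS16", "beta"] <- 0.10
  g
}

#' Small cohort spec for fast tests
#'
#' Four patients, eight trajectories, 48 recordings at 2 kHz / 4 s:
#' exercises every pipeline stage in seconds (6 recordings per trajectory,
#' of which 4 fall between the GPi borders, the inclusion minimum).
#' @param ... overrides passed to [cohort_spec()].
#' @export
tiny_cohort_spec <- function(...) {
  args <- utils::modifyList(
    list(patients_per_group = c(SGCE = 1L, THAP1 = 1L, VPS16 = 1L,
                                IDIOPATHIC = 1L),
         n_trajectories = 8L, n_recordings = 48L,
         fs = 2000, duration_s = 8),
    list(...))
  do.call(cohort_spec, args)
}

# deterministic child-seed chain, kept below 2^31
child_seed <- function(master, idx) {
  as.integer((as.double(master) * 48271 + idx * 7919) %% 2147483629)
}

#' Generate one synthetic MER signal
#'
#' Broadband Gaussian noise with a gentle high-frequency roll-off
#' (amplitude `1/sqrt(1 + f/300)`), amplitude-modulated as
#' `(1 + sum_b m_b sin(2 pi f_b t + phi_b))` with one modulation frequency
#' `f_b` drawn uniformly inside each band, then optional transient
#' high-amplitude artifact bursts. Fully reproducible from `seed`.
#'
#' @param fs sampling rate in Hz.
#' @param duration_s duration in seconds.
#' @param modulation named numeric over bands (theta, alpha, beta, gamma),
#'   each in `[0, 1]`.
#' @param artifact_rate expected artifact count (Poisson).
#' @param artifact_mult artifact amplitude multiple of background RMS.
#' @param seed RNG seed.
#' @return list with `samples` and `truth` (modulation depths and
#'   frequencies used, artifact intervals as 1-based sample spans).
#' @export
generate_recording_signal <- function(fs, duration_s, modulation,
                                      artifact_rate = 0, artifact_mult = 10,
                                      seed = 1L) {
  if (any(modulation < 0 | modulation > 1)) stop("modulation depths must lie in [0, 1]")
  n <- as.integer(round(fs * duration_s))
  with_seed(seed, {
    noise <- stats::rnorm(n)
    # gentle spectral tilt via FFT shaping
    f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
    h <- 1 / sqrt(1 + abs(f) / 300)
    noise <- Re(stats::fft(stats::fft(noise) * h, inverse = TRUE)) / n
    noise <- noise / stats::sd(noise)
    t <- seq(0, n - 1) / fs
    gain <- rep(1, n)
    fmod <- stats::setNames(rep(NA_real_, length(modulation)), names(modulation))
    for (b in names(modulation)) {
      m <- modulation[[b]]
      if (m > 0) {
        edges <- GPI_BANDS[[b]]
        fb <- stats::runif(1, edges[1], edges[2])
        fmod[b] <- fb
        gain <- gain + m * sin(2 * pi * fb * t + stats::runif(1, 0, 2 * pi))
      }
    }
    x <- noise * gain
    art <- inject_artifacts(x, fs, rate = artifact_rate, mult = artifact_mult,
                            seed = child_seed(seed, 1L))
    list(samples = art$samples,
         truth = list(modulation = modulation, mod_freqs = fmod,
                      artifact_intervals = art$intervals))
  })
}

#' Inject transient high-amplitude artifacts
#'
#' Adds a Poisson number of noise bursts (100--300 ms, amplitude
#' `mult` x background RMS) at uniform positions; rate 0 returns the input
#' unchanged. Intervals are recorded so stability detection can be tested
#' against ground truth.
#'
#' @param samples numeric signal.
#' @param fs sampling rate in Hz.
#' @param rate expected number of bursts.
#' @param mult amplitude multiple of the background RMS (must exceed 3 when
#'   `rate > 0`, otherwise detection is not guaranteed).
#' @param seed RNG seed.
#' @return list with `samples` and `intervals` (matrix with `start`, `end`
#'   1-based inclusive sample columns; 0 rows when no artifact).
#' @export
inject_artifacts <- function(samples, fs, rate, mult = 10, seed = 1L) {
  intervals <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  if (rate <= 0)
    return(list(samples = samples, intervals = intervals))
  if (mult <= 3) stop("artifact amplitude multiplier must exceed 3")
  n <- length(samples)
  with_seed(seed, {
    k <- stats::rpois(1, rate)
    if (k > 0) {
      bg_rms <- sqrt(mean(samples^2))
      for (i in seq_len(k)) {
        dur <- as.integer(round(stats::runif(1, 0.1, 0.3) * fs))
        dur <- min(dur, n)
        start <- as.integer(floor(stats::runif(1, 1, n - dur + 1)))
        idx <- start:(start + dur - 1L)
        samples[idx] <- samples[idx] + stats::rnorm(dur, sd = mult * bg_rms)
        intervals <- rbind(intervals, c(start, start + dur - 1L))
      }
    }
    list(samples = samples, intervals = intervals)
  })
}

#' Generate a full synthetic cohort
#'
#' Expands a [cohort_spec()] into recordings, trajectory metadata, clinical
#' scores and the programmed ground truth. Trajectories are allocated
#' round-robin over patients and recordings round-robin over trajectories;
#' recording depths span `[-0.5, span + 0.5]` mm around the GPi (entry at
#' 0), so a minority of recordings sit outside the borders, as in surgical
#' practice. Child seeds derive deterministically from the master seed.
#'
#' @param spec a `cohort_spec`.
#' @param signals if `FALSE`, recording stubs without samples are returned
#'   (cheap; useful for structural tests).
#' @return list with `recordings` (list of [mer_recording()]),
#'   `trajectories` (list of [trajectory_meta()] holding the recordings),
#'   `clinical` (data.frame), `truth` (per-recording data.frame plus the
#'   spec's programmed matrices).
#' @export
generate_cohort <- function(spec, signals = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$patients_per_group), spec$patients_per_group)
  n_pat <- length(groups)
  patient_ids <- sprintf("SIM%02d", seq_len(n_pat))
  traj_owner <- rep(seq_len(n_pat), length.out = spec$n_trajectories)
  traj_owner <- sort(traj_owner)
  traj_ids <- sprintf("%s_T%d", patient_ids[traj_owner],
                      stats::ave(traj_owner, traj_owner, FUN = seq_along))
  rec_traj <- sort(rep(seq_len(spec$n_trajectories),
                       length.out = spec$n_recordings))

  clinical <- with_seed(child_seed(spec$seed, 1L), {
    pre <- stats::runif(n_pat, 11.5, 60.5)
    improvement <- stats::rbeta(n_pat, 2, 2)
    if (spec$clinical_coupling != 0) {
      lf <- spec$group_modulation[groups, "theta"] +
        spec$group_modulation[groups, "alpha"]
      pre <- pre + spec$clinical_coupling * as.numeric(scale(lf)) * 10
      pre <- pmax(pre, 1)
    }
    data.frame(patient_id = patient_ids, group = groups,
               bfmdrs_pre = round(pre, 1),
               bfmdrs_post_1y = round(pre * (1 - improvement), 1))
  })
  clinical$percent_change <- 100 * (clinical$bfmdrs_pre - clinical$bfmdrs_post_1y) /
    clinical$bfmdrs_pre

  spans <- with_seed(child_seed(spec$seed, 2L),
                     stats::runif(spec$n_trajectories, spec$span_range_mm[1],
                                  spec$span_range_mm[2]))

  recordings <- vector("list", spec$n_recordings)
  truth_rows <- vector("list", spec$n_recordings)
  rec_k <- 0L
  trajectories <- vector("list", spec$n_trajectories)
  for (tj in seq_len(spec$n_trajectories)) {
    pat <- traj_owner[tj]
    g <- groups[pat]
    n_rec <- sum(rec_traj == tj)
    span <- spans[tj]
    depths <- round(seq(-0.5, span + 0.5, length.out = n_rec), 2)
    traj_recs <- vector("list", n_rec)
    for (ri in seq_len(n_rec)) {
      rec_k <- rec_k + 1L
      nd <- depths[ri] / span
      nd_clamped <- min(max(nd, 0), 1)
      mod <- pmin(pmax(spec$group_modulation[g, ] +
                         spec$depth_gradient[g, ] * nd_clamped, 0), 1)
      sd_seed <- child_seed(spec$seed, 100L + rec_k)
      if (signals) {
        sig <- generate_recording_signal(spec$fs, spec$duration_s, mod,
                                         artifact_rate = spec$artifact_rate,
                                         artifact_mult = spec$artifact_mult,
                                         seed = sd_seed)
        samples <- sig$samples
        n_art <- nrow(sig$truth$artifact_intervals)
      } else {
        samples <- 0
        n_art <- NA_integer_
      }
      rec <- mer_recording(patient_ids[pat], g, traj_ids[tj], depths[ri],
                           samples, spec$fs)
      recordings[[rec_k]] <- rec
      traj_recs[[ri]] <- rec
      truth_rows[[rec_k]] <- data.frame(
        patient_id = patient_ids[pat], group = g, trajectory_id = traj_ids[tj],
        depth_mm = depths[ri], normalized_depth = nd,
        m_theta = mod[["theta"]], m_alpha = mod[["alpha"]],
        m_beta = mod[["beta"]], m_gamma = mod[["gamma"]],
        n_artifacts = n_art, seed = sd_seed)
    }
    trajectories[[tj]] <- trajectory_meta(traj_ids[tj], gpi_entry_mm = 0,
                                          gpi_exit_mm = span,
                                          recordings = traj_recs)
  }
  list(recordings = recordings, trajectories = trajectories,
       clinical = clinical,
       truth = list(recordings = do.call(rbind, truth_rows),
                    group_modulation = spec$group_modulation,
                    depth_gradient = spec$depth_gradient,
                    clinical_coupling = spec$clinical_coupling,
                    seed = spec$seed))
}
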