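#' Read a cohort metadata table
#'
#' Expects a UTF-8 delimited table (TSV or CSV, sniffed from the header
#' line) with one row per recording and columns `patient_id`, `group`,
#' `trajectory_id`, `depth_mm`, `gpi_entry_mm`, `gpi_exit_mm`, optionally
#' `fs`, `signal_path` and the clinical columns `bfmdrs_pre`,
#' `bfmdrs_post_1y`.
#' Recording entries are returned as stubs (no samples) carrying a
#' `signal_path` attribute; load signals with [read_signal()].
#'
#' @param path file path.
#' @param fs sampling rate to record on the stubs (overridden by EDF
#'   headers when signals are loaded).
#' @return list with `trajectories` (list of [trajectory_meta()]) and
#'   `clinical` (data.frame, zero rows when clinical columns are absent).
#' @export
read_metadata <- function(path, fs = 24000) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character")
  required <- c("patient_id", "group", "trajectory_id", "depth_mm",
                "gpi_entry_mm", "gpi_exit_mm")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("metadata schema error: missing column(s) ", paste(miss, collapse = ", "))
  num_cols <- c("depth_mm", "gpi_entry_mm", "gpi_exit_mm")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(is.na(v) & !is.na(tab[[cc]]))
    if (length(bad))
      stop(sprintf("parse error: non-numeric %s at row %d ('%s')",
                   cc, bad[1], tab[[cc]][bad[1]]))
    tab[[cc]] <- v
  }
  key <- paste(tab$trajectory_id, tab$depth_mm, sep = "@")
  if (anyDuplicated(key))
    stop("duplicate (trajectory_id, depth_mm) key: ", key[duplicated(key)][1])

  if ("fs" %in% names(tab)) {
    v <- suppressWarnings(as.numeric(tab$fs))
    if (any(is.na(v))) stop("parse error: non-numeric fs at row ", which(is.na(v))[1])
    tab$fs <- v
  }
  trajectories <- lapply(split(tab, tab$trajectory_id), function(d) {
    recs <- lapply(seq_len(nrow(d)), function(i) {
      r <- mer_recording(d$patient_id[i], d$group[i], d$trajectory_id[i],
                         d$depth_mm[i], samples = 0,
                         fs = if ("fs" %in% names(d)) d$fs[i] else fs)
      attr(r, "signal_path") <- if ("signal_path" %in% names(d)) d$signal_path[i] else NA_character_
      r
    })
    trajectory_meta(d$trajectory_id[1], d$gpi_entry_mm[1], d$gpi_exit_mm[1], recs)
  })

  clinical <- data.frame(patient_id = character(0), bfmdrs_pre = numeric(0),
                         bfmdrs_post_1y = numeric(0), percent_change = numeric(0))
  if (all(c("bfmdrs_pre", "bfmdrs_post_1y") %in% names(tab))) {
    cl <- unique(tab[, c("patient_id", "bfmdrs_pre", "bfmdrs_post_1y")])
    cl$bfmdrs_pre <- as.numeric(cl$bfmdrs_pre)
    cl$bfmdrs_post_1y <- as.numeric(cl$bfmdrs_post_1y)
    pc <- lapply(seq_len(nrow(cl)), function(i)
      patient_clinical(cl$patient_id[i], cl$bfmdrs_pre[i], cl$bfmdrs_post_1y[i]))
    clinical <- clinical_table(pc)
  }
  list(trajectories = unname(trajectories), clinical = clinical)
}

#' Flatten clinical records to a data.frame
#'
#' @param x list of [patient_clinical()] objects.
#' @export
clinical_table <- function(x) {
  do.call(rbind, lapply(x, function(p)
    data.frame(patient_id = p$patient_id, bfmdrs_pre = p$bfmdrs_pre,
               bfmdrs_post_1y = p$bfmdrs_post_1y,
               percent_change = p$percent_change)))
}

#' Write a metadata table for a (synthetic) cohort
#'
#' Inverse of [read_metadata()] for in-memory cohorts; one row per
#' recording, TSV.
#'
#' @param cohort list with `trajectories` and optional `clinical` as
#'   produced by [generate_cohort()].
#' @param path output path.
#' @param signal_paths optional named character vector
#'   (`trajectory_id@depth`) of signal file paths.
#' @export
write_metadata <- function(cohort, path, signal_paths = NULL) {
  rows <- list()
  for (tm in cohort$trajectories) {
    for (r in tm$recordings) {
      key <- paste0(r$trajectory_id, "@", r$depth_mm)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = r$patient_id, group = r$group,
        trajectory_id = r$trajectory_id, depth_mm = r$depth_mm,
        gpi_entry_mm = tm$gpi_entry_mm, gpi_exit_mm = tm$gpi_exit_mm, fs = r$fs,
        signal_path = if (!is.null(signal_paths)) signal_paths[[key]] else NA_character_)
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(cohort$clinical) && nrow(cohort$clinical)) {
    tab <- merge(tab, cohort$clinical[, c("patient_id", "bfmdrs_pre", "bfmdrs_post_1y")],
                 by = "patient_id", sort = FALSE)
  }
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single-channel signal
#'
#' Accepts EDF (European Data Format, standard for clinical
#' electrophysiology; the header sampling rate takes precedence over the
#' `fs` argument) or single-column delimited text (one sample per line,
#' `fs` must be supplied).
#'
#' @param path file path; `.edf` extension selects the EDF reader.
#' @param fs sampling rate in Hz for delimited input.
#' @return list with `samples` and `fs`.
#' @export
read_signal <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(read_edf(path))
  if (is.null(fs)) stop("fs must be supplied for delimited signal input")
  txt <- readLines(path)
  txt <- txt[nzchar(trimws(txt))]
  x <- suppressWarnings(as.numeric(txt))
  bad <- which(!is.finite(x))
  if (length(bad))
    stop(sprintf("non-finite sample at index %d ('%s')", bad[1], txt[bad[1]]))
  list(samples = x, fs = fs)
}

#' Write a signal as single-column text
#'
#' @param samples numeric vector.
#' @param path output path.
#' @export
write_signal_txt <- function(samples, path) {
  writeLines(format(samples, digits = 17, scientific = TRUE, trim = TRUE), path)
  invisible(path)
}

#' Minimal EDF reader (first channel)
#'
#' Parses the fixed-layout EDF header and returns the first signal,
#' rescaled to physical units. Only continuous single-session EDF is
#' supported, which covers exported MER segments.
#'
#' @param path `.edf` file.
#' @return list with `samples` and `fs` (from the header).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(nc) trimws(rawToChar(readBin(con, "raw", nc)))
  hdr(8); hdr(80); hdr(80); hdr(8); hdr(8); hdr(8); hdr(44)
  n_rec <- as.integer(hdr(8))
  rec_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header")
  fld <- function(nc) vapply(seq_len(ns), function(i) hdr(nc), character(1))
  fld(16); fld(80); fld(8)                      # label, transducer, unit
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)                                       # prefiltering
  nspr <- as.integer(fld(8))
  fld(32)                                       # reserved
  samples <- numeric(0)
  out <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", n = nspr[s], size = 2, endian = "little")
      if (s == 1L) out[[r]] <- v
    }
  }
  dig <- unlist(out)
  scale <- (phys_max[1] - phys_min[1]) / (dig_max[1] - dig_min[1])
  list(samples = phys_min[1] + (dig - dig_min[1]) * scale,
       fs = nspr[1] / rec_dur)
}

#' Minimal EDF writer (single channel, one data record)
#'
#' Companion to [read_edf()] for round trips and fixture generation.
#' Samples are quantized to the 16-bit EDF range.
#'
#' @param samples numeric vector.
#' @param fs sampling rate in Hz.
#' @param path output `.edf` path.
#' @export
write_edf <- function(samples, fs, path) {
  n <- length(samples)
  pmin_ <- min(samples); pmax_ <- max(samples)
  if (pmax_ == pmin_) pmax_ <- pmin_ + 1
  dmin <- -32768L; dmax <- 32767L
  dig <- as.integer(round(dmin + (samples - pmin_) / (pmax_ - pmin_) * (dmax - dmin)))
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, nc) {
    s <- substr(format(x), 1, nc)
    writeChar(formatC(s, width = -nc), con, eos = NULL)
  }
  pad("0", 8); pad("synthetic", 80); pad("synthetic", 80)
  pad("01.01.26", 8); pad("00.00.00", 8); pad(as.character(256 + 256), 8)
  pad("", 44); pad("1", 8)                      # one data record
  pad(format(n / fs, digits = 10), 8); pad("1", 4)
  pad("MER", 16); pad("microelectrode", 80); pad("uV", 8)
  pad(format(pmin_, digits = 7), 8); pad(format(pmax_, digits = 7), 8)
  pad(as.character(dmin), 8); pad(as.character(dmax), 8)
  pad("none", 80); pad(as.character(n), 8); pad("", 32)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

# fixed, documented column order for feature tables on disk
feature_table_columns <- function() {
  c("patient_id", "group", "trajectory_id", "depth_mm", "normalized_depth",
    "in_gpi", feature_names(), "theta_elev", "alpha_elev", "beta_elev",
    "gamma_elev", "stable_duration_s")
}

#' Write a feature table
#'
#' Tidy TSV, one row per recording, fixed column order (ids, depths, the
#' seven-feature family, per-band baseline elevations, stable duration).
#' Values round-trip through [read_feature_table()] to better than 1e-12.
#'
#' @param tab feature table data.frame from [run_extract()].
#' @param path output path.
#' @export
write_feature_table <- function(tab, path) {
  if (!nrow(tab)) stop("empty feature table")
  check_feature_table(tab)
  if (any(tab$normalized_depth[tab$in_gpi] < -1e-12 |
          tab$normalized_depth[tab$in_gpi] > 1 + 1e-12))
    stop("in-GPi normalized_depth outside [0, 1]")
  cols <- intersect(feature_table_columns(), names(tab))
  out <- tab[, cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV path.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  check_feature_table(tab)
  tab
}

#' Write a normalized PSD as TSV
#'
#' @param psd a `mer_psd`.
#' @param path output path.
#' @export
write_psd <- function(psd, path) {
  utils::write.table(
    data.frame(freq_hz = format(psd$freqs, digits = 17, trim = TRUE),
               power = format(psd$power, digits = 17, trim = TRUE)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
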