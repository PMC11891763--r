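#' Pipeline run configuration
#'
#' All tunables in one validated list; the defaults are the analysis
#' constants the pipeline is built around (50 ms segments, 3 SD stability
#' threshold, 3 s PSD windows giving 1/3 Hz resolution, 2--200 Hz analysis
#' range, 2 mm / 4 depth trajectory inclusion, 10,000 permutations).
#'
#' @param seg_dur_s RMS segment duration (s).
#' @param stability_sd stability threshold in SD units.
#' @param psd_window_s Welch window (s); also the minimum usable stable
#'   duration.
#' @param analysis_range_hz length-2 numeric, PSD normalization range.
#' @param band_edges named list of band edges (defaults [GPI_BANDS]).
#' @param min_span_mm,min_depths trajectory inclusion thresholds.
#' @param envelope_fs target envelope rate after decimation (Hz).
#' @param n_perm permutation count for Spearman tests.
#' @param seed master seed for all stochastic steps.
#' @param pooling unit of analysis for group comparisons: `"epoch"` pools
#'   individual stable recordings per group, `"patient_median"` uses
#'   per-patient medians.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(seg_dur_s = 0.050, stability_sd = 3, psd_window_s = 3,
                       analysis_range_hz = c(2, 200), band_edges = GPI_BANDS,
                       min_span_mm = 2, min_depths = 4L, envelope_fs = 1000,
                       n_perm = 10000L, seed = 1L,
                       pooling = c("epoch", "patient_median")) {
  pooling <- match.arg(pooling)
  cfg <- list(seg_dur_s = seg_dur_s, stability_sd = stability_sd,
              psd_window_s = psd_window_s, analysis_range_hz = analysis_range_hz,
              band_edges = band_edges, min_span_mm = min_span_mm,
              min_depths = as.integer(min_depths), envelope_fs = envelope_fs,
              n_perm = as.integer(n_perm), seed = as.integer(seed),
              pooling = pooling)
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param cfg a candidate configuration list.
#' @export
validate_run_config <- function(cfg) {
  must_pos <- c("seg_dur_s", "stability_sd", "psd_window_s", "min_span_mm",
                "min_depths", "envelope_fs", "n_perm")
  for (f in must_pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("config error: ", f, " must be a positive scalar")
  ar <- cfg$analysis_range_hz
  if (length(ar) != 2L || ar[1] <= 0 || ar[2] <= ar[1])
    stop("config error: analysis_range_hz must be an increasing positive pair")
  for (b in names(cfg$band_edges)) {
    e <- cfg$band_edges[[b]]
    if (e[1] < ar[1] - 1e-9 || e[2] > ar[2] + 1e-9 || e[1] >= e[2])
      stop("config error: band ", b, " outside the analysis range")
  }
  if (!cfg$pooling %in% c("epoch", "patient_median"))
    stop("config error: unknown pooling mode")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- unclass(run_config())
  for (f in names(defaults)) if (is.null(cfg[[f]])) cfg[[f]] <- defaults[[f]]
  if (is.list(cfg$analysis_range_hz))
    cfg$analysis_range_hz <- unlist(cfg$analysis_range_hz)
  cfg$band_edges <- lapply(cfg$band_edges, unlist)
  cfg$min_depths <- as.integer(cfg$min_depths)
  cfg$n_perm <- as.integer(cfg$n_perm)
  cfg$seed <- as.integer(cfg$seed)
  validate_run_config(cfg[names(defaults)])
}

#' @rdname run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Feature extraction over a cohort
#'
#' Applies trajectory inclusion, stable-epoch detection and spectral
#' feature extraction to every recording, producing one feature-table row
#' per surviving recording and a reason-coded exclusion log for the rest.
#' Deterministic: rerunning with the same inputs gives identical output.
#'
#' @param cohort list with `trajectories` (list of [trajectory_meta()]
#'   whose recordings carry samples, or stubs with `signal_path`
#'   attributes) and optionally `clinical`.
#' @param config a [run_config()].
#' @param load_signals read stub signals from their `signal_path`.
#' @return list of class `extract_result`: `features` (data.frame),
#'   `exclusions` (data.frame with reason codes), `inclusion` (trajectory
#'   report from [filter_trajectories()]).
#' @export
run_extract <- function(cohort, config = run_config(), load_signals = FALSE) {
  config <- validate_run_config(config)
  maps <- lapply(cohort$trajectories, normalize_depths)
  names(maps) <- vapply(maps, `[[`, "", "trajectory_id")
  inclusion <- filter_trajectories(maps, config$min_span_mm, config$min_depths)
  feats <- list(); excl <- list()
  for (tm in cohort$trajectories) {
    inc <- inclusion[inclusion$trajectory_id == tm$trajectory_id, ]
    map <- maps[[tm$trajectory_id]]
    for (i in seq_along(tm$recordings)) {
      rec <- tm$recordings[[i]]
      rid <- sprintf("%s@%.2f", rec$trajectory_id, rec$depth_mm)
      if (!inc$included) {
        excl[[length(excl) + 1L]] <- data.frame(
          recording = rid, reason = paste0("trajectory_excluded:", inc$reason))
        next
      }
      if (load_signals) {
        sp <- attr(rec, "signal_path")
        if (is.na(sp)) stop("recording ", rid, " has no signal_path")
        sig <- read_signal(sp, fs = rec$fs)
        rec <- mer_recording(rec$patient_id, rec$group, rec$trajectory_id,
                             rec$depth_mm, sig$samples, sig$fs)
      }
      fv <- tryCatch(
        extract_features(rec, seg_dur = config$seg_dur_s,
                         n_sd = config$stability_sd,
                         min_duration_s = config$psd_window_s,
                         target_fs = config$envelope_fs),
        recording_excluded = function(e) e)
      if (inherits(fv, "condition")) {
        reason <- if (grepl("no_stable_segment", conditionMessage(fv)))
          "no_stable_segment" else "too_short"
        excl[[length(excl) + 1L]] <- data.frame(recording = rid, reason = reason)
        next
      }
      feats[[length(feats) + 1L]] <- data.frame(
        patient_id = rec$patient_id, group = rec$group,
        trajectory_id = rec$trajectory_id, depth_mm = rec$depth_mm,
        normalized_depth = map$depths$normalized_depth[i],
        in_gpi = map$depths$in_gpi[i],
        theta_frac = fv$theta_frac, alpha_frac = fv$alpha_frac,
        beta_frac = fv$beta_frac, gamma_frac = fv$gamma_frac,
        alpha_theta_ratio = fv$alpha_theta_ratio,
        beta_theta_ratio = fv$beta_theta_ratio,
        beta_alpha_ratio = fv$beta_alpha_ratio,
        theta_elev = fv$theta_elev, alpha_elev = fv$alpha_elev,
        beta_elev = fv$beta_elev, gamma_elev = fv$gamma_elev,
        stable_duration_s = fv$stable_duration_s)
    }
  }
  if (!length(feats)) stop("no recordings survived extraction; ",
                           nrow(inclusion) - sum(inclusion$included),
                           " trajectories excluded, ", length(excl),
                           " recordings excluded")
  structure(list(features = do.call(rbind, feats),
                 exclusions = if (length(excl)) do.call(rbind, excl) else
                   data.frame(recording = character(0), reason = character(0)),
                 inclusion = inclusion),
            class = "extract_result")
}

# internal: per-group value lists for one feature under a pooling mode
pool_feature <- function(tab, feature, pooling) {
  if (pooling == "patient_median") {
    agg <- stats::aggregate(tab[[feature]],
                            by = list(group = tab$group, patient_id = tab$patient_id),
                            FUN = stats::median, na.rm = TRUE)
    split(agg$x, agg$group)
  } else {
    split(tab[[feature]], tab$group)
  }
}

#' Run the full statistics battery
#'
#' Omnibus Kruskal-Wallis (Holm-adjusted across the feature family) and
#' Dunn post hoc tests per feature, feature-clinical permutation Spearman
#' correlations with BH-FDR, per-group depth correlations, and mixed-model
#' depth effects. With a single group present the group tests are skipped
#' with a warning and descriptives are still emitted.
#'
#' @param features feature table from [run_extract()].
#' @param clinical clinical data.frame (may be `NULL` / empty).
#' @param config a [run_config()].
#' @return list of class `stats_report` with elements `descriptives`,
#'   `omnibus`, `pairwise`, `clinical`, `depth`, `lmm`, `seeds`.
#' @export
run_stats <- function(features, clinical = NULL, config = run_config()) {
  config <- validate_run_config(config)
  if (!nrow(features)) stop("empty feature table")
  fam <- intersect(feature_names(), names(features))
  desc <- do.call(rbind, lapply(fam, function(f) {
    agg <- stats::aggregate(features[[f]], by = list(group = features$group),
                            FUN = stats::median, na.rm = TRUE)
    data.frame(feature = f, group = agg$group, median = agg$x)
  }))
  omnibus <- NULL; pairwise <- NULL
  if (length(unique(features$group)) < 2L) {
    warning("single group present: omnibus and post hoc tests skipped")
  } else {
    om <- lapply(fam, function(f) {
      g <- pool_feature(features, f, config$pooling)
      g <- lapply(g, function(v) v[is.finite(v)])
      g <- g[vapply(g, length, 1L) > 0L]
      kw <- kruskal_wallis(g)
      data.frame(feature = f, H = kw$H, df = kw$df, p = kw$p)
    })
    omnibus <- do.call(rbind, om)
    omnibus$p_holm <- holm_bonferroni(omnibus$p)
    pairwise <- do.call(rbind, lapply(fam, function(f) {
      g <- pool_feature(features, f, config$pooling)
      g <- lapply(g, function(v) v[is.finite(v)])
      g <- g[vapply(g, length, 1L) > 0L]
      d <- dunn_posthoc(g)
      cbind(feature = f, d)
    }))
  }
  clin <- NULL
  if (!is.null(clinical) && nrow(clinical) >= 3L) {
    clin <- clinical_correlations(features, clinical, features = fam,
                                  n_perm = config$n_perm, seed = config$seed)
  }
  depth <- depth_correlations(features, features = fam,
                              n_perm = config$n_perm, seed = config$seed + 1000L)
  lmm <- tryCatch(lmm_depth_effects(features, fam), error = function(e) NULL)
  structure(list(descriptives = desc, omnibus = omnibus, pairwise = pairwise,
                 clinical = clin, depth = depth, lmm = lmm,
                 seeds = c(clinical = config$seed, depth = config$seed + 1000L),
                 pooling = config$pooling, n_perm = config$n_perm),
            class = "stats_report")
}

#' Serialize a stats report
#'
#' Writes `report.json` plus one flat TSV per section into `dir`.
#'
#' @param report a `stats_report`.
#' @param dir output directory (created if needed).
#' @export
write_stats_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  for (part in c("descriptives", "omnibus", "pairwise", "clinical", "depth", "lmm")) {
    if (!is.null(report[[part]]))
      utils::write.table(report[[part]], file.path(dir, paste0(part, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Published reference values for the target cohort
#'
#' Group-level medians (percent of analysis-range power) and cohort counts
#' reported for the dystonia GPi cohort this pipeline was designed around;
#' used by [run_reproduce()] for side-by-side comparison against the
#' openly deposited spectral feature tables (Zenodo record
#' 10.5281/zenodo.14800798).
#'
#' @return list with `counts` and `medians_percent`.
#' @export
gpi_reference_values <- function() {
  list(counts = c(recordings = 597, trajectories = 70, patients = 30),
       medians_percent = data.frame(
         group = c("SGCE", "IDIOPATHIC", "THAP1",
                   "SGCE", "IDIOPATHIC", "THAP1", "VPS16"),
         feature = c(rep("alpha_frac", 3), rep("theta_frac", 3), "gamma_frac"),
         reference = c(2.97, 4.44, 4.51, 4.42, 7.91, 7.00, 37.04)))
}

#' Reproduce group descriptives from a deposited feature table
#'
#' Reads a tabular spectral-feature deposit (never auto-downloaded; pass a
#' local path), maps its columns onto the package schema, recomputes
#' group-level band-fraction medians under both pooling modes, reruns the
#' Kruskal-Wallis/Dunn family and depth correlations, and emits a
#' side-by-side comparison with the published reference values.
#'
#' @param path local delimited table.
#' @param column_map named character vector mapping package column names to
#'   the deposit's column names (identity entries may be omitted).
#' @param config a [run_config()].
#' @param fractions_in_percent deposit stores fractions as percentages.
#' @return list of class `reproduction_report` with `counts`, `medians`
#'   (both pooling modes), `comparison` (computed vs reference with
#'   deltas), `omnibus`, `pairwise`, `depth`.
#' @export
run_reproduce <- function(path, column_map = NULL, config = run_config(),
                          fractions_in_percent = FALSE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map))
    for (ours in names(column_map)) {
      theirs <- column_map[[ours]]
      if (!theirs %in% names(tab))
        stop("column-mapping error: expected deposit column '", theirs,
             "' (for '", ours, "'); found: ", paste(names(tab), collapse = ", "))
      names(tab)[names(tab) == theirs] <- ours
    }
  need <- c("patient_id", "group", "trajectory_id",
            "theta_frac", "alpha_frac", "beta_frac", "gamma_frac")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("column-mapping error: missing ", paste(miss, collapse = ", "),
         "; found: ", paste(names(tab), collapse = ", "))
  fr_cols <- c("theta_frac", "alpha_frac", "beta_frac", "gamma_frac")
  if (fractions_in_percent) tab[fr_cols] <- tab[fr_cols] / 100
  fam <- intersect(feature_names(), names(tab))

  med_mode <- function(pooling) {
    do.call(rbind, lapply(fam, function(f) {
      g <- pool_feature(tab, f, pooling)
      data.frame(feature = f, group = names(g),
                 median = vapply(g, stats::median, numeric(1), na.rm = TRUE),
                 pooling = pooling, row.names = NULL)
    }))
  }
  medians <- rbind(med_mode("epoch"), med_mode("patient_median"))

  ref <- gpi_reference_values()
  cmp <- merge(ref$medians_percent,
               transform(medians[medians$pooling == "epoch", ],
                         computed_percent = 100 * median)[, c("feature", "group", "computed_percent")],
               by = c("feature", "group"), all.x = TRUE)
  cmp$delta <- cmp$computed_percent - cmp$reference

  counts <- c(recordings = nrow(tab),
              trajectories = length(unique(tab$trajectory_id)),
              patients = length(unique(tab$patient_id)))
  count_cmp <- data.frame(quantity = names(counts), computed = as.numeric(counts),
                          reference = as.numeric(ref$counts[names(counts)]))

  rep_stats <- run_stats(tab, clinical = NULL, config = config)
  structure(list(counts = count_cmp, medians = medians, comparison = cmp,
                 omnibus = rep_stats$omnibus, pairwise = rep_stats$pairwise,
                 depth = if (!is.null(tab$normalized_depth)) rep_stats$depth else NULL),
            class = "reproduction_report")
}
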