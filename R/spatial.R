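#' Normalize recording depths to the GPi span
#'
#' Affine map sending the GPi entry to 0 and the exit to 1, applied to each
#' recording depth of a trajectory. Recordings outside `[entry, exit]` keep
#' their (out-of-range) normalized value but are flagged `in_gpi = FALSE`;
#' they still enter group-level feature statistics but are excluded from
#' depth-correlation and mixed-model analyses, which concern the region
#' between the GPi borders.
#'
#' @param meta a [trajectory_meta()].
#' @return object of class `trajectory_map`: list with `trajectory_id`,
#'   `gpi_span_mm` and a data.frame `depths` (`depth_mm`,
#'   `normalized_depth`, `in_gpi`).
#' @export
normalize_depths <- function(meta) {
  entry <- meta$gpi_entry_mm; exit <- meta$gpi_exit_mm
  if (entry == exit) stop("degenerate trajectory: entry == exit")
  d <- vapply(meta$recordings, function(r) r$depth_mm, numeric(1))
  nd <- (d - entry) / (exit - entry)
  structure(list(trajectory_id = meta$trajectory_id,
                 gpi_span_mm = abs(exit - entry),
                 depths = data.frame(depth_mm = d, normalized_depth = nd,
                                     in_gpi = nd >= -1e-12 & nd <= 1 + 1e-12)),
            class = "trajectory_map")
}

#' Trajectory inclusion filter
#'
#' Keeps trajectories with a GPi span of at least `min_span_mm` (default
#' 2 mm) and at least `min_depths` (default 4) distinct in-GPi recording
#' depths; both bounds are inclusive. Distinctness is judged after rounding
#' depths to 0.01 mm so numerically identical positions count once.
#'
#' @param maps list of `trajectory_map` objects from [normalize_depths()].
#' @param min_span_mm,min_depths inclusion thresholds.
#' @return data.frame with one row per trajectory: `trajectory_id`,
#'   `gpi_span_mm`, `n_depths`, `included`, `reason` (empty when included).
#' @export
filter_trajectories <- function(maps, min_span_mm = 2, min_depths = 4L) {
  rows <- lapply(maps, function(m) {
    nd <- length(unique(round(m$depths$depth_mm[m$depths$in_gpi], 2)))
    reason <- character(0)
    if (m$gpi_span_mm < min_span_mm) reason <- c(reason, "span_lt_min")
    if (nd < min_depths) reason <- c(reason, "too_few_depths")
    data.frame(trajectory_id = m$trajectory_id, gpi_span_mm = m$gpi_span_mm,
               n_depths = nd, included = length(reason) == 0L,
               reason = paste(reason, collapse = ";"))
  })
  do.call(rbind, rows)
}
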