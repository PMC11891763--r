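write_meta_fixture <- function(path, dup = FALSE) {
  rows <- expand.grid(depth_mm = c(0, 1, 2, 3, 4), trajectory_id = c("T1", "T2"),
                      stringsAsFactors = FALSE)
  rows$patient_id <- ifelse(rows$trajectory_id == "T1", "P5", "P6")
  rows$group <- "SGCE"
  rows$gpi_entry_mm <- 0; rows$gpi_exit_mm <- 4
  rows$bfmdrs_pre <- ifelse(rows$patient_id == "P5", 11.5, 16)
  rows$bfmdrs_post_1y <- ifelse(rows$patient_id == "P5", 10.5, 2.5)
  if (dup) rows <- rbind(rows, rows[1, ])
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

test_that("metadata reading builds trajectories and clinical records", {
  p <- write_meta_fixture(withr::local_tempfile(fileext = ".tsv"))
  md <- read_metadata(p)
  expect_length(md$trajectories, 2L)
  expect_true(all(vapply(md$trajectories, function(t) length(t$recordings), 1L) == 5L))
  # Table-1-shaped clinical row: pre 11.5, post 10.5 -> ~8.7% improvement
  p5 <- md$clinical[md$clinical$patient_id == "P5", ]
  expect_equal(p5$percent_change, 100 * (11.5 - 10.5) / 11.5, tolerance = 1e-12)
  expect_equal(round(p5$percent_change, 1), 8.7)
})

test_that("metadata schema and key errors are specific", {
  p <- write_meta_fixture(withr::local_tempfile(fileext = ".tsv"), dup = TRUE)
  expect_error(read_metadata(p), "duplicate.*T1")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tgroup\ttrajectory_id", "P1\tSGCE\tT1"), bad)
  expect_error(read_metadata(bad), "missing column.*depth_mm")
  bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("patient_id", "group", "trajectory_id", "depth_mm",
                     "gpi_entry_mm", "gpi_exit_mm", sep = "\t"),
               paste("P1", "SGCE", "T1", "deep", "0", "4", sep = "\t")), bad2)
  expect_error(read_metadata(bad2), "non-numeric depth_mm at row 1")
})

test_that("delimited signal round trip is exact and validates samples", {
  x <- rnorm(1000)
  p <- withr::local_tempfile(fileext = ".txt")
  write_signal_txt(x, p)
  back <- read_signal(p, fs = 24000)
  expect_equal(back$samples, x, tolerance = 1e-15)
  expect_equal(back$fs, 24000)
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.1", "nan", "0.3"), bad)
  expect_error(read_signal(bad, fs = 1000), "index 2")
  expect_error(read_signal(p), "fs must be supplied")
})

test_that("EDF header sampling rate overrides the fs argument", {
  # 1 s at 24 kHz so the EDF record duration is exactly representable
  x <- as.numeric(sample(-500:500, 24000, replace = TRUE))  # integer-safe
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(x, fs = 24000, path = p)
  back <- read_signal(p, fs = 1000)   # argument must be ignored
  expect_equal(back$fs, 24000, tolerance = 1e-6)
  expect_equal(length(back$samples), length(x))
  expect_equal(back$samples, x, tolerance = 0.05)  # 16-bit quantization
})

test_that("feature table round trip preserves values to 1e-12", {
  feats <- tiny_features()$features
  p <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(feats, p)
  back <- read_feature_table(p)
  expect_equal(nrow(back), nrow(feats))
  for (nm in feature_names())
    expect_equal(back[[nm]], feats[[nm]], tolerance = 1e-12)
  expect_true(all(back$normalized_depth[back$in_gpi] >= -1e-12 &
                    back$normalized_depth[back$in_gpi] <= 1 + 1e-12))
  expect_error(write_feature_table(feats[0, ], p), "empty")
})

test_that("metadata writer round-trips a synthetic cohort", {
  co <- generate_cohort(tiny_cohort_spec(seed = 14), signals = FALSE)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(co, p)
  md <- read_metadata(p, fs = 2000)
  expect_length(md$trajectories, length(co$trajectories))
  n_in <- sum(vapply(md$trajectories, function(t) length(t$recordings), 1L))
  expect_equal(n_in, length(co$recordings))
  expect_equal(sort(md$clinical$patient_id), sort(co$clinical$patient_id))
})
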