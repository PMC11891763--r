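# Shared fixtures, built in code. The tiny cohort and a long white-noise
# envelope are cached per test run because several files reuse them.

local_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(local_cache[[key]])) local_cache[[key]] <- force(expr)
  local_cache[[key]]
}

tiny_cohort <- function(seed = 11L) {
  cached(paste0("cohort", seed), generate_cohort(tiny_cohort_spec(seed = seed)))
}

tiny_features <- function(seed = 11L) {
  cached(paste0("feat", seed), {
    run_extract(tiny_cohort(seed), run_config(n_perm = 200L))
  })
}

# 60 s of unit white noise at 1 kHz: the flat-envelope reference signal
white_60s <- function() {
  cached("white60", {
    set.seed(4242)
    rnorm(60000)
  })
}

# brute-force oracle: longest contiguous stable run by exhaustive scan,
# independent of the rle-based implementation
brute_longest_run <- function(mask) {
  best_len <- 0L; best_start <- NA_integer_
  i <- 1L; n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1L]) j <- j + 1L
      if (j - i + 1L > best_len) { best_len <- j - i + 1L; best_start <- i }
      i <- j + 1L
    } else i <- i + 1L
  }
  list(start = best_start, len = best_len)
}

# feature-level LMM simulator (no signals): random patient intercepts plus
# a fixed depth slope
simulate_lmm_table <- function(seed, slope, n_pat = 30L, n_rec = 10L,
                               sd_pat = 0.1, sd_noise = 0.1) {
  set.seed(seed)
  grp <- rep(GPI_GROUPS, length.out = n_pat)
  do.call(rbind, lapply(seq_len(n_pat), function(i) {
    nd <- runif(n_rec)
    data.frame(patient_id = sprintf("P%02d", i), group = grp[i],
               normalized_depth = nd, in_gpi = TRUE,
               y = rnorm(1, 0, sd_pat) + slope * nd + rnorm(n_rec, 0, sd_noise))
  }))
}
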