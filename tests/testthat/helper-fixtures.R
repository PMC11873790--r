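# Shared fixtures and independent full-scan oracles. The oracles deliberately
# use only base R over the in-memory table, never the query module, so they
# stay independent of the code paths they check.

tiny_config <- function(seed = 1L, intensity_noise = "none",
                        noise_points_per_scan = 3L, ims = TRUE) {
  simulation_config(
    n_cycles = 12L, cycle_period = 0.005, level2_rt_offset = 0.002,
    n_bins = 10L, drift_slope = 0.071,
    compounds = list(
      compound_spec(300.1, rt_apex = 0.030, rt_sigma = 0.008,
                    dt_apex_bin = 5, dt_sigma_bins = 1.5, apex_intensity = 800,
                    isotope_offsets = data.frame(delta_mz = 1.0034, abundance = 0.25),
                    fragments = data.frame(mz = c(120.05, 180.08), abundance = c(0.5, 0.3))),
      compound_spec(410.2, rt_apex = 0.045, rt_sigma = 0.006,
                    dt_apex_bin = 7.4, dt_sigma_bins = 1.2, apex_intensity = 400,
                    fragments = data.frame(mz = 215.11, abundance = 0.6))
    ),
    noise_points_per_scan = noise_points_per_scan, noise_intensity_max = 30L,
    intensity_noise = intensity_noise, mz_range = c(50, 500), ims = ims, seed = seed
  )
}

# Random small configs for property tests; parameters drawn from their own
# seeded stream.
random_config <- function(seed) {
  set.seed(seed + 10000L)
  n_cycles <- sample(5:15, 1L)
  n_bins <- sample(4:12, 1L)
  n_cmp <- sample(1:3, 1L)
  compounds <- lapply(seq_len(n_cmp), function(i) {
    compound_spec(
      precursor_mz = runif(1, 100, 900),
      rt_apex = runif(1, 0, n_cycles * 0.005),
      rt_sigma = runif(1, 0.004, 0.02),
      dt_apex_bin = runif(1, 1, n_bins),
      dt_sigma_bins = runif(1, 0.8, 2.5),
      apex_intensity = sample(50:2000, 1L),
      fragments = data.frame(mz = runif(2, 60, 300), abundance = runif(2, 0.1, 1))
    )
  })
  simulation_config(
    n_cycles = n_cycles, cycle_period = 0.005, level2_rt_offset = 0.002,
    n_bins = n_bins, drift_slope = 0.071, compounds = compounds,
    noise_points_per_scan = sample(0:5, 1L), noise_intensity_max = 40L,
    intensity_noise = sample(c("none", "poisson"), 1L),
    mz_range = c(50, 1000), seed = seed
  )
}

write_temp_sample <- function(sim, rows_per_group = 5000L, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, paste0(sim$metadata$sample_name, ".parquet"))
  write_sample(sim$table, sim$metadata, path,
               write_options(row_group_target_rows = rows_per_group))
  path
}

# --- full-scan oracles ------------------------------------------------------

oracle_group <- function(sub, key, fun) {
  vals <- sort(unique(key))
  data.frame(key = vals,
             intensity = vapply(vals, function(v) fun(sub$intensity[key == v]), double(1L)))
}

oracle_tic <- function(table, level) {
  sub <- table[table$mslevel == level, ]
  g <- oracle_group(sub, sub$rt, sum)
  names(g) <- c("rt", "intensity")
  g
}

oracle_bpc <- function(table, level) {
  sub <- table[table$mslevel == level, ]
  g <- oracle_group(sub, sub$rt, max)
  names(g) <- c("rt", "intensity")
  g
}

oracle_eic <- function(table, lo, hi, level) {
  sub <- table[table$mslevel == level & table$mz >= lo & table$mz <= hi, ]
  g <- oracle_group(sub, sub$rt, sum)
  names(g) <- c("rt", "intensity")
  g
}

oracle_mobilogram <- function(table, level, mz_range = NULL) {
  sub <- table[table$mslevel == level, ]
  if (!is.null(mz_range)) sub <- sub[sub$mz >= mz_range[1] & sub$mz <= mz_range[2], ]
  bins <- sort(unique(sub$bin))
  data.frame(
    bin = bins,
    dt = vapply(bins, function(b) sub$dt[sub$bin == b][1L], double(1L)),
    intensity = vapply(bins, function(b) sum(sub$intensity[sub$bin == b]), double(1L))
  )
}

oracle_filter <- function(table, pred) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(pred$mslevel)) keep <- keep & table$mslevel == pred$mslevel
  if (!is.null(pred$rt_range)) keep <- keep & table$rt >= pred$rt_range[1] & table$rt <= pred$rt_range[2]
  if (!is.null(pred$mz_range)) keep <- keep & table$mz >= pred$mz_range[1] & table$mz <= pred$mz_range[2]
  if (!is.null(pred$scanid_set)) keep <- keep & table$scanid %in% pred$scanid_set
  if (!is.null(pred$bin_range)) keep <- keep & table$bin >= pred$bin_range[1] & table$bin <= pred$bin_range[2]
  table[keep, ]
}

expect_series_equal <- function(series, oracle) {
  expect_equal(as.double(series[[1]]), as.double(oracle[[1]]), tolerance = 0)
  expect_equal(as.double(series$intensity), as.double(oracle$intensity), tolerance = 0)
}

# strip query bookkeeping attributes for whole-table comparisons
as_plain <- function(df) {
  df <- as.data.frame(df)
  for (a in c("row_groups_scanned", "row_groups_total", "has_ims", "schema_version",
              "kind", "mslevel", "mz_window")) {
    attr(df, a) <- NULL
  }
  df
}
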