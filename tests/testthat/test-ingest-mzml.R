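headers_df <- function(levels, rts, dts = NA_real_, ce = NA_real_) {
  tibble::tibble(
    index = seq_along(levels),
    native_id = sprintf("scan=%d", seq_along(levels)),
    ms_level_declared = levels,
    scan_start_time = rts,
    drift_time = rep_len(dts, length(levels)),
    collision_energy = rep_len(ce, length(levels)),
    n_points = 1L
  )
}

test_that("cycles are assigned by the alternating low/high group structure", {
  # plain MSE: L1,L2,L1,L2 at distinct rts
  h <- headers_df(c(1L, 2L, 1L, 2L), c(0.1, 0.2, 0.3, 0.4))
  res <- assign_cycles(h)
  expect_identical(res$scanid, c(1L, 1L, 2L, 2L))
  expect_identical(res$mslevel, c(1L, 2L, 1L, 2L))

  # single low-energy scan
  expect_identical(assign_cycles(headers_df(1L, 0.1))$scanid, 1L)

  # HDMSE: 5 drift-resolved sub-spectra per scan group share scanid and level
  h <- headers_df(c(rep(1L, 5), rep(2L, 5), rep(1L, 5)),
                  c(rep(0.1, 5), rep(0.2, 5), rep(0.3, 5)),
                  dts = 1:5 * 0.5)
  res <- assign_cycles(h)
  expect_identical(res$scanid, c(rep(1L, 10), rep(2L, 5)))
  expect_identical(res$mslevel, c(rep(1L, 5), rep(2L, 5), rep(1L, 5)))

  # two high-energy groups in a row: warn, but still advance the cycle
  h <- headers_df(c(1L, 2L, 2L), c(0.1, 0.2, 0.3))
  expect_warning(res <- assign_cycles(h), "consecutive high-energy")
  expect_identical(res$scanid, c(1L, 1L, 2L))
})

test_that("bins follow drift-time order, with grid recovery for linear drift times", {
  # non-grid drift times fall back to the rank transform
  expect_identical(assign_bins(c(2.485, 2.769, 4.260)), c(1L, 2L, 3L))
  expect_identical(assign_bins(5.0), 1L)

  # a full linear ramp gets bins 1..n and the calibration recovers the slope
  dts <- 0.071 * (1:200)
  bins <- assign_bins(dts)
  expect_identical(bins, 1:200)
  cal <- fit_drift_calibration(data.frame(bin = bins, dt = dts))
  expect_equal(cal$slope, 0.071, tolerance = 1e-12)

  # sparse grid-consistent drift times keep their true indices
  expect_identical(assign_bins(0.071 * c(34, 35, 39, 40, 60)),
                   c(34L, 35L, 39L, 40L, 60L))

  # bins are invariant to the order drift times appear in
  set.seed(42)
  perm <- sample(200)
  expect_identical(assign_bins(dts[perm]), bins[perm])

  # reference lookup enforces global consistency
  ref <- data.frame(dt = dts, bin = bins)
  expect_identical(assign_bins(c(0.142, 0.071), reference = ref), c(2L, 1L))
  expect_error(assign_bins(3.1415, reference = ref), class = "msparquet_ingest_error")
})

test_that("MS-level mapping modes behave as configured", {
  h <- headers_df(c(1L, 1L), c(0.1, 0.2), ce = c(6, 30))
  thr <- level_map_config("collision_energy_threshold", ce_threshold = 15)
  expect_identical(map_ms_level(h, thr), c(1L, 2L))
  expect_identical(map_ms_level(h, level_map_config("declared")), c(1L, 1L))

  h_na <- headers_df(c(1L, 1L), c(0.1, 0.2))
  err <- expect_error(map_ms_level(h_na, thr), class = "msparquet_level_map_error")
  expect_match(conditionMessage(err), "scan=1")

  # alternating mode: groups by shared scan time, odd groups low energy
  h_alt <- headers_df(rep(1L, 6), c(0.1, 0.1, 0.2, 0.2, 0.3, 0.3))
  expect_identical(map_ms_level(h_alt, level_map_config("alternating")),
                   c(1L, 1L, 2L, 2L, 1L, 1L))

  ovr <- level_map_config("declared", override_map = c("scan=2" = 2L))
  expect_identical(map_ms_level(h, ovr), c(1L, 2L))
})

test_that("read_mzml recovers exactly the emitted points of a synthetic file", {
  # 10 cycles x 2 levels x 5 bins x 3 points, no zeros, no noise: a fully
  # dense block whose record count is known at generation time
  grid <- expand.grid(scanid = 1:10, mslevel = 1:2, bin = 1:5, point = 1:3)
  tab <- spectral_table(data.frame(
    rt = round((grid$scanid - 1) * 0.005 + (grid$mslevel - 1) * 0.002, 10),
    scanid = grid$scanid,
    mslevel = grid$mslevel,
    mz = 100 + 10 * grid$point + 0.001 * grid$bin,
    intensity = 10 * grid$point + grid$bin,
    bin = grid$bin,
    dt = round(0.071 * grid$bin, 6)
  ))
  meta <- sample_metadata("dense", has_ims = TRUE,
                          drift_calibration = drift_calibration(0.071))
  path <- file.path(withr::local_tempdir(), "dense.mzML")
  write_synthetic_mzml(tab, meta, path)

  ing <- read_mzml(path)
  expect_identical(nrow(ing$table), 300L)
  expect_identical(as.data.frame(ing$table), as.data.frame(canonical_sort(tab)))
  # losslessness: exact intensity conservation
  expect_identical(sum(ing$table$intensity), sum(tab$intensity))
  expect_true(ing$metadata$has_ims)
  expect_equal(ing$metadata$drift_calibration$slope, 0.071, tolerance = 1e-12)
})

test_that("zero-intensity padding is dropped at ingest, and empty spectra contribute nothing", {
  sim <- simulate_sample(tiny_config(seed = 11L, noise_points_per_scan = 0L))
  dir <- withr::local_tempdir()
  plain <- file.path(dir, "plain.mzML")
  padded <- file.path(dir, "padded.mzML")
  write_synthetic_mzml(sim$table, sim$metadata, plain, pad_zeros = FALSE)
  write_synthetic_mzml(sim$table, sim$metadata, padded, pad_zeros = TRUE)
  a <- read_mzml(plain)$table
  b <- read_mzml(padded)$table
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(as.data.frame(a), as.data.frame(sim$table))

  # keep_zeros retains the padding instead
  c <- read_mzml(padded, keep_zeros = TRUE)$table
  expect_gt(nrow(c), nrow(b))

  # a file holding one empty spectrum yields an empty table, not an error
  empty <- spectral_table(sim$table[0, ])
  one <- spectral_table(data.frame(rt = 0.01, scanid = 1L, mslevel = 1L,
                                   mz = 100.5, intensity = 42, bin = 1L, dt = 0.071))
  p2 <- file.path(dir, "single.mzML")
  write_synthetic_mzml(one, sim$metadata, p2)
  # append-style check via a table whose only spectrum has zero points
  p3 <- file.path(dir, "empty.mzML")
  write_synthetic_mzml(empty, sim$metadata, p3)
  expect_identical(nrow(read_mzml(p3)$table), 0L)
  expect_identical(as.data.frame(read_mzml(p2)$table), as.data.frame(one))
})

test_that("unreadable input raises a parse error and missing files an io error", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "broken.mzML")
  writeLines("<mzML><spectrumList", bad)
  expect_error(read_mzml(bad), class = "msparquet_parse_error")
  expect_error(read_mzml(file.path(dir, "nope.mzML")), class = "msparquet_io_error")
})

test_that("gzip-compressed mzML ingests identically to the plain file", {
  sim <- simulate_sample(tiny_config(seed = 5L))
  dir <- withr::local_tempdir()
  plain <- file.path(dir, "s.mzML")
  write_synthetic_mzml(sim$table, sim$metadata, plain)
  gz <- file.path(dir, "s.mzML.gz")
  con <- gzfile(gz, "wb")
  writeBin(readBin(plain, raw(), file.size(plain)), con)
  close(con)
  expect_identical(as.data.frame(read_mzml(gz)$table),
                   as.data.frame(read_mzml(plain)$table))
})
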