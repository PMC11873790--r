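toy_meta <- function() {
  tab <- example_spectral_table()
  sample_metadata("toy", has_ims = TRUE,
                  drift_calibration = fit_drift_calibration(data.frame(bin = tab$bin, dt = tab$dt)),
                  polarity = "positive", extras = list(study = "worked-example"))
}

test_that("a written sample reads back bit-exactly with its metadata", {
  tab <- example_spectral_table()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "toy.parquet")
  rep <- write_sample(tab, toy_meta(), path)
  expect_identical(rep$n_rows, 5L)
  expect_identical(rep$n_row_groups, 1L)
  expect_true(file.exists(path))
  expect_true(file.exists(file.path(dir, "toy-metadata.json")))

  back <- read_sample(path)
  expect_identical(as.data.frame(back), as.data.frame(canonical_sort(tab)))

  rt <- verify_roundtrip(tab, path)
  expect_true(rt$identical)
  expect_null(rt$first_divergence)

  meta <- read_metadata(path)
  expect_identical(meta$sample_name, "toy")
  expect_identical(meta$polarity, "positive")
  expect_identical(meta$extras$study, "worked-example")
  expect_equal(meta$drift_calibration$slope, 0.071, tolerance = 1e-12)

  # the embedded document and the sidecar are byte-identical
  kv <- arrow::ParquetFileReader$create(path)$GetSchema()$metadata$sample_metadata
  sc <- file.path(dir, "toy-metadata.json")
  expect_identical(kv, rawToChar(readBin(sc, raw(), file.size(sc))))
})

test_that("an empty valid table round-trips, and invalid tables are refused", {
  dir <- withr::local_tempdir()
  empty <- spectral_table(example_spectral_table()[0, ])
  p <- file.path(dir, "empty.parquet")
  write_sample(empty, toy_meta(), p)
  h <- open_sample(p)
  expect_identical(h$n_rows, 0L)
  expect_true(verify_roundtrip(empty, p)$identical)

  bad <- example_spectral_table()
  bad$intensity[1] <- -5
  err <- expect_error(write_sample(bad, toy_meta(), file.path(dir, "bad.parquet")),
                      class = "msparquet_invalid_table")
  expect_s3_class(err$report, "validation_report")
  expect_false(file.exists(file.path(dir, "bad.parquet")))
})

test_that("row grouping follows the target and zstd stays below the CSV rendering", {
  sim <- simulate_sample(tiny_config(seed = 2L))
  n <- nrow(sim$table)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "s.parquet")
  rep <- write_sample(sim$table, sim$metadata, p,
                      write_options(row_group_target_rows = 100L))
  expect_identical(rep$n_row_groups, as.integer(ceiling(n / 100)))

  csv <- file.path(dir, "s.csv")
  utils::write.csv(as.data.frame(sim$table), csv, row.names = FALSE)
  p_one <- file.path(dir, "s-one-group.parquet")
  rep_one <- write_sample(sim$table, sim$metadata, p_one)
  expect_lte(rep_one$file_bytes, file.size(csv))

  # compression monotonicity: zstd never larger than uncompressed
  p_none <- file.path(dir, "s-none.parquet")
  rep_none <- write_sample(sim$table, sim$metadata, p_none,
                           write_options(codec = "none"))
  p_zstd <- file.path(dir, "s-zstd.parquet")
  rep_zstd <- write_sample(sim$table, sim$metadata, p_zstd,
                           write_options(codec = "zstd"))
  expect_lte(rep_zstd$file_bytes, rep_none$file_bytes)
})

test_that("open_sample is lazy metadata access with schema checking", {
  sim <- simulate_sample(tiny_config(seed = 4L))
  p <- write_temp_sample(sim)
  h <- open_sample(p)
  expect_identical(h$n_rows, nrow(sim$table))
  expect_true(h$has_ims)
  expect_identical(h$metadata$sample_name, sim$metadata$sample_name)

  # non-IMS file: bin/dt columns absent entirely, handle reports no IMS
  sim2 <- simulate_sample(tiny_config(seed = 4L, ims = FALSE))
  p2 <- write_temp_sample(sim2)
  h2 <- open_sample(p2)
  expect_false(h2$has_ims)
  expect_identical(h2$columns, c("rt", "scanid", "mslevel", "mz", "intensity"))

  # a random parquet file is rejected with a schema error
  dir <- withr::local_tempdir()
  alien <- file.path(dir, "alien.parquet")
  arrow::write_parquet(data.frame(x = 1:3, y = letters[1:3]), alien)
  err <- expect_error(open_sample(alien), class = "msparquet_schema_error")
  expect_match(conditionMessage(err), "rt, scanid, mslevel")
})

test_that("metadata survives KV stripping via the sidecar, and mirrors must agree", {
  tab <- example_spectral_table()
  dir <- withr::local_tempdir()
  p <- file.path(dir, "toy.parquet")
  write_sample(tab, toy_meta(), p)

  # strip the embedded metadata (rewrite the payload without KV keys),
  # keeping the sidecar: open_sample reconstructs with a warning
  doc_before <- metadata_to_json(read_metadata(p))
  plain <- arrow::ParquetFileReader$create(p)$ReadTable()
  plain$metadata <- NULL
  arrow::write_parquet(plain, p)
  expect_warning(h <- open_sample(p), "sidecar")
  expect_identical(metadata_to_json(h$metadata), doc_before)
  expect_identical(metadata_to_json(read_metadata(p)), doc_before)

  # a hand-edited, divergent sidecar is detected
  p2 <- file.path(dir, "toy2.parquet")
  write_sample(tab, toy_meta(), p2)
  sc <- file.path(dir, "toy2-metadata.json")
  writeLines(sub("toy", "tampered", readLines(sc, warn = FALSE)), sc)
  expect_error(read_metadata(p2), class = "msparquet_metadata_mismatch")

  # no sidecar at all: KV is the single source
  p3 <- file.path(dir, "toy3.parquet")
  write_sample(tab, toy_meta(), p3, write_options(write_json_sidecar = FALSE))
  expect_false(file.exists(file.path(dir, "toy3-metadata.json")))
  expect_identical(read_metadata(p3)$sample_name, "toy")
})

test_that("verify_roundtrip pinpoints an injected divergence", {
  sim <- simulate_sample(tiny_config(seed = 6L))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "s.parquet")
  write_sample(sim$table, sim$metadata, p)

  perturbed <- canonical_sort(sim$table)
  i <- 17L
  perturbed$intensity[i] <- perturbed$intensity[i] + 1
  res <- verify_roundtrip(perturbed, p)
  expect_false(res$identical)
  expect_identical(res$first_divergence$column, "intensity")
  expect_identical(res$first_divergence$row, i)
})

test_that("the mzML route and the direct route produce identical stored samples", {
  sim <- simulate_sample(tiny_config(seed = 8L))
  dir <- withr::local_tempdir()
  mz <- file.path(dir, "s.mzML")
  write_synthetic_mzml(sim$table, sim$metadata, mz)
  ing <- read_mzml(mz)
  p1 <- file.path(dir, "via-mzml.parquet")
  p2 <- file.path(dir, "direct.parquet")
  write_sample(ing$table, ing$metadata, p1)
  write_sample(sim$table, sim$metadata, p2)
  expect_identical(as.data.frame(read_sample(p1)), as.data.frame(read_sample(p2)))
  expect_true(verify_roundtrip(sim$table, p1)$identical)
})
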