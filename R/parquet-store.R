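# Parquet persistence. On disk: rt/mz/dt float64, scanid int32, bin int32,
# intensity int64, mslevel dictionary-encoded string ("1"/"2") for
# byte-compatibility with files that filter mslevel as a string. The sample
# metadata document lives both in the file's key-value metadata (key
# "sample_metadata") and in a JSON sidecar "<stem>-metadata.json"; the two are
# byte-identical. A second KV key, "row_group_index", carries per-row-group
# min/max statistics used by the query layer for pruning.

KV_METADATA_KEY <- "sample_metadata"
KV_INDEX_KEY <- "row_group_index"

#' Describe a sample
#'
#' Identity, acquisition descriptors, unit conventions, drift calibration and
#' conversion provenance for one stored sample. Serialized to JSON (stable
#' key order) into both the Parquet key-value metadata and the sidecar file.
#'
#' @param sample_name Sample identifier (nonempty).
#' @param analysis_name Analysis identifier; defaults to `sample_name`.
#' @param acquisition_time ISO-8601 string, or NULL.
#' @param instrument_descriptor Free-text instrument description, or NULL.
#' @param polarity `"positive"`, `"negative"` or `"unknown"`.
#' @param has_ims Whether the sample carries the ion-mobility dimension.
#' @param drift_calibration A [drift_calibration()] (required iff `has_ims`).
#' @param rt_unit,dt_unit Unit labels; defaults `"minute"` / `"millisecond"`.
#' @param source_file Provenance of the raw data, or NULL.
#' @param extras Named list of additional string fields.
#' @return A `sample_metadata` object.
#' @export
sample_metadata <- function(sample_name, analysis_name = sample_name,
                            acquisition_time = NULL, instrument_descriptor = NULL,
                            polarity = c("unknown", "positive", "negative"),
                            has_ims = FALSE, drift_calibration = NULL,
                            rt_unit = "minute", dt_unit = "millisecond",
                            source_file = NULL, extras = list()) {
  polarity <- match.arg(polarity)
  if (!is.character(sample_name) || !nzchar(sample_name)) {
    msparquet_error("msparquet_config_error", "sample_name must be a nonempty string")
  }
  if (!is.null(drift_calibration) && !inherits(drift_calibration, "drift_calibration")) {
    msparquet_error("msparquet_config_error", "drift_calibration must be a drift_calibration object")
  }
  if (has_ims != !is.null(drift_calibration)) {
    msparquet_error("msparquet_config_error",
                    "has_ims must agree with the presence of drift_calibration")
  }
  structure(
    list(
      sample_name = sample_name, analysis_name = analysis_name,
      acquisition_time = acquisition_time,
      instrument_descriptor = instrument_descriptor,
      polarity = polarity, has_ims = has_ims,
      drift_calibration = drift_calibration,
      rt_unit = rt_unit, dt_unit = dt_unit,
      source_file = source_file,
      converter_name = "msparquet",
      converter_version = as.character(packageVersion("msparquet")),
      extras = extras
    ),
    class = "sample_metadata"
  )
}

#' @export
print.sample_metadata <- function(x, ...) {
  cat(sprintf("<sample_metadata> %s (analysis: %s)\n", x$sample_name, x$analysis_name))
  cat(sprintf("  polarity: %s | IMS: %s | rt in %s, dt in %s\n",
              x$polarity, x$has_ims, x$rt_unit, x$dt_unit))
  if (!is.null(x$drift_calibration)) print(x$drift_calibration)
  invisible(x)
}

#' Serialize sample metadata to its canonical JSON document
#' @param meta A `sample_metadata`.
#' @return A single JSON string (stable key order, UTF-8).
#' @export
metadata_to_json <- function(meta) {
  stopifnot(inherits(meta, "sample_metadata"))
  cal <- meta$drift_calibration
  doc <- list(
    schema_version = SCHEMA_VERSION,
    sample_name = meta$sample_name,
    analysis_name = meta$analysis_name,
    acquisition_time = meta$acquisition_time,
    instrument_descriptor = meta$instrument_descriptor,
    polarity = meta$polarity,
    has_ims = meta$has_ims,
    drift_calibration = if (is.null(cal)) NULL else list(
      slope = cal$slope, intercept = cal$intercept,
      n_points = cal$n_points, max_residual = cal$max_residual
    ),
    rt_unit = meta$rt_unit, dt_unit = meta$dt_unit,
    source_file = meta$source_file,
    converter_name = meta$converter_name,
    converter_version = meta$converter_version,
    extras = meta$extras
  )
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"))
}

#' Rebuild sample metadata from its JSON document
#' @param json A JSON string produced by [metadata_to_json()].
#' @return A `sample_metadata`.
#' @export
metadata_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  cal <- if (!is.null(doc$drift_calibration)) {
    drift_calibration(
      slope = doc$drift_calibration$slope,
      intercept = doc$drift_calibration$intercept %||% 0,
      n_points = doc$drift_calibration$n_points %||% 0L,
      max_residual = doc$drift_calibration$max_residual %||% NA_real_
    )
  }
  meta <- sample_metadata(
    sample_name = doc$sample_name,
    analysis_name = doc$analysis_name %||% doc$sample_name,
    acquisition_time = doc$acquisition_time,
    instrument_descriptor = doc$instrument_descriptor,
    polarity = doc$polarity %||% "unknown",
    has_ims = isTRUE(doc$has_ims),
    drift_calibration = cal,
    rt_unit = doc$rt_unit %||% "minute",
    dt_unit = doc$dt_unit %||% "millisecond",
    source_file = doc$source_file,
    extras = as.list(doc$extras %||% list())
  )
  meta$converter_name <- doc$converter_name %||% meta$converter_name
  meta$converter_version <- doc$converter_version %||% meta$converter_version
  meta
}

#' Options controlling how a sample is written
#' @param codec Compression codec: `"zstd"` (default), `"snappy"`, `"gzip"`,
#'   `"none"`.
#' @param row_group_target_rows Rows per Parquet row group (default 2^20).
#'   Smaller groups give finer pruning at the cost of footer overhead.
#' @param sort_before_write Apply [canonical_sort()] before writing (default
#'   TRUE; sorted files are what make row-group pruning effective).
#' @param write_json_sidecar Also write the `<stem>-metadata.json` sidecar
#'   (default TRUE).
#' @return A `write_options` object.
#' @export
write_options <- function(codec = c("zstd", "snappy", "gzip", "none"),
                          row_group_target_rows = 2L^20L,
                          sort_before_write = TRUE, write_json_sidecar = TRUE) {
  codec <- match.arg(codec)
  if (!is.finite(row_group_target_rows) || row_group_target_rows < 1) {
    msparquet_error("msparquet_config_error", "row_group_target_rows must be >= 1")
  }
  structure(list(codec = codec,
                 row_group_target_rows = as.integer(row_group_target_rows),
                 sort_before_write = isTRUE(sort_before_write),
                 write_json_sidecar = isTRUE(write_json_sidecar)),
            class = "write_options")
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "-metadata.json")
}

arrow_disk_schema <- function(ims) {
  fields <- list(
    rt = arrow::float64(), scanid = arrow::int32(),
    mslevel = arrow::dictionary(arrow::int32(), arrow::utf8()),
    mz = arrow::float64(), intensity = arrow::int64()
  )
  if (ims) {
    fields$bin <- arrow::int32()
    fields$dt <- arrow::float64()
  }
  do.call(arrow::schema, fields)
}

row_group_index_json <- function(table, target_rows) {
  n <- nrow(table)
  starts <- if (n == 0L) integer() else seq(1L, n, by = target_rows)
  groups <- lapply(starts, function(s) {
    e <- min(s + target_rows - 1L, n)
    sl <- table[s:e, ]
    g <- list(
      n_rows = e - s + 1L,
      rt = c(min(sl$rt), max(sl$rt)),
      scanid = c(min(sl$scanid), max(sl$scanid)),
      mslevel = sort(unique(as.character(sl$mslevel))),
      mz = c(min(sl$mz), max(sl$mz))
    )
    if (has_ims(table)) g$bin <- c(min(sl$bin), max(sl$bin))
    g
  })
  as.character(jsonlite::toJSON(
    list(version = 1L, row_group_target_rows = target_rows, row_groups = groups),
    auto_unbox = TRUE, digits = NA
  ))
}

#' Write a sample to a Parquet file
#'
#' Refuses to write a table that fails [validate_table()]. Rows are written
#' in canonical order (unless disabled) in row groups of
#' `row_group_target_rows` rows with column statistics enabled; the metadata
#' document is embedded under the key-value key `"sample_metadata"` and
#' mirrored byte-for-byte in the JSON sidecar.
#'
#' @param table A `spectral_table`.
#' @param metadata A [sample_metadata()].
#' @param path Destination; defaults to `"<sample_name>.parquet"` in the
#'   working directory.
#' @param options A [write_options()].
#' @return A write report: list with `path`, `n_rows`, `n_row_groups`,
#'   `file_bytes`.
#' @export
write_sample <- function(table, metadata, path = NULL, options = write_options()) {
  if (!inherits(table, "spectral_table")) table <- spectral_table(table)
  if (is.null(path)) path <- paste0(metadata$sample_name, ".parquet")
  rep <- validate_table(table)
  if (!rep$ok) {
    msparquet_error("msparquet_invalid_table",
                    sprintf("refusing to write an invalid table: %s",
                            paste(rep$violations$message, collapse = "; ")),
                    report = rep)
  }
  if (options$sort_before_write) table <- canonical_sort(table)
  ims <- has_ims(table)
  df <- as.data.frame(table)
  df$mslevel <- factor(as.character(df$mslevel), levels = c("1", "2"))
  tab <- arrow::arrow_table(df, schema = arrow_disk_schema(ims))
  doc <- metadata_to_json(metadata)
  tab$metadata[[KV_METADATA_KEY]] <- doc
  tab$metadata[[KV_INDEX_KEY]] <- row_group_index_json(table, options$row_group_target_rows)
  codec <- if (options$codec == "none") "uncompressed" else options$codec
  tryCatch(
    arrow::write_parquet(tab, path, chunk_size = options$row_group_target_rows,
                         compression = codec, write_statistics = TRUE),
    error = function(e) msparquet_error(
      "msparquet_io_error", sprintf("failed to write '%s': %s", path, conditionMessage(e))
    )
  )
  if (options$write_json_sidecar) {
    con <- file(sidecar_path(path), "wb")
    writeBin(charToRaw(doc), con)
    close(con)
  }
  pf <- arrow::ParquetFileReader$create(path)
  invisible(structure(list(path = path, n_rows = nrow(table),
                           n_row_groups = pf$num_row_groups,
                           file_bytes = as.numeric(file.size(path))),
                      class = "write_report"))
}

#' @export
print.write_report <- function(x, ...) {
  cat(sprintf("<write_report> %s: %d rows in %d row group(s), %.0f bytes\n",
              x$path, x$n_rows, x$n_row_groups, x$file_bytes))
  invisible(x)
}

read_kv_metadata <- function(path) {
  pf <- arrow::ParquetFileReader$create(path)
  md <- pf$GetSchema()$metadata
  list(doc = md[[KV_METADATA_KEY]], index = md[[KV_INDEX_KEY]],
       n_rows = pf$num_rows, n_row_groups = pf$num_row_groups,
       columns = names(pf$GetSchema()))
}

check_disk_schema <- function(columns, path) {
  ok <- identical(columns, SPECTRAL_COLUMNS) || identical(columns, SPECTRAL_COLUMNS_NO_IMS)
  if (!ok) {
    msparquet_error(
      "msparquet_schema_error",
      sprintf("'%s' does not have the long-format schema: expected columns %s (bin/dt jointly optional), found %s",
              path, paste(SPECTRAL_COLUMNS, collapse = ", "),
              paste(columns, collapse = ", "))
    )
  }
}

#' Read the metadata of a stored sample
#'
#' Prefers the document embedded in the Parquet key-value metadata; falls
#' back to the JSON sidecar. When both exist they must be byte-identical
#' mirrors, otherwise an error is raised.
#'
#' @param path Path to a sample Parquet file.
#' @return A `sample_metadata`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    msparquet_error("msparquet_io_error", sprintf("input not found: %s", path))
  }
  kv <- read_kv_metadata(path)$doc
  sc <- sidecar_path(path)
  side <- if (file.exists(sc)) rawToChar(readBin(sc, raw(), file.size(sc))) else NULL
  if (!is.null(kv) && !is.null(side) && !identical(kv, side)) {
    msparquet_error("msparquet_metadata_mismatch",
                    sprintf("embedded metadata and sidecar '%s' differ; they must mirror each other", sc))
  }
  doc <- kv %||% side
  if (is.null(doc)) {
    msparquet_error("msparquet_metadata_missing",
                    sprintf("no metadata found for '%s' (neither embedded nor sidecar)", path))
  }
  metadata_from_json(doc)
}

#' Open a stored sample for lazy, filtered access
#'
#' Reads only the Parquet footer and metadata; no row data is materialized.
#' The returned handle carries the row-group pruning index used by the query
#' functions ([tic()], [eic()], [filter_records()], ...).
#'
#' @param path Path to a sample Parquet file.
#' @return A `dataset_handle`.
#' @export
open_sample <- function(path) {
  if (!file.exists(path)) {
    msparquet_error("msparquet_io_error", sprintf("input not found: %s", path))
  }
  kv <- read_kv_metadata(path)
  check_disk_schema(kv$columns, path)
  meta <- if (!is.null(kv$doc)) {
    metadata_from_json(kv$doc)
  } else {
    sc <- sidecar_path(path)
    if (file.exists(sc)) {
      warning(sprintf("'%s' has no embedded metadata; reconstructed from sidecar", path),
              call. = FALSE)
      metadata_from_json(rawToChar(readBin(sc, raw(), file.size(sc))))
    } else {
      warning(sprintf("'%s' has no metadata (embedded or sidecar); using file-derived defaults", path),
              call. = FALSE)
      ims <- identical(kv$columns, SPECTRAL_COLUMNS)
      sample_metadata(sample_name = tools::file_path_sans_ext(basename(path)),
                      has_ims = ims,
                      drift_calibration = if (ims) drift_calibration(1) else NULL,
                      source_file = path)
    }
  }
  idx <- if (!is.null(kv$index)) jsonlite::fromJSON(kv$index, simplifyVector = FALSE)
  structure(
    list(path = path, n_rows = kv$n_rows, n_row_groups = kv$n_row_groups,
         columns = kv$columns, has_ims = identical(kv$columns, SPECTRAL_COLUMNS),
         metadata = meta, row_group_index = idx),
    class = "dataset_handle"
  )
}

#' @export
print.dataset_handle <- function(x, ...) {
  cat(sprintf("<dataset_handle> %s\n  %d rows, %d row group(s), IMS: %s\n",
              x$path, x$n_rows, x$n_row_groups, x$has_ims))
  invisible(x)
}

arrow_to_spectral <- function(tab) {
  ims <- "bin" %in% names(tab)
  target <- list(rt = arrow::float64(), scanid = arrow::int32(),
                 mslevel = arrow::utf8(), mz = arrow::float64(),
                 intensity = arrow::float64())
  if (ims) {
    target$bin <- arrow::int32()
    target$dt <- arrow::float64()
  }
  df <- as.data.frame(tab$cast(do.call(arrow::schema, target)))
  spectral_table(df)
}

#' Read a stored sample fully into memory
#'
#' The eager counterpart of [open_sample()]: materializes every row as a
#' `spectral_table`. Used for round-trip verification and as the full-scan
#' oracle in tests.
#'
#' @param path Path to a sample Parquet file.
#' @return A `spectral_table`.
#' @export
read_sample <- function(path) {
  kv <- read_kv_metadata(path)
  check_disk_schema(kv$columns, path)
  pf <- arrow::ParquetFileReader$create(path)
  arrow_to_spectral(pf$ReadTable())
}

#' Verify that a stored sample reproduces a table bit-exactly
#'
#' Reads the file back and compares every cell against `table`, both sides
#' in canonical order. Divergences are reported, not thrown.
#'
#' @param table The reference `spectral_table`.
#' @param path Path to the Parquet file written from it.
#' @return A list with `identical` (flag), `first_divergence` (NULL, or list
#'   with `row`, `column`, `expected`, `found`) and `n_rows_compared`.
#' @export
verify_roundtrip <- function(table, path) {
  if (!inherits(table, "spectral_table")) table <- spectral_table(table)
  a <- canonical_sort(table)
  b <- canonical_sort(read_sample(path))
  if (!identical(names(a), names(b))) {
    return(list(identical = FALSE,
                first_divergence = list(row = 0L, column = "<schema>",
                                        expected = paste(names(a), collapse = ","),
                                        found = paste(names(b), collapse = ",")),
                n_rows_compared = 0L))
  }
  if (nrow(a) != nrow(b)) {
    return(list(identical = FALSE,
                first_divergence = list(row = min(nrow(a), nrow(b)) + 1L,
                                        column = "<row count>",
                                        expected = nrow(a), found = nrow(b)),
                n_rows_compared = 0L))
  }
  for (col in names(a)) {
    same <- a[[col]] == b[[col]]
    if (!all(same)) {
      i <- which(!same)[1L]
      return(list(identical = FALSE,
                  first_divergence = list(row = i, column = col,
                                          expected = a[[col]][i], found = b[[col]][i]),
                  n_rows_compared = nrow(a)))
    }
  }
  list(identical = TRUE, first_divergence = NULL, n_rows_compared = nrow(a))
}
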