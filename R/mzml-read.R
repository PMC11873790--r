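# mzML ingestion: mzR (ProteoWizard backend) does the XML/binary-array work;
# this module owns cycle/scan attribution, MS-level mapping for alternating
# low/high collision-energy acquisitions, drift-bin assignment and assembly of
# the validated long-format table.

#' Configure how spectra are attributed to MS levels 1 and 2
#'
#' In alternating low/high collision-energy acquisitions, the low-energy
#' function maps to MS level 1 and the high-energy function to level 2.
#' Converted files mark the high-energy function inconsistently, so three
#' modes are offered: `declared` trusts the file's msLevel (clamped to 1/2),
#' `collision_energy_threshold` assigns level 2 to spectra whose collision
#' energy exceeds `ce_threshold`, and `alternating` derives levels from the
#' run structure (spectra sharing a scan start time form a group; groups
#' alternate 1, 2, 1, 2).
#'
#' @param mode One of `"declared"`, `"collision_energy_threshold"`,
#'   `"alternating"`.
#' @param ce_threshold Collision energy (eV) separating the functions in
#'   threshold mode; default 15 eV.
#' @param override_map Optional named integer vector of explicit
#'   native-id -> level assignments, consulted before the mode rule.
#' @return A `level_map_config` object.
#' @export
level_map_config <- function(mode = c("declared", "collision_energy_threshold", "alternating"),
                             ce_threshold = 15, override_map = NULL) {
  mode <- match.arg(mode)
  if (mode == "collision_energy_threshold" && (!is.finite(ce_threshold) || ce_threshold <= 0)) {
    msparquet_error("msparquet_config_error", "ce_threshold must be positive in threshold mode")
  }
  structure(list(mode = mode, ce_threshold = ce_threshold, override_map = override_map),
            class = "level_map_config")
}

#' Map spectrum headers to MS levels
#'
#' @param headers A data frame of spectrum headers with columns `native_id`,
#'   `ms_level_declared`, `scan_start_time`, `collision_energy`.
#' @param config A [level_map_config()].
#' @return Integer vector of levels (1 or 2), one per header.
#' @export
map_ms_level <- function(headers, config = level_map_config()) {
  headers <- as.data.frame(headers)
  n <- nrow(headers)
  lev <- switch(config$mode,
    declared = pmin(pmax(as.integer(headers$ms_level_declared), 1L), 2L),
    collision_energy_threshold = {
      ce <- headers$collision_energy
      if (is.null(ce) || any(is.na(ce))) {
        bad <- if (is.null(ce)) headers$native_id else headers$native_id[is.na(ce)]
        msparquet_error(
          "msparquet_level_map_error",
          sprintf("collision energy absent for spectra: %s",
                  paste(head(bad, 5L), collapse = ", ")),
          native_ids = bad
        )
      }
      ifelse(ce > config$ce_threshold, 2L, 1L)
    },
    alternating = {
      grp <- cumsum(c(TRUE, headers$scan_start_time[-1L] != headers$scan_start_time[-n]))
      ifelse(grp %% 2L == 1L, 1L, 2L)
    }
  )
  if (!is.null(config$override_map)) {
    hit <- match(headers$native_id, names(config$override_map))
    lev[!is.na(hit)] <- as.integer(config$override_map[hit[!is.na(hit)]])
  }
  lev
}

#' Assign acquisition-cycle ids and MS levels to a header sequence
#'
#' Consecutive headers sharing an MS level and a scan start time form one scan
#' group (a mobility frame is one group of many drift-resolved sub-spectra).
#' The cycle counter `scanid` starts at 1 and increments whenever a new group
#' does not move from level 1 to level 2 within the same cycle -- i.e. at
#' every 2 -> 1 transition, and at 1 -> 1 or 2 -> 2 group boundaries
#' (the latter emits a structure warning: a high-energy group with no
#' preceding low-energy group in the cycle).
#'
#' @param headers Data frame of headers in file order (columns as in
#'   [map_ms_level()]).
#' @param config A [level_map_config()].
#' @return A tibble with one row per header: `scanid`, `mslevel`.
#' @export
assign_cycles <- function(headers, config = level_map_config()) {
  headers <- as.data.frame(headers)
  n <- nrow(headers)
  if (n == 0L) return(tibble::tibble(scanid = integer(), mslevel = integer()))
  lev <- map_ms_level(headers, config)
  new_group <- c(TRUE, lev[-1L] != lev[-n] |
                   headers$scan_start_time[-1L] != headers$scan_start_time[-n])
  gid <- cumsum(new_group)
  glev <- lev[new_group]
  ng <- length(glev)
  cycle <- integer(ng)
  cycle[1L] <- 1L
  if (ng > 1L) {
    for (g in 2L:ng) {
      if (glev[g] == 2L && glev[g - 1L] == 1L) {
        cycle[g] <- cycle[g - 1L]
      } else {
        if (glev[g] == 2L && glev[g - 1L] == 2L) {
          warning(sprintf(
            "cycle structure: consecutive high-energy scan groups with no low-energy group between them (group %d); cycle incremented", g),
            call. = FALSE)
        }
        cycle[g] <- cycle[g - 1L] + 1L
      }
    }
  }
  tibble::tibble(scanid = cycle[gid], mslevel = lev)
}

#' Assign drift-bin indices to drift times
#'
#' Distinct drift times receive 1-based bin indices in ascending drift-time
#' order; equal drift times (after rounding to 6 decimals, the instrument
#' quantization guard) receive equal bins. Because mobility cells emit drift
#' times on a uniform grid `dt = slope * bin`, the default first tries to
#' recover the true bin index from that grid (spacing inferred as the
#' smallest gap between distinct drift times) so that bins sparsely
#' populated after zero-dropping keep their original indices; when the drift
#' times are not grid-consistent it falls back to a plain rank transform.
#' When a `reference` map is given (the file-wide bin table), drift times
#' are looked up in it so assignment is globally consistent across cycles.
#'
#' @param drift_times Positive drift times in milliseconds.
#' @param reference Optional data frame with columns `dt`, `bin` from a
#'   previous assignment.
#' @return Integer bin indices, one per drift time.
#' @export
assign_bins <- function(drift_times, reference = NULL) {
  if (length(drift_times) == 0L) return(integer())
  if (any(!is.finite(drift_times)) || any(drift_times <= 0)) {
    msparquet_error("msparquet_domain_error", "drift times must be positive")
  }
  key <- round(drift_times, 6L)
  if (is.null(reference)) {
    lv <- sort(unique(key))
    bins_lv <- seq_along(lv)
    if (length(lv) >= 2L) {
      s <- min(diff(lv))
      ratio <- lv / s
      if (all(abs(ratio - round(ratio)) < 1e-3) && all(round(ratio) >= 1)) {
        bins_lv <- as.integer(round(ratio))
      }
    }
    return(bins_lv[match(key, lv)])
  }
  ref_key <- round(reference$dt, 6L)
  hit <- match(key, ref_key)
  if (anyNA(hit)) {
    msparquet_error(
      "msparquet_ingest_error",
      sprintf("drift time(s) %s not present in the reference bin table",
              paste(head(unique(key[is.na(hit)]), 5L), collapse = ", "))
    )
  }
  as.integer(reference$bin[hit])
}

#' Read an mzML file into the long format
#'
#' Parses an mzML 1.1 document (plain or gzip-compressed) with the
#' ProteoWizard backend, attributes spectra to acquisition cycles and MS
#' levels, assigns drift bins from per-scan drift-time annotations when
#' present, and assembles a validated [spectral_table()] in canonical order
#' together with [sample_metadata()]. Ingestion is lossless apart from
#' zero-intensity profile padding, which is dropped by default (the long
#' format is sparse by construction); set `keep_zeros = TRUE` to retain it.
#' Scan start times are normalized to minutes and rounded to 10 decimal
#' places so the seconds/minutes conversion is idempotent.
#'
#' @param path Path to an mzML (or mzML.gz) file.
#' @param level_map A [level_map_config()].
#' @param keep_zeros Keep zero-intensity points (default FALSE).
#' @return A list with elements `table` (a `spectral_table`) and `metadata`
#'   (a `sample_metadata`).
#' @export
read_mzml <- function(path, level_map = level_map_config(), keep_zeros = FALSE) {
  if (!file.exists(path)) {
    msparquet_error("msparquet_io_error", sprintf("input not found: %s", path))
  }
  src <- path
  if (grepl("\\.gz$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".mzML")
    con_in <- gzfile(path, "rb")
    con_out <- file(tmp, "wb")
    while (length(chunk <- readBin(con_in, raw(), 1e6)) > 0L) writeBin(chunk, con_out)
    close(con_in); close(con_out)
    src <- tmp
    on.exit(unlink(tmp), add = TRUE)
  }
  ms <- tryCatch(
    mzR::openMSfile(src, backend = "pwiz"),
    error = function(e) msparquet_error(
      "msparquet_parse_error",
      sprintf("failed to parse mzML document '%s': %s", path, conditionMessage(e))
    )
  )
  on.exit(try(mzR::close(ms), silent = TRUE), add = TRUE)
  hd <- mzR::header(ms)
  headers <- tibble::tibble(
    index = hd$seqNum,
    native_id = hd$spectrumId,
    ms_level_declared = hd$msLevel,
    scan_start_time = round(hd$retentionTime / 60, 10L),
    # 6-decimal (sub-ns) quantization keeps the internal ms/s unit conversion
    # of the parser idempotent, mirroring the rt normalization above
    drift_time = if ("ionMobilityDriftTime" %in% names(hd)) round(hd$ionMobilityDriftTime, 6L) else NA_real_,
    collision_energy = if ("collisionEnergy" %in% names(hd)) hd$collisionEnergy else NA_real_,
    n_points = hd$peaksCount
  )
  n <- nrow(headers)
  ims_flags <- !is.na(headers$drift_time)
  file_has_ims <- any(ims_flags)
  if (file_has_ims && !all(ims_flags)) {
    bad <- headers$native_id[!ims_flags]
    msparquet_error(
      "msparquet_ingest_error",
      sprintf("inconsistent drift-time annotation: %d spectra lack a drift time, e.g. %s",
              sum(!ims_flags), paste(head(bad, 3L), collapse = ", ")),
      native_ids = bad
    )
  }
  cyc <- assign_cycles(headers, level_map)
  bins <- if (file_has_ims) assign_bins(headers$drift_time) else rep(NA_integer_, n)

  # spectra are fetched in bounded batches: memory stays proportional to a
  # batch plus the output buffers, not to the file
  chunks <- vector("list", n)
  batch_starts <- seq(1L, max(n, 1L), by = 1024L)
  peak_batch <- NULL
  batch_offset <- 0L
  for (i in seq_len(n)) {
    if (is.null(peak_batch) || i - batch_offset > length(peak_batch)) {
      batch_offset <- batch_starts[findInterval(i, batch_starts)] - 1L
      idx <- (batch_offset + 1L):min(batch_offset + 1024L, n)
      pb <- mzR::peaks(ms, idx)
      peak_batch <- if (length(idx) == 1L) list(pb) else pb
    }
    p <- peak_batch[[i - batch_offset]]
    if (is.null(dim(p)) || nrow(p) == 0L) next
    mz <- p[, 1L]
    inten <- p[, 2L]
    if (!keep_zeros) {
      keep <- inten > 0
      mz <- mz[keep]
      inten <- inten[keep]
    }
    if (!length(mz)) next
    chunk <- data.frame(
      rt = headers$scan_start_time[i],
      scanid = cyc$scanid[i],
      mslevel = cyc$mslevel[i],
      mz = mz,
      intensity = inten
    )
    if (file_has_ims) {
      chunk$bin <- bins[i]
      chunk$dt <- headers$drift_time[i]
    }
    chunks[[i]] <- chunk
  }
  chunks <- chunks[!vapply(chunks, is.null, logical(1L))]
  tab <- if (length(chunks)) {
    do.call(rbind, chunks)
  } else {
    empty <- data.frame(rt = double(), scanid = integer(), mslevel = integer(),
                        mz = double(), intensity = double())
    if (file_has_ims) { empty$bin <- integer(); empty$dt <- double() }
    empty
  }
  tab <- canonical_sort(spectral_table(tab))
  if (!keep_zeros) {
    # keep_zeros tables intentionally violate the sparse (intensity > 0)
    # invariant and are meant for inspection, not storage
    rep <- validate_table(tab)
    if (!rep$ok) {
      msparquet_error(
        "msparquet_ingest_error",
        sprintf("ingested table violates schema invariants: %s",
                paste(rep$violations$message, collapse = "; ")),
        report = rep
      )
    }
  }

  cal <- NULL
  if (file_has_ims && nrow(tab)) {
    pairs <- unique(data.frame(bin = tab$bin, dt = tab$dt))
    cal <- if (nrow(pairs) >= 2L) {
      fit_drift_calibration(pairs)
    } else {
      drift_calibration(slope = pairs$dt[1L] / pairs$bin[1L], n_points = 1L, max_residual = 0)
    }
  }
  instr <- tryCatch(mzR::instrumentInfo(ms), error = function(e) NULL)
  instr_desc <- if (!is.null(instr) && nzchar(instr$model %||% "")) instr$model else NULL
  meta <- sample_metadata(
    sample_name = sub("\\.(mzML|mzml)(\\.gz)?$", "", basename(path)),
    instrument_descriptor = instr_desc,
    has_ims = file_has_ims,
    drift_calibration = cal,
    source_file = path
  )
  list(table = tab, metadata = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
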