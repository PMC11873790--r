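# Filtered analytics over stored samples. All queries go through
# scan_records(), which prunes row groups against the index written at save
# time and reads only candidate groups, so memory use is bounded by the
# matching slice of the file, never its full contents. Every result carries
# `row_groups_scanned` / `row_groups_total` attributes so the pruning
# behaviour is observable.

#' Build a record predicate
#'
#' Conjunctive filter over the long-format columns. All intervals are closed
#' (`[lo, hi]`).
#'
#' @param mslevel MS level 1 or 2 (integer or the string form), or NULL.
#' @param rt_range Closed retention-time interval in minutes, or NULL.
#' @param mz_range Closed m/z interval in Th, or NULL.
#' @param bin_range Closed drift-bin interval, or NULL.
#' @param scanid_set Integer vector of acquisition-cycle ids, or NULL.
#' @return A `record_predicate`.
#' @export
record_predicate <- function(mslevel = NULL, rt_range = NULL, mz_range = NULL,
                             bin_range = NULL, scanid_set = NULL) {
  chk <- function(rng, what) {
    if (is.null(rng)) return(NULL)
    rng <- as.double(rng)
    if (length(rng) != 2L || anyNA(rng) || rng[1L] > rng[2L]) {
      msparquet_error("msparquet_domain_error",
                      sprintf("%s must be a closed interval with low <= high", what))
    }
    rng
  }
  structure(
    list(mslevel = normalize_mslevel(mslevel),
         rt_range = chk(rt_range, "rt_range"),
         mz_range = chk(mz_range, "mz_range"),
         bin_range = chk(bin_range, "bin_range"),
         scanid_set = if (is.null(scanid_set)) NULL else as.integer(scanid_set)),
    class = "record_predicate"
  )
}

normalize_mslevel <- function(mslevel) {
  if (is.null(mslevel)) return(NULL)
  lev <- as.integer(as.character(mslevel))
  if (length(lev) != 1L || is.na(lev) || !(lev %in% c(1L, 2L))) {
    msparquet_error("msparquet_domain_error", "mslevel must be 1 or 2 (integer or string)")
  }
  lev
}

empty_spectral <- function(ims) {
  df <- data.frame(rt = double(), scanid = integer(), mslevel = integer(),
                   mz = double(), intensity = double())
  if (ims) { df$bin <- integer(); df$dt <- double() }
  spectral_table(df)
}

# Which row groups can contain records matching the predicate?
candidate_row_groups <- function(handle, pred) {
  idx <- handle$row_group_index
  total <- handle$n_row_groups
  if (is.null(idx) || length(idx$row_groups) != total) return(seq_len(total))
  overlap <- function(stat, rng) {
    is.null(rng) || (stat[[1L]] <= rng[2L] && stat[[2L]] >= rng[1L])
  }
  keep <- vapply(idx$row_groups, function(g) {
    ok <- TRUE
    if (!is.null(pred$mslevel)) {
      ok <- as.character(pred$mslevel) %in% unlist(g$mslevel)
    }
    ok <- ok && overlap(g$rt, pred$rt_range) && overlap(g$mz, pred$mz_range)
    if (ok && !is.null(pred$scanid_set)) {
      ok <- any(pred$scanid_set >= g$scanid[[1L]] & pred$scanid_set <= g$scanid[[2L]])
    }
    if (ok && !is.null(pred$bin_range) && !is.null(g$bin)) {
      ok <- overlap(g$bin, pred$bin_range)
    }
    ok
  }, logical(1L))
  which(keep)
}

# Read candidate row groups, then apply the predicate exactly row-by-row.
scan_records <- function(handle, pred = record_predicate()) {
  stopifnot(inherits(handle, "dataset_handle"))
  cand <- candidate_row_groups(handle, pred)
  tab <- if (length(cand) == 0L || handle$n_rows == 0L) {
    empty_spectral(handle$has_ims)
  } else {
    pf <- arrow::ParquetFileReader$create(handle$path)
    arrow_to_spectral(pf$ReadRowGroups(as.integer(cand) - 1L))
  }
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(pred$mslevel)) keep <- keep & tab$mslevel == pred$mslevel
  if (!is.null(pred$rt_range)) keep <- keep & tab$rt >= pred$rt_range[1L] & tab$rt <= pred$rt_range[2L]
  if (!is.null(pred$mz_range)) keep <- keep & tab$mz >= pred$mz_range[1L] & tab$mz <= pred$mz_range[2L]
  if (!is.null(pred$scanid_set)) keep <- keep & tab$scanid %in% pred$scanid_set
  if (!is.null(pred$bin_range)) {
    keep <- if (has_ims(tab)) {
      keep & tab$bin >= pred$bin_range[1L] & tab$bin <= pred$bin_range[2L]
    } else {
      rep(FALSE, nrow(tab))
    }
  }
  out <- canonical_sort(tab[keep, ])
  attr(out, "row_groups_scanned") <- length(cand)
  attr(out, "row_groups_total") <- handle$n_row_groups
  out
}

#' Filter records of a stored sample
#'
#' Returns exactly the rows satisfying every clause of the predicate, in
#' canonical order, reading only the row groups that can match.
#'
#' @param handle A [open_sample()] handle.
#' @param pred A [record_predicate()].
#' @return A `spectral_table` with `row_groups_scanned` / `row_groups_total`
#'   attributes.
#' @export
filter_records <- function(handle, pred = record_predicate()) {
  scan_records(handle, pred)
}

chromatogram_series <- function(points, kind, mslevel, mz_window = NULL, src = NULL) {
  out <- tibble::as_tibble(points)
  class(out) <- c("chromatogram_series", class(out))
  attr(out, "kind") <- kind
  attr(out, "mslevel") <- mslevel
  attr(out, "mz_window") <- mz_window
  if (!is.null(src)) {
    attr(out, "row_groups_scanned") <- attr(src, "row_groups_scanned")
    attr(out, "row_groups_total") <- attr(src, "row_groups_total")
  }
  out
}

group_chromatogram <- function(records, fun) {
  if (nrow(records) == 0L) {
    return(tibble::tibble(rt = double(), intensity = double()))
  }
  records |>
    dplyr::group_by(rt) |>
    dplyr::summarise(intensity = fun(intensity), .groups = "drop") |>
    dplyr::arrange(rt)
}

#' Total ion chromatogram
#'
#' One point per distinct retention time at the given MS level; the value is
#' the exact sum of intensities at that rt (grouping uses the exact stored rt
#' values, no binning). An MS level absent from the file yields an empty
#' series.
#'
#' @param handle A [open_sample()] handle.
#' @param mslevel MS level (1 or 2; integer or string).
#' @return A `chromatogram_series` tibble with columns `rt`, `intensity`.
#' @export
tic <- function(handle, mslevel = 1) {
  rec <- scan_records(handle, record_predicate(mslevel = mslevel))
  chromatogram_series(group_chromatogram(rec, sum), "TIC", normalize_mslevel(mslevel), src = rec)
}

#' Base peak chromatogram
#'
#' As [tic()], but the value at each retention time is the maximum intensity.
#'
#' @inheritParams tic
#' @return A `chromatogram_series` tibble with columns `rt`, `intensity`.
#' @export
bpc <- function(handle, mslevel = 1) {
  rec <- scan_records(handle, record_predicate(mslevel = mslevel))
  chromatogram_series(group_chromatogram(rec, max), "BPC", normalize_mslevel(mslevel), src = rec)
}

#' Extracted ion chromatogram
#'
#' The TIC restricted to records whose m/z lies in the closed window
#' `[mz_lo, mz_hi]`; retention times with no surviving record are omitted.
#' Row groups whose m/z statistics cannot intersect the window are never
#' read.
#'
#' @param handle A [open_sample()] handle.
#' @param mz_lo,mz_hi Closed m/z window bounds (Th), `mz_lo <= mz_hi`.
#' @param mslevel MS level (1 or 2).
#' @return A `chromatogram_series` tibble with columns `rt`, `intensity`.
#' @export
eic <- function(handle, mz_lo, mz_hi, mslevel = 1) {
  if (is.na(mz_lo) || is.na(mz_hi) || mz_lo > mz_hi) {
    msparquet_error("msparquet_domain_error",
                    sprintf("inverted or invalid m/z window [%s, %s]", mz_lo, mz_hi))
  }
  rec <- scan_records(handle, record_predicate(mslevel = mslevel, mz_range = c(mz_lo, mz_hi)))
  chromatogram_series(group_chromatogram(rec, sum), "EIC", normalize_mslevel(mslevel),
                      mz_window = c(mz_lo, mz_hi), src = rec)
}

#' Extracted ion chromatogram around a target m/z
#'
#' Convenience wrapper over [eic()]: the window is `target +/- tol_da` Da, or
#' `target * (1 +/- tol_ppm * 1e-6)` when `tol_ppm` is given.
#'
#' @param handle A [open_sample()] handle.
#' @param mz_target Target m/z (Th).
#' @param tol_da Half-width in Da (default 0.01 when no ppm tolerance given).
#' @param tol_ppm Half-width in ppm (overrides `tol_da`).
#' @param mslevel MS level (1 or 2).
#' @return A `chromatogram_series`.
#' @export
eic_window <- function(handle, mz_target, tol_da = NULL, tol_ppm = NULL, mslevel = 1) {
  if (!is.null(tol_ppm)) {
    lo <- mz_target * (1 - tol_ppm * 1e-6)
    hi <- mz_target * (1 + tol_ppm * 1e-6)
  } else {
    tol_da <- tol_da %||% 0.01
    lo <- mz_target - tol_da
    hi <- mz_target + tol_da
  }
  eic(handle, lo, hi, mslevel)
}

#' Extract one spectrum
#'
#' All points of one (scanid, mslevel) scan group. With
#' `collapse_bins = TRUE` (default) intensities are summed over drift bins
#' per m/z; otherwise the per-bin breakdown is retained alongside.
#'
#' @param handle A [open_sample()] handle.
#' @param scanid Acquisition-cycle id.
#' @param mslevel MS level (1 or 2).
#' @param collapse_bins Sum over drift bins (default TRUE).
#' @return A `mass_spectrum`: list with `scanid`, `mslevel`, `rt`, `points`
#'   (tibble `mz`, `intensity`, m/z ascending) and `per_bin` (tibble or NULL).
#' @export
spectrum_at <- function(handle, scanid, mslevel, collapse_bins = TRUE) {
  rec <- scan_records(handle, record_predicate(mslevel = mslevel, scanid_set = scanid))
  if (nrow(rec) == 0L) {
    msparquet_error("msparquet_not_found",
                    sprintf("no records for scanid %s at mslevel %s", scanid, mslevel))
  }
  points <- rec |>
    dplyr::group_by(mz) |>
    dplyr::summarise(intensity = sum(intensity), .groups = "drop") |>
    dplyr::arrange(mz)
  per_bin <- NULL
  if (!collapse_bins && has_ims(rec)) {
    per_bin <- rec |>
      dplyr::select(bin, dt, mz, intensity) |>
      dplyr::arrange(bin, mz)
  }
  structure(
    list(scanid = as.integer(scanid), mslevel = normalize_mslevel(mslevel),
         rt = rec$rt[1L], points = points, per_bin = per_bin),
    class = "mass_spectrum"
  )
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> scanid %d, mslevel %d, rt %.4f min, %d point(s)\n",
              x$scanid, x$mslevel, x$rt, nrow(x$points)))
  print(x$points)
  invisible(x)
}

#' Mobilogram (drift-dimension profile)
#'
#' Records at the given MS level (optionally restricted to an m/z window)
#' grouped by drift bin, intensities summed; the drift time reported per bin
#' comes from the stored records.
#'
#' @param handle A [open_sample()] handle (must carry the IMS dimension).
#' @param mslevel MS level (1 or 2).
#' @param mz_range Optional closed m/z window.
#' @return A `mobility_series` tibble with columns `bin`, `dt`, `intensity`,
#'   bins ascending.
#' @export
mobilogram <- function(handle, mslevel = 1, mz_range = NULL) {
  if (!handle$has_ims) {
    msparquet_error("msparquet_capability_error",
                    sprintf("'%s' has no ion-mobility dimension; cannot compute a mobilogram",
                            handle$path))
  }
  rec <- scan_records(handle, record_predicate(mslevel = mslevel, mz_range = mz_range))
  points <- if (nrow(rec) == 0L) {
    tibble::tibble(bin = integer(), dt = double(), intensity = double())
  } else {
    rec |>
      dplyr::group_by(bin) |>
      dplyr::summarise(dt = dt[1L], intensity = sum(intensity), .groups = "drop") |>
      dplyr::arrange(bin)
  }
  out <- tibble::as_tibble(points)
  class(out) <- c("mobility_series", class(out))
  attr(out, "mslevel") <- normalize_mslevel(mslevel)
  attr(out, "mz_window") <- mz_range
  attr(out, "row_groups_scanned") <- attr(rec, "row_groups_scanned")
  attr(out, "row_groups_total") <- attr(rec, "row_groups_total")
  out
}

#' The most intense record in scope
#'
#' Ties are broken by lowest retention time, then lowest m/z.
#'
#' @param handle A [open_sample()] handle.
#' @param mslevel Optional MS level restriction.
#' @return A one-row `spectral_table`.
#' @export
base_peak_record <- function(handle, mslevel = NULL) {
  rec <- scan_records(handle, record_predicate(mslevel = mslevel))
  if (nrow(rec) == 0L) {
    msparquet_error("msparquet_not_found", "no records in scope for base_peak_record")
  }
  rec[order(-rec$intensity, rec$rt, rec$mz)[1L], ]
}

#' Number of row groups a query actually read
#' @param x A query result (chromatogram, mobilogram or filtered table).
#' @return Integer vector `c(scanned, total)`.
#' @export
row_groups_used <- function(x) {
  c(scanned = attr(x, "row_groups_scanned") %||% NA_integer_,
    total = attr(x, "row_groups_total") %||% NA_integer_)
}
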