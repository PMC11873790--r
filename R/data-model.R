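#' @importFrom stats coef lm median residuals
#' @importFrom utils head modifyList packageVersion
NULL

# Canonical column order of the long format. bin/dt are present iff the sample
# carries an ion-mobility dimension.
SPECTRAL_COLUMNS <- c("rt", "scanid", "mslevel", "mz", "intensity", "bin", "dt")
SPECTRAL_COLUMNS_NO_IMS <- c("rt", "scanid", "mslevel", "mz", "intensity")
SCHEMA_VERSION <- "longformat-1"

msparquet_error <- function(class, message, ..., call. = FALSE) {
  stop(structure(
    class = c(class, "msparquet_error", "error", "condition"),
    list(message = message, call = NULL, ...)
  ))
}

#' Build a long-format spectral table
#'
#' The long format stores one detected point per row: retention time `rt`
#' (minutes), acquisition-cycle id `scanid`, collision-energy function
#' `mslevel` (1 = low energy, 2 = high energy), `mz` (Th), `intensity`
#' (detector counts) and, for ion-mobility samples, the drift-bin index `bin`
#' and drift time `dt` (milliseconds). Column types are normalized to the
#' in-memory canonical representation (doubles for rt/mz/dt/intensity,
#' integers for scanid/mslevel/bin).
#'
#' @param x A data frame with columns `rt, scanid, mslevel, mz, intensity` and
#'   optionally both of `bin, dt`.
#' @return A `spectral_table` (a tibble with `has_ims` and `schema_version`
#'   attributes).
#' @export
spectral_table <- function(x) {
  x <- as.data.frame(x)
  check_spectral_columns(names(x))
  has_ims <- "bin" %in% names(x)
  cols <- if (has_ims) SPECTRAL_COLUMNS else SPECTRAL_COLUMNS_NO_IMS
  x <- x[, cols, drop = FALSE]
  x$rt <- as.double(x$rt)
  x$scanid <- as.integer(x$scanid)
  x$mz <- as.double(x$mz)
  x$intensity <- as.double(x$intensity)
  if (is.factor(x$mslevel) || is.character(x$mslevel)) {
    x$mslevel <- as.integer(as.character(x$mslevel))
  } else {
    x$mslevel <- as.integer(x$mslevel)
  }
  if (has_ims) {
    x$bin <- as.integer(x$bin)
    x$dt <- as.double(x$dt)
  }
  out <- tibble::as_tibble(x)
  class(out) <- c("spectral_table", class(out))
  attr(out, "has_ims") <- has_ims
  attr(out, "schema_version") <- SCHEMA_VERSION
  out
}

check_spectral_columns <- function(nm) {
  base_ok <- identical(nm[seq_along(SPECTRAL_COLUMNS_NO_IMS)], SPECTRAL_COLUMNS_NO_IMS)
  full <- length(nm) == 7L && identical(nm, SPECTRAL_COLUMNS)
  core <- length(nm) == 5L && base_ok
  if (!(full || core)) {
    missing <- setdiff(SPECTRAL_COLUMNS_NO_IMS, nm)
    if (("bin" %in% nm) != ("dt" %in% nm)) {
      missing <- c(missing, setdiff(c("bin", "dt"), nm))
    }
    extra <- setdiff(nm, SPECTRAL_COLUMNS)
    msparquet_error(
      "msparquet_schema_error",
      sprintf(
        "malformed column set: expected %s (bin/dt jointly optional); missing: %s; extra: %s",
        paste(SPECTRAL_COLUMNS, collapse = ", "),
        if (length(missing)) paste(missing, collapse = ", ") else "none",
        if (length(extra)) paste(extra, collapse = ", ") else "none"
      ),
      missing_columns = missing, extra_columns = extra
    )
  }
  invisible(TRUE)
}

#' Does a spectral table carry the ion-mobility dimension?
#' @param table A `spectral_table`.
#' @return Logical scalar.
#' @export
has_ims <- function(table) {
  isTRUE(attr(table, "has_ims")) || "bin" %in% names(table)
}

#' A minimal worked example of the long format
#'
#' Five rows of an HDMSE acquisition (three low-energy cycles and one
#' high-energy scan) used throughout the documentation and tests: two points
#' in cycle 1 at level 1, one fragment-level point in cycle 1 at level 2, and
#' one point each in cycles 2 and 3.
#'
#' @return A `spectral_table` with 5 rows.
#' @export
example_spectral_table <- function() {
  spectral_table(data.frame(
    rt = c(0.0074, 0.0074, 0.0116, 0.0158, 0.0241),
    scanid = c(1L, 1L, 1L, 2L, 3L),
    mslevel = c(1L, 1L, 2L, 1L, 1L),
    mz = c(105.9348, 128.9497, 172.8606, 87.9227, 128.9497),
    intensity = c(57, 123, 19, 14, 96),
    bin = c(39L, 35L, 60L, 40L, 34L),
    dt = c(2.769, 2.485, 4.260, 2.840, 2.414)
  ))
}

#' Validate a long-format spectral table
#'
#' Checks every schema invariant: positive intensities, positive m/z,
#' nonnegative retention times, mslevel restricted to \{1, 2\}, joint
#' presence of bin/dt, a single retention time per (scanid, mslevel) group,
#' drift time being a function of bin, and scanids non-decreasing with
#' retention time within each MS level. Non-integral intensities are
#' tolerated but flagged as warnings.
#'
#' @param table A `spectral_table` (or coercible data frame).
#' @return A `validation_report`: list with `ok` (TRUE iff no violations),
#'   `violations` and `warnings` tibbles (`invariant`, `where`, `message`).
#' @export
validate_table <- function(table) {
  if (!inherits(table, "spectral_table")) table <- spectral_table(table)
  v <- list()
  w <- list()
  note <- function(invariant, where, message) {
    tibble::tibble(invariant = invariant, where = where, message = message)
  }

  bad <- which(!is.finite(table$intensity) | table$intensity <= 0)
  if (length(bad)) {
    v[[length(v) + 1L]] <- note(
      "intensity_positive", paste(head(bad, 5L), collapse = ","),
      sprintf("%d record(s) with non-positive or missing intensity", length(bad))
    )
  }
  nonint <- which(is.finite(table$intensity) & table$intensity != trunc(table$intensity))
  if (length(nonint)) {
    w[[length(w) + 1L]] <- note(
      "intensity_integral", paste(head(nonint, 5L), collapse = ","),
      sprintf("%d record(s) with non-integral intensity (tolerated)", length(nonint))
    )
  }
  bad <- which(!is.finite(table$mz) | table$mz <= 0)
  if (length(bad)) {
    v[[length(v) + 1L]] <- note(
      "mz_positive", paste(head(bad, 5L), collapse = ","),
      sprintf("%d record(s) with non-positive m/z", length(bad))
    )
  }
  bad <- which(!is.finite(table$rt) | table$rt < 0)
  if (length(bad)) {
    v[[length(v) + 1L]] <- note(
      "rt_nonnegative", paste(head(bad, 5L), collapse = ","),
      sprintf("%d record(s) with negative or missing rt", length(bad))
    )
  }
  bad <- which(!(table$mslevel %in% c(1L, 2L)))
  if (length(bad)) {
    v[[length(v) + 1L]] <- note(
      "mslevel_domain", paste(head(bad, 5L), collapse = ","),
      sprintf("%d record(s) with mslevel outside {1, 2}", length(bad))
    )
  }
  bad <- which(is.na(table$scanid) | table$scanid < 1L)
  if (length(bad)) {
    v[[length(v) + 1L]] <- note(
      "scanid_positive", paste(head(bad, 5L), collapse = ","),
      sprintf("%d record(s) with non-positive scanid", length(bad))
    )
  }

  if (has_ims(table)) {
    bad <- which(is.na(table$bin) | is.na(table$dt) | table$bin < 1L | table$dt <= 0)
    if (length(bad)) {
      v[[length(v) + 1L]] <- note(
        "ims_present_everywhere", paste(head(bad, 5L), collapse = ","),
        sprintf("%d record(s) with missing/invalid bin or dt in an IMS table", length(bad))
      )
    }
    # dt must be a deterministic function of bin
    ok_rows <- !is.na(table$bin) & !is.na(table$dt)
    if (any(ok_rows)) {
      per_bin <- tapply(table$dt[ok_rows], table$bin[ok_rows],
                        function(d) length(unique(d)))
      multi <- names(per_bin)[per_bin > 1L]
      if (length(multi)) {
        v[[length(v) + 1L]] <- note(
          "dt_function_of_bin", paste(head(multi, 5L), collapse = ","),
          sprintf("dt not a function of bin: bin(s) %s map to multiple drift times",
                  paste(head(multi, 5L), collapse = ", "))
        )
      }
    }
  }

  if (nrow(table)) {
    key <- paste(table$scanid, table$mslevel, sep = "/")
    per_scan <- tapply(table$rt, key, function(r) length(unique(r)))
    multi <- names(per_scan)[per_scan > 1L]
    if (length(multi)) {
      v[[length(v) + 1L]] <- note(
        "rt_function_of_scan", paste(head(multi, 5L), collapse = ","),
        sprintf("(scanid, mslevel) group(s) %s carry multiple rt values",
                paste(head(multi, 5L), collapse = ", "))
      )
    }
    for (lev in unique(table$mslevel)) {
      sub <- table[table$mslevel == lev, c("scanid", "rt")]
      u <- unique(sub)
      o <- order(u$rt, u$scanid)
      if (is.unsorted(u$scanid[o])) {
        v[[length(v) + 1L]] <- note(
          "scanid_monotone_in_rt", sprintf("mslevel %s", lev),
          sprintf("scanid not non-decreasing with rt at mslevel %s", lev)
        )
      }
    }
  }

  violations <- if (length(v)) do.call(rbind, v) else
    tibble::tibble(invariant = character(), where = character(), message = character())
  warnings <- if (length(w)) do.call(rbind, w) else
    tibble::tibble(invariant = character(), where = character(), message = character())
  structure(
    list(ok = nrow(violations) == 0L, violations = violations, warnings = warnings),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> ok: %s\n", x$ok))
  if (nrow(x$violations)) {
    cat("violations:\n")
    print(as.data.frame(x$violations))
  }
  if (nrow(x$warnings)) {
    cat("warnings:\n")
    print(as.data.frame(x$warnings))
  }
  invisible(x)
}

#' Sort a spectral table into canonical order
#'
#' Canonical order is (mslevel, scanid, bin, mz) ascending, with a missing
#' bin sorting as 0; ties keep their input order (stable radix sort). Files
#' are written in this order so that row-group statistics on mslevel, rt and
#' mz support pruning.
#'
#' @param table A `spectral_table`.
#' @return The same rows in canonical order.
#' @export
canonical_sort <- function(table) {
  if (!inherits(table, "spectral_table")) table <- spectral_table(table)
  if (nrow(table) < 2L) return(table)
  binkey <- if (has_ims(table)) table$bin else rep.int(0L, nrow(table))
  ord <- order(table$mslevel, table$scanid, binkey, table$mz, method = "radix")
  table[ord, ]
}

#' Fit a linear drift-time calibration
#'
#' Drift time is modeled as a linear function of the drift-bin index:
#' `dt = slope * bin + intercept` (milliseconds). The default constrains the
#' intercept to zero, the through-origin least-squares solution
#' `slope = sum(bin * dt) / sum(bin^2)`; `intercept = "free"` fits ordinary
#' least squares.
#'
#' @param pairs A data frame (or 2-column matrix) with columns `bin` and `dt`.
#' @param intercept `"zero"` (default) or `"free"`.
#' @return A `drift_calibration`: list with `slope` (ms/bin), `intercept`
#'   (ms), `n_points`, `max_residual` (ms).
#' @export
fit_drift_calibration <- function(pairs, intercept = c("zero", "free")) {
  intercept <- match.arg(intercept)
  pairs <- as.data.frame(pairs)
  if (!all(c("bin", "dt") %in% names(pairs)) && ncol(pairs) >= 2L) {
    names(pairs)[1:2] <- c("bin", "dt")
  }
  bin <- as.double(pairs$bin)
  dt <- as.double(pairs$dt)
  if (any(!is.finite(dt)) || any(dt <= 0)) {
    msparquet_error("msparquet_domain_error", "drift times must be positive")
  }
  if (length(unique(bin)) < 2L) {
    msparquet_error("msparquet_insufficient_data",
                    "need at least 2 distinct bin values to fit a drift calibration")
  }
  if (intercept == "zero") {
    slope <- sum(bin * dt) / sum(bin^2)
    b0 <- 0
  } else {
    fit <- lm(dt ~ bin)
    slope <- unname(coef(fit)[["bin"]])
    b0 <- unname(coef(fit)[["(Intercept)"]])
  }
  if (!is.finite(slope) || slope <= 0) {
    msparquet_error("msparquet_domain_error",
                    sprintf("fitted slope %.6g is not positive; drift times must increase with bin", slope))
  }
  resid <- dt - (slope * bin + b0)
  drift_calibration(slope = slope, intercept = b0, n_points = length(bin),
                    max_residual = max(abs(resid)))
}

#' Construct a drift calibration directly
#' @param slope Milliseconds per bin (> 0).
#' @param intercept Milliseconds (default 0).
#' @param n_points Number of (bin, dt) pairs behind the fit.
#' @param max_residual Largest absolute fit residual in ms.
#' @return A `drift_calibration` object.
#' @export
drift_calibration <- function(slope, intercept = 0, n_points = 0L, max_residual = NA_real_) {
  if (!is.finite(slope) || slope <= 0) {
    msparquet_error("msparquet_domain_error", "drift calibration slope must be positive")
  }
  structure(
    list(slope = as.double(slope), intercept = as.double(intercept),
         n_points = as.integer(n_points), max_residual = as.double(max_residual)),
    class = "drift_calibration"
  )
}

#' @export
print.drift_calibration <- function(x, ...) {
  cat(sprintf("<drift_calibration> dt = %.6g ms/bin * bin + %.6g ms (n = %d, max |resid| = %.3g ms)\n",
              x$slope, x$intercept, x$n_points, x$max_residual))
  invisible(x)
}

#' Predict drift time from a bin index
#' @param cal A `drift_calibration`.
#' @param bin Bin index (>= 1; vectorized).
#' @return Drift time(s) in milliseconds.
#' @export
apply_drift_calibration <- function(cal, bin) {
  stopifnot(inherits(cal, "drift_calibration"))
  if (any(!is.finite(bin)) || any(bin < 1)) {
    msparquet_error("msparquet_domain_error", "bin indices must be >= 1")
  }
  cal$slope * as.double(bin) + cal$intercept
}
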