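# Deterministic generator of HDMSE-like samples. Compounds elute as Gaussian
# peaks in retention time and (optionally) in the drift dimension; low-energy
# scans carry the precursor and its isotopes, high-energy scans carry the
# fragments plus an attenuated precursor that co-drifts with it. Chemical
# noise adds uniform random points. Everything is reproducible from the
# config seed, and the generator reports ground truth for recovery checks.

#' Describe one simulated compound
#'
#' @param precursor_mz Precursor m/z (Th).
#' @param rt_apex Chromatographic apex (minutes).
#' @param rt_sigma Gaussian width in rt (minutes, > 0).
#' @param dt_apex_bin Drift-peak apex in (possibly fractional) bin units;
#'   NULL for non-IMS simulations.
#' @param dt_sigma_bins Gaussian width in bins (> 0).
#' @param apex_intensity Peak-top intensity in counts (>= 1).
#' @param isotope_offsets Data frame with columns `delta_mz`, `abundance`
#'   (relative to the precursor, in (0, 1]); the monoisotopic peak itself is
#'   implicit.
#' @param fragments Data frame with columns `mz`, `abundance`; emitted only
#'   at MS level 2.
#' @param precursor_survival Fraction of the precursor surviving at high
#'   collision energy (default 0.2).
#' @return A `compound_spec`.
#' @export
compound_spec <- function(precursor_mz, rt_apex, rt_sigma, dt_apex_bin = NULL,
                          dt_sigma_bins = NULL, apex_intensity = 1000,
                          isotope_offsets = NULL, fragments = NULL,
                          precursor_survival = 0.2) {
  if (precursor_mz <= 0) msparquet_error("msparquet_config_error", "precursor_mz must be positive")
  if (rt_sigma <= 0) msparquet_error("msparquet_config_error", "rt_sigma must be positive")
  if (apex_intensity < 1) msparquet_error("msparquet_config_error", "apex_intensity must be >= 1")
  if (!is.null(dt_apex_bin) && (is.null(dt_sigma_bins) || dt_sigma_bins <= 0)) {
    msparquet_error("msparquet_config_error", "dt_sigma_bins must be positive when dt_apex_bin is set")
  }
  chk_ab <- function(df, what) {
    if (is.null(df)) return(NULL)
    df <- as.data.frame(df)
    if (any(df$abundance <= 0 | df$abundance > 1)) {
      msparquet_error("msparquet_config_error", sprintf("%s abundances must lie in (0, 1]", what))
    }
    df
  }
  structure(
    list(precursor_mz = precursor_mz, rt_apex = rt_apex, rt_sigma = rt_sigma,
         dt_apex_bin = dt_apex_bin, dt_sigma_bins = dt_sigma_bins,
         apex_intensity = apex_intensity,
         isotope_offsets = chk_ab(isotope_offsets, "isotope"),
         fragments = chk_ab(fragments, "fragment"),
         precursor_survival = precursor_survival),
    class = "compound_spec"
  )
}

#' Configure a simulated acquisition
#'
#' Defaults emulate a short UPLC-IMS run: 600 cycles of 0.005 min, a
#' high-energy scan offset of 0.002 min within each cycle, 200 drift bins
#' and a drift calibration of 0.071 ms/bin.
#'
#' @param n_cycles Number of acquisition cycles.
#' @param cycle_period Cycle duration (minutes, > 0).
#' @param level2_rt_offset Offset of the high-energy scan within a cycle
#'   (minutes, in `[0, cycle_period)`).
#' @param n_bins Number of drift bins (>= 1).
#' @param drift_slope Drift time per bin (ms/bin).
#' @param compounds List of [compound_spec()].
#' @param noise_points_per_scan Chemical-noise points added per scan group.
#' @param noise_intensity_max Maximum noise intensity (counts).
#' @param intensity_noise `"none"` (deterministic rounding of the signal
#'   model) or `"poisson"` (counts drawn from Poisson at the model mean).
#' @param mz_range m/z range of the simulated window (Th); noise is placed
#'   uniformly inside it.
#' @param ims Simulate the ion-mobility dimension (default TRUE).
#' @param seed RNG seed (mandatory; default 1).
#' @return A `simulation_config`.
#' @export
simulation_config <- function(n_cycles = 600L, cycle_period = 0.005,
                              level2_rt_offset = 0.002, n_bins = 200L,
                              drift_slope = 0.071, compounds = list(),
                              noise_points_per_scan = 0L, noise_intensity_max = 50L,
                              intensity_noise = c("none", "poisson"),
                              mz_range = c(50, 1000), ims = TRUE, seed = 1L) {
  intensity_noise <- match.arg(intensity_noise)
  if (n_cycles < 1L) msparquet_error("msparquet_config_error", "n_cycles must be >= 1")
  if (cycle_period <= 0) msparquet_error("msparquet_config_error", "cycle_period must be positive")
  if (level2_rt_offset < 0 || level2_rt_offset >= cycle_period) {
    msparquet_error("msparquet_config_error", "level2_rt_offset must lie in [0, cycle_period)")
  }
  if (n_bins < 1L) msparquet_error("msparquet_config_error", "n_bins must be >= 1")
  if (drift_slope <= 0) msparquet_error("msparquet_config_error", "drift_slope must be positive")
  if (length(compounds) && !all(vapply(compounds, inherits, logical(1L), "compound_spec"))) {
    msparquet_error("msparquet_config_error", "compounds must be a list of compound_spec objects")
  }
  structure(
    list(n_cycles = as.integer(n_cycles), cycle_period = cycle_period,
         level2_rt_offset = level2_rt_offset, n_bins = as.integer(n_bins),
         drift_slope = drift_slope, compounds = compounds,
         noise_points_per_scan = as.integer(noise_points_per_scan),
         noise_intensity_max = as.integer(noise_intensity_max),
         intensity_noise = intensity_noise, mz_range = as.double(mz_range),
         ims = isTRUE(ims), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

compound_peaks <- function(cmp, level) {
  if (level == 1L) {
    mz <- cmp$precursor_mz
    ab <- 1
    if (!is.null(cmp$isotope_offsets) && nrow(cmp$isotope_offsets)) {
      mz <- c(mz, cmp$precursor_mz + cmp$isotope_offsets$delta_mz)
      ab <- c(ab, cmp$isotope_offsets$abundance)
    }
  } else {
    mz <- numeric()
    ab <- numeric()
    if (!is.null(cmp$fragments) && nrow(cmp$fragments)) {
      mz <- cmp$fragments$mz
      ab <- cmp$fragments$abundance
    }
    if (cmp$precursor_survival > 0) {
      mz <- c(mz, cmp$precursor_mz)
      ab <- c(ab, cmp$precursor_survival)
    }
  }
  list(mz = mz, ab = ab)
}

#' Simulate one sample
#'
#' Signal model, per compound, cycle and bin:
#' `apex_intensity * exp(-(rt - rt_apex)^2 / (2 rt_sigma^2)) *
#'  exp(-(bin - dt_apex_bin)^2 / (2 dt_sigma_bins^2)) * abundance`,
#' rounded to integer counts (or Poisson-drawn at that mean) and emitted when
#' at least 1. Retention times lie on the cycle grid, rounded to 10 decimal
#' places of a minute; drift times are `drift_slope * bin` rounded to 6 decimals of a millisecond. The same config
#' and seed always produce the identical table.
#'
#' @param config A [simulation_config()].
#' @return A list with `table` (a `spectral_table` in canonical order),
#'   `ground_truth` (per-compound apexes and emitted totals, per-level record
#'   counts and intensity sums) and `metadata` (a [sample_metadata()]).
#' @export
simulate_sample <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_cyc <- config$n_cycles
  rt_grid <- list(
    `1` = round((seq_len(n_cyc) - 1L) * config$cycle_period, 10L),
    `2` = round((seq_len(n_cyc) - 1L) * config$cycle_period + config$level2_rt_offset, 10L)
  )
  bins <- seq_len(config$n_bins)
  ims <- config$ims
  chunks <- list()
  truth_rows <- list()

  for (ci in seq_along(config$compounds)) {
    cmp <- config$compounds[[ci]]
    emitted <- c(`1` = 0, `2` = 0)
    for (level in c(1L, 2L)) {
      pk <- compound_peaks(cmp, level)
      if (!length(pk$mz)) next
      rts <- rt_grid[[as.character(level)]]
      amp_rt <- cmp$apex_intensity * exp(-(rts - cmp$rt_apex)^2 / (2 * cmp$rt_sigma^2))
      amp_bin <- if (ims) {
        exp(-(bins - cmp$dt_apex_bin)^2 / (2 * cmp$dt_sigma_bins^2))
      } else {
        1
      }
      base <- outer(amp_rt, amp_bin) # cycles x bins (or x 1)
      for (p in seq_along(pk$mz)) {
        lam <- base * pk$ab[p]
        counts <- if (config$intensity_noise == "poisson") {
          matrix(stats::rpois(length(lam), lam), nrow = nrow(lam))
        } else {
          round(lam)
        }
        hit <- which(counts >= 1, arr.ind = TRUE)
        if (!nrow(hit)) next
        chunk <- data.frame(
          rt = rts[hit[, 1L]],
          scanid = hit[, 1L],
          mslevel = level,
          mz = pk$mz[p],
          intensity = counts[hit]
        )
        if (ims) {
          chunk$bin <- bins[hit[, 2L]]
          chunk$dt <- round(config$drift_slope * bins[hit[, 2L]], 6L)
        }
        chunks[[length(chunks) + 1L]] <- chunk
        emitted[as.character(level)] <- emitted[as.character(level)] + sum(counts[hit])
      }
    }
    truth_rows[[ci]] <- tibble::tibble(
      compound = ci,
      precursor_mz = cmp$precursor_mz,
      rt_apex = cmp$rt_apex,
      dt_apex_bin = if (ims) cmp$dt_apex_bin else NA_real_,
      dt_apex_ms = if (ims) config$drift_slope * cmp$dt_apex_bin else NA_real_,
      emitted_intensity_level1 = emitted[["1"]],
      emitted_intensity_level2 = emitted[["2"]]
    )
  }

  if (config$noise_points_per_scan > 0L) {
    k <- config$noise_points_per_scan
    total <- n_cyc * 2L * k
    cyc <- rep(rep(seq_len(n_cyc), each = k), times = 2L)
    lev <- rep(c(1L, 2L), each = n_cyc * k)
    noise <- data.frame(
      rt = ifelse(lev == 1L, rt_grid[["1"]][cyc], rt_grid[["2"]][cyc]),
      scanid = cyc,
      mslevel = lev,
      mz = stats::runif(total, config$mz_range[1L], config$mz_range[2L]),
      intensity = sample.int(config$noise_intensity_max, total, replace = TRUE)
    )
    if (ims) {
      nb <- sample.int(config$n_bins, total, replace = TRUE)
      noise$bin <- nb
      noise$dt <- round(config$drift_slope * nb, 6L)
    }
    chunks[[length(chunks) + 1L]] <- noise
  }

  tab <- if (length(chunks)) {
    do.call(rbind, chunks)
  } else {
    df <- data.frame(rt = double(), scanid = integer(), mslevel = integer(),
                     mz = double(), intensity = double())
    if (ims) { df$bin <- integer(); df$dt <- double() }
    df
  }
  tab <- canonical_sort(spectral_table(tab))
  rep <- validate_table(tab)
  if (!rep$ok) {
    msparquet_error("msparquet_internal_error",
                    paste("simulated table failed validation:",
                          paste(rep$violations$message, collapse = "; ")))
  }

  per_level <- tibble::tibble(
    mslevel = c(1L, 2L),
    n_records = c(sum(tab$mslevel == 1L), sum(tab$mslevel == 2L)),
    total_intensity = c(sum(tab$intensity[tab$mslevel == 1L]),
                        sum(tab$intensity[tab$mslevel == 2L]))
  )
  truth <- list(
    per_compound = if (length(truth_rows)) do.call(rbind, truth_rows) else
      tibble::tibble(compound = integer(), precursor_mz = double(), rt_apex = double(),
                     dt_apex_bin = double(), dt_apex_ms = double(),
                     emitted_intensity_level1 = double(), emitted_intensity_level2 = double()),
    per_level = per_level,
    seed = config$seed
  )
  meta <- sample_metadata(
    sample_name = sprintf("synthetic-seed%d", config$seed),
    has_ims = ims,
    drift_calibration = if (ims) drift_calibration(
      slope = config$drift_slope, n_points = config$n_bins, max_residual = 0
    ) else NULL,
    source_file = "simulation",
    extras = list(simulation_seed = as.character(config$seed))
  )
  list(table = tab, ground_truth = truth, metadata = meta)
}

b64_doubles <- function(x) {
  if (!length(x)) return("")
  # single-line base64: binary decoders expect no whitespace in <binary>
  gsub("[\r\n]", "", jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8L, endian = "little")))
}

num17 <- function(x) sprintf("%.17g", x)

mzml_spectrum_xml <- function(index, native_id, level, rt_min, dt_ms, mz, inten) {
  dtp <- if (!is.na(dt_ms)) {
    sprintf('<cvParam cvRef="MS" accession="MS:1002476" name="ion mobility drift time" value="%s" unitCvRef="UO" unitAccession="UO:0000028" unitName="millisecond"/>', num17(dt_ms))
  } else ""
  b_mz <- b64_doubles(mz)
  b_in <- b64_doubles(inten)
  sprintf(paste0(
    '<spectrum index="%d" id="%s" defaultArrayLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
    '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>',
    '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
    '<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%s" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/>%s</scan></scanList>',
    '<binaryDataArrayList count="2">',
    '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/><binary>%s</binary></binaryDataArray>',
    '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/><binary>%s</binary></binaryDataArray>',
    '</binaryDataArrayList></spectrum>'),
    index, native_id, length(mz), level, num17(rt_min), dtp,
    nchar(b_mz), b_mz, nchar(b_in), b_in)
}

#' Render a long-format table as mzML
#'
#' One mzML spectrum per (scanid, mslevel, bin) group, in acquisition order
#' (cycle, then level, then bin), with scan start times in minutes, drift
#' times annotated per scan, and 64-bit uncompressed binary arrays. With
#' `pad_zeros = TRUE`, zero-intensity points flank every real point to
#' emulate profile-mode padding; ingesting either rendering through
#' [read_mzml()] reproduces the input table.
#'
#' @param table A `spectral_table`.
#' @param metadata A [sample_metadata()] (used for the run id).
#' @param path Destination mzML path.
#' @param pad_zeros Interleave zero-intensity padding points (default FALSE).
#' @return The path, invisibly.
#' @export
write_synthetic_mzml <- function(table, metadata, path, pad_zeros = FALSE) {
  if (!inherits(table, "spectral_table")) table <- spectral_table(table)
  ims <- has_ims(table)
  if (nrow(table)) {
    binkey <- if (ims) table$bin else rep.int(0L, nrow(table))
    ord <- order(table$scanid, table$mslevel, binkey, table$mz, method = "radix")
    table <- table[ord, ]
    key <- if (ims) {
      paste(table$scanid, table$mslevel, table$bin, sep = "/")
    } else {
      paste(table$scanid, table$mslevel, sep = "/")
    }
    starts <- which(!duplicated(key))
    ends <- c(starts[-1L] - 1L, nrow(table))
  } else {
    starts <- integer()
    ends <- integer()
  }
  specs <- character(length(starts))
  for (s in seq_along(starts)) {
    sl <- table[starts[s]:ends[s], ]
    mz <- sl$mz
    inten <- sl$intensity
    if (pad_zeros && length(mz)) {
      pad_mz <- setdiff(c(mz - 0.01, mz + 0.01), mz)
      mz <- c(mz, pad_mz)
      inten <- c(inten, rep(0, length(pad_mz)))
      o <- order(mz)
      mz <- mz[o]
      inten <- inten[o]
    }
    specs[s] <- mzml_spectrum_xml(
      index = s - 1L,
      native_id = sprintf("function=%d process=0 scan=%d", sl$mslevel[1L], s),
      level = sl$mslevel[1L],
      rt_min = sl$rt[1L],
      dt_ms = if (ims) sl$dt[1L] else NA_real_,
      mz = mz, inten = inten
    )
  }
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">\n',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" version="4.1.0" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '<cv id="UO" fullName="Unit Ontology" version="09:04:2014" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>\n',
    '</cvList>\n',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/></fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="sw" version="%s"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="msparquet"/></software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="%s" defaultInstrumentConfigurationRef="IC">\n',
    '<spectrumList count="%d" defaultDataProcessingRef="dp">\n%s\n</spectrumList></run></mzML>'),
    as.character(packageVersion("msparquet")),
    metadata$sample_name, length(specs), paste(specs, collapse = "\n"))
  con <- file(path, "wb")
  writeBin(charToRaw(doc), con)
  close(con)
  invisible(path)
}

#' Check apex recovery against the ground truth
#'
#' For each simulated compound, extracts an EIC in a narrow window around the
#' precursor at MS level 1 and (for IMS samples) the matching mobilogram, and
#' reports the distance of the observed apexes from the true ones. In the
#' noise-free case errors are bounded by the sampling grid (one cycle period
#' in rt, one bin in drift).
#'
#' @param table A simulated `spectral_table`.
#' @param ground_truth The `ground_truth` component of [simulate_sample()].
#' @param config The [simulation_config()] that produced the sample.
#' @param mz_halfwidth Half-width of the extraction window (Th, default 0.005).
#' @return A tibble with one row per compound: true/estimated rt apex, rt
#'   error (absolute and in grid steps), true/estimated drift-bin apex and
#'   bin error.
#' @export
apex_recovery_check <- function(table, ground_truth, config, mz_halfwidth = 0.005) {
  tc <- ground_truth$per_compound
  rows <- lapply(seq_len(nrow(tc)), function(i) {
    mz0 <- tc$precursor_mz[i]
    sel <- table$mslevel == 1L & table$mz >= mz0 - mz_halfwidth & table$mz <= mz0 + mz_halfwidth
    sub <- table[sel, ]
    if (nrow(sub) == 0L) {
      return(tibble::tibble(compound = tc$compound[i], rt_apex_true = tc$rt_apex[i],
                            rt_apex_est = NA_real_, rt_error = NA_real_,
                            rt_error_steps = NA_real_, bin_apex_true = tc$dt_apex_bin[i],
                            bin_apex_est = NA_real_, bin_error = NA_real_))
    }
    x <- tapply(sub$intensity, sub$rt, sum)
    rt_est <- as.double(names(x)[which.max(x)])
    if (config$ims) {
      m <- tapply(sub$intensity, sub$bin, sum)
      bin_est <- as.double(names(m)[which.max(m)])
      bin_err <- abs(bin_est - tc$dt_apex_bin[i])
    } else {
      bin_est <- NA_real_
      bin_err <- NA_real_
    }
    tibble::tibble(
      compound = tc$compound[i], rt_apex_true = tc$rt_apex[i], rt_apex_est = rt_est,
      rt_error = abs(rt_est - tc$rt_apex[i]),
      rt_error_steps = abs(rt_est - tc$rt_apex[i]) / config$cycle_period,
      bin_apex_true = tc$dt_apex_bin[i], bin_apex_est = bin_est, bin_error = bin_err
    )
  })
  if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(compound = integer(), rt_apex_true = double(), rt_apex_est = double(),
                   rt_error = double(), rt_error_steps = double(), bin_apex_true = double(),
                   bin_apex_est = double(), bin_error = double())
}

#' The package's reference simulated sample
#'
#' A fixed simulation describing a short 3-minute UPLC-IMS-MSE gradient:
#' 600 cycles of 0.005 min, 200 drift bins at 0.071 ms/bin, three compounds
#' with isotopes and fragments at distinct retention/drift apexes, and 10
#' chemical-noise points per scan. Used by the worked examples and as the
#' default study condition for end-to-end checks; only the seed and the
#' intensity-noise model are open.
#'
#' @param seed RNG seed (default 1).
#' @param intensity_noise `"none"` or `"poisson"`.
#' @return A [simulation_config()].
#' @export
demo_simulation_config <- function(seed = 1L, intensity_noise = "none") {
  simulation_config(
    n_cycles = 600L, cycle_period = 0.005, level2_rt_offset = 0.002,
    n_bins = 200L, drift_slope = 0.071,
    compounds = list(
      compound_spec(301.1412, rt_apex = 0.9, rt_sigma = 0.05,
                    dt_apex_bin = 85, dt_sigma_bins = 4, apex_intensity = 8e4,
                    isotope_offsets = data.frame(delta_mz = 1.0034, abundance = 0.22),
                    fragments = data.frame(mz = c(121.0648, 135.0441),
                                           abundance = c(0.45, 0.30))),
      compound_spec(455.2903, rt_apex = 1.6, rt_sigma = 0.07,
                    dt_apex_bin = 120.4, dt_sigma_bins = 5, apex_intensity = 5e4,
                    isotope_offsets = data.frame(delta_mz = c(1.0034, 2.0067),
                                                 abundance = c(0.30, 0.06)),
                    fragments = data.frame(mz = c(119.0855, 163.1117),
                                           abundance = c(0.50, 0.25))),
      compound_spec(212.1075, rt_apex = 2.2, rt_sigma = 0.04,
                    dt_apex_bin = 60.7, dt_sigma_bins = 3.5, apex_intensity = 2e4,
                    fragments = data.frame(mz = 91.0542, abundance = 0.60))
    ),
    noise_points_per_scan = 10L, noise_intensity_max = 50L,
    intensity_noise = intensity_noise, mz_range = c(50, 500), seed = seed
  )
}
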