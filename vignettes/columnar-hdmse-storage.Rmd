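---
title: "Columnar storage and filtered access for ion-mobility MSE data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Columnar storage and filtered access for ion-mobility MSE data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The data model

msparquet stores high-resolution mass-spectrometry runs acquired in
data-independent mode (alternating low and high collision energy, optionally
with an ion-mobility separation) as one long, sparse table: one row per
detected point.

| column      | type       | meaning                                               |
|-------------|------------|-------------------------------------------------------|
| `rt`        | double     | retention time, minutes                               |
| `scanid`    | int32      | acquisition-cycle id, shared by both energy functions |
| `mslevel`   | 1 or 2     | 1 = low collision energy, 2 = high collision energy   |
| `mz`        | double     | mass-to-charge ratio, Th                              |
| `intensity` | counts     | detector counts, strictly positive                    |
| `bin`       | int32      | drift-bin index (ion-mobility samples only)           |
| `dt`        | double     | drift time, milliseconds (ion-mobility samples only)  |

The format is sparse by construction: zero-intensity profile padding is
dropped at ingest (`keep_zeros = TRUE` retains it for inspection, but such
tables intentionally fail validation and cannot be stored). `bin` and `dt`
are either present everywhere or absent entirely — a sample either has the
mobility dimension or it does not; absent dimensions are omitted columns,
not null-filled ones. Within a table, `rt` is a function of
`(scanid, mslevel)` — a whole mobility frame shares one scan time — and `dt`
is a function of `bin`. `validate_table()` checks every one of these
invariants and reports violations individually; non-integral intensities are
tolerated (some converters emit floats) but flagged as warnings.

The two energy functions of one cycle are acquired a fraction of a cycle
apart, so the level-1 and level-2 scans of one `scanid` carry *different*
retention times; the package never merges them, and chromatogram grouping
uses exact stored `rt` values with no binning.

Units are minutes for `rt` and milliseconds for `dt`, matching vendor
convention; both unit labels are recorded in the sample metadata so
alternatives remain representable.

### Canonical order

Tables are kept in `(mslevel, scanid, bin, mz)` ascending order, stable for
ties, with a missing `bin` sorting as zero. This order groups each energy
level contiguously and keeps `rt` monotone within a level, which is what
makes row-group statistics useful for pruning (below).

### Drift-time calibration

Drift time is modeled as linear in the bin index, `dt = slope * bin +
intercept`. The default fit constrains the intercept to zero — the closed
form `slope = sum(bin * dt) / sum(bin^2)` — because observed bin/drift-time
pairs from converted instrument data are consistent with a pure
proportionality (0.071 ms/bin in the worked example used throughout the
package); an ordinary least-squares mode with free intercept is available.
The fit reports its point count and maximum absolute residual so a
non-linear cell would be visible immediately.

## mzML ingestion

`read_mzml()` parses mzML 1.1 (plain or gzipped) through the ProteoWizard
backend of mzR and owns three decisions the file format leaves open:

**MS-level attribution.** Converted DIA files disagree on how the
high-energy function is marked, so the mapping is configurable
(`level_map_config()`): trust the declared `msLevel` (default, clamped to
1/2), threshold on collision energy (default 15 eV — typical low-energy MSE
transfer energies are ~4–6 eV and high-energy ramps 15–45 eV), or derive
levels from strict alternation of scan groups. An explicit per-spectrum
override map wins over any mode.

**Cycle attribution.** Consecutive spectra sharing a level and a scan start
time form one scan group (a mobility frame). The cycle counter starts at 1
and increments at every group boundary that does not move from level 1 to
level 2 within a cycle; a high-energy group following another high-energy
group emits a structure warning but still advances the cycle, so malformed
files remain ingestible.

**Bin assignment.** mzML records drift times, not bin indices. Distinct
drift times (rounded to 6 decimals — instrument quantization makes exact
comparison across cycles safe at that precision) are first tested against a
uniform grid: if every value is an integer multiple of the smallest gap
between distinct values, the multiples are taken as the true bin indices.
This recovers the original sparse indices of a zero-dropped mobility frame
(a drift peak occupying bins 34–40 keeps those indices instead of being
renumbered 1–7). Drift times that are not grid-consistent fall back to a
1-based rank transform. The limitation is inherent: a file in which no two
adjacent bins are populated would have its spacing over-estimated, and a
single-bin file can only receive bin 1.

Two further normalizations make ingestion idempotent at the bit level:
scan start times are converted to minutes and rounded to 10 decimal places
(~0.6 ns of gradient time), and drift times to 6 decimals (sub-ns), so the
unit conversions inside the parser round-trip exactly. Ingestion streams
spectra in bounded batches; peak memory is proportional to a batch plus the
output table, not to the XML size.

## Parquet storage

`write_sample()` refuses invalid tables, sorts canonically (disable with
`sort_before_write = FALSE`), and writes row groups of
`row_group_target_rows` rows (default 2^20) with column statistics enabled.
On disk, `mz`, `rt`, `dt` are 64-bit floats (lossless for the identity
checks below), `intensity` a 64-bit integer, `bin` 32-bit, and `mslevel` a
dictionary-encoded string `"1"`/`"2"` for byte-compatibility with files
whose consumers filter the level as a string; in memory the level is always
a small integer and queries accept either form. The default codec is zstd;
snappy, gzip and uncompressed are selectable for comparisons.

The sample-metadata document — identity, polarity, units, drift
calibration, provenance, free-form extras — is serialized once as canonical
JSON and stored in two mirrored places: the Parquet key-value metadata
(key `sample_metadata`) and a `<stem>-metadata.json` sidecar. The two must
stay byte-identical; `read_metadata()` prefers the embedded copy, falls back
to the sidecar, and errors if both exist but differ.

### Row-group pruning

Queries must not materialize a whole file. The R Arrow bindings do not
expose per-row-group Parquet column statistics, so the writer records its
own pruning index — per-row-group min/max of `rt`, `mz`, `scanid`, `bin`
and the set of `mslevel` values — in a second key-value entry. A query
first intersects its predicate with this index and then reads only the
candidate row groups. Because files are written in canonical order, a
level filter alone excludes the other level's groups, and narrow m/z or
rt windows exclude most of the rest. Every query result carries
`row_groups_scanned` / `row_groups_total` attributes
(`row_groups_used()`), making the contract observable rather than assumed.
Files whose index is missing (e.g. written by other software with the same
schema) are still queryable — all groups are scanned.

## Queries

All analytics are conjunctive filters followed by a group-and-reduce:

* `tic(h, level)` — sum of intensities per exact `rt`;
* `bpc(h, level)` — maximum intensity per `rt`;
* `eic(h, lo, hi, level)` — TIC restricted to the closed window
  `[lo, hi]`; `eic_window()` accepts target ± Da or ppm;
* `spectrum_at(h, scanid, level)` — one scan group, optionally with the
  per-bin breakdown instead of bin-collapsed intensities;
* `mobilogram(h, level, mz_range)` — intensities grouped by drift bin;
* `filter_records(h, record_predicate(...))` — the raw rows;
* `base_peak_record(h)` — the most intense record, ties broken by lowest
  `rt` then lowest `mz`.

Interval semantics are closed everywhere. Empty results are empty series,
not errors; the one structural error is asking for a mobilogram of a sample
that has no mobility dimension. An MS level absent from a file yields an
empty series.

## The synthetic generator

Real instrument data cannot ship with a package, so the generator produces
ground-truthed samples with the features the queries exercise. Each
compound elutes as a Gaussian in retention time and, independently, in the
drift dimension — the minimal shape with a well-defined apex; no
exponential tailing in this version. Level-1 scans carry the precursor and
its isotope satellites; level-2 scans carry the fragments plus the
precursor attenuated by `precursor_survival` (default 0.2), co-drifting
with it as fragments produced after mobility separation do. The point
intensity is the product model rounded to integer counts (emitted only when
at least 1, which guarantees the no-zero-rows invariant), or a Poisson draw
at that mean when shot noise is requested. Chemical noise adds uniformly
placed random points per scan. A single RNG stream seeded from the config
makes every sample bit-reproducible.

Defaults describe a short UPLC-IMS run: 600 cycles of 0.005 min, level-2
scans offset 0.002 min into the cycle (the observed low/high gap in vendor
data is of this magnitude), 200 bins at 0.071 ms/bin.
`demo_simulation_config()` fixes three compounds on that grid and is the
reference study condition for the end-to-end checks; problem sizes there
(~58 000 records, ~22 000 spectra when rendered as mzML, 100 randomized
small samples for the oracle-equivalence property, 20 Poisson replicates
for apex recovery) were chosen so a desk machine reproduces everything in
about a minute.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: mass-accuracy drift and lock-mass behavior,
detector saturation and dead time, realistic isotope patterns computed from
formulas, chimeric co-elution, peak tailing, and vendor-specific scan-time
jitter. Conclusions about the *storage and query machinery* transfer to real
data because they are exact-arithmetic properties; conclusions about
recovery *statistics* are only as real as Gaussians-plus-Poisson.

`apex_recovery_check()` quantifies end-to-end fidelity: in the noise-free
case the estimated apex can differ from the truth only by the sampling
grid (one cycle period in rt; one bin in drift, plus the sub-bin offset of
a fractional true apex), and that bound is asserted, not assumed.

## Numerical choices, edge cases

* Retention times are decimals on a 10-decimal grid of minutes; drift
  times on a 6-decimal grid of milliseconds. Both quantizations are far
  below instrument resolution and exist to make unit conversions
  idempotent.
* Intensities are stored as signed 64-bit integers (R has no native
  unsigned 64-bit path); sums in queries are exact because every count is
  an integer-valued double well below 2^53.
* Stable radix sorting everywhere; equal keys keep input order.
* Empty tables validate, store, reopen and query as empty — never as
  errors.
* `verify_roundtrip()` compares cell-by-cell after canonical sorting and
  names the first diverging row and column instead of returning a bare
  flag.

## Command-line surface

`inst/cli/msparquet.R` is a three-line dispatcher over `run_cli()`, which
exposes `convert`, `info`, `validate`, `simulate`, `tic`, `bpc`, `eic`,
`spectrum` and `mobilogram`. Output is comma-separated at `%.15g`
precision — enough to round-trip every value the package produces; errors go
to standard error with a nonzero exit status. The CLI adds no logic of its
own, and the tests assert its output equals the corresponding function
results byte-for-byte.

## Known limitations

* Vendor acquisition APIs and raw-file readers are out of scope; ingestion
  starts at mzML.
* Bin recovery needs grid-consistent drift times (see above); exotic
  mobility programs fall back to rank indices.
* No peak picking, centroiding, CCS calibration or alignment — the package
  ends where dedicated downstream tools begin.
* Single-sample files only; no partitioned multi-sample datasets or object
  stores.
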