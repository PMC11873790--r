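# msparquet

Columnar storage and fast filtered access for data-independent-acquisition
high-resolution mass-spectrometry data, with or without an ion-mobility
dimension.

## The problem

DIA acquisitions that alternate low and high collision energy (MSE; HDMSE
when an ion-mobility separation is added) produce large, multi-dimensional
runs. XML-based interchange formats are slow to parse and poor at random
access; vendor formats are fast but closed. msparquet converts mzML runs
into a simple long-format table stored in Apache Parquet — one row per
detected point:

```
rt  scanid  mslevel  mz  intensity  [bin  dt]
```

with `rt` the retention time (minutes), `scanid` the acquisition cycle,
`mslevel` 1/2 for the low/high-energy function, and — for mobility data —
the drift-bin index `bin` and drift time `dt` (ms), linearly related by a
fitted calibration `dt = slope · bin`. Sample metadata (identity, units,
polarity, drift calibration, provenance) travels both inside the Parquet
key-value metadata and in a mirrored JSON sidecar.

Chromatograms and spectra are then one group-by away — for a total ion
chromatogram, sum `intensity` over `rt` at a given `mslevel`:

$$\mathrm{TIC}_L(t) = \sum_{i:\; rt_i = t,\; mslevel_i = L} I_i$$

and likewise BPC (max instead of sum), EIC (TIC restricted to a closed m/z
window) and mobilograms (grouped by `bin`). Queries are evaluated lazily:
files are written in canonical `(mslevel, scanid, bin, mz)` order with a
per-row-group min/max index, and each query reads only the row groups its
predicate can touch — never the whole file.

The package also contains a deterministic synthetic HDMSE generator
(Gaussian chromatographic and mobility peaks, isotopes, fragments, Poisson
shot noise, chemical noise) with ground truth, so the entire pipeline is
testable without instrument data, plus an mzML renderer for round-trip
verification.

## Worked example

The five-row example table used throughout the documentation (two cycles'
worth of an HDMSE acquisition):

```r
library(msparquet)

tab <- example_spectral_table()
cal <- fit_drift_calibration(data.frame(bin = tab$bin, dt = tab$dt))
cal
#> <drift_calibration> dt = 0.071 ms/bin * bin + 0 ms (n = 5, max |resid| = 4.44e-16 ms)
```

Drift times in this table are exactly proportional to the bin index —
0.071 ms per bin, zero residual. Store the table and query it:

```r
meta <- sample_metadata("toy", has_ims = TRUE, drift_calibration = cal)
write_sample(tab, meta, "toy.parquet")
h <- open_sample("toy.parquet")

tic(h, mslevel = 1)
#> # A tibble: 3 × 2
#>       rt intensity
#>    <dbl>     <dbl>
#> 1 0.0074       180
#> 2 0.0158        14
#> 3 0.0241        96
```

At the first scan time two points (57 + 123) sum to 180. The base peak of
the run and the drift profile of the low-energy records:

```r
base_peak_record(h)[, c("rt", "mz", "intensity")]
#>       rt    mz intensity
#> 1 0.0074  129.       123

mobilogram(h, 1)
#> # A tibble: 4 × 3
#>     bin    dt intensity
#>   <int> <dbl>     <dbl>
#> 1    34  2.41        96
#> 2    35  2.48       123
#> 3    39  2.77        57
#> 4    40  2.84        14
```

At realistic scale, pruning is visible. The reference simulated sample
(600 cycles, 200 drift bins, three compounds, 57 998 records):

```r
sim <- simulate_sample(demo_simulation_config(seed = 1))
write_sample(sim$table, sim$metadata, "demo.parquet",
             write_options(row_group_target_rows = 4000))
h2 <- open_sample("demo.parquet")

e <- eic_window(h2, 301.1412, tol_da = 0.04, mslevel = 1)
e[e$intensity == max(e$intensity), ]
#> # A tibble: 1 × 2
#>      rt intensity
#>   <dbl>     <dbl>
#> 1   0.9    802124

row_groups_used(e)
#> scanned   total
#>       7      15
```

The extracted chromatogram peaks at 0.9 min — the compound's simulated
apex — and the query touched 7 of the file's 15 row groups.

Converting an mzML file from the shell, then pulling the high-energy TIC:

```sh
Rscript inst/cli/msparquet.R convert run.mzML run.parquet
Rscript inst/cli/msparquet.R tic run.parquet --mslevel 2
```

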