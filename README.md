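# tabreport

Portable, interactive HTML reports from tabular data — declared in YAML,
viewable in any browser, maintained by nobody.

## Who this is for

Analysts and bioinformaticians who need to hand collaborators, reviewers,
or journal readers a *rich* view of tabular results — variant tables,
per-gene statistics, survey data — without standing up a Shiny server and
without the hazards of raw spreadsheets (where a gene symbol like `SEPT2`
silently becomes a date). A `tabreport` bundle is a folder of static HTML
files: attach it to an email, drop it on any static host, or ship it as a
manuscript supplement. Nothing to install, nothing to keep running.

## What it does

From tabular inputs (CSV, TSV, JSON, Parquet) and one declarative YAML
configuration, `tabreport` generates a self-contained report with:

* **per-cell visualizations** — linear/categorical heatmaps, tick plots
  with uncertainty bands, bar plots, pill plots for delimited multi-value
  cells, ellipsis with tooltips, templated linkouts, scientific notation;
* **cross-table linking** — foreign-key jumps between corresponding rows of
  related tables, plus hierarchical per-key-value subtables;
* **scalability without a server** — browsers forbid `file://` pages from
  reading sibling files (same-origin policy), so data is embedded in script
  payloads: each table is dictionary-encoded (column names once; distinct
  strings once, in first-occurrence order; rows as index codes) and
  LZ-string-compressed into JavaScript-safe strings. Tables beyond 20000
  rows are partitioned into per-page HTML files with pre-built per-column
  search indices mapping each value to its `(page, row)` occurrences;
* **safe exports** — an XLSX workbook whose text cells are explicitly
  typed text (identifiers cannot be auto-converted), per-row share URLs
  carrying the row as a compressed query parameter, and QR codes for them;
* **spells** — reusable parameterized column templates (e.g. a boolean
  renderer, or a p-value heatmap whose color gradient follows a
  significance threshold);
* **a `suggest` step** that infers column types from the data and writes a
  ready-to-run starter configuration.

## Worked example

```r
library(tabreport)

dir <- file.path(tempdir(), "demo")
make_fixtures(dir, seed = 1)          # genes.csv, variants.tsv, config.yaml
cmd_generate(file.path(dir, "config.yaml"), file.path(dir, "report"))
#> [info] bundle written to /tmp/.../demo/report: 210 files (3.85s)
```

Open `report/index.html` in a browser: the `genes` view shows score
heatmaps, effect-size ticks with uncertainty bands, p-value significance
coloring, keyword pills, NCBI linkouts, and jump buttons into the per-gene
variant subtables; the `variants` view links back to each gene's row.

The pieces are ordinary functions on data frames:

```r
tabs <- simulate_report_tables(seed = 1)

compression_report(tabs$genes, page_sizes = 50)
#> # A tibble: 4 × 3
#>   serialization       bytes ratio
#>   <chr>               <dbl> <dbl>
#> 1 raw_csv             18578 1
#> 2 packed_json         19700 0.943
#> 3 compressed          10507 1.77
#> 4 compressed_pages_50 11908 1.56
```

The whole table compresses 1.77× relative to its CSV; compressing each
50-row page separately drops that to 1.56× — the memoized dictionary and
the LZ window both lose power on small chunks, which is why the page size
trades browser memory against storage.

```r
infer_column_type(c("3.1", "2e-3", ""))
#> <column_type> float, 2 distinct, has missing

encode_share_url(tabs$genes[1, ], base_url = "https://viewer.example/share")
#> https://viewer.example/share?row=N4Igxg9gNgrgtgOwM4gFwG0QHMCmCcgA0ISkATgcVBFgEwBmYRJlI1...
```

The share URL carries the full row, compressed into a URL-safe alphabet;
`decode_share_url()` restores it exactly, and `make_qr(url, "row.png")`
turns it into a scannable code.

A command-line launcher with the same behavior is installed at
`inst/cli/tabreport` (`generate`, `suggest`, `fixtures` subcommands).

## Configuration dialect

The YAML schema is documented in `inst/schema/report-config.schema.json`
(the single source of truth); built-in spells live in `inst/spells/`. See
the methods vignette (`vignettes/tabreport-methods.Rmd`) for the packing
dialect, the numerical conventions behind every renderer, and the design
rationale.
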