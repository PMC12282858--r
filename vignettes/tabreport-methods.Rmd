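---
title: "How tabreport builds portable interactive table reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How tabreport builds portable interactive table reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabreport)
```

## The problem and the architecture

Tabular results — variant tables, per-gene statistics, survey responses —
are usually shared as spreadsheets (limited visuals, identifier-mangling
hazards) or as server-backed dashboards (deployment and maintenance burden).
`tabreport` takes a third route: it compiles tabular files plus a
declarative YAML configuration into a folder of static HTML files that any
browser renders from disk, with no server and no installation on the
reader's side.

Browsers enforce the same-origin policy on `file://` pages, so a report
page cannot dynamically read sibling data files. The generator therefore
embeds all data as JavaScript string constants loaded through static
`<script>` tags. Three mechanisms keep this scalable:

1. **Memoized packing.** A table is stored as its column header (once), a
   dictionary of distinct text cells in first-occurrence order (scanning
   rows top-to-bottom, left-to-right), and rows of cell codes — text cells
   become 0-based dictionary indices, numbers and booleans stay themselves,
   missing cells become `null`. The dialect is fixed and documented in
   `packed_to_json()`; `unpack_table(pack_table(x))` is an exact identity.
2. **LZ-string compression.** The packed JSON is compressed with an LZW
   variant that emits literal-escape codes and grows its code width, bit-packed
   into JavaScript-safe strings: 15 bits per character for embedded
   payloads, 6 bits per character over a 65-character URL-safe alphabet for
   share links. The C++ codec in `src/` is the production path; the test
   suite carries an independently written pure-R codec and requires exact
   agreement in both directions on both alphabets.
3. **Partitioning with search indices.** Tables larger than the page-size
   threshold are split into per-page HTML files with their own payloads.
   Because pages cannot load each other's data, a pre-built per-column
   search index maps every canonical cell value to its ordered
   `(page, row offset)` occurrences; each column's index is emitted as its
   own self-contained document so opening one never loads the others.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `default_page_size` | 20000 rows | Rows per page; also the threshold above which a view switches from in-memory filtering to partitioned search. The comparison is strictly greater-than: exactly 20000 rows stay in memory. |
| `page_size` (per view) | inherits | Override for views whose column count makes pages heavier or lighter. |
| `ellipsis_limit` | unset | Character budget per cell; longer text is truncated to the first *n* characters with the full text in a tooltip. |
| categorical cutoff | 12 distinct values | Above it, nominal columns get a keyword box instead of a multi-select, and `suggest` stops proposing categorical heatmaps. |
| `share_base_url` | bundled viewer | Base URL of the share-row page. Organizations keep row payloads inside their network by pointing this at an internally hosted copy. |

The 20000-row default is the partitioning constant the system is calibrated
around; one constant governs both the threshold and the chunk size. The
cutoff of 12 matches the size at which a multi-select stops being faster
than typing.

## Type inference and missingness

Raw text cells are classified with a strict precedence: all-integer →
integer, else all-numeric → float, else all `true`/`false`
(case-insensitive) → boolean, else nominal. The **empty string is the only
missing token**. Tokens like `NA` or `NaN` stay nominal text on purpose:
silently coercing identifier-like values is precisely the failure mode
(gene symbols turning into dates) this tool exists to prevent, so nothing
is ever guessed. `{0,1}` columns infer as integer; users who want tick/cross
rendering apply the boolean spell explicitly.

## Spells

A spell is a reusable column-configuration template: a YAML file with
`identifier`, `parameters` (defaults; a null default marks a required
parameter), and a `body` whose scalars may contain `<param>` placeholders.
Resolution is plain textual substitution followed by re-validation of the
body — deliberately not a full template language. Substitution covers the
cases that matter (boolean rendering, significance-threshold heatmaps)
while keeping resolved configurations auditable by eye; conditionals and
loops in configuration files tend to hide errors rather than prevent them.
`with` values must be scalars, and that restriction is documented rather
than half-supported. Merge precedence: explicit column settings override
spell-provided settings, which override built-in defaults. Spells load from
local directories by identifier; there is no remote catalog fetching.

```{r spell, eval = FALSE}
resolve_spell("p-value", list(threshold = 0.01))
# linear heatmap over [0, 0.01]: values past the threshold clamp to white
```

## Per-cell visuals: numerical choices

* **Heatmaps.** Linear scales place their color anchors evenly over
  `[min, max]` and interpolate each RGB channel linearly between adjacent
  anchors, rounding half-up; out-of-domain values clamp to the endpoints.
  Interpolation is in plain RGB — not a perceptual space — because exact,
  platform-independent integer results make the rendering testable to the
  byte. Categorical scales are exact lookups; unmapped values fall back to
  white with a warning rather than failing a build over one stray cell.
* **Ticks and bars.** `(value − min)/(max − min)`, clamped to `[0, 1]`.
  Domains default to the observed column range, resolved at generation
  time. A tick's optional `aux_range` names two companion columns that draw
  an uncertainty band behind the tick, clamped the same way.
* **Scientific notation.** Three significant digits (`3.20e-5`); under
  `auto`, only nonzero values below 10⁻³ or at least 10⁶ convert. The
  thresholds and digit count are this package's documented constants — they
  are display choices, not statistics.
* **Histograms.** Numeric columns: 10 equal-width bins over the observed
  range, right-open except the last bin, one bin for constant columns.
  Nominal columns: counts descending, ties by first occurrence, top 15.
* **Escaping.** Every cell renders HTML-escaped, with exactly two sanctioned
  exceptions: `custom_script` sources and `custom_plot` specs are embedded
  verbatim, because arbitrary user-defined rendering is their purpose.

## Linking

Row links match a source column against a target view's key column using
one shared canonicalization (`canonical_text()`): logicals print as
`true`/`false`, integral numbers print without an exponent, missing is the
empty string. Canonical matching is what lets a CSV-derived text key equal
a Parquet-derived numeric key. A key column must be target-unique; a
duplicate aborts generation naming the value. Missing foreign keys are
always unresolved (rendered inactive), never errors — only a present but
unmatched value aborts, and only when the link is not `optional`.
Hierarchical links split a detail dataset into one child table per key
value; child view ids percent-encode the key, and a post-encoding collision
is a hard error rather than a silent merge.

Link targets are stored as `(view, page, offset)` under the target's
pagination, but which physical row is targeted is invariant to page size —
a property the suite tests directly.

## Output bundle and determinism

The bundle is `index.html`, `<view>/page_<k>.html`,
`<view>/index_<column>.html`, `data/<view>/<k>.js`, `static/` (the
hand-written, dependency-free runtime), `share/viewer.html`, and
`export/report.xlsx`. Generation is atomic (build into a temporary
directory, then move) and byte-deterministic: no timestamps, fixed file
ordering, shortest-round-trip number formatting. Determinism is load-bearing:
it makes reports diffable and the emission pipeline regression-testable.

The XLSX export writes every text cell as an explicit inline string and
every numeric cell as a number, through an in-package OOXML writer with a
deterministic zip container. `readxl` serves as the independent round-trip
oracle in the tests. Share URLs serialize a row as JSON, compress it with
the URI-safe codec, and append it as one query parameter;
`decode_share_url()` is the exact inverse. QR codes for share URLs are
generated in-package (byte mode, error-correction level L, versions 1–10,
penalty-scored mask selection); payloads beyond 271 bytes raise a capacity
error suggesting fewer shared columns. The test oracle for QR output is an
independent structural reader that re-derives the format information,
unmasks, checks all Reed-Solomon syndromes, and re-extracts the payload.

Custom plot specifications pass through verbatim to a small bundled viewer
that renders a pragmatic subset (bar, point, line with x/y field encodings)
as SVG and otherwise displays the spec; compiling a full plotting grammar
is out of scope, and the subset keeps the bundle self-contained.

## The filter contract

In-memory views filter client-side; the semantics are defined by the R
reference `apply_filters()` and mirrored by the runtime: per-column
predicates (numeric interval, discrete value set, case-insensitive
substring keyword) combine conjunctively, and missing cells fail every
active predicate. Partitioned views instead search via the per-column
indices and highlight the target row after navigation; sorting there acts
within the loaded page, and the control is labelled accordingly.

## What the synthetic generator does and does not cover

`simulate_report_tables()` produces a gene-overview table (unique symbols
including `SEPT2`, scores, effect sizes with uncertainty columns,
p-values spanning 10⁻⁹–1, booleans, a low-cardinality category with
missing cells, delimited keyword lists, free text) and a variants detail
table keyed by gene — mirroring the linked overview/detail structure of a
small genomics report, with sizes (100 genes, 400 variants) typical of a
gene-panel summary. Primary-key uniqueness holds by construction.
`simulate_mixed_table()` adds the remaining type-inference cases. What the
generator deliberately does not emulate: adversarial CSV quoting, multi-GB
inputs, temporal columns (not an inferred type), ragged JSON beyond
missing keys, and non-UTF-8 encodings. Passing tests demonstrate the
pipeline's correctness on well-formed mixed-type data, not robustness to
arbitrary real-world files.

Test and acceptance problem sizes were chosen to exercise each mechanism at
its natural scale: 45,000 rows for partition arithmetic (three pages at the
default size), 50,000 rows for index completeness and the compression-rate
trend, 5,000 rows × 200 random states for filter semantics, 1,000 seeded
tables for round-trip identities.

## Known limitations

* The embedded JavaScript runtime mirrors the tested R semantics but is
  itself exercised only by construction, not by an automated browser; the
  generator-side R implementations are the tested contract.
* The search index keys exact canonical text; numeric columns are not
  range-binned, so index search on floats is exact-match only.
* QR generation covers versions 1–10 at level L (271 bytes), which fits
  typical share URLs but not very wide rows; the error message says so.
* Spell substitution is scalar-only; structured `with` values are rejected.
* Compatibility with any other tool's payload wire format is a non-goal;
  the packed dialect is this package's own.
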