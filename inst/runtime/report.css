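:root {
  --accent: #4682b4;
  --border: #d8dde3;
  --muted: #6b7682;
}
* { box-sizing: border-box; }
body {
  font-family: "Helvetica Neue", Arial, sans-serif;
  margin: 1.5rem 2rem;
  color: #1c2530;
  background: #fbfcfd;
}
nav.views {
  display: flex;
  flex-wrap: wrap;
  gap: 0.5rem;
  border-bottom: 2px solid var(--border);
  padding-bottom: 0.5rem;
  margin-bottom: 1rem;
}
nav.views a {
  text-decoration: none;
  color: var(--accent);
  padding: 0.2rem 0.6rem;
  border-radius: 4px;
}
nav.views a.active { background: var(--accent); color: #fff; }
h1 { font-size: 1.4rem; }
.view-description { max-width: 60rem; color: #333; }
.view-description .math { font-style: italic; font-family: Georgia, serif; }
.pager { margin: 0.6rem 0; }
.pager a, .pager .current { padding: 0.1rem 0.45rem; }
.pager .current { background: var(--accent); color: #fff; border-radius: 3px; }
.index-frame { width: 100%; height: 22rem; border: 1px solid var(--border); }
table.tabreport {
  border-collapse: collapse;
  font-size: 0.86rem;
  background: #fff;
}
table.tabreport th, table.tabreport td {
  border: 1px solid var(--border);
  padding: 0.25rem 0.5rem;
  text-align: left;
  vertical-align: middle;
  max-width: 28rem;
}
table.tabreport thead th {
  background: #eef2f6;
  cursor: pointer;
  white-space: nowrap;
}
table.tabreport thead tr.extra-header th {
  background: #f7f9fb;
  font-weight: normal;
  font-style: italic;
  cursor: default;
}
table.tabreport tr.highlight td { outline: 3px solid #e6a23c; }
td.line-number { color: var(--muted); text-align: right; }
.tick-cell, .bar-cell {
  position: relative;
  min-width: 9rem;
  height: 1.1rem;
  background: #f2f5f8;
}
.tick-cell .aux {
  position: absolute;
  top: 35%;
  height: 30%;
  background: #d9534f;
  opacity: 0.65;
}
.tick-cell .tick {
  position: absolute;
  top: 0;
  width: 3px;
  height: 100%;
  background: var(--accent);
}
.bar-cell .bar { position: absolute; top: 0; left: 0; height: 100%; }
.tick-cell .value, .bar-cell .value {
  position: relative;
  z-index: 1;
  padding-left: 0.2rem;
  font-size: 0.78rem;
}
.pill {
  display: inline-block;
  background: #e4ecf4;
  border-radius: 9px;
  padding: 0 0.5rem;
  margin: 0 0.15rem 0.1rem 0;
  font-size: 0.78rem;
}
.pill .count { color: var(--muted); margin-left: 0.2rem; }
.bool-true { color: #2ca02c; font-weight: bold; }
.bool-false { color: #d62728; font-weight: bold; }
abbr.ellipsis { text-decoration: none; border-bottom: 1px dotted var(--muted); }
a.linkout { margin-left: 0.3rem; font-size: 0.78rem; }
a.share-link { font-size: 0.78rem; margin-left: 0.3rem; }
a.row-jump {
  display: inline-block;
  background: var(--accent);
  color: #fff;
  border-radius: 3px;
  padding: 0 0.4rem;
  margin-right: 0.2rem;
  text-decoration: none;
  font-size: 0.78rem;
}
a.row-jump.inactive { background: #c4ccd4; pointer-events: none; }
.filters {
  display: flex;
  flex-wrap: wrap;
  gap: 0.8rem;
  margin: 0.6rem 0;
  padding: 0.6rem;
  background: #f2f5f8;
  border: 1px solid var(--border);
  border-radius: 4px;
}
.filters .filter { font-size: 0.8rem; }
.filters .filter label { display: block; font-weight: bold; }
.filters input[type="number"] { width: 5.5rem; }
.filters select { max-width: 11rem; }
.column-toggles { float: right; font-size: 0.8rem; }
.histogram { display: flex; align-items: flex-end; gap: 1px; height: 1.6rem; }
.histogram .hbin { background: var(--accent); width: 6px; min-height: 1px; }
tr.detail-row td { background: #f7f9fb; font-size: 0.8rem; }
#index-root table { margin-top: 0.6rem; }
.meta { color: var(--muted); }
details.config-echo pre {
  background: #f2f5f8;
  padding: 0.6rem;
  overflow-x: auto;
}
.error-banner {
  background: #fdecea;
  border: 1px solid #d9534f;
  color: #a11e22;
  padding: 0.6rem 1rem;
  border-radius: 4px;
}
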