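/* Minimal grammar-of-graphics viewer for plot views and per-cell custom
 * plots. Specs are passed through verbatim by the generator; this viewer
 * renders a pragmatic subset (bar, point, line marks with x/y field
 * encodings) as inline SVG and falls back to showing the spec itself for
 * anything richer. Hand-written so bundles stay self-contained. */
(function (global) {
  "use strict";

  function esc(s) {
    return String(s).replace(/&/g, "&amp;").replace(/</g, "&lt;")
      .replace(/>/g, "&gt;").replace(/"/g, "&quot;");
  }

  function fieldValues(rows, header, field) {
    var j = header.indexOf(field);
    return rows.map(function (r) { return j >= 0 ? r[j] : null; });
  }

  function renderSpecSVG(spec, rows, header) {
    var mark = typeof spec.mark === "string" ? spec.mark :
      (spec.mark && spec.mark.type);
    var enc = spec.encoding || {};
    if (!mark || !enc.x || !enc.y ||
        ["bar", "point", "line"].indexOf(mark) < 0) {
      return null;
    }
    var xs = fieldValues(rows, header, enc.x.field);
    var ys = fieldValues(rows, header, enc.y.field).map(Number);
    var W = 640, H = 360, pad = 45;
    var yMax = Math.max.apply(null, ys.filter(isFinite).concat([0]));
    var yMin = Math.min.apply(null, ys.filter(isFinite).concat([0]));
    if (!(yMax > yMin)) { yMax = yMin + 1; }
    var numericX = xs.every(function (v) { return typeof v === "number"; });
    var xPos;
    if (numericX) {
      var xMax = Math.max.apply(null, xs), xMin = Math.min.apply(null, xs);
      if (!(xMax > xMin)) xMax = xMin + 1;
      xPos = xs.map(function (v) {
        return pad + (W - 2 * pad) * (v - xMin) / (xMax - xMin);
      });
    } else {
      xPos = xs.map(function (_, i) {
        return pad + (W - 2 * pad) * (i + 0.5) / xs.length;
      });
    }
    var yPos = ys.map(function (v) {
      return H - pad - (H - 2 * pad) * (v - yMin) / (yMax - yMin);
    });
    var parts = ["<svg xmlns=\"http://www.w3.org/2000/svg\" viewBox=\"0 0 " +
      W + " " + H + "\" class=\"plot\">"];
    parts.push("<line x1=\"" + pad + "\" y1=\"" + (H - pad) + "\" x2=\"" +
      (W - pad) + "\" y2=\"" + (H - pad) + "\" stroke=\"#888\"/>");
    parts.push("<line x1=\"" + pad + "\" y1=\"" + pad + "\" x2=\"" + pad +
      "\" y2=\"" + (H - pad) + "\" stroke=\"#888\"/>");
    var zeroY = H - pad - (H - 2 * pad) * (0 - yMin) / (yMax - yMin);
    if (mark === "bar") {
      var bw = Math.max(2, (W - 2 * pad) / xs.length - 2);
      for (var i = 0; i < xs.length; i++) {
        if (!isFinite(ys[i])) continue;
        var top = Math.min(yPos[i], zeroY);
        parts.push("<rect x=\"" + (xPos[i] - bw / 2) + "\" y=\"" + top +
          "\" width=\"" + bw + "\" height=\"" +
          Math.abs(zeroY - yPos[i]) + "\" fill=\"#4682b4\"><title>" +
          esc(xs[i]) + ": " + esc(ys[i]) + "</title></rect>");
      }
    } else if (mark === "line") {
      var pts = [];
      for (var k = 0; k < xs.length; k++) {
        if (isFinite(ys[k])) pts.push(xPos[k] + "," + yPos[k]);
      }
      parts.push("<polyline fill=\"none\" stroke=\"#4682b4\" stroke-width=\"2\" points=\"" +
        pts.join(" ") + "\"/>");
    } else {
      for (var p = 0; p < xs.length; p++) {
        if (!isFinite(ys[p])) continue;
        parts.push("<circle cx=\"" + xPos[p] + "\" cy=\"" + yPos[p] +
          "\" r=\"3.5\" fill=\"#4682b4\"><title>" + esc(xs[p]) + ": " +
          esc(ys[p]) + "</title></circle>");
      }
    }
    parts.push("<text x=\"" + (W / 2) + "\" y=\"" + (H - 8) +
      "\" text-anchor=\"middle\" font-size=\"12\">" + esc(enc.x.field) + "</text>");
    parts.push("<text x=\"12\" y=\"" + (H / 2) +
      "\" transform=\"rotate(-90 12 " + (H / 2) + ")\" text-anchor=\"middle\"" +
      " font-size=\"12\">" + esc(enc.y.field) + "</text>");
    parts.push("</svg>");
    return parts.join("");
  }

  function fallback(spec) {
    return "<p class=\"meta\">Plot specification (not renderable by the " +
      "bundled viewer subset):</p><pre>" +
      esc(JSON.stringify(spec, null, 2)) + "</pre>";
  }

  function render() {
    var root = document.getElementById("plot-root");
    var spec = global.tabreportPlotSpec;
    var payload = (global.tabreportData || {})[global.tabreportPlotView + "/1"];
    var table;
    try {
      table = global.tabreport.unpackTable(
        global.tabreport.lzDecompressUTF16(payload));
    } catch (e) {
      root.innerHTML = "<div class=\"error-banner\">Corrupt plot data.</div>";
      return;
    }
    var svg = renderSpecSVG(spec, table.rows, table.header);
    root.innerHTML = svg || fallback(spec);
  }

  function cellPlot(spec, value, row) {
    /* compact per-cell rendering: single value bar over the spec's domain */
    return "<span class=\"meta\" title=\"" + esc(JSON.stringify(spec)) +
      "\">" + esc(value === null ? "" : value) + "</span>";
  }

  global.tabreportPlotViewer = { render: render, cellPlot: cellPlot };
})(typeof window !== "undefined" ? window : this);
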