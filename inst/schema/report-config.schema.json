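{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "report-config.schema.json",
  "title": "tabreport configuration",
  "description": "Declarative description of a report: datasets, views, column renderers, links, and spells. YAML configurations must conform to this schema after YAML-to-JSON conversion; unknown keys are errors everywhere.",
  "type": "object",
  "additionalProperties": false,
  "required": ["datasets", "views"],
  "properties": {
    "report_name": { "type": "string", "default": "Report" },
    "default_page_size": { "type": "integer", "minimum": 1, "default": 20000 },
    "share_base_url": { "type": "string" },
    "datasets": {
      "type": "object",
      "minProperties": 1,
      "additionalProperties": { "$ref": "#/definitions/dataset" }
    },
    "views": {
      "type": "object",
      "minProperties": 1,
      "additionalProperties": { "$ref": "#/definitions/view" }
    }
  },
  "definitions": {
    "dataset": {
      "type": "object",
      "additionalProperties": false,
      "required": ["path"],
      "properties": {
        "path": { "type": "string", "minLength": 1 },
        "format": { "enum": ["csv", "tsv", "json", "parquet"] },
        "separator": { "type": "string", "minLength": 1, "maxLength": 1 },
        "has_header": { "type": "boolean", "default": true },
        "links": {
          "type": "object",
          "additionalProperties": { "$ref": "#/definitions/link" }
        }
      }
    },
    "link": {
      "type": "object",
      "additionalProperties": false,
      "required": ["kind", "source_column"],
      "properties": {
        "kind": { "enum": ["row_link", "subtable_link"] },
        "source_column": { "type": "string" },
        "target_view": { "type": "string" },
        "target_key_column": { "type": "string" },
        "detail_dataset": { "type": "string" },
        "optional": { "type": "boolean", "default": false }
      },
      "allOf": [
        {
          "if": { "properties": { "kind": { "const": "row_link" } } },
          "then": { "required": ["target_view", "target_key_column"],
                    "not": { "required": ["detail_dataset"] } }
        },
        {
          "if": { "properties": { "kind": { "const": "subtable_link" } } },
          "then": { "required": ["detail_dataset"],
                    "not": { "anyOf": [ { "required": ["target_view"] },
                                         { "required": ["target_key_column"] } ] } }
        }
      ]
    },
    "view": {
      "type": "object",
      "additionalProperties": false,
      "required": ["dataset"],
      "properties": {
        "dataset": { "type": "string" },
        "description": { "type": "string",
          "description": "Markdown; $...$ spans render as math." },
        "page_size": { "type": "integer" },
        "render_kind": { "enum": ["table", "plot", "html"], "default": "table" },
        "columns": {
          "type": "object",
          "additionalProperties": { "$ref": "#/definitions/column" }
        },
        "plot_spec": { "type": "object",
          "description": "Grammar-of-graphics document, passed through verbatim." },
        "html_body": { "type": "string" },
        "show_line_numbers": { "type": "boolean", "default": false },
        "extra_header_rows": { "type": "integer", "minimum": 0, "default": 0 }
      }
    },
    "column": {
      "type": ["object", "null"],
      "additionalProperties": false,
      "properties": {
        "label": { "type": "string" },
        "description": { "type": "string" },
        "display_mode": {
          "enum": ["normal", "detail", "available", "pinned", "hidden"],
          "default": "normal"
        },
        "renderer": { "$ref": "#/definitions/renderer" },
        "ellipsis_limit": { "type": "integer", "minimum": 1 },
        "linkouts": {
          "type": "array",
          "items": {
            "type": "object",
            "additionalProperties": false,
            "required": ["name", "url_template"],
            "properties": {
              "name": { "type": "string" },
              "url_template": { "type": "string",
                "description": "{value} and {column-name} placeholders." }
            }
          }
        },
        "numeric_format": { "enum": ["auto", "scientific", "plain"],
                             "default": "auto" },
        "spell": {
          "type": "object",
          "additionalProperties": false,
          "required": ["identifier"],
          "properties": {
            "identifier": { "type": "string", "pattern": "^[A-Za-z0-9_-]+$" },
            "with": {
              "type": "object",
              "additionalProperties": {
                "type": ["string", "number", "boolean"],
                "description": "Spell parameters accept scalars only."
              }
            }
          }
        }
      }
    },
    "renderer": {
      "type": "object",
      "required": ["kind"],
      "oneOf": [
        { "properties": { "kind": { "const": "plain" } },
          "additionalProperties": false },
        { "properties": {
            "kind": { "const": "tick" },
            "domain": { "$ref": "#/definitions/numeric_domain" },
            "aux_range": { "type": "array", "minItems": 2, "maxItems": 2,
                            "items": { "type": "string" } }
          },
          "additionalProperties": false },
        { "properties": {
            "kind": { "const": "bar" },
            "domain": { "$ref": "#/definitions/numeric_domain" },
            "color_scale": { "$ref": "#/definitions/scale" },
            "aux_range": { "type": "array", "minItems": 2, "maxItems": 2,
                            "items": { "type": "string" } }
          },
          "additionalProperties": false },
        { "properties": {
            "kind": { "const": "heatmap" },
            "scale": { "$ref": "#/definitions/scale" }
          },
          "required": ["scale"],
          "additionalProperties": false },
        { "properties": {
            "kind": { "const": "pills" },
            "separator": { "type": "string", "minLength": 1, "maxLength": 1,
                            "default": "," }
          },
          "additionalProperties": false },
        { "properties": {
            "kind": { "const": "custom_script" },
            "source": { "type": "string",
              "description": "JavaScript function(value, row) returning HTML; embedded verbatim." }
          },
          "required": ["source"],
          "additionalProperties": false },
        { "properties": {
            "kind": { "const": "custom_plot" },
            "spec": { "type": "object" }
          },
          "required": ["spec"],
          "additionalProperties": false }
      ]
    },
    "numeric_domain": {
      "type": "array",
      "minItems": 2,
      "maxItems": 2,
      "items": { "type": "number" },
      "description": "[min, max] with min < max; defaults to the observed column range."
    },
    "scale": {
      "type": "object",
      "additionalProperties": false,
      "required": ["kind"],
      "properties": {
        "kind": { "enum": ["linear", "categorical"] },
        "domain": {
          "oneOf": [
            { "$ref": "#/definitions/numeric_domain" },
            { "type": "array", "items": { "type": ["string", "number"] } }
          ]
        },
        "colors": {
          "oneOf": [
            { "type": "array", "minItems": 2,
              "items": { "type": "string", "pattern": "^#[0-9a-fA-F]{6}$" } },
            { "type": "object",
              "additionalProperties": { "type": "string",
                                         "pattern": "^#[0-9a-fA-F]{6}$" } }
          ]
        },
        "clamp": { "type": "boolean", "default": true }
      }
    }
  }
}
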