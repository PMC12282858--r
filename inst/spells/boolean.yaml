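identifier: boolean
parameters:
  true_value: "true"
  false_value: "false"
body:
  renderer:
    kind: custom_script
    source: |
      function(value, row) {
        var text = String(value);
        if (text === "<true_value>") {
          return "<span class='bool-true' title='" + text + "'>+</span>";
        }
        if (text === "<false_value>") {
          return "<span class='bool-false' title='" + text + "'>−</span>";
        }
        return "";
      }
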