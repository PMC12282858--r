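identifier: p-value
parameters:
  threshold: 0.05
body:
  numeric_format: scientific
  renderer:
    kind: heatmap
    scale:
      kind: linear
      domain: [0, <threshold>]
      colors: ["#a11e22", "#e9a16e", "#ffffff"]
      clamp: true
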