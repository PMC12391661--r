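# Demo pipeline configuration: a small ensemble of 1 um beads confined in
# 16 um spherical pores, analysed end to end. Output directory and seed can
# be overridden on the command line (porehull pipeline --config ... --out-dir ...).
seed: 1
out_dir: porehull_demo
simulate:
  geometry: sphere
  diameter_um: 16
  bead_um: 1
  temp_k: 300
  viscosity: 0.001
  interval_s: 5
  steps: 150
  beads: 8
sem:
  volume_budget: 300000
  min_diameter: 1
  min_area: 1
layout:
  mode: packed
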