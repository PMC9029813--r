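# Heterogeneous benchmark emulation: 10 structurally diverse classes
# targeting the 0.10-0.13 intra-class similarity band, plus decoys.
feature_dim: 1024
n_background: 1000
density: 0.05
lambda: 3
seed: 1
classes:
  - {label: d01, size: 100, target: 0.11}
  - {label: d02, size: 100, target: 0.10}
  - {label: d03, size: 100, target: 0.10}
  - {label: d04, size: 100, target: 0.13}
  - {label: d05, size: 100, target: 0.12}
  - {label: d06, size: 100, target: 0.10}
  - {label: d07, size: 100, target: 0.11}
  - {label: d08, size: 100, target: 0.11}
  - {label: d09, size: 100, target: 0.12}
  - {label: d10, size: 100, target: 0.11}
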