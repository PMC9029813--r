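# Homogeneous benchmark emulation: 10 activity classes whose mean
# intra-class pairwise Tanimoto similarity targets the 0.23-0.36 band
# typical of homogeneous MDDR activity classes, plus background decoys.
feature_dim: 1024
n_background: 1000
density: 0.05
lambda: 3
seed: 1
classes:
  - {label: h01, size: 100, target: 0.23}
  - {label: h02, size: 100, target: 0.31}
  - {label: h03, size: 100, target: 0.29}
  - {label: h04, size: 100, target: 0.36}
  - {label: h05, size: 100, target: 0.34}
  - {label: h06, size: 100, target: 0.32}
  - {label: h07, size: 100, target: 0.27}
  - {label: h08, size: 100, target: 0.26}
  - {label: h09, size: 100, target: 0.31}
  - {label: h10, size: 100, target: 0.30}
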