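# Reference three-layer hierarchy for predicting low FFR (<= 0.8).
# Local weights are the published eigenvector weights of the
# importance-degree matrices (intermediate layer and per-criterion
# variable layers).
schema_version: 1
target: predicting FFR
criteria:
  - name: clinical statistics
    weight: 0.32
    factors:
      - {name: gender, weight: 0.35}
      - {name: age, weight: 0.1}
      - {name: hr, weight: 0.093}
      - {name: sp, weight: 0.11}
      - {name: dp, weight: 0.091}
      - {name: bmi, weight: 0.256}
  - name: coronary angiography
    weight: 0.51
    factors:
      - {name: ls, weight: 0.288}
      - {name: ds, weight: 0.387}
      - {name: tcad, weight: 0.242}
      - {name: cc, weight: 0.083}
  - name: cardiac ultrasound
    weight: 0.17
    factors:
      - {name: av, weight: 0.13}
      - {name: lvef, weight: 0.59}
      - {name: lvm, weight: 0.28}
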