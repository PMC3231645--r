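{
  "description": "Printed values of the reference worked example, with flags where the printed numbers disagree with recomputation from the membership table under weighted-average composition.",
  "B_printed": [[0.23, 0.57, 0.20], [0.23, 0.53, 0.21], [0.26, 0.54, 0.20]],
  "B_recomputed": [[0.23, 0.57, 0.20], [0.23, 0.56, 0.21], [0.24, 0.56, 0.20]],
  "B_printed_discrepancy": [[false, false, false], [false, true, false], [true, true, false]],
  "V_printed": [0.2345, 0.5575, 0.202],
  "V_recomputed": [0.2345, 0.5635, 0.202],
  "V_printed_discrepancy": [false, true, false],
  "V_normalized_printed": [0.2359, 0.5609, 0.2032],
  "decided_class": "B4L"
}
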