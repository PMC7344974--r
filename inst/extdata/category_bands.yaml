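# Exposure categories: bands of the log-transformed exposure score, printed
# at 2 decimal places.  Band 1 is the single point 1.00 (the no-exposure
# convention); bands 2-4 are inclusive ranges.  The percentage column records
# each band's upper limit as a share of the maximum attainable score (14.01).
version: "1.0"
bands:
  - category: 1
    lower: 1.00
    upper: 1.00
    description: No exposure (e.g., office worker)
    percent_of_max: "-"
  - category: 2
    lower: 1.01
    upper: 4.76
    description: Low level of exposure (fully enclosed and highly controlled)
    percent_of_max: "<34%"
  - category: 3
    lower: 4.77
    upper: 9.38
    description: Medium level of exposure (partially enclosed and well controlled)
    percent_of_max: "34-67%"
  - category: 4
    lower: 9.39
    upper: 14.01
    description: High level of exposure (little enclosed and poorly controlled)
    percent_of_max: "67-100%"
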