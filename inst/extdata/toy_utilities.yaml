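# Health-state utilities (base case with low/high sensitivity bounds).
# The incurable-HCC values are the literature-pooled anchor; the other
# states are synthetic placeholders for the non-public pooled values and
# should be replaced for real analyses.
reference: 0.85
states:
  noncirrhosis: {base: 0.80, low: 0.72, high: 0.88}
  compensated_cirrhosis: {base: 0.72, low: 0.64, high: 0.80}
  decompensated_cirrhosis: {base: 0.66, low: 0.55, high: 0.75}
  post_lt_sr: {base: 0.75, low: 0.65, high: 0.85}
  incurable_hcc: {base: 0.40, low: 0.32, high: 0.48}
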