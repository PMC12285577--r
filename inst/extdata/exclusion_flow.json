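{
  "initial_n": 338645,
  "n_missing_bmi": 1079,
  "n_missing_outcome": 21,
  "n_missing_both": 9
}
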