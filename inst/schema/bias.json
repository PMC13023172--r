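{
  "title": "representation-bias diagnostic report",
  "required": ["rho", "p_value", "n_bins", "degenerate", "method", "bins"]
}
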