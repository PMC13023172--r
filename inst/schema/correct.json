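{
  "title": "per-bin z-score correction report",
  "required": ["rho_before", "p_before", "rho_after", "p_after", "n_bins",
               "zscore_mode"]
}
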