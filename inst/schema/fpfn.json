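{
  "title": "per-screen false positive / negative estimation report",
  "required": [],
  "each_required": ["elbow_threshold", "fraction", "total_fp", "total_fn",
                    "total_misclassified", "ks", "bins"]
}
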