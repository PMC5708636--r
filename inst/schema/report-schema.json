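{
  "title": "lpm pipeline report",
  "type": "object",
  "required": ["features_a", "features_b", "candidates", "inliers",
               "inlier_ratio", "ok", "seed", "scenario"],
  "properties": {
    "config_hash": {"type": "string"},
    "features_a": {"type": "integer"},
    "features_b": {"type": "integer"},
    "described_a": {"type": "integer"},
    "described_b": {"type": "integer"},
    "border_removed_a": {"type": "integer"},
    "border_removed_b": {"type": "integer"},
    "degenerate_a": {"type": "integer"},
    "degenerate_b": {"type": "integer"},
    "candidates": {"type": "integer"},
    "inliers": {"type": "integer"},
    "inlier_ratio": {"type": "number"},
    "scenario": {"type": "string"},
    "seed": {"type": "integer"},
    "ok": {"type": "boolean"}
  }
}
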