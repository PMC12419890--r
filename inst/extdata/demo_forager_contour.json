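{
  "scale_nm_per_px": 42.1667,
  "specimen_id": "demo_forager",
  "note": "synthetic wedge-plus-arc contour, true radius 2530 nm, wedge angle 93 deg"
}
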