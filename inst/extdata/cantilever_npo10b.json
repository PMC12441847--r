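{
  "model": "NPO-10.B (silicon nitride, gold-coated underside)",
  "n_prongs": 2,
  "prong_area_um2": 4800,
  "tip_area_um2": 9100,
  "total_area_um2": 18700,
  "tolerance_um2": 500,
  "min_width_um": 44
}
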