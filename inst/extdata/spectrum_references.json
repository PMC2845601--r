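{
  "comment": "Published EMS substitution-spectrum percentages from reverse TILLING screens of other species, for side-by-side comparison columns.",
  "classes": ["GC/AT", "GC/TA", "AT/TA", "AT/GC", "AT/CG", "GC/CG"],
  "columns": {
    "barley": [70.0, 10.0, 10.0, 10.0, 0.0, 0.0],
    "rice":   [70.0,  4.0, 15.0, 11.0, 0.0, 0.0]
  }
}
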