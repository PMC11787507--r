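[
  {"id": "2-1CH3-I",   "heme": "I",   "delta_red": 3.2, "delta_ox_prot": 16.5, "delta_ox_deprot": 16.9},
  {"id": "12-1CH3-III","heme": "III", "delta_red": 3.0, "delta_ox_prot": 22.1, "delta_ox_deprot": 22.6},
  {"id": "18-1CH3-IV", "heme": "IV",  "delta_red": 3.4, "delta_ox_prot": 13.8, "delta_ox_deprot": 14.3}
]
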