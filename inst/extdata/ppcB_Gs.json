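{
  "protein": "PpcB_Gs",
  "temperature_K": 288.15,
  "g_ox": {"I": -150, "III": -166, "IV": -125},
  "i_redox": {"I-III": 17, "I-IV": 8, "III-IV": 32},
  "g_H": 426,
  "i_bohr": {"I": -16, "III": -9, "IV": -38}
}
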