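{
  "protein": "PpcA_Gs",
  "temperature_K": 288.15,
  "g_ox": {"I": -154, "III": -138, "IV": -125},
  "i_redox": {"I-III": 27, "I-IV": 16, "III-IV": 41},
  "g_H": 495,
  "i_bohr": {"I": -32, "III": -31, "IV": -58}
}
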