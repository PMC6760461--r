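{
  "fronto_limbic": ["SPFC", "OFC", "APFC", "LPFC", "ACC", "INS", "PHG"],
  "occipito_parietal": ["SPL", "IPC", "PVC", "FUS", "PCC", "SMA"]
}
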