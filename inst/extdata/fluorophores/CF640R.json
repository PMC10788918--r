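{
  "name": "CF640R",
  "scheme": "triplet",
  "parameters": {
    "sigma_S": 4e-16,
    "k_isc": 7e5,
    "k_T": 5e5,
    "k10": 1e9
  }
}
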