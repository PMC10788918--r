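{
  "name": "Cy5_free",
  "scheme": "isomerization",
  "parameters": {
    "sigma_N": 6.2e-16,
    "k_iso": 2.9e7,
    "sigma_biso": 1.5e-17,
    "k10": 1e9,
    "k_biso_th": 1600,
    "k_isc": 1.1e6,
    "k_T": 5e5
  }
}
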