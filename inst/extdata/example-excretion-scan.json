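{
  "scenario": "scan:excretion",
  "duration": 300,
  "affinity_ratio": 1000,
  "RA_values": [0, 0.05, 0.15, 0.5, 2, 8, 32, 128]
}
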