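[
  {"compound": "glucose", "mz": [180.0634, 203.0526], "description": "hexose; [M+NH4]+ and [M+Na]+", "expected_rt": 4.2},
  {"compound": "citrate", "mz": 191.0197, "expected_rt": 6.8}
]
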