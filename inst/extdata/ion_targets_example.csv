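compound,mz,description,expected_rt
glucose,180.0634,[M+NH4]+ hexose,4.2
citrate,191.0197,[M-H]-,6.8
caffeine,195.0877,[M+H]+,5.1
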