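caffeine,5.1,xanthine alkaloid
theobromine,4.4
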